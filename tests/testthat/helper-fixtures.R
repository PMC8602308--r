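# Shared in-code fixtures for the test suite. Everything is built
# programmatically; no data files.

# Diatomic with a single typed bond; optional charges, no other terms.
make_diatomic <- function(r = 1.5, kb = 2000, r0 = 1.5, q = c(0, 0),
                          eps = 1e-12, rstar = 3.4) {
  s <- ts_structure(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, r)),
                    rbind(c(1, 2)), types = c("X", "Y"), charges = q)
  ff <- ts_forcefield(
    stretch = list("X|Y" = list(kb = kb, r0 = r0)),
    vdw = list(X = list(eps = eps, rstar = rstar),
               Y = list(eps = eps, rstar = rstar)))
  list(s = s, ff = ff)
}

# Two nonbonded atoms (no bond at all) for pair-term checks.
make_pair <- function(r, eps = 0.3, rstar = 3.4, q = c(0, 0)) {
  s <- ts_structure(c("Ar", "Ar"), rbind(c(0, 0, 0), c(0, 0, r)),
                    matrix(integer(0), ncol = 2), types = c("X", "X"),
                    charges = q)
  ff <- ts_forcefield(vdw = list(X = list(eps = eps, rstar = rstar)))
  list(s = s, ff = ff)
}

# Finite-difference gradient of the energy (independent oracle).
fd_gradient <- function(s, ff, h = 1e-5) {
  g <- matrix(0, n_atoms(s), 3)
  for (a in seq_len(n_atoms(s))) {
    for (c3 in 1:3) {
      cp <- s; cp$coords[a, c3] <- cp$coords[a, c3] + h
      cm <- s; cm$coords[a, c3] <- cm$coords[a, c3] - h
      g[a, c3] <- (energy(cp, ff) - energy(cm, ff)) / (2 * h)
    }
  }
  g
}

# Fully numeric energy-based Hessian (slow oracle).
fd_hessian_energy <- function(s, ff, h = 1e-4) {
  n <- n_atoms(s)
  x0 <- as.numeric(t(s$coords))
  f <- function(x) {
    s$coords <- matrix(x, ncol = 3, byrow = TRUE)
    energy(s, ff)
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(3 * n)) for (q in seq_len(p)) {
    xpp <- x0; xpp[p] <- xpp[p] + h; xpp[q] <- xpp[q] + h
    xpm <- x0; xpm[p] <- xpm[p] + h; xpm[q] <- xpm[q] - h
    xmp <- x0; xmp[p] <- xmp[p] - h; xmp[q] <- xmp[q] + h
    xmm <- x0; xmm[p] <- xmm[p] - h; xmm[q] <- xmm[q] - h
    H[p, q] <- H[q, p] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h * h)
  }
  H
}

# Construct two vectors whose sample Pearson correlation is exactly rho.
vectors_with_correlation <- function(n, rho, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  z <- stats::residuals(stats::lm(z ~ x))
  z <- z / stats::sd(z)
  y <- rho * x + sqrt(1 - rho^2) * z
  list(x = x, y = y)
}
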