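# MM3*-like molecular-mechanics energy model.
#
#   E = sum 1/2 kb (r - r0)^2
#     + sum 1/2 ka (theta - theta0)^2                      [degrees]
#     + sum 1/2 [v1(1+cos phi) + v2(1-cos 2phi) + v3(1+cos 3phi)]
#     + sum_pairs eps [1.84e5 exp(-12 r/r*) - 2.25 (r*/r)^6]
#     + sum_pairs 1389.35 qi qj / (eps_d r)
#
# Nonbonded pairs are those separated by >= 3 bonds (1-2 and 1-3 excluded,
# 1-4 counted in full) plus atoms in different fragments. Below the inner
# turnover of the exp-6 curve a quadratic wall continues the potential so
# that minimization cannot collapse through the spurious short-range hole.

COULOMB_KJ <- 1389.35       # kJ mol^-1 A e^-2
EXP6_A <- 1.84e5
EXP6_B <- 12
EXP6_C <- 2.25
EXP6_WALL_K <- 1e6          # reduced stiffness of the inner quadratic wall

.tsforge_cache <- new.env(parent = emptyenv())

# Universal reduced turnover x_c where d/dx [A e^(-Bx) - C x^-6] = 0 on the
# repulsive inner branch (x = r/r*); a constant of the functional form.
exp6_turnover <- function() {
  if (is.null(.tsforge_cache$xc)) {
    dfdx <- function(x) -EXP6_A * EXP6_B * exp(-EXP6_B * x) + 6 * EXP6_C * x^-7
    .tsforge_cache$xc <- stats::uniroot(dfdx, c(0.05, 0.6), tol = 1e-12)$root
  }
  .tsforge_cache$xc
}

# Reduced exp-6 energy and d/dx, with quadratic continuation below x_c.
exp6_reduced <- function(x) {
  xc <- exp6_turnover()
  e <- numeric(length(x)); de <- numeric(length(x))
  lo <- x < xc
  if (any(!lo)) {
    xi <- x[!lo]
    ex <- EXP6_A * exp(-EXP6_B * xi)
    e[!lo] <- ex - EXP6_C * xi^-6
    de[!lo] <- -EXP6_B * ex + 6 * EXP6_C * xi^-7
  }
  if (any(lo)) {
    exc <- EXP6_A * exp(-EXP6_B * xc) - EXP6_C * xc^-6
    d <- xc - x[lo]
    e[lo] <- exc + 0.5 * EXP6_WALL_K * d * d
    de[lo] <- -EXP6_WALL_K * d
  }
  list(e = e, de = de)
}

#' Compile a structure against a force field
#'
#' Resolves every bonded term and nonbonded pair to numeric parameter arrays
#' once, so that repeated energy/gradient evaluations (minimization, Monte
#' Carlo search, Hessians) avoid string lookups. Raises a missing-parameter
#' error naming the offending type tuple.
#'
#' @param s a [ts_structure()].
#' @param ff a [ts_forcefield()].
#' @return an opaque compiled-system list used by [energy()], [gradient()],
#'   [hessian()] and [minimize()].
#' @export
compile_system <- function(s, ff) {
  topo <- internal_topology(s)
  ty <- s$types

  nb <- nrow(topo$bonds)
  kb <- r0 <- numeric(nb)
  for (r in seq_len(nb)) {
    key <- canon_stretch_key(ty[topo$bonds[r, 1]], ty[topo$bonds[r, 2]])
    p <- lookup_term(ff$stretch, key, "stretch")
    kb[r] <- p$kb; r0[r] <- p$r0
  }

  na <- nrow(topo$angles)
  ka <- th0 <- numeric(na)
  for (r in seq_len(na)) {
    key <- canon_bend_key(ty[topo$angles[r, 1]], ty[topo$angles[r, 2]],
                          ty[topo$angles[r, 3]])
    p <- lookup_term(ff$bend, key, "bend")
    ka[r] <- p$ka; th0[r] <- p$theta0
  }

  nt <- nrow(topo$torsions)
  v1 <- v2 <- v3 <- numeric(nt)
  for (r in seq_len(nt)) {
    key <- canon_torsion_key(ty[topo$torsions[r, 1]], ty[topo$torsions[r, 2]],
                             ty[topo$torsions[r, 3]], ty[topo$torsions[r, 4]])
    p <- lookup_term(ff$torsion, key, "torsion")
    v1[r] <- p$v1; v2[r] <- p$v2; v3[r] <- p$v3
  }

  # per-atom vdW (strict) and charges (per-type override, else per-atom)
  n <- n_atoms(s)
  eps_i <- rs_i <- q_i <- numeric(n)
  for (a in seq_len(n)) {
    p <- lookup_term(ff$vdw, ty[a], "vdw")
    eps_i[a] <- p$eps; rs_i[a] <- p$rstar
    q_i[a] <- if (!is.null(ff$charge[[ty[a]]])) as.numeric(ff$charge[[ty[a]]])
              else s$charges[a]
  }

  gd <- graph_distances(s)
  pr <- which(upper.tri(gd) & (gd >= 3 | !is.finite(gd)), arr.ind = TRUE)
  pairs <- matrix(as.integer(pr), ncol = 2)
  peps <- sqrt(eps_i[pairs[, 1]] * eps_i[pairs[, 2]])
  prs <- (rs_i[pairs[, 1]] + rs_i[pairs[, 2]]) / 2
  pqq <- COULOMB_KJ * q_i[pairs[, 1]] * q_i[pairs[, 2]] / ff$dielectric

  list(n = n, topo = topo,
       kb = kb, r0 = r0, ka = ka, th0 = th0, v1 = v1, v2 = v2, v3 = v3,
       pairs = pairs, peps = peps, prs = prs, pqq = pqq,
       charges = q_i)
}

energy_compiled <- function(sys, coords) {
  e <- 0
  topo <- sys$topo
  if (nrow(topo$bonds)) {
    dr <- bond_values(coords, topo$bonds) - sys$r0
    e <- e + sum(0.5 * sys$kb * dr * dr)
  }
  if (nrow(topo$angles)) {
    dth <- angle_values(coords, topo$angles) - sys$th0
    e <- e + sum(0.5 * sys$ka * dth * dth)
  }
  if (nrow(topo$torsions)) {
    phi <- torsion_values(coords, topo$torsions) / RAD2DEG
    e <- e + sum(0.5 * (sys$v1 * (1 + cos(phi)) +
                        sys$v2 * (1 - cos(2 * phi)) +
                        sys$v3 * (1 + cos(3 * phi))))
  }
  if (nrow(sys$pairs)) {
    r <- bond_values(coords, sys$pairs)
    x <- r / sys$prs
    e <- e + sum(sys$peps * exp6_reduced(x)$e)
    e <- e + sum(sys$pqq / r)
  }
  e
}

gradient_compiled <- function(sys, coords) {
  g <- matrix(0, sys$n, 3)
  topo <- sys$topo
  add <- function(g, idx, contrib) {
    for (col in 1:3)
      g[, col] <- g[, col] + tabulate_sum(idx, contrib[, col], sys$n)
    g
  }
  if (nrow(topo$bonds)) {
    i <- topo$bonds[, 1]; j <- topo$bonds[, 2]
    d <- coords[j, , drop = FALSE] - coords[i, , drop = FALSE]
    r <- row_norm(d)
    f <- sys$kb * (r - sys$r0) / r    # dE/dr / r
    g <- add(g, j, d * f)
    g <- add(g, i, -d * f)
  }
  if (nrow(topo$angles)) {
    idx <- topo$angles
    th <- angle_values(coords, idx)
    dEdth <- sys$ka * (th - sys$th0)
    gr <- angle_grad(coords, idx)
    g <- add(g, idx[, 1], gr$i * dEdth)
    g <- add(g, idx[, 2], gr$j * dEdth)
    g <- add(g, idx[, 3], gr$k * dEdth)
  }
  if (nrow(topo$torsions)) {
    idx <- topo$torsions
    phi <- torsion_values(coords, idx) / RAD2DEG
    # dE/dphi in kJ/mol/rad; torsion_grad returns deg/A -> convert
    dEdphi <- 0.5 * (-sys$v1 * sin(phi) + 2 * sys$v2 * sin(2 * phi) -
                     3 * sys$v3 * sin(3 * phi))
    sc <- dEdphi / RAD2DEG
    gr <- torsion_grad(coords, idx)
    g <- add(g, idx[, 1], gr$i * sc)
    g <- add(g, idx[, 2], gr$j * sc)
    g <- add(g, idx[, 3], gr$k * sc)
    g <- add(g, idx[, 4], gr$l * sc)
  }
  if (nrow(sys$pairs)) {
    i <- sys$pairs[, 1]; j <- sys$pairs[, 2]
    d <- coords[j, , drop = FALSE] - coords[i, , drop = FALSE]
    r <- row_norm(d)
    x <- r / sys$prs
    dEdr <- sys$peps * exp6_reduced(x)$de / sys$prs - sys$pqq / (r * r)
    f <- dEdr / r
    g <- add(g, j, d * f)
    g <- add(g, i, -d * f)
  }
  g
}

# sum contributions `w` into bins `idx` of length n (duplicate-safe)
tabulate_sum <- function(idx, w, n) {
  out <- numeric(n)
  acc <- rowsum(w, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Molecular-mechanics energy
#'
#' Evaluates the MM3*-like energy (harmonic stretches and bends, three-term
#' Fourier torsions, exp-6 van der Waals and Coulomb electrostatics with a
#' constant dielectric) of a structure under a force field. Nonbonded terms
#' run over atom pairs separated by three or more bonds (1-4 interactions
#' fully counted) and over pairs in different connected fragments.
#'
#' @param s a [ts_structure()].
#' @param ff a [ts_forcefield()].
#' @param sys optional precompiled system from [compile_system()].
#' @return scalar energy in kJ/mol.
#' @export
energy <- function(s, ff, sys = NULL) {
  if (is.null(sys)) sys <- compile_system(s, ff)
  energy_compiled(sys, s$coords)
}

#' Analytic energy gradient
#' @inheritParams energy
#' @return N x 3 matrix, kJ/mol/A.
#' @export
gradient <- function(s, ff, sys = NULL) {
  if (is.null(sys)) sys <- compile_system(s, ff)
  gradient_compiled(sys, s$coords)
}

#' Cartesian Hessian by central differences of the analytic gradient
#'
#' @inheritParams energy
#' @param step finite-difference displacement in Angstrom.
#' @return symmetric 3N x 3N matrix (kJ/mol/A^2), atom-major ordering
#'   (x1, y1, z1, x2, ...), symmetrized as (H + t(H))/2.
#' @export
hessian <- function(s, ff, sys = NULL, step = 1e-4) {
  if (is.null(sys)) sys <- compile_system(s, ff)
  n <- sys$n
  h <- matrix(0, 3 * n, 3 * n)
  coords <- s$coords
  for (a in seq_len(n)) {
    for (col in 1:3) {
      cp <- coords; cp[a, col] <- cp[a, col] + step
      cm <- coords; cm[a, col] <- cm[a, col] - step
      gp <- gradient_compiled(sys, cp)
      gm <- gradient_compiled(sys, cm)
      h[, 3 * (a - 1) + col] <- as.numeric(t(gp - gm)) / (2 * step)
    }
  }
  (h + t(h)) / 2
}

#' Local energy minimization
#'
#' Quasi-Newton (BFGS) minimization of the MM energy with the analytic
#' gradient, restarted until the RMS gradient falls below `grad_tol` or the
#' iteration budget is exhausted.
#'
#' @inheritParams energy
#' @param max_steps iteration budget (default 500).
#' @param grad_tol RMS-gradient convergence threshold, kJ/mol/A
#'   (default 0.01).
#' @return the relaxed `ts_structure` with attributes `energy` (kJ/mol),
#'   `converged` (logical) and `grad_rms`.
#' @export
minimize <- function(s, ff, max_steps = 500, grad_tol = 0.01, sys = NULL) {
  if (is.null(sys)) sys <- compile_system(s, ff)
  x0 <- as.numeric(t(s$coords))
  fn <- function(x) {
    e <- energy_compiled(sys, matrix(x, ncol = 3, byrow = TRUE))
    if (!is.finite(e)) 1e30 else e
  }
  gr <- function(x) {
    g <- gradient_compiled(sys, matrix(x, ncol = 3, byrow = TRUE))
    g[!is.finite(g)] <- 0
    as.numeric(t(g))
  }
  x <- x0
  used <- 0L
  repeat {
    budget <- max_steps - used
    if (budget <= 0L) break
    opt <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = budget, reltol = 1e-14))
    x <- opt$par
    used <- used + max(1L, opt$counts[["gradient"]])
    g <- gr(x)
    if (sqrt(mean(g * g)) <= grad_tol || opt$convergence == 0) break
  }
  e <- fn(x)
  if (!is.finite(e) || e >= 1e30)
    stop("minimization diverged to a non-finite energy")
  g <- gr(x)
  grms <- sqrt(mean(g * g))
  out <- s
  out$coords <- matrix(x, ncol = 3, byrow = TRUE)
  attr(out, "energy") <- e
  attr(out, "converged") <- grms <= grad_tol
  attr(out, "grad_rms") <- grms
  out
}
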