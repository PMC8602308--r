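# Energy model, derivatives, minimization and geometric utilities.

test_that("structure invariants are enforced", {
  expect_error(ts_structure("C", rbind(c(0, 0, NA)), NULL), "finite")
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  expect_error(ts_structure(c("C", "C"), co, rbind(c(1, 1))), "self-bonds")
  expect_error(ts_structure(c("C", "C"), co, rbind(c(1, 2), c(2, 1))),
               "duplicate")
  expect_error(ts_structure(c("C", "C"), co, rbind(c(1, 2)),
                            forming_bond = c(1, 3)), "out of range|bonds")
  s <- ts_structure(c("C", "C"), co, rbind(c(2, 1)), forming_bond = c(2, 1))
  expect_equal(s$bonds, matrix(c(1L, 2L), 1))
  expect_equal(s$forming_bond, c(1L, 2L))
})

test_that("build_internals enumerates bonds, angles and torsions", {
  # two bonded atoms: a single bond entry, nothing else
  s2 <- ts_structure(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                     rbind(c(1, 2)))
  ic <- build_internals(s2)
  expect_equal(ic$bonds$value, 1.5)
  expect_equal(nrow(ic$angles), 0)
  expect_equal(nrow(ic$torsions), 0)

  # three collinear atoms at 1.0 A spacing: one angle of exactly 180
  s3 <- ts_structure(rep("C", 3),
                     rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)),
                     rbind(c(1, 2), c(2, 3)))
  ic3 <- build_internals(s3)
  expect_equal(nrow(ic3$angles), 1)
  expect_equal(ic3$angles$value, 180)

  # butane-like chain placed at a 60-degree torsion reads back 60
  th <- 112 * pi / 180
  base <- ts_structure(rep("C", 4),
                       rbind(c(1.5 - 1.5 * cos(th), 1.5 * sin(th), 0),
                             c(1.5, 0, 0), c(0, 0, 0),
                             c(-1.5 * cos(th), 1.5 * sin(th), 0)),
                       rbind(c(1, 2), c(2, 3), c(3, 4)))
  quad <- c(1L, 2L, 3L, 4L)
  s60 <- tsforge:::set_torsion(base, quad, 60)
  ic60 <- build_internals(s60)
  expect_equal(ic60$torsions$value, 60, tolerance = 1e-8)
  expect_equal(nrow(ic60$angles), 2)

  # coincident atoms make the angle undefined
  bad <- ts_structure(rep("C", 3),
                      rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1)),
                      rbind(c(1, 2), c(2, 3)))
  expect_error(build_internals(bad), "degenerate")
})

test_that("energy matches closed forms", {
  # diatomic at equilibrium: zero
  d <- make_diatomic(r = 1.5, r0 = 1.5)
  expect_equal(energy(d$s, d$ff), 0)
  # stretched by 0.1 A at kb = 2000: 1/2 * 2000 * 0.01 = 10 kJ/mol
  d <- make_diatomic(r = 1.6, r0 = 1.5, kb = 2000)
  expect_equal(energy(d$s, d$ff), 10, tolerance = 1e-10)
  # exp-6 at r = r*: eps (1.84e5 e^-12 - 2.25)
  p <- make_pair(r = 3.4, eps = 0.3, rstar = 3.4)
  expect_equal(energy(p$s, p$ff), 0.3 * (1.84e5 * exp(-12) - 2.25),
               tolerance = 1e-12)
  # Coulomb: 1389.35 q1 q2 / r, dielectric 1
  p <- make_pair(r = 2.0, eps = 1e-12, q = c(0.2, -0.3))
  expect_equal(energy(p$s, p$ff), 1389.35 * 0.2 * -0.3 / 2, tolerance = 1e-9)
})

test_that("missing parameters raise errors naming the type tuple", {
  s <- ts_structure(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5)),
                    rbind(c(1, 2)), types = c("QQ", "ZZ"))
  expect_error(energy(s, ts_forcefield()), "QQ\\|ZZ")
})

test_that("1-2 and 1-3 nonbonded pairs are excluded, 1-4 counted in full", {
  # linear 4-chain with huge charges: only the 1-4 pair contributes
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(4.5, 0, 0))
  s <- ts_structure(rep("C", 4), co, rbind(c(1, 2), c(2, 3), c(3, 4)),
                    types = rep("X", 4), charges = c(1, 1, 1, 1))
  ff <- ts_forcefield(
    stretch = list("X|X" = list(kb = 1000, r0 = 1.5)),
    bend = list("X|X|X" = list(ka = 0.03, theta0 = 180)),
    torsion = list("X|X|X|X" = list(v1 = 0, v2 = 0, v3 = 0)),
    vdw = list(X = list(eps = 1e-12, rstar = 3.4)))
  expect_equal(energy(s, ff), 1389.35 / 4.5, tolerance = 1e-9)
})

test_that("analytic gradient agrees with finite differences", {
  # diatomic stretched along z: force +/- kb * dr on the two atoms, z only
  d <- make_diatomic(r = 1.7, r0 = 1.5, kb = 2000)
  g <- gradient(d$s, d$ff)
  expect_equal(g[1, ], c(0, 0, -2000 * 0.2), tolerance = 1e-8)
  expect_equal(g[2, ], c(0, 0, 2000 * 0.2), tolerance = 1e-8)

  for (seed in c(2, 3, 11)) {
    sys <- make_toy_ts_system(n_heavy = 5, seed = seed)
    # displace off the minimum so every term is active
    s <- sys$structure
    set.seed(seed)
    s$coords <- s$coords + matrix(stats::rnorm(3 * n_atoms(s), sd = 0.05),
                                  ncol = 3)
    expect_lt(max(abs(gradient(s, sys$ff) - fd_gradient(s, sys$ff))), 1e-4)
  }
})

test_that("minimum has near-zero gradient and Hessian eigen-structure", {
  sys <- make_toy_ts_system(n_heavy = 5, seed = 3)
  g <- gradient(sys$structure, sys$ff)
  expect_lt(sqrt(mean(g * g)), 0.01)

  # diatomic harmonic bond: one eigenvalue 2 kb, five ~0
  d <- make_diatomic(r = 1.5, r0 = 1.5, kb = 2000)
  ev <- eigen(hessian(d$s, d$ff), symmetric = TRUE)$values
  expect_equal(max(ev), 2 * 2000, tolerance = 1e-4)
  expect_lt(max(abs(ev[-1])), 1e-4)
})

test_that("gradient-based Hessian matches the energy-based oracle", {
  sys <- make_toy_ts_system(n_heavy = 4, seed = 8)
  H <- hessian(sys$structure, sys$ff)
  expect_equal(max(abs(H - t(H))), 0)
  H0 <- fd_hessian_energy(sys$structure, sys$ff)
  ev <- eigen(H, symmetric = TRUE)$values
  ev0 <- eigen((H0 + t(H0)) / 2, symmetric = TRUE)$values
  expect_lt(max(abs(ev - ev0)), 1e-2)
})

test_that("energy is invariant under atom-order swaps in term definitions", {
  sys <- make_toy_ts_system(n_heavy = 5, seed = 9)
  s <- sys$structure
  e0 <- energy(s, sys$ff)
  s$bonds <- s$bonds[rev(seq_len(nrow(s$bonds))), c(2, 1)]
  s$bonds <- tsforge:::canonical_bonds(s$bonds, n_atoms(s))
  expect_equal(energy(s, sys$ff), e0, tolerance = 1e-12)
})

test_that("minimize relaxes to the known minimum and reports convergence", {
  d <- make_diatomic(r = 1.8, r0 = 1.5, kb = 2000)
  m <- minimize(d$s, d$ff, grad_tol = 1e-6)
  expect_true(attr(m, "converged"))
  expect_equal(build_internals(m)$bonds$value, 1.5, tolerance = 1e-4)
  # already-minimized input returns essentially unchanged
  m2 <- minimize(m, d$ff, grad_tol = 1e-6)
  expect_lt(max(abs(m2$coords - m$coords)), 1e-6)
})

test_that("minimize lands in the nearest torsional well", {
  sys <- make_toy_ts_system(n_heavy = 4, seed = 5)
  s <- sys$structure; ff <- sys$ff
  quad <- rotatable_torsions(s)[1, ]
  # 1-degree scan of the relaxed energy: the well containing 40 degrees
  scan <- vapply(30:90, function(phi)
    attr(minimize(tsforge:::set_torsion(s, quad, phi), ff,
                  grad_tol = 1e-4), "energy"), numeric(1))
  m <- minimize(tsforge:::set_torsion(s, quad, 40), ff, grad_tol = 1e-4)
  expect_equal(attr(m, "energy"), min(scan), tolerance = 1e-3)
})

test_that("superpose_rmsd is a proper rigid-motion metric", {
  set.seed(4)
  a <- matrix(stats::rnorm(15), 5, 3)
  expect_equal(superpose_rmsd(a, a), 0)
  rot <- tsforge:::axis_angle_rotation(c(0, 0, 1), pi / 2)
  b <- a %*% t(rot) + matrix(c(1, 2, 3), 5, 3, byrow = TRUE)
  expect_lt(superpose_rmsd(a, b), 1e-6)   # SVD route: sqrt of a ~1e-15 msd
  expect_error(superpose_rmsd(a, a[1:3, ]), "equal atom counts|equal")
  # mirror images are NOT superimposable (no reflections allowed)
  amir <- a; amir[, 1] <- -amir[, 1]
  expect_gt(superpose_rmsd(a, amir), 0.1)
})

test_that("superpose_rmsd matches a brute-force rotation-grid oracle", {
  a <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0.4, 1.1, 0.3))
  b <- rbind(c(0.1, 0.2, 0), c(1.0, 0.4, 0.5), c(0.2, 1.3, -0.2))
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  obj <- function(p) {
    r <- tsforge:::axis_angle_rotation(c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]),
                               cos(p[1])), p[3])
    sqrt(mean(rowSums((ac - bc %*% t(r))^2)))
  }
  grid <- expand.grid(t = seq(0, pi, length.out = 10),
                      p = seq(0, 2 * pi, length.out = 12),
                      g = seq(-pi, pi, length.out = 12))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  ref <- stats::optim(best, obj, control = list(reltol = 1e-14))$value
  expect_equal(superpose_rmsd(a, b), ref, tolerance = 1e-6)
})
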