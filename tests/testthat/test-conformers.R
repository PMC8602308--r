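# Monte-Carlo torsional search, deduplication, determinism.

test_that("rotatable_torsions counts single non-ring non-terminal bonds", {
  # ethane-like: two heavy atoms each with pendants -> 1 rotatable torsion
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0),
              c(-0.5, 1, 0), c(2, 1, 0))
  s <- ts_structure(rep("C", 4), co,
                    rbind(c(1, 2), c(1, 3), c(2, 4)))
  expect_equal(nrow(rotatable_torsions(s)), 1)

  # ring-only molecule: 0 torsions
  ring <- ts_structure(rep("C", 4),
                       rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1.5, 0),
                             c(0, 1.5, 0)),
                       rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  expect_equal(nrow(rotatable_torsions(ring)), 0)

  # linear 5-atom heavy chain: bonds 2-3 and 3-4 are rotatable
  chain <- ts_structure(rep("C", 5),
                        matrix(c(0:4 * 1.5, rep(0, 10)), 5, 3),
                        cbind(1:4, 2:5))
  expect_equal(nrow(rotatable_torsions(chain)), 2)

  # the forming bond is never driven
  chain_fb <- ts_structure(rep("C", 5),
                           matrix(c(0:4 * 1.5, rep(0, 10)), 5, 3),
                           cbind(1:4, 2:5), forming_bond = c(2, 3))
  expect_equal(nrow(rotatable_torsions(chain_fb)), 1)
})

test_that("dedupe keeps the lowest-energy representative per cluster", {
  sys <- make_toy_ts_system(n_heavy = 4, seed = 5)
  s <- minimize(sys$structure, sys$ff)
  opts <- search_options(n_steps = 1, seed = 1)
  mk <- function(base, de = 0) {
    attr(base, "energy") <- attr(base, "energy") + de
    base
  }
  # identical coordinates twice -> one conformer
  ens <- dedupe(list(mk(s), mk(s)), opts)
  expect_length(ens$energies, 1)
  # far-apart conformers both kept
  quad <- rotatable_torsions(sys$structure)[1, ]
  other <- minimize(tsforge:::rotate_torsion(s, quad, 120), sys$ff)
  expect_gt(superpose_rmsd(s$coords, other$coords), 0.25)
  ens2 <- dedupe(list(mk(s), other), opts)
  expect_length(ens2$energies, 2)
})

test_that("dedupe equals a brute-force reference clustering", {
  sys <- make_toy_ts_system(n_heavy = 4, seed = 7)
  s0 <- minimize(sys$structure, sys$ff)
  quad <- rotatable_torsions(sys$structure)[1, ]
  set.seed(31)
  pool <- lapply(1:15, function(k)
    minimize(tsforge:::rotate_torsion(s0, quad, stats::runif(1, -180, 180)),
             sys$ff))
  opts <- search_options(n_steps = 1, seed = 1)
  ens <- dedupe(pool, opts)
  # brute force: energy-sorted greedy O(n^2) clustering, written separately
  e <- vapply(pool, function(cf) attr(cf, "energy"), numeric(1))
  ord <- order(e)
  kept_idx <- integer(0)
  for (idx in ord) {
    if (e[idx] > e[ord[1]] + opts$window) next
    dup <- any(vapply(kept_idx, function(kk)
      abs(e[idx] - e[kk]) < opts$energy_tol &&
        superpose_rmsd(pool[[idx]]$coords, pool[[kk]]$coords) < opts$rmsd_tol,
      logical(1)))
    if (!dup) kept_idx <- c(kept_idx, idx)
  }
  expect_equal(ens$energies, sort(e[kept_idx]))
})

test_that("mc_search finds every well of an enumerable torsional system", {
  sys <- make_toy_ts_system(n_heavy = 4, seed = 5)
  s <- sys$structure; ff <- sys$ff
  ens <- mc_search(s, ff, search_options(n_steps = 120, seed = 1))
  # exhaustive 10-degree relaxed scan of the single torsion (oracle);
  # relaxation collapses each start into its well
  quad <- rotatable_torsions(s)[1, ]
  scan <- vapply(seq(0, 350, by = 10), function(phi)
    attr(minimize(tsforge:::set_torsion(s, quad, phi), ff, grad_tol = 1e-3),
         "energy"), numeric(1))
  wells <- sort(unique(round(scan, 3)))
  expect_equal(sort(unique(round(ens$energies, 3))), wells)
})

test_that("mc_search is deterministic for a fixed seed and seed-independent
           in the energies it finds on an enumerable system", {
  sys <- make_toy_ts_system(n_heavy = 4, seed = 5)
  o1 <- search_options(n_steps = 120, seed = 1)
  e1 <- mc_search(sys$structure, sys$ff, o1)
  e1b <- mc_search(sys$structure, sys$ff, o1)
  expect_identical(e1$energies, e1b$energies)
  expect_identical(lapply(e1$conformers, `[[`, "coords"),
                   lapply(e1b$conformers, `[[`, "coords"))
  e2 <- mc_search(sys$structure, sys$ff, search_options(n_steps = 120, seed = 42))
  expect_equal(sort(round(e1$energies, 4)), sort(round(e2$energies, 4)))
})

test_that("mc_search handles zero rotatable torsions and rigid motion", {
  d <- make_diatomic(r = 1.6, r0 = 1.5)
  ens <- mc_search(d$s, d$ff, search_options(n_steps = 5, seed = 1))
  expect_length(ens$energies, 1)
  expect_equal(ens$energies, 0, tolerance = 1e-6)

  # ensemble energies invariant under rigid motion of the input
  sys <- make_toy_ts_system(n_heavy = 4, seed = 5)
  set.seed(8)
  s2 <- transform_structure(sys$structure, random_rotation(), c(3, -1, 2))
  eA <- mc_search(sys$structure, sys$ff, search_options(n_steps = 80, seed = 3))
  eB <- mc_search(s2, sys$ff, search_options(n_steps = 80, seed = 3))
  expect_equal(sort(round(eA$energies, 5)), sort(round(eB$energies, 5)))
})

test_that("window and search options are validated", {
  expect_error(search_options(n_steps = 0), "n_steps")
  expect_error(search_options(window = -1), "window")
  expect_error(dedupe(list()), "empty")
})
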