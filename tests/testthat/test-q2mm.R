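# Force-field fitting against mock quantum reference data.

test_that("modify_ts_hessian replaces the single negative eigenvalue", {
  # diagonal case: eigenvalues become {omega, 50, 80}
  H <- diag(c(-100, 50, 80))
  out <- modify_ts_hessian(H, omega = 4184)
  expect_equal(sort(eigen(out, symmetric = TRUE)$values), c(50, 80, 4184))
  expect_equal(attr(out, "replaced_index"),
               which.min(eigen(H, symmetric = TRUE)$values))
  # trace bookkeeping: tr(H') = tr(H) - lambda_neg + omega
  expect_equal(sum(diag(out)), sum(diag(H)) + 100 + 4184, tolerance = 1e-6)

  # already-positive spectra pass through unchanged
  Hpos <- diag(c(5, 50, 80))
  expect_equal(unclass(modify_ts_hessian(Hpos, 4184)), Hpos,
               ignore_attr = TRUE)

  # two negative eigenvalues: not a first-order saddle
  expect_error(modify_ts_hessian(diag(c(-100, -50, 80)), 4184),
               "first-order saddle")
})

test_that("modify_ts_hessian preserves all other eigenpairs", {
  set.seed(7)
  A <- matrix(stats::rnorm(81), 9, 9); A <- (A + t(A)) / 2
  ed <- eigen(A, symmetric = TRUE)
  lam <- sort(abs(ed$values) + 2, decreasing = TRUE)
  lam[9] <- -lam[9]                     # exactly one negative
  H <- ed$vectors %*% (lam * t(ed$vectors))
  out <- modify_ts_hessian((H + t(H)) / 2, omega = 1234)
  edo <- eigen(out, symmetric = TRUE)
  expect_equal(edo$values, sort(c(1234, lam[1:8]), decreasing = TRUE),
               tolerance = 1e-8)
  # non-replaced eigenvectors are reproduced (up to sign)
  for (k in 1:8) {
    v <- ed$vectors[, k]
    overlap <- max(abs(crossprod(edo$vectors, v)))
    expect_gt(overlap, 1 - 1e-8)
  }
})

test_that("residuals vanish on a self-consistent reference set", {
  sys <- make_toy_ts_system(n_heavy = 5, seed = 3)
  ref <- mock_qm_reference(sys$structure, sys$ff, noise_sd = 0)
  expect_equal(sum(eigen(ref$hessian_ref, symmetric = TRUE)$values < -1), 1)
  cfg <- penalty_config(theta = "stretch:T1|T2:kb",
                        omega = ref$ts_mode_eigenvalue)
  r <- q2mm_residuals(sys$ff, list(ref), cfg)
  expect_lt(max(abs(r)), 1e-4)
  expect_lt(q2mm_penalty(sys$ff, list(ref), cfg), 1e-6)
})

test_that("bond residual matches hand arithmetic and weights act linearly", {
  # reference diatomic at 1.50 A; force field has r0 = 1.52, so the MM
  # minimum is off by 0.02 A; with w_bond = 100 the single bond residual is 2
  d_ref <- make_diatomic(r = 1.50, kb = 2000, r0 = 1.50)
  d_off <- make_diatomic(r = 1.50, kb = 2000, r0 = 1.52)
  H <- hessian(d_ref$s, d_ref$ff)
  ref <- reference_structure(d_ref$s, H, charges_ref = c(0, 0), is_ts = FALSE)
  cfg <- penalty_config(theta = "stretch:X|Y:kb",
                        weights = c(bond = 100, angle = 0, torsion = 0,
                                    hessian_diag = 0, hessian_offdiag = 0,
                                    charge = 0))
  r <- q2mm_residuals(d_off$ff, list(ref), cfg)
  cls <- attr(r, "class_labels")
  expect_equal(as.numeric(r[cls == "bond"]), 2.0, tolerance = 1e-3)

  # doubling the charge weight doubles exactly the charge-class entries
  sys <- make_toy_ts_system(n_heavy = 4, seed = 2)
  refq <- mock_qm_reference(sys$structure, sys$ff, noise_sd = 0.05, seed = 5)
  cfg1 <- penalty_config(theta = "charge:T1:q",
                         omega = refq$ts_mode_eigenvalue,
                         weights = c(charge = 30))
  cfg2 <- penalty_config(theta = "charge:T1:q",
                         omega = refq$ts_mode_eigenvalue,
                         weights = c(charge = 60))
  r1 <- q2mm_residuals(sys$ff, list(refq), cfg1)
  r2 <- q2mm_residuals(sys$ff, list(refq), cfg2)
  c1 <- attr(r1, "class_labels")
  expect_equal(as.numeric(r2[c1 == "charge"]),
               2 * as.numeric(r1[c1 == "charge"]))
  expect_equal(as.numeric(r2[c1 != "charge"]),
               as.numeric(r1[c1 != "charge"]))
})

test_that("penalty is the sum of squared residuals", {
  sys <- make_toy_ts_system(n_heavy = 4, seed = 4)
  ref <- mock_qm_reference(sys$structure, sys$ff, noise_sd = 0.02, seed = 9)
  cfg <- penalty_config(theta = "stretch:T1|T2:kb",
                        omega = ref$ts_mode_eigenvalue)
  r <- q2mm_residuals(sys$ff, list(ref), cfg)
  expect_equal(q2mm_penalty(sys$ff, list(ref), cfg), sum(r^2))
  expect_gte(q2mm_penalty(sys$ff, list(ref), cfg), 0)
})

test_that("fit recovers perturbed forming-bond parameters", {
  sys <- make_toy_ts_system(n_heavy = 5, seed = 3)
  ref <- mock_qm_reference(sys$structure, sys$ff, noise_sd = 0)
  keys <- c("stretch:T1|T2:kb", "stretch:T1|T2:r0")
  cfg <- penalty_config(theta = keys, omega = ref$ts_mode_eigenvalue)
  truth <- ff_get_params(sys$ff, keys)

  # starting from the truth: essentially immediate, penalty ~ 0
  fit0 <- q2mm_fit(sys$ff, list(ref), cfg)
  expect_lt(utils::tail(fit0$penalty_trace, 1), 1e-6)

  ffp <- perturb_ff(sys$ff, 0.2, seed = 21, keys = keys)
  fit <- q2mm_fit(ffp, list(ref), cfg)
  expect_true(all(diff(fit$penalty_trace) <= 0))
  got <- fit$theta
  expect_lt(abs(got[1] - truth[1]) / truth[1], 0.05)
  expect_lt(abs(got[2] - truth[2]), 0.01)
  # untouched records are bit-identical
  expect_identical(fit$ff_opt$bend, sys$ff$bend)
  expect_identical(fit$ff_opt$torsion, sys$ff$torsion)
  expect_identical(fit$ff_opt$vdw, sys$ff$vdw)
})

test_that("internal validation computes per-class squared correlations", {
  sys <- make_toy_ts_system(n_heavy = 5, seed = 6)
  ref <- mock_qm_reference(sys$structure, sys$ff, noise_sd = 0)
  cfg <- penalty_config(theta = "stretch:T1|T2:kb",
                        omega = ref$ts_mode_eigenvalue)
  r2map <- internal_validate(sys$ff, list(ref), cfg)
  for (cl in c("bond", "angle", "torsion", "hessian_diag", "charge"))
    expect_equal(r2map[[cl]], 1.0, tolerance = 1e-6)
  # off-diagonal targets are all zero: zero reference variance -> absent
  expect_true(is.na(r2map$hessian_offdiag))

  # R^2 is the squared Pearson correlation: rho = 0.9 -> 0.81, and it is
  # invariant under a constant offset
  v <- vectors_with_correlation(200, 0.9, seed = 2)
  expect_equal(stats::cor(v$x, v$y)^2, 0.81, tolerance = 1e-10)
  expect_equal(stats::cor(v$x, v$y + 5)^2, 0.81, tolerance = 1e-10)
})

test_that("fit errors early on bad input", {
  sys <- make_toy_ts_system(n_heavy = 4, seed = 1)
  ref <- mock_qm_reference(sys$structure, sys$ff)
  expect_error(q2mm_fit(sys$ff, list(ref), penalty_config()),
               "at least one parameter")
  expect_error(penalty_config(theta = "x", omega = -1), "omega")
})
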