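# Quantum-guided force-field fitting. The penalty compares, per reference
# structure: internal coordinates of the MM-relaxed geometry against the
# reference internals; the MM Hessian at the reference geometry projected
# into the eigenbasis of the (eigenvalue-modified) reference Hessian against
# that modified spectrum; and assigned charges against reference charges.
# All residual classes carry configurable unit-balancing weights.

#' Quantum-reference training structure
#'
#' @param structure a [ts_structure()] at the reference (QM-optimized)
#'   geometry, with types, charges and -- for transition states -- the
#'   forming bond set.
#' @param hessian_ref symmetric 3N x 3N Cartesian Hessian, kJ/mol/A^2,
#'   atom-major ordering. A transition state must show exactly one
#'   eigenvalue below `-eps_neg` (checked in [modify_ts_hessian()]).
#' @param charges_ref per-atom reference charges, e.
#' @param is_ts whether this member is a first-order saddle (TRUE) or a
#'   plain minimum (FALSE).
#' @param ts_mode_eigenvalue optional bookkeeping: the curvature (kJ/mol/A^2)
#'   of the reaction-coordinate mode before sign inversion; synthetic
#'   references record it so the replacement eigenvalue can be made exactly
#'   consistent with the generating force field.
#' @param weight_overrides optional named list overriding penalty-class
#'   weights for this structure.
#' @return an object of class `reference_structure`.
#' @export
reference_structure <- function(structure, hessian_ref, charges_ref,
                                is_ts = TRUE, ts_mode_eigenvalue = NULL,
                                weight_overrides = NULL) {
  n <- n_atoms(structure)
  hessian_ref <- as.matrix(hessian_ref)
  if (!isTRUE(all.equal(dim(hessian_ref), c(3L * n, 3L * n))))
    stop("hessian_ref must be 3N x 3N")
  if (max(abs(hessian_ref - t(hessian_ref))) > 1e-6)
    stop("hessian_ref must be symmetric")
  if (length(charges_ref) != n)
    stop("charges_ref must have one value per atom")
  structure(
    list(structure = structure,
         hessian_ref = (hessian_ref + t(hessian_ref)) / 2,
         charges_ref = as.numeric(charges_ref),
         internals_ref = build_internals(structure),
         is_ts = isTRUE(is_ts),
         ts_mode_eigenvalue = if (is.null(ts_mode_eigenvalue)) NULL
                              else as.numeric(ts_mode_eigenvalue),
         weight_overrides = weight_overrides),
    class = "reference_structure")
}

#' Penalty configuration for Q2MM fitting
#'
#' Class weights are unit scalers bringing the residual classes to
#' comparable magnitudes; none is prescribed by theory and all are
#' configurable.
#'
#' @param theta character vector of parameter keys to fit
#'   (see [ff_get_params()]); must be non-empty for [q2mm_fit()].
#' @param weights named numeric: `bond` (1/A), `angle` (1/deg), `torsion`
#'   (1/deg), `hessian_diag`, `hessian_offdiag` (mol A^2/kJ-ish scalers),
#'   `charge` (1/e).
#' @param omega replacement eigenvalue for the transition-state mode,
#'   kJ/mol/A^2; must be > 0. Default 4184 (a stiff, MM-minimum-enforcing
#'   choice: about 1 kcal/mol at 0.032 A displacement).
#' @param eps_neg threshold below which an eigenvalue counts as negative.
#' @param max_iter,rel_tol,jac_step Levenberg-Marquardt settings: iteration
#'   cap, relative penalty-change convergence threshold (held for 3
#'   iterations), and relative forward-difference Jacobian step.
#' @param min_steps,min_grad_tol settings of the inner geometry relaxations.
#' @return an object of class `penalty_config`.
#' @export
penalty_config <- function(theta = character(0),
                           weights = c(bond = 100, angle = 2, torsion = 1,
                                       hessian_diag = 0.03,
                                       hessian_offdiag = 0.03, charge = 30),
                           omega = 4184, eps_neg = 1,
                           max_iter = 100, rel_tol = 1e-6, jac_step = 1e-4,
                           min_steps = 500, min_grad_tol = 0.01) {
  defaults <- c(bond = 100, angle = 2, torsion = 1, hessian_diag = 0.03,
                hessian_offdiag = 0.03, charge = 30)
  w <- defaults
  w[names(weights)] <- weights
  if (any(w < 0)) stop("weights must be >= 0")
  if (omega <= 0) stop("omega must be > 0")
  structure(list(theta = theta, weights = w, omega = omega, eps_neg = eps_neg,
                 max_iter = max_iter, rel_tol = rel_tol, jac_step = jac_step,
                 min_steps = min_steps, min_grad_tol = min_grad_tol),
            class = "penalty_config")
}

#' Replace the transition-state eigenvalue of a Hessian
#'
#' Eigendecomposes a symmetric Hessian, replaces the single most-negative
#' eigenvalue (the reaction-coordinate curvature of a first-order saddle) by
#' `+omega`, and reassembles the matrix. This converts the transition state
#' into a stiff minimum along the reaction coordinate, which is what lets a
#' force field treat the TS as a regular energy minimum. Matrices whose
#' spectrum is already non-negative (beyond `-eps_neg`) are returned
#' unchanged.
#'
#' @param H symmetric matrix, kJ/mol/A^2.
#' @param omega replacement eigenvalue, > 0.
#' @param eps_neg negativity threshold (default 1 kJ/mol/A^2).
#' @return the modified matrix, with attributes `vectors` (eigenbasis V,
#'   columns in decreasing-eigenvalue order), `values` (the modified
#'   spectrum aligned with V) and `replaced_index` (the slot replaced, or
#'   NA when nothing was negative).
#' @export
modify_ts_hessian <- function(H, omega = 4184, eps_neg = 1) {
  H <- as.matrix(H)
  if (max(abs(H - t(H))) > 1e-6) stop("Hessian must be symmetric")
  if (omega <= 0) stop("omega must be > 0")
  ed <- eigen((H + t(H)) / 2, symmetric = TRUE)
  lam <- ed$values
  n_neg <- sum(lam < -eps_neg)
  if (n_neg >= 2)
    stop(sprintf("not a first-order saddle: %d eigenvalues below -%g",
                 n_neg, eps_neg))
  if (n_neg == 0) {
    out <- H
    attr(out, "vectors") <- ed$vectors
    attr(out, "values") <- lam
    attr(out, "replaced_index") <- NA_integer_
    return(out)
  }
  k <- which.min(lam)
  lam[k] <- omega
  out <- ed$vectors %*% (lam * t(ed$vectors))
  out <- (out + t(out)) / 2
  attr(out, "vectors") <- ed$vectors
  attr(out, "values") <- lam
  attr(out, "replaced_index") <- k
  out
}

# Per-structure observables under a force field: relaxed internals,
# projected Hessian, assigned charges. Targets come from the reference.
reference_observables <- function(ff, ref, cfg) {
  s <- ref$structure
  sys <- compile_system(s, ff)
  relaxed <- minimize(s, ff, max_steps = cfg$min_steps,
                      grad_tol = cfg$min_grad_tol, sys = sys)
  ints_mm <- internals_at(internal_topology(s), relaxed$coords)

  Hmod <- modify_ts_hessian(ref$hessian_ref,
                            omega = if (ref$is_ts) cfg$omega else 1,
                            eps_neg = cfg$eps_neg)
  V <- attr(Hmod, "vectors")
  lam_target <- attr(Hmod, "values")
  Hmm <- hessian(s, ff, sys = sys)
  P <- crossprod(V, Hmm %*% V)

  qmm <- sys$charges
  list(ints_mm = ints_mm, P = P, lam_target = lam_target, qmm = qmm)
}

ref_weights <- function(cfg, ref) {
  w <- cfg$weights
  ov <- ref$weight_overrides
  if (!is.null(ov)) w[names(ov)] <- unlist(ov)
  w
}

#' Q2MM residual vector
#'
#' Concatenated, class-weighted differences between force-field observables
#' and reference observables over all training structures: bond/angle/
#' torsion internals of the MM-relaxed geometry vs the reference internals
#' (torsion differences wrapped to (-180, 180]); the MM Hessian at the
#' reference geometry projected into the modified reference eigenbasis vs
#' the modified spectrum (off-diagonal targets are zero); and assigned vs
#' reference charges.
#'
#' @param ff a [ts_forcefield()].
#' @param refset list of [reference_structure()] objects.
#' @param cfg a [penalty_config()].
#' @return numeric residual vector with a `class` attribute labeling each
#'   entry (`bond`, `angle`, `torsion`, `hessian_diag`, `hessian_offdiag`,
#'   `charge`).
#' @export
q2mm_residuals <- function(ff, refset, cfg) {
  if (inherits(refset, "reference_structure")) refset <- list(refset)
  res <- numeric(0)
  cls <- character(0)
  for (si in seq_along(refset)) {
    ref <- refset[[si]]
    w <- ref_weights(cfg, ref)
    obs <- tryCatch(reference_observables(ff, ref, cfg), error = function(e)
      stop(sprintf("residual computation failed for structure %d (%s): %s",
                   si, ref$structure$label, conditionMessage(e))))
    rb <- obs$ints_mm$bonds$value - ref$internals_ref$bonds$value
    ra <- obs$ints_mm$angles$value - ref$internals_ref$angles$value
    rt <- wrap_angle(obs$ints_mm$torsions$value - ref$internals_ref$torsions$value)
    res <- c(res, w["bond"] * rb, w["angle"] * ra, w["torsion"] * rt)
    cls <- c(cls, rep("bond", length(rb)), rep("angle", length(ra)),
             rep("torsion", length(rt)))
    D <- obs$P - diag(obs$lam_target)
    rd <- diag(D)
    ro <- D[upper.tri(D)]
    res <- c(res, w["hessian_diag"] * rd, w["hessian_offdiag"] * ro)
    cls <- c(cls, rep("hessian_diag", length(rd)),
             rep("hessian_offdiag", length(ro)))
    rq <- obs$qmm - ref$charges_ref
    res <- c(res, w["charge"] * rq)
    cls <- c(cls, rep("charge", length(rq)))
  }
  attr(res, "class_labels") <- cls
  res
}

#' Q2MM penalty (sum of squared residuals)
#' @inheritParams q2mm_residuals
#' @return non-negative scalar; zero iff every residual vanishes.
#' @export
q2mm_penalty <- function(ff, refset, cfg) {
  r <- q2mm_residuals(ff, refset, cfg)
  sum(r * r)
}

# theta <-> internal optimizer space (log for positivity-constrained fields)
theta_to_internal <- function(keys, values) {
  pos <- vapply(keys, function(k) parse_param_key(k)$field %in% POSITIVE_FIELDS,
                logical(1))
  ifelse(pos, log(values), values)
}

theta_from_internal <- function(keys, z) {
  pos <- vapply(keys, function(k) parse_param_key(k)$field %in% POSITIVE_FIELDS,
                logical(1))
  ifelse(pos, exp(z), z)
}

#' Fit selected force-field parameters to reference data
#'
#' Levenberg-Marquardt least squares on the Q2MM residual vector with a
#' forward-difference Jacobian. Positivity-constrained parameters (force
#' constants, vdW eps and rstar) are optimized in log space. The damping
#' factor adapts by x3 / /3; steps are accepted only when the penalty
#' decreases, and after five consecutive rejections a Nelder-Mead simplex
#' restart is attempted before declaring no-progress. Convergence is a
#' relative penalty change below `rel_tol` on three consecutive accepted
#' iterations.
#'
#' @param ff0 starting [ts_forcefield()].
#' @param refset list of [reference_structure()] objects.
#' @param cfg a [penalty_config()] with non-empty `theta`.
#' @return an object of class `q2mm_fit`: list with `ff_opt`,
#'   `penalty_trace` (penalty after each accepted iteration, starting with
#'   the initial value), `theta` (fitted values, named), `status`
#'   (`"converged"`, `"max_iter"` or `"no_progress"`) and `class_r2`
#'   (from [internal_validate()]).
#' @export
q2mm_fit <- function(ff0, refset, cfg) {
  if (!length(cfg$theta)) stop("cfg$theta must select at least one parameter")
  keys <- cfg$theta
  z <- theta_to_internal(keys, ff_get_params(ff0, keys))
  ff_at <- function(z) ff_set_params(ff0, keys, theta_from_internal(keys, z))
  resid_at <- function(z) q2mm_residuals(ff_at(z), refset, cfg)

  r <- resid_at(z)
  pen <- sum(r * r)
  if (!is.finite(pen)) stop("penalty is non-finite at the starting force field")
  trace <- pen
  lambda <- 1e-3
  n_reject <- 0L
  n_converged <- 0L
  status <- "max_iter"

  jac <- function(z, r0) {
    J <- matrix(0, length(r0), length(z))
    for (p in seq_along(z)) {
      h <- cfg$jac_step * max(abs(z[p]), 1e-8)
      zp <- z; zp[p] <- zp[p] + h
      J[, p] <- (resid_at(zp) - r0) / h
    }
    J
  }

  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    J <- jac(z, r)
    g <- crossprod(J, r)
    A <- crossprod(J)
    step_ok <- FALSE
    for (inner in 1:8) {
      Ad <- A + lambda * diag(pmax(diag(A), 1e-12), nrow(A))
      delta <- tryCatch(-solve(Ad, g), error = function(e) NULL)
      if (!is.null(delta)) {
        z_new <- z + as.numeric(delta)
        r_new <- tryCatch(resid_at(z_new), error = function(e) NULL)
        pen_new <- if (is.null(r_new)) Inf else sum(r_new * r_new)
        if (is.finite(pen_new) && pen_new < pen) {
          rel <- (pen - pen_new) / max(pen, 1e-300)
          z <- z_new; r <- r_new; pen <- pen_new
          trace <- c(trace, pen)
          lambda <- lambda / 3
          n_reject <- 0L
          step_ok <- TRUE
          n_converged <- if (rel < cfg$rel_tol) n_converged + 1L else 0L
          break
        }
      }
      lambda <- lambda * 3
    }
    if (!step_ok) {
      n_reject <- n_reject + 1L
      if (n_reject >= 5L) {
        # simplex fallback from the current point
        nm <- stats::optim(z, function(zz) {
          rr <- tryCatch(resid_at(zz), error = function(e) NULL)
          if (is.null(rr)) 1e30 else sum(rr * rr)
        }, method = "Nelder-Mead", control = list(maxit = 200))
        if (is.finite(nm$value) && nm$value < pen) {
          z <- nm$par; r <- resid_at(z); pen <- sum(r * r)
          trace <- c(trace, pen)
          n_reject <- 0L
        } else {
          status <- "no_progress"
          break
        }
      }
    }
    if (n_converged >= 3L) { status <- "converged"; break }
    if (pen <= 1e-14) { status <- "converged"; break }
  }

  ff_opt <- ff_at(z)
  structure(list(ff_opt = ff_opt,
                 penalty_trace = trace,
                 theta = stats::setNames(theta_from_internal(keys, z), keys),
                 status = status,
                 class_r2 = internal_validate(ff_opt, refset, cfg)),
            class = "q2mm_fit")
}

#' @export
print.q2mm_fit <- function(x, ...) {
  cat(sprintf("<q2mm_fit> status %s, penalty %.4g -> %.4g (%d accepted steps)\n",
              x$status, x$penalty_trace[1], x$penalty_trace[length(x$penalty_trace)],
              length(x$penalty_trace) - 1L))
  if (length(x$class_r2)) {
    cat("internal validation R^2:\n")
    print(round(unlist(x$class_r2), 4))
  }
  invisible(x)
}

#' Internal validation of a force field against its training data
#'
#' Per residual class, the squared Pearson correlation between the MM
#' observables and the reference observables, pooled across the training
#' set. Classes with fewer than two data points are skipped with a warning;
#' classes with zero reference variance are reported as absent (NA).
#'
#' @inheritParams q2mm_residuals
#' @return named list of R^2 values per class present.
#' @export
internal_validate <- function(ff, refset, cfg = penalty_config()) {
  if (inherits(refset, "reference_structure")) refset <- list(refset)
  mm <- list(bond = numeric(0), angle = numeric(0), torsion = numeric(0),
             hessian_diag = numeric(0), hessian_offdiag = numeric(0),
             charge = numeric(0))
  refv <- mm
  for (ref in refset) {
    obs <- reference_observables(ff, ref, cfg)
    mm$bond <- c(mm$bond, obs$ints_mm$bonds$value)
    refv$bond <- c(refv$bond, ref$internals_ref$bonds$value)
    mm$angle <- c(mm$angle, obs$ints_mm$angles$value)
    refv$angle <- c(refv$angle, ref$internals_ref$angles$value)
    # torsions are circular: compare on the reference branch so that a pair
    # like (-179.9, +179.9) counts as a 0.2-degree difference, not 359.8
    tref <- ref$internals_ref$torsions$value
    tmm <- tref + wrap_angle(obs$ints_mm$torsions$value - tref)
    mm$torsion <- c(mm$torsion, tmm)
    refv$torsion <- c(refv$torsion, tref)
    mm$hessian_diag <- c(mm$hessian_diag, diag(obs$P))
    refv$hessian_diag <- c(refv$hessian_diag, obs$lam_target)
    mm$hessian_offdiag <- c(mm$hessian_offdiag, obs$P[upper.tri(obs$P)])
    refv$hessian_offdiag <- c(refv$hessian_offdiag,
                              rep(0, sum(upper.tri(obs$P))))
    mm$charge <- c(mm$charge, obs$qmm)
    refv$charge <- c(refv$charge, ref$charges_ref)
  }
  out <- list()
  for (cl in names(mm)) {
    x <- refv[[cl]]; y <- mm[[cl]]
    if (length(x) < 2L) {
      if (length(x) == 1L)
        warning("class '", cl, "' has fewer than 2 data points; skipped")
      next
    }
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      out[[cl]] <- NA_real_
      next
    }
    out[[cl]] <- stats::cor(x, y)^2
  }
  out
}
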