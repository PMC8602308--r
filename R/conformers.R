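# Seeded Monte-Carlo torsional conformational search. Torsional-only moves
# (no low-mode component): perturb a random subset of rotatable torsions,
# relax, keep every relaxed candidate within the energy window of the
# running best, deduplicate by superposition RMSD + energy. Acceptance is
# window-based rather than Metropolis because the goal is conformer
# collection, not canonical sampling.

#' Search options for the Monte-Carlo conformational search
#'
#' @param n_steps number of MC perturbation steps (the production default in
#'   the field is 40000; toy systems need far fewer).
#' @param seed integer RNG seed; fixes the search bit-wise.
#' @param max_perturbed maximum number of torsions perturbed per step.
#' @param perturb_range length-2 numeric, degrees: magnitude range of a
#'   torsion perturbation (sign drawn separately).
#' @param window energy window W above the running best energy within which
#'   relaxed candidates are kept, kJ/mol.
#' @param rmsd_tol,energy_tol deduplication thresholds: two conformers are
#'   duplicates when RMSD < `rmsd_tol` (Angstrom) and |dE| < `energy_tol`
#'   (kJ/mol).
#' @param min_steps,grad_tol inner minimizer settings.
#' @return an object of class `search_options`.
#' @export
search_options <- function(n_steps = 40000, seed = 1, max_perturbed = 3,
                           perturb_range = c(30, 180), window = 21,
                           rmsd_tol = 0.25, energy_tol = 0.1,
                           min_steps = 500, grad_tol = 0.01) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (window <= 0) stop("window must be > 0")
  structure(list(n_steps = as.integer(n_steps), seed = as.integer(seed),
                 max_perturbed = as.integer(max_perturbed),
                 perturb_range = perturb_range, window = window,
                 rmsd_tol = rmsd_tol, energy_tol = energy_tol,
                 min_steps = min_steps, grad_tol = grad_tol),
            class = "search_options")
}

#' Rotatable torsions of a structure
#'
#' One torsion quadruple per rotatable bond: single bonds that are not in a
#' ring, not terminal on either side, and not the forming bond (the reaction
#' coordinate is never driven). For each rotatable bond j-k the reference
#' quadruple uses the lowest-index neighbor on each side; ordering follows
#' the canonical bond list, so the result is deterministic.
#'
#' @param s a [ts_structure()].
#' @return integer matrix with columns i, j, k, l (possibly zero rows).
#' @export
rotatable_torsions <- function(s) {
  nb <- neighbors_list(s)
  out <- list()
  for (r in seq_len(nrow(s$bonds))) {
    j <- s$bonds[r, 1]; k <- s$bonds[r, 2]
    if (!is.null(s$forming_bond) &&
        j == s$forming_bond[1] && k == s$forming_bond[2]) next
    if (length(nb[[j]]) < 2L || length(nb[[k]]) < 2L) next
    side <- reachable_without_bond(s, k, j, k)
    if (j %in% side) next   # ring bond
    i <- min(setdiff(nb[[j]], k))
    l <- min(setdiff(nb[[k]], j))
    out[[length(out) + 1L]] <- c(i, j, k, l)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 4,
                                  dimnames = list(NULL, c("i", "j", "k", "l"))))
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("i", "j", "k", "l"))
  m
}

# Rotate the k-side of bond j-k so the torsion i-j-k-l changes by delta_deg.
rotate_torsion <- function(s, quad, delta_deg) {
  j <- quad[2]; k <- quad[3]
  moving <- reachable_without_bond(s, k, j, k)
  # rotating the far side about j->k by -delta increases the measured
  # dihedral by +delta under the atan2 sign convention used here
  axis <- s$coords[k, ] - s$coords[j, ]
  rot <- axis_angle_rotation(axis, -delta_deg * pi / 180)
  pivot <- s$coords[j, ]
  s$coords[moving, ] <- sweep(sweep(s$coords[moving, , drop = FALSE], 2, pivot)
                              %*% t(rot), 2, pivot, FUN = "+")
  s
}

# Set a torsion to an absolute value (degrees).
set_torsion <- function(s, quad, target_deg) {
  cur <- torsion_values(s$coords, matrix(quad, nrow = 1))
  rotate_torsion(s, quad, wrap_angle(target_deg - cur))
}

#' Transition-state conformer ensemble
#'
#' @param conformers list of `ts_structure`s, each with an `energy`
#'   attribute (kJ/mol); stored sorted ascending by energy.
#' @param label parent label (typically the product configuration).
#' @param opts the [search_options()] used (for the window invariant).
#' @return an object of class `ts_ensemble` with fields `conformers`,
#'   `energies`, `label`, `n_failed` (minimization failures during search).
#' @export
ts_ensemble <- function(conformers, label = "", opts = search_options(),
                        n_failed = 0L) {
  e <- vapply(conformers, function(cf) attr(cf, "energy"), numeric(1))
  ord <- order(e)
  structure(list(conformers = conformers[ord], energies = e[ord],
                 label = label, n_failed = n_failed, opts = opts),
            class = "ts_ensemble")
}

#' @export
print.ts_ensemble <- function(x, ...) {
  cat(sprintf("<ts_ensemble> '%s': %d conformers, E = [%.3f, %.3f] kJ/mol\n",
              x$label, length(x$energies),
              if (length(x$energies)) min(x$energies) else NA,
              if (length(x$energies)) max(x$energies) else NA))
  invisible(x)
}

# TRUE when cand duplicates kept (RMSD and energy both within tolerance)
is_duplicate <- function(cand_coords, cand_e, kept_coords, kept_e, opts) {
  abs(cand_e - kept_e) < opts$energy_tol &&
    superpose_rmsd(cand_coords, kept_coords) < opts$rmsd_tol
}

#' Deduplicate a conformer pool
#'
#' Greedy energy-ordered clustering: walking up in energy, a conformer is
#' kept unless some already-kept conformer lies within both the RMSD and the
#' energy tolerance, so each duplicate cluster is represented by its
#' lowest-energy member. Conformers above `min(E) + window` are dropped.
#'
#' @param pool list of `ts_structure`s with `energy` attributes.
#' @param opts a [search_options()].
#' @param label ensemble label.
#' @return a [ts_ensemble()].
#' @export
dedupe <- function(pool, opts = search_options(), label = "") {
  if (!length(pool)) stop("empty conformer pool")
  e <- vapply(pool, function(cf) attr(cf, "energy"), numeric(1))
  ord <- order(e)
  emin <- e[ord[1]]
  kept <- list()
  kept_e <- numeric(0)
  for (idx in ord) {
    if (e[idx] > emin + opts$window) break
    dup <- FALSE
    for (kk in seq_along(kept)) {
      if (is_duplicate(pool[[idx]]$coords, e[idx],
                       kept[[kk]]$coords, kept_e[kk], opts)) { dup <- TRUE; break }
    }
    if (!dup) {
      kept[[length(kept) + 1L]] <- pool[[idx]]
      kept_e <- c(kept_e, e[idx])
    }
  }
  ts_ensemble(kept, label = label, opts = opts)
}

#' Monte-Carlo torsional conformational search
#'
#' Starting from the relaxed input, repeatedly perturbs a random subset of
#' rotatable torsions of a randomly chosen pool member, relaxes the
#' perturbed geometry, and keeps it when it lands within the energy window
#' of the running best. The pool is deduplicated incrementally. All
#' randomness flows from `opts$seed`, so a fixed seed reproduces the
#' ensemble bit-wise; the RNG state of the calling session is restored on
#' exit.
#'
#' @param s a [ts_structure()].
#' @param ff a [ts_forcefield()].
#' @param opts a [search_options()].
#' @return a [ts_ensemble()] labeled with `s$label`.
#' @export
mc_search <- function(s, ff, opts = search_options()) {
  sys <- compile_system(s, ff)
  tors <- rotatable_torsions(s)
  start <- minimize(s, ff, max_steps = opts$min_steps,
                    grad_tol = opts$grad_tol, sys = sys)
  if (nrow(tors) == 0L)
    return(ts_ensemble(list(start), label = s$label, opts = opts))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(opts$seed)

  pool <- list(start)
  pool_e <- attr(start, "energy")
  best <- pool_e
  n_failed <- 0L
  for (step in seq_len(opts$n_steps)) {
    base <- pool[[sample.int(length(pool), 1L)]]
    n_pert <- sample.int(min(opts$max_perturbed, nrow(tors)), 1L)
    which_t <- sample.int(nrow(tors), n_pert)
    cand <- base
    for (tq in which_t) {
      mag <- stats::runif(1, opts$perturb_range[1], opts$perturb_range[2])
      sgn <- sample(c(-1, 1), 1L)
      cand <- rotate_torsion(cand, tors[tq, ], sgn * mag)
    }
    relaxed <- tryCatch(
      minimize(cand, ff, max_steps = opts$min_steps,
               grad_tol = opts$grad_tol, sys = sys),
      error = function(e) NULL)
    if (is.null(relaxed)) {
      n_failed <- n_failed + 1L
      if (n_failed > opts$n_steps / 2)
        stop("more than half of the MC steps failed to minimize")
      next
    }
    e_new <- attr(relaxed, "energy")
    if (e_new > best + opts$window) next
    # incremental dedupe: replace a duplicate only if strictly lower
    dup_of <- 0L
    for (kk in seq_along(pool)) {
      if (is_duplicate(relaxed$coords, e_new, pool[[kk]]$coords, pool_e[kk],
                       opts)) { dup_of <- kk; break }
    }
    if (dup_of > 0L) {
      if (e_new < pool_e[dup_of]) {
        pool[[dup_of]] <- relaxed
        pool_e[dup_of] <- e_new
      }
    } else {
      pool[[length(pool) + 1L]] <- relaxed
      pool_e <- c(pool_e, e_new)
    }
    if (e_new < best) best <- e_new
  }
  ens <- dedupe(pool, opts, label = s$label)
  ens$n_failed <- n_failed
  ens
}

#' Write an ensemble to a multi-record SDF
#'
#' Energies go to the `TSFF_ENERGY_KJMOL` data field.
#' @param ens a [ts_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_sdf <- function(ens, path) {
  ef <- lapply(ens$energies, function(e) list(TSFF_ENERGY_KJMOL = sprintf("%.10g", e)))
  write_sdf(ens$conformers, path, extra_fields = ef)
}

#' Read an ensemble from a multi-record SDF
#' @param path input file written by [write_ensemble_sdf()].
#' @param opts a [search_options()] (tolerances for downstream use).
#' @return a [ts_ensemble()].
#' @export
read_ensemble_sdf <- function(path, opts = search_options()) {
  structs <- read_sdf(path)
  for (k in seq_along(structs)) {
    fields <- attr(structs[[k]], "sdf_fields")
    attr(structs[[k]], "energy") <- as.numeric(fields$TSFF_ENERGY_KJMOL)
  }
  ts_ensemble(structs, label = structs[[1]]$label, opts = opts)
}
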