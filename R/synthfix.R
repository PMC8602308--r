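# Synthetic-fixture generators: toy transition-state systems with known
# ground-truth force fields, mock quantum reference bundles fabricated from
# those force fields, perturbed starting force fields for parameter-recovery
# experiments, and synthetic validation tables with planted stereochemical
# misassignments. Everything is seeded and reproducible bit-wise; no
# quantum-chemical data or downloads are involved anywhere.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a toy transition-state system with a known force field
#'
#' Builds a heavy-atom chain of `n_heavy` atoms with one distinct atom type
#' per position (so every parameter is individually addressable), designates
#' the terminal bond 1-2 as the forming bond, draws a complete ground-truth
#' force field with mildly jittered, chemically sensible magnitudes
#' (stretches ~2000 kJ/mol/A^2 around 1.5 A, bends ~0.03 kJ/mol/deg^2 around
#' 112 deg, 1-3 kJ/mol torsion barriers, exp-6 wells of ~0.25 kJ/mol at
#' ~3.4 A, alternating charges of magnitude `charge_scale`), and relaxes the
#' chain under that force field. A chain of n atoms has n - 3 rotatable
#' torsions.
#'
#' @param n_heavy number of heavy atoms (4-20).
#' @param charge_scale magnitude of the alternating partial charges, e.
#' @param include_forming_bond designate bond 1-2 as the forming bond.
#' @param seed RNG seed.
#' @return list with `structure` (relaxed [ts_structure()]) and `ff`
#'   (ground-truth [ts_forcefield()]).
#' @export
make_toy_ts_system <- function(n_heavy = 6, charge_scale = 0.1,
                               include_forming_bond = TRUE, seed = 1) {
  if (n_heavy < 4 || n_heavy > 20) stop("n_heavy must be in 4..20")
  with_seed(seed, {
    types <- paste0("T", seq_len(n_heavy))
    elements <- rep("C", n_heavy)
    elements[1] <- "N"   # the attacking nucleophile atom of the forming bond
    charges <- charge_scale * (-1)^(seq_len(n_heavy))
    bonds <- cbind(seq_len(n_heavy - 1), 2:n_heavy)

    stretch <- list(); bend <- list(); torsion <- list()
    vdw <- list(); charge <- list()
    for (b in seq_len(nrow(bonds))) {
      key <- canon_stretch_key(types[bonds[b, 1]], types[bonds[b, 2]])
      stretch[[key]] <- list(kb = stats::runif(1, 1700, 2300),
                             r0 = stats::runif(1, 1.46, 1.56))
    }
    for (j in 2:(n_heavy - 1)) {
      key <- canon_bend_key(types[j - 1], types[j], types[j + 1])
      bend[[key]] <- list(ka = stats::runif(1, 0.025, 0.040),
                          theta0 = stats::runif(1, 108, 116))
    }
    if (n_heavy >= 4) {
      for (j in 2:(n_heavy - 2)) {
        key <- canon_torsion_key(types[j - 1], types[j], types[j + 1], types[j + 2])
        torsion[[key]] <- list(v1 = stats::runif(1, 0.5, 1.5),
                               v2 = stats::runif(1, 0.2, 0.8),
                               v3 = stats::runif(1, 1.5, 3.5))
      }
    }
    for (ty in types) {
      vdw[[ty]] <- list(eps = stats::runif(1, 0.2, 0.35),
                        rstar = stats::runif(1, 3.2, 3.6))
    }
    for (a in seq_len(n_heavy)) charge[[types[a]]] <- charges[a]
    ff <- ts_forcefield(stretch, bend, torsion, vdw, charge, dielectric = 1.0)

    # zig-zag chain start near the stretch/bend equilibria, staggered torsions
    coords <- matrix(0, n_heavy, 3)
    dir_flip <- 1
    for (a in 2:n_heavy) {
      key <- canon_stretch_key(types[a - 1], types[a])
      r0 <- stretch[[key]]$r0
      step <- c(r0 * cos(0.6 * dir_flip), r0 * sin(0.6 * dir_flip), 0)
      coords[a, ] <- coords[a - 1, ] + step
      dir_flip <- -dir_flip
    }
    # kick out of plane so torsions relax into a generic well
    coords[, 3] <- coords[, 3] + 0.15 * sin(seq_len(n_heavy))

    s <- ts_structure(elements, coords, bonds, types = types, charges = charges,
                      forming_bond = if (include_forming_bond) c(1, 2) else NULL,
                      label = "toy_ts")
    s <- minimize(s, ff, max_steps = 2000, grad_tol = 1e-3)
    list(structure = s, ff = ff)
  })
}

#' Fabricate a mock quantum reference from a known force field
#'
#' Stands in for a quantum-chemically characterized transition state: the
#' reference internals are those of the (already relaxed) input geometry,
#' the reference charges come from the force field's charge records
#' (optionally with seeded Gaussian noise), and the reference Hessian is the
#' MM Hessian under the generating force field with the eigenvalue of the
#' mode overlapping the forming-bond stretch negated, emulating the single
#' imaginary mode of a first-order saddle. The negated mode's original
#' (positive) eigenvalue is recorded as `ts_mode_eigenvalue`: setting the
#' replacement eigenvalue omega to it makes the generating force field an
#' exact zero of the fitting penalty.
#'
#' @param s a [ts_structure()] relaxed under `ff_true`, with a forming bond
#'   when `is_ts = TRUE`.
#' @param ff_true the generating [ts_forcefield()].
#' @param noise_sd standard deviation of Gaussian noise added to the
#'   reference charges, e (0 = exact).
#' @param seed RNG seed for the noise.
#' @param is_ts fabricate a saddle (negated mode) or a plain minimum.
#' @return a [reference_structure()].
#' @export
mock_qm_reference <- function(s, ff_true, noise_sd = 0, seed = 1, is_ts = TRUE) {
  sys <- compile_system(s, ff_true)
  H <- hessian(s, ff_true, sys = sys)
  lam_ts <- NULL
  if (is_ts) {
    if (is.null(s$forming_bond))
      stop("a transition-state reference needs a forming bond")
    ed <- eigen(H, symmetric = TRUE)
    n <- n_atoms(s)
    d <- numeric(3 * n)
    i <- s$forming_bond[1]; j <- s$forming_bond[2]
    u <- s$coords[j, ] - s$coords[i, ]
    u <- u / sqrt(sum(u * u))
    d[3 * (i - 1) + 1:3] <- -u
    d[3 * (j - 1) + 1:3] <- u
    d <- d / sqrt(sum(d * d))
    overlap <- abs(as.numeric(crossprod(ed$vectors, d)))
    cand <- which(ed$values > 1)
    k <- cand[which.max(overlap[cand])]
    lam_ts <- ed$values[k]
    v <- ed$vectors[, k]
    H <- H - 2 * lam_ts * tcrossprod(v)
    H <- (H + t(H)) / 2
  }
  charges_ref <- sys$charges
  if (noise_sd > 0)
    charges_ref <- with_seed(seed,
      charges_ref + stats::rnorm(length(charges_ref), 0, noise_sd))
  reference_structure(s, H, charges_ref, is_ts = is_ts,
                      ts_mode_eigenvalue = lam_ts)
}

#' Enumerate all parameter keys of a force field
#' @param ff a [ts_forcefield()].
#' @return character vector of `"section:types:field"` keys.
#' @export
ff_all_keys <- function(ff) {
  fields <- list(stretch = c("kb", "r0"), bend = c("ka", "theta0"),
                 torsion = c("v1", "v2", "v3"), vdw = c("eps", "rstar"),
                 charge = "q")
  out <- character(0)
  for (sec in names(fields))
    for (key in names(ff[[sec]]))
      out <- c(out, paste(sec, key, fields[[sec]], sep = ":"))
  out
}

#' Randomly perturb force-field parameters
#'
#' Each selected parameter is multiplied by (1 + u), u uniform in
#' +/- `rel_fraction`; positivity-constrained parameters are perturbed in
#' log space (multiplied by exp(u)), so all invariants survive.
#'
#' @param ff a [ts_forcefield()].
#' @param rel_fraction relative perturbation half-width in (0, 1).
#' @param seed RNG seed.
#' @param keys parameter keys to perturb (default: all).
#' @return the perturbed [ts_forcefield()].
#' @export
perturb_ff <- function(ff, rel_fraction, seed = 1, keys = ff_all_keys(ff)) {
  if (rel_fraction <= 0 || rel_fraction >= 1)
    stop("rel_fraction must be in (0, 1)")
  with_seed(seed, {
    vals <- ff_get_params(ff, keys)
    u <- stats::runif(length(vals), -rel_fraction, rel_fraction)
    pos <- vapply(keys, function(k)
      parse_param_key(k)$field %in% POSITIVE_FIELDS, logical(1))
    new <- ifelse(pos, vals * exp(u), vals * (1 + u))
    ff_set_params(ff, keys, new)
  })
}

#' Fill missing force-field records with generic defaults
#'
#' Walks the bonded topology and atom types of a structure and adds a
#' generic record for every tuple the force field does not yet resolve
#' (stretch 1800 kJ/mol/A^2 at 1.52 A; bend 0.03 kJ/mol/deg^2 at 112 deg;
#' torsion 0.4/0.2/2.5 kJ/mol; vdW 0.25 kJ/mol at 3.4 A). Existing records
#' are never touched. Useful for completing a force field over the
#' cross-junction terms created by fragment assembly.
#'
#' @param s a [ts_structure()].
#' @param ff a [ts_forcefield()] to extend (default: empty).
#' @return the completed [ts_forcefield()].
#' @export
complete_forcefield <- function(s, ff = ts_forcefield()) {
  topo <- internal_topology(s)
  ty <- s$types
  for (r in seq_len(nrow(topo$bonds))) {
    key <- canon_stretch_key(ty[topo$bonds[r, 1]], ty[topo$bonds[r, 2]])
    if (is.null(ff$stretch[[key]]))
      ff$stretch[[key]] <- list(kb = 1800, r0 = 1.52)
  }
  for (r in seq_len(nrow(topo$angles))) {
    key <- canon_bend_key(ty[topo$angles[r, 1]], ty[topo$angles[r, 2]],
                          ty[topo$angles[r, 3]])
    if (is.null(ff$bend[[key]]))
      ff$bend[[key]] <- list(ka = 0.03, theta0 = 112)
  }
  for (r in seq_len(nrow(topo$torsions))) {
    key <- canon_torsion_key(ty[topo$torsions[r, 1]], ty[topo$torsions[r, 2]],
                             ty[topo$torsions[r, 3]], ty[topo$torsions[r, 4]])
    if (is.null(ff$torsion[[key]]))
      ff$torsion[[key]] <- list(v1 = 0.4, v2 = 0.2, v3 = 2.5)
  }
  for (t1 in unique(ty)) {
    if (is.null(ff$vdw[[t1]]))
      ff$vdw[[t1]] <- list(eps = 0.25, rstar = 3.4)
  }
  ff
}

#' Mirror-image diastereomeric TS fixture (achiral ligand)
#'
#' Builds a planar three-atom TS template (forming bond set), declares one
#' ligand anchor site, mirrors the template to obtain the opposite-
#' configuration pathway, and assembles both with the same achiral chain
#' ligand. Because template and ligand are achiral, the two assembled
#' transition states are mirror images with identical conformational energy
#' landscapes: the predicted ddG is zero up to conformational-sampling
#' noise. This is the end-to-end chirality null fixture.
#'
#' @param ligand_atoms number of real atoms in the chain ligand (>= 2).
#' @param seed RNG seed (only used for tiny coordinate jitter-free defaults;
#'   kept for interface symmetry).
#' @return list with `structures` (list of two labeled [ts_structure()]s,
#'   R_exo and S_exo), `ff` (complete force field) and `templates`.
#' @export
make_mirror_ts_pair <- function(ligand_atoms = 3, seed = 1) {
  th <- 112 * pi / 180
  core_elem <- c("C", "C", "N", "Du")
  core_ty <- c("A1", "A2", "A3", "DL")
  core_xy <- rbind(c(0, 0, 0),
                   c(1.5, 0, 0),
                   c(1.5 - 1.5 * cos(th), 1.5 * sin(th), 0),
                   c(-1.5 * cos(th), -1.5 * sin(th), 0))  # dummy on atom 1
  core_bonds <- rbind(c(1, 2), c(2, 3), c(1, 4))
  core <- ts_structure(core_elem, core_xy, core_bonds, types = core_ty,
                       charges = c(0.05, -0.1, 0.05, 0),
                       forming_bond = c(2, 3), label = "core")
  anchors <- list(L = list(dummy = 4L, class = "ligand"))
  tpl_R <- ts_template(core, anchors, product_config = "R", allyl_isomer = "exo")
  tpl_S <- ts_template(mirror_structure(core), anchors,
                       product_config = "S", allyl_isomer = "exo")

  la <- max(2L, as.integer(ligand_atoms))
  lig_elem <- c("Du", rep("C", la))
  lig_ty <- c("DL", paste0("L", seq_len(la)))
  lig_xy <- matrix(0, la + 1, 3)
  dirs <- rbind(c(1, 0, 0), c(0.4, 0.9, 0))
  for (a in 2:(la + 1))
    lig_xy[a, ] <- lig_xy[a - 1, ] + 1.5 * dirs[(a %% 2) + 1, ]
  lig_bonds <- cbind(seq_len(la), 2:(la + 1))
  lig <- ts_fragment(ts_structure(lig_elem, lig_xy, lig_bonds, types = lig_ty,
                                  charges = c(0, 0.08 * (-1)^(seq_len(la))),
                                  label = "ligand"),
                     class = "ligand")

  draft <- attach_fragment(tpl_R, lig, "L", ff = NULL)
  ff <- complete_forcefield(draft)
  structures <- enumerate_ts(list(tpl_R, tpl_S), list(lig), ff = ff)
  list(structures = structures, ff = ff, templates = list(tpl_R, tpl_S))
}

#' Synthetic validation table with planted misassignments
#'
#' Draws true ddG values uniformly on +/- 12 kJ/mol, sets the prediction to
#' truth plus Gaussian noise, derives the experimental ee and configuration
#' from the truth, and then inverts the reported configuration for the
#' planted `mismatch_ids` -- emulating a literature table containing
#' stereochemical misassignments. Planted records are guaranteed confident
#' (|true ddG| >= 2.5 kJ/mol and a same-sign, confident prediction), and
#' non-planted records are guaranteed not to be confident sign mismatches
#' (noise redrawn when one would arise), so [flag_mismatches()] at the
#' default 20% ee threshold recovers exactly the planted set.
#'
#' @param n number of records.
#' @param error_sd_kJmol prediction-error standard deviation (default 3.5,
#'   the scale of a well-behaved TSFF validation).
#' @param mismatch_ids integer indices (subset of 1..n) whose reported
#'   configuration is inverted.
#' @param exclusion_ids integer indices tagged `"indphox"` (excluded-ligand
#'   stand-ins) in `exclusion_tag`.
#' @param seed RNG seed.
#' @return a validation data.frame with derived columns (see
#'   [derive_validation_columns()]) plus `true_ddg_kJmol`.
#' @export
make_validation_fixture <- function(n = 77, error_sd_kJmol = 3.5,
                                    mismatch_ids = integer(0),
                                    exclusion_ids = integer(0), seed = 1) {
  stopifnot(all(mismatch_ids %in% seq_len(n)),
            all(exclusion_ids %in% seq_len(n)))
  tc <- thermo_context()
  conf_ddg <- ee_to_ddg(20, tc)       # ddG at the 20% ee confidence edge
  with_seed(seed, {
    true_ddg <- stats::runif(n, -12, 12)
    planted <- seq_len(n) %in% mismatch_ids
    # planted cases must be confidently selective
    if (any(planted)) {
      mag <- stats::runif(sum(planted), 2.5, 12)
      true_ddg[planted] <- sign(true_ddg[planted] + .Machine$double.eps) * mag
    }
    pred <- true_ddg + stats::rnorm(n, 0, error_sd_kJmol)
    for (r in seq_len(n)) {
      tries <- 0L
      if (planted[r]) {
        # need same sign as truth and confident: stays flagged after inversion
        while ((sign(pred[r]) != sign(true_ddg[r]) ||
                abs(pred[r]) < 1.1 * conf_ddg) && tries < 200L) {
          pred[r] <- true_ddg[r] + stats::rnorm(1, 0, error_sd_kJmol)
          tries <- tries + 1L
        }
        if (sign(pred[r]) != sign(true_ddg[r]) || abs(pred[r]) < 1.1 * conf_ddg)
          pred[r] <- true_ddg[r]
      } else {
        # must not be a confident sign mismatch vs the (true) assignment
        confident_flip <- function(p)
          sign(p) != sign(true_ddg[r]) &&
            min(abs(p), abs(true_ddg[r])) >= conf_ddg
        while (confident_flip(pred[r]) && tries < 200L) {
          pred[r] <- true_ddg[r] + stats::rnorm(1, 0, error_sd_kJmol)
          tries <- tries + 1L
        }
        if (confident_flip(pred[r])) pred[r] <- true_ddg[r]
      }
    }
    ee_true <- vapply(true_ddg, function(d) ddg_to_ee(d, tc)$ee, numeric(1))
    config <- ifelse(true_ddg > 0, "S", "R")
    config[planted] <- ifelse(config[planted] == "S", "R", "S")
    records <- data.frame(
      case_id = sprintf("case_%03d", seq_len(n)),
      ligand_id = sprintf("L%02d", ((seq_len(n) - 1) %% 53) + 1),
      nucleophile_id = sprintf("N%02d", ((seq_len(n) - 1) %% 16) + 1),
      exp_ee_percent = abs(ee_true),
      exp_config = config,
      pred_ddg_kJmol = pred,
      temp_K = 298.15,
      exclusion_tag = ifelse(seq_len(n) %in% exclusion_ids, "indphox", ""),
      true_ddg_kJmol = true_ddg,
      stringsAsFactors = FALSE)
    derive_validation_columns(records)
  })
}
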