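# Boltzmann statistics over diastereomeric transition-state ensembles.
# Sign convention throughout: positive ddG means the S product is preferred,
# i.e. ddG = G(R pathway) - G(S pathway).

#' Thermodynamic context
#' @param T_K absolute temperature in Kelvin (default 298.15).
#' @return list with gas constant `R` (8.314 J/mol/K, fixed), `T_K`, and
#'   `RT_kJ` (kJ/mol).
#' @export
thermo_context <- function(T_K = 298.15) {
  if (T_K <= 0) stop("temperature must be > 0 K")
  R <- 8.314
  list(R = R, T_K = T_K, RT_kJ = R * T_K / 1000)
}

#' Boltzmann-averaged free-energy score of an ensemble
#'
#' The effective free energy of a conformer ensemble,
#' G = -RT ln sum_i exp(-E_i / RT), computed with the log-sum-exp shift for
#' overflow safety. Always <= min(E); equals E for a single conformer.
#'
#' @param energies numeric vector of conformer energies, kJ/mol (nonempty).
#' @param tc a [thermo_context()].
#' @return scalar G in kJ/mol.
#' @export
boltzmann_score <- function(energies, tc = thermo_context()) {
  if (!length(energies)) stop("empty energy list")
  emin <- min(energies)
  emin - tc$RT_kJ * log(sum(exp(-(energies - emin) / tc$RT_kJ)))
}

#' Free-energy difference between diastereomeric ensembles
#'
#' ddG = G(R) - G(S): a lower-lying S ensemble gives a positive value, so
#' positive means S preferred.
#'
#' @param ens_R,ens_S [ts_ensemble()] objects (or bare numeric energy
#'   vectors) for the R- and S-product pathways.
#' @param tc a [thermo_context()].
#' @return ddG in kJ/mol.
#' @export
ddg_from_ensembles <- function(ens_R, ens_S, tc = thermo_context()) {
  e_R <- if (inherits(ens_R, "ts_ensemble")) ens_R$energies else as.numeric(ens_R)
  e_S <- if (inherits(ens_S, "ts_ensemble")) ens_S$energies else as.numeric(ens_S)
  if (!length(e_R) || !length(e_S))
    stop("both diastereomeric ensembles must be nonempty")
  boltzmann_score(e_R, tc) - boltzmann_score(e_S, tc)
}

#' Convert ddG to enantiomeric ratio and excess
#'
#' er = exp(|ddG|/RT) (for the major pathway, so er >= 1) and
#' ee = 100 (er - 1)/(er + 1), signed by the sign of ddG: positive ee means
#' S is the major enantiomer.
#'
#' @param ddg free-energy difference, kJ/mol (positive = S preferred).
#' @param tc a [thermo_context()].
#' @return list with `er`, `ee` (signed percent) and `major`
#'   (`"R"`, `"S"` or `"racemic"` when |ee| < 1e-9).
#' @export
ddg_to_ee <- function(ddg, tc = thermo_context()) {
  if (!is.finite(ddg)) stop("ddg must be finite")
  er <- exp(abs(ddg) / tc$RT_kJ)
  ee <- sign(ddg) * 100 * (er - 1) / (er + 1)
  major <- if (abs(ee) < 1e-9) "racemic" else if (ddg > 0) "S" else "R"
  list(er = er, ee = ee, major = major)
}

#' Convert a signed enantiomeric excess back to ddG
#'
#' ddG = RT ln er with er = (100 + ee) / (100 - ee); the inverse of
#' [ddg_to_ee()]. Positive ee (S major) gives positive ddG.
#'
#' @param ee signed enantiomeric excess in percent, |ee| < 100.
#' @param tc a [thermo_context()].
#' @return ddG in kJ/mol.
#' @export
ee_to_ddg <- function(ee, tc = thermo_context()) {
  if (any(abs(ee) >= 100)) stop("|ee| must be < 100%")
  tc$RT_kJ * log((100 + ee) / (100 - ee))
}

#' Predict enantioselectivity from labeled transition-state structures
#'
#' Runs the Monte-Carlo conformational search on every structure, pools the
#' resulting ensembles by product-configuration label, and converts the
#' Boltzmann-averaged ensemble free-energy difference into er/ee. Structure
#' labels must start with `"R"` or `"S"` (e.g. `"R_exo"`, `"S_endo"`).
#'
#' @param ts_structures list of labeled [ts_structure()]s, at least one per
#'   configuration.
#' @param ff a [ts_forcefield()].
#' @param opts a [search_options()]; the same seed is used for every
#'   structure so a fixed seed fixes the whole prediction.
#' @param tc a [thermo_context()].
#' @return an object of class `selectivity_result`: list with `ddg`, `er`,
#'   `ee` (signed, positive = S), `major`, `n_conformers` (named, R and S)
#'   and the pooled `ensembles`.
#' @export
predict_selectivity <- function(ts_structures, ff, opts = search_options(),
                                tc = thermo_context()) {
  config_of <- function(s) {
    cf <- toupper(substr(s$label, 1, 1))
    if (!cf %in% c("R", "S"))
      stop("structure label must start with the product configuration R or S: ",
           s$label)
    cf
  }
  cfgs <- vapply(ts_structures, config_of, character(1))
  if (!all(c("R", "S") %in% cfgs))
    stop("need at least one transition-state structure per configuration")
  pool <- list(R = numeric(0), S = numeric(0))
  ensembles <- list(R = list(), S = list())
  for (k in seq_along(ts_structures)) {
    ens <- mc_search(ts_structures[[k]], ff, opts)
    pool[[cfgs[k]]] <- c(pool[[cfgs[k]]], ens$energies)
    ensembles[[cfgs[k]]][[length(ensembles[[cfgs[k]]]) + 1L]] <- ens
  }
  ddg <- ddg_from_ensembles(pool$R, pool$S, tc)
  conv <- ddg_to_ee(ddg, tc)
  structure(list(ddg = ddg, er = conv$er, ee = conv$ee, major = conv$major,
                 n_conformers = c(R = length(pool$R), S = length(pool$S)),
                 ensembles = ensembles, T_K = tc$T_K),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf(
    "<selectivity_result> ddG = %+.3f kJ/mol, er = %.3f, ee = %.1f%% (%s), %d R / %d S conformers\n",
    x$ddg, x$er, abs(x$ee), x$major, x$n_conformers["R"], x$n_conformers["S"]))
  invisible(x)
}
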