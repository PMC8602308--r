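# Validation against experimental records and stereochemistry proofreading.
# A validation table is a data.frame with columns case_id, ligand_id,
# nucleophile_id, exp_ee_percent (unsigned), exp_config (R|S),
# pred_ddg_kJmol (signed, positive = S preferred) and the optional columns
# temp_K, exclusion_tag, source_ref. Derived columns: exp_ddg_kJmol (signed
# via the ee->ddG relation with S positive) and pred_ee_percent.

#' Attach derived columns to a validation table
#'
#' Computes the signed experimental ddG from the unsigned experimental ee
#' and configuration (S counts positive), and the signed predicted ee from
#' the predicted ddG, at each record's temperature (column `temp_K`,
#' default 298.15). Experimental ee of 100% is clamped to 99.9% with a
#' warning (the ee -> ddG conversion is singular at 100).
#'
#' @param records validation data.frame (see module description).
#' @return the data.frame with `exp_ddg_kJmol` and `pred_ee_percent` columns.
#' @export
derive_validation_columns <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (!all(records$exp_config %in% c("R", "S")))
    stop("exp_config must be R or S")
  if (any(records$exp_ee_percent < 0 | records$exp_ee_percent > 100))
    stop("exp_ee_percent must be in [0, 100]")
  if (is.null(records$temp_K)) records$temp_K <- 298.15
  ee <- records$exp_ee_percent
  if (any(ee >= 100)) {
    warning("experimental ee of 100% clamped to 99.9% before conversion")
    ee[ee >= 100] <- 99.9
  }
  signed_ee <- ifelse(records$exp_config == "S", ee, -ee)
  records$exp_ddg_kJmol <- vapply(seq_len(nrow(records)), function(r)
    ee_to_ddg(signed_ee[r], thermo_context(records$temp_K[r])), numeric(1))
  records$pred_ee_percent <- vapply(seq_len(nrow(records)), function(r)
    ddg_to_ee(records$pred_ddg_kJmol[r], thermo_context(records$temp_K[r]))$ee,
    numeric(1))
  records
}

needs_derived <- function(records) {
  if (is.null(records$exp_ddg_kJmol) || is.null(records$pred_ee_percent))
    derive_validation_columns(records)
  else records
}

#' Mean unsigned error of predicted vs experimental ddG
#' @param records validation data.frame.
#' @return MUE in kJ/mol.
#' @export
mue <- function(records) {
  records <- needs_derived(records)
  if (!nrow(records)) stop("no records")
  mean(abs(records$pred_ddg_kJmol - records$exp_ddg_kJmol))
}

#' Squared Pearson correlation of predicted vs experimental ddG
#' @param records validation data.frame (>= 2 records).
#' @return R^2 in [0, 1], or NA when either side has zero variance.
#' @export
r2 <- function(records) {
  records <- needs_derived(records)
  if (nrow(records) < 2) stop("need at least 2 records for R^2")
  x <- records$exp_ddg_kJmol; y <- records$pred_ddg_kJmol
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Flag suspected stereochemical misassignments
#'
#' A record is flagged when the predicted and experimental ddG disagree in
#' sign while both selectivities are confident: min(|predicted ee|,
#' experimental ee) >= `min_ee`. These are the cases where a high predicted
#' selectivity opposes the reported configuration -- candidates for
#' experimental re-examination rather than force-field error.
#'
#' @param records validation data.frame.
#' @param min_ee confidence threshold in percent ee (default 20).
#' @return character vector of flagged `case_id`s.
#' @export
flag_mismatches <- function(records, min_ee = 20) {
  records <- needs_derived(records)
  mism <- sign(records$pred_ddg_kJmol) != sign(records$exp_ddg_kJmol)
  conf <- pmin(abs(records$pred_ee_percent), records$exp_ee_percent) >= min_ee
  as.character(records$case_id[mism & conf])
}

#' Invert the reported configuration of selected records
#'
#' Flips `exp_config` and the sign of the derived experimental ddG (and
#' signed quantities that depend on it) for the listed case ids; everything
#' else is untouched. Applying the same correction twice restores the
#' original table.
#'
#' @param records validation data.frame.
#' @param ids character vector of case ids to invert (must all exist).
#' @return the corrected data.frame.
#' @export
apply_corrections <- function(records, ids) {
  records <- needs_derived(records)
  if (!length(ids)) return(records)
  hit <- records$case_id %in% ids
  missing <- setdiff(ids, records$case_id)
  if (length(missing))
    stop("unknown case ids: ", paste(missing, collapse = ", "))
  records$exp_config[hit] <- ifelse(records$exp_config[hit] == "R", "S", "R")
  records$exp_ddg_kJmol[hit] <- -records$exp_ddg_kJmol[hit]
  records
}

#' Proofreading report
#'
#' Computes MUE and R^2 on the non-excluded subset, flags confident sign
#' mismatches, applies the corrections and recomputes the statistics, so
#' the report carries both the pre- and post-correction numbers.
#'
#' @param records validation data.frame.
#' @param exclude_tags character vector of `exclusion_tag` values to drop
#'   from the statistics (e.g. cases argued to be outside the model's
#'   mechanistic regime).
#' @param min_ee confidence threshold for flagging, percent ee.
#' @return an object of class `proofread_report`: list with `n_total`,
#'   `n_excluded`, `mue`, `r2` (pre-correction), `flagged` (case ids),
#'   `n_flagged`, `mue_corrected`, `r2_corrected` and the corrected
#'   `records`.
#' @export
proofread_report <- function(records, exclude_tags = character(0), min_ee = 20) {
  records <- needs_derived(records)
  keep <- if (!is.null(records$exclusion_tag) && length(exclude_tags))
    !(records$exclusion_tag %in% exclude_tags)
  else rep(TRUE, nrow(records))
  sub <- records[keep, , drop = FALSE]
  if (!nrow(sub)) stop("all records excluded")
  flagged <- flag_mismatches(sub, min_ee = min_ee)
  corrected <- apply_corrections(sub, flagged)
  structure(list(n_total = nrow(sub),
                 n_excluded = sum(!keep),
                 mue = mue(sub),
                 r2 = r2(sub),
                 flagged = flagged,
                 n_flagged = length(flagged),
                 mue_corrected = mue(corrected),
                 r2_corrected = r2(corrected),
                 records = corrected),
            class = "proofread_report")
}

#' @export
print.proofread_report <- function(x, ...) {
  cat(sprintf("<proofread_report> %d records (%d excluded)\n", x$n_total, x$n_excluded))
  cat(sprintf("  pre-correction : MUE %.3f kJ/mol, R^2 %.3f\n", x$mue, x$r2))
  cat(sprintf("  flagged        : %d case(s)%s\n", x$n_flagged,
              if (x$n_flagged) paste0(" [", paste(x$flagged, collapse = ", "), "]") else ""))
  cat(sprintf("  post-correction: MUE %.3f kJ/mol, R^2 %.3f\n",
              x$mue_corrected, x$r2_corrected))
  invisible(x)
}

#' Read / write validation tables
#'
#' CSV with the columns documented in [derive_validation_columns()].
#' @param path file path.
#' @return `read_validation_table`: a data.frame with derived columns.
#' @export
read_validation_table <- function(path) {
  derive_validation_columns(
    utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_validation_table
#' @param records validation data.frame.
#' @export
write_validation_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
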