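#' Force-field parameter set
#'
#' Typed parameter records for an MM3*-like functional form. Lookups are
#' symmetric under reversal of the type tuple (a stretch for types `A-B`
#' also answers `B-A`, and likewise for bends and torsions). Units are fixed
#' package-wide: kJ/mol, Angstrom, degrees, elementary charges.
#'
#' @param stretch named list, key `"A|B"` -> `list(kb, r0)` with `kb` in
#'   kJ/mol/A^2 and `r0` in Angstrom.
#' @param bend named list, key `"A|B|C"` -> `list(ka, theta0)` with `ka` in
#'   kJ/mol/deg^2 and `theta0` in degrees.
#' @param torsion named list, key `"A|B|C|D"` -> `list(v1, v2, v3)` in kJ/mol.
#' @param vdw named list, key `"A"` -> `list(eps, rstar)`; `eps` kJ/mol,
#'   `rstar` Angstrom (the pair distance at the well for identical types;
#'   pairs combine as geometric mean in eps, arithmetic mean in rstar).
#' @param charge named list, key `"A"` -> charge in e. Optional per-type
#'   override; atom types without a record keep their per-atom charges.
#' @param dielectric constant dielectric for the Coulomb term (default 1.0).
#' @return an object of class `ts_forcefield`.
#' @export
ts_forcefield <- function(stretch = list(), bend = list(), torsion = list(),
                          vdw = list(), charge = list(), dielectric = 1.0) {
  ff <- structure(list(stretch = stretch, bend = bend, torsion = torsion,
                       vdw = vdw, charge = charge,
                       dielectric = as.numeric(dielectric)),
                  class = "ts_forcefield")
  validate_forcefield(ff)
  ff
}

validate_forcefield <- function(ff) {
  for (k in names(ff$stretch)) {
    p <- ff$stretch[[k]]
    if (!is.finite(p$kb) || p$kb <= 0) stop("stretch kb must be > 0 for ", k)
  }
  for (k in names(ff$bend)) {
    p <- ff$bend[[k]]
    if (!is.finite(p$ka) || p$ka <= 0) stop("bend ka must be > 0 for ", k)
  }
  for (k in names(ff$vdw)) {
    p <- ff$vdw[[k]]
    if (!is.finite(p$eps) || p$eps <= 0) stop("vdw eps must be > 0 for ", k)
    if (!is.finite(p$rstar) || p$rstar <= 0) stop("vdw rstar must be > 0 for ", k)
  }
  if (!is.finite(ff$dielectric) || ff$dielectric <= 0)
    stop("dielectric must be > 0")
  invisible(ff)
}

#' @export
print.ts_forcefield <- function(x, ...) {
  cat(sprintf(paste0("<ts_forcefield> %d stretch, %d bend, %d torsion, ",
                     "%d vdw, %d charge records; dielectric %g\n"),
              length(x$stretch), length(x$bend), length(x$torsion),
              length(x$vdw), length(x$charge), x$dielectric))
  invisible(x)
}

# ---- canonical keys -------------------------------------------------------

ff_key <- function(types) paste(types, collapse = "|")

canon_stretch_key <- function(t1, t2) ff_key(sort(c(t1, t2)))

canon_bend_key <- function(t1, t2, t3) {
  ends <- sort(c(t1, t3))
  ff_key(c(ends[1], t2, ends[2]))
}

canon_torsion_key <- function(t1, t2, t3, t4) {
  fwd <- c(t1, t2, t3, t4); rev <- c(t4, t3, t2, t1)
  if (paste(fwd, collapse = "|") <= paste(rev, collapse = "|"))
    ff_key(fwd) else ff_key(rev)
}

lookup_term <- function(records, key, section) {
  p <- records[[key]]
  if (is.null(p))
    stop(sprintf("missing %s parameter for type tuple '%s'", section, key))
  p
}

# ---- the fit vector theta -------------------------------------------------

# A parameter key is "<section>:<type key>:<field>", e.g. "stretch:C1|N1:kb".
# Positivity-constrained fields are handled in log space by the optimizer.
POSITIVE_FIELDS <- c("kb", "ka", "eps", "rstar")

parse_param_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L)
    stop("parameter key must be '<section>:<types>:<field>': ", key)
  list(section = parts[1], types = parts[2], field = parts[3])
}

#' Get force-field parameter values by key
#' @param ff a [ts_forcefield()].
#' @param keys character vector of `"section:types:field"` keys, e.g.
#'   `"stretch:C1|N1:kb"` or `"charge:N1:q"`.
#' @return named numeric vector of current values.
#' @export
ff_get_params <- function(ff, keys) {
  vapply(keys, function(key) {
    p <- parse_param_key(key)
    sec <- ff[[p$section]]
    if (is.null(sec)) stop("unknown force-field section: ", p$section)
    rec <- sec[[p$types]]
    if (is.null(rec)) stop("no ", p$section, " record for types ", p$types)
    if (p$section == "charge") return(as.numeric(rec))
    v <- rec[[p$field]]
    if (is.null(v)) stop("no field '", p$field, "' in ", p$section, " record")
    as.numeric(v)
  }, numeric(1))
}

#' Set force-field parameter values by key
#' @inheritParams ff_get_params
#' @param values numeric vector aligned with `keys`.
#' @return the modified `ts_forcefield`.
#' @export
ff_set_params <- function(ff, keys, values) {
  stopifnot(length(keys) == length(values))
  for (idx in seq_along(keys)) {
    p <- parse_param_key(keys[idx])
    if (p$section == "charge") {
      ff$charge[[p$types]] <- values[idx]
    } else {
      ff[[p$section]][[p$types]][[p$field]] <- values[idx]
    }
  }
  validate_forcefield(ff)
  ff
}

# ---- file I/O (JSON schema: sections stretch/bend/torsion/vdw/charge/meta)

#' Read / write force-field files
#'
#' The on-disk format is JSON with sections `stretch`, `bend`, `torsion`,
#' `vdw`, `charge` and `meta` (holding `dielectric`). Keys are the canonical
#' `"A|B"`-style type tuples; units are kJ/mol, Angstrom, degrees, e.
#'
#' @param path file path.
#' @return `read_forcefield` returns a [ts_forcefield()];
#'   `write_forcefield` returns `path` invisibly.
#' @export
read_forcefield <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  chg <- lapply(raw$charge, function(x) as.numeric(x))
  ts_forcefield(
    stretch = lapply(raw$stretch, function(x) list(kb = as.numeric(x$kb), r0 = as.numeric(x$r0))),
    bend = lapply(raw$bend, function(x) list(ka = as.numeric(x$ka), theta0 = as.numeric(x$theta0))),
    torsion = lapply(raw$torsion, function(x) list(v1 = as.numeric(x$v1), v2 = as.numeric(x$v2), v3 = as.numeric(x$v3))),
    vdw = lapply(raw$vdw, function(x) list(eps = as.numeric(x$eps), rstar = as.numeric(x$rstar))),
    charge = if (is.null(chg)) list() else chg,
    dielectric = if (is.null(raw$meta$dielectric)) 1.0 else as.numeric(raw$meta$dielectric))
}

#' @rdname read_forcefield
#' @param ff a [ts_forcefield()].
#' @export
write_forcefield <- function(ff, path) {
  obj <- list(stretch = ff$stretch, bend = ff$bend, torsion = ff$torsion,
              vdw = ff$vdw, charge = ff$charge,
              meta = list(dielectric = ff$dielectric,
                          units = "kJ/mol, Angstrom, degrees, e"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
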