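# Structure I/O. SDF/MOL V2000 carries connectivity; tsforge-specific data
# travel in data fields: TSFF_ATOM_TYPES (space-separated type labels),
# TSFF_CHARGES (space-separated partial charges, e), TSFF_FORMING_BOND
# ("i j", 1-based), TSFF_ENERGY_KJMOL, and -- for templates/fragments --
# TSFF_ANCHOR, TSFF_PRODUCT_CONFIG, TSFF_ALLYL_ISOMER. The molecule title
# line holds the structure label. Units: Angstrom throughout.

#' Read / write XYZ files
#'
#' Bare Cartesian geometries: atom count, comment line, then
#' `element x y z` rows (Angstrom). XYZ carries no connectivity; the reader
#' returns elements and coordinates only.
#'
#' @param path file path.
#' @return `read_xyz`: list with `elements` and `coords`; `write_xyz`
#'   returns `path` invisibly.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  list(elements = vapply(rows, `[[`, "", 1L),
       coords = matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))),
                       ncol = 3, byrow = TRUE))
}

#' @rdname read_xyz
#' @param s a [ts_structure()] (or any list with `elements` and `coords`).
#' @param comment comment-line text.
#' @export
write_xyz <- function(s, path, comment = "") {
  n <- nrow(s$coords)
  lines <- c(as.character(n), comment,
             sprintf("%-3s %14.8f %14.8f %14.8f", s$elements,
                     s$coords[, 1], s$coords[, 2], s$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

format_ctab <- function(s) {
  n <- n_atoms(s); m <- nrow(s$bonds)
  out <- c(if (nzchar(s$label)) s$label else "tsforge", "  tsforge", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        s$coords[, 1], s$coords[, 2], s$coords[, 3], s$elements))
  if (m > 0)
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0", s$bonds[, 1], s$bonds[, 2], 1L))
  c(out, "M  END")
}

sdf_field <- function(name, value) c(sprintf(">  <%s>", name), value, "")

structure_to_sdf_block <- function(s, extra_fields = list()) {
  out <- format_ctab(s)
  out <- c(out, sdf_field("TSFF_ATOM_TYPES", paste(s$types, collapse = " ")))
  out <- c(out, sdf_field("TSFF_CHARGES",
                          paste(sprintf("%.8g", s$charges), collapse = " ")))
  if (!is.null(s$forming_bond))
    out <- c(out, sdf_field("TSFF_FORMING_BOND",
                            paste(s$forming_bond, collapse = " ")))
  for (nm in names(extra_fields))
    out <- c(out, sdf_field(nm, as.character(extra_fields[[nm]])))
  c(out, "$$$$")
}

#' Write structures to an SDF (MOL V2000) file
#'
#' @param structures a single [ts_structure()] or a list of them.
#' @param path output file.
#' @param extra_fields named list (or list of named lists, one per record)
#'   of additional SDF data fields, e.g. `TSFF_ENERGY_KJMOL`.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(structures, path, extra_fields = list()) {
  if (inherits(structures, "ts_structure")) structures <- list(structures)
  per_record <- length(extra_fields) && is.null(names(extra_fields))
  blocks <- unlist(lapply(seq_along(structures), function(k) {
    ef <- if (per_record) extra_fields[[k]] else extra_fields
    structure_to_sdf_block(structures[[k]], ef)
  }))
  writeLines(blocks, path)
  invisible(path)
}

parse_sdf_block <- function(lines) {
  label <- trimws(lines[1])
  counts <- lines[4]
  n <- as.integer(substr(counts, 1, 3))
  m <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + n)]
  coords <- matrix(0, n, 3)
  elements <- character(n)
  for (a in seq_len(n)) {
    ln <- atom_lines[a]
    coords[a, ] <- as.numeric(c(substr(ln, 1, 10), substr(ln, 11, 20),
                                substr(ln, 21, 30)))
    elements[a] <- trimws(substr(ln, 32, 34))
  }
  bonds <- matrix(integer(0), ncol = 2)
  if (m > 0) {
    bl <- lines[(5 + n):(4 + n + m)]
    bonds <- cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)))
  }
  # data fields
  fields <- list()
  k <- 5 + n + m
  while (k <= length(lines)) {
    ln <- lines[k]
    if (grepl("^>", ln)) {
      nm <- sub(".*<([^>]+)>.*", "\\1", ln)
      vals <- character(0)
      k <- k + 1
      while (k <= length(lines) && nzchar(trimws(lines[k]))) {
        vals <- c(vals, lines[k]); k <- k + 1
      }
      fields[[nm]] <- paste(vals, collapse = "\n")
    }
    k <- k + 1
  }
  types <- if (!is.null(fields$TSFF_ATOM_TYPES))
    strsplit(trimws(fields$TSFF_ATOM_TYPES), "\\s+")[[1]] else elements
  charges <- if (!is.null(fields$TSFF_CHARGES))
    as.numeric(strsplit(trimws(fields$TSFF_CHARGES), "\\s+")[[1]])
  else numeric(n)
  forming <- if (!is.null(fields$TSFF_FORMING_BOND))
    as.integer(strsplit(trimws(fields$TSFF_FORMING_BOND), "\\s+")[[1]]) else NULL
  s <- ts_structure(elements, coords, bonds, types = types, charges = charges,
                    forming_bond = forming, label = label)
  attr(s, "sdf_fields") <- fields
  s
}

#' Read structures from an SDF (MOL V2000) file
#'
#' @param path input file.
#' @return a list of [ts_structure()] objects; each carries its raw data
#'   fields in the `sdf_fields` attribute.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path)
  breaks <- grep("^\\$\\$\\$\\$", lines)
  if (!length(breaks)) breaks <- length(lines) + 1L
  start <- 1L
  out <- list()
  for (b in breaks) {
    chunk <- lines[start:(b - 1L)]
    chunk <- chunk[cumsum(nzchar(trimws(chunk))) > 0 | seq_along(chunk) <= 3]
    if (sum(nzchar(trimws(chunk))) >= 2)
      out[[length(out) + 1L]] <- parse_sdf_block(chunk)
    start <- b + 1L
  }
  out
}

# ---- reference bundles ----------------------------------------------------

#' Read / write a quantum-reference bundle directory
#'
#' One directory per training structure holding `geometry.sdf` (geometry
#' plus connectivity, types, charges and forming bond), `hessian.txt` (first
#' line 3N, then 3N whitespace-separated rows, kJ/mol/A^2, atom-major
#' ordering), `charges.txt` (one charge per line, e) and `meta.json`
#' (`is_ts` flag, optional `ts_mode_eigenvalue` and per-class weight
#' overrides).
#'
#' @param dir bundle directory.
#' @return `read_reference_bundle` returns a `reference_structure` (see
#'   [reference_structure()]); the writer returns `dir` invisibly.
#' @export
read_reference_bundle <- function(dir) {
  s <- read_sdf(file.path(dir, "geometry.sdf"))[[1]]
  hl <- readLines(file.path(dir, "hessian.txt"))
  n3 <- as.integer(trimws(hl[1]))
  vals <- as.numeric(unlist(strsplit(trimws(hl[-1]), "\\s+")))
  H <- matrix(vals, n3, n3, byrow = TRUE)
  charges <- as.numeric(readLines(file.path(dir, "charges.txt")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  reference_structure(s, H, charges,
                      is_ts = isTRUE(meta$is_ts),
                      ts_mode_eigenvalue = meta$ts_mode_eigenvalue,
                      weight_overrides = meta$weights)
}

#' @rdname read_reference_bundle
#' @param ref a `reference_structure`.
#' @export
write_reference_bundle <- function(ref, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sdf(ref$structure, file.path(dir, "geometry.sdf"))
  H <- ref$hessian_ref
  writeLines(c(as.character(nrow(H)),
               apply(H, 1, function(r) paste(sprintf("%.12g", r), collapse = " "))),
             file.path(dir, "hessian.txt"))
  writeLines(sprintf("%.10g", ref$charges_ref), file.path(dir, "charges.txt"))
  jsonlite::write_json(
    list(is_ts = ref$is_ts, ts_mode_eigenvalue = ref$ts_mode_eigenvalue,
         weights = ref$weight_overrides),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
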