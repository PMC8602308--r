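#' Molecular structure with connectivity
#'
#' The basic container used throughout tsforge: a set of atoms with Cartesian
#' coordinates (Angstrom), element symbols, force-field atom-type labels,
#' partial charges (elementary charge units), an undirected bond list and an
#' optional *forming bond* -- the bond being created at the transition state,
#' which is modeled as a regular bonded term.
#'
#' @param elements character vector of element symbols (dummy atoms are "Du").
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param bonds integer m x 2 matrix of 1-based atom index pairs.
#' @param types character vector of atom-type labels; defaults to `elements`.
#' @param charges numeric vector of per-atom partial charges in e; default 0.
#' @param forming_bond optional length-2 integer vector; must also be listed
#'   in `bonds`.
#' @param label free-text label (e.g. `"R_exo"`), carried through assembly and
#'   conformational search.
#' @return an object of class `ts_structure`.
#' @export
ts_structure <- function(elements, coords, bonds,
                         types = elements,
                         charges = numeric(length(elements)),
                         forming_bond = NULL,
                         label = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (nrow(coords) != n || ncol(coords) != 3)
    stop("coords must be an N x 3 matrix matching length(elements)")
  if (!all(is.finite(coords)))
    stop("coords must be finite")
  if (length(types) != n || length(charges) != n)
    stop("types and charges must have one entry per atom")
  bonds <- canonical_bonds(bonds, n)
  if (!is.null(forming_bond)) {
    forming_bond <- sort(as.integer(forming_bond))
    if (length(forming_bond) != 2L)
      stop("forming_bond must be a pair of atom indices")
    if (!any(bonds[, 1] == forming_bond[1] & bonds[, 2] == forming_bond[2]))
      stop("forming_bond must also appear in bonds")
  }
  structure(
    list(elements = as.character(elements),
         types = as.character(types),
         charges = as.numeric(charges),
         coords = coords,
         bonds = bonds,
         forming_bond = forming_bond,
         label = as.character(label)[1]),
    class = "ts_structure")
}

# Validate, deduplicate and sort a bond matrix (i < j per row).
canonical_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || length(bonds) == 0L)
    return(matrix(integer(0), ncol = 2))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(bonds < 1L | bonds > n_atoms))
    stop("bond index out of range")
  if (any(bonds[, 1] == bonds[, 2]))
    stop("self-bonds are not allowed")
  bonds <- t(apply(bonds, 1, sort))
  bonds <- matrix(bonds, ncol = 2)
  if (anyDuplicated(bonds))
    stop("duplicate bonds are not allowed")
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

#' @export
print.ts_structure <- function(x, ...) {
  cat(sprintf("<ts_structure> %d atoms, %d bonds%s%s\n",
              n_atoms(x), nrow(x$bonds),
              if (!is.null(x$forming_bond))
                sprintf(", forming bond %d-%d", x$forming_bond[1], x$forming_bond[2])
              else "",
              if (nzchar(x$label)) paste0(", label '", x$label, "'") else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `ts_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) length(s$elements)

#' Adjacency list of the bond graph
#' @param s a `ts_structure`.
#' @return list of integer vectors, neighbors per atom (sorted).
#' @export
neighbors_list <- function(s) {
  n <- n_atoms(s)
  nb <- vector("list", n)
  for (r in seq_len(nrow(s$bonds))) {
    i <- s$bonds[r, 1]; j <- s$bonds[r, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) sort(unique(as.integer(v))))
}

# Breadth-first graph (bond-count) distances from every atom; Inf when
# disconnected. Small dense systems only -- O(N^2) is fine here.
graph_distances <- function(s) {
  n <- n_atoms(s)
  nb <- neighbors_list(s)
  d <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    d[src, src] <- 0
    frontier <- src
    depth <- 0L
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[!is.finite(d[src, nxt])]
      if (!length(nxt)) break
      d[src, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Atoms reachable from `from` without traversing the bond (a, b).
# Used to pick the moving side for torsion rotations and ring detection.
reachable_without_bond <- function(s, from, a, b) {
  nb <- neighbors_list(s)
  seen <- logical(n_atoms(s))
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in nb[[v]]) {
        if ((v == a && w == b) || (v == b && w == a)) next
        if (!seen[w]) { seen[w] <- TRUE; nxt <- c(nxt, w) }
      }
    }
    frontier <- nxt
  }
  which(seen)
}

#' Apply a rigid motion or reflection to a structure
#'
#' @param s a `ts_structure`.
#' @param rotation 3 x 3 matrix applied on the right of the coordinates
#'   (orthogonal for a rigid motion; a reflection is allowed and gives the
#'   mirror image).
#' @param translation length-3 numeric vector, Angstrom.
#' @return the transformed `ts_structure`.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  s$coords <- s$coords %*% t(rotation) +
    matrix(translation, n_atoms(s), 3, byrow = TRUE)
  s
}

#' Mirror image of a structure
#'
#' Reflects all coordinates through the yz plane. Molecular-mechanics
#' energies are invariant under reflection, so this yields the enantiomeric
#' geometry with an identical conformational energy landscape.
#' @param s a `ts_structure`.
#' @param label optional new label.
#' @return the reflected `ts_structure`.
#' @export
mirror_structure <- function(s, label = s$label) {
  s$coords[, 1] <- -s$coords[, 1]
  s$label <- label
  s
}
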