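#' Internal coordinates of a structure
#'
#' Enumerates every bond, every angle (paths i-j-k through the bond graph)
#' and every proper torsion (paths i-j-k-l with four distinct atoms), and
#' evaluates them at the current coordinates. The enumeration is a pure
#' function of the bond graph, so two structures with the same connectivity
#' yield entry-by-entry comparable lists -- this is the carrier for the
#' structural part of the internal validation of a fitted force field.
#'
#' @param s a [ts_structure()].
#' @return an object of class `internal_coords`: a list with components
#'   `bonds` (data.frame i, j, value in Angstrom), `angles` (i, j, k, value
#'   in degrees) and `torsions` (i, j, k, l, value in degrees, range
#'   (-180, 180]).
#' @export
build_internals <- function(s) {
  topo <- internal_topology(s)
  internals_at(topo, s$coords)
}

# Index sets only (no values); deterministic ordering.
internal_topology <- function(s) {
  nb <- neighbors_list(s)
  bonds <- s$bonds

  ang <- list()
  for (j in seq_len(n_atoms(s))) {
    nbj <- nb[[j]]
    if (length(nbj) < 2L) next
    cmb <- utils::combn(nbj, 2L)
    ang[[length(ang) + 1L]] <- cbind(cmb[1, ], j, cmb[2, ])
  }
  angles <- if (length(ang)) do.call(rbind, ang) else matrix(integer(0), ncol = 3)

  tor <- list()
  for (r in seq_len(nrow(bonds))) {
    j <- bonds[r, 1]; k <- bonds[r, 2]
    ni <- setdiff(nb[[j]], k)
    nl <- setdiff(nb[[k]], j)
    if (!length(ni) || !length(nl)) next
    grid <- expand.grid(i = ni, l = nl)
    grid <- grid[grid$i != grid$l, , drop = FALSE]
    if (nrow(grid))
      tor[[length(tor) + 1L]] <- cbind(grid$i, j, k, grid$l)
  }
  torsions <- if (length(tor)) do.call(rbind, tor) else matrix(integer(0), ncol = 4)

  list(bonds = bonds, angles = angles, torsions = torsions)
}

internals_at <- function(topo, coords) {
  b <- topo$bonds; a <- topo$angles; t4 <- topo$torsions
  structure(
    list(
      bonds = data.frame(i = b[, 1], j = b[, 2],
                         value = bond_values(coords, b)),
      angles = data.frame(i = a[, 1], j = a[, 2], k = a[, 3],
                          value = angle_values(coords, a)),
      torsions = data.frame(i = t4[, 1], j = t4[, 2], k = t4[, 3], l = t4[, 4],
                            value = torsion_values(coords, t4))),
    class = "internal_coords")
}

#' @export
print.internal_coords <- function(x, ...) {
  cat(sprintf("<internal_coords> %d bonds, %d angles, %d torsions\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions)))
  invisible(x)
}
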