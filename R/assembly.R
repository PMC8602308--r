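# Building competing diastereomeric TS structures by merging fragments onto
# authored templates. Stereochemical bookkeeping is declared on the
# template (product configuration and allyl isomer), not perceived from the
# geometry; the template author encodes which pathway each template models.
# Attachment geometry: the fragment is rigidly placed so its attachment
# bond is collinear with the anchor's dummy bond, then the new torsion is
# resolved by a coarse scan plus local refinement of either the MM energy
# (when a force field resolves all terms) or a soft steric score.

#' Transition-state template
#'
#' @param structure a [ts_structure()] whose dummy atoms (element `"Du"`)
#'   mark anchor sites; the forming bond must be set.
#' @param anchors named list: site name -> `list(dummy = <atom index>,
#'   class = "ligand"|"substrate_terminus"|"nucleophile")`. Every dummy atom
#'   must belong to exactly one site.
#' @param product_config `"R"` or `"S"`: the product configuration this
#'   template's pathway yields.
#' @param allyl_isomer `"exo"` or `"endo"`.
#' @return an object of class `ts_template`.
#' @export
ts_template <- function(structure, anchors, product_config, allyl_isomer) {
  if (!product_config %in% c("R", "S")) stop("product_config must be R or S")
  if (!allyl_isomer %in% c("exo", "endo")) stop("allyl_isomer must be exo or endo")
  dummies <- which(structure$elements == "Du")
  declared <- vapply(anchors, function(a) as.integer(a$dummy), integer(1))
  if (!setequal(dummies, declared) || anyDuplicated(declared))
    stop("every dummy atom must belong to exactly one anchor site")
  for (a in anchors)
    if (!a$class %in% c("ligand", "substrate_terminus", "nucleophile"))
      stop("unknown anchor class: ", a$class)
  structure(list(structure = structure, anchors = anchors,
                 product_config = product_config, allyl_isomer = allyl_isomer),
            class = "ts_template")
}

#' Attachable fragment
#'
#' @param structure a [ts_structure()] with exactly one dummy atom (element
#'   `"Du"`); removing it must leave the graph connected.
#' @param class fragment class: `"ligand"`, `"substrate_terminus"` or
#'   `"nucleophile"`.
#' @return an object of class `ts_fragment`.
#' @export
ts_fragment <- function(structure, class) {
  dummies <- which(structure$elements == "Du")
  if (length(dummies) != 1L) stop("fragment must have exactly one dummy atom")
  keep <- setdiff(seq_len(n_atoms(structure)), dummies)
  sub <- drop_atoms(structure, dummies)
  if (length(keep) > 1L) {
    reach <- reachable_without_bond(sub, 1L, 0L, 0L)
    if (length(reach) != n_atoms(sub))
      stop("removing the dummy must leave a connected fragment")
  }
  if (!class %in% c("ligand", "substrate_terminus", "nucleophile"))
    stop("unknown fragment class: ", class)
  structure(list(structure = structure, dummy = dummies, class = class),
            class = "ts_fragment")
}

# Remove atoms and remap bonds / forming bond.
drop_atoms <- function(s, drop) {
  keep <- setdiff(seq_len(n_atoms(s)), drop)
  remap <- integer(n_atoms(s))
  remap[keep] <- seq_along(keep)
  b <- s$bonds
  b <- b[!(b[, 1] %in% drop | b[, 2] %in% drop), , drop = FALSE]
  b <- cbind(remap[b[, 1]], remap[b[, 2]])
  fb <- s$forming_bond
  if (!is.null(fb)) {
    if (any(fb %in% drop)) fb <- NULL else fb <- remap[fb]
  }
  ts_structure(s$elements[keep], s$coords[keep, , drop = FALSE], b,
               types = s$types[keep], charges = s$charges[keep],
               forming_bond = fb, label = s$label)
}

# Soft steric score over cross pairs >= 3 bonds apart in the merged graph.
steric_score <- function(s, pairs) {
  d <- bond_values(s$coords, pairs)
  sum((1 / pmax(d, 0.05))^6)
}

#' Attach a fragment to an anchor site
#'
#' The fragment is rigidly rotated so its attachment bond is antiparallel to
#' the site's dummy bond, translated so the new bond takes the equilibrium
#' length of its stretch type (1.5 A when the force field does not resolve
#' the pair), both dummies are deleted and one new bond is created. The
#' remaining rotational freedom about the new bond is resolved by a 30-degree
#' scan (plus local refinement) of the MM energy when `ff` resolves every
#' term, otherwise of a soft steric score; scan points bringing any two
#' atoms closer than 0.7 A are rejected, and if every point clashes an error
#' is raised.
#'
#' @param host a [ts_template()] or a bare [ts_structure()] (partially
#'   assembled).
#' @param frag a [ts_fragment()].
#' @param site site name (when `host` is a template) or a list
#'   `list(dummy = <index>, class = <class>)`.
#' @param ff optional [ts_forcefield()] for bond length and torsion scoring.
#' @return the merged [ts_structure()]; host real atoms first (original
#'   order), fragment real atoms after. The attribute `new_bond` holds the
#'   created bond's atom indices.
#' @export
attach_fragment <- function(host, frag, site, ff = NULL) {
  if (inherits(host, "ts_template")) {
    anchor <- host$anchors[[site]]
    if (is.null(anchor)) stop("unknown anchor site: ", site)
    hs <- host$structure
  } else {
    anchor <- site
    hs <- host
  }
  if (!inherits(frag, "ts_fragment")) stop("frag must be a ts_fragment")
  if (anchor$class != frag$class)
    stop(sprintf("site accepts class '%s' but fragment is '%s'",
                 anchor$class, frag$class))
  fs <- frag$structure
  d_t <- anchor$dummy
  nb_t <- neighbors_list(hs)[[d_t]]
  if (length(nb_t) != 1L) stop("anchor dummy must have exactly one bond")
  a_t <- nb_t
  d_f <- frag$dummy
  a_f <- neighbors_list(fs)[[d_f]]
  if (length(a_f) != 1L) stop("fragment dummy must have exactly one bond")

  # bond length from the stretch record of the new typed bond, else 1.5 A
  key <- canon_stretch_key(hs$types[a_t], fs$types[a_f])
  r0 <- if (!is.null(ff) && !is.null(ff$stretch[[key]]))
    ff$stretch[[key]]$r0 else 1.5

  u <- hs$coords[d_t, ] - hs$coords[a_t, ]
  u <- u / sqrt(sum(u * u))
  v <- fs$coords[d_f, ] - fs$coords[a_f, ]
  rot <- rotation_between(v, -u)
  fc <- sweep(fs$coords, 2, fs$coords[a_f, ]) %*% t(rot)
  fc <- sweep(fc, 2, hs$coords[a_t, ] + r0 * u, FUN = "+")

  # merge (dummies dropped), host atoms first
  keep_t <- setdiff(seq_len(n_atoms(hs)), d_t)
  keep_f <- setdiff(seq_len(n_atoms(fs)), d_f)
  map_t <- integer(n_atoms(hs)); map_t[keep_t] <- seq_along(keep_t)
  map_f <- integer(n_atoms(fs)); map_f[keep_f] <- length(keep_t) + seq_along(keep_f)
  bt <- hs$bonds[!(hs$bonds[, 1] == d_t | hs$bonds[, 2] == d_t), , drop = FALSE]
  bf <- fs$bonds[!(fs$bonds[, 1] == d_f | fs$bonds[, 2] == d_f), , drop = FALSE]
  bonds <- rbind(cbind(map_t[bt[, 1]], map_t[bt[, 2]]),
                 cbind(map_f[bf[, 1]], map_f[bf[, 2]]),
                 c(map_t[a_t], map_f[a_f]))
  fb <- if (!is.null(hs$forming_bond)) map_t[hs$forming_bond] else NULL
  merged <- ts_structure(
    c(hs$elements[keep_t], fs$elements[keep_f]),
    rbind(hs$coords[keep_t, , drop = FALSE], fc[keep_f, , drop = FALSE]),
    bonds,
    types = c(hs$types[keep_t], fs$types[keep_f]),
    charges = c(hs$charges[keep_t], fs$charges[keep_f]),
    forming_bond = fb, label = hs$label)

  new_a <- map_t[a_t]; new_b <- map_f[a_f]
  host_idx <- seq_along(keep_t)
  frag_idx <- length(keep_t) + seq_along(keep_f)

  # Torsion resolution about the new bond scores the new fragment against
  # the ORIGINAL template core only (not previously attached fragments), so
  # the final geometry is independent of the order in which sites are
  # filled; the clash check below still covers every atom pair. Downstream
  # conformational search re-relaxes all of this, so the attachment torsion
  # only needs to avoid contacts.
  core_prev <- attr(hs, "core_atoms")
  core_now <- if (is.null(core_prev)) map_t[keep_t] else map_t[core_prev]
  gd <- graph_distances(merged)
  cross <- expand.grid(i = core_now, j = frag_idx)
  sep3 <- gd[cbind(cross$i, cross$j)] >= 3
  score_pairs <- matrix(as.integer(c(cross$i[sep3], cross$j[sep3])), ncol = 2)
  objective <- function(s2) steric_score(s2, score_pairs)
  clash_free <- function(s2) {
    all_pairs <- which(upper.tri(diag(n_atoms(s2))), arr.ind = TRUE)
    bonded <- gd[all_pairs] <= 1
    min(bond_values(s2$coords, all_pairs[!bonded, , drop = FALSE])) >= 0.7
  }
  rotate_about_new_bond <- function(delta) {
    axis <- merged$coords[new_b, ] - merged$coords[new_a, ]
    rotm <- axis_angle_rotation(axis, delta * pi / 180)
    out <- merged
    out$coords[frag_idx, ] <-
      sweep(sweep(out$coords[frag_idx, , drop = FALSE], 2,
                  out$coords[new_a, ]) %*% t(rotm),
            2, out$coords[new_a, ], FUN = "+")
    out
  }
  if (length(frag_idx) > 1L && length(host_idx) > 1L) {
    grid <- seq(0, 330, by = 30)
    vals <- rep(NA_real_, length(grid))
    for (g in seq_along(grid)) {
      cand <- rotate_about_new_bond(grid[g])
      if (clash_free(cand)) vals[g] <- objective(cand)
    }
    if (all(is.na(vals)))
      stop("unresolvable steric clash: every scan point has contacts < 0.7 A")
    g0 <- grid[which.min(vals)]
    refine <- stats::optimize(function(dd) {
      cand <- rotate_about_new_bond(dd)
      if (!clash_free(cand)) return(1e30)
      objective(cand)
    }, interval = c(g0 - 30, g0 + 30), tol = 1e-4)
    merged <- rotate_about_new_bond(refine$minimum)
    if (!clash_free(merged)) merged <- rotate_about_new_bond(g0)
  } else if (!clash_free(merged)) {
    stop("unresolvable steric clash: contacts < 0.7 A after attachment")
  }
  attr(merged, "new_bond") <- c(new_a, new_b)
  attr(merged, "core_atoms") <- core_now
  merged
}

#' Enumerate assembled diastereomeric TS structures
#'
#' For every template, attaches the fragment matching each anchor site's
#' class (sites are filled in sorted name order, so the atom ordering of the
#' result is canonical), and labels the assembly
#' `"<product_config>_<allyl_isomer>"`. Templates whose assembly fails are
#' skipped with a warning; if either product configuration ends up with no
#' structure at all the enumeration errors, because selectivity would be
#' undefined.
#'
#' @param templates list of [ts_template()]s covering both configurations.
#' @param fragments named or unnamed list of [ts_fragment()]s; each anchor
#'   site takes the first fragment of its class.
#' @param ff optional [ts_forcefield()] passed to [attach_fragment()].
#' @return list of labeled [ts_structure()]s.
#' @export
enumerate_ts <- function(templates, fragments, ff = NULL) {
  if (!length(templates)) stop("empty template list")
  frag_classes <- vapply(fragments, function(f) f$class, character(1))
  out <- list()
  for (tp in templates) {
    res <- tryCatch({
      s <- NULL
      for (site in sort(names(tp$anchors))) {
        anchor <- tp$anchors[[site]]
        fi <- which(frag_classes == anchor$class)[1]
        if (is.na(fi))
          stop("no fragment of class ", anchor$class)
        if (is.null(s)) {
          s <- attach_fragment(tp, fragments[[fi]], site, ff = ff)
        } else {
          # dummies keep their identity through merging: recompute index
          d_now <- which(s$elements == "Du")
          target_type <- tp$structure$types[anchor$dummy]
          d_idx <- d_now[s$types[d_now] == target_type][1]
          if (is.na(d_idx)) stop("anchor dummy lost during assembly")
          s <- attach_fragment(s, fragments[[fi]],
                               list(dummy = d_idx, class = anchor$class),
                               ff = ff)
        }
      }
      s$label <- paste(tp$product_config, tp$allyl_isomer, sep = "_")
      s
    }, error = function(e) {
      warning("template ", tp$product_config, "_", tp$allyl_isomer,
              " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  labs <- vapply(out, function(s) substr(s$label, 1, 1), character(1))
  if (!all(c("R", "S") %in% labs))
    stop("an entire configuration class is empty; selectivity undefined")
  out
}
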