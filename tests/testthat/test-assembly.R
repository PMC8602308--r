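# Fragment merging onto labeled TS templates.

# Planar core with one ligand anchor (dummy atom 4 on atom 1).
mk_template <- function(config = "R") {
  th <- 112 * pi / 180
  core <- ts_structure(
    c("C", "C", "N", "Du"),
    rbind(c(0, 0, 0), c(1.5, 0, 0),
          c(1.5 - 1.5 * cos(th), 1.5 * sin(th), 0),
          c(-1.5 * cos(th), -1.5 * sin(th), 0)),
    rbind(c(1, 2), c(2, 3), c(1, 4)),
    types = c("A1", "A2", "A3", "DL"),
    charges = c(0.05, -0.1, 0.05, 0),
    forming_bond = c(2, 3), label = "core")
  if (config == "S") core <- mirror_structure(core)
  ts_template(core, list(L = list(dummy = 4L, class = "ligand")),
              product_config = config, allyl_isomer = "exo")
}

mk_chain_fragment <- function(n = 3, class = "ligand") {
  xy <- matrix(0, n + 1, 3)
  dirs <- rbind(c(1, 0, 0), c(0.4, 0.9, 0))
  for (a in 2:(n + 1)) xy[a, ] <- xy[a - 1, ] + 1.5 * dirs[(a %% 2) + 1, ]
  ts_fragment(ts_structure(c("Du", rep("C", n)), xy, cbind(1:n, 2:(n + 1)),
                           types = c("DL", paste0("L", 1:n)),
                           charges = c(0, 0.08 * (-1)^(1:n))),
              class = class)
}

test_that("type and class invariants of templates and fragments hold", {
  tpl <- mk_template()
  expect_error(ts_template(tpl$structure, list(), "R", "exo"), "dummy")
  expect_error(ts_template(tpl$structure, tpl$anchors, "Q", "exo"), "R or S")
  frag <- mk_chain_fragment()
  expect_error(ts_fragment(frag$structure, "solvent"), "unknown")
  expect_error(attach_fragment(mk_template(), mk_chain_fragment(class = "nucleophile"), "L"),
               "class")
})

test_that("attach merges atoms, creates the typed bond, drops dummies", {
  tpl <- mk_template()
  # single-heavy-atom fragment: one more real atom than the template has
  tiny <- ts_fragment(
    ts_structure(c("Du", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                 rbind(c(1, 2)), types = c("DL", "L1")), "ligand")
  out <- attach_fragment(tpl, tiny, "L")
  expect_equal(n_atoms(out), 4)          # 3 real template atoms + 1
  expect_false(any(out$elements == "Du"))
  expect_equal(out$forming_bond, c(2L, 3L))

  # created bond takes the r0 of its stretch type
  ff <- complete_forcefield(attach_fragment(tpl, mk_chain_fragment(), "L"))
  ff$stretch[["A1|L1"]] <- list(kb = 1800, r0 = 1.47)
  out2 <- attach_fragment(tpl, mk_chain_fragment(), "L", ff = ff)
  nb <- attr(out2, "new_bond")
  expect_equal(sqrt(sum((out2$coords[nb[1], ] - out2$coords[nb[2], ])^2)),
               1.47, tolerance = 1e-6)
  # and 1.5 A when no force field resolves the pair
  out3 <- attach_fragment(tpl, mk_chain_fragment(), "L")
  nb3 <- attr(out3, "new_bond")
  expect_equal(sqrt(sum((out3$coords[nb3[1], ] - out3$coords[nb3[2], ])^2)),
               1.5, tolerance = 1e-6)
})

test_that("the attachment torsion matches an exhaustive 1-degree scan", {
  tpl <- mk_template()
  frag <- mk_chain_fragment()
  out <- attach_fragment(tpl, frag, "L")
  nb <- attr(out, "new_bond")
  core_idx <- 1:3
  frag_idx <- 4:6
  gd <- tsforge:::graph_distances(out)
  cross <- expand.grid(i = core_idx, j = frag_idx)
  keep <- gd[cbind(cross$i, cross$j)] >= 3
  pairs <- cbind(cross$i[keep], cross$j[keep])
  score <- function(s) {
    d <- sqrt(rowSums((s$coords[pairs[, 1], , drop = FALSE] -
                       s$coords[pairs[, 2], , drop = FALSE])^2))
    sum((1 / pmax(d, 0.05))^6)
  }
  quad <- c(2L, nb, which(out$types == "L2"))
  grid <- -179:180
  es <- vapply(grid, function(phi)
    score(tsforge:::set_torsion(out, quad, phi)), numeric(1))
  best <- grid[which.min(es)]
  got <- tsforge:::torsion_values(out$coords, matrix(quad, 1))
  expect_lt(abs(tsforge:::wrap_angle(got - best)), 1)
})

test_that("enumerate_ts labels assemblies and guards configuration classes", {
  tplR <- mk_template("R"); tplS <- mk_template("S")
  frag <- mk_chain_fragment()
  draft <- attach_fragment(tplR, frag, "L")
  ff <- complete_forcefield(draft)
  out <- enumerate_ts(list(tplR, tplS), list(frag), ff = ff)
  expect_length(out, 2)
  expect_setequal(vapply(out, `[[`, "", "label"), c("R_exo", "S_exo"))
  expect_error(enumerate_ts(list(), list(frag)), "empty template")
  expect_error(enumerate_ts(list(tplR), list(frag), ff = ff),
               "configuration class")
})

test_that("mirror-related assemblies have identical MM energy surfaces", {
  mp <- make_mirror_ts_pair(ligand_atoms = 3)
  eR <- attr(minimize(mp$structures[[1]], mp$ff), "energy")
  eS <- attr(minimize(mp$structures[[2]], mp$ff), "energy")
  expect_equal(eR, eS, tolerance = 1e-4)
})

test_that("site fill order does not change the assembled geometry", {
  # two anchor sites far apart on a rigid core; fill L then N vs N then L
  core <- ts_structure(
    c("C", "C", "C", "Du", "Du"),
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0),
          c(-1.06, 1.06, 0), c(4.06, 1.06, 0)),
    rbind(c(1, 2), c(2, 3), c(1, 4), c(3, 5)),
    types = c("A1", "A2", "A3", "DL", "DN"),
    forming_bond = c(1, 2), label = "core2")
  tpl <- ts_template(core,
                     list(L = list(dummy = 4L, class = "ligand"),
                          N = list(dummy = 5L, class = "nucleophile")),
                     "R", "exo")
  lig <- mk_chain_fragment(2, "ligand")
  nuc <- ts_fragment(
    ts_structure(c("Du", "N"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                 rbind(c(1, 2)), types = c("DN", "Nu")), "nucleophile")
  a1 <- attach_fragment(tpl, lig, "L")
  d1 <- which(a1$elements == "Du")
  a1 <- attach_fragment(a1, nuc, list(dummy = d1, class = "nucleophile"))
  a2 <- attach_fragment(tpl, nuc, "N")
  d2 <- which(a2$elements == "Du")
  a2 <- attach_fragment(a2, lig, list(dummy = d2, class = "ligand"))
  # canonical reindex: sort atoms by type label, then compare geometries
  canon <- function(s) s$coords[order(s$types), ]
  expect_lt(superpose_rmsd(canon(a1), canon(a2)), 1e-6)
})

test_that("unresolvable clashes raise an error", {
  tpl <- mk_template()
  # a fragment that folds straight back onto the template core
  bad <- ts_fragment(
    ts_structure(c("Du", "C", "C"),
                 rbind(c(0, 0, 0), c(1.5, 0, 0), c(1.5, 0, 1.4)),
                 rbind(c(1, 2), c(2, 3)),
                 types = c("DL", "L1", "L2")), "ligand")
  # point the anchor bond INTO the core: the placed atom lands on atom 2,
  # which no torsion position can resolve
  sq <- tpl$structure
  sq$coords[4, ] <- c(0.75, 0, 0)
  tpl2 <- ts_template(sq, tpl$anchors, "R", "exo")
  expect_error(attach_fragment(tpl2, bad, "L"), "clash")
})
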