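test_that("default core has the canonical bead counts on the right shells", {
  core <- build_core(144, 60, seed = 0)
  expect_identical(sum(core$type == "Au"), 144L)
  expect_identical(sum(core$type == "CD"), 60L)
  expect_identical(length(core$rigid), 204L)
  # CD beads sit on the outer shell
  r_cd <- sqrt(rowSums(core$positions[core$type == "CD", ]^2))
  expect_equal(r_cd, rep(core$radius, 60), tolerance = 1e-12)
  r_au <- sqrt(rowSums(core$positions[core$type == "Au", ]^2))
  expect_true(all(r_au < core$radius))
})

test_that("degenerate single-CD core is a bead at the origin", {
  core <- build_core(0, 1, seed = 0)
  expect_identical(core$type, "CD")
  expect_equal(core$positions, matrix(0, 1, 3))
})

test_that("core generation is overlap-free and deterministic in the seed", {
  c1 <- build_core(12, 12, radius = 0.5, seed = 0)
  c2 <- build_core(12, 12, radius = 0.5, seed = 0)
  c3 <- build_core(12, 12, radius = 0.5, seed = 9)
  expect_identical(c1$positions, c2$positions)
  expect_false(isTRUE(all.equal(c1$positions, c3$positions)))
  expect_gt(min(dist(c1$positions)), 0)
  expect_error(build_core(-1, 10), "non-negative")
  expect_error(build_core(144, 60, radius = 0.3), "radius too small")
})

test_that("externally supplied coordinates override generation", {
  xyz <- matrix(rnorm(9), 3, 3)
  core <- build_core(1, 2, coords = xyz)
  expect_equal(core$positions, xyz, ignore_attr = TRUE)
  expect_error(build_core(1, 1, coords = xyz), "matrix")
})

test_that("grafting gives every CD exactly one ligand with exact composition", {
  core <- build_core(144, 60, seed = 0)
  np <- graft_ligands(core, list(ot_template()), 1.0, seed = 1)
  expect_identical(length(np$ligands), 60L)
  expect_identical(sum(np$charge), 0)

  np2 <- graft_ligands(core, list(ot_template(), mua_template()),
                       c(0.5, 0.5), seed = 1)
  tpl <- vapply(np2$ligands, `[[`, "", "template")
  expect_identical(sum(tpl == "OT"), 30L)
  expect_identical(sum(tpl == "MUA"), 30L)
  expect_identical(sum(np2$charge), -30)
  # CD grafting points are all distinct and cover every CD
  expect_setequal(vapply(np2$ligands, `[[`, integer(1), "cd"),
                  which(core$type == "CD"))
})

test_that("ligand assignment permutes with the seed but keeps composition", {
  core <- build_core(12, 12, radius = 0.5, seed = 0)
  t2 <- list(ot_template(), mua_template())
  a <- graft_ligands(core, t2, c(0.5, 0.5), seed = 1)
  b <- graft_ligands(core, t2, c(0.5, 0.5), seed = 2)
  ta <- vapply(a$ligands, `[[`, "", "template")
  tb <- vapply(b$ligands, `[[`, "", "template")
  expect_identical(sort(ta), sort(tb))
  expect_false(identical(ta, tb))
  expect_identical(graft_ligands(core, t2, c(0.5, 0.5), seed = 1)$positions,
                   a$positions)
})

test_that("non-integral ligand splits are rejected", {
  core <- build_core(12, 11, radius = 0.5, seed = 0)
  expect_error(graft_ligands(core, list(ot_template(), mua_template()),
                             c(0.5, 0.5)), "non-integral")
})

test_that("rigid group contains exactly the core beads", {
  core <- build_core(12, 12, radius = 0.5, seed = 0)
  np <- graft_ligands(core, list(ot_template()), 1.0, seed = 1)
  expect_identical(np$rigid_group, 1:24)
  shell <- setdiff(seq_along(np$type), np$rigid_group)
  expect_false(any(np$type[shell] %in% c("Au", "CD")))
  expect_true(all(np$type[np$rigid_group] %in% c("Au", "CD")))
})

test_that("ligand templates map to the declared bead sequences", {
  expect_identical(ot_template()$bead_sequence, c("CM2", "CM2", "CM2", "CT2"))
  expect_identical(mua_template()$bead_sequence,
                   c("CM2", "CM2", "CM", "CM", "ASP"))
})

test_that("lattice placement produces n_side^3 copies at safe distances", {
  np <- tiny_np()
  s27 <- place_lattice(np, 3, 1.2, 4.5, seed = 1)
  expect_identical(length(s27$nps), 27L)
  expect_identical(length(s27$type), 27L * length(np$type))

  s1 <- place_lattice(np, 1, 5, 4, seed = 1)
  expect_identical(length(s1$nps), 1L)

  s8 <- place_lattice(np, 2, 1.8, 4, seed = 1)
  centers <- t(vapply(s8$nps, function(g)
    colSums(s8$positions[g$core, ] * s8$mass[g$core]) /
      sum(s8$mass[g$core]), numeric(3)))
  dmin <- Inf
  for (i in 1:7) for (j in (i + 1):8) {
    d <- abs(centers[i, ] - centers[j, ])
    d <- d - 4 * round(d / 4)
    dmin <- min(dmin, sqrt(sum(d^2)))
  }
  expect_gte(dmin, 1.8 - 1e-9)
  expect_error(place_lattice(np, 3, 2, 4), "too small")
})

test_that("solvation honours counts, exclusion zones and box validity", {
  empty <- cgnp:::empty_system(c(5, 5, 5))
  s <- solvate(empty, count = 1000, seed = 1)
  expect_identical(sum(s$type == "W"), 1000L)

  np <- tiny_np()
  sys <- place_lattice(np, 1, 1, 4.5, seed = 1)
  sys <- solvate(sys, density = 3, seed = 1, exclusion = 0.4)
  solv <- sys$solvent_idx
  solute <- setdiff(seq_along(sys$type), solv)
  dmin <- Inf
  for (i in solute) {
    d <- abs(sweep(sys$positions[solv, , drop = FALSE], 2, sys$positions[i, ]))
    d <- d - matrix(4.5, length(solv), 3) * round(d / 4.5)
    dmin <- min(dmin, sqrt(min(rowSums(d * d))))
  }
  expect_gt(dmin, 0.4)
  expect_error(solvate(cgnp:::empty_system(c(0, 0, 0)), count = 10),
               "box")
})

test_that("neutralization adds the counterions and salt pairs the box demands", {
  np <- tiny_np(fractions = c(0.5, 0.5),
                templates = list(ot_template(), mua_template()))
  sys <- place_lattice(np, 1, 1, 4.5, seed = 1)
  sys <- solvate(sys, count = 400, seed = 1)
  neut <- neutralize_and_salt(sys, 0, seed = 5)
  expect_identical(sum(neut$type == "SOD"), 6L)  # one per MUA ligand
  expect_identical(sum(neut$charge), 0)

  # neutral solute, no salt: nothing to add
  np_ot <- tiny_np()
  s2 <- solvate(place_lattice(np_ot, 1, 1, 4.5, seed = 1), count = 100, seed = 1)
  expect_identical(neutralize_and_salt(s2, 0), s2)

  # 100 mM in a 10x10x10 box: round(0.1 * 0.6022 / nm^3 * 1000 nm^3) pairs
  wbox <- solvate(cgnp:::empty_system(c(10, 10, 10)), count = 7000, seed = 1)
  salted <- neutralize_and_salt(wbox, 0.1, seed = 2)
  expect_identical(sum(salted$type == "SOD"), 60L)
  expect_identical(sum(salted$type == "CLA"), 60L)
  expect_identical(sum(salted$charge), 0)
  expect_error(neutralize_and_salt(
    solvate(cgnp:::empty_system(c(10, 10, 10)), count = 10, seed = 1), 0.1),
    "not enough solvent")
})

test_that("the default 50%OT nanoparticle pipeline reproduces printed counts", {
  core <- build_core(144, 60, seed = 0)
  np <- graft_ligands(core, list(ot_template(), mua_template()),
                      c(0.5, 0.5), seed = 1)
  expect_identical(sum(core$type == "Au"), 144L)
  expect_identical(length(np$ligands), 60L)
  expect_identical(sum(np$charge), -30)
})
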