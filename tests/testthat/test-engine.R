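ff <- default_forcefield()

two_bead_system <- function(r, types = c("W", "W"), box = 6) {
  sys <- cgnp:::empty_system(rep(box, 3))
  sys$positions <- rbind(c(1, 1, 1), c(1 + r, 1, 1))
  sys$type <- types
  sys$charge <- cgnp:::bead_property(ff, types, "charge")
  sys$mass <- cgnp:::bead_property(ff, types, "mass")
  sys$molecule <- 1:2
  sys
}

test_that("neighbour list equals brute force and honours exclusions", {
  sys <- w_fluid(100, box = 4, seed = 1)
  nl <- build_neighbor_list(sys, cutoff = 1.5)
  # O(N^2) oracle
  want <- NULL
  for (i in 1:99) for (j in (i + 1):100) {
    d <- abs(sys$positions[i, ] - sys$positions[j, ])
    d <- d - 4 * round(d / 4)
    if (sum(d^2) < 1.5^2) want <- rbind(want, c(i, j))
  }
  expect_identical(nl[order(nl[, 1], nl[, 2]), , drop = FALSE],
                   want[order(want[, 1], want[, 2]), , drop = FALSE])

  # two beads beyond / within cutoff
  sys2 <- two_bead_system(1.4)
  expect_identical(nrow(build_neighbor_list(sys2, 1.5)), 1L)
  expect_identical(nrow(build_neighbor_list(sys2, 1.3)), 0L)

  # bonded pair and rigid-partner pair excluded
  sys2$bonds <- data.frame(i = 1, j = 2, type_i = "W", type_j = "W")
  expect_identical(nrow(build_neighbor_list(sys2, 1.5)), 0L)
  sys3 <- two_bead_system(1.4)
  sys3$rigid_groups <- list(1:2)
  expect_identical(nrow(build_neighbor_list(sys3, 1.5)), 0L)
})

test_that("pair energies at landmarks: zero beyond cutoff, -eps at the minimum", {
  p <- resolve_pair("W", "W", ff)
  far <- compute_forces(two_bead_system(1.6), ff,
                        engine_config(cutoff = 1.5))
  expect_identical(far$energy$lj, 0)
  rmin <- 3^(1 / 8) * p$sigma / 10
  atmin <- compute_forces(two_bead_system(rmin), ff, engine_config())
  expect_equal(atmin$energy$lj, -p$epsilon, tolerance = 1e-12)
  expect_lt(max(abs(atmin$forces)), 1e-8)
})

test_that("forces obey Newton's third law and decompose by term", {
  np <- tiny_np(fractions = c(0.5, 0.5),
                templates = list(ot_template(), mua_template()))
  sys <- solvated_np_system(np, n_w = 150)
  sys <- neutralize_and_salt(sys, 0.05, seed = 3)
  out <- compute_forces(sys, ff, engine_config())
  expect_lt(max(abs(colSums(out$forces))), 1e-9)
  expect_named(out$energy, c("bond", "angle", "lj", "coulomb",
                             "restraint", "total"))
  expect_true(out$energy$coulomb != 0)  # charged system engages Coulomb
  expect_equal(out$energy$total,
               with(out$energy, bond + angle + lj + coulomb + restraint))
})

test_that("overlapping beads trigger a descriptive error", {
  expect_error(compute_forces(two_bead_system(0.01), ff, engine_config()),
               "overlapping particles.*beads 1 and 2")
})

test_that("free particles travel in straight lines without forces", {
  sys <- two_bead_system(3, box = 10)
  v <- matrix(0, 2, 3); v[1, 1] <- 0.1
  cfg <- engine_config(timestep = 0.01, friction = 0, temperature = 0,
                       cutoff = 0.5)
  r <- run_md(sys, ff, cfg, 100, stride = 100, velocities = v)
  expect_equal(r$final$positions[1, 1], 1 + 0.1 * 1.0, tolerance = 1e-12)
  expect_equal(r$final$positions[2, ], c(4, 1, 1), tolerance = 1e-12)
})

test_that("bond oscillator period matches the closed form at small dt", {
  # U = k (b - b0)^2 with k = 2580 kJ/mol/nm^2 (CM-CM bond), mass 42.08
  sys <- cgnp:::empty_system(c(10, 10, 10))
  sys$positions <- rbind(c(5, 5, 5), c(5.504, 5, 5))  # stretched 0.14 nm
  sys$type <- c("CM", "CM")
  sys$charge <- c(0, 0); sys$mass <- c(42.08, 42.08); sys$molecule <- 1:2
  sys$bonds <- data.frame(i = 1, j = 2, type_i = "CM", type_j = "CM")
  cfg <- engine_config(timestep = 0.001, friction = 0, temperature = 0)
  r <- run_md(sys, ff, cfg, 6000, stride = 1, velocities = matrix(0, 2, 3))
  b <- abs(r$trajectory$coords[2, 1, ] - r$trajectory$coords[1, 1, ])
  peaks <- which(diff(sign(diff(b))) == -2) + 1
  measured <- mean(diff(r$trajectory$times[peaks]))
  mu <- 42.08 / 2
  k_b <- cgnp:::ff_bond_entry(ff, "CM", "CM")$k_b
  expect_equal(measured, 2 * pi * sqrt(mu / (2 * k_b)), tolerance = 1e-3)
  # total energy conserved to high precision
  expect_lt(diff(range(r$energies$total)) / mean(r$energies$kinetic + 1e-9),
            0.05)
})

test_that("NVE total energy is conserved on the LJ fluid", {
  sys <- w_fluid(200, box = 4, seed = 7)
  pre <- relax_system(sys, ff, n_steps = 3000)
  cfg <- engine_config(timestep = 0.005, friction = 0, seed = 3,
                       lj_shift = TRUE)
  r <- run_md(pre$system, ff, cfg, 10000, stride = 100,
              velocities = pre$velocities)
  e <- r$energies
  drift <- abs(e$total[nrow(e)] - e$total[1]) / mean(e$kinetic)
  expect_lt(drift, 1e-3)
})

test_that("Langevin thermostat equilibrates to the target temperature", {
  sys <- w_fluid(200, box = 4, seed = 7)
  pre <- relax_system(sys, ff)
  cfg <- engine_config(timestep = 0.01, friction = 5, temperature = 298,
                       seed = 11)
  r <- run_md(pre$system, ff, cfg, 6000, stride = 20)
  temps <- r$energies$temperature[-(1:100)]  # discard equilibration
  se <- sd(temps) / sqrt(length(temps) / 10)  # ~10-sample correlation blocks
  expect_lt(abs(mean(temps) - 298), 3 * se + 3)
})

test_that("rigid cores keep every internal distance exactly fixed", {
  np <- tiny_np()
  sys <- solvated_np_system(np, n_w = 150)
  cfg <- engine_config(timestep = 0.005, friction = 5, seed = 2)
  r <- run_md(sys, ff, cfg, 2000, stride = 2000)
  core <- sys$rigid_groups[[1]]
  d0 <- dist(sys$positions[core, ])
  dT <- dist(r$final$positions[core, ])
  expect_lt(max(abs(dT - d0)), 1e-8)
})

test_that("trajectories are deterministic under identical config and seed", {
  sys <- w_fluid(60, box = 3.5, seed = 4)
  cfg <- engine_config(timestep = 0.01, friction = 5, seed = 123)
  r1 <- run_md(sys, ff, cfg, 500, stride = 50)
  r2 <- run_md(sys, ff, cfg, 500, stride = 50)
  expect_identical(r1$trajectory$coords, r2$trajectory$coords)
  expect_identical(r1$energies, r2$energies)
})

test_that("COM restraint bias, forces and pulling advance as declared", {
  np <- tiny_np()
  sys <- place_lattice(np, 2, 3.5, 7.2, seed = 2)
  a <- sys$nps[[1]]$core; b <- sys$nps[[2]]$core

  # at r = r0 the bias force vanishes
  rst0 <- com_restraint(a, b, k = 1300, r0 = 3.5)
  rf <- restraint_force(sys$positions, sys$mass, sys$box, rst0)
  expect_equal(rf$reaction_coordinate, 3.5, tolerance = 1e-9)
  expect_lt(max(abs(rf$forces)), 1e-8)

  # declared no-half convention: k = 1300, displacement 0.1 -> U = 13
  rst1 <- com_restraint(a, b, k = 1300, r0 = 3.4)
  rf1 <- restraint_force(sys$positions, sys$mass, sys$box, rst1)
  expect_equal(rf1$energy, 13.0, tolerance = 1e-6)
  # half convention on request
  rf1h <- restraint_force(sys$positions, sys$mass, sys$box, rst1,
                          half = TRUE)
  expect_equal(rf1h$energy, 6.5, tolerance = 1e-6)
  # engine agrees with the reference evaluation
  eng <- compute_forces(sys, ff, engine_config(), restraint = rst1)
  expect_equal(eng$energy$restraint, 13.0, tolerance = 1e-6)
  expect_equal(eng$reaction_coordinate, 3.5, tolerance = 1e-9)

  # pulling at 0.001 nm/ps for 100 ps advances r0 by 0.1 nm
  pull <- com_restraint(a, b, k = 1300, r0 = 3.5, velocity = 0.001)
  cfg <- engine_config(timestep = 0.01, friction = 5, seed = 1)
  r <- run_md(sys, ff, cfg, 10000, stride = 1000, restraint = pull)
  expect_equal(r$final$r0, 3.6, tolerance = 1e-9)
})
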