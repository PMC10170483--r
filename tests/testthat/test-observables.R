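test_that("ideal-gas RDF is flat at one", {
  traj <- ideal_gas_frames(800, 5, n_frames = 30, seed = 3)
  # centre on one bead, target all others
  g <- rdf_around_center(traj, center_group = 1, target_group = 2:800,
                         r_max = 2.4, bin_width = 0.08)
  # Poisson tolerance: 3 sigma per bin from the expected count
  rho <- g$meta$rho_target
  expected <- rho * 4 / 3 * pi * diff(g$meta$edges^3) * g$n_frames
  skip_bins <- 2
  dev <- abs(g$g[-(1:skip_bins)] - 1)
  tol <- 3 / sqrt(expected[-(1:skip_bins)])
  expect_true(all(dev < pmax(tol, 0.05)))
  # integral of rho g(r) over shells recovers the mean target count
  recovered <- sum(g$g * rho * 4 / 3 * pi * diff(g$meta$edges^3))
  enclosed <- 4 / 3 * pi * 2.4^3 * rho
  expect_equal(recovered, enclosed, tolerance = 0.01)
})

test_that("a single fixed target puts all RDF mass in its own bin", {
  coords <- array(0, dim = c(2, 3, 1))
  coords[1, , 1] <- c(2, 2, 2)
  coords[2, , 1] <- c(2 + 0.73, 2, 2)
  traj <- cg_trajectory(coords, 5)
  g <- rdf_around_center(traj, 1, 2, r_max = 2, bin_width = 0.02)
  hit <- which(g$g > 0)
  expect_length(hit, 1)
  expect_true(abs(g$r[hit] - 0.73) <= 0.011)
})

test_that("RDF normalisation is density-independent", {
  g1 <- rdf_around_center(ideal_gas_frames(500, 5, 40, seed = 1),
                          1, 2:500, r_max = 2, bin_width = 0.1)
  g2 <- rdf_around_center(ideal_gas_frames(1000, 5, 40, seed = 2),
                          1, 2:1000, r_max = 2, bin_width = 0.1)
  expect_equal(mean(g1$g[-(1:2)]), mean(g2$g[-(1:2)]), tolerance = 0.03)
})

test_that("r_max beyond the half box is rejected", {
  traj <- ideal_gas_frames(10, 4, 1, seed = 1)
  expect_error(rdf_around_center(traj, 1, 2:10, r_max = 2.5),
               "half the smallest box edge")
})

test_that("NP-NP RDF peaks where the nanoparticles sit", {
  coords <- array(0, dim = c(2, 3, 5))
  for (f in 1:5) {
    coords[1, , f] <- c(3, 3, 3)
    coords[2, , f] <- c(3 + 2.4, 3, 3)
  }
  traj <- cg_trajectory(coords, 8)
  g <- np_np_rdf(traj, np_groups = list(1, 2), r_max = 3.5, bin_width = 0.1)
  expect_lte(abs(g$r[which.max(g$g)] - 2.4), 0.051)
  expect_error(np_np_rdf(centers = array(0, c(2, 3, 0)), r_max = 1),
               "empty trajectory|no box")
})

test_that("lattice of NP centres shows its first shell at the lattice spacing", {
  centers <- as.matrix(expand.grid(x = 1:3, y = 1:3, z = 1:3)) * 2.0
  arr <- array(centers, dim = c(27, 3, 1))
  attr(arr, "box") <- c(6, 6, 6)
  g <- np_np_rdf(centers = arr, r_max = 2.9, bin_width = 0.1)
  expect_lte(abs(g$r[which.max(g$g)] - 2.0), 0.051)
})

test_that("cluster detection handles singletons, chains and transitivity", {
  # all far apart: N singletons
  far <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0), 3, 3, byrow = TRUE)
  cl <- detect_clusters(far, cutoff = 1, box = c(10, 10, 10))
  expect_identical(cl$n_clusters, 3L)
  expect_identical(cl$sizes, rep(1L, 3))
  # chain A-B-C joined through consecutive links only
  chain <- matrix(c(0, 0, 0, 0.9, 0, 0, 1.8, 0, 0), 3, 3, byrow = TRUE)
  cl <- detect_clusters(chain, cutoff = 1, box = c(10, 10, 10))
  expect_identical(cl$n_clusters, 1L)
  expect_identical(cl$sizes, 3L)
})

test_that("cluster partition matches brute-force union-find on random configs", {
  withr::with_seed(7, {
    for (rep in 1:200) {
      n <- sample(3:25, 1)
      box <- c(6, 6, 6)
      centers <- matrix(runif(3 * n, 0, 6), n, 3)
      cutoff <- runif(1, 0.5, 2.5)
      got <- detect_clusters(centers, cutoff, box)$membership
      want <- uf_components(centers, cutoff, box)
      expect_identical(canon_partition(got), canon_partition(want))
    }
  })
})

test_that("aggregation kinetics tracks cluster membership over time", {
  # three NPs: all monomers for 3 frames, then two merge at frame 4
  coords <- array(0, dim = c(3, 3, 6))
  for (f in 1:6) {
    coords[1, , f] <- c(1, 1, 1)
    coords[2, , f] <- if (f >= 4) c(2.0, 1, 1) else c(4, 1, 1)
    coords[3, , f] <- c(7, 7, 7)
  }
  traj <- cg_trajectory(coords, 9)
  tr <- aggregation_kinetics(traj, np_groups = list(1, 2, 3), cutoff = 1.5)
  expect_equal(tr$fraction, c(0, 0, 0, 2 / 3, 2 / 3, 2 / 3))
  expect_identical(tr$n_clusters, c(3L, 3L, 3L, 2L, 2L, 2L))
  # all-monomer and fully merged extremes
  expect_true(all(aggregation_kinetics(traj, np_groups = list(1, 2, 3),
                                       cutoff = 0.1)$fraction == 0))
  expect_true(all(aggregation_kinetics(traj, np_groups = list(1, 2, 3),
                                       cutoff = 20)$fraction == 1))
})

test_that("exponential fit recovers noiseless kinetics exactly", {
  tr <- synthetic_kinetics(A = 0.6, tau = 200, t_grid = seq(0, 1000, 10))
  fit <- fit_exponential(tr)
  expect_true(fit$converged)
  expect_equal(fit$A, 0.6, tolerance = 1e-6)
  expect_equal(fit$tau, 200, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("exponential fit flags degenerate and recovers noisy traces", {
  zero <- aggregation_trace(seq(0, 100, 10), rep(0, 11))
  fit <- fit_exponential(zero)
  expect_equal(fit$A, 0)
  expect_true(fit$converged)
  expect_error(fit_exponential(aggregation_trace(1:3 * 1.0, rep(0, 3))),
               "at least 5")

  ok <- 0
  for (s in 1:10) {
    tr <- synthetic_kinetics(A = 0.6, tau = 200, noise = 0.05,
                             t_grid = seq(0, 1500, 10), seed = s)
    fit <- fit_exponential(tr)
    if (abs(fit$A - 0.6) <= 3 * fit$se_A) ok <- ok + 1
  }
  expect_gte(ok, 8)  # ~99.7% coverage per trial; 10 trials
})

test_that("convergence extrapolation separates plateaued from early traces", {
  plateaued <- synthetic_kinetics(A = 0.6, tau = 50, t_grid = seq(0, 1000, 10))
  out <- convergence_extrapolation(plateaued, horizon = 10000)
  expect_true(out$converged)
  expect_lt(out$change, 0.01)

  early <- synthetic_kinetics(A = 0.6, tau = 5000, t_grid = seq(0, 500, 10))
  out2 <- convergence_extrapolation(early, horizon = 50000)
  expect_false(out2$converged)
  # closed form: A (e^{-t_end/tau} - e^{-horizon/tau}) with fitted params
  pred <- abs(out2$fit$A * (exp(-500 / out2$fit$tau) -
                              exp(-50000 / out2$fit$tau)))
  expect_equal(out2$change, pred, tolerance = 1e-9)
  # threshold override respected
  expect_true(convergence_extrapolation(early, horizon = 50000,
                                        threshold = 1)$converged)
})
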