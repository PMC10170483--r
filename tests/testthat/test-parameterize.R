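test_that("relative entropy is the two-term KL sum on simple cases", {
  expect_identical(relative_entropy(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # P = (1, 0) vs Q = (1/2, 1/2): S -> ln 2 as the pseudocount vanishes
  expect_equal(relative_entropy(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-6)
  # asymmetry of the divergence
  p <- c(0.8, 0.15, 0.05); q <- c(0.3, 0.3, 0.4)
  expect_false(isTRUE(all.equal(relative_entropy(p, q),
                                relative_entropy(q, p))))
})

test_that("relative entropy validates bins and rejects empty input", {
  a <- binned_distribution(1:5, rep(0.2, 5))
  b <- binned_distribution(1:5 + 0.5, rep(0.2, 5))
  expect_error(relative_entropy(a, b), "mismatched bin grids")
  expect_error(relative_entropy(c(1, 0), c(0.5, 0.5, 0)),
               "mismatched bin grids")
  expect_error(relative_entropy(c(0, 0), c(1, 1)), "all-zero")
})

test_that("relative entropy is non-negative and zero only at equality", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      n <- sample(5:50, 1)
      p <- runif(n); q <- runif(n)
      s <- relative_entropy(p, q)
      expect_gte(s, 0)
    }
    # identity case across random shapes
    for (i in 1:50) {
      p <- runif(20)
      expect_lt(relative_entropy(p, p), 1e-12)
    }
  })
})

test_that("grid evaluation scores every cell against each feature target", {
  grid <- interaction_grid(c(3, 4, 5), c(0.1, 0.2, 0.3), "CD:W")
  target <- gaussian_feature_surrogate(4, 0.2)
  calls <- new.env(); calls$n <- 0
  sim <- function(sigma, epsilon, seed) {
    calls$n <- calls$n + 1
    gaussian_feature_surrogate(sigma, epsilon)
  }
  sf <- evaluate_grid(grid, sim, target)
  expect_identical(calls$n, 9)
  expect_named(sf, c("solvent", "shell"))
  expect_identical(dim(sf$solvent$values), c(3L, 3L))
  # the matching cell scores exactly zero, all others positive
  expect_equal(sf$solvent$values[2, 2], 0)
  expect_equal(sf$shell$values[2, 2], 0)
  expect_true(all(sf$solvent$values[-5] > 0))
  # surfaces increase monotonically away from the optimum on each axis
  expect_true(all(diff(sf$solvent$values[2:3, 2]) > 0))
  expect_true(all(diff(sf$solvent$values[2, 2:3]) > 0))
})

test_that("failed grid cells are flagged, not silently filled", {
  grid <- interaction_grid(c(3, 4), c(0.1, 0.2), "CD:W")
  target <- gaussian_feature_surrogate(3, 0.1)
  sim <- function(sigma, epsilon, seed) {
    if (sigma > 3.5) stop("simulation blew up")
    gaussian_feature_surrogate(sigma, epsilon)
  }
  sf <- suppressWarnings(evaluate_grid(grid, sim, target))
  expect_identical(sum(is.na(sf$solvent$values)), 2L)
  expect_length(sf$solvent$failures, 2)
  expect_match(sf$solvent$failures[[1]]$message, "blew up")
})

test_that("surface fitting selects the generating degree on a clean bowl", {
  grid <- interaction_grid(seq(3, 5, 0.5), seq(0.1, 0.5, 0.1), "CD:W")
  vals <- outer(grid$sigma, grid$epsilon,
                function(s, e) (s - 4)^2 + 10 * (e - 0.3)^2)
  surf <- structure(list(values = vals, sigma = grid$sigma,
                         epsilon = grid$epsilon, feature = "solvent",
                         pair = "CD:W", failures = list()),
                    class = "re_surface")
  fit <- fit_surface(surf, degrees = 2:5, seed = 1)
  expect_identical(fit$degree, 2L)
  expect_lt(fit$test_mse, 1e-12)
  expect_identical(fit$n_train, 20L)
  expect_identical(fit$n_test, 5L)
})

test_that("surface fitting does not overfit white noise", {
  grid <- interaction_grid(seq(3, 5, length.out = 6),
                           seq(0.1, 0.6, length.out = 6), "CD:W")
  vals <- withr::with_seed(3, matrix(rnorm(36), 6, 6))
  surf <- structure(list(values = vals, sigma = grid$sigma,
                         epsilon = grid$epsilon, feature = "solvent",
                         pair = "CD:W", failures = list()),
                    class = "re_surface")
  fit <- fit_surface(surf, degrees = 2:5, seed = 4)
  expect_lte(fit$degree, 3L)
})

test_that("combining surfaces preserves single-feature optima", {
  grid <- interaction_grid(seq(3, 5, 0.5), seq(0.1, 0.5, 0.1), "CD:W")
  mk <- function(s0, e0) {
    vals <- outer(grid$sigma, grid$epsilon,
                  function(s, e) (s - s0)^2 + 25 * (e - e0)^2)
    surf <- structure(list(values = vals, sigma = grid$sigma,
                           epsilon = grid$epsilon, feature = "f",
                           pair = "CD:W", failures = list()),
                      class = "re_surface")
    fit_surface(surf, degrees = 2:4, seed = 2)
  }
  m1 <- mk(4, 0.3)
  single <- combine_surfaces(list(m1), resolution = 10)
  opt1 <- select_optimum(single)
  expect_equal(opt1$sigma, 4, tolerance = 0.06)
  expect_equal(opt1$epsilon, 0.3, tolerance = 0.015)
  # two identical bowls: argmin unchanged
  both <- combine_surfaces(list(m1, mk(4, 0.3)), resolution = 10)
  expect_identical(select_optimum(both)$index, opt1$index)
  # two offset bowls: the combined minimum lies between the two
  mix <- combine_surfaces(list(mk(3.6, 0.2), mk(4.4, 0.4)), resolution = 10)
  optm <- select_optimum(mix)
  expect_gt(optm$sigma, 3.6); expect_lt(optm$sigma, 4.4)
  expect_gt(optm$epsilon, 0.2); expect_lt(optm$epsilon, 0.4)
})

test_that("optimum selection smooths single-cell spikes and breaks ties", {
  # constant matrix: smoothing is the identity; tie-break picks the
  # lowest-epsilon (then lowest-sigma) cell
  const <- list(values = matrix(1, 4, 4), sigma = 1:4, epsilon = 1:4)
  opt <- select_optimum(const)
  expect_identical(opt$index, c(1L, 1L))
  expect_true(all(opt$smoothed == 1))

  # a deep single-cell spike loses to a broad shallow basin
  m <- matrix(1, 5, 5)
  m[2, 2] <- -3                      # isolated spike
  m[4:5, 4:5] <- 0; m[4, 4] <- -0.5  # broad basin centred near (4:5, 4:5)
  comb <- list(values = m, sigma = 1:5, epsilon = 1:5)
  opt <- select_optimum(comb)
  expect_true(all(opt$index >= c(4L, 4L)))

  # smoothed argmin equals brute force over the smoothed matrix
  withr::with_seed(9, {
    for (i in 1:20) {
      m <- matrix(rnorm(30), 5, 6)
      sm <- cgnp:::smooth_neighbors(m)
      opt <- select_optimum(list(values = m, sigma = 1:5, epsilon = 1:6))
      expect_identical(opt$smoothed, sm)
      expect_equal(sm[opt$index[1], opt$index[2]], min(sm))
    }
  })
})

test_that("full pipeline recovers the optimum of the closed-form surrogate", {
  sstar <- 4.0; estar <- 0.3
  grid <- interaction_grid(seq(0.8, 1.2, 0.1) * sstar,
                           seq(0.8, 1.2, 0.1) * estar, "CD:W")
  target <- gaussian_feature_surrogate(sstar, estar)
  sim <- function(sigma, epsilon, seed)
    gaussian_feature_surrogate(sigma, epsilon, noise = 0.02, seed = seed)
  res <- derive_pair_parameters(grid, sim, target, seed = 5)
  expect_lte(abs(res$optimum$sigma - sstar), 0.05 * sstar)
  expect_lte(abs(res$optimum$epsilon - estar), 0.05 * estar)
  # determinism under the seed
  res2 <- derive_pair_parameters(grid, sim, target, seed = 5)
  expect_identical(res2$optimum, res$optimum)
})

test_that("Boltzmann inversion recovers harmonic bond parameters", {
  kb <- 0.0083144621; temp <- 298
  k_true <- 5000; b0 <- 0.35
  # sample from the exact Boltzmann density of U = k (b - b0)^2
  sd_true <- sqrt(kb * temp / (2 * k_true))
  samples <- withr::with_seed(21, rnorm(20000, b0, sd_true))
  inv <- boltzmann_invert(samples, temperature = temp, kind = "bond")
  expect_false(inv$flat); expect_false(inv$multimodal)
  expect_equal(inv$x_eq, b0, tolerance = 0.01 * b0)
  expect_equal(inv$k, k_true, tolerance = 0.10 * k_true)
  expect_s3_class(inv$params, "bond_params")

  # narrower distribution implies a stiffer bond
  tighter <- withr::with_seed(22, rnorm(20000, b0, sd_true / 2))
  expect_gt(boltzmann_invert(tighter, temp, "bond")$k, inv$k)
})

test_that("Boltzmann inversion of angles applies the sin Jacobian", {
  kb <- 0.0083144621; temp <- 298
  k_true <- 25; t0 <- 120  # kJ/mol/rad^2, degrees
  U <- function(th_deg) k_true * ((th_deg - t0) * pi / 180)^2
  # Metropolis samples on the sin-weighted density
  dens_U <- function(th) U(th) - kb * temp * log(sin(pmin(pmax(th, 1e-3),
                                                          180 - 1e-3) * pi / 180))
  samples <- boltzmann_sampler_1d(dens_U, temp, 30000, seed = 31, x0 = 120,
                                  step = 8)
  inv <- boltzmann_invert(samples, temperature = temp, kind = "angle")
  expect_equal(inv$x_eq, t0, tolerance = 2)
  expect_equal(inv$k, k_true, tolerance = 0.2 * k_true)
  expect_s3_class(inv$params, "angle_params")
})

test_that("flat and multimodal distributions are flagged", {
  flat <- withr::with_seed(5, runif(5000, 0.2, 0.6))
  inv <- boltzmann_invert(flat, kind = "bond")
  expect_true(inv$flat)
  expect_null(inv$params)

  bimodal <- withr::with_seed(6, c(rnorm(5000, 0.3, 0.01),
                                   rnorm(5000, 0.5, 0.01)))
  inv2 <- boltzmann_invert(bimodal, kind = "bond")
  expect_true(inv2$multimodal)
})
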