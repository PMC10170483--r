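ff <- default_forcefield()

test_that("LJ 9-6 form has its root at sigma and a well of depth epsilon", {
  p <- pair_params(4.0, 1.3, "lj9-6")
  expect_equal(lj96_energy(0.40, p), 0)
  rmin <- (3 / 2)^(1 / 3) * 0.40
  expect_equal(lj96_energy(rmin, p), -1.3, tolerance = 1e-12)
  expect_equal(lj96_force(rmin, p), 0, tolerance = 1e-10)
  # decays to zero at long range
  expect_lt(abs(lj96_energy(10, p)), 1e-7)
})

test_that("LJ 12-4 form has its root at sigma and a well of depth epsilon", {
  p <- pair_params(4.371, 3.74, "lj12-4")
  expect_equal(lj124_energy(0.4371, p), 0)
  rmin <- 3^(1 / 8) * 0.4371
  expect_equal(lj124_energy(rmin, p), -3.74, tolerance = 1e-12)
  expect_equal(lj124_force(rmin, p), 0, tolerance = 1e-8)
})

test_that("analytic LJ forces match central-difference derivatives", {
  withr::with_seed(42, {
    r <- runif(20, 0.3, 1.4)
    h <- 1e-7
    for (p in list(pair_params(4.1, 0.7, "lj9-6"),
                   pair_params(3.9, 2.2, "lj12-4"))) {
      fd <- -(lj_energy(r + h, p) - lj_energy(r - h, p)) / (2 * h)
      expect_equal(lj_force(r, p), fd, tolerance = 1e-6)
    }
  })
})

test_that("LJ energies and forces vanish beyond the cutoff", {
  p <- pair_params(4.0, 1.0, "lj9-6")
  expect_identical(lj96_energy(1.6, p, cutoff = 1.5), 0)
  expect_identical(lj96_force(1.6, p, cutoff = 1.5), 0)
  expect_error(lj96_energy(0, p))
})

test_that("harmonic bond follows the no-half convention and is symmetric", {
  p <- bond_params(k_b = 100, b_eq = 0.3)
  expect_equal(harmonic_bond(0.3, p), 0)
  expect_equal(harmonic_bond(0.4, p), 1.0)   # k (b - b0)^2 = 100 * 0.01
  d <- 0.07
  expect_equal(harmonic_bond(0.3 + d, p), harmonic_bond(0.3 - d, p))
})

test_that("harmonic angle follows the no-half convention in radians", {
  p <- angle_params(k_theta = 10, theta_eq = 120)
  expect_equal(harmonic_angle(120, p), 0)
  expect_equal(harmonic_angle(130, p), 10 * (10 * pi / 180)^2)
  expect_equal(harmonic_angle(110, p), harmonic_angle(130, p))
})

test_that("Lorentz-Berthelot combines sigma arithmetically, epsilon geometrically", {
  ff2 <- ff
  ff2$pairs[["A:A"]] <- pair_params(3, 0.1, "lj9-6")
  ff2$pairs[["B:B"]] <- pair_params(4, 0.4, "lj9-6")
  ff2$beads <- rbind(ff2$beads,
                     data.frame(name = c("A", "B"), mass = 1, charge = 0))
  p <- lorentz_berthelot("A", "B", ff2)
  expect_equal(p$sigma, 3.5)
  expect_equal(p$epsilon, 0.2)
  expect_identical(p$origin, "combination-rule")
  same <- lorentz_berthelot("A", "A", ff2)
  expect_equal(same$sigma, 3)
  expect_equal(same$epsilon, 0.1)
})

test_that("resolver reproduces the fitted core-decoy pair table", {
  cases <- list(
    list("CD", "CM",  0.2760, 3.798),
    list("CD", "CT2", 0.3284, 4.078),
    list("CD", "CM2", 0.2489, 4.176),
    list("CD", "W",   0.2517, 3.774),
    list("CD", "SOD", 0.2517, 3.774),
    list("CD", "CLA", 0.2517, 3.774))
  for (cs in cases) {
    p <- resolve_pair(cs[[1]], cs[[2]], ff)
    expect_identical(p$epsilon, cs[[3]])
    expect_identical(p$sigma, cs[[4]])
  }
})

test_that("similarity rules give CD:ASP the CD:CT2 parameters", {
  p <- resolve_pair("CD", "ASP", ff)
  expect_identical(p$epsilon, 0.3284)
  expect_identical(p$sigma, 4.078)
  expect_identical(p$origin, "similarity")
})

test_that("gold and CD-CD pairs are purely repulsive", {
  for (other in c("W", "CM", "ASP", "SOD", "Au", "CD")) {
    p <- resolve_pair("Au", other, ff)
    expect_identical(p$sigma, 4.0)
    expect_identical(p$epsilon, 1e-4)
  }
  p <- resolve_pair("CD", "CD", ff)
  expect_identical(p$sigma, 2.785)
  expect_identical(p$epsilon, 1e-4)
})

test_that("resolver is symmetric and total over all shipped bead pairs", {
  types <- ff$beads$name
  for (a in types) for (b in types) {
    pab <- resolve_pair(a, b, ff)
    pba <- resolve_pair(b, a, ff)
    expect_identical(pab$sigma, pba$sigma)
    expect_identical(pab$epsilon, pba$epsilon)
    expect_identical(pab$form, pba$form)
    # water pairs use 12-4, everything else 9-6
    expected_form <- if (a == "W" || b == "W") "lj12-4" else "lj9-6"
    expect_identical(pab$form, expected_form)
  }
  expect_error(resolve_pair("CD", "XX", ff), "unknown bead type")
})

test_that("force-field files round-trip exactly", {
  tmp <- tempfile(fileext = ".ff")
  write_forcefield(ff, tmp)
  ff2 <- read_forcefield(tmp)
  expect_equal(ff2$beads, ff$beads)
  expect_equal(ff2$pairs, ff$pairs)
  expect_equal(ff2$bonds, ff$bonds)
  expect_equal(ff2$angles, ff$angles)
  expect_equal(ff2$similarity, ff$similarity)
  expect_identical(ff2$dielectric, ff$dielectric)
})

test_that("malformed force-field files raise descriptive errors", {
  tmp <- tempfile(fileext = ".ff")
  writeLines("pair CD", tmp)
  expect_error(read_forcefield(tmp), "malformed pair record")
  writeLines("frobnicate 1 2", tmp)
  expect_error(read_forcefield(tmp), "unrecognised record")
  expect_error(read_forcefield(tempfile()), "not found")
})

test_that("bead charges match the electrostatic model", {
  ch <- setNames(ff$beads$charge, ff$beads$name)
  expect_identical(ch[["Au"]], 0)
  expect_identical(ch[["CD"]], 0)
  expect_identical(ch[["W"]], 0)
  expect_identical(ch[["ASP"]], -1)
  expect_identical(ch[["SOD"]], 1)
  expect_identical(ch[["CLA"]], -1)
})
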