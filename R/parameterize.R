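# Relative-entropy grid-search derivation of nonbonded pair parameters,
# polynomial surface fitting, surface combination and optimum selection,
# plus Boltzmann inversion for bonded terms.

#' Relative entropy between two binned distributions
#'
#' The Kullback-Leibler divergence `S = sum_x P(x) ln(P(x) / Q(x))` with
#' `P` the measured (coarse-grained) feature and `Q` the target. Both
#' inputs receive an additive pseudocount per bin before normalisation to
#' unit sum, which regularises empty bins; `S = 0` exactly iff `P = Q`,
#' and smaller values mean better superposition. The measure is
#' asymmetric in its arguments by construction.
#'
#' @param p,q [binned_distribution]s on the same bin grid, or bare numeric
#'   vectors of equal length.
#' @param pseudocount Additive regulariser per bin. Default `1e-10`.
#' @return Non-negative scalar divergence (nats).
#' @export
relative_entropy <- function(p, q, pseudocount = 1e-10) {
  if (inherits(p, "binned_distribution") || inherits(q, "binned_distribution")) {
    if (!(inherits(p, "binned_distribution") &&
          inherits(q, "binned_distribution")))
      stop("mix of binned_distribution and bare vector")
    if (length(p$x) != length(q$x) || max(abs(p$x - q$x)) > 1e-9)
      stop("mismatched bin grids")
    pv <- p$p; qv <- q$p
  } else {
    if (length(p) != length(q)) stop("mismatched bin grids")
    pv <- as.numeric(p); qv <- as.numeric(q)
  }
  if (sum(pv) <= 0 || sum(qv) <= 0) stop("all-zero distribution")
  pv <- pv + pseudocount; qv <- qv + pseudocount
  pv <- pv / sum(pv); qv <- qv / sum(qv)
  sum(pv * log(pv / qv))
}

#' Sigma/epsilon search grid
#'
#' The matrix of candidate pair parameters explored by the grid search.
#'
#' @param sigma Strictly increasing sigma values, Angstrom (>= 2 values).
#' @param epsilon Strictly increasing epsilon values, kJ/mol (>= 2 values).
#' @param pair Pair identity label, e.g. `"CD:W"`.
#' @return An object of class `interaction_grid`.
#' @export
interaction_grid <- function(sigma, epsilon, pair = "CD:W") {
  stopifnot(length(sigma) >= 2, length(epsilon) >= 2,
            all(diff(sigma) > 0), all(diff(epsilon) > 0))
  structure(list(sigma = as.numeric(sigma), epsilon = as.numeric(epsilon),
                 pair = pair),
            class = "interaction_grid")
}

#' Default search grid around a combination-rule guess
#'
#' Candidate values span +/- 20% around the Lorentz-Berthelot educated
#' guess for the pair, 5 points per axis.
#'
#' @param bead_i,bead_j Bead type labels.
#' @param ff Force field supplying diagonal parameters.
#' @param span Half-width as a fraction of the guess. Default 0.2.
#' @param n Points per axis. Default 5.
#' @return An [interaction_grid].
#' @export
grid_around_guess <- function(bead_i, bead_j, ff = ff_default_cached(),
                              span = 0.2, n = 5) {
  guess <- lorentz_berthelot(bead_i, bead_j, ff)
  interaction_grid(seq(guess$sigma * (1 - span), guess$sigma * (1 + span),
                       length.out = n),
                   seq(guess$epsilon * (1 - span), guess$epsilon * (1 + span),
                       length.out = n),
                   pair = pair_key(bead_i, bead_j))
}

#' Evaluate a search grid against target feature distributions
#'
#' For every `(sigma, epsilon)` cell, runs the injected
#' `simulate_and_measure` procedure and scores each measured feature
#' against its target with [relative_entropy], producing one
#' relative-entropy surface per feature. The simulation procedure is
#' injected so that tests (and the closed-form surrogate) can stand in
#' for real dynamics; every cell receives a deterministic seed derived
#' from `seed`.
#'
#' @param grid An [interaction_grid].
#' @param simulate_and_measure `function(sigma, epsilon, seed)` returning
#'   a named list of [binned_distribution]s (names must cover
#'   `names(targets)`).
#' @param targets Named list of target [binned_distribution]s, binned
#'   identically to the measured features.
#' @param seed Base integer seed.
#' @param pseudocount Passed to [relative_entropy].
#' @return Named list of `re_surface` objects (matrix `values` indexed
#'   `[sigma, epsilon]`, the grid axes, the feature label and any cell
#'   failures). Failed cells are `NA` and listed in `$failures`, never
#'   silently filled.
#' @export
evaluate_grid <- function(grid, simulate_and_measure, targets, seed = 1,
                          pseudocount = 1e-10) {
  stopifnot(inherits(grid, "interaction_grid"), length(targets) >= 1,
            !is.null(names(targets)))
  ns <- length(grid$sigma); ne <- length(grid$epsilon)
  surfaces <- lapply(targets, function(...)
    matrix(NA_real_, ns, ne, dimnames = list(NULL, NULL)))
  failures <- list()
  cell <- 0L
  for (i in seq_len(ns)) for (j in seq_len(ne)) {
    cell <- cell + 1L
    res <- tryCatch(
      simulate_and_measure(grid$sigma[i], grid$epsilon[j], seed + cell),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(i = i, j = j, sigma = grid$sigma[i], epsilon = grid$epsilon[j],
             message = conditionMessage(res))
      next
    }
    for (feat in names(targets)) {
      if (is.null(res[[feat]])) stop("feature '", feat,
                                     "' missing from simulation output")
      surfaces[[feat]][i, j] <-
        relative_entropy(res[[feat]], targets[[feat]], pseudocount)
    }
  }
  out <- lapply(names(targets), function(feat) {
    structure(list(values = surfaces[[feat]], sigma = grid$sigma,
                   epsilon = grid$epsilon, feature = feat,
                   pair = grid$pair, failures = failures,
                   n_evaluated = cell - length(failures)),
              class = "re_surface")
  })
  names(out) <- names(targets)
  out
}

#' @export
print.re_surface <- function(x, ...) {
  cat(sprintf("<re_surface '%s' (%s): %d x %d cells, min %.4g>\n",
              x$feature, x$pair, length(x$sigma), length(x$epsilon),
              min(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Fit a polynomial regression model to a relative-entropy surface
#'
#' Bivariate polynomial regression of the surface values on
#' `(sigma, epsilon)`. The cells are split into a training and a test set
#' (default 80:20, seeded); one model per candidate degree is fitted on
#' the training set and the degree minimising the test-set mean squared
#' error is selected (ties broken toward the lower degree).
#'
#' @param surface An `re_surface` from [evaluate_grid].
#' @param degrees Candidate polynomial total degrees. Default `2:5`.
#' @param split Training fraction. Default 0.8.
#' @param seed Integer seed for the split.
#' @param transform `"identity"` fits the scores directly; `"log"` fits
#'   `log(S)` and back-transforms predictions. The log scale stabilises
#'   the fit when the surface spans orders of magnitude (steeply
#'   divergent cells otherwise dominate the least-squares loss and can
#'   displace the fitted minimum). Default `"identity"`.
#' @param clip_quantile Scores above this quantile are capped before
#'   fitting. Divergent cells at the grid edge carry no information about
#'   the minimum's location beyond "much worse"; capping keeps their
#'   ordering while preventing them from dominating the regression.
#'   Default 1 (no clipping).
#' @param log_epsilon Fit the polynomial in `(sigma, log(epsilon))`
#'   coordinates. Epsilon is a positive scale parameter and
#'   relative-entropy valleys are typically more symmetric in its
#'   logarithm, which removes the vertex bias a quadratic fit suffers on
#'   a skewed valley. Default `FALSE`.
#' @return An object of class `fit_model`: selected `degree`, the fitted
#'   `lm` object, `test_mse`, the per-degree MSE table and the grid axes.
#' @export
fit_surface <- function(surface, degrees = 2:5, split = 0.8, seed = 1,
                        transform = c("identity", "log"),
                        clip_quantile = 1, log_epsilon = FALSE) {
  transform <- match.arg(transform)
  stopifnot(inherits(surface, "re_surface"), length(degrees) >= 1)
  dat <- expand.grid(sigma = surface$sigma, epsilon = surface$epsilon)
  dat$s <- as.vector(surface$values)
  dat <- dat[!is.na(dat$s), ]
  if (clip_quantile < 1)
    dat$s <- pmin(dat$s, stats::quantile(dat$s, clip_quantile))
  if (transform == "log") dat$s <- log(dat$s + 1e-12)
  dat$eps_c <- if (log_epsilon) log(dat$epsilon) else dat$epsilon
  n <- nrow(dat)
  n_train <- round(split * n)
  if (n_train < 3 || n_train >= n)
    stop("not enough cells (", n, ") for a ", split, " train/test split")
  n_train <- as.integer(n_train)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  train <- dat[idx, ]; test <- dat[-idx, ]
  fits <- lapply(degrees, function(d) {
    stats::lm(s ~ polym(sigma, eps_c, degree = d, raw = TRUE), data = train)
  })
  mses <- vapply(seq_along(degrees), function(k) {
    pred <- suppressWarnings(stats::predict(fits[[k]], newdata = test))
    if (anyNA(pred)) return(Inf)  # rank-deficient at this degree
    mean((pred - test$s)^2)
  }, numeric(1))
  best <- which.min(mses)  # first minimum = lowest degree on ties
  # degree chosen on the held-out cells; final coefficients use all cells
  final <- stats::lm(s ~ polym(sigma, eps_c, degree = degrees[best],
                               raw = TRUE), data = dat)
  structure(list(degree = degrees[best], model = final,
                 test_mse = mses[best],
                 mse_table = data.frame(degree = degrees, test_mse = mses),
                 sigma = surface$sigma, epsilon = surface$epsilon,
                 feature = surface$feature, split = split, seed = seed,
                 transform = transform, clip_quantile = clip_quantile,
                 log_epsilon = isTRUE(log_epsilon),
                 n_train = n_train, n_test = n - n_train),
            class = "fit_model")
}

#' @export
print.fit_model <- function(x, ...) {
  cat(sprintf("<fit_model '%s': degree %d, test MSE %.4g (%d train / %d test)>\n",
              x$feature, x$degree, x$test_mse, x$n_train, x$n_test))
  invisible(x)
}

predict_fit_model <- function(model, sigma, epsilon) {
  grd <- expand.grid(sigma = sigma, epsilon = epsilon)
  grd$eps_c <- if (isTRUE(model$log_epsilon)) log(grd$epsilon) else grd$epsilon
  pred <- suppressWarnings(stats::predict(model$model, newdata = grd))
  if (identical(model$transform, "log")) pred <- exp(pred)
  matrix(pred, length(sigma), length(epsilon))
}

#' Combine per-feature fitted surfaces
#'
#' Evaluates each fitted surface on an upsampled grid (default 10x finer
#' per axis), normalises each by its number of elements and sums them
#' element-wise, yielding the single discretised matrix whose smallest
#' values mark the sigma/epsilon pairs that simultaneously satisfy all
#' features.
#'
#' @param models List of `fit_model`s over the same grid.
#' @param resolution Upsampling factor per axis. Default 10.
#' @return Object of class `combined_surface`: `values`, `sigma`,
#'   `epsilon`.
#' @export
combine_surfaces <- function(models, resolution = 10) {
  stopifnot(length(models) >= 1)
  m1 <- models[[1]]
  up <- function(v) {
    n <- (length(v) - 1L) * resolution + 1L
    seq(min(v), max(v), length.out = n)
  }
  sig <- up(m1$sigma); eps <- up(m1$epsilon)
  total <- matrix(0, length(sig), length(eps))
  for (m in models) {
    vals <- predict_fit_model(m, sig, eps)
    total <- total + vals / length(vals)
  }
  structure(list(values = total, sigma = sig, epsilon = eps,
                 features = vapply(models, `[[`, "", "feature"),
                 resolution = resolution),
            class = "combined_surface")
}

# 3x3 mean filter; edge cells average over their available neighbours.
smooth_neighbors <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    ri <- max(1, 1 + di):min(nr, nr + di)
    rj <- max(1, 1 + dj):min(nc, nc + dj)
    si <- ri - di; sj <- rj - dj
    out[ri, rj] <- out[ri, rj] + m[si, sj]
    cnt[ri, rj] <- cnt[ri, rj] + 1
  }
  out / cnt
}

#' Select the optimal sigma/epsilon pair from a combined surface
#'
#' To avoid single-cell numerical artifacts the matrix is first convolved
#' with a kernel averaging each element with its first Euclidean
#' neighbours (the 8-connected neighbourhood plus the centre; edge cells
#' use the neighbours that exist). The cell with the smallest smoothed
#' value is returned; exact ties break toward the lowest epsilon, then
#' the lowest sigma.
#'
#' @param combined A `combined_surface` (or any list with `values`,
#'   `sigma`, `epsilon`).
#' @return List with `sigma`, `epsilon`, `index` (row, col) and the
#'   `smoothed` matrix.
#' @export
select_optimum <- function(combined) {
  sm <- smooth_neighbors(combined$values)
  best <- which(sm == min(sm), arr.ind = TRUE)
  if (nrow(best) > 1)  # tie-break: lowest epsilon (col), then sigma (row)
    best <- best[order(best[, 2], best[, 1]), , drop = FALSE]
  i <- unname(best[1, 1]); j <- unname(best[1, 2])
  list(sigma = combined$sigma[i], epsilon = combined$epsilon[j],
       index = c(i, j), smoothed = sm)
}

#' Run the full grid-search parameterization pipeline
#'
#' Convenience wrapper: [evaluate_grid] then per-feature [fit_surface],
#' [combine_surfaces] and [select_optimum].
#'
#' @inheritParams evaluate_grid
#' @inheritParams fit_surface
#' @inheritParams combine_surfaces
#' @return List with `surfaces`, `models`, `combined` and `optimum`.
#' @export
derive_pair_parameters <- function(grid, simulate_and_measure, targets,
                                   degrees = 2:5, split = 0.8,
                                   resolution = 10, seed = 1,
                                   transform = "identity",
                                   clip_quantile = 1, log_epsilon = FALSE) {
  surfaces <- evaluate_grid(grid, simulate_and_measure, targets, seed = seed)
  models <- lapply(surfaces, fit_surface, degrees = degrees, split = split,
                   seed = seed, transform = transform,
                   clip_quantile = clip_quantile, log_epsilon = log_epsilon)
  combined <- combine_surfaces(models, resolution = resolution)
  optimum <- select_optimum(combined)
  list(surfaces = surfaces, models = models, combined = combined,
       optimum = optimum)
}

#' Engine-backed feature simulator for the grid search
#'
#' Builds the `simulate_and_measure` procedure used by [evaluate_grid]
#' for real (engine-generated) features: for a candidate
#' `(sigma, epsilon)` of the chosen pair, it runs a short thermostatted
#' simulation of the solvated nanoparticle system and measures the two
#' parameterization features, namely the radial distribution of the
#' solvent and of the terminal ligand-shell beads around the
#' nanoparticle core's centre of mass, returned as distance
#' distributions on a fixed bin grid.
#'
#' @param system A solvated single-NP `cg_system`.
#' @param ff Base force field; the candidate pair entry is overridden at
#'   each call.
#' @param pair Character vector of the two bead types being
#'   parameterized. Default `c("CD", "W")`.
#' @param core_group,solvent_group,shell_group Bead index groups; by
#'   default the first NP's core, all `W` beads, and `shell_group` must
#'   be supplied (e.g. [terminal_beads]).
#' @param config Engine configuration template (its seed is replaced per
#'   call).
#' @param n_equil,n_prod Equilibration / production steps.
#' @param stride Sampling stride during production.
#' @param r_max,bin_width Feature histogram geometry, nm.
#' @param replicas Independent short runs averaged per evaluation (the
#'   replica seeds are derived deterministically from the call seed);
#'   averaging suppresses the sampling noise of the feature estimates.
#'   Default 1.
#' @return `function(sigma, epsilon, seed)` returning a named list of
#'   [binned_distribution]s `solvent` and `shell`.
#' @export
make_np_feature_simulator <- function(system, ff, pair = c("CD", "W"),
                                      core_group = system$nps[[1]]$core,
                                      solvent_group = which(system$type == "W"),
                                      shell_group,
                                      config = engine_config(timestep = 0.01,
                                                             friction = 5),
                                      n_equil = 600, n_prod = 1500,
                                      stride = 15, r_max = 2.2,
                                      r_max_shell = r_max,
                                      bin_width = 0.05, replicas = 1) {
  force(system); force(ff); force(pair); force(core_group)
  force(solvent_group); force(shell_group); force(config); force(replicas)
  force(r_max_shell)
  key <- pair_key(pair[1], pair[2])
  form <- if (any(pair == "W")) "lj12-4" else "lj9-6"
  # The feature distribution is the density-normalised RDF itself (scaled
  # to unit mass over the bins): this weights the structured contact
  # region on a par with the bulk, unlike the raw distance histogram
  # whose r^2 volume factor would drown the first shell in bulk mass.
  one_run <- function(ff2, seed) {
    cfg <- config
    cfg$seed <- seed
    eq <- run_md(system, ff2, cfg, n_equil, stride = n_equil)
    sys2 <- system
    sys2$positions <- eq$final$positions
    pr <- run_md(sys2, ff2, cfg, n_prod, stride = stride,
                 velocities = eq$final$velocities)
    traj <- pr$trajectory
    solv <- rdf_around_center(traj, core_group, solvent_group, r_max,
                              bin_width)
    shel <- rdf_around_center(traj, core_group, shell_group, r_max_shell,
                              bin_width)
    list(solvent = solv$g, shell = shel$g, r = solv$r, r_shell = shel$r)
  }
  function(sigma, epsilon, seed) {
    ff2 <- ff
    ff2$pairs[[key]] <- pair_params(sigma, epsilon, form, origin = "fitted")
    acc <- NULL
    for (rep in seq_len(replicas)) {
      run <- one_run(ff2, seed * 1000L + rep)
      if (is.null(acc)) acc <- run
      else {
        acc$solvent <- acc$solvent + run$solvent
        acc$shell <- acc$shell + run$shell
      }
    }
    norm <- function(x, w) binned_distribution(x,
                                               if (sum(w) > 0) w / sum(w) else w)
    list(solvent = norm(acc$r, acc$solvent),
         shell = norm(acc$r_shell, acc$shell))
  }
}

#' Boltzmann inversion of a bond or angle distribution
#'
#' Extracts harmonic bonded parameters from an equilibrium distribution:
#' the equilibrium value is the distribution mode and the force constant
#' comes from a quadratic fit of `-kB T ln p` around the mode (for angles
#' the histogram is first corrected by the `sin(theta)` Jacobian). The
#' harmonic convention is `U = k (x - x0)^2` (no 1/2 prefactor), so a
#' Boltzmann-distributed harmonic sample has variance `kB T / (2 k)`.
#'
#' @param samples Numeric vector of bond lengths (nm) or angles (degrees).
#' @param temperature Kelvin.
#' @param kind `"bond"` or `"angle"`.
#' @param n_bins Histogram bins. Default `max(20, sqrt(n))`.
#' @param fit_window Fraction of the peak height above which bins enter
#'   the quadratic fit. Default 0.2.
#' @return Object of class `boltzmann_fit`: `kind`, `x_eq` (nm or
#'   degrees), `k` (kJ/mol/nm^2 or kJ/mol/rad^2), `params` (a
#'   [bond_params]/[angle_params], or `NULL` when the inversion is
#'   degenerate), and flags `multimodal` and `flat`.
#' @export
boltzmann_invert <- function(samples, temperature = 298,
                             kind = c("bond", "angle"), n_bins = NULL,
                             fit_window = 0.2) {
  kind <- match.arg(kind)
  n <- length(samples)
  stopifnot(n >= 50)
  if (is.null(n_bins)) n_bins <- max(20L, as.integer(round(sqrt(n))))
  h <- graphics::hist(samples, breaks = n_bins, plot = FALSE)
  x <- h$mids
  p <- h$density
  if (kind == "angle") {
    jac <- sin(pmax(1e-6, x * pi / 180))
    p <- p / jac
  }
  keep <- p > 0
  # multimodality: modes of a kernel density estimate above 30% of the peak
  dens <- stats::density(samples)
  is_max <- which(diff(sign(diff(dens$y))) == -2) + 1L
  peaks <- is_max[dens$y[is_max] > 0.3 * max(dens$y)]
  multimodal <- length(peaks) > 1 &&
    diff(range(dens$x[peaks])) > 0.1 * diff(range(samples))
  mode_x <- x[which.max(p)]
  pmax_ <- max(p)
  sel <- keep & (p >= fit_window * pmax_)
  # contiguous window around the mode
  im <- which.max(p)
  lo <- im; while (lo > 1 && sel[lo - 1]) lo <- lo - 1
  hi <- im; while (hi < length(x) && sel[hi + 1]) hi <- hi + 1
  win <- lo:hi
  flat <- FALSE; k <- NA_real_; x_eq <- mode_x
  if (length(win) < 4) {
    flat <- FALSE
    # distribution narrower than the binning: refit with finer bins
    return(boltzmann_invert(samples, temperature, kind,
                            n_bins = n_bins * 2, fit_window = fit_window))
  }
  xr <- if (kind == "angle") x[win] * pi / 180 else x[win]
  u <- -KB_KJ * temperature * log(p[win] / pmax_)
  qf <- stats::lm(u ~ xr + I(xr^2))
  c2 <- unname(stats::coef(qf)[3])
  if (is.na(c2) || c2 <= 0) {
    flat <- TRUE
    k <- max(0, c2, na.rm = TRUE)
  } else {
    k <- c2
    x_eq_fit <- -unname(stats::coef(qf)[2]) / (2 * c2)
    x_eq <- if (kind == "angle") x_eq_fit * 180 / pi else x_eq_fit
    # guard against an off-window parabola vertex
    if (x_eq < min(samples) || x_eq > max(samples)) x_eq <- mode_x
  }
  # a genuinely flat distribution also shows a tiny curvature
  if (!flat && !is.na(k)) {
    spread <- diff(range(samples))
    if (k * spread^2 < 0.5 * KB_KJ * temperature) flat <- TRUE
  }
  params <- NULL
  if (!flat && !multimodal && !is.na(k) && k > 0) {
    params <- if (kind == "bond") bond_params(k, x_eq)
              else angle_params(k, x_eq)
  }
  structure(list(kind = kind, x_eq = x_eq, k = k, params = params,
                 multimodal = multimodal, flat = flat,
                 temperature = temperature, n = n),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit %s: x_eq = %.4g, k = %.4g%s%s>\n",
              x$kind, x$x_eq, x$k,
              if (x$flat) " [flat]" else "",
              if (x$multimodal) " [multimodal]" else ""))
  invisible(x)
}
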