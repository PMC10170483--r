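# Deterministic synthetic-data generators. These are first-class package
# code (not test helpers): they provide analytically tractable inputs for
# every analysis routine, and the CLI can write them to disk so the
# documented examples run without any external data.

#' Construct a trajectory object
#'
#' The common container for time-ordered coordinate frames analysed by the
#' observables module.
#'
#' @param coords Numeric array `n_beads x 3 x n_frames` (nm).
#' @param box Orthogonal box lengths, nm (length 1 or 3).
#' @param times Frame times (ps for engine output); defaults to frame index.
#' @param type Optional bead type labels (length `n_beads`).
#' @param mass Optional bead masses (amu); default 1 (uniform weighting).
#' @return An object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(coords, box, times = NULL, type = NULL, mass = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n <- dim(coords)[1]; nf <- dim(coords)[3]
  box <- rep(as.numeric(box), length.out = 3)
  if (is.null(times)) times <- seq_len(nf)
  if (is.null(mass)) mass <- rep(1, n)
  stopifnot(length(times) == nf, length(mass) == n)
  structure(list(coords = coords, box = box, times = times,
                 type = type, mass = mass),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory: %d beads, %d frames, box %.2f x %.2f x %.2f nm>\n",
              dim(x$coords)[1], dim(x$coords)[3], x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Ideal-gas trajectory fixture
#'
#' Frames of uniform i.i.d. positions in the box: the exact null model for
#' the radial distribution function (`g(r) = 1` at all distances).
#'
#' @param n Beads per frame.
#' @param box Box lengths, nm.
#' @param n_frames Number of frames.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A [cg_trajectory].
#' @export
ideal_gas_frames <- function(n, box, n_frames = 1, seed = 1) {
  box <- rep(as.numeric(box), length.out = 3)
  coords <- withr::with_seed(seed, {
    a <- array(stats::runif(n * 3 * n_frames), dim = c(n, 3, n_frames))
    for (d in 1:3) a[, d, ] <- a[, d, ] * box[d]
    a
  })
  cg_trajectory(coords, box, times = seq_len(n_frames))
}

#' One-dimensional Boltzmann sampler
#'
#' Metropolis Monte-Carlo sampling of `exp(-U(x) / kB T)`. Serves as the
#' independent oracle for the WHAM reconstruction and for
#' Boltzmann-inversion of bonded terms: its samples follow the target
#' density exactly in the long-chain limit.
#'
#' @param U Potential function of one variable, kJ/mol.
#' @param temperature Kelvin.
#' @param n Number of retained samples.
#' @param seed Integer seed.
#' @param x0 Starting point.
#' @param step Proposal half-width (uniform proposals).
#' @param burn Discarded equilibration steps. Default 1000.
#' @param thin Keep every `thin`-th state. Default 1.
#' @return Numeric vector of samples with attribute `acceptance_rate`.
#' @export
boltzmann_sampler_1d <- function(U, temperature, n, seed = 1, x0 = 0,
                                 step = 0.1, burn = 1000, thin = 1) {
  beta <- 1 / (KB_KJ * temperature)
  withr::with_seed(seed, {
    total <- burn + n * thin
    prop <- stats::runif(total, -step, step)
    urand <- stats::runif(total)
    out <- numeric(n)
    x <- x0; ux <- U(x); acc <- 0L; k <- 0L
    for (t in seq_len(total)) {
      y <- x + prop[t]
      uy <- U(y)
      if (urand[t] < exp(-beta * (uy - ux))) {
        x <- y; ux <- uy; acc <- acc + 1L
      }
      if (t > burn && (t - burn) %% thin == 0L) {
        k <- k + 1L
        out[k] <- x
      }
    }
    attr(out, "acceptance_rate") <- acc / total
    out
  })
}

#' Gaussian feature surrogate for grid-search tests
#'
#' A cheap, closed-form stand-in for "run a short simulation and measure
#' the solvent and shell RDF features": two binned Gaussian-shaped
#' distributions whose locations shift monotonically with `sigma` and
#' whose widths change monotonically with `epsilon`. Used to exercise the
#' full grid-search pipeline (evaluate, fit, combine, select) against a
#' known optimum without any dynamics.
#'
#' @param sigma Pair sigma in Angstrom.
#' @param epsilon Pair epsilon in kJ/mol.
#' @param noise Standard deviation of multiplicative bin noise. Default 0.
#' @param seed Integer seed for the noise.
#' @param r Bin centres in nm. Default `seq(0.01, 2.99, by = 0.02)`.
#' @return Named list of two [binned_distribution]s: `solvent` and `shell`.
#' @export
gaussian_feature_surrogate <- function(sigma, epsilon, noise = 0, seed = 1,
                                       r = seq(0.01, 2.99, by = 0.02)) {
  mu_solv <- 0.55 + 0.10 * sigma        # contact distance tracks sigma
  w_solv  <- 0.06 + 0.03 / (0.05 + epsilon)  # deeper well -> sharper peak
  mu_shel <- 1.05 + 0.05 * sigma
  w_shel  <- 0.04 + 0.12 * epsilon
  shape <- function(mu, w) {
    p <- exp(-(r - mu)^2 / (2 * w^2))
    if (noise > 0)
      p <- p * exp(stats::rnorm(length(r), 0, noise))
    p / sum(p)
  }
  withr::with_seed(seed, {
    list(solvent = binned_distribution(r, shape(mu_solv, w_solv)),
         shell   = binned_distribution(r, shape(mu_shel, w_shel)))
  })
}

#' Synthetic aggregation-kinetics trace
#'
#' A saturating exponential `f(t) = A (1 - exp(-t / tau))` with optional
#' additive Gaussian noise, clipped to `[0, 1]`: the closed-form fixture
#' for [fit_exponential] and [convergence_extrapolation].
#'
#' @param A Plateau fraction.
#' @param tau Time constant (same unit as `t_grid`).
#' @param noise Additive noise standard deviation. Default 0.
#' @param t_grid Time points.
#' @param seed Integer seed for the noise.
#' @return An [aggregation_trace].
#' @export
synthetic_kinetics <- function(A, tau, noise = 0, t_grid = seq(0, 1000, by = 10),
                               seed = 1) {
  f <- A * (1 - exp(-t_grid / tau))
  if (noise > 0)
    f <- withr::with_seed(seed, f + stats::rnorm(length(t_grid), 0, noise))
  f <- pmin(1, pmax(0, f))
  aggregation_trace(t_grid, f)
}
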