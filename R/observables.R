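# Trajectory-derived observables: radial distribution functions, cluster
# detection, aggregation kinetics and their exponential fits.

#' Binned distribution
#'
#' A probability distribution on a fixed bin grid; the unit of exchange
#' between measured features and parameterization targets.
#'
#' @param x Bin centres (strictly increasing).
#' @param p Non-negative bin masses (need not be normalised).
#' @return An object of class `binned_distribution`.
#' @export
binned_distribution <- function(x, p) {
  stopifnot(length(x) == length(p), all(diff(x) > 0), all(p >= 0))
  structure(list(x = as.numeric(x), p = as.numeric(p)),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf("<binned_distribution: %d bins on [%.3g, %.3g]>\n",
              length(x$x), x$x[1], x$x[length(x$x)]))
  invisible(x)
}

min_image <- function(d, box) d - box * round(d / box)

# Mass-weighted centre of mass of a compact group, unwrapped relative to
# its first member so periodic images do not split the group.
group_com <- function(pos, idx, mass, box) {
  ref <- pos[idx[1], ]
  d <- sweep(pos[idx, , drop = FALSE], 2, ref)
  for (k in 1:3) d[, k] <- min_image(d[, k], box[k])
  w <- mass[idx] / sum(mass[idx])
  ref + colSums(d * w)
}

rdf_curve <- function(r, g, bin_width, n_frames, meta = list()) {
  structure(list(r = r, g = g, bin_width = bin_width, n_frames = n_frames,
                 meta = meta),
            class = "rdf_curve")
}

#' @export
print.rdf_curve <- function(x, ...) {
  cat(sprintf("<rdf_curve: %d bins up to %.2f nm, %d frames>\n",
              length(x$r), max(x$r) + x$bin_width / 2, x$n_frames))
  invisible(x)
}

#' Radial distribution function around a group's centre of mass
#'
#' Density-normalised histogram of minimum-image distances from the
#' (mass-weighted) centre of mass of `center_group` to every bead of
#' `target_group`, averaged over frames. This is the primitive behind the
#' two parameterization features: the solvent RDF (targets = solvent
#' beads) and the ligand-shell RDF (targets = the terminal bead of each
#' ligand), both measured from the nanoparticle core's centre of mass.
#'
#' @param traj A [cg_trajectory].
#' @param center_group Indices defining the centre.
#' @param target_group Indices of the target beads.
#' @param r_max Histogram range, nm; must not exceed half the smallest box
#'   edge.
#' @param bin_width Bin width in nm. Default 0.02.
#' @return An `rdf_curve`: bin centres `r`, values `g`, and normalisation
#'   metadata.
#' @export
rdf_around_center <- function(traj, center_group, target_group, r_max,
                              bin_width = 0.02) {
  stopifnot(inherits(traj, "cg_trajectory"),
            length(center_group) > 0, length(target_group) > 0)
  box <- traj$box
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max (", r_max, ") exceeds half the smallest box edge (",
         min(box) / 2, ")")
  edges <- seq(0, r_max, by = bin_width)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    pos <- traj$coords[, , f]
    com <- group_com(pos, center_group, traj$mass, box)
    d <- sweep(pos[target_group, , drop = FALSE], 2, com)
    for (k in 1:3) d[, k] <- min_image(d[, k], box[k])
    r <- sqrt(rowSums(d * d))
    counts <- counts + graphics::hist(r[r < r_max], breaks = edges,
                                      plot = FALSE)$counts
  }
  rho <- length(target_group) / prod(box)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  g <- counts / nf / (shell_vol * rho)
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  rdf_curve(centres, g, bin_width, nf,
            meta = list(rho_target = rho, n_center = length(center_group),
                        n_target = length(target_group), edges = edges))
}

# Per-frame core centres of mass for a list of NP bead groups.
np_centers <- function(traj, np_groups) {
  nf <- n_frames(traj)
  out <- array(NA_real_, dim = c(length(np_groups), 3, nf))
  for (f in seq_len(nf)) {
    pos <- traj$coords[, , f]
    for (i in seq_along(np_groups))
      out[i, , f] <- group_com(pos, np_groups[[i]], traj$mass, traj$box)
  }
  out
}

#' Nanoparticle-nanoparticle radial distribution function
#'
#' Pair RDF with the nanoparticle core centres of mass as both the centre
#' and target sets, averaged over frames.
#'
#' @param traj A [cg_trajectory]; may be omitted if `centers` is given.
#' @param np_groups List of bead index vectors, one per nanoparticle core.
#' @param centers Alternative to `np_groups`: precomputed centre array
#'   `n_np x 3 x n_frames`.
#' @param r_max Histogram range, nm.
#' @param bin_width Bin width in nm. Default 0.02.
#' @return An `rdf_curve`.
#' @export
np_np_rdf <- function(traj = NULL, np_groups = NULL, centers = NULL,
                      r_max, bin_width = 0.02) {
  if (is.null(centers)) {
    stopifnot(!is.null(traj), !is.null(np_groups))
    centers <- np_centers(traj, np_groups)
    box <- traj$box
  } else {
    box <- if (!is.null(traj)) traj$box else attr(centers, "box")
  }
  if (is.null(box)) stop("no box information available")
  nf <- dim(centers)[3]
  if (is.na(nf) || nf == 0) stop("empty trajectory: no frames to analyse")
  n <- dim(centers)[1]
  if (n < 2) stop("need at least two nanoparticles")
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box edge")
  edges <- seq(0, r_max, by = bin_width)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1)
  for (f in seq_len(nf)) {
    p <- centers[, , f, drop = FALSE][, , 1]
    dm <- pair_distances(p, box)
    counts <- counts + graphics::hist(dm[dm < r_max], breaks = edges,
                                      plot = FALSE)$counts
  }
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  # pair normalisation: N(N-1)/2 pairs against the ideal-gas density
  g <- counts / nf / (shell_vol * n * (n - 1) / 2 / prod(box))
  centres <- (edges[-1] + edges[-length(edges)]) / 2
  rdf_curve(centres, g, bin_width, nf, meta = list(n_np = n))
}

# Upper-triangle minimum-image pair distances of a point set.
pair_distances <- function(p, box) {
  n <- nrow(p)
  out <- numeric(n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    d <- sweep(p[(i + 1):n, , drop = FALSE], 2, p[i, ])
    for (c in 1:3) d[, c] <- min_image(d[, c], box[c])
    m <- nrow(d)
    out[k + seq_len(m)] <- sqrt(rowSums(d * d))
    k <- k + m
  }
  out
}

#' Detect nanoparticle clusters in one frame
#'
#' Connected components of the contact graph linking nanoparticle pairs
#' whose centre distance (minimum image) is at most `cutoff`. A
#' nanoparticle is "aggregated" when its component has size at least two.
#'
#' @param centers `n x 3` matrix of nanoparticle centres (one frame).
#' @param cutoff Contact distance in nm.
#' @param box Box lengths for minimum image; `NULL` for non-periodic.
#' @return List with `membership` (component id per nanoparticle),
#'   `sizes` (component sizes) and `n_clusters`.
#' @export
detect_clusters <- function(centers, cutoff, box = NULL) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n == 0) stop("no nanoparticle centres given")
  if (is.null(box)) box <- rep(1e12, 3) else box <- rep(box, length.out = 3)
  edges <- NULL
  for (i in seq_len(max(0, n - 1))) {
    d <- sweep(centers[(i + 1):n, , drop = FALSE], 2, centers[i, ])
    for (c in 1:3) d[, c] <- min_image(d[, c], box[c])
    hit <- which(rowSums(d * d) <= cutoff^2)
    if (length(hit))
      edges <- rbind(edges, cbind(i, i + hit))
  }
  if (is.null(edges)) {
    membership <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    membership <- igraph::components(g)$membership
  }
  sizes <- as.integer(table(membership))
  list(membership = as.integer(membership), sizes = sizes,
       n_clusters = length(sizes))
}

#' Aggregation trace
#'
#' @param times Frame times.
#' @param fraction Fraction of nanoparticles in clusters of size >= 2,
#'   in `[0, 1]`.
#' @param n_clusters Optional per-frame cluster counts.
#' @param size_distributions Optional per-frame cluster size tables.
#' @param cutoff Contact cutoff used, nm (recorded for provenance).
#' @return An object of class `aggregation_trace`.
#' @export
aggregation_trace <- function(times, fraction, n_clusters = NULL,
                              size_distributions = NULL, cutoff = NA_real_) {
  stopifnot(length(times) == length(fraction),
            all(fraction >= 0), all(fraction <= 1))
  structure(list(times = times, fraction = fraction,
                 n_clusters = n_clusters,
                 size_distributions = size_distributions, cutoff = cutoff),
            class = "aggregation_trace")
}

#' Aggregation kinetics along a trajectory
#'
#' Per-frame fraction of nanoparticles belonging to a cluster of size at
#' least two (i.e. no longer free in solution), together with cluster
#' counts and size histograms.
#'
#' @param traj A [cg_trajectory]; may be omitted if `centers` is given.
#' @param np_groups List of per-nanoparticle core bead indices.
#' @param centers Alternative: precomputed `n_np x 3 x n_frames` array.
#' @param cutoff Contact distance in nm defining a cluster link.
#' @return An [aggregation_trace].
#' @export
aggregation_kinetics <- function(traj = NULL, np_groups = NULL,
                                 centers = NULL, cutoff) {
  if (is.null(centers)) {
    stopifnot(!is.null(traj), !is.null(np_groups))
    centers <- np_centers(traj, np_groups)
  }
  box <- if (!is.null(traj)) traj$box else attr(centers, "box")
  nf <- dim(centers)[3]
  n <- dim(centers)[1]
  frac <- numeric(nf); ncl <- integer(nf); dists <- vector("list", nf)
  for (f in seq_len(nf)) {
    cl <- detect_clusters(centers[, , f, drop = FALSE][, , 1], cutoff, box)
    agg <- sum(cl$sizes[cl$membership] >= 2)
    frac[f] <- agg / n
    ncl[f] <- cl$n_clusters
    dists[[f]] <- cl$sizes
  }
  times <- if (!is.null(traj)) traj$times else seq_len(nf)
  aggregation_trace(times, frac, ncl, dists, cutoff)
}

#' Fit a saturating exponential to an aggregation trace
#'
#' Least-squares fit of `f(t) = A (1 - exp(-t / tau))`: the fitted
#' quantity is a bounded, growing fraction, so the saturating form gives a
#' direct plateau read-off `A` (the fraction of nanoparticles that will
#' eventually aggregate).
#'
#' @param trace An [aggregation_trace], or a numeric vector of times when
#'   `fraction` is supplied separately.
#' @param fraction Optional fractions if `trace` is a plain time vector.
#' @return List with `A` (plateau), `tau`, `r_squared`, `se_A` (standard
#'   error of the plateau), `converged` and the underlying `fit` object
#'   (or `NULL`). Non-convergence is flagged, never thrown.
#' @export
fit_exponential <- function(trace, fraction = NULL) {
  if (inherits(trace, "aggregation_trace")) {
    t <- trace$times; f <- trace$fraction
  } else {
    t <- trace; f <- fraction
  }
  if (length(t) < 5) stop("need at least 5 time points")
  if (stats::sd(f) < 1e-12) {
    return(list(A = mean(f), tau = NA_real_, r_squared = NA_real_,
                se_A = 0, converged = TRUE, degenerate = TRUE, fit = NULL))
  }
  dat <- data.frame(t = t, f = f)
  a0 <- max(f)
  tau0 <- max(t[which(f >= 0.63 * a0)][1], diff(range(t)) / 10, na.rm = TRUE)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ A * (1 - exp(-t / tau)), data = dat,
                      start = list(A = a0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(A = NA_real_, tau = NA_real_, r_squared = NA_real_,
                se_A = NA_real_, converged = FALSE, degenerate = FALSE,
                fit = NULL))
  }
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((f - mean(f))^2)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(A = NA, tau = NA))
  list(A = unname(co["A"]), tau = unname(co["tau"]), r_squared = r2,
       se_A = unname(se["A"]), converged = TRUE, degenerate = FALSE,
       fit = fit)
}

#' Convergence check by exponential extrapolation
#'
#' Fits the trace with [fit_exponential] and reports the predicted change
#' in aggregated fraction between the end of the trace and a longer
#' horizon. The trace is deemed converged when that change falls below the
#' threshold.
#'
#' @param trace An [aggregation_trace].
#' @param horizon Extrapolation time, same unit as the trace times.
#' @param threshold Convergence threshold on the predicted change.
#'   Default 0.01.
#' @return List with `change`, `converged` (logical), `horizon`,
#'   `threshold` and the underlying `fit`.
#' @export
convergence_extrapolation <- function(trace, horizon, threshold = 0.01) {
  fit <- fit_exponential(trace)
  t_end <- max(trace$times)
  if (!isTRUE(fit$converged) || is.na(fit$A)) {
    return(list(change = NA_real_, converged = FALSE, horizon = horizon,
                threshold = threshold, fit = fit))
  }
  predict_f <- function(t) {
    if (isTRUE(fit$degenerate)) rep(fit$A, length(t))
    else fit$A * (1 - exp(-t / fit$tau))
  }
  change <- abs(predict_f(horizon) - predict_f(t_end))
  list(change = change, converged = change < threshold, horizon = horizon,
       threshold = threshold, fit = fit)
}
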