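# Umbrella-sampling windows, WHAM reconstruction of the potential of mean
# force along the NP-NP core centre-of-mass distance, and extraction of
# the profile's physical features (primary-minimum depth, barrier,
# plateau distance).

KCAL_PER_KJ <- 1 / 4.184

#' Generate an umbrella window ladder
#'
#' Window centres start at `r_start` and advance in steps of `spacing`
#' (default 0.2 nm, the standard extraction spacing along the NP-NP core
#' centre-of-mass distance) up to `r_end`; the count is
#' `floor((r_end - r_start) / spacing) + 1`.
#'
#' @param r_start,r_end Reaction-coordinate range, nm.
#' @param spacing Window spacing, nm. Default 0.2.
#' @param k Bias constant, kJ/mol/nm^2 (`U = k (r - r0)^2`, no 1/2
#'   prefactor). Default 1300, the pulling constant reused for the
#'   windows.
#' @return `data.frame` with columns `center` and `k`, class
#'   `umbrella_windows`.
#' @export
generate_windows <- function(r_start, r_end, spacing = 0.2, k = 1300) {
  if (spacing <= 0) stop("spacing must be positive")
  if (r_end < r_start) stop("r_end must be >= r_start")
  n <- floor((r_end - r_start) / spacing + 1e-9) + 1
  out <- data.frame(center = r_start + spacing * (seq_len(n) - 1), k = k)
  class(out) <- c("umbrella_windows", "data.frame")
  out
}

#' Umbrella window with samples
#'
#' @param center Bias centre r0, nm.
#' @param k Bias constant, kJ/mol/nm^2 (no 1/2 convention).
#' @param samples Reaction-coordinate time series, nm.
#' @param discard Equilibration fraction discarded from the start of the
#'   series. Default 0.1.
#' @return Object of class `umbrella_window` with the retained samples.
#' @export
umbrella_window <- function(center, k, samples, discard = 0.1) {
  stopifnot(k > 0, discard >= 0, discard < 1)
  n0 <- length(samples)
  keep <- samples[(floor(discard * n0) + 1):n0]
  if (length(keep) < 1) stop("no samples retained")
  structure(list(center = center, k = k, samples = keep,
                 n_discarded = n0 - length(keep)),
            class = "umbrella_window")
}

#' WHAM reconstruction of the potential of mean force
#'
#' Standard self-consistent weighted-histogram iteration over the window
#' free-energy offsets: histograms of all windows are combined into the
#' unbiased density `rho(r)` and the profile `F(r) = -kB T ln rho(r)`,
#' iterating until the largest offset change drops below `tol`. The
#' profile is returned in kcal/mol, shifted so that the detected plateau
#' region (see [analyze_pmf]) sits at zero; if no plateau is detected the
#' outermost sampled bin is used as the reference.
#'
#' @param windows List of [umbrella_window]s (order is irrelevant).
#' @param temperature Kelvin. Default 298.
#' @param bin_width Histogram bin width, nm. Default 0.02.
#' @param tol Convergence tolerance on the offsets, kcal/mol.
#'   Default 1e-8.
#' @param max_iter Iteration cap; exceeding it flags (not fails) the
#'   result. Default 50000.
#' @param n_boot Block-bootstrap replicates for per-bin uncertainties
#'   (0 = off). Default 0.
#' @param n_blocks Blocks per window for the bootstrap. Default 5.
#' @return Object of class `pmf_profile`: `r`, `F` (kcal/mol), `sigma_F`,
#'   `converged`, `n_iter`. Windows whose histograms do not overlap
#'   trigger a warning.
#' @export
wham <- function(windows, temperature = 298, bin_width = 0.02, tol = 1e-8,
                 max_iter = 50000, n_boot = 0, n_blocks = 5) {
  stopifnot(length(windows) >= 1)
  windows <- lapply(windows, function(w) {
    if (inherits(w, "umbrella_window")) w
    else umbrella_window(w$center, w$k, w$samples,
                         discard = if (is.null(w$discard)) 0.1 else w$discard)
  })
  profile <- wham_core(windows, temperature, bin_width, tol, max_iter)
  sigma_F <- rep(NA_real_, length(profile$r))
  if (n_boot > 0) {
    boots <- matrix(NA_real_, n_boot, length(profile$r))
    for (b in seq_len(n_boot)) {
      wb <- withr::with_seed(b, lapply(windows, function(w) {
        n <- length(w$samples)
        bl <- max(1L, floor(n / n_blocks))
        starts <- sample.int(max(1L, n - bl + 1L), n_blocks, replace = TRUE)
        smp <- unlist(lapply(starts, function(s) w$samples[s:(s + bl - 1L)]))
        structure(list(center = w$center, k = w$k, samples = smp,
                       n_discarded = 0L), class = "umbrella_window")
      }))
      pb <- tryCatch(wham_core(wb, temperature, bin_width, tol,
                               max_iter, grid = profile$r),
                     error = function(e) NULL)
      if (!is.null(pb)) boots[b, ] <- pb$F
    }
    sigma_F <- apply(boots, 2, stats::sd, na.rm = TRUE)
  }
  profile$sigma_F <- sigma_F
  profile
}

wham_core <- function(windows, temperature, bin_width, tol, max_iter,
                      grid = NULL) {
  beta <- 1 / (KB_KJ * temperature)
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  if (is.null(grid)) {
    lo <- min(all_s); hi <- max(all_s)
    edges <- seq(lo - 1e-9, hi + bin_width, by = bin_width)
    grid <- (edges[-1] + edges[-length(edges)]) / 2
  } else {
    edges <- c(grid - bin_width / 2, grid[length(grid)] + bin_width / 2)
  }
  nb <- length(grid); nw <- length(windows)
  H <- matrix(0, nw, nb)
  N <- integer(nw)
  for (i in seq_len(nw)) {
    s <- windows[[i]]$samples
    s <- s[s >= edges[1] & s <= edges[length(edges)]]
    H[i, ] <- graphics::hist(s, breaks = edges, plot = FALSE)$counts
    N[i] <- length(s)
  }
  # warn on non-overlapping neighbouring histograms
  occ <- H > 0
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  for (k in seq_len(nw - 1)) {
    a <- occ[ord[k], ]; b <- occ[ord[k + 1], ]
    if (!any(a & b))
      warning("umbrella histograms of windows at ",
              windows[[ord[k]]]$center, " and ",
              windows[[ord[k + 1]]]$center,
              " nm do not overlap; PMF may be disconnected")
  }
  # bias factors c_i(r)
  C <- matrix(0, nw, nb)
  for (i in seq_len(nw))
    C[i, ] <- exp(-beta * windows[[i]]$k * (grid - windows[[i]]$center)^2)
  numer <- colSums(H)
  f <- rep(1, nw)         # window normalisation constants
  converged <- FALSE
  iter <- 0L
  tol_nats <- tol / KCAL_PER_KJ * beta  # kcal/mol -> dimensionless ln f
  repeat {
    iter <- iter + 1L
    denom <- colSums((N * f) * C)
    rho <- ifelse(denom > 0, numer / denom, 0)
    rho <- rho / sum(rho)
    f_new <- 1 / pmax(C %*% rho, .Machine$double.xmin)[, 1]
    delta <- max(abs(log(f_new / f)))
    f <- f_new
    if (delta < tol_nats) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  Fr <- ifelse(rho > 0, -log(rho) / beta, NA_real_) * KCAL_PER_KJ
  keep <- !is.na(Fr)
  prof <- structure(list(r = grid[keep], F = Fr[keep],
                         sigma_F = rep(NA_real_, sum(keep)),
                         converged = converged, n_iter = iter,
                         temperature = temperature, bin_width = bin_width),
                    class = "pmf_profile")
  # plateau-zeroed reference
  feat <- tryCatch(analyze_pmf(prof, shift = FALSE), error = function(e) NULL)
  ref <- if (!is.null(feat) && isTRUE(feat$ok)) feat$plateau_level
         else prof$F[length(prof$F)]
  prof$F <- prof$F - ref
  prof
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile: %d bins on [%.2f, %.2f] nm%s>\n",
              length(x$r), min(x$r), max(x$r),
              if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Extract the physical features of a PMF profile
#'
#' Detects the flat large-distance plateau (the fully separated state),
#' then reports: the depth of the primary minimum relative to the plateau
#' (the stabilisation of the dimer state), the free-energy barrier that
#' must be overcome between the plateau and the minimum, and the plateau
#' distance (the separation beyond which the nanoparticles no longer
#' interact, i.e. their effective interaction range).
#'
#' The plateau is the outermost maximal run of bins whose local slope
#' magnitude stays below `slope_threshold` over at least `plateau_width`;
#' both criteria are this package's own operational definition and are
#' configurable. All features are invariant to adding a constant to `F`.
#'
#' @param profile A `pmf_profile` (or list with `r`, `F` in kcal/mol).
#' @param slope_threshold Flatness threshold, kcal/mol/nm. Default 0.5.
#' @param plateau_width Minimum plateau extent, nm. Default 0.4.
#' @param shift Internal: also report the plateau level. Default TRUE.
#' @return List with `depth`, `barrier`, `plateau_distance`, `r_min`,
#'   `plateau_level`, `ok` and `diagnostics`. When no plateau is found
#'   the features are `NA` with `ok = FALSE`.
#' @export
analyze_pmf <- function(profile, slope_threshold = 0.5, plateau_width = 0.4,
                        shift = TRUE) {
  r <- profile$r; Fr <- profile$F
  stopifnot(length(r) == length(Fr), length(r) >= 5)
  # light smoothing for the slope estimate only
  Fs <- stats::filter(Fr, rep(1 / 3, 3), sides = 2)
  Fs[is.na(Fs)] <- Fr[is.na(Fs)]
  slope <- c(diff(Fs) / diff(r), 0)
  flat <- abs(slope) < slope_threshold
  runs <- rle(flat)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  plateau_run <- NULL
  for (k in rev(seq_along(runs$values))) {  # outermost first
    if (!runs$values[k]) next
    if (r[ends[k]] - r[starts[k]] >= plateau_width - 1e-9) {
      plateau_run <- c(starts[k], ends[k]); break
    }
  }
  if (is.null(plateau_run)) {
    return(list(depth = NA_real_, barrier = NA_real_,
                plateau_distance = NA_real_, r_min = NA_real_,
                plateau_level = NA_real_, ok = FALSE,
                diagnostics = list(reason = "no plateau detected",
                                   max_flat_run_nm =
                                     if (any(runs$values))
                                       max(r[ends[runs$values]] -
                                           r[starts[runs$values]]) else 0)))
  }
  pl <- plateau_run[1]:plateau_run[2]
  plateau_level <- mean(Fr[pl])
  plateau_distance <- r[plateau_run[1]]
  inner <- which(r < plateau_distance)
  no_minimum <- FALSE
  if (!length(inner)) {
    r_min <- NA_real_; depth <- 0; barrier <- 0; no_minimum <- TRUE
  } else {
    i_min <- inner[which.min(Fr[inner])]
    r_min <- r[i_min]
    depth <- plateau_level - Fr[i_min]
    if (depth < 1e-9) no_minimum <- TRUE
    between <- which(r > r_min & r < plateau_distance)
    barrier <- if (length(between))
      max(0, max(Fr[between]) - plateau_level) else 0
  }
  list(depth = depth, barrier = barrier,
       plateau_distance = plateau_distance, r_min = r_min,
       plateau_level = plateau_level, ok = TRUE,
       diagnostics = list(no_minimum = no_minimum,
                          plateau_run = plateau_run))
}

#' Compare PMF features between two models
#'
#' Report-generator arithmetic for the worked comparison between a
#' coarse-grained profile and a reference (e.g. atomistic) profile: the
#' relative difference in primary-minimum depth and in plateau distance,
#' both quoted as percentages of the coarse-grained value.
#'
#' @param depth_cg,depth_ref Primary-minimum depths, kcal/mol.
#' @param plateau_cg,plateau_ref Plateau distances, nm. Optional.
#' @return List with `depth_rel_err_pct` and (when plateau distances are
#'   given) `plateau_mismatch_pct`.
#' @export
compare_pmf_features <- function(depth_cg, depth_ref,
                                 plateau_cg = NULL, plateau_ref = NULL) {
  out <- list(depth_rel_err_pct = abs(depth_cg - depth_ref) / depth_cg * 100)
  if (!is.null(plateau_cg) && !is.null(plateau_ref))
    out$plateau_mismatch_pct <- abs(plateau_cg - plateau_ref) / plateau_cg * 100
  out
}
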