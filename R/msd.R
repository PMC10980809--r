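#' Time-averaged mean squared displacement of one track
#'
#' MSD(tau) is the average of squared displacements over all overlapping pairs
#' of samples separated by the lag tau = k*dt, for k = 1 ..
#' `floor(max_lag_fraction * (N - 1))`. Sampling must be uniform at the
#' track-set interval; the number of pairs entering each lag is recorded.
#'
#' @param tr a [track()] with at least 3 samples and uniform sampling.
#' @param max_lag_fraction largest lag as a fraction of the track span
#'   (default 0.5; long lags average very few pairs and are extremely noisy).
#' @param dt sampling interval in hours; defaults to the track's own (modal)
#'   step.
#' @return An object of class `"msd_curve"`: list with `lags` (hours),
#'   `values` (square micrometres) and `n_pairs`.
#' @export
track_msd <- function(tr, max_lag_fraction = 0.5, dt = NULL) {
  stopifnot(inherits(tr, "track"))
  N <- length(tr$times)
  if (N < 3) stop(sprintf("track '%s': need >= 3 samples for an MSD", tr$id))
  steps <- diff(tr$times)
  if (is.null(dt)) dt <- min(steps)
  if (any(abs(steps - dt) > 1e-6))
    stop(sprintf("track '%s': sampling is not uniform at dt = %g h", tr$id, dt))
  if (max_lag_fraction <= 0 || max_lag_fraction > 1)
    stop("max_lag_fraction must be in (0, 1]")
  K <- max(1L, floor(max_lag_fraction * (N - 1)))
  vals <- numeric(K)
  npairs <- integer(K)
  pos <- tr$positions
  for (k in seq_len(K)) {
    d <- pos[(1 + k):N, , drop = FALSE] - pos[1:(N - k), , drop = FALSE]
    vals[k] <- mean(rowSums(d^2))
    npairs[k] <- N - k
  }
  msd_curve(dt * seq_len(K), vals, npairs)
}

msd_curve <- function(lags, values, n_pairs) {
  stopifnot(length(lags) == length(values), length(lags) == length(n_pairs))
  if (any(lags <= 0) || any(diff(lags) <= 0))
    stop("lags must be positive and strictly increasing")
  if (any(values < -1e-12)) stop("MSD values must be non-negative")
  structure(list(lags = as.numeric(lags), values = pmax(values, 0),
                 n_pairs = as.integer(n_pairs)),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, tau in [%g, %g] h, MSD in [%g, %g] um^2\n",
              length(x$lags), min(x$lags), max(x$lags),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.msd_curve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(lag_h = x$lags, msd_um2 = x$values, n_pairs = x$n_pairs)
}

#' Population-averaged mean squared displacement
#'
#' Per lag, the unweighted mean of the per-track time-averaged MSD values
#' over the tracks long enough to contribute at that lag. `n_pairs` records
#' the number of contributing tracks per lag.
#'
#' @param ts a `track_set` with at least one track of >= 3 samples.
#' @param max_lag_fraction passed to [track_msd()] per track.
#' @return an `msd_curve`.
#' @export
population_msd <- function(ts, max_lag_fraction = 0.5) {
  stopifnot(inherits(ts, "track_set"))
  usable <- Filter(function(tr) length(tr$times) >= 3, ts$tracks)
  if (!length(usable)) stop("no track has >= 3 samples")
  curves <- lapply(usable, track_msd, max_lag_fraction = max_lag_fraction,
                   dt = ts$dt)
  K <- max(vapply(curves, function(m) length(m$lags), integer(1)))
  sums <- numeric(K)
  n <- integer(K)
  for (m in curves) {
    k <- seq_along(m$values)
    sums[k] <- sums[k] + m$values
    n[k] <- n[k] + 1L
  }
  msd_curve(ts$dt * seq_len(K), sums / n, n)
}

#' Power-law exponent of an MSD curve
#'
#' Ordinary least-squares line fit of log(MSD) against log(tau) over the lags
#' inside `lag_range`; the slope is the anomalous-diffusion exponent alpha
#' (1 for Brownian motion, 2 for ballistic motion).
#'
#' @param msd an `msd_curve`.
#' @param lag_range numeric length-2, inclusive lag window in hours; at least
#'   3 lags must fall inside.
#' @return An object of class `"alpha_fit"`: list with `alpha`, `prefactor`
#'   (MSD at tau = 1 h under the fit) and `lag_range`.
#' @export
fit_alpha <- function(msd, lag_range = range(msd$lags)) {
  stopifnot(inherits(msd, "msd_curve"), length(lag_range) == 2)
  sel <- msd$lags >= lag_range[1] & msd$lags <= lag_range[2]
  if (sum(sel) < 3) stop("need >= 3 lags inside lag_range")
  if (any(msd$values[sel] <= 0))
    stop("zero MSD values inside lag_range: log-log fit undefined")
  fit <- stats::lm(log(msd$values[sel]) ~ log(msd$lags[sel]))
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 prefactor = exp(unname(stats::coef(fit)[1])),
                 lag_range = as.numeric(lag_range)),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("<alpha_fit> MSD ~ %.4g * tau^%.4f over tau in [%g, %g] h\n",
              x$prefactor, x$alpha, x$lag_range[1], x$lag_range[2]))
  invisible(x)
}

#' Angular displacement distribution between successive steps
#'
#' For every track, displacement vectors over the lag tau are formed and the
#' angle between each vector and the vector one lag later is computed as
#' `acos(v_t . v_(t+tau) / (|v_t| |v_(t+tau)|))`, pooled over all tracks and
#' times. Pairs containing a zero-magnitude vector are skipped (their count
#' is recorded). The result is a probability density histogram per degree on
#' \[0, 180\].
#'
#' @param ts a `track_set`.
#' @param lag lag in hours; must be an integer multiple of `dt`.
#' @param n_bins number of equal-width bins on \[0, 180\] degrees.
#' @return An object of class `"angular_distribution"`: list with `lag`,
#'   `bin_edges` (degrees), `density` (per degree; integrates to 1),
#'   `n_angles` and `n_skipped`.
#' @export
angular_displacements <- function(ts, lag = ts$dt, n_bins = 18) {
  stopifnot(inherits(ts, "track_set"))
  m <- lag / ts$dt
  if (abs(m - round(m)) > 1e-6) stop("lag must be an integer multiple of dt")
  m <- as.integer(round(m))
  if (m < 1) stop("lag must be at least dt")
  angles <- c()
  skipped <- 0L
  for (tr in ts$tracks) {
    N <- length(tr$times)
    if (N < 2 * m + 1) next
    v <- tr$positions[(1 + m):N, , drop = FALSE] -
         tr$positions[1:(N - m), , drop = FALSE]
    a <- v[1:(nrow(v) - m), , drop = FALSE]
    b <- v[(1 + m):nrow(v), , drop = FALSE]
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    ok <- na > 0 & nb > 0
    skipped <- skipped + sum(!ok)
    cosang <- rowSums(a[ok, , drop = FALSE] * b[ok, , drop = FALSE]) /
      (na[ok] * nb[ok])
    angles <- c(angles, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
  }
  if (!length(angles))
    stop("lag too large: no track contributes an angle pair")
  edges <- seq(0, 180, length.out = n_bins + 1)
  counts <- graphics::hist(angles, breaks = edges, plot = FALSE)$counts
  width <- 180 / n_bins
  structure(list(lag = lag, bin_edges = edges,
                 density = counts / (sum(counts) * width),
                 n_angles = length(angles), n_skipped = skipped),
            class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf(
    "<angular_distribution> lag %g h, %d bins, %d angles (%d zero-step pairs skipped)\n",
    x$lag, length(x$density), x$n_angles, x$n_skipped))
  invisible(x)
}
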