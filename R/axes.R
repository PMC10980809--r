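#' Primary and non-primary migration axes of a 2D track
#'
#' Singular value decomposition of the track's velocity matrix (rows = steps
#' at the sampling interval, columns = coordinates). The right singular
#' vector belonging to the larger singular value is the primary migration
#' axis; the orthogonal one is the non-primary axis. The velocity matrix is
#' deliberately not mean-centred, so net drift contributes to the primary
#' direction.
#'
#' @param tr a 2D [track()] with >= 3 samples.
#' @return An object of class `"axis_decomposition"`: list with `p_axis`,
#'   `np_axis` (unit 2-vectors), `singular_values` (s1 >= s2),
#'   `rotated_velocities` (matrix of (v_p, v_np) in micrometres/hour) and
#'   `basis` (2x2 orthonormal matrix with the axes as columns).
#' @export
svd_axes <- function(tr) {
  stopifnot(inherits(tr, "track"))
  if (ncol(tr$positions) != 2L) stop("svd_axes requires a 2D track")
  if (length(tr$times) < 3L) stop("need >= 3 samples")
  V <- diff(tr$positions) / diff(tr$times)
  if (all(abs(V) < 1e-300))
    stop(sprintf("track '%s': all velocities are zero; axes are degenerate",
                 tr$id))
  sv <- svd(V)
  W <- sv$v  # columns ordered by decreasing singular value
  structure(list(p_axis = W[, 1], np_axis = W[, 2],
                 singular_values = sv$d,
                 rotated_velocities = V %*% W,
                 basis = W),
            class = "axis_decomposition")
}

#' @export
print.axis_decomposition <- function(x, ...) {
  cat(sprintf("<axis_decomposition> p = (%.3f, %.3f), s = (%.3g, %.3g)\n",
              x$p_axis[1], x$p_axis[2],
              x$singular_values[1], x$singular_values[2]))
  invisible(x)
}

#' Per-axis mean squared displacements
#'
#' Projects the track coordinates onto the primary and non-primary axes and
#' computes the 1D time-averaged MSD of each projection. By orthonormality
#' the two curves sum exactly to the 2D MSD at every lag.
#'
#' @param tr a 2D [track()].
#' @param axes its [svd_axes()] decomposition (computed if missing).
#' @param max_lag_fraction passed to [track_msd()].
#' @return list with elements `p` and `np`, each an `msd_curve`.
#' @export
axis_msds <- function(tr, axes = svd_axes(tr), max_lag_fraction = 0.5) {
  stopifnot(inherits(tr, "track"), inherits(axes, "axis_decomposition"))
  rot <- tr$positions %*% axes$basis
  mk <- function(j) {
    tr1 <- track(tr$id, tr$times, cbind(rot[, j], 0))
    m <- track_msd(tr1, max_lag_fraction)
    # second (zero) column contributes nothing; this is the 1D MSD
    m
  }
  list(p = mk(1), np = mk(2))
}

#' Velocity magnitude profile around the primary axis
#'
#' For every track, step velocities are expressed in that track's own
#' (primary, non-primary) frame and their orientations measured from the
#' primary axis; the mean velocity magnitude per angular bin is pooled over
#' all tracks. Anisotropic migration shows maxima at 0 and 180 degrees.
#'
#' @param ts a 2D `track_set`.
#' @param n_bins number of equal angular bins on \[0, 360) degrees.
#' @return An object of class `"orientation_profile"`: list with
#'   `angle_bins` (bin centres, degrees), `mean_speed` (micrometres/hour,
#'   `NA` for empty bins) and `n_steps` per bin.
#' @export
orientation_profile <- function(ts, n_bins = 24) {
  stopifnot(inherits(ts, "track_set"))
  if (ts$dim != 2L) stop("orientation_profile requires a 2D track set")
  ang <- c(); spd <- c()
  for (tr in ts$tracks) {
    if (length(tr$times) < 3) next
    ax <- tryCatch(svd_axes(tr), error = function(e) NULL)
    if (is.null(ax)) next
    V <- ax$rotated_velocities
    mag <- sqrt(rowSums(V^2))
    ok <- mag > 0
    ang <- c(ang, (atan2(V[ok, 2], V[ok, 1]) * 180 / pi) %% 360)
    spd <- c(spd, mag[ok])
  }
  if (!length(ang)) stop("no usable velocity steps")
  edges <- seq(0, 360, length.out = n_bins + 1)
  bin <- findInterval(ang, edges, rightmost.closed = TRUE)
  ms <- rep(NA_real_, n_bins)
  ns <- integer(n_bins)
  agg <- tapply(spd, bin, mean)
  cnt <- tapply(spd, bin, length)
  ms[as.integer(names(agg))] <- as.numeric(agg)
  ns[as.integer(names(cnt))] <- as.integer(cnt)
  structure(list(angle_bins = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 mean_speed = ms, n_steps = ns),
            class = "orientation_profile")
}

#' @export
print.orientation_profile <- function(x, ...) {
  cat(sprintf("<orientation_profile> %d bins, mean speed %.3g um/hr\n",
              length(x$angle_bins), mean(x$mean_speed, na.rm = TRUE)))
  invisible(x)
}
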