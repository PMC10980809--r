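#' Radial spheroid outgrowth from a binary mask
#'
#' Casts `n_rays` equally spaced rays from the spheroid centre and records,
#' per ray, the distance to the farthest positive pixel (sampled every
#' `step` pixels along the ray); the mean of the per-ray distances minus the
#' spheroid radius, floored at zero, is the average cell outgrowth.
#'
#' Coordinate convention: the mask is indexed `[y, x]` (row = y, column =
#' x); `center` is `c(x, y)` in pixel units; ray angle 0 points along +x
#' ("east") and angles increase counterclockwise in the (x, y) plane. Rays
#' that never hit a positive pixel contribute distance 0 and are flagged.
#'
#' @param mask binary matrix (`[y, x]`), at least one positive pixel.
#' @param center spheroid centre `c(x, y)`, pixels; must lie inside the
#'   image.
#' @param spheroid_radius spheroid radius, micrometres.
#' @param pixel_size micrometres per pixel.
#' @param n_rays number of rays (default 8).
#' @param start_angle angle of the first ray, degrees.
#' @param step ray sampling step, pixels (default 0.25).
#' @return An object of class `"outgrowth_measurement"`: list with
#'   `per_ray_distance` (micrometres from the centre), `mean_outgrowth`
#'   (micrometres beyond the spheroid radius), `center`, `spheroid_radius`
#'   and `rays_missed` (indices of rays with no positive pixel).
#' @export
radial_outgrowth <- function(mask, center, spheroid_radius, pixel_size = 1,
                             n_rays = 8, start_angle = 0, step = 0.25) {
  mask <- as.matrix(mask)
  if (!any(mask > 0)) stop("mask has no positive pixels")
  ny <- nrow(mask); nx <- ncol(mask)
  if (center[1] < 1 || center[1] > nx || center[2] < 1 || center[2] > ny)
    stop("center must lie inside the image")
  if (spheroid_radius < 0) stop("spheroid_radius must be >= 0")
  angles <- start_angle + 360 / n_rays * (seq_len(n_rays) - 1)
  rad <- angles * pi / 180
  rmax_px <- sqrt(nx^2 + ny^2)
  per_ray_px <- numeric(n_rays)
  missed <- integer()
  for (k in seq_len(n_rays)) {
    rs <- seq(0, rmax_px, by = step)
    xs <- center[1] + rs * cos(rad[k])
    ys <- center[2] + rs * sin(rad[k])
    inside <- xs >= 0.5 & xs <= nx + 0.5 & ys >= 0.5 & ys <= ny + 0.5
    rs <- rs[inside]
    ij <- cbind(pmin(pmax(round(ys[inside]), 1), ny),
                pmin(pmax(round(xs[inside]), 1), nx))
    hit <- mask[ij] > 0
    if (!any(hit)) {
      per_ray_px[k] <- 0
      missed <- c(missed, k)
    } else {
      per_ray_px[k] <- rs[max(which(hit))]
    }
  }
  per_ray <- per_ray_px * pixel_size
  structure(list(per_ray_distance = per_ray,
                 mean_outgrowth = max(mean(per_ray) - spheroid_radius, 0),
                 center = center, spheroid_radius = spheroid_radius,
                 rays_missed = missed),
            class = "outgrowth_measurement")
}

#' @export
print.outgrowth_measurement <- function(x, ...) {
  cat(sprintf("<outgrowth_measurement> mean outgrowth %.2f um (%d rays%s)\n",
              x$mean_outgrowth, length(x$per_ray_distance),
              if (length(x$rays_missed))
                sprintf(", %d missed", length(x$rays_missed)) else ""))
  invisible(x)
}

#' Extent along the shortest principal axis of a 3D point cloud
#'
#' Principal axes are taken from the eigenvectors of the point covariance
#' matrix; the extent is max minus min of the projections onto the axis of
#' smallest variance. This approximates the shortest side of an
#' object-oriented bounding box (exact minimum-volume boxes require a
#' combinatorial search) and is invariant under rigid rotation and
#' translation. Used to quantify outgrowth perpendicular to a planar
#' interface.
#'
#' @param points numeric matrix, one 3D coordinate (micrometres) per row;
#'   at least 2 points.
#' @return An object of class `"perp_extent"`: list with `extent`
#'   (micrometres), `axis` (unit 3-vector) and `degenerate` (`TRUE` when the
#'   points are (nearly) coplanar or fewer than 4 non-coplanar points were
#'   given).
#' @export
perpendicular_extent <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  if (ncol(points) != 3) stop("points must be 3D")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  axis <- ev$vectors[, 3]
  proj <- X %*% axis
  extent <- max(proj) - min(proj)
  degenerate <- nrow(points) < 4 ||
    ev$values[3] <= 1e-12 * max(ev$values[1], 1e-300)
  structure(list(extent = extent, axis = axis, degenerate = degenerate),
            class = "perp_extent")
}

#' @export
print.perp_extent <- function(x, ...) {
  cat(sprintf("<perp_extent> %.3f um%s\n", x$extent,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Infiltration depth statistics
#'
#' Maximum infiltration is the 95th percentile of the depth distribution
#' (linear interpolation between order statistics), a robust alternative to
#' the raw maximum; the depth profile is the fraction of cells per depth
#' bin. Bins are `[edge_i, edge_(i+1))` with the final bin closed; depths
#' beyond the last edge are counted in the final bin so the fractions always
#' form a probability vector.
#'
#' @param depths non-negative infiltration depths, micrometres (>= 1 value).
#' @param bin_edges increasing bin edges, micrometres (default
#'   `c(0, 50, 100)`).
#' @param probability quantile level for the maximum-infiltration statistic
#'   (default 0.95).
#' @return An object of class `"infiltration_profile"`: list with `depths`,
#'   `max_infiltration` (micrometres), `bin_edges` and `bin_fractions`.
#' @export
infiltration_stats <- function(depths, bin_edges = c(0, 50, 100),
                               probability = 0.95) {
  if (!length(depths)) stop("depths is empty")
  if (any(!is.finite(depths)) || any(depths < 0))
    stop("depths must be finite and >= 0")
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop("bin_edges must be increasing with >= 2 values")
  q <- stats::quantile(depths, probability, names = FALSE, type = 7)
  nb <- length(bin_edges) - 1
  clamped <- pmin(depths, bin_edges[length(bin_edges)])
  bin <- findInterval(clamped, bin_edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), nb)
  fractions <- tabulate(bin, nbins = nb) / length(depths)
  structure(list(depths = depths, max_infiltration = q,
                 bin_edges = bin_edges, bin_fractions = fractions),
            class = "infiltration_profile")
}

#' @export
print.infiltration_profile <- function(x, ...) {
  cat(sprintf("<infiltration_profile> n = %d, 95%% depth %.1f um\n",
              length(x$depths), x$max_infiltration))
  nb <- length(x$bin_fractions)
  for (i in seq_len(nb))
    cat(sprintf("  [%g, %g%s: %.3f\n", x$bin_edges[i], x$bin_edges[i + 1],
                if (i == nb) "]" else ")", x$bin_fractions[i]))
  invisible(x)
}
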