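#' Indentation force-depth curve
#'
#' The loading portion of a spherical-probe nanoindentation, assumed zeroed
#' at the contact point: depth non-negative and non-decreasing.
#'
#' @param depth indentation depths, micrometres.
#' @param force forces, nanonewtons (same length).
#' @param probe_radius sphere radius, micrometres (> 0).
#' @param poisson Poisson's ratio; 0.49 by convention for highly swollen
#'   hydrogels.
#' @return An object of class `"force_curve"`.
#' @export
force_curve <- function(depth, force, probe_radius, poisson = 0.49) {
  if (length(depth) != length(force)) stop("depth and force lengths differ")
  if (any(!is.finite(depth)) || any(!is.finite(force)))
    stop("depth and force must be finite")
  if (any(depth < 0)) stop("depths must be >= 0 (curve zeroed at contact)")
  if (any(diff(depth) < 0)) stop("depth must be non-decreasing")
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  if (poisson < 0 || poisson >= 0.5) stop("poisson must be in [0, 0.5)")
  structure(list(depth = as.numeric(depth), force = as.numeric(force),
                 probe_radius = probe_radius, poisson = poisson),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %d points, depth to %.3g um, force to %.3g nN (R = %g um, nu = %g)\n",
              length(x$depth), max(x$depth), max(x$force), x$probe_radius,
              x$poisson))
  invisible(x)
}

# Hertz spherical-contact forward model.
# Units: E kPa, R and delta micrometres, force nanonewtons
# (1 kPa = 1 nN/um^2, so no conversion factor appears).
hertz_force <- function(depth, E, R, nu) {
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * pmax(depth, 0)^1.5
}

#' Hertz fit of an indentation curve
#'
#' Least-squares fit of the spherical Hertz contact model
#' `F = (4/3) (E_ind / (1 - nu^2)) sqrt(R) delta^(3/2)` to the entire
#' loading portion, giving the effective indentation modulus `E_ind` in kPa
#' (with depth in micrometres and force in nanonewtons the unit conversion
#' is exactly 1). With `fit_offset = FALSE` (default; curves assumed zeroed
#' at contact) the model is linear in `E_ind` and solved in closed form,
#' floored at zero. With `fit_offset = TRUE` a contact offset `delta_0` is
#' fitted as a second parameter for un-zeroed inputs.
#'
#' @param curve a [force_curve()] with >= 5 points.
#' @param fit_offset also fit the contact-point offset (default `FALSE`).
#' @return An object of class `"indentation_result"`: list with `E_ind`
#'   (kPa, >= 0), `contact_offset` (micrometres), `rss` (nN^2) and
#'   `converged`.
#' @export
fit_hertz <- function(curve, fit_offset = FALSE) {
  stopifnot(inherits(curve, "force_curve"))
  if (length(curve$depth) < 5) stop("need >= 5 points")
  d <- curve$depth; f <- curve$force
  R <- curve$probe_radius; nu <- curve$poisson
  k_geom <- (4 / 3) * sqrt(R) / (1 - nu^2)
  if (!fit_offset) {
    x <- d^1.5
    E <- if (sum(x^2) > 0) max(sum(f * x) / sum(x^2) / k_geom, 0) else 0
    res <- f - hertz_force(d, E, R, nu)
    return(structure(list(E_ind = E, contact_offset = 0,
                          rss = sum(res^2), converged = TRUE),
                     class = "indentation_result"))
  }
  obj <- function(par) {
    sum((f - hertz_force(d - par[2], par[1], R, nu))^2)
  }
  x0 <- d^1.5
  E0 <- if (sum(x0^2) > 0) max(sum(f * x0) / sum(x0^2) / k_geom, 0) else 0
  best <- NULL
  for (off0 in c(0, 0.1, 0.25) * max(d)) {
    o <- tryCatch(
      stats::optim(c(max(E0, 1e-6), off0), obj, method = "L-BFGS-B",
                   lower = c(0, -max(d)), upper = c(Inf, max(d) * 0.9),
                   control = list(maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("Hertz fit failed: optimizer error")
  structure(list(E_ind = best$par[1], contact_offset = best$par[2],
                 rss = best$value, converged = best$convergence == 0),
            class = "indentation_result")
}

#' @export
print.indentation_result <- function(x, ...) {
  cat(sprintf("<indentation_result> E_ind = %.3g kPa (offset %.3g um, rss %.3g nN^2)\n",
              x$E_ind, x$contact_offset, x$rss))
  invisible(x)
}

#' Spatial force map of fitted moduli
#'
#' A rectangular grid of effective indentation moduli (e.g. from an 8 x 8
#' AFM force map) together with a removal mask; outliers are flagged, never
#' silently deleted.
#'
#' @param E matrix of moduli, kPa (`NA` allowed for failed nodes).
#' @param spacing grid spacing, micrometres.
#' @return An object of class `"force_map"`: list with `E`, `removed`
#'   (logical matrix, initially all `FALSE`) and `spacing`.
#' @export
force_map <- function(E, spacing = 15) {
  E <- as.matrix(E)
  structure(list(E = E, removed = array(FALSE, dim = dim(E)) | is.na(E),
                 spacing = spacing),
            class = "force_map")
}

#' Force-map summary statistics with IQR outlier removal
#'
#' Removes map entries outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (quartiles by
#' linear interpolation; the conventional "IQR method"), then reports the
#' mean modulus and coefficient of variation (sd/mean, sample sd) of the
#' survivors. Fences are computed from all measured (non-`NA`) entries, so
#' applying the removal repeatedly never flags anything further: the rule is
#' idempotent.
#'
#' @param map a [force_map()] (or bare matrix) with >= 4 valid entries.
#' @return An object of class `"force_map_stats"`: list with `mean_modulus`
#'   (kPa), `cv`, `n_outliers`, `n_valid` and the updated `map` (outliers
#'   flagged in `removed`).
#' @export
map_stats <- function(map) {
  if (!inherits(map, "force_map")) map <- force_map(map)
  vals <- map$E[!is.na(map$E)]
  if (sum(!map$removed) < 4) stop("need >= 4 valid map entries")
  q <- stats::quantile(vals, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[2] + 1.5 * iqr
  out <- !map$removed & (map$E < lo | map$E > hi)
  out[is.na(out)] <- FALSE
  map$removed <- map$removed | out
  surv <- map$E[!map$removed]
  if (!length(surv)) stop("all map entries removed as outliers")
  structure(list(mean_modulus = mean(surv),
                 cv = stats::sd(surv) / mean(surv),
                 n_outliers = sum(out), n_valid = length(surv),
                 map = map),
            class = "force_map_stats")
}

#' @export
print.force_map_stats <- function(x, ...) {
  cat(sprintf("<force_map_stats> mean %.3g kPa, CV %.3f, %d outlier(s) removed, %d valid\n",
              x$mean_modulus, x$cv, x$n_outliers, x$n_valid))
  invisible(x)
}
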