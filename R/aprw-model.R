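#' Fit the anisotropic persistent random walk model to a track set
#'
#' The central fitting function of the package. For every track: (i) the
#' velocity matrix is decomposed by SVD into primary and non-primary
#' migration axes ([svd_axes()]); (ii) the 1D time-averaged MSDs along the
#' two axes are computed ([axis_msds()]); (iii) both curves are fitted
#' jointly to the per-axis persistent-random-walk MSD model with a shared
#' positional-noise variance ([fit_aprw()]); (iv) diffusivities and the
#' anisotropy index are derived ([motility_metrics()]). Per-cell results are
#' then averaged arithmetically into a population summary
#' ([population_summary()]).
#'
#' 3D input is first projected onto the xy-plane, mirroring the standard
#' treatment of confocal trajectory data whose axial resolution is much
#' coarser than the in-plane one.
#'
#' The fit window defaults to the first `max(10, ceiling(0.05 * (N - 1)))`
#' lags of each track. Short lags carry essentially all of the recoverable
#' information: the time-averaged MSD of a single finite track fluctuates
#' with a relative standard deviation that grows like `sqrt(tau/T)` and is
#' strongly correlated across lags, so extending the window degrades rather
#' than improves the fit (see the vignette for the supporting simulation).
#'
#' @param x a [track_set()] (2D or 3D).
#' @param max_lag_fraction per-track MSD length as a fraction of the track
#'   span (default 0.5); curves are stored at this length, fitting uses
#'   `n_fit_lags`.
#' @param n_fit_lags number of short lags used in each per-cell fit;
#'   `NULL` (default) applies the rule above.
#' @param loss residual scale for [fit_aprw()] (`"log"` default).
#' @param min_samples tracks with fewer samples are skipped (default 11, the
#'   smallest N giving 5 lags at `max_lag_fraction = 0.5`).
#' @param ... ignored.
#' @return An object of class `"aprw"`: list with `fits` (per-cell
#'   `aprw_fit`s), `metrics` (per-cell data frame), `summary`
#'   (`aprw_summary`), `msd` (per-cell per-axis curves), `skipped` (ids of
#'   unusable tracks), `dt`, `n_tracks` and the matched `call`.
#' @examples
#' cfg <- aprw_sim_config(S_p = 30, P_p = 1, S_np = 15, P_np = 0.5,
#'                        sigma = 0.5, n_tracks = 20, duration = 20,
#'                        sample_dt = 0.25, seed = 1)
#' ts <- simulate_aprw_tracks(cfg)
#' fit <- aprw(ts)
#' fit
#' coef(fit)
#' @export
aprw <- function(x, max_lag_fraction = 0.5, n_fit_lags = NULL,
                 loss = c("log", "absolute"), min_samples = 11, ...) {
  stopifnot(inherits(x, "track_set"))
  loss <- match.arg(loss)
  cl <- match.call()
  if (x$dim == 3L) x <- suppressWarnings(project_to_2d(x))

  fits <- list(); msds <- list(); skipped <- character()
  for (tr in x$tracks) {
    N <- length(tr$times)
    if (N < min_samples) { skipped <- c(skipped, tr$id); next }
    ax <- tryCatch(svd_axes(tr), error = function(e) NULL)
    if (is.null(ax)) { skipped <- c(skipped, tr$id); next }
    am <- axis_msds(tr, ax, max_lag_fraction)
    nf <- if (is.null(n_fit_lags)) max(10L, ceiling(0.05 * (N - 1))) else n_fit_lags
    nf <- min(nf, length(am$p$lags))
    if (nf < 5) { skipped <- c(skipped, tr$id); next }
    sub <- function(m) msd_curve(m$lags[1:nf], m$values[1:nf], m$n_pairs[1:nf])
    f <- fit_aprw(sub(am$p), sub(am$np), loss = loss)
    f$id <- tr$id
    fits[[tr$id]] <- f
    msds[[tr$id]] <- am
  }
  if (!length(fits))
    stop("no track was long enough to fit (need >= min_samples samples)")
  summ <- population_summary(fits)
  met <- summ$per_cell
  met <- cbind(data.frame(track_id = vapply(fits, `[[`, character(1), "id")[
    vapply(fits, function(f) isTRUE(f$converged), logical(1))],
    stringsAsFactors = FALSE), met)
  rownames(met) <- NULL
  structure(list(fits = fits, metrics = met, summary = summ, msd = msds,
                 skipped = skipped, dt = x$dt,
                 n_tracks = length(x$tracks), call = cl),
            class = "aprw")
}

#' @export
print.aprw <- function(x, ...) {
  cat("Anisotropic persistent random walk fit\n")
  cat(sprintf("  %d tracks (%d fitted, %d skipped), dt = %g h\n",
              x$n_tracks, length(x$fits), length(x$skipped), x$dt))
  s <- x$summary
  cat(sprintf("  S_p = %.2f um/hr, P_p = %.3f h, S_np = %.2f um/hr, P_np = %.3f h\n",
              s$S_p, s$P_p, s$S_np, s$P_np))
  cat(sprintf("  D_t = %.1f um^2/hr, phi = %.2f\n", s$D_t, s$phi))
  invisible(x)
}

#' @export
summary.aprw <- function(object, ...) object$summary

#' Population-mean APRW parameters
#'
#' @param object an `aprw` fit.
#' @param ... ignored.
#' @return named vector of the population means `S_p`, `P_p`, `S_np`,
#'   `P_np`, `sigma2`.
#' @export
coef.aprw <- function(object, ...) {
  s <- object$summary
  c(S_p = s$S_p, P_p = s$P_p, S_np = s$S_np, P_np = s$P_np,
    sigma2 = s$sigma2)
}

#' Model MSD curves implied by an APRW fit
#'
#' Evaluates the fitted per-axis MSD model at the requested lags, either for
#' one cell or for the population-mean parameters.
#'
#' @param object an `aprw` fit.
#' @param lags lag vector in hours (default: the fitted lag window).
#' @param cell a track id, or `NULL` (default) for population means.
#' @param ... ignored.
#' @return data frame with columns `lag_h`, `msd_p`, `msd_np`.
#' @export
predict.aprw <- function(object, lags = NULL, cell = NULL, ...) {
  p <- if (is.null(cell)) as.list(coef(object)) else {
    f <- object$fits[[cell]]
    if (is.null(f)) stop(sprintf("no fit for track '%s'", cell))
    list(S_p = f$S_p, P_p = f$P_p, S_np = f$S_np, P_np = f$P_np,
         sigma2 = f$sigma2)
  }
  if (is.null(lags)) lags <- object$fits[[1]]$lags
  data.frame(lag_h = lags,
             msd_p = aprw_msd_model(lags, p$S_p, p$P_p, p$sigma2),
             msd_np = aprw_msd_model(lags, p$S_np, p$P_np, p$sigma2))
}

#' Per-cell MSD residuals of an APRW fit
#'
#' Observed minus fitted per-axis MSD over each cell's fitted lag window.
#'
#' @param object an `aprw` fit.
#' @param ... ignored.
#' @return long data frame with columns `track_id`, `axis`, `lag_h`,
#'   `residual_um2`.
#' @export
residuals.aprw <- function(object, ...) {
  out <- lapply(object$fits, function(f) {
    if (!isTRUE(f$converged)) return(NULL)
    am <- object$msd[[f$id]]
    nf <- length(f$lags)
    rbind(
      data.frame(track_id = f$id, axis = "p", lag_h = f$lags,
                 residual_um2 = am$p$values[1:nf] -
                   aprw_msd_model(f$lags, f$S_p, f$P_p, f$sigma2)),
      data.frame(track_id = f$id, axis = "np", lag_h = f$lags,
                 residual_um2 = am$np$values[1:nf] -
                   aprw_msd_model(f$lags, f$S_np, f$P_np, f$sigma2)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate trajectories from a fitted APRW model
#'
#' Draws new track sets from the population-mean parameters of the fit, the
#' model-checking loop used to compare simulated against experimental MSD
#' and velocity-orientation profiles.
#'
#' @param object an `aprw` fit.
#' @param nsim number of track sets to generate.
#' @param seed integer seed.
#' @param n_tracks,duration,sample_dt simulation size; `sample_dt` defaults
#'   to the fitted sampling interval.
#' @param sigma positional noise sd, micrometres (default: from the fitted
#'   `sigma2`).
#' @param ... ignored.
#' @return a `track_set` (`nsim = 1`) or list of track sets.
#' @export
simulate.aprw <- function(object, nsim = 1, seed = 1, n_tracks = 50,
                          duration = 40, sample_dt = object$dt,
                          sigma = sqrt(pmax(object$summary$sigma2, 0)), ...) {
  p <- coef(object)
  out <- lapply(seq_len(nsim), function(i) {
    cfg <- aprw_sim_config(S_p = p[["S_p"]], P_p = p[["P_p"]],
                           S_np = p[["S_np"]], P_np = p[["P_np"]],
                           sigma = sigma, n_tracks = n_tracks,
                           duration = duration, sample_dt = sample_dt,
                           seed = seed + i - 1L)
    simulate_aprw_tracks(cfg)
  })
  if (nsim == 1) out[[1]] else out
}

#' Plot observed and fitted per-axis MSD curves
#'
#' Log-log display of the per-cell MSDs along the primary (solid grey) and
#' non-primary (dashed grey) axes, their population means, and the MSD model
#' at the population-mean parameters.
#'
#' @param x an `aprw` fit.
#' @param max_cells draw at most this many individual cells (default 30).
#' @param ... passed to [graphics::plot()].
#' @export
plot.aprw <- function(x, max_cells = 30, ...) {
  ids <- names(x$msd)
  show <- ids[seq_len(min(length(ids), max_cells))]
  all_lags <- x$msd[[show[1]]]$p$lags
  rng_y <- range(unlist(lapply(x$msd[show], function(am)
    c(am$p$values, am$np$values))))
  rng_y[1] <- max(rng_y[1], 1e-3)
  graphics::plot(NA, xlim = range(all_lags), ylim = rng_y, log = "xy",
                 xlab = "lag (h)", ylab = expression(MSD ~ (mu * m^2)), ...)
  for (id in show) {
    am <- x$msd[[id]]
    graphics::lines(am$p$lags, pmax(am$p$values, 1e-3),
                    col = grDevices::grey(0.8))
    graphics::lines(am$np$lags, pmax(am$np$values, 1e-3),
                    col = grDevices::grey(0.8), lty = 2)
  }
  pr <- predict(x, lags = all_lags)
  graphics::lines(pr$lag_h, pr$msd_p, col = "black", lwd = 2)
  graphics::lines(pr$lag_h, pr$msd_np, col = "black", lwd = 2, lty = 2)
  graphics::legend("topleft", c("primary (fit)", "non-primary (fit)"),
                   lty = c(1, 2), lwd = 2, bty = "n")
  invisible(x)
}
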