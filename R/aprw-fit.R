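#' Model MSD of a persistent random walk along one axis
#'
#' `S^2 P^2 (exp(-tau/P) + tau/P - 1) + 2 sigma2`: the 1D time-averaged MSD
#' of a persistent random walk with speed `S` (micrometres/hour) and
#' persistence time `P` (hours), observed with independent positional noise
#' of variance `sigma2` (square micrometres) per coordinate.
#'
#' @param tau lag(s), hours.
#' @param S speed, micrometres/hour.
#' @param P persistence time, hours.
#' @param sigma2 positional noise variance, square micrometres.
#' @return model MSD values, square micrometres.
#' @export
aprw_msd_model <- function(tau, S, P, sigma2 = 0) {
  S^2 * P^2 * (exp(-tau / P) + tau / P - 1) + 2 * sigma2
}

#' Joint APRW fit of the two per-axis MSD curves
#'
#' Fits the primary-axis curve to `S_p^2 P_p^2 (exp(-tau/P_p) + tau/P_p - 1)
#' + 2 sigma^2` and the non-primary curve to the same form in `S_np, P_np`,
#' with one shared positional-noise variance `sigma^2`, by bounded nonlinear
#' least squares (multi-start L-BFGS-B over log-parameters, all parameters
#' >= 0; persistence times are capped at twice the longest fitted lag, since
#' longer persistence is not identifiable from the window). After fitting,
#' axes are swapped if needed so that `S_p^2 P_p >= S_np^2 P_np` (the primary
#' axis is the more diffusive one by convention).
#'
#' Residuals are taken on the log scale by default (`loss = "log"`),
#' equivalent to weighting each lag by its relative error. This matters: the
#' time-averaged MSD of a single track has fluctuations that grow roughly
#' linearly with lag and are strongly correlated, so unweighted absolute
#' residuals (`loss = "absolute"`) let the longest lags dominate and are
#' useless for parameter recovery unless the curve is truncated to short
#' lags. See the package vignette for the simulation study behind this
#' default.
#'
#' @param msd_p,msd_np per-axis `msd_curve`s sharing the same lags (>= 5).
#' @param loss `"log"` (default) or `"absolute"` residuals.
#' @param n_starts number of persistence-time multi-starts (default 5).
#' @return An object of class `"aprw_fit"`: list with `S_p`, `P_p`, `S_np`,
#'   `P_np` (micrometres/hour and hours), `sigma2` (square micrometres),
#'   `rss` (sum of squared absolute residuals, um^4), `converged`, `loss`,
#'   and the fitted lag window `lags`.
#' @export
fit_aprw <- function(msd_p, msd_np, loss = c("log", "absolute"), n_starts = 5) {
  stopifnot(inherits(msd_p, "msd_curve"), inherits(msd_np, "msd_curve"))
  loss <- match.arg(loss)
  if (length(msd_p$lags) != length(msd_np$lags) ||
      any(abs(msd_p$lags - msd_np$lags) > 1e-9))
    stop("the two MSD curves must share the same lags")
  tau <- msd_p$lags
  if (length(tau) < 5) stop("need >= 5 shared lags for the joint fit")
  yp <- msd_p$values; yn <- msd_np$values

  obj <- if (loss == "log") {
    eps <- 1e-12
    function(par) {
      a <- aprw_msd_model(tau, par[1], par[2], par[5])
      b <- aprw_msd_model(tau, par[3], par[4], par[5])
      sum((log(pmax(yp, eps)) - log(pmax(a, eps)))^2 +
          (log(pmax(yn, eps)) - log(pmax(b, eps)))^2)
    }
  } else {
    function(par) {
      a <- aprw_msd_model(tau, par[1], par[2], par[5])
      b <- aprw_msd_model(tau, par[3], par[4], par[5])
      sum((yp - a)^2 + (yn - b)^2)
    }
  }

  # Optimisation runs over log-parameters: all quantities are positive
  # scales, the boundary S = 0 or sigma2 = 0 is reached smoothly at the
  # lower box edge, and the flat "ballistic valley" (S fixed, P -> Inf,
  # indistinguishable fits for P beyond the observed lags) is cut off by
  # capping P at twice the longest fitted lag -- persistence beyond the fit
  # window is not identifiable from the data.
  dt <- tau[1]
  P_cap <- 2 * max(tau)
  lo <- log(c(1e-8, 1e-6, 1e-8, 1e-6, 1e-10))
  hi <- log(c(1e6, P_cap, 1e6, P_cap, 1e8))
  objl <- function(th) obj(exp(th))
  half <- max(1L, length(tau) %/% 2L):length(tau)
  slope <- function(y) {
    if (length(half) < 2) return(max(y[length(y)] / tau[length(tau)], 1e-8))
    max(unname(stats::coef(stats::lm(y[half] ~ tau[half]))[2]), 1e-8)
  }
  sp <- slope(yp); sn <- slope(yn)
  P0s <- pmin(dt * c(0.5, 1, 2, 5, 10)[seq_len(max(1, n_starts))], P_cap)
  best <- NULL
  for (P0 in P0s) {
    start <- pmin(pmax(log(c(sqrt(sp / P0), P0, sqrt(sn / P0), P0,
                             max(yp[1] / 4, 1e-3))), lo), hi)
    o <- tryCatch(
      stats::optim(start, objl, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 1000, factr = 1e5)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    return(structure(list(S_p = NA_real_, P_p = NA_real_, S_np = NA_real_,
                          P_np = NA_real_, sigma2 = NA_real_, rss = Inf,
                          converged = FALSE, loss = loss, lags = tau),
                     class = "aprw_fit"))
  converged <- best$convergence == 0 && is.finite(best$value)
  # polish from the best start (tight tolerance; its own iteration-limit
  # flag is uninformative, so convergence is judged from the stage above)
  o2 <- tryCatch(
    stats::optim(best$par, objl, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 2000, factr = 1e1)),
    error = function(e) NULL)
  if (!is.null(o2) && o2$value <= best$value) {
    converged <- converged || o2$convergence == 0
    best <- o2
  }

  par <- exp(best$par)
  # snap effectively-zero boundary values to zero
  par[c(1, 3)][par[c(1, 3)] <= 2e-8] <- 0
  if (par[5] <= 2e-10) par[5] <- 0
  if (par[1]^2 * par[2] < par[3]^2 * par[4]) par <- par[c(3, 4, 1, 2, 5)]
  a <- aprw_msd_model(tau, par[1], par[2], par[5])
  b <- aprw_msd_model(tau, par[3], par[4], par[5])
  structure(list(S_p = par[1], P_p = par[2], S_np = par[3], P_np = par[4],
                 sigma2 = par[5],
                 rss = sum((yp - a)^2 + (yn - b)^2),
                 converged = converged,
                 loss = loss, lags = tau),
            class = "aprw_fit")
}

#' @export
print.aprw_fit <- function(x, ...) {
  cat(sprintf(
    "<aprw_fit> S_p %.3g um/hr  P_p %.3g h  S_np %.3g um/hr  P_np %.3g h  sigma2 %.3g um^2%s\n",
    x$S_p, x$P_p, x$S_np, x$P_np, x$sigma2,
    if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' Diffusivities and anisotropy index from an APRW fit
#'
#' `D_p = S_p^2 P_p / 4`, `D_np = S_np^2 P_np / 4` (square micrometres/hour),
#' total diffusivity `D_t = D_p + D_np`, anisotropy index `phi = D_p / D_np`
#' (`NA` with `phi_defined = FALSE` when `D_np = 0`).
#'
#' @param fit a converged `aprw_fit`.
#' @return An object of class `"motility_metrics"`: list with `D_p`, `D_np`,
#'   `D_t`, `phi`, `phi_defined`.
#' @export
motility_metrics <- function(fit) {
  stopifnot(inherits(fit, "aprw_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  D_p <- fit$S_p^2 * fit$P_p / 4
  D_np <- fit$S_np^2 * fit$P_np / 4
  structure(list(D_p = D_p, D_np = D_np, D_t = D_p + D_np,
                 phi = if (D_np > 0) D_p / D_np else NA_real_,
                 phi_defined = D_np > 0),
            class = "motility_metrics")
}

#' @export
print.motility_metrics <- function(x, ...) {
  cat(sprintf("<motility_metrics> D_p %.4g  D_np %.4g  D_t %.4g um^2/hr  phi %.3g\n",
              x$D_p, x$D_np, x$D_t, x$phi))
  invisible(x)
}

#' Population summary of per-cell APRW fits
#'
#' Arithmetic mean over the converged fits of each per-cell quantity: speeds,
#' persistence times, noise variance, diffusivities and anisotropy index are
#' computed per cell and then averaged. Non-converged fits are excluded and
#' counted. Because the mean of per-cell ratios `D_p/D_np` differs in general
#' from the ratio of mean diffusivities, both are reported (`phi` is the
#' per-cell mean, the default; `phi_ratio_of_means` the alternative).
#'
#' @param fits list of `aprw_fit` objects (at least one converged).
#' @return An object of class `"aprw_summary"`: list with the population
#'   means (`S_p`, `P_p`, `S_np`, `P_np`, `sigma2`, `D_p`, `D_np`, `D_t`,
#'   `phi`, `phi_ratio_of_means`), standard deviations in `sd`, and counts
#'   `n_converged`, `n_excluded`.
#' @export
population_summary <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  ok <- vapply(fits, function(f) inherits(f, "aprw_fit") && isTRUE(f$converged),
               logical(1))
  if (!any(ok)) stop("no converged fits to summarise")
  conv <- fits[ok]
  met <- lapply(conv, motility_metrics)
  tab <- data.frame(
    S_p = vapply(conv, `[[`, numeric(1), "S_p"),
    P_p = vapply(conv, `[[`, numeric(1), "P_p"),
    S_np = vapply(conv, `[[`, numeric(1), "S_np"),
    P_np = vapply(conv, `[[`, numeric(1), "P_np"),
    sigma2 = vapply(conv, `[[`, numeric(1), "sigma2"),
    D_p = vapply(met, `[[`, numeric(1), "D_p"),
    D_np = vapply(met, `[[`, numeric(1), "D_np"),
    D_t = vapply(met, `[[`, numeric(1), "D_t"),
    phi = vapply(met, `[[`, numeric(1), "phi"))
  means <- colMeans(tab, na.rm = TRUE)
  sds <- vapply(tab, stats::sd, numeric(1), na.rm = TRUE)
  structure(c(as.list(means),
              list(phi_ratio_of_means = means[["D_p"]] / means[["D_np"]],
                   sd = sds, per_cell = tab,
                   n_converged = sum(ok), n_excluded = sum(!ok))),
            class = "aprw_summary")
}

#' @export
print.aprw_summary <- function(x, ...) {
  cat(sprintf("<aprw_summary> %d cells (%d excluded)\n",
              x$n_converged, x$n_excluded))
  cat(sprintf("  S_p  %8.3f um/hr   P_p  %6.3f h\n", x$S_p, x$P_p))
  cat(sprintf("  S_np %8.3f um/hr   P_np %6.3f h\n", x$S_np, x$P_np))
  cat(sprintf("  D_p %8.2f  D_np %8.2f  D_t %8.2f um^2/hr\n",
              x$D_p, x$D_np, x$D_t))
  cat(sprintf("  phi (mean of per-cell ratios) %.3f   (ratio of means) %.3f\n",
              x$phi, x$phi_ratio_of_means))
  invisible(x)
}
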