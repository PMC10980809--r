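#' Configuration for the APRW trajectory simulator
#'
#' Bundles and validates the parameters of the stochastic simulation:
#' per-axis speeds and persistence times, positional noise, track count,
#' duration, the observation interval `sample_dt` and the finer integration
#' step `internal_dt`. The integration step must resolve the fastest
#' persistence time (`internal_dt <= min(P)/10`) and divide `sample_dt`
#' exactly; the default picks the largest divisor of `sample_dt` that is
#' `<= min(P)/20`.
#'
#' @param S_p,S_np per-axis speeds, micrometres/hour (>= 0).
#' @param P_p,P_np per-axis persistence times, hours (> 0).
#' @param sigma positional observation noise sd per coordinate, micrometres.
#' @param n_tracks number of tracks.
#' @param duration observed duration per track, hours.
#' @param sample_dt observation interval, hours.
#' @param internal_dt integration step, hours (`NULL` for the default rule).
#' @param seed integer RNG seed (Mersenne-Twister; simulations are exactly
#'   reproducible per seed).
#' @return An object of class `"aprw_sim_config"`.
#' @export
aprw_sim_config <- function(S_p, P_p, S_np, P_np, sigma = 0.5, n_tracks = 100,
                            duration = 40, sample_dt = 0.1,
                            internal_dt = NULL, seed = 1) {
  if (S_p < 0 || S_np < 0) stop("speeds must be >= 0")
  if (P_p <= 0 || P_np <= 0) stop("persistence times must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_tracks < 1 || duration <= 0 || sample_dt <= 0)
    stop("n_tracks, duration and sample_dt must be positive")
  Pmin <- min(P_p, P_np)
  if (is.null(internal_dt)) {
    k <- max(1L, ceiling(sample_dt / (Pmin / 20)))
    internal_dt <- sample_dt / k
  }
  k <- sample_dt / internal_dt
  if (abs(k - round(k)) > 1e-9)
    stop("sample_dt must be an integer multiple of internal_dt")
  if (internal_dt > Pmin / 10 + 1e-12)
    stop("internal_dt must be <= min(P_p, P_np)/10")
  structure(list(S_p = S_p, P_p = P_p, S_np = S_np, P_np = P_np,
                 sigma = sigma, n_tracks = as.integer(n_tracks),
                 duration = duration, sample_dt = sample_dt,
                 internal_dt = internal_dt, seed = as.integer(seed)),
            class = "aprw_sim_config")
}

#' Simulate APRW cell trajectories
#'
#' Each track carries two independent discrete Ornstein-Uhlenbeck velocity
#' processes, one per migration axis: `v <- (1 - dt/P) v + S sqrt(dt/P) w`
#' with standard normal `w`, integrated at `internal_dt`. Velocities start
#' from the stationary distribution of the discrete update (variance
#' `S^2/(2 - dt/P)`, which tends to the continuum value `S^2/2`) and a
#' burn-in of `10 max(P)` is discarded, so observed displacement statistics
#' are stationary. Positions are sampled every `sample_dt`; each track's
#' (primary, non-primary) frame is rotated by an independent uniform angle
#' (cells orient their primary axes individually); finally independent
#' normal positional noise of sd `sigma` is added per coordinate.
#'
#' The long-lag per-axis MSD slope of the generated tracks is `S^2 P`, the
#' diffusive limit of the persistent-random-walk MSD model.
#'
#' @param cfg an [aprw_sim_config()].
#' @param rotate rotate each track's frame by a random angle (default
#'   `TRUE`; `FALSE` keeps the primary axis on x, useful for axis-resolved
#'   checks).
#' @return a [track_set()] with times 0, `sample_dt`, ..., `duration`.
#' @export
simulate_aprw_tracks <- function(cfg, rotate = TRUE) {
  stopifnot(inherits(cfg, "aprw_sim_config"))
  set.seed(cfg$seed)
  dt <- cfg$internal_dt
  k <- as.integer(round(cfg$sample_dt / dt))
  nstep <- as.integer(round(cfg$duration / dt))
  burn <- as.integer(ceiling(10 * max(cfg$P_p, cfg$P_np) / dt))
  ou_axis <- function(S, P) {
    a <- 1 - dt / P
    b <- S * sqrt(dt / P)
    v0 <- stats::rnorm(1, 0, if (S > 0) sqrt(S^2 / (2 - dt / P)) else 0)
    w <- stats::rnorm(nstep + burn)
    v <- stats::filter(b * w, a, method = "recursive", init = v0)
    cumsum(as.numeric(v)[(burn + 1):(burn + nstep)] * dt)
  }
  tracks <- vector("list", cfg$n_tracks)
  for (i in seq_len(cfg$n_tracks)) {
    xy <- cbind(ou_axis(cfg$S_p, cfg$P_p), ou_axis(cfg$S_np, cfg$P_np))
    xy <- rbind(c(0, 0), xy[seq(k, nstep, by = k), , drop = FALSE])
    if (rotate) {
      th <- stats::runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      xy <- xy %*% t(R)
    }
    if (cfg$sigma > 0)
      xy <- xy + matrix(stats::rnorm(length(xy), 0, cfg$sigma), ncol = 2)
    tracks[[i]] <- track(sprintf("sim_%04d", i),
                         cfg$sample_dt * (0:(nrow(xy) - 1L)), xy)
  }
  track_set(tracks, dt = cfg$sample_dt, split_gaps = FALSE)
}

#' Configuration for the bicontinuous volume generator
#'
#' @param shape integer length-3 voxel dimensions.
#' @param voxel_size micrometres per voxel along each array dimension.
#' @param length_scale smoothing length scale, micrometres (>= 1 voxel).
#' @param fill_fraction target phase-1 (foreground) volume fraction, in
#'   (0, 1).
#' @param seed integer RNG seed.
#' @return An object of class `"volume_config"`.
#' @export
volume_config <- function(shape = c(128, 128, 128), voxel_size = c(1, 1, 1),
                          length_scale = 8, fill_fraction = 0.5, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 2)) stop("shape must be 3 dims >= 2")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  if (length_scale < min(voxel_size))
    stop("length_scale must be at least one voxel")
  if (fill_fraction <= 0 || fill_fraction >= 1)
    stop("fill_fraction must be in (0, 1)")
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 length_scale = length_scale, fill_fraction = fill_fraction,
                 seed = as.integer(seed)),
            class = "volume_config")
}

#' Generate a two-phase volume by thresholding a smoothed random field
#'
#' Seeded white noise is Gaussian-smoothed at the configured length scale
#' (per-axis sigma = `length_scale / voxel_size`, periodic FFT convolution)
#' and thresholded at the `1 - fill_fraction` quantile of the field, so the
#' phase-1 fraction equals `fill_fraction` up to ties. Low fill fractions
#' (<= 0.2) give sparse disconnected blobs; fill near 0.5 gives a
#' bicontinuous morphology in which both phases form single spanning
#' components when the length scale is well below the domain size.
#'
#' @param cfg a [volume_config()].
#' @return a [labeled_volume()].
#' @export
generate_bicontinuous_volume <- function(cfg) {
  stopifnot(inherits(cfg, "volume_config"))
  set.seed(cfg$seed)
  n <- cfg$shape
  noise <- array(stats::rnorm(prod(n)), dim = n)
  sig <- cfg$length_scale / cfg$voxel_size  # in voxels, per axis
  # Gaussian transfer function, separable over dimensions
  H <- 1
  for (d in 1:3) {
    f <- c(0:(n[d] %/% 2), -rev(seq_len(n[d] - n[d] %/% 2 - 1))) / n[d]
    h <- exp(-2 * (pi * sig[d] * f)^2)
    H <- H * array(rep(h, each = prod(n[seq_len(d - 1)])), dim = n)
  }
  field <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / prod(n)
  thr <- stats::quantile(field, 1 - cfg$fill_fraction, names = FALSE)
  labeled_volume(array(as.integer(field >= thr), dim = n),
                 voxel_size = cfg$voxel_size)
}

#' Generate a spheroid-outgrowth star mask with known per-ray truth
#'
#' Builds a binary mask whose boundary radius interpolates linearly (in
#' angle, periodically) between `n_rays` prescribed ray distances, so the
#' ray-cast outgrowth measurement has an exact constructed ground truth.
#'
#' @param center pixel coordinate `c(x, y)` of the spheroid centre.
#' @param spheroid_radius spheroid radius, micrometres.
#' @param per_ray_truth distances (micrometres) from the centre to the mask
#'   boundary along the `n_rays` equally spaced directions (angle 0 = +x,
#'   counterclockwise).
#' @param image_shape `c(nx, ny)` mask size in pixels.
#' @param pixel_size micrometres per pixel.
#' @param start_angle angle of the first ray, degrees.
#' @return list with `mask` (matrix indexed `[y, x]`, 0/1), `truth` (the
#'   per-ray distances) and the generator arguments.
#' @export
generate_outgrowth_mask <- function(center, spheroid_radius, per_ray_truth,
                                    image_shape, pixel_size = 1,
                                    start_angle = 0) {
  n_rays <- length(per_ray_truth)
  if (n_rays < 3) stop("need at least 3 ray distances")
  if (any(per_ray_truth < 0)) stop("ray distances must be >= 0")
  nx <- image_shape[1]; ny <- image_shape[2]
  xs <- (seq_len(nx) - center[1]) * pixel_size
  ys <- (seq_len(ny) - center[2]) * pixel_size
  px <- matrix(xs, nrow = ny, ncol = nx, byrow = TRUE)
  py <- matrix(ys, nrow = ny, ncol = nx)
  r <- sqrt(px^2 + py^2)
  theta <- (atan2(py, px) * 180 / pi - start_angle) %% 360
  seg <- 360 / n_rays
  i0 <- floor(theta / seg)        # ray index before each pixel angle
  frac <- theta / seg - i0
  r0 <- per_ray_truth[(i0 %% n_rays) + 1]
  r1 <- per_ray_truth[((i0 + 1) %% n_rays) + 1]
  bound <- r0 * (1 - frac) + r1 * frac
  mask <- matrix(as.integer(r <= bound), nrow = ny, ncol = nx)
  list(mask = mask, truth = per_ray_truth, center = center,
       spheroid_radius = spheroid_radius, pixel_size = pixel_size,
       start_angle = start_angle)
}

#' Generate infiltration depths from a named distribution
#'
#' @param n number of cells.
#' @param distribution `"uniform"` (parameters `min`, `max`),
#'   `"exponential"` (`rate`, truncated at >= 0 by construction) or
#'   `"point"` (`at`).
#' @param parameters named list of distribution parameters.
#' @param seed integer RNG seed.
#' @return numeric vector of non-negative depths, micrometres.
#' @export
generate_infiltration_depths <- function(n,
                                         distribution = c("uniform",
                                                          "exponential",
                                                          "point"),
                                         parameters = list(), seed = 1) {
  distribution <- match.arg(distribution)
  set.seed(seed)
  p <- parameters
  switch(distribution,
    uniform = stats::runif(n, p$min %||% 0, p$max %||% 100),
    exponential = stats::rexp(n, p$rate %||% 0.02),
    point = rep(p$at %||% 0, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate Hertz spherical-indentation force curves
#'
#' Forward model `F = (4/3) (E/(1 - nu^2)) sqrt(R) delta^(3/2)` (kPa,
#' micrometres, nanonewtons) with optional additive normal force noise.
#'
#' @param E_true modulus, kPa.
#' @param probe_radius sphere radius, micrometres.
#' @param poisson Poisson's ratio (default 0.49, the convention for highly
#'   swollen hydrogels).
#' @param noise_sd additive force noise sd, nanonewtons.
#' @param n_points samples per curve.
#' @param max_depth maximum indentation depth, micrometres.
#' @param n_curves number of curves.
#' @param seed integer RNG seed.
#' @return a [force_curve()] (`n_curves = 1`) or list of force curves.
#' @export
generate_hertz_curves <- function(E_true, probe_radius = 5, poisson = 0.49,
                                  noise_sd = 0, n_points = 100,
                                  max_depth = 1, n_curves = 1, seed = 1) {
  if (E_true < 0) stop("E_true must be >= 0")
  set.seed(seed)
  depth <- seq(0, max_depth, length.out = n_points)
  mk <- function() {
    f <- hertz_force(depth, E_true, probe_radius, poisson)
    if (noise_sd > 0) f <- f + stats::rnorm(n_points, 0, noise_sd)
    force_curve(depth, f, probe_radius, poisson)
  }
  out <- replicate(n_curves, mk(), simplify = FALSE)
  if (n_curves == 1) out[[1]] else out
}
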