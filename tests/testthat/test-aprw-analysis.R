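# MSD computation, axis decomposition and APRW fitting

test_that("track_msd matches closed forms and the O(N^2) brute force", {
  still <- track("s", 0:9, matrix(2, 10, 2))
  expect_true(all(track_msd(still)$values == 0))

  v <- c(3, -4)  # |v| = 5
  bal <- track("b", 0:20, outer(0:20, v))
  m <- track_msd(bal)
  expect_equal(m$values, 25 * m$lags^2, tolerance = 1e-12)
  expect_equal(m$n_pairs, 21L - seq_along(m$lags))

  set.seed(5)
  for (n in c(8, 20, 50)) {
    tr <- random_track(n = n, dt = 0.5)
    got <- track_msd(tr)
    want <- msd_brute(tr$positions, 0.5)
    expect_equal(got$lags, want$lags)
    expect_equal(got$values, want$values, tolerance = 1e-12)
  }
  expect_error(track_msd(track("u", c(0, 1, 3), cbind(0:2, 0:2))),
               "not uniform")
})

test_that("population_msd averages per-track MSDs over contributors", {
  tr <- straight_track(n = 15, step = c(1, 1))
  ts <- track_set(list(tr, tr, tr), dt = 1)
  expect_equal(population_msd(ts)$values, track_msd(tr)$values)

  still <- track("s", 0:14, matrix(0, 15, 2))
  bal <- straight_track("b", n = 15, step = c(2, 0))
  both <- population_msd(track_set(list(still, bal), dt = 1))
  expect_equal(both$values, track_msd(bal)$values / 2)

  set.seed(6)
  trs <- lapply(1:5, function(i) random_track(paste0("r", i),
                                              n = sample(10:30, 1)))
  ts2 <- track_set(trs, dt = 1)
  pm <- population_msd(ts2)
  per <- lapply(trs, function(tr) msd_brute(tr$positions, 1)$values)
  for (k in seq_along(pm$lags)) {
    contrib <- Filter(function(v) length(v) >= k, per)
    expect_equal(pm$values[k], mean(vapply(contrib, `[`, numeric(1), k)),
                 tolerance = 1e-12)
  }
})

test_that("fit_alpha recovers exact power laws", {
  lags <- 1:20
  lin <- msd_curve(lags, 7 * lags, rep(50L, 20))
  expect_equal(fit_alpha(lin)$alpha, 1, tolerance = 1e-12)
  quad <- msd_curve(lags, 0.3 * lags^2, rep(50L, 20))
  expect_equal(fit_alpha(quad)$alpha, 2, tolerance = 1e-12)
  expect_equal(fit_alpha(quad)$prefactor, 0.3, tolerance = 1e-12)
  expect_error(fit_alpha(lin, c(1, 2.5)), ">= 3 lags")
})

test_that("angular displacements follow the inner-product definition", {
  # straight line: all angles 0 -> first bin only
  ts <- track_set(list(straight_track(n = 20)), dt = 1)
  d <- angular_displacements(ts, lag = 1, n_bins = 18)
  expect_equal(sum(d$density) * 10, 1, tolerance = 1e-9)  # integrates to 1
  expect_equal(d$density[1] * 10, 1, tolerance = 1e-9)

  # perfect back-and-forth: all angles 180 -> last bin
  bf <- track("bf", 0:20, cbind(rep(c(0, 1), length.out = 21), 0))
  d2 <- angular_displacements(track_set(list(bf), dt = 1), 1, 18)
  expect_equal(d2$density[18] * 10, 1, tolerance = 1e-9)

  # hand-computed 3-step path
  pos <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  tr <- track("h", 0:3, pos)
  # steps: (1,0), (0,1), (-1,0); angles between consecutive: 90, 90
  d3 <- angular_displacements(track_set(list(tr), dt = 1), 1, 4)
  expect_equal(d3$n_angles, 2L)
  expect_equal(d3$density[2] * 45, 1, tolerance = 1e-9)  # 90 deg in (45, 90]

  # zero-magnitude pairs are skipped and counted
  wz <- track("z", 0:4, rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0), c(3, 0)))
  d4 <- angular_displacements(track_set(list(wz), dt = 1), 1, 4)
  expect_equal(d4$n_skipped, 2L)
  expect_equal(d4$n_angles, 1L)
})

test_that("svd_axes finds the dominant axis with the expected symmetries", {
  ax <- svd_axes(straight_track(n = 10, step = c(2, 0)))
  expect_equal(abs(ax$p_axis), c(1, 0), tolerance = 1e-12)
  expect_equal(ax$singular_values[2], 0, tolerance = 1e-12)

  set.seed(8)
  tr <- random_track(n = 30)
  ax0 <- svd_axes(tr)
  # energy conservation under the orthonormal rotation
  V <- diff(tr$positions)
  expect_equal(sum(ax0$rotated_velocities^2), sum(V^2), tolerance = 1e-9)
  # equivariance: rotating the track rotates the primary axis (up to sign)
  for (th in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    trR <- track("rot", tr$times, tr$positions %*% t(R))
    axR <- svd_axes(trR)
    expect_equal(abs(sum(axR$p_axis * (R %*% ax0$p_axis))), 1,
                 tolerance = 1e-9)
  }
  expect_error(svd_axes(track("0", 0:5, matrix(1, 6, 2))), "degenerate")
})

test_that("axis MSDs obey the Pythagorean sum rule", {
  set.seed(9)
  for (i in 1:5) {
    tr <- random_track(n = 40)
    ax <- svd_axes(tr)
    am <- axis_msds(tr, ax)
    m2 <- track_msd(tr)
    expect_equal(am$p$values + am$np$values, m2$values, tolerance = 1e-9)
  }
  # motion along p only -> MSD_np identically zero
  tr1 <- straight_track(n = 20, step = c(1, 0))
  am1 <- axis_msds(tr1, svd_axes(tr1))
  expect_true(all(abs(am1$np$values) < 1e-18))
})

test_that("fit_aprw round-trips noiseless forward-model curves to 1e-4", {
  tau <- 0.1 * (1:40)
  truth <- c(S_p = 30, P_p = 1, S_np = 15, P_np = 0.5, sigma2 = 0.25)
  mp <- msd_curve(tau, aprw_msd_model(tau, 30, 1, 0.25), rep(100L, 40))
  mn <- msd_curve(tau, aprw_msd_model(tau, 15, 0.5, 0.25), rep(100L, 40))
  fit <- fit_aprw(mp, mn)
  expect_true(fit$converged)
  got <- c(fit$S_p, fit$P_p, fit$S_np, fit$P_np, fit$sigma2)
  expect_equal(got, unname(truth), tolerance = 1e-4)

  # degenerate limit: S = 0 on both axes -> flat curves at 2 sigma^2
  s2 <- 0.8
  flat <- msd_curve(tau, rep(2 * s2, 40), rep(100L, 40))
  fit0 <- fit_aprw(flat, flat)
  expect_equal(fit0$sigma2, s2, tolerance = 1e-6)
  expect_equal(fit0$S_p^2 * fit0$P_p, 0, tolerance = 1e-6)

  # axis ordering: swapped inputs come back with the diffusive axis primary
  fit_sw <- fit_aprw(mn, mp)
  expect_true(fit_sw$S_p^2 * fit_sw$P_p >= fit_sw$S_np^2 * fit_sw$P_np)
  expect_equal(fit_sw$S_p^2 * fit_sw$P_p, 30^2 * 1, tolerance = 1e-3)
})

test_that("motility metrics apply the diffusivity formulas", {
  f <- structure(list(S_p = 2, P_p = 1, S_np = 2, P_np = 1, sigma2 = 0,
                      rss = 0, converged = TRUE, loss = "log", lags = 1:5),
                 class = "aprw_fit")
  m <- motility_metrics(f)
  expect_equal(m$D_p, 1)
  expect_equal(m$D_t, m$D_p + m$D_np)
  expect_equal(m$phi, 1)
  f$S_np <- 0
  m0 <- motility_metrics(f)
  expect_false(m0$phi_defined)
  expect_true(is.na(m0$phi))
})

test_that("population_summary averages per-cell quantities", {
  mkfit <- function(S_p, P_p, S_np, P_np) {
    structure(list(S_p = S_p, P_p = P_p, S_np = S_np, P_np = P_np,
                   sigma2 = 0.1, rss = 0, converged = TRUE, loss = "log",
                   lags = 1:5),
              class = "aprw_fit")
  }
  one <- population_summary(list(mkfit(10, 1, 5, 1)))
  expect_equal(one$S_p, 10)
  expect_equal(one$phi, 4)

  two <- population_summary(list(mkfit(10, 1, 5, 1), mkfit(20, 1, 5, 2)))
  expect_equal(two$S_p, 15)
  # mean of per-cell ratios differs from ratio of mean diffusivities
  # (cell ratios 4 and 8; diffusivity means 62.5 and 9.375)
  expect_equal(two$phi, mean(c(4, 8)))
  expect_equal(two$phi_ratio_of_means, (25 + 100) / (6.25 + 12.5))
  expect_true(two$phi != two$phi_ratio_of_means)

  bad <- mkfit(1, 1, 1, 1); bad$converged <- FALSE
  three <- population_summary(list(mkfit(10, 1, 5, 1), bad))
  expect_equal(three$n_excluded, 1L)
  expect_error(population_summary(list(bad)), "no converged")
})

test_that("orientation_profile is concentrated for 1D motion and flat for PRW", {
  ts <- track_set(list(straight_track(n = 30, step = c(3, 0)),
                       track("back", 0:29,
                             cbind(rep(c(0, 2), 15), 0))), dt = 1)
  pr <- orientation_profile(ts, n_bins = 8)
  occupied <- which(!is.na(pr$mean_speed))
  expect_true(all(pr$angle_bins[occupied] %in% c(22.5, 157.5, 202.5, 337.5)))

  cfg <- aprw_sim_config(S_p = 20, P_p = 1, S_np = 20, P_np = 1, sigma = 0,
                         n_tracks = 40, duration = 30, sample_dt = 0.5,
                         seed = 21)
  iso <- orientation_profile(simulate_aprw_tracks(cfg), n_bins = 8)
  spread <- diff(range(iso$mean_speed)) / mean(iso$mean_speed)
  expect_lt(spread, 0.35)  # flat within Monte-Carlo error
})

test_that("population APRW estimates stay accurate as track count grows", {
  # per-cell fits carry a small finite-track bias; the population mean must
  # remain within a few percent of truth and not degrade with sample size
  errs <- sapply(c(50, 200, 800), function(n) {
    cfg <- aprw_sim_config(S_p = 30, P_p = 0.5, S_np = 15, P_np = 0.5,
                           sigma = 0.5, n_tracks = n, duration = 15,
                           sample_dt = 0.1, seed = 60 + n)
    s <- aprw(simulate_aprw_tracks(cfg))$summary
    c(S_p = (s$S_p - 30) / 30, P_p = (s$P_p - 0.5) / 0.5)
  })
  expect_true(all(abs(errs["S_p", ]) < 0.05))
  expect_true(all(abs(errs["P_p", ]) < 0.15))
  expect_lt(abs(errs["S_p", 3]), abs(errs["S_p", 1]))
})

test_that("APRW estimators are translation invariant", {
  set.seed(13)
  tr <- random_track(n = 40)
  shift <- c(1000, -500)
  trS <- track(tr$id, tr$times, sweep(tr$positions, 2, -shift))
  expect_equal(track_msd(trS)$values, track_msd(tr)$values, tolerance = 1e-9)
  axA <- svd_axes(tr); axB <- svd_axes(trS)
  expect_equal(abs(sum(axA$p_axis * axB$p_axis)), 1, tolerance = 1e-12)
})
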