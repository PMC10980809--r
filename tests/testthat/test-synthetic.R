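# Seeded generators: statistical structure and reproducibility

test_that("simulator config enforces its invariants", {
  expect_error(aprw_sim_config(S_p = -1, P_p = 1, S_np = 1, P_np = 1), ">= 0")
  expect_error(aprw_sim_config(S_p = 1, P_p = 0, S_np = 1, P_np = 1), "> 0")
  expect_error(aprw_sim_config(S_p = 1, P_p = 1, S_np = 1, P_np = 1,
                               sample_dt = 0.3, internal_dt = 0.2),
               "integer multiple")
  expect_error(aprw_sim_config(S_p = 1, P_p = 1, S_np = 1, P_np = 1,
                               sample_dt = 0.4, internal_dt = 0.2),
               "min\\(P_p, P_np\\)/10")
  cfg <- aprw_sim_config(S_p = 10, P_p = 0.56, S_np = 5, P_np = 0.56,
                         sample_dt = 0.1)
  expect_lte(cfg$internal_dt, 0.56 / 20 + 1e-12)
  expect_equal(cfg$sample_dt / cfg$internal_dt,
               round(cfg$sample_dt / cfg$internal_dt))
})

test_that("simulated tracks are deterministic given the seed", {
  cfg <- aprw_sim_config(S_p = 20, P_p = 1, S_np = 10, P_np = 0.5,
                         n_tracks = 3, duration = 5, sample_dt = 0.25,
                         seed = 99)
  a <- simulate_aprw_tracks(cfg)
  b <- simulate_aprw_tracks(cfg)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_false(identical(simulate_aprw_tracks(cfg2), a))
})

test_that("zero-speed tracks show the pure noise floor 2 sigma^2", {
  sg <- 0.7
  cfg <- aprw_sim_config(S_p = 0, P_p = 1, S_np = 0, P_np = 1, sigma = sg,
                         n_tracks = 60, duration = 30, sample_dt = 1,
                         internal_dt = 0.1, seed = 17)
  ts <- simulate_aprw_tracks(cfg, rotate = FALSE)
  pm <- population_msd(ts)
  # per-axis noise floor is 2 sigma^2; the 2D MSD doubles it
  expect_equal(mean(pm$values), 4 * sg^2, tolerance = 0.1)
  x_msds <- sapply(ts$tracks, function(tr)
    mean(track_msd(track(tr$id, tr$times,
                         cbind(tr$positions[, 1], 0)))$values))
  expect_equal(mean(x_msds), 2 * sg^2, tolerance = 0.1)
})

test_that("ensemble per-axis MSD matches the closed form within 3 SE", {
  S_p <- 25; P_p <- 1; S_np <- 12; P_np <- 0.5; sg <- 0.3
  cfg <- aprw_sim_config(S_p = S_p, P_p = P_p, S_np = S_np, P_np = P_np,
                         sigma = sg, n_tracks = 500, duration = 12,
                         sample_dt = 0.25, seed = 23)
  ts <- simulate_aprw_tracks(cfg, rotate = FALSE)
  check_axis <- function(col, S, P) {
    per_track <- t(sapply(ts$tracks, function(tr)
      track_msd(track(tr$id, tr$times, cbind(tr$positions[, col], 0)),
                max_lag_fraction = 0.4)$values))
    lags <- cfg$sample_dt * seq_len(ncol(per_track))
    mu <- colMeans(per_track)
    se <- apply(per_track, 2, sd) / sqrt(nrow(per_track))
    expect_true(all(abs(mu - aprw_msd_model(lags, S, P, sg^2)) <=
                      3 * se + 0.02 * mu))
  }
  check_axis(1, S_p, P_p)
  check_axis(2, S_np, P_np)
})

test_that("long-lag per-axis MSD slope approaches S^2 P", {
  S <- 20; P <- 0.5
  cfg <- aprw_sim_config(S_p = S, P_p = P, S_np = 0, P_np = P, sigma = 0,
                         n_tracks = 300, duration = 30, sample_dt = 0.5,
                         seed = 31)
  ts <- simulate_aprw_tracks(cfg, rotate = FALSE)
  pm <- population_msd(ts)
  sel <- pm$lags >= 5 & pm$lags <= 15
  slope <- unname(coef(lm(pm$values[sel] ~ pm$lags[sel]))[2])
  expect_equal(slope, S^2 * P, tolerance = 0.1)
})

test_that("bicontinuous volume generator hits its fill fraction and morphology", {
  for (fill in c(0.1, 0.3, 0.5)) {
    v <- generate_bicontinuous_volume(
      volume_config(shape = c(48, 48, 48), length_scale = 5,
                    fill_fraction = fill, seed = 7))
    expect_equal(volume_fractions(v)[["phase1"]], fill, tolerance = 0.01)
  }
  # determinism
  cfgv <- volume_config(shape = c(24, 24, 24), length_scale = 3, seed = 5)
  expect_identical(generate_bicontinuous_volume(cfgv)$labels,
                   generate_bicontinuous_volume(cfgv)$labels)
  # sparse blobs at low fill: many objects, low phase-1 connectivity;
  # bicontinuous at 50% fill: both phases essentially one object
  lo <- generate_bicontinuous_volume(
    volume_config(shape = c(64, 64, 64), length_scale = 4,
                  fill_fraction = 0.1, seed = 8))
  hi <- generate_bicontinuous_volume(
    volume_config(shape = c(64, 64, 64), length_scale = 4,
                  fill_fraction = 0.5, seed = 8))
  expect_lt(phase_connectivity(lo, 1), 90)
  expect_gt(object_count(lo, 1), 5)
  expect_gt(phase_connectivity(hi, 1), 90)
  expect_gt(phase_connectivity(hi, 0), 90)
})

test_that("outgrowth mask generator reproduces its ground truth", {
  R_out <- 50; R_sph <- 20
  g <- generate_outgrowth_mask(c(70, 70), R_sph, rep(R_out, 8), c(140, 140))
  got <- radial_outgrowth(g$mask, g$center, R_sph)
  expect_equal(got$mean_outgrowth, R_out - R_sph, tolerance = 1)
  g0 <- generate_outgrowth_mask(c(70, 70), R_sph, rep(R_sph, 8), c(140, 140))
  expect_equal(radial_outgrowth(g0$mask, g0$center, R_sph)$mean_outgrowth, 0,
               tolerance = 1)
})

test_that("infiltration depth generator has the advertised quantiles", {
  d <- generate_infiltration_depths(10, "point", list(at = 42), seed = 1)
  expect_equal(infiltration_stats(d)$max_infiltration, 42)
  du <- generate_infiltration_depths(20000, "uniform",
                                     list(min = 0, max = 200), seed = 2)
  expect_equal(infiltration_stats(du)$max_infiltration, 190, tolerance = 2)
  expect_identical(generate_infiltration_depths(50, "exponential",
                                                list(rate = 0.02), seed = 3),
                   generate_infiltration_depths(50, "exponential",
                                                list(rate = 0.02), seed = 3))
})
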