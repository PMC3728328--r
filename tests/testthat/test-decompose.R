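test_that("washout correction leaves a constant trace unchanged", {
  t_s <- seq(0, 3600, by = 5)
  tr <- make_trace(t_s, rep(5, length(t_s)), rep(4, length(t_s)))
  out <- washout_correct(tr, tau_s = 420)
  expect_equal(out$vo2_ml_min, rep(5, length(t_s)), tolerance = 1e-9)
  expect_equal(out$vco2_ml_min, rep(4, length(t_s)), tolerance = 1e-9)
})

test_that("washout correction inverts a first-order step response", {
  tau <- 420
  t_s <- seq(0, 7200, by = 5)
  s <- 2; base <- 4
  vo2 <- base + s * (1 - exp(-t_s / tau))
  tr <- make_trace(t_s, vo2, 0.8 * vo2, tau_s = tau)
  out <- washout_correct(tr)
  interior <- t_s > 300 & t_s < 7000
  expect_true(all(abs(out$vo2_ml_min[interior] - (base + s)) < 0.01 * s))
})

test_that("washout correction round-trips generator output on steady segments", {
  cfg <- quick_session_config(seed = 21, noise_sd_vo2 = 0, noise_sd_vco2 = 0,
                              activity_burst_rate_per_h = 0,
                              rest_ee_sd_w = 0, rq_sd = 0, freeze_gap_s = 0)
  sim <- simulate_session(NULL, cfg)
  out <- washout_correct(sim$trace)
  mid <- sim$latent$time_s > -7200 & sim$latent$time_s < -600
  expect_equal(mean(out$vo2_ml_min[mid]),
               mean(sim$latent$true_rest_vo2[mid]), tolerance = 1e-3)
  expect_error(washout_correct(make_trace(seq(0, 30, 5), rep(5, 7),
                                          rep(4, 7))),
               "smoothing window")
})

test_that("missing gaps propagate with a guard band through the correction", {
  t_s <- seq(0, 3600, by = 5)
  vo2 <- rep(5, length(t_s)); vco2 <- rep(4, length(t_s))
  miss <- t_s >= 1800 & t_s < 1900
  vo2[miss] <- NA; vco2[miss] <- NA
  tr <- make_trace(t_s, vo2, vco2, missing_flag = miss)
  out <- washout_correct(tr, tau_s = 420)
  expect_true(all(out$missing_flag[miss]))
  expect_gt(sum(out$missing_flag), sum(miss))          # guard band widens it
  expect_lt(sum(out$missing_flag), sum(miss) + 40)     # but only locally
})

test_that("decomposition recovers rest and a known activity cost within 5%", {
  cfg <- quick_session_config(seed = 31, noise_sd_vo2 = 0.01,
                              noise_sd_vco2 = 0.01, rest_ee_sd_w = 0,
                              rq_sd = 0, tef_fraction = 0, rq_rise_mean = 0,
                              post_meal_act_cost_gain = 0)
  t_s <- session_time_grid_for_tests(cfg)
  # piecewise-constant activity blocks with known cost
  act <- rep(0, length(t_s))
  act[t_s > -9000 & t_s < -7800] <- 20
  act[t_s > -3600 & t_s < -2400] <- 35
  act[t_s > 3600 & t_s < 4800] <- 25
  cost_vo2 <- 0.045; cost_vco2 <- 0.038
  lat <- make_latent(t_s, rep(4.5, length(t_s)), rep(3.6, length(t_s)),
                     rep(cost_vo2, length(t_s)), rep(cost_vco2, length(t_s)),
                     act, cfg)
  trace <- apply_chamber_mixing(lat, cfg)
  dec <- decompose_session(trace)$decomposed
  on <- act > 1
  expect_equal(median(dec$cost_vo2[on]), cost_vo2, tolerance = 0.05)
  expect_equal(median(dec$cost_vco2[on]), cost_vco2, tolerance = 0.05)
  off <- t_s < -10000
  expect_equal(mean(dec$rest_vo2[off]), 4.5, tolerance = 0.01)
})

test_that("zero activity flags the cost states as non-identifiable", {
  cfg <- quick_session_config(seed = 41, activity_burst_rate_per_h = 0,
                              rest_ee_sd_w = 0, rq_sd = 0, tef_fraction = 0,
                              rq_rise_mean = 0)
  trace <- simulate_session(NULL, cfg)$trace
  corrected <- washout_correct(trace)
  expect_warning(dec <- kalman_decompose(corrected), "not identifiable")
  expect_false(attr(dec, "cost_identifiable"))
  # rest states agree with the trace mean within 2 SE of the mean
  ok <- !trace$missing_flag
  se2 <- 2 * sd(trace$vo2_ml_min[ok]) / sqrt(sum(ok))
  expect_lt(abs(mean(dec$rest_vo2) - mean(trace$vo2_ml_min[ok])),
            max(2 * se2, 0.01))
  expect_error(kalman_decompose(corrected[0, ]), "grid")
})

test_that("Kalman states agree with windowed least squares on low-noise data", {
  cfg <- quick_session_config(seed = 51, noise_sd_vo2 = 0.005,
                              noise_sd_vco2 = 0.005, rest_ee_sd_w = 0,
                              rq_sd = 0, tef_fraction = 0, rq_rise_mean = 0,
                              post_meal_act_cost_gain = 0, freeze_gap_s = 0)
  t_s <- session_time_grid_for_tests(cfg)
  act <- 15 + 10 * sin(2 * pi * t_s / 3600)   # persistent varying activity
  lat <- make_latent(t_s, rep(4.5, length(t_s)), rep(3.6, length(t_s)),
                     rep(0.045, length(t_s)), rep(0.038, length(t_s)),
                     act, cfg)
  trace <- apply_chamber_mixing(lat, cfg)
  corrected <- washout_correct(trace)
  dec <- kalman_decompose(corrected)
  ols <- ols_decompose(corrected, window_s = 600)
  mid <- which(!is.na(ols$rest_vo2_ols))
  mid <- mid[seq(120, length(mid) - 120, by = 240)]  # thin for speed
  expect_equal(dec$rest_vo2[mid], ols$rest_vo2_ols[mid], tolerance = 0.10)
  expect_equal(dec$cost_vo2[mid], ols$cost_vo2_ols[mid], tolerance = 0.10)
})

test_that("derived components follow the Weir identities", {
  cfg <- quick_session_config(seed = 61)
  dec <- decompose_session(simulate_session(list(hcd_gain_pct = 2),
                                            cfg)$trace)$decomposed
  expect_equal(dec$rest_rq, dec$rest_vco2 / dec$rest_vo2)
  expect_equal(dec$ree_w, weir_ee(dec$rest_vo2, dec$rest_vco2))
  # Weir linearity: rest + activity EE = EE of the reconstructed total
  total <- weir_ee(dec$rest_vo2 + dec$cost_vo2 * dec$activity_au,
                   dec$rest_vco2 + dec$cost_vco2 * dec$activity_au)
  expect_equal(dec$ree_w + dec$act_ee_w, total, tolerance = 1e-12)
  # no negative rates after flooring, RQ physiological where defined
  expect_true(all(dec$rest_vo2 > 0 & dec$rest_vco2 > 0))
  expect_true(all(dec$cost_vo2 >= 0))
  pre <- dec$time_s > -7200 & dec$time_s < 0
  expect_true(all(dec$rest_rq[pre] > 0.6 & dec$rest_rq[pre] < 1.1))
})

test_that("equal cost components give Act-RQ of one; low activity is masked", {
  n <- 1000
  dt <- tibble::tibble(
    time_s = seq(0, by = 5, length.out = n),
    activity_au = rep(c(0, 10), n / 2),
    missing_flag = FALSE,
    rest_vo2 = 5, rest_vco2 = 4, cost_vo2 = 0.04, cost_vco2 = 0.04)
  class(dt) <- c("decomposed_trace", class(dt))
  out <- derive_components(dt)
  expect_true(all(out$act_rq[out$activity_au == 10] == 1))
  expect_true(all(is.na(out$act_rq[out$activity_au == 0])))
  # all-subthreshold activity: fully masked, no error
  dt2 <- dt; dt2$activity_au <- 0
  out2 <- derive_components(dt2)
  expect_true(all(is.na(out2$act_rq)))
})

test_that("binning aligns to the meal and flags mostly-missing bins", {
  cfg <- quick_session_config(seed = 71, freeze_gap_s = 600)
  dec <- decompose_session(simulate_session(NULL, cfg)$trace)
  b <- dec$binned
  expect_true(all(b$bin_start_min %% 15 == 0))
  full_bins <- b$n[b$bin_mid_min > -200 & b$bin_mid_min < 200]
  expect_true(all(full_bins == 180))  # 5-s samples, 15-min bins
  # 600-s freeze: first post-meal bin >50% missing (plus guard band), flagged
  gap_bin <- b$flagged[b$bin_start_min == 0]
  expect_true(gap_bin)
  expect_false(b$flagged[b$bin_start_min == -30])
  expect_false(b$flagged[b$bin_start_min == 30])
  # constant series bins to the constant
  dtc <- tibble::tibble(time_s = seq(0, 8995, by = 5), missing_flag = FALSE,
                        rest_vo2 = 5)
  expect_true(all(bin_trace(dtc, 15)$rest_vo2 == 5))
  expect_error(bin_trace(dtc, width_min = 0.07), "multiple")
})
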