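test_that("session generation is bit-reproducible given the seed", {
  cfg <- quick_session_config(seed = 4)
  a <- simulate_session(list(hcd_gain_pct = 2), cfg)
  b <- simulate_session(list(hcd_gain_pct = 2), cfg)
  expect_identical(a$latent, b$latent)
  expect_identical(a$trace, b$trace)
})

test_that("quiet configuration yields constant resting trace and zero activity", {
  cfg <- quick_session_config(seed = 1, activity_burst_rate_per_h = 0,
                              tef_fraction = 0, rq_rise_mean = 0,
                              rest_ee_sd_w = 0, rq_sd = 0)
  lat <- generate_latent_session(NULL, cfg)
  expect_true(all(lat$activity == 0))
  expect_equal(diff(range(lat$true_rest_vo2)), 0)
  expect_equal(lat$true_rest_rq, rep(cfg$basal_rq, nrow(lat)))
  expect_equal(lat$true_rest_ee_w, rep(cfg$basal_ee_w, nrow(lat)))
})

test_that("carbohydrate-sensitive rats exceed the HC diet food quotient at peak", {
  cfg <- quick_session_config(seed = 8, meal_type = "HC", rq_sd = 0)
  cs <- generate_latent_session(list(hcd_gain_pct = 4), cfg)
  cr <- generate_latent_session(list(hcd_gain_pct = 0.5), cfg)
  fq_hcd <- ref_diet("HCD")$food_quotient
  expect_gt(max(cs$true_rest_rq), fq_hcd)
  expect_lt(max(cr$true_rest_rq), fq_hcd)
  # sensitivity never drives RQ above 1 (no net lipogenesis in the model)
  expect_lt(max(cs$true_rest_rq), 1)
})

test_that("HF meals raise the latent window-mean Rest-RQ by the configured 0.035", {
  cfg <- quick_session_config(seed = 3, meal_type = "HF", rq_sd = 0)
  lat <- generate_latent_session(list(hcd_gain_pct = 3), cfg)
  pre <- lat$time_s > -7200 & lat$time_s < 0
  post <- lat$time_s > 0 & lat$time_s <= 18000
  expect_equal(mean(lat$true_rest_rq[post]) - mean(lat$true_rest_rq[pre]),
               0.035, tolerance = 1e-9)
  # HF excursion is insensitive to the rat's carbohydrate class
  lat2 <- generate_latent_session(list(hcd_gain_pct = 0), cfg)
  expect_equal(max(lat2$true_rest_rq), max(lat$true_rest_rq))
})

test_that("generator conserves TEF energy over the post-meal window", {
  cfg <- quick_session_config(seed = 2, rest_ee_sd_w = 0, rq_sd = 0,
                              tef_fraction = 0.1)
  lat <- generate_latent_session(NULL, cfg)
  post <- lat$time_s > 0 & lat$time_s <= 18000
  extra_kj <- sum((lat$true_rest_ee_w[post] - cfg$basal_ee_w) *
                    cfg$sampling_interval_s) / 1000
  expect_equal(extra_kj, 0.1 * cfg$meal_energy_kj, tolerance = 1e-3)
})

test_that("chamber time constant is dilution volume over flow", {
  cfg <- session_config()
  expect_equal(60 * cfg$dilution_volume_l / cfg$flow_l_min, 420)  # 7 min
})

test_that("chamber mixing is the first-order step response", {
  cfg <- quick_session_config(seed = 1, noise_sd_vo2 = 0, noise_sd_vco2 = 0,
                              freeze_gap_s = 0)
  t_s <- seq(-3600, 7200, by = 5)
  s <- 2
  base <- 4
  rest_vo2 <- ifelse(t_s > 0, base + s, base)
  lat <- make_latent(t_s, rest_vo2, 0.8 * rest_vo2, rep(0, length(t_s)),
                     rep(0, length(t_s)), rep(0, length(t_s)), cfg)
  trace <- apply_chamber_mixing(lat, cfg)
  tau <- 60 * cfg$dilution_volume_l / cfg$flow_l_min
  post <- t_s > 0
  expected <- base + s * (1 - exp(-t_s[post] / tau))
  expect_equal(trace$vo2_ml_min[post], expected, tolerance = 1e-6)
  # converged to the latent input within 1% after five time constants
  late <- t_s > 5 * tau
  expect_true(all(abs(trace$vo2_ml_min[late] - (base + s)) < 0.01 * s))
})

test_that("the meal-delivery freeze is explicit missing data, never zeros", {
  cfg <- quick_session_config(seed = 6, freeze_gap_s = 120)
  trace <- simulate_session(NULL, cfg)$trace
  gap <- trace$time_s >= 0 & trace$time_s < 120
  expect_true(all(trace$missing_flag[gap]))
  expect_true(all(is.na(trace$vo2_ml_min[gap])))
  expect_true(all(is.na(trace$vco2_ml_min[gap])))
  expect_false(any(trace$missing_flag[!gap]))
  expect_true(all(trace$vo2_ml_min[!gap] > 0))
})

test_that("session configuration is validated", {
  expect_error(session_config(basal_rq = 0.5), "basal_rq")
  expect_error(session_config(dilution_volume_l = 0), "dilution_volume_l")
  expect_error(session_config(sampling_interval_s = 0),
               "sampling_interval_s")
  expect_error(session_config(tef_fraction = 2), "tef_fraction")
})
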