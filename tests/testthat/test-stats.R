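test_that("pearson correlation handles the exact and degenerate cases", {
  x <- rnorm(20)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 20)), "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("significance labels follow the fixed thresholds", {
  expect_equal(significance_label(c(0.005, 0.01, 0.03, 0.05, 0.2, NA)),
               c("significant", "significant", "marginal", "marginal",
                 "ns", NA))
})

test_that("meal-response fit recovers its generating fixed effects", {
  truth <- c(intercept = 0.80, adchg = 0.0003, mealtime = 0.09,
             interaction = 0.0086)
  tab <- simulate_meal_response(n_rats = 24, seed = 7, fixed = truth)
  fit <- fit_meal_response(tab)
  expect_true(fit$converged)
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  se <- setNames(fit$fixed$se, fit$fixed$term)
  for (term in names(truth)) {
    expect_lt(abs(est[term] - truth[term]), 3 * se[term])
  }
  # SE-matched generator scales land near the target standard errors
  expect_equal(unname(se["interaction"]), 0.0026, tolerance = 0.5)
})

test_that("mixed model equals ordinary least squares when rat variance is zero", {
  tab <- simulate_meal_response(n_rats = 24, seed = 11, sd_rat = 0,
                                sd_resid = 0.013)
  fit <- fit_meal_response(tab)
  ols <- lm(mp_value ~ adchg * mealtime, data = tab)
  expect_equal(unname(setNames(fit$fixed$estimate, fit$fixed$term)
                      [c("intercept", "adchg", "mealtime", "interaction")]),
               unname(coef(ols)), tolerance = 1e-6)
})

test_that("fixed effects are invariant to relabeling of rats", {
  tab <- simulate_meal_response(n_rats = 16, seed = 13)
  perm <- sample(unique(tab$rat_id))
  relab <- tab
  relab$rat_id <- setNames(sprintf("Z%02d", seq_along(perm)),
                           perm)[tab$rat_id]
  relab$session_id <- paste0(relab$rat_id, "_S1")
  f1 <- fit_meal_response(tab)
  f2 <- fit_meal_response(relab)
  expect_equal(f1$fixed$estimate, f2$fixed$estimate, tolerance = 1e-8)
})

test_that("constant adchg is flagged as inestimable, not silently fitted", {
  tab <- simulate_meal_response(n_rats = 12, seed = 3)
  tab$adchg <- 2.5
  fit <- fit_meal_response(tab)
  expect_false(fit$converged)
  expect_match(fit$flags, "inestimable")
  expect_error(fit_meal_response(simulate_meal_response(n_rats = 6)),
               "8 rats")
})

test_that("interaction test holds its nominal type-I error under the null", {
  null_fixed <- c(intercept = 0.8, adchg = 0, mealtime = 0, interaction = 0)
  p <- vapply(1:400, function(i) {
    tab <- simulate_meal_response(n_rats = 24, seed = 20000 + i,
                                  fixed = null_fixed)
    fit <- fit_meal_response(tab)
    fit$fixed$p_value[fit$fixed$term == "interaction"]
  }, numeric(1))
  rate <- mean(p < 0.05)
  # binomial 3-sigma band around 5% at 400 replicates
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  # p-values roughly uniform: quartiles in broad bands
  expect_gt(median(p), 0.35)
  expect_lt(median(p), 0.65)
})

test_that("pointwise group tests mask exactly the separated timepoints", {
  set.seed(9)
  times <- seq(15, 300, by = 15)
  make_group <- function(label, shift_at) {
    do.call(rbind, lapply(times, function(tp) {
      data.frame(time = tp, group = label,
                 value = rnorm(12, mean = ifelse(tp %in% shift_at, 10, 0),
                               sd = 1))
    }))
  }
  shifted <- c(120, 135, 150)
  dat <- rbind(make_group("CR", integer(0)), make_group("CS", shifted))
  res <- pointwise_group_tests(dat, threshold = 0.01)
  expect_setequal(res$by_time$time[res$by_time$significant], shifted)
  expect_equal(res$spans$span_start, 120)
  expect_equal(res$spans$span_end, 150)
  # identical groups: empty mask
  same <- rbind(make_group("CR", integer(0)), make_group("CS", integer(0)))
  same$value[same$group == "CS"] <- same$value[same$group == "CR"]
  res2 <- pointwise_group_tests(same)
  expect_false(any(res2$by_time$significant))
  expect_equal(nrow(res2$spans), 0)
  # constant values in both groups: timepoint skipped with a flag
  flat <- data.frame(time = rep(1, 8), group = rep(c("a", "b"), each = 4),
                     value = 1)
  res3 <- pointwise_group_tests(flat)
  expect_equal(res3$by_time$flag, "degenerate variance")
  expect_false(res3$by_time$significant)
})

test_that("sensitive rats separate from resistant in Gox after an HC meal", {
  # small end-to-end check of the group-comparison machinery on generator
  # output: clearly separated sensitivity classes, HC meal
  summ <- list()
  for (i in 1:6) {
    gain <- if (i <= 3) 0.5 else 4   # CR-like vs CS-like
    cfg <- quick_session_config(seed = 300 + i, meal_type = "HC")
    b <- decompose_session(simulate_session(list(hcd_gain_pct = gain),
                                            cfg)$trace)$binned
    b <- b[b$bin_mid_min > 0 & b$bin_mid_min < 300 & !b$flagged, ]
    summ[[i]] <- data.frame(time = b$bin_mid_min,
                            group = ifelse(gain < 2, "CR", "CS"),
                            value = b$rest_gox_w)
  }
  res <- pointwise_group_tests(do.call(rbind, summ), threshold = 0.01)
  sig_times <- res$by_time$time[res$by_time$significant]
  expect_gt(length(sig_times), 0)
  expect_true(any(sig_times >= 90 & sig_times <= 255))
})
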