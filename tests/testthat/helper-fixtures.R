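# Shared fixtures: small, fast configurations and hand-built traces.

# Short session (4 h fast + 5 h post-meal) for decomposition tests; full
# overnight sessions are exercised in the acceptance suite.
quick_session_config <- function(seed = 1L, ...) {
  session_config(seed = seed, session_start = "06:00", meal_time = "10:00",
                 session_end = "15:00", ...)
}

# Sampling grid of a session config, seconds relative to meal delivery.
session_time_grid_for_tests <- function(cfg) {
  hhmm <- function(x) {
    p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
    p[1] * 3600 + p[2] * 60
  }
  start_s <- hhmm(cfg$session_start); meal_s <- hhmm(cfg$meal_time)
  end_s <- hhmm(cfg$session_end)
  if (start_s >= meal_s) start_s <- start_s - 86400
  if (end_s <= meal_s) end_s <- end_s + 86400
  seq(start_s - meal_s, end_s - meal_s, by = cfg$sampling_interval_s)
}

# Latent session with piecewise-constant ground truth, built by hand.
make_latent <- function(time_s, rest_vo2, rest_vco2, cost_vo2, cost_vco2,
                        activity, config) {
  out <- tibble::tibble(
    time_s = time_s,
    true_rest_vo2 = rest_vo2, true_rest_vco2 = rest_vco2,
    true_cost_vo2 = cost_vo2, true_cost_vco2 = cost_vco2,
    activity = activity,
    true_rest_rq = rest_vco2 / rest_vo2,
    true_rest_ee_w = weir_ee(rest_vo2, rest_vco2)
  )
  attr(out, "config") <- config
  class(out) <- c("latent_session", class(out))
  out
}

# Noise-free gas trace from explicit series.
make_trace <- function(time_s, vo2, vco2, activity = rep(0, length(time_s)),
                       missing_flag = rep(FALSE, length(time_s)),
                       tau_s = 420) {
  new_gas_trace(time_s, vo2, vco2, activity, missing_flag, tau_s = tau_s)
}

# Binned table with constant REE, for BMR/TEF arithmetic tests.
make_binned <- function(ree_w, width_min = 15, from_min = -120,
                        to_min = 300, flagged = NULL) {
  mids <- seq(from_min + width_min / 2, to_min - width_min / 2,
              by = width_min)
  ree <- rep_len(ree_w, length(mids))
  tibble::tibble(
    bin_start_min = mids - width_min / 2,
    bin_mid_min = mids,
    bin_width_min = width_min,
    n = width_min * 12,
    frac_missing = 0,
    flagged = if (is.null(flagged)) rep(FALSE, length(mids)) else flagged,
    ree_w = ree
  )
}

# Sliding-window ordinary least squares of gas on activity: the brute-force
# oracle for the Kalman decomposition (intercept = rest, slope = cost).
ols_decompose <- function(trace, window_s = 600) {
  dt <- attr(trace, "sampling_interval_s")
  half <- round(window_s / dt / 2)
  n <- nrow(trace)
  act <- if (!is.null(trace$activity_matched_au)) trace$activity_matched_au
    else trace$activity_au
  rest <- cost <- rep(NA_real_, n)
  for (k in seq(half + 1, n - half)) {
    idx <- (k - half):(k + half)
    a <- act[idx]
    y <- trace$vo2_ml_min[idx]
    ok <- is.finite(a) & is.finite(y)
    if (sum(ok) > 10 && stats::sd(a[ok]) > 0) {
      fit <- stats::lm(y[ok] ~ a[ok])
      rest[k] <- coef(fit)[1]
      cost[k] <- coef(fit)[2]
    }
  }
  tibble::tibble(time_s = trace$time_s, rest_vo2_ols = rest,
                 cost_vo2_ols = cost)
}
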