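#' Calorimetry session configuration
#'
#' Parameters of one overnight fasting-refeeding session in the metabolic
#' cage: animals enter at `session_start` without food, a calibrated test
#' meal is delivered at `meal_time` the next morning, and recording continues
#' to `session_end`. Cage physics are a first-order mixing chamber with
#' washout time constant `dilution_volume / flow` (default 10.5 L / 1.5 L/min
#' = 7 min).
#'
#' The latent physiology has three pieces. (1) Resting energy expenditure:
#' basal level plus a slow Ornstein-Uhlenbeck wander plus, after the meal, a
#' thermic-effect-of-feeding bump shaped as a gamma kernel (shape 2) scaled
#' so `tef_fraction` of the meal energy is dissipated over the post-meal
#' window. (2) Resting RQ: basal 0.80 (overnight-fasted, mixed oxidation
#' leaning on fat) plus a post-meal excursion whose window-mean rise is
#' `rq_rise_mean`; for HC meals the rise additionally scales with the rat's
#' carbohydrate-sensitivity (its adiposity gain under HCD) at
#' `rq_sens_slope_per_pct`, so sensitive rats peak above the diet food
#' quotient while resistant rats stay below. (3) Spontaneous activity: a
#' marked point process of bursts (exponential inter-event times, log-normal
#' magnitudes, exponentially decaying shape) with an energy cost per
#' activity unit that increases after feeding.
#'
#' @param seed integer seed.
#' @param sampling_interval_s sampling interval, s.
#' @param dilution_volume_l practical chamber dilution volume, L.
#' @param flow_l_min ventilation flow, L/min.
#' @param session_start,meal_time,session_end clock times "HH:MM"; the start
#'   is the evening before the meal.
#' @param meal_type `"HC"` or `"HF"`.
#' @param meal_energy_kj test-meal energy, kJ.
#' @param basal_ee_w basal (fasted resting) energy expenditure, W.
#' @param basal_rq fasted resting RQ (in \[0.65, 1\]).
#' @param rq_rise_mean mean Rest-RQ rise over the post-meal window at zero
#'   sensitivity; `NULL` picks the meal-type default (HC 0.075, HF 0.035).
#' @param rq_sens_slope_per_pct extra window-mean RQ rise per percentage
#'   point of HCD adiposity gain (HC meals only).
#' @param rq_kernel_scale_min gamma-kernel scale of the RQ excursion, min
#'   (shape 2; peak at the scale).
#' @param tef_fraction fraction of meal energy dissipated as TEF over the
#'   post-meal window.
#' @param tef_kernel_scale_min gamma-kernel scale of the TEF bump, min.
#' @param post_window_min length of the post-meal analysis window, min.
#' @param activity_burst_rate_per_h burst rate, events/h.
#' @param act_burst_mag_meanlog,act_burst_mag_sdlog log-normal burst
#'   magnitude parameters (arbitrary activity units).
#' @param act_burst_dur_mean_s mean burst decay time, s.
#' @param act_cost_w_per_au fasted energy cost of activity, W per AU.
#' @param post_meal_act_cost_gain fractional post-meal rise of the activity
#'   cost (smooth ~30-min onset).
#' @param act_rq_offset Act-RQ minus Rest-RQ (working muscle runs slightly
#'   more glycolytic).
#' @param rest_ee_sd_w,rest_ee_tau_min stationary SD (W) and time constant
#'   (min) of the resting-EE wander.
#' @param rq_sd,rq_tau_min same for the resting-RQ wander.
#' @param noise_sd_vo2,noise_sd_vco2 analyzer observation noise, mL/min.
#' @param freeze_gap_s seconds of acquisition freeze at meal delivery
#'   (recorded as explicit missing samples, never zeros).
#' @return a `session_config` list.
#' @export
session_config <- function(seed = 1L, sampling_interval_s = 5,
                           dilution_volume_l = 10.5, flow_l_min = 1.5,
                           session_start = "18:00", meal_time = "10:00",
                           session_end = "17:00",
                           meal_type = c("HC", "HF"), meal_energy_kj = 60,
                           basal_ee_w = 1.35, basal_rq = 0.80,
                           rq_rise_mean = NULL,
                           rq_sens_slope_per_pct = 0.0086,
                           rq_kernel_scale_min = 90,
                           tef_fraction = 0.1, tef_kernel_scale_min = 60,
                           post_window_min = 300,
                           activity_burst_rate_per_h = 8,
                           act_burst_mag_meanlog = log(15),
                           act_burst_mag_sdlog = 0.5,
                           act_burst_dur_mean_s = 60,
                           act_cost_w_per_au = 0.015,
                           post_meal_act_cost_gain = 0.3,
                           act_rq_offset = 0.02,
                           rest_ee_sd_w = 0.03, rest_ee_tau_min = 80,
                           rq_sd = 0.005, rq_tau_min = 80,
                           noise_sd_vo2 = 0.05, noise_sd_vco2 = 0.05,
                           freeze_gap_s = 120) {
  meal_type <- match.arg(meal_type)
  cfg <- as.list(environment())
  if (is.null(cfg$rq_rise_mean)) {
    cfg$rq_rise_mean <- if (meal_type == "HC") 0.075 else 0.035
  }
  if (meal_type == "HF") cfg$rq_sens_slope_per_pct <- 0
  validate_session_config(cfg)
  structure(cfg, class = "session_config")
}

validate_session_config <- function(cfg) {
  check_scalar(cfg$basal_rq, "basal_rq", 0.65, 1.0)
  check_scalar(cfg$dilution_volume_l, "dilution_volume_l", lower = 1e-9)
  check_scalar(cfg$flow_l_min, "flow_l_min", lower = 1e-9)
  check_scalar(cfg$sampling_interval_s, "sampling_interval_s", lower = 1e-9)
  check_scalar(cfg$basal_ee_w, "basal_ee_w", lower = 1e-9)
  check_scalar(cfg$tef_fraction, "tef_fraction", 0, 1)
  for (nm in c("noise_sd_vo2", "noise_sd_vco2", "activity_burst_rate_per_h",
               "rest_ee_sd_w", "rq_sd", "freeze_gap_s",
               "act_cost_w_per_au")) {
    check_scalar(cfg[[nm]], nm, lower = 0)
  }
  grid <- session_time_grid(cfg)
  if (grid$start_rel >= 0 || grid$end_rel <= 0) {
    abort("meal_time must fall strictly inside the session")
  }
  invisible(cfg)
}

# session clock -> seconds relative to meal delivery (meal at 0).
# The session starts the evening before the meal when its clock time is
# later in the day than the meal's.
session_time_grid <- function(cfg) {
  start_s <- parse_clock(cfg$session_start)
  meal_s <- parse_clock(cfg$meal_time)
  end_s <- parse_clock(cfg$session_end)
  if (start_s >= meal_s) start_s <- start_s - 86400
  if (end_s <= meal_s) end_s <- end_s + 86400
  start_rel <- start_s - meal_s
  end_rel <- end_s - meal_s
  list(start_rel = start_rel, end_rel = end_rel,
       time_s = seq(start_rel, end_rel, by = cfg$sampling_interval_s))
}

# washout time constant in seconds
session_tau_s <- function(cfg) {
  60 * cfg$dilution_volume_l / cfg$flow_l_min
}

# stationary AR(1) (discretised Ornstein-Uhlenbeck) sample path
ou_path <- function(n, sd_stat, tau_s, dt) {
  if (sd_stat == 0) return(numeric(n))
  phi <- exp(-dt / tau_s)
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_stat)
  eps <- rnorm(n - 1, 0, innov_sd)
  for (k in 2:n) x[k] <- phi * x[k - 1] + eps[k - 1]
  x
}

# gamma(shape 2) rise-decay kernel on the post-meal grid, normalised either
# to unit window mean ("mean") or unit window integral in seconds ("integral")
post_meal_kernel <- function(time_s, scale_min, window_min, dt,
                             normalize = c("mean", "integral")) {
  normalize <- match.arg(normalize)
  theta <- scale_min * 60
  k <- ifelse(time_s > 0, time_s * exp(-time_s / theta), 0)
  win <- time_s > 0 & time_s <= window_min * 60
  if (!any(win)) abort("post-meal window not on the time grid")
  k_norm <- switch(normalize,
                   mean = mean(k[win]),
                   integral = sum(k[win]) * dt)
  k / k_norm
}

#' Generate the latent physiology of one session
#'
#' Simulates the ground-truth resting and activity components of a
#' fasting-refeeding session on the sampling grid, before any chamber
#' mixing or measurement noise. See [session_config()] for the model.
#'
#' @param rat a one-row slice of a cohort `rats` tibble (or any list with
#'   `hcd_gain_pct`); the HCD adiposity gain sets the carbohydrate
#'   sensitivity that scales the HC-meal RQ excursion. `NULL` means a
#'   zero-sensitivity animal.
#' @param config a [session_config()].
#' @return a `latent_session` tibble with columns `time_s` (relative to meal
#'   delivery), `true_rest_vo2`, `true_rest_vco2` (mL/min),
#'   `true_cost_vo2`, `true_cost_vco2` (mL/min per AU), `activity` (AU),
#'   `true_rest_rq`, `true_rest_ee_w`; the config is attached as an
#'   attribute.
#' @export
generate_latent_session <- function(rat = NULL, config = session_config()) {
  validate_session_config(config)
  cfg <- config
  set.seed(child_seed(cfg$seed, 1L))
  grid <- session_time_grid(cfg)
  t_s <- grid$time_s
  n <- length(t_s)
  dt <- cfg$sampling_interval_s

  sens_gain <- if (is.null(rat)) 0 else (rat$hcd_gain_pct %||% 0)
  rise_mean <- cfg$rq_rise_mean + cfg$rq_sens_slope_per_pct * sens_gain

  k_rq <- post_meal_kernel(t_s, cfg$rq_kernel_scale_min, cfg$post_window_min,
                           dt, normalize = "mean")
  k_tef <- post_meal_kernel(t_s, cfg$tef_kernel_scale_min, cfg$post_window_min,
                            dt, normalize = "integral")

  rq <- cfg$basal_rq + ou_path(n, cfg$rq_sd, cfg$rq_tau_min * 60, dt) +
    rise_mean * k_rq
  rq <- pmin(pmax(rq, 0.6), 1.08)
  ee <- cfg$basal_ee_w + ou_path(n, cfg$rest_ee_sd_w,
                                 cfg$rest_ee_tau_min * 60, dt) +
    cfg$tef_fraction * cfg$meal_energy_kj * 1000 * k_tef
  ee <- pmax(ee, 0.2)

  rest_vo2 <- 60 * ee / (16.3 + 4.57 * rq)
  rest_vco2 <- rq * rest_vo2

  activity <- simulate_activity(t_s, cfg)
  act_rq <- pmin(rq + cfg$act_rq_offset, 1.08)
  cost_w <- cfg$act_cost_w_per_au *
    (1 + cfg$post_meal_act_cost_gain * ifelse(t_s > 0, 1 - exp(-t_s / 1800), 0))
  cost_vo2 <- 60 * cost_w / (16.3 + 4.57 * act_rq)
  cost_vco2 <- act_rq * cost_vo2

  out <- tibble::tibble(
    time_s = t_s,
    true_rest_vo2 = rest_vo2,
    true_rest_vco2 = rest_vco2,
    true_cost_vo2 = cost_vo2,
    true_cost_vco2 = cost_vco2,
    activity = activity,
    true_rest_rq = rq,
    true_rest_ee_w = ee
  )
  attr(out, "config") <- cfg
  class(out) <- c("latent_session", class(out))
  out
}

# burst point process on the session grid
simulate_activity <- function(t_s, cfg) {
  n <- length(t_s)
  activity <- numeric(n)
  hours <- (t_s[n] - t_s[1]) / 3600
  n_events <- rpois(1, cfg$activity_burst_rate_per_h * hours)
  if (n_events == 0) return(activity)
  onset <- sort(runif(n_events, t_s[1], t_s[n]))
  mag <- rlnorm(n_events, cfg$act_burst_mag_meanlog, cfg$act_burst_mag_sdlog)
  dur <- rexp(n_events, 1 / cfg$act_burst_dur_mean_s)
  for (j in seq_len(n_events)) {
    idx <- which(t_s >= onset[j] & t_s <= onset[j] + 5 * dur[j])
    if (length(idx)) {
      activity[idx] <- activity[idx] +
        mag[j] * exp(-(t_s[idx] - onset[j]) / dur[j])
    }
  }
  activity
}

#' Pass latent gas production through the mixing chamber
#'
#' The analyzer sees the first-order low-pass response of total gas
#' production (resting + cost x activity) with time constant
#' `tau = dilution_volume / flow`, plus additive Gaussian observation noise.
#' Samples inside the acquisition freeze at meal delivery are recorded as
#' missing (`NA` with `missing_flag`), never as zeros.
#'
#' @param latent a `latent_session` from [generate_latent_session()].
#' @param config the [session_config()]; defaults to the one attached to
#'   `latent`.
#' @return a `gas_trace` tibble: `time_s`, `vo2_ml_min`, `vco2_ml_min`,
#'   `activity_au`, `missing_flag`, with the sampling interval and washout
#'   `tau_s` as attributes.
#' @export
apply_chamber_mixing <- function(latent, config = attr(latent, "config")) {
  stopifnot(inherits(latent, "latent_session") || is.data.frame(latent))
  cfg <- config
  validate_session_config(cfg)
  t_s <- latent$time_s
  if (!is_uniform_grid(t_s)) abort("sampling grid must be uniform")
  dt <- cfg$sampling_interval_s
  set.seed(child_seed(cfg$seed, 2L))

  x_vo2 <- latent$true_rest_vo2 + latent$true_cost_vo2 * latent$activity
  x_vco2 <- latent$true_rest_vco2 + latent$true_cost_vco2 * latent$activity
  tau <- session_tau_s(cfg)
  y_vo2 <- lowpass_first_order(x_vo2, dt, tau)
  y_vco2 <- lowpass_first_order(x_vco2, dt, tau)

  n <- length(t_s)
  y_vo2 <- y_vo2 + rnorm(n, 0, cfg$noise_sd_vo2)
  y_vco2 <- y_vco2 + rnorm(n, 0, cfg$noise_sd_vco2)

  missing <- t_s >= 0 & t_s < cfg$freeze_gap_s
  y_vo2[missing] <- NA_real_
  y_vco2[missing] <- NA_real_
  act <- latent$activity
  act[missing] <- NA_real_

  new_gas_trace(time_s = t_s, vo2_ml_min = y_vo2, vco2_ml_min = y_vco2,
                activity_au = act, missing_flag = missing,
                sampling_interval_s = dt, tau_s = tau)
}

# exact zero-order-hold discretisation of dy/dt = (x - y)/tau, started at
# steady state (y0 = x0)
lowpass_first_order <- function(x, dt, tau) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                           init = x[1]))
}

#' Construct a gas-exchange trace
#'
#' @param time_s sample times (s, uniform grid; 0 = meal delivery).
#' @param vo2_ml_min,vco2_ml_min measured gas exchange, mL/min (`NA` where
#'   missing).
#' @param activity_au activity, arbitrary units.
#' @param missing_flag logical missingness marker.
#' @param sampling_interval_s grid step, s.
#' @param tau_s chamber washout time constant, s (may be `NA` if unknown).
#' @return a `gas_trace` tibble.
#' @export
new_gas_trace <- function(time_s, vo2_ml_min, vco2_ml_min, activity_au,
                          missing_flag = is.na(vo2_ml_min),
                          sampling_interval_s = NULL, tau_s = NA_real_) {
  if (!is_uniform_grid(time_s)) abort("gas_trace requires a uniform time grid")
  ok <- !missing_flag
  if (any(vo2_ml_min[ok] <= 0, na.rm = TRUE) ||
      any(vco2_ml_min[ok] <= 0, na.rm = TRUE)) {
    abort("non-missing gas rates must be positive")
  }
  out <- tibble::tibble(time_s = time_s, vo2_ml_min = vo2_ml_min,
                        vco2_ml_min = vco2_ml_min,
                        activity_au = activity_au,
                        missing_flag = missing_flag)
  attr(out, "sampling_interval_s") <-
    sampling_interval_s %||% (time_s[2] - time_s[1])
  attr(out, "tau_s") <- tau_s
  class(out) <- c("gas_trace", class(out))
  out
}

#' Simulate one full calorimetry session
#'
#' Convenience wrapper: latent physiology plus chamber mixing.
#'
#' @inheritParams generate_latent_session
#' @return list with `latent` (the `latent_session`) and `trace` (the
#'   measured `gas_trace`).
#' @export
simulate_session <- function(rat = NULL, config = session_config()) {
  latent <- generate_latent_session(rat, config)
  list(latent = latent, trace = apply_chamber_mixing(latent, config))
}
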