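#' Invert first-order chamber washout
#'
#' The mixing chamber low-passes the animal's gas production with time
#' constant `tau = dilution_volume / flow`; since `y + tau * dy/dt = x`,
#' adding `tau` times the time-derivative of the measured trace recovers the
#' production signal. The derivative is taken on a smoothed copy (30-s
#' moving average, slope over +/- one smoothing width) to keep noise
#' amplification bounded. Missing gaps propagate with a guard band of one
#' smoothing width on each side.
#'
#' The activity channel is measured directly (it is not mixed in the
#' chamber), but the decomposition regresses corrected gas on activity, and
#' the approximate inverse is band-limited: fast activity modulations
#' survive in the regressor yet are attenuated in the corrected gas. To keep
#' the regression consistent at all frequencies, the returned trace carries
#' `activity_matched_au`: the activity passed through the chamber low-pass
#' and then through the same approximate inverse, i.e. filtered exactly as
#' the gas signals were. [kalman_decompose()] uses it automatically; the raw
#' counts stay in `activity_au`.
#'
#' @param trace a `gas_trace`.
#' @param tau_s washout time constant in seconds; defaults to the trace's
#'   `tau_s` attribute.
#' @param smooth_width_s width of the derivative smoothing window, s.
#' @return a `gas_trace` with washout-corrected `vo2_ml_min`/`vco2_ml_min`
#'   and the chamber-matched activity regressor `activity_matched_au`.
#' @export
washout_correct <- function(trace, tau_s = attr(trace, "tau_s"),
                            smooth_width_s = 30) {
  stopifnot(is.data.frame(trace))
  if (is.null(tau_s) || !is.finite(tau_s) || tau_s <= 0) {
    abort("washout_correct() needs a positive tau_s")
  }
  dt <- attr(trace, "sampling_interval_s") %||%
    (trace$time_s[2] - trace$time_s[1])
  if (!is_uniform_grid(trace$time_s)) abort("non-uniform sampling grid")
  w <- max(1L, round(smooth_width_s / dt))
  n <- nrow(trace)
  if (n < 2 * w + 3) abort("trace shorter than the smoothing window")

  invert <- function(m) {
    s <- moving_average(m, 2L * (w %/% 2L) + 1L)
    d <- numeric(n)
    idx <- (w + 1):(n - w)
    d[idx] <- (s[idx + w] - s[idx - w]) / (2 * w * dt)
    d[1:w] <- d[w + 1]
    d[(n - w + 1):n] <- d[n - w]
    m + tau_s * d
  }
  vo2 <- invert(trace$vo2_ml_min)
  vco2 <- invert(trace$vco2_ml_min)
  act0 <- trace$activity_au
  act0[is.na(act0)] <- 0
  act_matched <- invert(lowpass_first_order(act0, dt, tau_s))
  # corrected rates can graze zero in noise troughs; keep them positive
  missing <- is.na(vo2) | is.na(vco2) | trace$missing_flag
  vo2[!missing] <- pmax(vo2[!missing], 1e-6)
  vco2[!missing] <- pmax(vco2[!missing], 1e-6)
  vo2[missing] <- NA_real_
  vco2[missing] <- NA_real_
  out <- new_gas_trace(trace$time_s, vo2, vco2, trace$activity_au,
                       missing_flag = missing,
                       sampling_interval_s = dt, tau_s = tau_s)
  out$activity_matched_au <- act_matched
  attr(out, "washout_corrected") <- TRUE
  out
}

#' Decompose a gas trace into resting and activity components
#'
#' State-space separation of resting gas exchange from the activity-specific
#' cost. The state `[rest_vo2, rest_vco2, cost_vo2, cost_vco2]` follows a
#' random walk (slow resting drift, near-constant cost); the observations
#' are `vo2 = rest_vo2 + cost_vo2 * activity + noise` and likewise for VCO2.
#' A forward Kalman filter is followed (by default) by fixed-interval RTS
#' smoothing. Observation noise is estimated from the first ten minutes of
#' the trace by robust residual MAD unless supplied. Missing samples are
#' predicted through without an update. Resting states are floored at a
#' small positive bound, cost states at zero.
#'
#' @param trace a washout-corrected `gas_trace` (see [washout_correct()]).
#' @param q_rest,q_cost random-walk process-noise variances per sample for
#'   the resting and cost states ((mL/min)^2 and (mL/min/AU)^2).
#' @param obs_noise_var optional length-2 numeric: observation noise
#'   variances for VO2 and VCO2; `NULL` estimates them from the trace.
#' @param smooth run the fixed-interval smoother (`TRUE`) or return the
#'   causal filter only.
#' @param floor_rest positive floor for the resting gas rates, mL/min.
#' @return a `decomposed_trace` tibble: `time_s`, `activity_au`,
#'   `missing_flag`, `rest_vo2`, `rest_vco2`, `cost_vo2`, `cost_vco2` and
#'   their per-sample state variances `var_*`. The attribute
#'   `cost_identifiable` is `FALSE` when the trace carries no activity, in
#'   which case the cost states sit at their prior.
#' @export
kalman_decompose <- function(trace, q_rest = 1e-4, q_cost = 1e-6,
                             obs_noise_var = NULL, smooth = TRUE,
                             floor_rest = 1e-3) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "vo2_ml_min", "vco2_ml_min", "activity_au",
                  "missing_flag") %in% names(trace)))
  if (!is_uniform_grid(trace$time_s)) abort("non-uniform sampling grid")
  miss <- trace$missing_flag | is.na(trace$vo2_ml_min) |
    is.na(trace$vco2_ml_min)
  if (all(miss)) abort("all samples missing; nothing to decompose")
  dt <- attr(trace, "sampling_interval_s") %||%
    (trace$time_s[2] - trace$time_s[1])

  # prefer the chamber-matched regressor from washout_correct(): it has
  # seen the same filtering as the gas channels
  act <- trace$activity_matched_au %||% trace$activity_au
  act[is.na(act)] <- 0
  identifiable <- any(abs(act) > 0)
  if (!identifiable) {
    warn("activity is identically zero: cost states are not identifiable and remain at their prior")
  }

  head_idx <- which(!miss & trace$time_s <= trace$time_s[1] + 600)
  if (is.null(obs_noise_var)) {
    est_r <- function(x) {
      v <- x[head_idx]
      if (length(v) < 20) v <- x[!miss][seq_len(min(200, sum(!miss)))]
      # MAD of first differences; /sqrt(2) maps to per-sample noise SD
      max((mad(diff(v), na.rm = TRUE) / sqrt(2))^2, 1e-8)
    }
    obs_noise_var <- c(est_r(trace$vo2_ml_min), est_r(trace$vco2_ml_min))
  }
  stopifnot(length(obs_noise_var) == 2, all(obs_noise_var > 0))

  x0 <- c(median(trace$vo2_ml_min[head_idx], na.rm = TRUE),
          median(trace$vco2_ml_min[head_idx], na.rm = TRUE), 0, 0)
  if (anyNA(x0)) x0[is.na(x0)] <- c(5, 4, 0, 0)[is.na(x0)]
  p0 <- c(1, 1, 0.01, 0.01)  # broad priors; cost ~ a few 0.01 mL/min per AU

  y <- cbind(trace$vo2_ml_min, trace$vco2_ml_min)
  y[is.na(y)] <- 0  # masked by miss; never used
  fit <- kalman_rw_cpp(y, act, miss,
                       q = c(q_rest, q_rest, q_cost, q_cost),
                       r = obs_noise_var, x0 = x0, p0 = p0,
                       do_smooth = smooth)
  st <- fit$state
  st[, 1:2] <- pmax(st[, 1:2], floor_rest)
  st[, 3:4] <- pmax(st[, 3:4], 0)

  act_raw <- trace$activity_au
  act_raw[is.na(act_raw)] <- 0
  out <- tibble::tibble(
    time_s = trace$time_s,
    activity_au = act_raw,
    missing_flag = miss,
    rest_vo2 = st[, 1], rest_vco2 = st[, 2],
    cost_vo2 = st[, 3], cost_vco2 = st[, 4],
    var_rest_vo2 = fit$state_var[, 1], var_rest_vco2 = fit$state_var[, 2],
    var_cost_vo2 = fit$state_var[, 3], var_cost_vco2 = fit$state_var[, 4]
  )
  attr(out, "sampling_interval_s") <- dt
  attr(out, "cost_identifiable") <- identifiable
  attr(out, "obs_noise_var") <- obs_noise_var
  class(out) <- c("decomposed_trace", class(out))
  out
}

#' Derive RQ, energy-expenditure and oxidation series from a decomposition
#'
#' Fills the physiological series: resting RQ, activity RQ (masked where
#' activity is below threshold, since the cost ratio is numerically
#' meaningless without activity), resting energy expenditure and activity
#' cost in Watts (Weir formula), activity EE, and resting glucose/lipid
#' oxidation.
#'
#' @param dt a `decomposed_trace` from [kalman_decompose()].
#' @param activity_threshold mask Act-RQ where activity is at or below this
#'   value; `NULL` uses the 5th percentile of non-zero activity.
#' @return the input with columns `rest_rq`, `act_rq`, `ree_w`,
#'   `act_cost_w_per_au`, `act_ee_w`, `rest_gox_w`, `rest_lox_w` added.
#' @export
derive_components <- function(dt, activity_threshold = NULL) {
  stopifnot(inherits(dt, "decomposed_trace") ||
              all(c("rest_vo2", "rest_vco2", "cost_vo2", "cost_vco2",
                    "activity_au") %in% names(dt)))
  if (is.null(activity_threshold)) {
    nz <- dt$activity_au[dt$activity_au > 0]
    activity_threshold <- if (length(nz)) quantile(nz, 0.05, names = FALSE)
      else Inf
  }
  act_on <- dt$activity_au >= activity_threshold & dt$activity_au > 0 &
    dt$cost_vo2 > 1e-9
  ox <- substrate_oxidation(dt$rest_vo2, dt$rest_vco2)
  dt$rest_rq <- dt$rest_vco2 / dt$rest_vo2
  dt$act_rq <- ifelse(act_on, dt$cost_vco2 / dt$cost_vo2, NA_real_)
  dt$ree_w <- weir_ee(dt$rest_vo2, dt$rest_vco2)
  dt$act_cost_w_per_au <- weir_ee(dt$cost_vo2, dt$cost_vco2)
  dt$act_ee_w <- dt$act_cost_w_per_au * dt$activity_au
  dt$rest_gox_w <- ox$gox_w
  dt$rest_lox_w <- ox$lox_w
  attr(dt, "activity_threshold") <- activity_threshold
  dt
}

#' Bin a decomposed trace into fixed windows aligned to the meal
#'
#' Averages every derived series in consecutive bins whose edges fall at
#' multiples of the bin width relative to meal delivery (time 0), e.g.
#' ..., -15, 0, 15, ... min for the default 15-min bins. Bins with more than
#' half their samples missing are flagged.
#'
#' @param dt a `decomposed_trace` with derived columns (see
#'   [derive_components()]).
#' @param width_min bin width in minutes; must be a multiple of the
#'   sampling interval.
#' @return tibble with one row per bin: `bin_start_min`, `bin_mid_min`,
#'   `bin_width_min`, `n`, `frac_missing`, `flagged` and the per-bin means
#'   of the decomposition series.
#' @export
bin_trace <- function(dt, width_min = 15) {
  stopifnot(is.data.frame(dt), "time_s" %in% names(dt))
  dt_s <- attr(dt, "sampling_interval_s") %||% (dt$time_s[2] - dt$time_s[1])
  if (abs((width_min * 60) %% dt_s) > 1e-9) {
    abort("bin width must be a multiple of the sampling interval")
  }
  w_s <- width_min * 60
  df <- tibble::as_tibble(dt)
  df$bin <- floor(df$time_s / w_s)
  value_cols <- intersect(
    c("rest_vo2", "rest_vco2", "cost_vo2", "cost_vco2", "rest_rq", "act_rq",
      "ree_w", "act_cost_w_per_au", "act_ee_w", "activity_au",
      "rest_gox_w", "rest_lox_w"), names(df))
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$bin),
    n = dplyr::n(),
    frac_missing = mean(.data$missing_flag),
    dplyr::across(dplyr::all_of(value_cols),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  out <- dplyr::mutate(out,
    bin_start_min = .data$bin * width_min,
    bin_mid_min = (.data$bin + 0.5) * width_min,
    bin_width_min = width_min,
    flagged = .data$frac_missing > 0.5)
  dplyr::select(out, "bin_start_min", "bin_mid_min", "bin_width_min", "n",
                "frac_missing", "flagged", dplyr::all_of(value_cols))
}
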