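#' Energy expenditure by the Weir formula
#'
#' Converts oxygen consumption and carbon-dioxide production into power.
#' With gas rates in mL/min, `((vo2 * 16.3) + (vco2 * 4.57)) / 60` gives
#' Watts.
#'
#' @param vo2,vco2 gas exchange rates, mL/min; vectors are accepted and
#'   recycled by the usual rules. Must be non-negative (NA passes through).
#' @return energy expenditure in Watts.
#' @examples
#' weir_ee(10, 8) # 3.326 W
#' @export
weir_ee <- function(vo2, vco2) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE)) {
    abort("weir_ee() requires non-negative gas rates")
  }
  ((vo2 * 16.3) + (vco2 * 4.57)) / 60
}

#' Glucose and lipid oxidation rates from resting gas exchange
#'
#' Nitrogen-free stoichiometric estimates of whole-body glucose (Gox) and
#' lipid (Lox) oxidation, in Watts:
#' `Gox = ((4.57 * vco2 - 3.23 * vo2) * 15.6) / 60` and
#' `Lox = ((1.69 * vo2 - 1.69 * vco2) * 39.5) / 60`,
#' with gas rates in mL/min, 15.6 kJ/g for glucose and 39.5 kJ/g for lipid.
#' Values can be negative near the formula roots (RQ close to 0.707 for Gox,
#' above 1 for Lox) and are returned as-is.
#'
#' @param vo2,vco2 resting gas exchange rates, mL/min, positive.
#' @return tibble with columns `gox_w` and `lox_w` (Watts).
#' @examples
#' substrate_oxidation(10, 8)
#' @export
substrate_oxidation <- function(vo2, vco2) {
  tibble::tibble(
    gox_w = ((4.57 * vco2 - 3.23 * vo2) * 15.6) / 60,
    lox_w = ((1.69 * vo2 - 1.69 * vco2) * 39.5) / 60
  )
}

#' Basal metabolic rate from the pre-meal window
#'
#' BMR is the mean resting metabolic rate over the fasted pre-meal window
#' (default -120..0 min relative to meal delivery), using clean bins only.
#'
#' @param binned a binned decomposition table from [bin_trace()] (needs
#'   columns `bin_mid_min`, `ree_w`, `flagged`).
#' @param window numeric length-2, window in minutes relative to the meal.
#' @param min_bins minimum number of clean bins required.
#' @return BMR in Watts.
#' @export
compute_bmr <- function(binned, window = c(-120, 0), min_bins = 4L) {
  stopifnot(is.data.frame(binned),
            all(c("bin_mid_min", "ree_w", "flagged") %in% names(binned)))
  sel <- binned$bin_mid_min > window[1] & binned$bin_mid_min < window[2] &
    !binned$flagged & is.finite(binned$ree_w)
  if (sum(sel) < min_bins) {
    abort(sprintf("compute_bmr(): only %d clean bins in [%g, %g] min (need %d)",
                  sum(sel), window[1], window[2], min_bins))
  }
  mean(binned$ree_w[sel])
}

#' Thermic effect of feeding
#'
#' Net area under the post-meal resting metabolic rate curve above the basal
#' (pre-meal) level, over the post-meal window (default 0..300 min). Bin
#' means are integrated over their width, so a sustained +0.2 W excess over
#' 300 min yields 3.6 kJ. Negative excursions subtract (net AUC). TEF is a
#' property of the meal, so it is always computed from absolute RMR, never
#' from body-mass-normalised rates.
#'
#' @param binned binned decomposition table from [bin_trace()].
#' @param bmr basal metabolic rate in Watts, from [compute_bmr()].
#' @param meal_energy_kj meal energy for the percentage, kJ.
#' @param window numeric length-2, post-meal window in minutes.
#' @return list with `tef_kj` and `tef_pct_meal`.
#' @export
compute_tef <- function(binned, bmr, meal_energy_kj = 60,
                        window = c(0, 300)) {
  stopifnot(is.data.frame(binned),
            all(c("bin_mid_min", "bin_width_min", "ree_w", "flagged")
                %in% names(binned)))
  check_scalar(bmr, "bmr", lower = 1e-9)
  sel <- binned$bin_mid_min > window[1] & binned$bin_mid_min < window[2]
  b <- binned[sel, ]
  ok <- !b$flagged & is.finite(b$ree_w)
  if (nrow(b) == 0 || mean(ok) < 0.5) {
    abort("compute_tef(): more than half of the post-meal bins are missing")
  }
  b <- b[ok, ]
  auc_j <- sum((b$ree_w - bmr) * b$bin_width_min * 60)  # W * s = J
  # rescale for dropped bins so a few flagged bins do not bias TEF downwards
  covered <- sum(b$bin_width_min)
  span <- diff(window)
  auc_j <- auc_j * span / covered
  tef_kj <- auc_j / 1000
  list(tef_kj = tef_kj, tef_pct_meal = 100 * tef_kj / meal_energy_kj)
}

#' Normalise a metabolic rate to metabolic body mass
#'
#' Scales a rate to a standard 300 g of metabolic mass, where metabolic mass
#' is fat-free mass plus 20% of fat mass (FFM + 0.2 FM): adipose tissue
#' contributes far less to resting metabolism per gram than lean tissue.
#'
#' @param value rate in Watts (vectorised).
#' @param ffm_g,fm_g fat-free and fat mass, g.
#' @return Watts per 300 g metabolic mass.
#' @examples
#' normalize_to_metabolic_mass(1.3, ffm_g = 250, fm_g = 50) # 1.5
#' @export
normalize_to_metabolic_mass <- function(value, ffm_g, fm_g) {
  if (any(!is.finite(ffm_g)) || any(ffm_g <= 0) || any(fm_g < 0)) {
    abort("need ffm_g > 0 and fm_g >= 0")
  }
  mm <- ffm_g + 0.2 * fm_g
  if (any(mm <= 0)) abort("non-positive metabolic mass")
  value * 300 / mm
}

#' Session-level metabolic parameter summary
#'
#' Collapses a binned, decomposed calorimetry session into the standard
#' meal-response parameters: BMR (absolute and per 300 g metabolic mass),
#' TEF, and pre-/post-meal means of Rest-RQ, Act-RQ, activity and activity
#' cost, plus net post-meal glucose/lipid oxidation AUCs relative to basal.
#'
#' @param binned binned decomposition table from [bin_trace()].
#' @param rat_id identifier carried into the output.
#' @param meal_type `"HC"` or `"HF"`.
#' @param meal_energy_kj meal energy, kJ.
#' @param ffm_g,fm_g body composition on the session day (g); if `NA` the
#'   normalised BMR is `NA`.
#' @param pre_window,post_window analysis windows in minutes relative to meal.
#' @return one-row tibble of session parameters.
#' @export
summarize_session <- function(binned, rat_id = NA_character_,
                              meal_type = NA_character_,
                              meal_energy_kj = 60,
                              ffm_g = NA_real_, fm_g = NA_real_,
                              pre_window = c(-120, 0),
                              post_window = c(0, 300)) {
  bmr <- compute_bmr(binned, window = pre_window)
  tef <- compute_tef(binned, bmr, meal_energy_kj, window = post_window)
  pre <- binned$bin_mid_min > pre_window[1] & binned$bin_mid_min < pre_window[2] &
    !binned$flagged
  post <- binned$bin_mid_min > post_window[1] & binned$bin_mid_min < post_window[2] &
    !binned$flagged
  wmean <- function(x, sel) mean(x[sel], na.rm = TRUE)
  gox_pre <- wmean(binned$rest_gox_w, pre)
  lox_pre <- wmean(binned$rest_lox_w, pre)
  b_post <- binned[post, ]
  gox_auc_kj <- sum((b_post$rest_gox_w - gox_pre) * b_post$bin_width_min * 60,
                    na.rm = TRUE) / 1000
  lox_auc_kj <- sum((b_post$rest_lox_w - lox_pre) * b_post$bin_width_min * 60,
                    na.rm = TRUE) / 1000
  tibble::tibble(
    rat_id = as.character(rat_id),
    meal_type = meal_type,
    bmr_w = bmr,
    bmr_w_per_300g_mm = if (is.na(ffm_g)) NA_real_ else
      normalize_to_metabolic_mass(bmr, ffm_g, fm_g),
    tef_kj = tef$tef_kj,
    tef_pct_meal = tef$tef_pct_meal,
    rest_rq_pre = wmean(binned$rest_rq, pre),
    rest_rq_post = wmean(binned$rest_rq, post),
    act_rq_pre = wmean(binned$act_rq, pre),
    act_rq_post = wmean(binned$act_rq, post),
    activity_pre = wmean(binned$activity_au, pre),
    activity_post = wmean(binned$activity_au, post),
    act_cost_pre = wmean(binned$act_cost_w_per_au, pre),
    act_cost_post = wmean(binned$act_cost_w_per_au, post),
    rest_gox_auc_kj = gox_auc_kj,
    rest_lox_auc_kj = lox_auc_kj
  )
}
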