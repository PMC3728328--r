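#' Fat mass from MRI adipose volume
#'
#' Converts segmented adipose-tissue volume to mass assuming a density of
#' 0.9 g/cm^3.
#'
#' @param volume_cm3 adipose volume, cm^3 (vectorised, non-negative).
#' @return fat mass in g.
#' @export
fm_from_volume <- function(volume_cm3) {
  if (any(volume_cm3 < 0, na.rm = TRUE)) abort("volume must be >= 0")
  volume_cm3 * 0.9
}

#' Adiposity percentage
#'
#' @param fm_g fat mass, g.
#' @param bw_g body weight, g.
#' @return (fm / bw) * 100, percent.
#' @export
adiposity_pct <- function(fm_g, bw_g) {
  if (any(bw_g <= 0, na.rm = TRUE)) abort("body weight must be positive")
  100 * fm_g / bw_g
}

#' Interpolate body composition to a calorimetry day
#'
#' FFM and FM are assumed to evolve linearly between two bracketing imaging
#' sessions (a few weeks apart at most); both are interpolated independently.
#' No extrapolation outside the bracket is allowed.
#'
#' @param composition imaging table for one rat: data frame with columns
#'   `day`, `ffm_g`, `fm_g` (at least two rows).
#' @param day target day (scalar, within the observed day range).
#' @return list with `ffm_g` and `fm_g` at `day`.
#' @export
interpolate_composition <- function(composition, day) {
  stopifnot(is.data.frame(composition),
            all(c("day", "ffm_g", "fm_g") %in% names(composition)))
  comp <- composition[order(composition$day), ]
  if (nrow(comp) < 2) abort("need at least two imaging sessions")
  check_scalar(day, "day")
  if (day < min(comp$day) || day > max(comp$day)) {
    abort(sprintf("day %g outside imaging bracket [%g, %g]; refusing to extrapolate",
                  day, min(comp$day), max(comp$day)))
  }
  list(
    ffm_g = approx(comp$day, comp$ffm_g, xout = day)$y,
    fm_g  = approx(comp$day, comp$fm_g,  xout = day)$y
  )
}

#' Validate composition interpolation against measured body weight
#'
#' Regresses interpolated FFM+FM on body weight measured on the same days
#' (ordinary least squares across all rat-days). A slope near 1 and R^2 near
#' 1 indicate the linear-evolution assumption is adequate.
#'
#' @param predicted_bw_g interpolated FFM+FM, g.
#' @param measured_bw_g weighed body weight on the same days, g.
#' @return list: `slope`, `slope_se`, `r_squared`, `n`.
#' @export
validate_interpolation <- function(predicted_bw_g, measured_bw_g) {
  ok <- is.finite(predicted_bw_g) & is.finite(measured_bw_g)
  if (sum(ok) < 3) abort("need at least 3 paired points")
  fit <- lm(predicted_bw_g[ok] ~ measured_bw_g[ok])
  # summary.lm warns on essentially perfect fits; that is the expected
  # outcome of the identity check, not a problem
  s <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]),
       slope_se = s$coefficients[2, 2],
       r_squared = s$r.squared,
       n = sum(ok))
}

#' Median-split sensitivity classification
#'
#' Splits an even-sized cohort into resistant (lower half of adiposity
#' gainers) and sensitive (upper half) groups. Applied to gains under the
#' high-carbohydrate diet this yields CR/CS labels; under the high-fat diet,
#' FR/FS. Ties straddling the median are resolved by stable `rat_id` order
#' with a warning, so the split is always exactly n/2 : n/2.
#'
#' @param gains per-rat adiposity gains (percentage points).
#' @param rat_id identifiers aligned with `gains`.
#' @param labels character length-2: resistant then sensitive label.
#' @return tibble: rat_id, gain, class (factor with the two labels).
#' @examples
#' classify_cohort(c(1, 2, 3, 4), paste0("r", 1:4))
#' @export
classify_cohort <- function(gains, rat_id = seq_along(gains),
                            labels = c("resistant", "sensitive")) {
  n <- length(gains)
  if (n < 2 || n %% 2 != 0) abort("cohort size must be even and >= 2")
  if (any(!is.finite(gains))) abort("gains must be finite")
  stopifnot(length(rat_id) == n, length(labels) == 2)
  ord <- order(gains, seq_len(n))  # stable in input (rat_id) order on ties
  half <- n %/% 2
  if (gains[ord[half]] == gains[ord[half + 1L]]) {
    warn("tie straddles the median; resolved by stable rat_id order")
  }
  cls <- character(n)
  cls[ord[seq_len(half)]] <- labels[1]
  cls[ord[(half + 1L):n]] <- labels[2]
  tibble::tibble(rat_id = as.character(rat_id), gain = gains,
                 class = factor(cls, levels = labels))
}

#' Visceral-to-subcutaneous fat distribution statistics
#'
#' Summarises paired visceral:subcutaneous fat-mass ratios across imaging
#' timepoints as median +/- 0.5 IQR (quartiles by linear interpolation,
#' type 7) and compares timepoints with paired two-sided Wilcoxon
#' signed-rank tests.
#'
#' @param ratios data frame with columns `rat_id`, `timepoint`, `ratio`;
#'   every rat must appear at every timepoint (paired design).
#' @return list with `summary` (tibble: timepoint, n, median, half_iqr) and
#'   `tests` (tibble: timepoint_a, timepoint_b, p_value).
#' @export
fat_distribution_stats <- function(ratios) {
  stopifnot(is.data.frame(ratios),
            all(c("rat_id", "timepoint", "ratio") %in% names(ratios)))
  wide <- tidyr::pivot_wider(ratios, id_cols = "rat_id",
                             names_from = "timepoint",
                             values_from = "ratio")
  tps <- setdiff(names(wide), "rat_id")
  if (length(tps) < 2) abort("need ratios at >= 2 timepoints")
  if (anyNA(wide[tps])) abort("unpaired records: every rat needs every timepoint")
  summ <- tibble::tibble(
    timepoint = tps,
    n = nrow(wide),
    median = vapply(tps, function(tp) median(wide[[tp]]), numeric(1)),
    half_iqr = vapply(tps, function(tp)
      0.5 * diff(quantile(wide[[tp]], c(0.25, 0.75), names = FALSE, type = 7)),
      numeric(1))
  )
  pairs <- utils::combn(tps, 2)
  tests <- tibble::tibble(
    timepoint_a = pairs[1, ],
    timepoint_b = pairs[2, ],
    p_value = apply(pairs, 2, function(p) {
      d <- wide[[p[1]]] - wide[[p[2]]]
      if (all(d == 0)) return(1)
      suppressWarnings(
        wilcox.test(wide[[p[1]]], wide[[p[2]]], paired = TRUE,
                    exact = FALSE)$p.value)
    })
  )
  list(summary = summ, tests = tests)
}
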