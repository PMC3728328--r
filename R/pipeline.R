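#' Pipeline run configuration
#'
#' Bundles everything an end-to-end run needs: master seed, cohort and
#' session settings, analysis windows and bin width. Windows are anchored to
#' meal delivery (time 0) and must not overlap.
#'
#' @param seed master seed; cohort and per-session seeds are derived from it
#'   deterministically.
#' @param n_rats cohort size.
#' @param bin_width_min bin width for the decomposed traces, min.
#' @param pre_window,post_window analysis windows, min relative to the meal.
#' @param cohort_overrides,session_overrides named lists of overrides passed
#'   to [cohort_config()] / [session_config()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_rats = 24L, bin_width_min = 15,
                       pre_window = c(-120, 0), post_window = c(0, 300),
                       cohort_overrides = list(),
                       session_overrides = list()) {
  if (pre_window[2] > post_window[1]) abort("analysis windows overlap")
  if (pre_window[1] >= pre_window[2] || post_window[1] >= post_window[2]) {
    abort("windows must be increasing")
  }
  structure(as.list(environment()), class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Decompose one measured session end to end
#'
#' Washout correction, Kalman decomposition, derived series, binning.
#'
#' @param trace a `gas_trace`.
#' @param tau_s washout time constant, s.
#' @param bin_width_min bin width, min.
#' @param ... passed to [kalman_decompose()].
#' @return list with `decomposed` (sample level) and `binned`.
#' @export
decompose_session <- function(trace, tau_s = attr(trace, "tau_s"),
                              bin_width_min = 15, ...) {
  corrected <- washout_correct(trace, tau_s = tau_s)
  dec <- kalman_decompose(corrected, ...)
  dec <- derive_components(dec)
  list(decomposed = dec, binned = bin_trace(dec, bin_width_min))
}

#' Build the long-format meal-response table for the mixed model
#'
#' Joins per-session pre/post parameter means to per-rat adiposity changes.
#' HC and HF meals, and HCD vs HFD adiposity changes, are never pooled: one
#' table (and one model) per combination.
#'
#' @param summaries session-summary tibble (one row per rat x meal).
#' @param gains tibble from [cohort_gains()].
#' @param meal `"HC"` or `"HF"`: which sessions to keep.
#' @param adchg_under `"hcd"` or `"hfd"`: which adiposity change is the
#'   covariate.
#' @param mp which metabolic parameter: base name with `_pre`/`_post`
#'   columns in `summaries` (default `"rest_rq"`).
#' @return a meal-response tibble for [fit_meal_response()].
#' @export
build_meal_response_table <- function(summaries, gains,
                                      meal = c("HC", "HF"),
                                      adchg_under = c("hcd", "hfd"),
                                      mp = "rest_rq") {
  meal <- match.arg(meal)
  adchg_under <- match.arg(adchg_under)
  pre_col <- paste0(mp, "_pre"); post_col <- paste0(mp, "_post")
  check_columns(summaries, c("rat_id", "meal_type", pre_col, post_col),
                "session summary")
  gain_col <- paste0(adchg_under, "_gain_pct")
  check_columns(gains, c("rat_id", gain_col), "gains table")
  s <- summaries[summaries$meal_type == meal, ]
  s <- dplyr::left_join(s, gains[c("rat_id", gain_col)], by = "rat_id")
  long <- tidyr::pivot_longer(
    s, cols = dplyr::all_of(c(pre_col, post_col)),
    names_to = "mealtime", values_to = "mp_value")
  long$mealtime <- factor(ifelse(endsWith(long$mealtime, "_pre"),
                                 "pre", "post"),
                          levels = c("pre", "post"))
  tibble::tibble(
    rat_id = long$rat_id,
    session_id = paste0(long$rat_id, "_", meal),
    mealtime = long$mealtime,
    meal_type = meal,
    adchg = long[[gain_col]],
    mp_value = long$mp_value
  )
}

#' Run the full synthetic study end to end
#'
#' Generates a cohort, simulates every scheduled calorimetry session,
#' decomposes and summarises each, classifies the cohort into
#' carbohydrate/fat resistant and sensitive halves, fits the meal-response
#' mixed models for Rest-RQ, and computes the cohort correlation and
#' fat-distribution statistics. Fully deterministic given the master seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, result CSVs and JSON
#'   reports are written there.
#' @return a results list: `cohort`, `summaries`, `gains`,
#'   `classification`, `fits`, `correlations`, `fat_distribution`,
#'   `diet_metrics`, `provenance`.
#' @export
run_full_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- stage("cohort", {
    args <- utils::modifyList(
      list(n_rats = config$n_rats, seed = child_seed(config$seed, 1L)),
      config$cohort_overrides)
    generate_cohort(do.call(cohort_config, args))
  })

  summaries <- stage("sessions", {
    sess <- cohort$sessions
    res <- vector("list", nrow(sess))
    for (i in seq_len(nrow(sess))) {
      rat <- cohort$rats[cohort$rats$rat_id == sess$rat_id[i], ]
      args <- utils::modifyList(
        list(seed = child_seed(config$seed, 100L + i),
             meal_type = sess$meal_type[i]),
        config$session_overrides)
      scfg <- do.call(session_config, args)
      sim <- simulate_session(rat, scfg)
      dec <- decompose_session(sim$trace, bin_width_min = config$bin_width_min)
      comp_rat <- cohort$composition[cohort$composition$rat_id ==
                                       sess$rat_id[i], ]
      bc <- interpolate_composition(
        comp_rat[comp_rat$mri_session %in% c(1, 2), ], sess$day[i])
      res[[i]] <- summarize_session(
        dec$binned, rat_id = sess$rat_id[i], meal_type = sess$meal_type[i],
        meal_energy_kj = scfg$meal_energy_kj,
        ffm_g = bc$ffm_g, fm_g = bc$fm_g,
        pre_window = config$pre_window, post_window = config$post_window)
    }
    dplyr::bind_rows(res)
  })

  gains <- stage("gains", cohort_gains(cohort))
  classification <- stage("classify", {
    cr_cs <- classify_cohort(gains$hcd_gain_pct, gains$rat_id,
                             labels = c("CR", "CS"))
    fr_fs <- classify_cohort(gains$hfd_gain_pct, gains$rat_id,
                             labels = c("FR", "FS"))
    tibble::tibble(rat_id = gains$rat_id,
                   hcd_gain_pct = gains$hcd_gain_pct,
                   hfd_gain_pct = gains$hfd_gain_pct,
                   class_hcd = cr_cs$class,
                   class_hfd = fr_fs$class)
  })

  fits <- stage("models", {
    combos <- expand.grid(meal = c("HC", "HF"), adchg = c("hcd", "hfd"),
                          stringsAsFactors = FALSE)
    out <- lapply(seq_len(nrow(combos)), function(i) {
      tab <- build_meal_response_table(summaries, gains,
                                       meal = combos$meal[i],
                                       adchg_under = combos$adchg[i])
      fit_meal_response(tab)
    })
    names(out) <- paste0(combos$meal, "_meal_", combos$adchg, "_gain")
    out
  })

  correlations <- stage("correlations", {
    bw <- cohort$rats
    list(
      hcd_vs_hfd_gain = pearson_correlation(gains$hcd_gain_pct,
                                            gains$hfd_gain_pct),
      bw_vs_adiposity_hcd = pearson_correlation(bw$bw_gain_hcd_g,
                                                gains$hcd_gain_pct),
      bw_vs_adiposity_hfd = pearson_correlation(bw$bw_gain_hfd_g,
                                                gains$hfd_gain_pct)
    )
  })

  fat_distribution <- stage("fat_distribution", {
    comp <- cohort$composition
    fat_distribution_stats(tibble::tibble(
      rat_id = comp$rat_id,
      timepoint = c("start", "post_hcd", "post_hfd")[comp$mri_session],
      ratio = comp$fm_visc_g / comp$fm_subc_g))
  })

  diets <- dplyr::bind_rows(diet_metrics(ref_diet("HCD")),
                            diet_metrics(ref_diet("HFD")))

  results <- list(
    cohort = cohort, summaries = summaries, gains = gains,
    classification = classification, fits = fits,
    correlations = correlations, fat_distribution = fat_distribution,
    diet_metrics = diets,
    provenance = provenance_record(config, config$seed)
  )
  if (!is.null(out_dir)) {
    stage("write", write_results(results, out_dir))
  }
  results
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(results$cohort$composition, file.path(out_dir, "cohort.csv"))
  write_summary(results$summaries, file.path(out_dir, "session_summaries.csv"))
  readr::write_csv(results$classification,
                   file.path(out_dir, "classification.csv"), na = "NA")
  readr::write_csv(results$diet_metrics,
                   file.path(out_dir, "diet_metrics.csv"), na = "NA")
  fits_json <- lapply(results$fits, function(f) {
    list(nesting = f$nesting, converged = f$converged, flags = f$flags,
         fixed = f$fixed, varcomp = as.list(f$varcomp))
  })
  jsonlite::write_json(fits_json, file.path(out_dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(results$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
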