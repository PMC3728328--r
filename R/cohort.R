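#' Cohort generator configuration
#'
#' Parameters of the synthetic cohort: starting body weight and adiposity,
#' adiposity gains under sequential high-carbohydrate (HCD, 3 weeks) then
#' high-fat (HFD, 3 weeks) feeding, the loose correlation between the two
#' gains, the coupling of body-weight gain to adiposity gain under each diet,
#' and the visceral:subcutaneous fat distribution at the three imaging
#' timepoints.
#'
#' Defaults reproduce the statistical structure of a 24-rat Wistar cohort:
#' start BW 303.3 +/- 24.5 g, HCD-vs-HFD adiposity-gain correlation 0.482,
#' BW-gain/adiposity-gain coupling 0.911 under HFD and 0.525 under HCD, and
#' visceral:subcutaneous ratio medians 1.44 (start), 1.82 (post-HCD), 1.53
#' (post-HFD).
#'
#' @param n_rats cohort size (even, >= 4).
#' @param seed integer seed; generation is fully reproducible.
#' @param start_bw_mean,start_bw_sd starting body weight, g.
#' @param start_adiposity_mean,start_adiposity_sd starting adiposity, percent.
#' @param hcd_gain_mean,hcd_gain_sd adiposity gain under HCD, percentage points.
#' @param hfd_gain_mean,hfd_gain_sd adiposity gain under HFD, percentage points.
#' @param gain_correlation Pearson correlation between the two gains.
#' @param bw_gain_hcd_mean,bw_gain_hcd_sd,bw_gain_hfd_mean,bw_gain_hfd_sd
#'   body-weight gain over each diet period, g.
#' @param bw_adiposity_coupling_hcd,bw_adiposity_coupling_hfd target Pearson
#'   correlation of BW gain with adiposity gain under each diet.
#' @param visc_subc_ratio_start,visc_subc_ratio_post_hcd,visc_subc_ratio_post_hfd
#'   median visceral:subcutaneous fat ratios at the three timepoints.
#' @param ratio_sdlog_between,ratio_sdlog_within log-scale spread of the
#'   ratio across rats (persistent) and across timepoints within a rat.
#' @param depot_fraction fraction of total fat mass in the visceral +
#'   subcutaneous depots.
#' @param bw_noise_sd day-to-day weighing noise, g.
#' @param mri_days days of the three imaging sessions (study start = day 0).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_rats = 24L, seed = 1L,
                          start_bw_mean = 303.3, start_bw_sd = 24.5,
                          start_adiposity_mean = 10, start_adiposity_sd = 2.5,
                          hcd_gain_mean = 2.0, hcd_gain_sd = 1.5,
                          hfd_gain_mean = 5.0, hfd_gain_sd = 2.0,
                          gain_correlation = 0.482,
                          bw_gain_hcd_mean = 80, bw_gain_hcd_sd = 15,
                          bw_gain_hfd_mean = 100, bw_gain_hfd_sd = 20,
                          bw_adiposity_coupling_hcd = 0.525,
                          bw_adiposity_coupling_hfd = 0.911,
                          visc_subc_ratio_start = 1.44,
                          visc_subc_ratio_post_hcd = 1.82,
                          visc_subc_ratio_post_hfd = 1.53,
                          ratio_sdlog_between = 0.15,
                          ratio_sdlog_within = 0.16,
                          depot_fraction = 0.85,
                          bw_noise_sd = 2,
                          mri_days = c(0L, 21L, 42L)) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_rats < 4 || cfg$n_rats %% 2 != 0) {
    abort("n_rats must be even and >= 4")
  }
  for (nm in c("start_bw_sd", "start_adiposity_sd", "hcd_gain_sd",
               "hfd_gain_sd", "bw_gain_hcd_sd", "bw_gain_hfd_sd",
               "ratio_sdlog_between", "ratio_sdlog_within", "bw_noise_sd")) {
    check_scalar(cfg[[nm]], nm, lower = 0)
  }
  check_scalar(cfg$gain_correlation, "gain_correlation", -1, 1)
  check_scalar(cfg$bw_adiposity_coupling_hcd, "bw_adiposity_coupling_hcd", -1, 1)
  check_scalar(cfg$bw_adiposity_coupling_hfd, "bw_adiposity_coupling_hfd", -1, 1)
  check_scalar(cfg$depot_fraction, "depot_fraction", 0, 1)
  # joint feasibility: the implied correlation matrix of the two adiposity
  # gains must be positive definite for the bivariate draw to exist
  g2 <- matrix(c(1, cfg$gain_correlation, cfg$gain_correlation, 1), 2)
  if (min(eigen(g2, symmetric = TRUE, only.values = TRUE)$values) <= 0 &&
      abs(cfg$gain_correlation) < 1) {
    abort("gain correlation matrix is not positive definite")
  }
  if (length(cfg$mri_days) != 3 || any(diff(cfg$mri_days) <= 0)) {
    abort("mri_days must be three increasing days")
  }
  invisible(cfg)
}

#' Generate a synthetic rat cohort
#'
#' Draws a cohort with the configured moments: starting BW and adiposity,
#' bivariate-normal HCD/HFD adiposity gains with the configured correlation,
#' body-weight gains coupled to adiposity gains at the configured Pearson
#' strengths, and per-timepoint visceral:subcutaneous fat splits with
#' log-normal spread around the configured medians (a persistent per-rat
#' component keeps the timepoints paired). Each rat also gets two
#' calorimetry-session days in weeks 2-3 of the HCD period, one HC and one
#' HF test meal in randomised order.
#'
#' @param config a [cohort_config()].
#' @return a `rat_cohort` list with tibbles:
#'   * `rats` - per-rat generating values (start BW/adiposity, gains);
#'   * `composition` - long imaging table (rat_id, day, mri_session, source,
#'     bw_g, fm_g, ffm_g, fm_visc_g, fm_subc_g);
#'   * `bodyweight` - weighing series (rat_id, day, bw_g) including the
#'     calorimetry days;
#'   * `sessions` - calorimetry schedule (rat_id, session_no, day, meal_type);
#'   plus the `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_rats = 8, seed = 42))
#' head(coh$composition)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_rats
  set.seed(cfg$seed)
  rat_id <- sprintf("R%02d", seq_len(n))

  bw0 <- pmax(rnorm(n, cfg$start_bw_mean, cfg$start_bw_sd), 150)
  rho <- cfg$gain_correlation

  # joint draw of starting adiposity and the two gains; rats whose
  # trajectory would leave (0.5, 60)% adiposity are redrawn (a negligible
  # truncation of the extreme tail at realistic settings)
  a0 <- g_hcd <- g_hfd <- rep(NA_real_, n)
  todo <- rep(TRUE, n)
  for (iter in 1:100) {
    k <- sum(todo)
    if (k == 0) break
    a0[todo] <- rnorm(k, cfg$start_adiposity_mean, cfg$start_adiposity_sd)
    z1 <- rnorm(k); z2 <- rnorm(k)
    g_hcd[todo] <- cfg$hcd_gain_mean + cfg$hcd_gain_sd * z1
    g_hfd[todo] <- cfg$hfd_gain_mean +
      cfg$hfd_gain_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
    todo <- a0 < 0.5 | a0 > 30 | a0 + g_hcd < 0.5 | a0 + g_hcd > 60 |
      a0 + g_hcd + g_hfd < 0.5 | a0 + g_hcd + g_hfd > 60
  }
  if (any(todo)) {
    abort("configured means/sds cannot keep adiposity inside (0.5, 60)%")
  }

  couple_bw <- function(gain, gain_mean, gain_sd, bw_mean, bw_sd, r) {
    if (gain_sd == 0) return(bw_mean + bw_sd * rnorm(n))
    bw_mean + r * bw_sd * (gain - gain_mean) / gain_sd +
      sqrt(1 - r^2) * bw_sd * rnorm(n)
  }
  bwg_hcd <- couple_bw(g_hcd, cfg$hcd_gain_mean, cfg$hcd_gain_sd,
                       cfg$bw_gain_hcd_mean, cfg$bw_gain_hcd_sd,
                       cfg$bw_adiposity_coupling_hcd)
  bwg_hfd <- couple_bw(g_hfd, cfg$hfd_gain_mean, cfg$hfd_gain_sd,
                       cfg$bw_gain_hfd_mean, cfg$bw_gain_hfd_sd,
                       cfg$bw_adiposity_coupling_hfd)

  bw <- cbind(bw0, bw0 + bwg_hcd, bw0 + bwg_hcd + bwg_hfd)
  adip <- cbind(a0, a0 + g_hcd, a0 + g_hcd + g_hfd)
  fm <- adip / 100 * bw
  ffm <- bw - fm

  # visceral:subcutaneous ratios, paired via a persistent per-rat component
  med <- c(cfg$visc_subc_ratio_start, cfg$visc_subc_ratio_post_hcd,
           cfg$visc_subc_ratio_post_hfd)
  u <- rnorm(n, 0, cfg$ratio_sdlog_between)
  ratio <- exp(log(rep(med, each = n)) + rep(u, 3) +
                 rnorm(3 * n, 0, cfg$ratio_sdlog_within))
  ratio <- matrix(ratio, n, 3)
  depot <- cfg$depot_fraction * fm
  fm_visc <- depot * ratio / (1 + ratio)
  fm_subc <- depot / (1 + ratio)

  composition <- tibble::tibble(
    rat_id = rep(rat_id, 3),
    day = rep(cfg$mri_days, each = n),
    mri_session = rep(1:3, each = n),
    source = rep(c("mri", "mri", "dissection"), each = n),
    bw_g = as.vector(bw),
    fm_g = as.vector(fm),
    ffm_g = as.vector(ffm),
    fm_visc_g = as.vector(fm_visc),
    fm_subc_g = as.vector(fm_subc)
  )
  composition <- dplyr::arrange(composition, .data$rat_id, .data$day)

  # calorimetry schedule: one day in HCD week 2, one in week 3, meals in
  # random order
  wk2 <- cfg$mri_days[1] + 7 + sample.int(5, n, replace = TRUE)
  wk3 <- cfg$mri_days[1] + 14 + sample.int(5, n, replace = TRUE)
  first_hc <- runif(n) < 0.5
  sessions <- tibble::tibble(
    rat_id = rep(rat_id, each = 2),
    session_no = rep(1:2, n),
    day = as.vector(rbind(wk2, wk3)),
    meal_type = as.vector(rbind(ifelse(first_hc, "HC", "HF"),
                                ifelse(first_hc, "HF", "HC")))
  )

  # weighing series: every 2 days plus the calorimetry days, piecewise-linear
  # truth between the imaging anchors with weighing noise
  days <- sort(unique(c(seq(cfg$mri_days[1], cfg$mri_days[3], by = 2),
                        sessions$day, cfg$mri_days)))
  bw_line <- vapply(seq_len(n), function(i)
    approx(cfg$mri_days, bw[i, ], xout = days)$y,
    numeric(length(days)))
  bodyweight <- tibble::tibble(
    rat_id = rep(rat_id, each = length(days)),
    day = rep(days, n),
    bw_g = as.vector(bw_line) + rnorm(n * length(days), 0, cfg$bw_noise_sd)
  )
  # the imaging-day weights are shared with the composition table
  bodyweight <- dplyr::rows_update(
    bodyweight,
    dplyr::select(composition, "rat_id", "day", "bw_g"),
    by = c("rat_id", "day"))

  rats <- tibble::tibble(
    rat_id = rat_id,
    bw_start_g = bw0,
    adiposity_start_pct = a0,
    hcd_gain_pct = g_hcd,
    hfd_gain_pct = g_hfd,
    bw_gain_hcd_g = bwg_hcd,
    bw_gain_hfd_g = bwg_hfd
  )
  structure(list(rats = rats, composition = composition,
                 bodyweight = bodyweight, sessions = sessions,
                 config = cfg),
            class = "rat_cohort")
}

#' @export
print.rat_cohort <- function(x, ...) {
  cat("<rat_cohort>", nrow(x$rats), "rats,",
      nrow(x$composition), "imaging records,",
      nrow(x$sessions), "calorimetry sessions\n")
  invisible(x)
}

#' Measured adiposity gains of a cohort
#'
#' Computes per-rat adiposity at each imaging session from the composition
#' table and returns the gains over the HCD (session 1 to 2) and HFD
#' (session 2 to 3) periods.
#'
#' @param cohort a `rat_cohort` (or any list with a conforming
#'   `$composition` tibble).
#' @param definition `"difference"` (percentage-point change, default) or
#'   `"relative"` (percent change of the adiposity percentage).
#' @return tibble: rat_id, adiposity at the three sessions, hcd_gain_pct,
#'   hfd_gain_pct.
#' @export
cohort_gains <- function(cohort, definition = c("difference", "relative")) {
  definition <- match.arg(definition)
  comp <- cohort$composition
  comp$adiposity <- adiposity_pct(comp$fm_g, comp$bw_g)
  wide <- tidyr::pivot_wider(comp, id_cols = "rat_id",
                             names_from = "mri_session",
                             names_prefix = "adiposity_mri",
                             values_from = "adiposity")
  gain <- function(a, b) {
    if (definition == "difference") b - a else 100 * (b - a) / a
  }
  dplyr::mutate(wide,
    hcd_gain_pct = gain(.data$adiposity_mri1, .data$adiposity_mri2),
    hfd_gain_pct = gain(.data$adiposity_mri2, .data$adiposity_mri3))
}

#' Keep the extremes of starting adiposity
#'
#' Optional arrival-screen filter: within consecutive arrival groups, keep
#' the `k` leanest and `k` fattest rats by starting adiposity and drop the
#' rest, inflating starting-adiposity variance. Off by default in every
#' pipeline; provided for sensitivity analyses.
#'
#' @param cohort a `rat_cohort`.
#' @param group_size arrival-group size.
#' @param k number kept at each extreme per group.
#' @return the filtered `rat_cohort`.
#' @export
select_extreme_adiposity <- function(cohort, group_size = 8L, k = 2L) {
  rats <- cohort$rats
  n <- nrow(rats)
  grp <- rep(seq_len(ceiling(n / group_size)), each = group_size)[seq_len(n)]
  keep <- unlist(lapply(split(seq_len(n), grp), function(idx) {
    ord <- idx[order(rats$adiposity_start_pct[idx])]
    kk <- min(k, floor(length(ord) / 2))
    c(head(ord, kk), tail(ord, kk))
  }))
  keep_ids <- rats$rat_id[sort(keep)]
  out <- cohort
  out$rats <- rats[rats$rat_id %in% keep_ids, ]
  for (nm in c("composition", "bodyweight", "sessions")) {
    out[[nm]] <- out[[nm]][out[[nm]]$rat_id %in% keep_ids, ]
  }
  out
}
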