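#' Significance labels at the package's fixed conventions
#'
#' P <= 0.01 is "significant", 0.01 < P <= 0.05 "marginal", larger "ns".
#' No multiple-testing correction is applied anywhere in the package; the
#' conservative threshold is the compensation.
#'
#' @param p numeric vector of p-values.
#' @return character vector of labels.
#' @export
significance_label <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p <= 0.01, "significant",
                ifelse(p <= 0.05, "marginal", "ns")))
}

#' Random-effect scales implied by target fixed-effect standard errors
#'
#' For the meal-response model with one pre and one post period mean per
#' rat, the standard error of the `adchg` slope is
#' `sqrt(sd_rat^2 + sd_resid^2) / (adchg_sd * sqrt(n - 1))` and that of the
#' interaction is `sqrt(2) * sd_resid / (adchg_sd * sqrt(n - 1))`. This
#' inverts those identities, giving generator scales that reproduce target
#' standard errors.
#'
#' @param se_adchg,se_interaction target standard errors.
#' @param adchg_sd SD of the adiposity-change covariate across rats.
#' @param n_rats cohort size.
#' @return list with `sd_rat` and `sd_resid`.
#' @export
re_scales_from_se <- function(se_adchg = 0.0041, se_interaction = 0.0026,
                              adchg_sd = 1.5, n_rats = 24) {
  k <- adchg_sd * sqrt(n_rats - 1)
  sd_resid <- se_interaction * k / sqrt(2)
  tot_var <- (se_adchg * k)^2
  if (tot_var < sd_resid^2) {
    abort("target SEs are inconsistent: interaction SE implies more residual variance than the adchg SE allows")
  }
  list(sd_rat = sqrt(tot_var - sd_resid^2), sd_resid = sd_resid)
}

#' Simulate a meal-response table from known fixed effects
#'
#' Generates the long-format pre/post meal-response data the mixed model
#' consumes, from explicit ground truth: per-rat adiposity change drawn
#' normal, response `mp = intercept + adchg_slope * adchg + mealtime_shift *
#' post + interaction * adchg * post + rat intercept + (session intercept) +
#' residual`. Default variance scales are chosen so the fitted model's
#' `adchg` and interaction standard errors land near 0.0041 and 0.0026 in a
#' 24-rat cohort (see [re_scales_from_se()]).
#'
#' @param n_rats rats per cohort.
#' @param seed integer seed.
#' @param fixed named numeric: `intercept`, `adchg`, `mealtime`,
#'   `interaction`.
#' @param adchg_mean,adchg_sd distribution of the adiposity-change covariate
#'   (percentage points).
#' @param sd_rat,sd_session,sd_resid random-intercept SDs for rat and
#'   session and the residual SD; `NULL` for the SE-matched defaults.
#' @param n_sessions sessions per rat (all same meal type here).
#' @param meal_type label carried through.
#' @return a `meal_response` tibble: rat_id, session_id, mealtime
#'   (factor pre/post), meal_type, adchg, mp_value.
#' @export
simulate_meal_response <- function(n_rats = 24, seed = 1L,
                                   fixed = c(intercept = 0.80,
                                             adchg = 0.0003,
                                             mealtime = 0.09,
                                             interaction = 0.0086),
                                   adchg_mean = 2, adchg_sd = 1.5,
                                   sd_rat = NULL, sd_session = 0,
                                   sd_resid = NULL,
                                   n_sessions = 1, meal_type = "HC") {
  stopifnot(all(c("intercept", "adchg", "mealtime", "interaction")
                %in% names(fixed)))
  if (is.null(sd_rat) || is.null(sd_resid)) {
    sc <- re_scales_from_se(adchg_sd = adchg_sd, n_rats = n_rats)
    sd_rat <- sd_rat %||% sc$sd_rat
    sd_resid <- sd_resid %||% sc$sd_resid
  }
  set.seed(seed)
  adchg <- rnorm(n_rats, adchg_mean, adchg_sd)
  u_rat <- rnorm(n_rats, 0, sd_rat)
  rows <- expand.grid(rat = seq_len(n_rats), session = seq_len(n_sessions),
                      period = c("pre", "post"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  u_sess <- rnorm(n_rats * n_sessions, 0, sd_session)
  sess_key <- (rows$rat - 1) * n_sessions + rows$session
  post <- as.numeric(rows$period == "post")
  mp <- fixed[["intercept"]] + fixed[["adchg"]] * adchg[rows$rat] +
    fixed[["mealtime"]] * post +
    fixed[["interaction"]] * adchg[rows$rat] * post +
    u_rat[rows$rat] + u_sess[sess_key] + rnorm(nrow(rows), 0, sd_resid)
  out <- tibble::tibble(
    rat_id = sprintf("R%02d", rows$rat),
    session_id = sprintf("R%02d_S%d", rows$rat, rows$session),
    mealtime = factor(rows$period, levels = c("pre", "post")),
    meal_type = meal_type,
    adchg = adchg[rows$rat],
    mp_value = mp
  )
  class(out) <- c("meal_response", class(out))
  out
}

#' Fit the nested mixed-effects meal-response model
#'
#' Fits `mp_value ~ adchg * mealtime` by REML with nested random
#' intercepts, the package's core inferential model: the intercept is the
#' pre-meal parameter in a rat with zero adiposity change, `adchg` the
#' pre-meal slope against adiposity change, `mealtime` the post-meal shift,
#' and the interaction the change of slope after the meal (how the meal
#' response relates to adiposity gain). P-values are nlme's conditional
#' t-tests.
#'
#' The full nesting is rat / session / period. When the table carries one
#' aggregated value per period (the usual case: period means), the
#' period-level intercept is confounded with the residual, and with one
#' session per rat the session level is confounded with the rat level;
#' `nesting = "auto"` keeps only the identifiable levels.
#'
#' @param table a meal-response table: columns `rat_id`, `session_id`,
#'   `mealtime` (pre/post), `adchg`, `mp_value`.
#' @param nesting `"auto"`, `"rat"`, `"rat/session"` or
#'   `"rat/session/period"`.
#' @return a `meal_response_fit` list: `fixed` (tibble term/estimate/se/df/
#'   t_value/p_value/label), `varcomp` (named SDs), `converged`, `flags`
#'   (character vector of problems, empty when clean), `nesting`, and the
#'   underlying `nlme::lme` object as `fit`.
#' @export
fit_meal_response <- function(table,
                              nesting = c("auto", "rat", "rat/session",
                                          "rat/session/period")) {
  nesting <- match.arg(nesting)
  need <- c("rat_id", "session_id", "mealtime", "adchg", "mp_value")
  stopifnot(is.data.frame(table), all(need %in% names(table)))
  df <- as.data.frame(table[need])
  df$mealtime <- factor(df$mealtime, levels = c("pre", "post"))
  df <- df[complete.cases(df), ]
  n_rats <- length(unique(df$rat_id))
  if (n_rats < 8) abort("need at least 8 rats")

  flags <- character()
  if (sd(df$adchg) < 1e-12) {
    return(structure(list(
      fixed = NULL, varcomp = NULL, converged = FALSE,
      flags = "adchg has no variance: adchg and interaction effects are inestimable",
      nesting = nesting, fit = NULL), class = "meal_response_fit"))
  }

  per_period <- stats::aggregate(seq_len(nrow(df)),
    by = df[c("rat_id", "session_id", "mealtime")], FUN = length)$x
  multi_session <- any(tapply(df$session_id, df$rat_id,
                              function(s) length(unique(s))) > 1)
  if (nesting == "auto") {
    nesting <- if (any(per_period > 1)) "rat/session/period"
      else if (multi_session) "rat/session" else "rat"
  }
  df$periodID <- interaction(df$session_id, df$mealtime, drop = TRUE)
  random <- switch(nesting,
    "rat" = ~ 1 | rat_id,
    "rat/session" = ~ 1 | rat_id / session_id,
    "rat/session/period" = ~ 1 | rat_id / session_id / periodID)

  fit <- tryCatch(
    nlme::lme(mp_value ~ adchg * mealtime, random = random, data = df,
              method = "REML",
              control = nlme::lmeControl(returnObject = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(
      fixed = NULL, varcomp = NULL, converged = FALSE,
      flags = paste("lme failed:", conditionMessage(fit)),
      nesting = nesting, fit = NULL), class = "meal_response_fit"))
  }
  tt <- summary(fit)$tTable
  term_map <- c("(Intercept)" = "intercept", "adchg" = "adchg",
                "mealtimepost" = "mealtime", "adchg:mealtimepost" = "interaction")
  fixed <- tibble::tibble(
    term = unname(term_map[rownames(tt)]),
    estimate = tt[, "Value"],
    se = tt[, "Std.Error"],
    df = tt[, "DF"],
    t_value = tt[, "t-value"],
    p_value = tt[, "p-value"],
    label = significance_label(tt[, "p-value"])
  )
  vc <- nlme::VarCorr(fit)
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  names(sds) <- rownames(vc)
  if (any(!is.finite(fixed$se)) || any(fixed$se <= 0)) {
    flags <- c(flags, "non-positive fixed-effect standard error")
  }
  structure(list(fixed = fixed, varcomp = sds,
                 converged = length(flags) == 0, flags = flags,
                 nesting = nesting, fit = fit),
            class = "meal_response_fit")
}

#' @export
print.meal_response_fit <- function(x, ...) {
  cat("<meal_response_fit> nesting:", x$nesting,
      if (!x$converged) "(FLAGGED)", "\n")
  if (!is.null(x$fixed)) print(as.data.frame(x$fixed), digits = 4)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y numeric vectors, length >= 3, finite, non-degenerate.
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Per-timepoint two-sample comparisons of binned group series
#'
#' Runs a two-sided two-sample t-test at every binned timepoint between two
#' groups of per-subject values, masks at the configured threshold, and
#' reports contiguous significant spans.
#'
#' @param data long tibble: columns `time` (bin midpoint or index), `group`
#'   (two levels), `value` (one per subject per timepoint).
#' @param threshold significance threshold (default 0.01).
#' @return list: `by_time` (tibble time/n_a/n_b/p_value/significant/flag)
#'   and `spans` (tibble span_start/span_end of contiguous significant
#'   timepoints).
#' @export
pointwise_group_tests <- function(data, threshold = 0.01) {
  stopifnot(is.data.frame(data),
            all(c("time", "group", "value") %in% names(data)))
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) != 2) abort("need exactly two groups")
  times <- sort(unique(data$time))
  res <- lapply(times, function(tp) {
    a <- data$value[data$time == tp & data$group == groups[1]]
    b <- data$value[data$time == tp & data$group == groups[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(time = tp, n_a = length(a), n_b = length(b),
                            p_value = NA_real_, flag = "too few values"))
    }
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble::tibble(time = tp, n_a = length(a), n_b = length(b),
                            p_value = NA_real_, flag = "degenerate variance"))
    }
    tibble::tibble(time = tp, n_a = length(a), n_b = length(b),
                   p_value = t.test(a, b)$p.value, flag = NA_character_)
  })
  by_time <- dplyr::bind_rows(res)
  by_time$significant <- !is.na(by_time$p_value) & by_time$p_value < threshold
  r <- rle(by_time$significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  spans <- tibble::tibble(
    span_start = by_time$time[starts[r$values]],
    span_end = by_time$time[ends[r$values]])
  list(by_time = by_time, spans = spans)
}
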