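# CSV codecs for the package's tabular interfaces. All artifacts are plain
# RFC-4180 CSV with header rows, so every output is diffable.

trace_cols <- c("time_s", "vo2_ml_min", "vco2_ml_min", "activity_au",
                "missing_flag")
cohort_cols <- c("rat_id", "day", "bw_g", "ffm_g", "fm_g", "fm_visc_g",
                 "fm_subc_g", "mri_session")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# header check before a typed read, so a missing column is reported by name
# rather than as a parser mismatch
check_header <- function(path, required, what) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  missing <- setdiff(required, header)
  if (length(missing)) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(header)
}

check_parse_problems <- function(df, path) {
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(paste0("malformed rows in ", path, " at line(s) ",
                 paste(unique(probs$row), collapse = ", "), ": ",
                 probs$expected[1], " vs ", probs$actual[1]))
  }
  invisible(df)
}

#' Read and write gas-exchange traces
#'
#' Trace CSVs carry `time_s`, `vo2_ml_min`, `vco2_ml_min`, `activity_au`
#' and `missing_flag`; missing samples are explicit `NA` rows with the flag
#' set, never zeros. Round-trips are lossless.
#'
#' @param trace a `gas_trace`.
#' @param path file path.
#' @return `read_trace()` returns a `gas_trace`; `write_trace()` its path,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  check_columns(trace, trace_cols, "gas trace")
  readr::write_csv(trace[trace_cols], path, na = "NA")
  invisible(path)
}

#' @rdname write_trace
#' @param tau_s washout time constant to attach, s.
#' @export
read_trace <- function(path, tau_s = NA_real_) {
  check_header(path, trace_cols, basename(path))
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = "d", vo2_ml_min = "d", vco2_ml_min = "d",
    activity_au = "d", missing_flag = "l"), progress = FALSE)
  check_parse_problems(df, path)
  check_columns(df, trace_cols, basename(path))
  new_gas_trace(df$time_s, df$vo2_ml_min, df$vco2_ml_min, df$activity_au,
                df$missing_flag, tau_s = tau_s)
}

#' Read and write cohort composition tables
#'
#' Long-format imaging table: one row per rat per imaging session with
#' body weight and the fat-mass split.
#'
#' @param composition a composition tibble (see [generate_cohort()]).
#' @param path file path.
#' @export
write_cohort <- function(composition, path) {
  check_columns(composition, cohort_cols, "cohort table")
  readr::write_csv(composition[union(cohort_cols,
                                     intersect("source", names(composition)))],
                   path, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  check_header(path, cohort_cols, basename(path))
  df <- readr::read_csv(path, col_types = readr::cols(
    rat_id = "c", day = "d", bw_g = "d", ffm_g = "d", fm_g = "d",
    fm_visc_g = "d", fm_subc_g = "d", mri_session = "i",
    .default = "c"), progress = FALSE)
  check_parse_problems(df, path)
  check_columns(df, cohort_cols, basename(path))
  bad <- which(abs(df$ffm_g - (df$bw_g - df$fm_g)) > 0.5)
  if (length(bad)) {
    abort(paste0("cohort rows violate ffm = bw - fm at line(s) ",
                 paste(bad + 1L, collapse = ", ")))
  }
  df
}

#' Read and write session summaries
#'
#' One row per rat x meal type of session-level metabolic parameters, as
#' produced by [summarize_session()].
#'
#' @param summary a session-summary tibble.
#' @param path file path.
#' @export
write_summary <- function(summary, path) {
  check_columns(summary, c("rat_id", "meal_type", "bmr_w", "tef_kj"),
                "session summary")
  readr::write_csv(summary, path, na = "NA")
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  check_header(path, c("rat_id", "meal_type", "bmr_w", "tef_kj"),
               basename(path))
  df <- readr::read_csv(path, col_types = readr::cols(
    rat_id = "c", meal_type = "c", .default = "d"), progress = FALSE)
  check_parse_problems(df, path)
  check_columns(df, c("rat_id", "meal_type", "bmr_w", "tef_kj"),
                basename(path))
  df
}

#' Read and write generator configurations as YAML
#'
#' Configuration files mirror the field names of [cohort_config()] /
#' [session_config()] / [run_config()] exactly; unknown fields are an
#' error, so typos do not silently fall back to defaults.
#'
#' @param config a `cohort_config`, `session_config` or `run_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  type <- intersect(class(config), c("cohort_config", "session_config",
                                     "run_config"))
  if (!length(type)) abort("not a cagecal configuration object")
  yaml::write_yaml(c(list(type = sub("_config$", "", type[1])),
                     unclass(config)), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @return `read_config()` returns the validated configuration object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  type <- raw$type %||% abort("config file lacks a 'type' field")
  raw$type <- NULL
  ctor <- switch(type,
    cohort = cohort_config, session = session_config, run = run_config,
    abort(paste0("unknown config type '", type, "'")))
  known <- names(formals(ctor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(ctor, raw)
}

#' Machine-readable provenance for a pipeline run
#'
#' @param config the run configuration (hashed into the record).
#' @param seed master seed.
#' @return list: package and R versions, seed, config hash.
#' @export
provenance_record <- function(config, seed) {
  list(
    package = "cagecal",
    package_version = as.character(utils::packageVersion("cagecal")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    config_hash = rlang::hash(config)
  )
}
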