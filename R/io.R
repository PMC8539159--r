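#' Read and write force logs
#'
#' Force logs are plain CSV with a required header
#' `time_s,left_N,right_N`: time in seconds from bout start, per-side
#' footrest force in newtons. Readers validate rather than coerce: a missing
#' column, non-numeric data, non-monotone time stamps or a non-uniform
#' sampling grid are errors, never silently repaired.
#'
#' @param path File path.
#' @param trace A [force_trace()] (for the writer).
#' @return `read_force_log()` returns a [force_trace()];
#'   `write_force_log()` returns `path` invisibly.
#' @export
read_force_log <- function(path) {
  force_trace(read_checked_csv(path, c("time_s", "left_N", "right_N")))
}

#' @rdname read_force_log
#' @export
write_force_log <- function(trace, path) {
  if (!inherits(trace, "force_trace")) {
    kf_stop("`trace` must be a force_trace.", "validation")
  }
  readr::write_csv(tibble::as_tibble(trace), path)
  invisible(path)
}

#' Read and write velocity traces
#'
#' Velocity CSV: header `time_s,velocity_kmh`, time in seconds, velocity in
#' km/h.
#'
#' @param path File path.
#' @param trace A [velocity_trace()] (for the writer).
#' @return `read_velocity_trace()` returns a [velocity_trace()].
#' @export
read_velocity_trace <- function(path) {
  velocity_trace(read_checked_csv(path, c("time_s", "velocity_kmh")))
}

#' @rdname read_velocity_trace
#' @export
write_velocity_trace <- function(trace, path) {
  if (!inherits(trace, "velocity_trace")) {
    kf_stop("`trace` must be a velocity_trace.", "validation")
  }
  readr::write_csv(tibble::as_tibble(trace), path)
  invisible(path)
}

#' Read and write feature tables
#'
#' One row per paddler-bout with the identifying metadata and the five
#' leg-force characteristics plus velocity. Group labels are restricted to
#' `girls_u16`, `boys_u18`, `senior_women`, `senior_men` and bout labels to
#' `12kmh`, `15kmh`, `maximal` (NA allowed); force quantities must be
#' non-negative. Round trips are lossless up to float formatting.
#'
#' @param records A feature-record data frame (as produced by
#'   [extract_features()] or [generate_cohort()]).
#' @param path File path.
#' @return `read_feature_table()` returns a tibble of feature records.
#' @export
write_feature_table <- function(records, path) {
  records <- validate_feature_table(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  cols <- c("paddler_id", "group", "bout", kf_feature_cols)
  if (!file.exists(path)) {
    kf_stop(sprintf("file not found: %s", path), "format")
  }
  tab <- suppressWarnings(readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      paddler_id = readr::col_character(),
      group = readr::col_character(),
      bout = readr::col_character(),
      .default = readr::col_double()
    )
  ))
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols)) {
    kf_stop(paste0("missing required column(s): ",
                   paste(missing_cols, collapse = ", ")), "format")
  }
  validate_feature_table(tab[cols])
}

validate_feature_table <- function(records) {
  if (!is.data.frame(records)) {
    kf_stop("`records` must be a data frame.", "validation")
  }
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(c("paddler_id", "group", "bout", kf_feature_cols),
                          names(records))
  if (length(missing_cols)) {
    kf_stop(paste0("missing required column(s): ",
                   paste(missing_cols, collapse = ", ")), "format")
  }
  bad_group <- setdiff(stats::na.omit(unique(records$group)), kf_groups)
  if (length(bad_group)) {
    kf_stop(paste0("unknown group label(s): ",
                   paste(bad_group, collapse = ", ")), "validation")
  }
  bad_bout <- setdiff(stats::na.omit(unique(records$bout)), kf_bouts)
  if (length(bad_bout)) {
    kf_stop(paste0("unknown bout label(s): ",
                   paste(bad_bout, collapse = ", ")), "validation")
  }
  force_cols <- setdiff(kf_feature_cols, "velocity_kmh")
  neg <- force_cols[vapply(records[force_cols],
                           function(x) any(x < 0, na.rm = TRUE), logical(1))]
  if (length(neg)) {
    kf_stop(paste0("negative values in: ", paste(neg, collapse = ", ")),
            "validation")
  }
  records
}

#' Read and write normalized stroke-cycle profiles
#'
#' Profile CSV: header `percent,left_mean_N,left_sd_N,right_mean_N,
#' right_sd_N`, with `percent` running 0-100.
#'
#' @param profile A `normalized_profile` from [normalize_and_average()].
#' @param path File path.
#' @return `read_profile()` returns a `normalized_profile` tibble.
#' @export
write_profile <- function(profile, path) {
  if (!inherits(profile, "normalized_profile")) {
    kf_stop("`profile` must be a normalized_profile.", "validation")
  }
  readr::write_csv(tibble::as_tibble(profile), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  cols <- c("percent", "left_mean_N", "left_sd_N", "right_mean_N",
            "right_sd_N")
  tab <- read_checked_csv(path, cols, monotone_col = "percent")
  if (any(tab$left_sd_N < 0) || any(tab$right_sd_N < 0)) {
    kf_stop("profile SD columns must be non-negative.", "validation")
  }
  structure(tab, class = c("normalized_profile", class(tibble::tibble())))
}

#' Read and write pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A configuration list, see [default_config()]. Unknown keys
#'   are rejected; missing keys fall back to defaults.
#' @return `read_config()` returns a `kayak_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_config()
  bad <- setdiff(names(raw), names(base))
  if (length(bad)) {
    kf_stop(paste0("unknown config section(s): ", paste(bad, collapse = ", ")),
            "format")
  }
  for (section in names(raw)) {
    bad_key <- setdiff(names(raw[[section]]), names(base[[section]]))
    if (length(bad_key)) {
      kf_stop(paste0("unknown config key(s) in ", section, ": ",
                     paste(bad_key, collapse = ", ")), "format")
    }
    for (key in names(raw[[section]])) {
      base[[section]][[key]] <- raw[[section]][[key]]
    }
  }
  base
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(s)
    Filter(Negate(is.null), s)), path)
  invisible(path)
}

# shared CSV reader: header must contain exactly the expected numeric
# columns; time-like column must be strictly increasing
read_checked_csv <- function(path, cols, monotone_col = "time_s") {
  if (!file.exists(path)) {
    kf_stop(sprintf("file not found: %s", path), "format")
  }
  tab <- suppressWarnings(readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_double())
  ))
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols)) {
    kf_stop(paste0("missing required column(s): ",
                   paste(missing_cols, collapse = ", ")), "format")
  }
  tab <- tab[cols]
  if (anyNA(tab)) {
    kf_stop("non-numeric or missing values in numeric columns.", "data")
  }
  if (monotone_col %in% cols && nrow(tab) >= 2) {
    bad <- which(diff(tab[[monotone_col]]) <= 0)
    if (length(bad)) {
      kf_stop(sprintf(
        "`%s` must be strictly increasing; first offending data row: %d.",
        monotone_col, bad[1] + 1L
      ), "data")
    }
  }
  tab
}
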