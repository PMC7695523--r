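#' Read an oximetry CSV
#'
#' Expects columns `patient_id,timestamp,heart_rate,spo2` with ISO-8601
#' timestamps. Samples are returned sorted by patient and time. Readings
#' outside physiological plausibility (heart rate outside 20-250 beats/min,
#' SpO2 outside 50-100%) are retained but flagged `valid = FALSE`, so QC
#' counts stay auditable; downstream aggregation ignores invalid samples.
#'
#' @param path CSV file path. Lines starting with `#` are ignored.
#' @return tibble with columns `patient_id`, `timestamp` (POSIXct, UTC),
#'   `heart_rate`, `spo2`, `valid`.
#' @export
read_oximetry <- function(path) {
  df <- read_checked_csv(path, c("patient_id", "timestamp", "heart_rate", "spo2"))
  ts <- parse_iso_datetime(df$timestamp)
  bad <- which(is.na(ts) & !is.na(df$timestamp) & df$timestamp != "")
  if (length(bad)) {
    abort(sprintf("unparseable timestamp in %s at line(s) %s",
                  basename(path),
                  paste(head(bad, 5) + 1L, collapse = ", ")),
          class = "oxicopd_format_error")
  }
  tibble(patient_id = as.character(df$patient_id),
         timestamp = ts,
         heart_rate = as.numeric(df$heart_rate),
         spo2 = as.numeric(df$spo2)) |>
    arrange(.data$patient_id, .data$timestamp) |>
    flag_valid_samples()
}

# physiological plausibility flags; out-of-range readings are excluded from
# nightly aggregation but never silently dropped from the table
flag_valid_samples <- function(oximetry) {
  mutate(oximetry,
         valid = !is.na(.data$heart_rate) & !is.na(.data$spo2) &
           .data$heart_rate >= 20 & .data$heart_rate <= 250 &
           .data$spo2 >= 50 & .data$spo2 <= 100)
}

#' Read a daily diary CSV (CAT and PEF)
#'
#' Expects columns `patient_id,date,cat,pef`; one entry per patient per
#' date. CAT must lie in 0-40 and PEF must be nonnegative.
#'
#' @param path CSV file path. Lines starting with `#` are ignored.
#' @return tibble with columns `patient_id`, `date` (Date), `cat`
#'   (integer), `pef`.
#' @export
read_diary <- function(path) {
  df <- read_checked_csv(path, c("patient_id", "date", "cat", "pef"))
  date <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(date) & !is.na(df$date) & df$date != "")
  if (length(bad)) {
    abort(sprintf("unparseable date in %s at line(s) %s", basename(path),
                  paste(head(bad, 5) + 1L, collapse = ", ")),
          class = "oxicopd_format_error")
  }
  cat <- as.numeric(df$cat)
  out_of_range <- which(!is.na(cat) & (cat < 0 | cat > 40))
  if (length(out_of_range)) {
    abort(sprintf("CAT outside 0-40 in %s (e.g. %s on %s)", basename(path),
                  cat[out_of_range[1]], date[out_of_range[1]]),
          class = "oxicopd_validation_error")
  }
  pef <- as.numeric(df$pef)
  if (any(!is.na(pef) & pef < 0)) {
    abort(sprintf("negative PEF in %s", basename(path)),
          class = "oxicopd_validation_error")
  }
  out <- tibble(patient_id = as.character(df$patient_id), date = date,
                cat = as.integer(cat), pef = pef)
  dup <- out |> count(.data$patient_id, .data$date) |> filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicate diary entries in %s: %s", basename(path),
                  paste(sprintf("%s on %s", dup$patient_id, dup$date),
                        collapse = "; ")),
          class = "oxicopd_validation_error")
  }
  arrange(out, .data$patient_id, .data$date)
}

#' Read a cohort manifest CSV
#'
#' Expects columns `patient_id,arm,treatment_day`; an empty `treatment_day`
#' means the patient had no treated exacerbation. An optional
#' `monitoring_start` column records the first monitored date (otherwise it
#' is inferred downstream from the data streams).
#'
#' @param path CSV file path. Lines starting with `#` are ignored.
#' @return tibble with columns `patient_id`, `arm` (`"once_daily"` or
#'   `"overnight"`), `treatment_day` (Date or NA) and, when present,
#'   `monitoring_start`.
#' @export
read_manifest <- function(path) {
  df <- read_checked_csv(path, c("patient_id", "arm", "treatment_day"))
  arm <- as.character(df$arm)
  bad <- setdiff(unique(arm), c("once_daily", "overnight"))
  if (length(bad)) {
    abort(sprintf("unknown arm label(s) in %s: %s (expected once_daily or overnight)",
                  basename(path), paste(bad, collapse = ", ")),
          class = "oxicopd_validation_error")
  }
  td <- as.character(df$treatment_day)
  td[!is.na(td) & td == ""] <- NA_character_
  out <- tibble(patient_id = as.character(df$patient_id), arm = arm,
                treatment_day = as.Date(td))
  if ("monitoring_start" %in% names(df)) {
    out$monitoring_start <- as.Date(as.character(df$monitoring_start))
    out <- relocate(out, "monitoring_start", .before = "treatment_day")
  }
  out
}

# shared CSV reader: enforces required header, tolerates extra columns,
# reads everything as character so validation controls the coercions
read_checked_csv <- function(path, required) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "oxicopd_format_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        comment = "#", progress = FALSE,
                        show_col_types = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s", basename(path),
                  paste(missing, collapse = ", ")),
          class = "oxicopd_format_error")
  }
  df
}

parse_iso_datetime <- function(x) {
  x <- as.character(x)
  ts <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  fallback <- is.na(ts) & !is.na(x) & x != ""
  if (any(fallback)) {
    ts[fallback] <- as.POSIXct(x[fallback], tz = "UTC",
                               format = "%Y-%m-%d %H:%M:%S")
  }
  ts
}

#' Write a cohort to its CSV interchange files
#'
#' Writes `oximetry.csv`, `diary.csv`, `manifest.csv` and, when truth is
#' available (simulated cohorts), `truth.csv` into `dir`. Timestamps are
#' ISO-8601 UTC; the files round-trip through [read_oximetry()],
#' [read_diary()] and [read_manifest()].
#'
#' @param cohort a `copd_cohort` (or any list with the same tables).
#' @param dir output directory, created if needed.
#' @param config_hash optional hash string written as a `# config_hash:`
#'   provenance comment at the top of each file.
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir, config_hash = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ox <- cohort$oximetry
  ox$timestamp <- format(ox$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  ox$valid <- NULL
  paths <- c(
    write_output_csv(ox, file.path(dir, "oximetry.csv"), config_hash),
    write_output_csv(cohort$diary, file.path(dir, "diary.csv"), config_hash),
    write_output_csv(cohort$manifest, file.path(dir, "manifest.csv"),
                     config_hash)
  )
  if (!is.null(cohort$truth)) {
    paths <- c(paths, write_output_csv(cohort$truth,
                                       file.path(dir, "truth.csv"),
                                       config_hash))
  }
  invisible(paths)
}

# CSV writer used for all pipeline outputs: header always present, optional
# provenance comment line naming the resolved config hash
write_output_csv <- function(df, path, config_hash = NULL) {
  if (!is.null(config_hash)) {
    writeLines(sprintf("# config_hash: %s", config_hash), path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}
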