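#' Load a participant cohort table
#'
#' Reads a delimited-text table of participant demographics and clinical
#' characteristics (one row per participant) and validates it. The packaged
#' fixture `system.file("extdata", "cohort_table1.csv", package = "cibalance")`
#' holds the 13-participant study cohort: adolescents who received a first
#' cochlear implant (CI-1) in the right ear in early childhood and a second
#' implant (CI-2) in the left ear about a decade later.
#'
#' Required columns: `participant_id`, `age_onset_deafness`,
#' `duration_bilateral_deafness`, `age_ci1`, `electrode_array_ci1`, `age_ci2`,
#' `electrode_array_ci2`, `inter_implant_delay`, `etiology`. Ages and
#' durations are in years. Missing electrode arrays must be marked
#' `"Not available"` (they are preserved, never dropped).
#'
#' @param path Path to a comma- or tab-delimited UTF-8 file with a header row.
#' @return A `data.frame` of class `cohort_table`, sorted ascending by
#'   `age_ci1`.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           colClasses = "character", check.names = TRUE,
                           fill = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L) stop("cohort validation error: file contains no participant rows")
  required <- c("participant_id", "age_onset_deafness",
                "duration_bilateral_deafness", "age_ci1",
                "electrode_array_ci1", "age_ci2", "electrode_array_ci2",
                "inter_implant_delay", "etiology")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("cohort validation error: missing columns: ",
         paste(missing_cols, collapse = ", "))

  numeric_cols <- c("age_onset_deafness", "duration_bilateral_deafness",
                    "age_ci1", "age_ci2", "inter_implant_delay")
  out <- raw[required]
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & nzchar(out[[col]]))
    if (length(bad))
      stop(sprintf("cohort parse error: non-numeric value '%s' in row %d, column '%s'",
                   out[[col]][bad[1L]], bad[1L], col))
    out[[col]] <- vals
  }
  if (anyDuplicated(out$participant_id))
    stop("cohort validation error: duplicate participant_id: ",
         paste(unique(out$participant_id[duplicated(out$participant_id)]),
               collapse = ", "))

  if (any(out$age_ci1 < 0, na.rm = TRUE))
    stop("cohort validation error: age_ci1 must be >= 0")
  if (any(out$age_ci2 <= out$age_ci1, na.rm = TRUE))
    stop("cohort validation error: age_ci2 must exceed age_ci1")
  recon <- out$age_ci2 - out$age_ci1
  off <- which(abs(recon - out$inter_implant_delay) > 0.05)
  if (length(off))
    warning("inter_implant_delay differs from age_ci2 - age_ci1 by > 0.05 y for participant(s): ",
            paste(out$participant_id[off], collapse = ", "))

  arr_cols <- c("electrode_array_ci1", "electrode_array_ci2")
  for (col in arr_cols) {
    blank <- !nzchar(trimws(out[[col]])) | is.na(out[[col]])
    out[[col]][blank] <- "Not available"
  }

  out <- out[order(out$age_ci1), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Summarize a cohort table
#'
#' Mean and sample standard deviation (n - 1 denominator) for every numeric
#' column, reported to two decimals as in published demographic summary rows.
#'
#' @param cohort A `cohort_table` from [load_cohort()].
#' @param digits Decimals to round to (default 2).
#' @return A `data.frame` with columns `variable`, `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(cohort, digits = 2) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) < 2L)
    stop("insufficient data: cohort summary requires at least 2 records")
  numeric_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  out <- data.frame(
    variable = numeric_cols,
    mean = vapply(numeric_cols, function(v) round(mean(cohort[[v]]), digits), 0),
    sd = vapply(numeric_cols, function(v) round(stats::sd(cohort[[v]]), digits), 0),
    n = nrow(cohort),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Write a cohort summary to delimited text and JSON
#'
#' @param summary A summary table from [summarize_cohort()].
#' @param path Output path; `.json` extension selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(summary, path, row.names = FALSE)
  }
  invisible(path)
}

#' Time-bin boundaries (days since CI-2 activation)
#'
#' The four categorical follow-up windows used throughout the longitudinal
#' models. Recording sessions cluster around 8.7, 42.4, 100.5 and 285.1 days
#' after activation of the second implant; boundaries are placed between the
#' cluster means (21 / 75 / 135 days) so that every cluster mean +/- SD falls
#' inside its own bin.
#'
#' @format Named numeric vector of upper bin edges in days (the last bin is
#'   unbounded).
#' @export
time_bin_breaks <- c(weeks_1_2 = 21, months_1_2 = 75, months_3_4 = 135,
                     months_6_14 = Inf)

#' Time-bin labels in chronological order
#' @export
time_bin_levels <- names(time_bin_breaks)

#' Assign recording sessions to categorical time bins
#'
#' Maps days since activation of the second implant onto the four follow-up
#' bins: `[0, 21]` weeks_1_2, `(21, 75]` months_1_2, `(75, 135]` months_3_4,
#' `(135, Inf)` months_6_14.
#'
#' @param days_since_activation Numeric vector of days, all `>= 0`.
#' @param breaks Upper bin edges; override to move the (unpublished)
#'   boundaries.
#' @return Ordered factor with levels [time_bin_levels].
#' @export
assign_time_bin <- function(days_since_activation, breaks = time_bin_breaks) {
  if (any(is.na(days_since_activation)))
    stop("domain error: days_since_activation contains NA")
  if (any(days_since_activation < 0))
    stop("domain error: days_since_activation must be >= 0")
  stopifnot(length(breaks) >= 2L, !is.unsorted(breaks))
  idx <- vapply(days_since_activation,
                function(d) which(d <= breaks)[1L], integer(1))
  factor(names(breaks)[idx], levels = names(breaks), ordered = TRUE)
}

#' Flag participants with more than one session in a time bin
#'
#' Sessions are kept; duplicates within a participant-by-bin cell are flagged
#' so the caller can decide which to retain for categorical-time analyses.
#'
#' @param sessions A `data.frame` with columns `participant_id` and
#'   `days_since_activation`.
#' @return `sessions` with added columns `time_bin` and `duplicate_bin`.
#' @export
flag_duplicate_bins <- function(sessions) {
  stopifnot(all(c("participant_id", "days_since_activation") %in% names(sessions)))
  sessions$time_bin <- assign_time_bin(sessions$days_since_activation)
  key <- interaction(sessions$participant_id, sessions$time_bin, drop = TRUE)
  dup_keys <- names(which(table(key) > 1L))
  sessions$duplicate_bin <- as.character(key) %in% dup_keys
  sessions
}
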