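#' Read an epoch-count CSV export
#'
#' Reads the plain-text epoch export written by [write_epoch_csv()] (an
#' ActiLife-like layout): a fixed metadata header block (subject,
#' placement, visit, start time, epoch length, serial) terminated by a
#' `------` line, followed by comma-separated columns `Date, Time, Axis1,
#' Axis2, Axis3, Steps`. Extra columns are ignored. If the `Date`/`Time`
#' columns are absent the timestamps are reconstructed contiguously from
#' the header start time.
#'
#' @param path path to the CSV file.
#' @param dialect `"standard"` (metadata header block, the interchange
#'   format) or `"bare"` (no header; `Date` and `Time` columns required and
#'   identity taken from arguments).
#' @param subject_id,placement,visit identity fields used for
#'   `dialect = "bare"`.
#' @return an [epoch_series()].
#' @export
read_epoch_csv <- function(path, dialect = c("standard", "bare"),
                           subject_id = "unknown", placement = "waist",
                           visit = "baseline") {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  meta <- list(subject_id = subject_id, placement = placement, visit = visit,
               epoch_length = 60L, start_time = NA)
  skip <- 0L
  if (dialect == "standard") {
    sep <- which(grepl("^-{3,}\\s*$", lines))[1]
    if (is.na(sep)) {
      stop("malformed header: no '------' separator line found in ", path,
           call. = FALSE)
    }
    for (i in seq_len(sep - 1L)) {
      ln <- lines[i]
      if (i == 1L) next  # title line, free text
      m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) {
        stop(sprintf("malformed header at line %d: %s", i, ln), call. = FALSE)
      }
      key <- tolower(trimws(m[2])); val <- trimws(m[3])
      if (key == "subject") meta$subject_id <- val
      if (key == "placement") meta$placement <- val
      if (key == "visit") meta$visit <- val
      if (key == "start time") meta$start_time <- val
      if (key == "epoch length (s)") {
        el <- suppressWarnings(as.integer(val))
        if (is.na(el)) {
          stop(sprintf("malformed header at line %d: bad epoch length '%s'",
                       i, val), call. = FALSE)
        }
        meta$epoch_length <- el
      }
    }
    skip <- sep
  }
  df <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE,
                        check.names = TRUE)
  need <- c("Axis1", "Axis2", "Axis3", "Steps")
  if (!all(need %in% names(df))) {
    stop("epoch CSV must contain columns Axis1, Axis2, Axis3, Steps",
         call. = FALSE)
  }
  n <- nrow(df)
  if (all(c("Date", "Time") %in% names(df)) && n > 0) {
    tm <- as.POSIXct(paste(df$Date, df$Time), tz = "UTC",
                     format = "%Y-%m-%d %H:%M:%S")
    if (anyNA(tm)) stop("unparseable Date/Time values in ", path, call. = FALSE)
  } else {
    if (is.na(meta$start_time)) {
      stop("no Date/Time columns and no header start time to reconstruct from",
           call. = FALSE)
    }
    t0 <- as.POSIXct(meta$start_time, tz = "UTC")
    tm <- t0 + (seq_len(n) - 1L) * meta$epoch_length
  }
  epoch_series(
    time = tm, axis1 = df$Axis1, axis2 = df$Axis2, axis3 = df$Axis3,
    steps = df$Steps, subject_id = meta$subject_id,
    placement = meta$placement, visit = meta$visit,
    epoch_length = meta$epoch_length
  )
}

#' Write an epoch-count CSV export
#'
#' Inverse of [read_epoch_csv()]; the round trip is bit-exact on counts and
#' second-exact on timestamps.
#'
#' @param series an [epoch_series()].
#' @param path output file path.
#' @param serial device serial string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path, serial = "SYN-0000") {
  validate_epoch_series(series)
  start <- if (length(series) > 0) {
    format(series$time[1], "%Y-%m-%d %H:%M:%S")
  } else ""
  hdr <- c(
    "Epoch count export",
    paste0("Subject: ", series$subject_id),
    paste0("Placement: ", series$placement),
    paste0("Visit: ", series$visit),
    paste0("Start Time: ", start),
    paste0("Epoch Length (s): ", series$epoch_length),
    paste0("Serial: ", serial),
    "------"
  )
  df <- data.frame(
    Date = format(series$time, "%Y-%m-%d"),
    Time = format(series$time, "%H:%M:%S"),
    Axis1 = series$axis1, Axis2 = series$axis2, Axis3 = series$axis3,
    Steps = series$steps
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wear diary table
#'
#' Diary CSV with columns `subject_id, date, on_time, off_time`: one row
#' per worn interval as reported by the participant. Free-text note
#' columns are ignored. Intervals are validated to be positive-length and
#' non-overlapping within a subject.
#'
#' @param path diary CSV path.
#' @return data.frame of class `diary_log` with `subject_id`, `on`, `off`
#'   (POSIXct interval bounds).
#' @export
read_diary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "date", "on_time", "off_time")
  if (!all(need %in% names(df))) {
    stop("diary CSV must contain columns subject_id, date, on_time, off_time",
         call. = FALSE)
  }
  on <- as.POSIXct(paste(df$date, df$on_time), tz = "UTC",
                   format = "%Y-%m-%d %H:%M:%S")
  off <- as.POSIXct(paste(df$date, df$off_time), tz = "UTC",
                    format = "%Y-%m-%d %H:%M:%S")
  if (anyNA(on) || anyNA(off)) stop("unparseable diary timestamps", call. = FALSE)
  if (any(off <= on)) stop("diary intervals must have off_time > on_time",
                           call. = FALSE)
  out <- data.frame(subject_id = as.character(df$subject_id), on = on, off = off)
  out <- out[order(out$subject_id, out$on), ]
  for (sid in unique(out$subject_id)) {
    d <- out[out$subject_id == sid, ]
    if (nrow(d) > 1 && any(d$on[-1] < d$off[-nrow(d)])) {
      stop("overlapping diary intervals for subject ", sid, call. = FALSE)
    }
  }
  class(out) <- c("diary_log", "data.frame")
  out
}

#' Write a wear diary table
#'
#' @param diary a `diary_log` data.frame (see [read_diary_csv()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(diary, path) {
  df <- data.frame(
    subject_id = diary$subject_id,
    date = format(diary$on, "%Y-%m-%d"),
    on_time = format(diary$on, "%H:%M:%S"),
    off_time = format(diary$off, "%H:%M:%S")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Columns of the clinical table; score columns may be missing (NA), never
# imputed.
clinical_columns <- c(
  "subject_id", "visit", "group", "sex", "age", "bmi",
  "sara", "sara_gait", "mfars", "fars_e", "adl", "ccfs", "t8mwt",
  "gaa1", "gaa2", "age_at_onset", "disease_duration"
)

#' Read the clinical table
#'
#' One row per subject x visit with group membership, demographics and
#' clinical scores (SARA total and gait sub-score, mFARS, FARS part E, ADL,
#' CCFS, 8-m walk time, GAA repeat sizes, onset and duration). Missing
#' scores are carried as `NA` and never imputed.
#'
#' @param path clinical CSV path.
#' @return typed data.frame with one row per subject x visit.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "group")
  if (!all(need %in% names(df))) {
    stop("clinical CSV must contain columns subject_id, visit, group",
         call. = FALSE)
  }
  bad <- setdiff(unique(df$group), c("FRDA", "CTR"))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$visit), c("baseline", "followup"))
  if (length(bad) > 0) {
    stop("unknown visit label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$subject_id, df$visit)
  if (anyDuplicated(key)) {
    stop("duplicated subject x visit row(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(clinical_columns, c("subject_id", "visit", "group", "sex"))) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Write the clinical table
#'
#' @param clinical data.frame as returned by [read_clinical_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
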