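#' Parameters of the Choi non-wear classification
#'
#' Defaults are the published values: a non-wear period is at least 90
#' consecutive minutes of zero counts, in which artifactual movement
#' spikes of at most 2 minutes are tolerated provided each spike is
#' flanked on both sides by at least 30 minutes of zero counts.
#'
#' @param min_nonwear_window minimal non-wear run length, minutes.
#' @param spike_tolerance maximal length of a tolerated nonzero spike,
#'   minutes.
#' @param spike_flank_window minimal zero-count flank on each side of a
#'   tolerated spike, minutes.
#' @param axis `"axis1"` (vertical, default) or `"vector_magnitude"`.
#' @return list of class `choi_params`.
#' @export
choi_params <- function(min_nonwear_window = 90, spike_tolerance = 2,
                        spike_flank_window = 30, axis = c("axis1", "vector_magnitude")) {
  axis <- match.arg(axis)
  stopifnot(min_nonwear_window > 0, spike_tolerance > 0, spike_flank_window > 0,
            spike_tolerance < min_nonwear_window)
  structure(list(min_nonwear_window = min_nonwear_window,
                 spike_tolerance = spike_tolerance,
                 spike_flank_window = spike_flank_window, axis = axis),
            class = "choi_params")
}

#' Choi non-wear detection
#'
#' Flags each 60-s epoch as wear or non-wear. An epoch is non-wear iff it
#' lies in a maximal run of zero-count epochs (on the chosen axis) of
#' total length at least `min_nonwear_window` minutes, where nonzero
#' spikes of at most `spike_tolerance` consecutive minutes are absorbed
#' into the run when each spike is immediately flanked on both sides by at
#' least `spike_flank_window` minutes of zeros. The absorbed spike epochs
#' themselves are flagged non-wear. Runs are evaluated over the recording
#' as ordered (a non-wear run may span midnight).
#'
#' @param series an [epoch_series()] at 60-s epochs.
#' @param params a [choi_params()] object.
#' @return the series with a logical `wear` field set.
#' @export
detect_nonwear_choi <- function(series, params = choi_params()) {
  validate_epoch_series(series)
  if (series$epoch_length != 60L) {
    stop("Choi detection requires 60-s epochs; aggregate first", call. = FALSE)
  }
  counts <- if (params$axis == "axis1") series$axis1 else
    sqrt(series$axis1^2 + series$axis2^2 + series$axis3^2)
  n <- length(counts)
  if (n < params$min_nonwear_window) {
    warning("series shorter than one non-wear window; all epochs kept as wear")
    series$wear <- rep(TRUE, n)
    return(series)
  }
  z <- counts == 0
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$lengths)
  # absorb tolerated spikes: short nonzero runs with long zero flanks
  zero_like <- z
  if (k >= 3) {
    for (i in 2:(k - 1)) {
      if (!r$values[i] && r$lengths[i] <= params$spike_tolerance &&
          r$lengths[i - 1] >= params$spike_flank_window &&
          r$lengths[i + 1] >= params$spike_flank_window) {
        zero_like[starts[i]:ends[i]] <- TRUE
      }
    }
  }
  r2 <- rle(zero_like)
  nonwear <- inverse.rle(list(
    lengths = r2$lengths,
    values = r2$values & r2$lengths >= params$min_nonwear_window
  ))
  series$wear <- !nonwear
  series
}

#' Reconcile wear flags with the participant diary
#'
#' Epochs outside the diary's worn intervals for the series' subject are
#' forced to non-wear; epochs inside keep their algorithmic flags. The
#' diary can only remove wear time, never add it, so the correction is
#' idempotent and monotone. An absent diary (or one with no rows for the
#' subject) leaves the flags unchanged.
#'
#' @param series an [epoch_series()] with wear flags.
#' @param diary a `diary_log` (see [read_diary_csv()]) or `NULL`.
#' @return the series with corrected wear flags.
#' @export
apply_diary_correction <- function(series, diary = NULL) {
  if (is.null(series$wear)) stop("run detect_nonwear_choi first", call. = FALSE)
  if (is.null(diary)) return(series)
  d <- diary[diary$subject_id == series$subject_id, , drop = FALSE]
  if (nrow(d) == 0) return(series)
  t <- as.numeric(series$time)
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(d))) {
    inside <- inside | (t >= as.numeric(d$on[i]) & t < as.numeric(d$off[i]))
  }
  series$wear <- series$wear & inside
  series
}

# Integer calendar-day key (local wall clock is carried as UTC, so the
# day boundary is plain integer division).
day_key <- function(time) floor(as.numeric(time) / 86400)

#' Valid wear days
#'
#' Cuts the wear flags by calendar day and marks each day valid iff its
#' total wear time reaches `min_wear_hours` (inclusive). Days below the
#' threshold are excluded from every downstream activity measure.
#'
#' @param series an [epoch_series()] with wear flags.
#' @param min_wear_hours minimal wear time for a valid day, hours.
#' @return data.frame of class `wear_day_set` with columns `date`,
#'   `wear_minutes`, `valid`.
#' @export
valid_wear_days <- function(series, min_wear_hours = 8) {
  if (is.null(series$wear)) stop("run detect_nonwear_choi first", call. = FALSE)
  key <- day_key(series$time)
  wm <- rowsum(series$wear * series$epoch_length / 60, key)
  keys <- as.numeric(rownames(wm))
  out <- data.frame(date = format(as.Date(keys, origin = "1970-01-01")),
                    wear_minutes = as.numeric(wm),
                    valid = as.numeric(wm) >= min_wear_hours * 60,
                    row.names = NULL)
  class(out) <- c("wear_day_set", "data.frame")
  out
}

# Logical mask of epochs that enter the activity measures: wear epochs on
# valid days.
analysis_mask <- function(series, min_wear_hours = 8) {
  if (is.null(series$wear)) stop("run detect_nonwear_choi first", call. = FALSE)
  key <- day_key(series$time)
  wm <- rowsum(series$wear * series$epoch_length / 60, key)
  ok <- as.numeric(rownames(wm))[as.numeric(wm) >= min_wear_hours * 60]
  series$wear & (key %in% ok)
}
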