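#' Epoch-level activity count series
#'
#' Container for one subject x placement x visit recording of fixed-length
#' epochs exported from a triaxial accelerometer. Axis 1 is the vertical
#' axis; all counts are non-negative integers per epoch. Timestamps are
#' local wall-clock times on the epoch grid; overnight gaps are allowed
#' (waking-hours protocols export no records outside the worn window), but
#' every gap must be a whole number of epochs.
#'
#' @param time POSIXct epoch start times, strictly increasing, aligned to
#'   the epoch grid.
#' @param axis1,axis2,axis3 integer activity counts per epoch (axis1 =
#'   vertical).
#' @param steps integer step counts per epoch (device-computed).
#' @param subject_id opaque subject identifier.
#' @param placement `"waist"` or `"wrist"`.
#' @param visit `"baseline"` or `"followup"`.
#' @param epoch_length epoch duration in seconds; must divide 60 or be a
#'   multiple of 60.
#' @param wear optional logical wear flag per epoch (set by
#'   [detect_nonwear_choi()]).
#' @return An object of class `epoch_series`.
#' @seealso [read_epoch_csv()], [aggregate_epochs()], [detect_nonwear_choi()]
#' @export
epoch_series <- function(time, axis1, axis2 = NULL, axis3 = NULL,
                         steps = NULL, subject_id = "unknown",
                         placement = c("waist", "wrist"),
                         visit = c("baseline", "followup"),
                         epoch_length = 60L, wear = NULL) {
  placement <- match.arg(placement)
  visit <- match.arg(visit)
  n <- length(axis1)
  if (is.null(axis2)) axis2 <- integer(n)
  if (is.null(axis3)) axis3 <- integer(n)
  if (is.null(steps)) steps <- integer(n)
  x <- structure(list(
    subject_id = as.character(subject_id),
    placement = placement,
    visit = visit,
    epoch_length = as.integer(epoch_length),
    time = as.POSIXct(time, tz = "UTC"),
    axis1 = as.numeric(axis1),
    axis2 = as.numeric(axis2),
    axis3 = as.numeric(axis3),
    steps = as.numeric(steps),
    wear = wear
  ), class = "epoch_series")
  validate_epoch_series(x)
}

#' Validate an epoch series
#'
#' Checks the structural invariants: equal array lengths, non-negative
#' integral counts, an admissible epoch length, and timestamps that are
#' strictly increasing whole-epoch multiples apart.
#'
#' @param x an `epoch_series`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_epoch_series <- function(x) {
  stopifnot(inherits(x, "epoch_series"))
  n <- length(x$axis1)
  lens <- c(length(x$time), length(x$axis2), length(x$axis3), length(x$steps))
  if (any(lens != n)) {
    stop("epoch_series arrays must have equal length", call. = FALSE)
  }
  el <- x$epoch_length
  if (!(el >= 1 && (60 %% el == 0 || el %% 60 == 0))) {
    stop("epoch_length must divide 60 s or be a multiple of 60 s", call. = FALSE)
  }
  for (f in c("axis1", "axis2", "axis3", "steps")) {
    v <- x[[f]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != floor(v))) {
      stop(sprintf("%s counts must be non-negative integers", f), call. = FALSE)
    }
  }
  if (n > 1) {
    d <- as.numeric(diff(x$time), units = "secs")
    if (any(d <= 0) || any(d %% el != 0)) {
      stop("timestamps must be strictly increasing on the epoch grid",
           call. = FALSE)
    }
  }
  if (!is.null(x$wear) && length(x$wear) != n) {
    stop("wear flags must match series length", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> %s / %s / %s: %d epochs of %ds, start %s\n",
    x$subject_id, x$placement, x$visit, length(x$axis1), x$epoch_length,
    format(x$time[1], "%Y-%m-%d %H:%M:%S")
  ))
  if (!is.null(x$wear)) {
    cat(sprintf("  wear flags: %d/%d wear\n", sum(x$wear), length(x$wear)))
  }
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$axis1)

#' Aggregate epochs to a longer epoch length
#'
#' Sums counts and steps within consecutive windows so that, e.g., 1-s
#' exports are summarized into the 60-s analysis epochs. Totals are
#' conserved exactly. The series must be contiguous (no gaps) and its
#' length a whole number of target windows.
#'
#' @param series an `epoch_series`.
#' @param target_epoch_length target epoch length in seconds; must be an
#'   integer multiple of `series$epoch_length`.
#' @return An `epoch_series` at the target epoch length.
#' @examples
#' s <- epoch_series(as.POSIXct("2022-03-07 08:00:00", tz = "UTC") +
#'                     seq(0, 119), rep(1, 120), epoch_length = 1)
#' aggregate_epochs(s, 60)$axis1  # 60 60
#' @export
aggregate_epochs <- function(series, target_epoch_length) {
  validate_epoch_series(series)
  el <- series$epoch_length
  tl <- as.integer(target_epoch_length)
  if (tl %% el != 0) {
    stop("target_epoch_length must be an integer multiple of the source epoch length",
         call. = FALSE)
  }
  r <- tl %/% el
  if (r == 1L) return(series)
  n <- length(series)
  if (n %% r != 0) {
    stop("series length is not a whole number of target windows", call. = FALSE)
  }
  if (n > 1) {
    d <- as.numeric(diff(series$time), units = "secs")
    if (any(d != el)) {
      stop("series must be contiguous for aggregation", call. = FALSE)
    }
  }
  grp <- rep(seq_len(n %/% r), each = r)
  wsum <- function(v) as.numeric(rowsum(v, grp))
  epoch_series(
    time = series$time[seq(1, n, by = r)],
    axis1 = wsum(series$axis1), axis2 = wsum(series$axis2),
    axis3 = wsum(series$axis3), steps = wsum(series$steps),
    subject_id = series$subject_id, placement = series$placement,
    visit = series$visit, epoch_length = tl
  )
}

#' Counts per minute on a chosen axis
#'
#' Rescales per-epoch counts to a per-minute rate. At the default 60-s
#' epoch the counts already are CPM.
#'
#' @param series an `epoch_series`.
#' @param axis one of `"axis1"`, `"axis2"`, `"axis3"`.
#' @return numeric vector of CPM, one value per epoch.
#' @export
epoch_cpm <- function(series, axis = "axis1") {
  series[[match.arg(axis, c("axis1", "axis2", "axis3"))]] *
    (60 / series$epoch_length)
}
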