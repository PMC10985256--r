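# Build a contiguous 60-s epoch series starting on a Monday morning.
make_series <- function(axis1, axis2 = NULL, axis3 = NULL, steps = NULL,
                        start = "2022-03-07 08:00:00", wear = NULL,
                        subject_id = "T001", placement = "waist",
                        visit = "baseline", epoch_length = 60L) {
  n <- length(axis1)
  s <- epoch_series(
    time = as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * epoch_length,
    axis1 = axis1, axis2 = axis2, axis3 = axis3, steps = steps,
    subject_id = subject_id, placement = placement, visit = visit,
    epoch_length = epoch_length
  )
  s$wear <- wear
  s
}

# A series of full wear days: one day per element of `day_axis1`, each a
# vector of 1440 (or fewer) per-minute counts placed from midnight.
make_week <- function(day_axis1, steps = NULL, start_date = "2022-03-07",
                      wear = TRUE, subject_id = "T001", ...) {
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  time <- c(); a1 <- c(); sp <- c()
  for (d in seq_along(day_axis1)) {
    v <- day_axis1[[d]]
    time <- c(time, as.numeric(t0) + (d - 1) * 86400 + (seq_along(v) - 1) * 60)
    a1 <- c(a1, v)
    sp <- c(sp, if (is.null(steps)) rep(0, length(v)) else steps[[d]])
  }
  s <- epoch_series(time = as.POSIXct(time, tz = "UTC",
                                      origin = "1970-01-01"),
                    axis1 = a1, steps = sp, subject_id = subject_id, ...)
  if (isTRUE(wear)) s$wear <- rep(TRUE, length(a1))
  s
}
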