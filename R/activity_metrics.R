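#' Intensity cut-points on the vertical axis
#'
#' CPM thresholds partitioning epochs into sedentary, light, moderate and
#' vigorous intensity. Defaults are the Freedson adult vertical-axis
#' values: sedentary 0-99 CPM, light 100-1951, moderate 1952-5724,
#' vigorous 5725 and above. The same scheme is applied at both placements;
#' wrist values are interpreted per placement and never pooled with waist.
#'
#' @param sedentary_max,light_max,moderate_max upper bin edges in CPM
#'   (inclusive); must be strictly increasing.
#' @return list of class `cut_points`.
#' @export
cut_points <- function(sedentary_max = 99, light_max = 1951,
                       moderate_max = 5724) {
  stopifnot(sedentary_max < light_max, light_max < moderate_max)
  structure(list(sedentary_max = sedentary_max, light_max = light_max,
                 moderate_max = moderate_max), class = "cut_points")
}

intensity_levels <- c("sedentary", "light", "moderate", "vigorous")

#' Classify epoch intensity from vertical-axis CPM
#'
#' Half-open bins: `[0, sedentary_max]`, `(sedentary_max, light_max]`,
#' `(light_max, moderate_max]`, `(moderate_max, Inf)`.
#'
#' @param cpm numeric vector of vertical-axis counts per minute.
#' @param cutpoints a [cut_points()] object.
#' @return factor with levels sedentary, light, moderate, vigorous.
#' @examples
#' classify_intensity(c(0, 99, 100, 1952, 6000), cut_points())
#' @export
classify_intensity <- function(cpm, cutpoints = cut_points()) {
  stopifnot(all(cpm >= 0))
  cut(cpm,
      breaks = c(-Inf, cutpoints$sedentary_max, cutpoints$light_max,
                 cutpoints$moderate_max, Inf),
      labels = intensity_levels)
}

#' Percentage of wear time by intensity class
#'
#' Percentages of wear epochs on valid days spent in sedentary, light and
#' moderate-to-vigorous (MVPA) activity; moderate and vigorous are pooled.
#' The three percentages sum to 100 exactly.
#'
#' @param series an [epoch_series()] with wear flags.
#' @param cutpoints a [cut_points()] object.
#' @param min_wear_hours valid-day threshold passed to [valid_wear_days()].
#' @return named numeric vector `pct_sedentary`, `pct_light`, `pct_mvpa`.
#' @export
activity_percentages <- function(series, cutpoints = cut_points(),
                                 min_wear_hours = 8) {
  m <- analysis_mask(series, min_wear_hours)
  if (!any(m)) {
    return(c(pct_sedentary = NA_real_, pct_light = NA_real_, pct_mvpa = NA_real_))
  }
  lev <- classify_intensity(epoch_cpm(series)[m], cutpoints)
  tab <- table(lev)
  n <- sum(tab)
  c(pct_sedentary = 100 * tab[["sedentary"]] / n,
    pct_light = 100 * tab[["light"]] / n,
    pct_mvpa = 100 * (tab[["moderate"]] + tab[["vigorous"]]) / n)
}

#' Mean triaxial vector magnitude (VM3)
#'
#' Mean over wear epochs of valid days of the per-epoch Euclidean norm of
#' the three axis CPM values. A raw measure: no cut-points, no model.
#'
#' @inheritParams activity_percentages
#' @return mean VM3 in CPM.
#' @export
vm3_mean <- function(series, min_wear_hours = 8) {
  m <- analysis_mask(series, min_wear_hours)
  if (!any(m)) return(NA_real_)
  f <- 60 / series$epoch_length
  mean(sqrt((series$axis1[m] * f)^2 + (series$axis2[m] * f)^2 +
              (series$axis3[m] * f)^2))
}

#' MET rate
#'
#' Energy expenditure in metabolic equivalents (1 MET = 3.5 mL O2/kg/min,
#' resting). Each wear epoch above the light/moderate cut-point is scored
#' with the Freedson regression `1.439008 + 0.000795 x CPM`; epochs at or
#' below it are scored at the 1.0 MET resting floor. The summary is the
#' mean over wear epochs of valid days, so it is bounded below by 1.
#'
#' @inheritParams activity_percentages
#' @param met_intercept,met_slope coefficients of the CPM-to-MET
#'   regression applied above `light_max`.
#' @return mean METs per wear epoch.
#' @export
met_rate <- function(series, cutpoints = cut_points(), min_wear_hours = 8,
                     met_intercept = 1.439008, met_slope = 0.000795) {
  m <- analysis_mask(series, min_wear_hours)
  if (!any(m)) return(NA_real_)
  cpm <- epoch_cpm(series)[m]
  mets <- ifelse(cpm > cutpoints$light_max, met_intercept + met_slope * cpm, 1)
  mean(mets)
}

#' Count moderate-to-vigorous activity bouts
#'
#' A bout is a maximal run of consecutive wear epochs (valid days) at
#' moderate-or-vigorous intensity lasting at least `min_duration` minutes;
#' each maximal run is counted once. With `drop_tolerance > 0` (the
#' ActiLife drop-time convention) up to that many sub-threshold minutes in
#' total are absorbed into a bout without splitting it; absorbed minutes
#' count toward the bout duration. Non-wear or invalid-day epochs always
#' break a bout.
#'
#' @inheritParams activity_percentages
#' @param min_duration minimal bout length, minutes.
#' @param drop_tolerance sub-threshold minutes absorbed per bout.
#' @return integer bout count.
#' @export
count_bouts <- function(series, cutpoints = cut_points(), min_duration = 10,
                        drop_tolerance = 0, min_wear_hours = 8) {
  if (series$epoch_length != 60L) {
    stop("bout counting requires 60-s epochs", call. = FALSE)
  }
  m <- analysis_mask(series, min_wear_hours)
  mvpa <- epoch_cpm(series) > cutpoints$light_max
  n <- length(m)
  if (n == 0) return(0L)
  # a recording gap (missing epochs, e.g. overnight) always breaks a bout
  seg <- cumsum(c(1L, as.numeric(diff(series$time), units = "secs") !=
                    series$epoch_length))
  n_bouts <- 0L
  for (sid in unique(seg)) {
    idx <- which(seg == sid)
    v <- m[idx] & mvpa[idx]
    if (drop_tolerance == 0) {
      r <- rle(v)
      n_bouts <- n_bouts + sum(r$values & r$lengths >= min_duration)
      next
    }
    keep <- m[idx]
    i <- 1L
    nn <- length(v)
    while (i <= nn) {
      if (v[i]) {
        # extend a candidate bout, absorbing up to drop_tolerance
        # sub-threshold minutes (never at the ends, never across non-wear)
        len <- 0L; drops <- 0L; pending_gap <- 0L
        j <- i
        while (j <= nn && keep[j]) {
          if (v[j]) {
            len <- len + 1L + pending_gap
            drops <- drops + pending_gap
            pending_gap <- 0L
          } else {
            pending_gap <- pending_gap + 1L
            if (drops + pending_gap > drop_tolerance) break
          }
          j <- j + 1L
        }
        if (len >= min_duration) n_bouts <- n_bouts + 1L
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  n_bouts
}

#' Average steps per wear minute
#'
#' Total device-reported steps over wear epochs of valid days divided by
#' total wear minutes. Steps are consumed as an input column; no step
#' detection is attempted from counts.
#'
#' @inheritParams activity_percentages
#' @return steps per minute.
#' @export
steps_per_minute <- function(series, min_wear_hours = 8) {
  m <- analysis_mask(series, min_wear_hours)
  if (!any(m)) return(NA_real_)
  sum(series$steps[m]) / (sum(m) * series$epoch_length / 60)
}

#' Summarize the seven digital activity measures for one recording
#'
#' Computes MET rate, bout count, the three intensity percentages, mean
#' VM3 and steps/min from a single shared wear mask (wear epochs of valid
#' days), together with wear bookkeeping. Recordings with no valid wear
#' day yield `wear_days = 0` and `NA` measures; such recordings are
#' excluded from cohort analyses.
#'
#' @inheritParams count_bouts
#' @return list of class `activity_summary` with fields `met_rate`,
#'   `n_bouts`, `pct_sedentary`, `pct_light`, `pct_mvpa`, `vm3`,
#'   `steps_per_min`, `wear_days`, `wear_minutes`.
#' @export
summarize_subject <- function(series, cutpoints = cut_points(),
                              min_duration = 10, drop_tolerance = 0,
                              min_wear_hours = 8) {
  if (is.null(series$wear)) stop("run detect_nonwear_choi first", call. = FALSE)
  days <- valid_wear_days(series, min_wear_hours)
  m <- analysis_mask(series, min_wear_hours)  # single shared wear mask
  f <- 60 / series$epoch_length
  if (!any(m)) {
    out <- list(subject_id = series$subject_id, placement = series$placement,
                visit = series$visit, met_rate = NA_real_,
                n_bouts = NA_integer_, pct_sedentary = NA_real_,
                pct_light = NA_real_, pct_mvpa = NA_real_, vm3 = NA_real_,
                steps_per_min = NA_real_, wear_days = 0L, wear_minutes = 0)
    class(out) <- "activity_summary"
    return(out)
  }
  cpm <- series$axis1[m] * f
  nsed <- sum(cpm <= cutpoints$sedentary_max)
  nlight <- sum(cpm > cutpoints$sedentary_max & cpm <= cutpoints$light_max)
  nmvpa <- sum(cpm > cutpoints$light_max)
  nw <- length(cpm)
  out <- list(
    subject_id = series$subject_id, placement = series$placement,
    visit = series$visit,
    met_rate = mean(ifelse(cpm > cutpoints$light_max,
                           1.439008 + 0.000795 * cpm, 1)),
    n_bouts = count_bouts(series, cutpoints, min_duration, drop_tolerance,
                          min_wear_hours),
    pct_sedentary = 100 * nsed / nw,
    pct_light = 100 * nlight / nw,
    pct_mvpa = 100 * nmvpa / nw,
    vm3 = mean(sqrt((series$axis1[m] * f)^2 + (series$axis2[m] * f)^2 +
                      (series$axis3[m] * f)^2)),
    steps_per_min = sum(series$steps[m]) / (nw * series$epoch_length / 60),
    wear_days = sum(days$valid),
    wear_minutes = sum(days$wear_minutes[days$valid])
  )
  class(out) <- "activity_summary"
  out
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("<activity_summary> %s / %s / %s (%d valid days, %.0f wear min)\n",
              x$subject_id, x$placement, x$visit, x$wear_days, x$wear_minutes))
  cat(sprintf("  MET %.3f | bouts %s | sed %.1f%% light %.1f%% MVPA %.1f%% | VM3 %.1f | steps/min %.2f\n",
              x$met_rate, format(x$n_bouts), x$pct_sedentary, x$pct_light,
              x$pct_mvpa, x$vm3, x$steps_per_min))
  invisible(x)
}

#' @export
as.data.frame.activity_summary <- function(x, ...) {
  data.frame(subject_id = x$subject_id, placement = x$placement,
             visit = x$visit, met_rate = x$met_rate,
             n_bouts = x$n_bouts, pct_sedentary = x$pct_sedentary,
             pct_light = x$pct_light, pct_mvpa = x$pct_mvpa, vm3 = x$vm3,
             steps_per_min = x$steps_per_min, wear_days = x$wear_days,
             wear_minutes = x$wear_minutes)
}

activity_measures <- c("met_rate", "n_bouts", "pct_sedentary", "pct_light",
                       "pct_mvpa", "vm3", "steps_per_min")
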