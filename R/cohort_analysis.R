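#' Wear-process one recording
#'
#' Choi non-wear detection followed by diary reconciliation: the standard
#' preprocessing applied to every recording before any activity measure.
#'
#' @param series an [epoch_series()].
#' @param diary a `diary_log` or `NULL`.
#' @param choi a [choi_params()] object.
#' @return the series with wear flags set.
#' @export
process_series <- function(series, diary = NULL, choi = choi_params()) {
  apply_diary_correction(detect_nonwear_choi(series, choi), diary)
}

#' Summarize every recording of a cohort
#'
#' Runs wear processing and [summarize_subject()] on each series and
#' returns one row per subject x placement x visit. Recordings without a
#' valid wear day are kept with `wear_days = 0` and `NA` measures so the
#' caller can report exclusions; cohort statistics drop them.
#'
#' @param cohort a [simulate_cohort()] result, or a named list of
#'   [epoch_series()].
#' @param diary optional `diary_log` (taken from the cohort if present).
#' @param choi [choi_params()].
#' @param cutpoints [cut_points()].
#' @param min_duration,drop_tolerance bout parameters.
#' @param min_wear_hours valid-day threshold, hours.
#' @return data.frame with identity columns, the seven measures and wear
#'   bookkeeping.
#' @export
summarize_cohort <- function(cohort, diary = NULL, choi = choi_params(),
                             cutpoints = cut_points(), min_duration = 10,
                             drop_tolerance = 0, min_wear_hours = 8) {
  if (inherits(cohort, "synthetic_cohort")) {
    if (is.null(diary)) diary <- cohort$diary
    cohort <- cohort$series
  }
  rows <- lapply(cohort, function(s) {
    s <- process_series(s, diary, choi)
    as.data.frame(summarize_subject(s, cutpoints, min_duration,
                                    drop_tolerance, min_wear_hours))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline patient-vs-control comparison of every measure
#'
#' Applies [compare_groups()] to each digital measure at each placement at
#' baseline and Bonferroni-adjusts with one family slot per measure
#' (waist and wrist pooled, default family size 7).
#'
#' @param summaries output of [summarize_cohort()].
#' @param clinical clinical table with `subject_id` and `group`.
#' @param n_families Bonferroni family size.
#' @return data.frame with `measure`, `placement`, group means, `test`,
#'   `p`, `p_adj`.
#' @export
baseline_group_tests <- function(summaries, clinical, n_families = 7) {
  base <- summaries[summaries$visit == "baseline" & summaries$wear_days > 0, ]
  grp <- clinical$group[match(base$subject_id, clinical$subject_id)]
  out <- expand.grid(measure = activity_measures,
                     placement = c("waist", "wrist"),
                     stringsAsFactors = FALSE)
  out$mean_frda <- out$mean_ctr <- NA_real_
  out$test <- NA_character_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- base$placement == out$placement[i]
    v <- base[[out$measure[i]]][sel]
    g <- grp[sel]
    out$mean_frda[i] <- mean(v[g == "FRDA"], na.rm = TRUE)
    out$mean_ctr[i] <- mean(v[g == "CTR"], na.rm = TRUE)
    if (sum(g == "FRDA") >= 3 && sum(g == "CTR") >= 3) {
      cg <- compare_groups(v[g == "FRDA"], v[g == "CTR"])
      out$test[i] <- cg$test
      out$p[i] <- cg$p
    }
  }
  out$p_adj <- bonferroni(out$p, n_families)
  out
}

#' Correlate digital measures with clinical severity (patients, baseline)
#'
#' Spearman rank correlation of the baseline digital measures at one
#' placement against the clinical scores of the patient group.
#'
#' @param summaries output of [summarize_cohort()].
#' @param clinical clinical table.
#' @param placement `"waist"` or `"wrist"`.
#' @param scores clinical columns to correlate.
#' @return long data.frame from [spearman_matrix()].
#' @export
clinical_correlations <- function(summaries, clinical,
                                  placement = "waist",
                                  scores = c("sara", "mfars", "adl", "ccfs",
                                             "disease_duration")) {
  base <- summaries[summaries$visit == "baseline" &
                      summaries$placement == placement &
                      summaries$wear_days > 0, ]
  cl <- clinical[clinical$visit == "baseline" & clinical$group == "FRDA", ]
  cl <- cl[match(base$subject_id, cl$subject_id), , drop = FALSE]
  keep <- !is.na(cl$subject_id)
  spearman_matrix(cl[keep, intersect(scores, names(cl)), drop = FALSE],
                  base[keep, activity_measures])
}

#' Longitudinal change, responsiveness and trial sizing per measure
#'
#' Pairs baseline and follow-up summaries within subject for one group,
#' runs [paired_change_test()] on each measure x placement, and derives
#' SRM and per-arm sample size where the change variance is nonzero.
#'
#' @param summaries output of [summarize_cohort()].
#' @param clinical clinical table.
#' @param group group to analyze (patients by default).
#' @param n_families Bonferroni family size for the change p-values.
#' @param delta trial effect fraction passed to [sample_size_from_srm()].
#' @return data.frame with `measure`, `placement`, `mean_change`,
#'   `sd_change`, `test`, `p`, `p_adj`, `srm`, `n_per_arm`, `n`.
#' @export
longitudinal_analysis <- function(summaries, clinical, group = "FRDA",
                                  n_families = 7, delta = 1) {
  ids <- unique(clinical$subject_id[clinical$group == group])
  out <- expand.grid(measure = activity_measures,
                     placement = c("waist", "wrist"),
                     stringsAsFactors = FALSE)
  for (col in c("mean_change", "sd_change", "p", "srm")) out[[col]] <- NA_real_
  out$test <- NA_character_; out$n_per_arm <- NA_integer_; out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    sel <- summaries$placement == out$placement[i] &
      summaries$subject_id %in% ids & summaries$wear_days > 0
    b <- summaries[sel & summaries$visit == "baseline", ]
    f <- summaries[sel & summaries$visit == "followup", ]
    common <- intersect(b$subject_id, f$subject_id)
    if (length(common) < 3) next
    bv <- b[[out$measure[i]]][match(common, b$subject_id)]
    fv <- f[[out$measure[i]]][match(common, f$subject_id)]
    pt <- paired_change_test(bv, fv)
    out$mean_change[i] <- pt$mean_change
    out$sd_change[i] <- pt$sd_change
    out$test[i] <- pt$test
    out$p[i] <- pt$p
    out$n[i] <- pt$n
    if (pt$sd_change > 0) {
      out$srm[i] <- srm(fv - bv)
      # a mean change of exactly 0 has no finite trial size
      if (out$srm[i] != 0) {
        out$n_per_arm[i] <- sample_size_from_srm(out$srm[i], delta = delta)
      }
    }
  }
  out$p_adj <- bonferroni(out$p, n_families)
  out
}

#' Odd/even split-half reliability per measure
#'
#' Splits each baseline recording into odd (Mon/Wed/Fri) and even
#' (Tue/Thu/Sat) valid days, summarizes each half, and estimates ICC(2,1),
#' SEM and MDC95 per measure x placement across subjects.
#'
#' @param cohort a `synthetic_cohort` or named list of wear-flagged series.
#' @param diary optional diary; `choi`, `cutpoints`, `min_wear_hours` as in
#'   [summarize_cohort()].
#' @param choi [choi_params()].
#' @param cutpoints [cut_points()].
#' @param min_wear_hours valid-day threshold.
#' @return data.frame with `measure`, `placement`, `icc`, `sem`, `mdc95`,
#'   `n`.
#' @export
reliability_analysis <- function(cohort, diary = NULL, choi = choi_params(),
                                 cutpoints = cut_points(),
                                 min_wear_hours = 8) {
  if (inherits(cohort, "synthetic_cohort")) {
    if (is.null(diary)) diary <- cohort$diary
    cohort <- cohort$series
  }
  cohort <- cohort[vapply(cohort, function(s) s$visit == "baseline", TRUE)]
  halves <- lapply(cohort, function(s) {
    s <- process_series(s, diary, choi)
    tryCatch(odd_even_split(s, cutpoints, min_wear_hours),
             error = function(e) NULL)
  })
  halves <- halves[!vapply(halves, is.null, TRUE)]
  out <- expand.grid(measure = activity_measures,
                     placement = c("waist", "wrist"),
                     stringsAsFactors = FALSE)
  out$icc <- out$sem <- out$mdc95 <- NA_real_; out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    pl <- vapply(halves, function(h) h$odd$placement, "") == out$placement[i]
    x <- vapply(halves[pl], function(h) h$odd[[out$measure[i]]], 0)
    y <- vapply(halves[pl], function(h) h$even[[out$measure[i]]], 0)
    r <- tryCatch(icc21(x, y), error = function(e) NULL)
    if (!is.null(r)) {
      out$icc[i] <- r$icc; out$sem[i] <- r$sem; out$mdc95[i] <- r$mdc95
      out$n[i] <- r$n_subjects
    }
  }
  out
}

#' Full cohort statistical report
#'
#' Bundles the baseline group tests, clinical correlations, longitudinal
#' responsiveness table and split-half reliability into one list, the
#' package-level analogue of the study's statistical battery.
#'
#' @param cohort a `synthetic_cohort` (or list of series) to analyze.
#' @param clinical clinical table (taken from the cohort if present).
#' @inheritParams summarize_cohort
#' @param n_families Bonferroni family size.
#' @param delta trial effect fraction.
#' @param reliability also compute the odd/even ICC table (the slowest
#'   block).
#' @return list of class `cohort_report` with elements `summaries`,
#'   `group_tests`, `correlations`, `longitudinal`, `reliability`.
#' @export
cohort_report <- function(cohort, clinical = NULL, choi = choi_params(),
                          cutpoints = cut_points(), min_duration = 10,
                          drop_tolerance = 0, min_wear_hours = 8,
                          n_families = 7, delta = 1, reliability = TRUE) {
  if (inherits(cohort, "synthetic_cohort") && is.null(clinical)) {
    clinical <- cohort$clinical
  }
  summaries <- summarize_cohort(cohort, choi = choi, cutpoints = cutpoints,
                                min_duration = min_duration,
                                drop_tolerance = drop_tolerance,
                                min_wear_hours = min_wear_hours)
  rel <- if (reliability) {
    reliability_analysis(cohort, choi = choi, cutpoints = cutpoints,
                         min_wear_hours = min_wear_hours)
  } else NULL
  structure(list(
    summaries = summaries,
    group_tests = baseline_group_tests(summaries, clinical, n_families),
    correlations = clinical_correlations(summaries, clinical),
    longitudinal = longitudinal_analysis(summaries, clinical,
                                         n_families = n_families,
                                         delta = delta),
    reliability = rel
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  %d recordings summarized\n", nrow(x$summaries)))
  sig <- sum(x$group_tests$p_adj < 0.05, na.rm = TRUE)
  cat(sprintf("  baseline group tests: %d/%d significant after Bonferroni\n",
              sig, sum(!is.na(x$group_tests$p_adj))))
  cat(sprintf("  longitudinal rows: %d; reliability rows: %s\n",
              nrow(x$longitudinal),
              if (is.null(x$reliability)) "skipped" else nrow(x$reliability)))
  invisible(x)
}
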