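# Shapiro-Wilk p-value with a defined answer for degenerate samples:
# constant or too-short samples cannot be declared normal, so they fall
# through to the rank-based branch.
shapiro_gate_p <- function(v) {
  if (length(v) < 3 || length(unique(v)) == 1) return(0)
  stats::shapiro.test(v)$p.value
}

#' Two-group comparison with a normality gate
#'
#' Runs Shapiro-Wilk on each group; if both groups look normal at
#' `normality_alpha` the groups are compared with Welch's t-test,
#' otherwise with the Mann-Whitney U test. Constant groups always take
#' the Mann-Whitney path. The returned object records which test ran.
#'
#' @param x,y numeric samples for the two groups (at least 3 values each).
#' @param normality_alpha significance level of the Shapiro-Wilk gate.
#' @return list with `test` (`"t"` or `"mann-whitney"`), `statistic`, `p`,
#'   and the two group sizes.
#' @export
compare_groups <- function(x, y, normality_alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    stop("compare_groups needs at least 3 values per group", call. = FALSE)
  }
  normal <- shapiro_gate_p(x) >= normality_alpha &&
    shapiro_gate_p(y) >= normality_alpha
  if (normal) {
    ht <- stats::t.test(x, y)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    test <- "mann-whitney"
  }
  p <- ht$p.value
  if (!is.finite(p)) p <- 1  # fully tied degenerate comparison
  list(test = test, statistic = unname(ht$statistic), p = p,
       n = c(length(x), length(y)))
}

#' Bonferroni correction over a family of unrelated measures
#'
#' Adjusts p-values for the number of distinct activity measures tested;
#' the waist and wrist versions of one measure share a single family slot,
#' so the default family size is 7 (MET rate, bouts, sedentary %, light %,
#' MVPA %, VM3, steps/min).
#'
#' @param p numeric vector of raw p-values.
#' @param n_families family size used as the multiplier.
#' @return adjusted p-values, capped at 1.
#' @examples
#' bonferroni(0.01)       # 0.07
#' bonferroni(0.2)        # 1
#' @export
bonferroni <- function(p, n_families = 7) {
  stopifnot(n_families >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, p * n_families)
}

#' Spearman correlation matrix between clinical scores and digital measures
#'
#' Rank correlation of every clinical column against every digital-measure
#' column, pairwise-complete. Ties are handled by the normal
#' approximation.
#'
#' @param clinical data.frame of clinical/demographic variables (rows =
#'   subjects).
#' @param digital data.frame of digital measures, same row order.
#' @return long data.frame with `clinical_var`, `digital_var`, `rho`, `p`,
#'   `n`.
#' @export
spearman_matrix <- function(clinical, digital) {
  stopifnot(nrow(clinical) == nrow(digital))
  out <- expand.grid(clinical_var = names(clinical),
                     digital_var = names(digital),
                     stringsAsFactors = FALSE)
  out$rho <- NA_real_; out$p <- NA_real_; out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    a <- clinical[[out$clinical_var[i]]]
    b <- digital[[out$digital_var[i]]]
    ok <- stats::complete.cases(a, b)
    out$n[i] <- sum(ok)
    if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
      ct <- suppressWarnings(
        stats::cor.test(a[ok], b[ok], method = "spearman", exact = FALSE))
      out$rho[i] <- unname(ct$estimate)
      out$p[i] <- ct$p.value
    }
  }
  out
}

#' Paired longitudinal change test
#'
#' Tests follow-up minus baseline within subject. The change scores pass
#' through the same Shapiro-Wilk gate as [compare_groups()]: normal-looking
#' changes take the paired t-test, otherwise the Wilcoxon signed-rank test
#' (also the tie-break when the gate is ambiguous, e.g. all-zero changes).
#' Subjects missing either visit are dropped.
#'
#' @param baseline,followup paired numeric vectors (same subjects, same
#'   order).
#' @param normality_alpha significance level of the Shapiro-Wilk gate.
#' @return list with `test`, `statistic`, `p`, `mean_change`, `sd_change`,
#'   `n`.
#' @export
paired_change_test <- function(baseline, followup, normality_alpha = 0.05) {
  ok <- stats::complete.cases(baseline, followup)
  b <- baseline[ok]; f <- followup[ok]
  if (length(b) < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  ch <- f - b
  res <- list(mean_change = mean(ch), sd_change = stats::sd(ch), n = length(ch))
  if (all(ch == 0)) {
    return(c(list(test = "wilcoxon", statistic = 0, p = 1), res))
  }
  if (shapiro_gate_p(ch) >= normality_alpha) {
    ht <- stats::t.test(f, b, paired = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(f, b, paired = TRUE, exact = FALSE))
    test <- "wilcoxon"
  }
  p <- ht$p.value
  if (!is.finite(p)) p <- 1
  c(list(test = test, statistic = unname(ht$statistic), p = p), res)
}

#' Split a recording into odd and even weekdays
#'
#' Partitions the valid wear days of one recording into odd weekdays
#' (Monday, Wednesday, Friday) and even weekdays (Tuesday, Thursday,
#' Saturday); Sundays are excluded. Each half is summarized independently
#' with the same wear mask restricted to its days, giving the split-half
#' design used for test-retest reliability.
#'
#' @param series an [epoch_series()] with wear flags.
#' @param cutpoints a [cut_points()] object.
#' @param min_wear_hours valid-day threshold.
#' @return list with `odd` and `even` [summarize_subject()] results.
#' @export
odd_even_split <- function(series, cutpoints = cut_points(),
                           min_wear_hours = 8) {
  days <- valid_wear_days(series, min_wear_hours)
  vdates <- days$date[days$valid]
  wd <- as.integer(format(as.Date(vdates), "%u"))  # 1 = Monday ... 7 = Sunday
  odd_dates <- vdates[wd %in% c(1, 3, 5)]
  even_dates <- vdates[wd %in% c(2, 4, 6)]
  if (length(odd_dates) == 0 || length(even_dates) == 0) {
    stop("odd/even split needs at least one valid day in each half",
         call. = FALSE)
  }
  restrict <- function(dates) {
    s <- series
    s$wear <- s$wear & (format(s$time, "%Y-%m-%d") %in% dates)
    summarize_subject(s, cutpoints, min_wear_hours = min_wear_hours)
  }
  list(odd = restrict(odd_dates), even = restrict(even_dates))
}

#' Test-retest intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from
#' the two-way ANOVA mean squares of an n-subjects x 2-splits table,
#' together with the standard error of measurement (SEM) and the minimal
#' detectable change at 95% confidence (MDC95). SEM uses the pooled SD of
#' all measurements and the ICC clipped at zero.
#'
#' @param x,y the two repeated measurements (e.g. odd-day and even-day
#'   summaries), one value per subject; at least 5 complete pairs.
#' @param split_label free-text label of the split design.
#' @return list of class `reliability_result`: `icc`, `sem`, `mdc95`,
#'   `n_subjects`, `split_label`.
#' @export
icc21 <- function(x, y, split_label = "odd-even days") {
  ok <- stats::complete.cases(x, y)
  M <- cbind(x[ok], y[ok])
  n <- nrow(M)
  if (n < 5) stop("ICC needs at least 5 complete pairs", call. = FALSE)
  if (stats::var(as.vector(M)) == 0) {
    stop("ICC undefined: zero total variance", call. = FALSE)
  }
  grand <- mean(M)
  rm_ <- rowMeans(M); cm_ <- colMeans(M)
  msr <- 2 * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2)
  res <- M - outer(rm_, c(1, 1)) - rep(cm_, each = n) + grand
  mse <- sum(res^2) / (n - 1)
  icc <- (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
  sd_all <- stats::sd(as.vector(M))
  sem <- sd_all * sqrt(1 - max(icc, 0))
  structure(list(icc = icc, sem = sem,
                 mdc95 = stats::qnorm(0.975) * sqrt(2) * sem,
                 n_subjects = n, split_label = split_label),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> ICC(2,1) = %.3f, SEM = %.3f, MDC95 = %.3f (n = %d, %s)\n",
              x$icc, x$sem, x$mdc95, x$n_subjects, x$split_label))
  invisible(x)
}

#' Minimal detectable change from an ICC
#'
#' `SEM = sd * sqrt(1 - ICC)` (ICC clipped at 0) and
#' `MDC = z * sqrt(2) * SEM` with `z` the two-sided standard-normal
#' quantile at the requested confidence; at 95% this is the usual
#' `1.96 * sqrt(2) * SEM`.
#'
#' @param sd standard deviation of the measurements.
#' @param icc intraclass correlation in `[-1, 1]`.
#' @param confidence confidence level of the detectable change.
#' @return the MDC in measurement units.
#' @examples
#' mdc_from_icc(10, 0.84)  # 1.96 * sqrt(2) * 4
#' @export
mdc_from_icc <- function(sd, icc, confidence = 0.95) {
  stopifnot(sd >= 0, icc <= 1, confidence > 0, confidence < 1)
  sem <- sd * sqrt(1 - max(icc, 0))
  stats::qnorm((1 + confidence) / 2) * sqrt(2) * sem
}

#' Standardized response mean
#'
#' Mean longitudinal change divided by the standard deviation of the
#' change; the conventional responsiveness effect size (|SRM| > 0.8
#' large, 0.5-0.8 moderate, < 0.5 low).
#'
#' @param changes numeric vector of within-subject changes.
#' @return the SRM.
#' @export
srm <- function(changes) {
  changes <- changes[!is.na(changes)]
  s <- stats::sd(changes)
  if (length(changes) < 2 || s == 0) {
    stop("SRM undefined: zero change variance", call. = FALSE)
  }
  mean(changes) / s
}

#' Responsiveness category of an SRM
#'
#' Conventional bands on the absolute SRM: large above 0.8, moderate from
#' 0.5 to 0.8, low below 0.5.
#'
#' @param srm standardized response mean(s).
#' @return character vector `"low"`, `"moderate"` or `"large"`.
#' @export
srm_category <- function(srm) {
  ifelse(abs(srm) > 0.8, "large",
         ifelse(abs(srm) >= 0.5, "moderate", "low"))
}

#' Two-arm trial sample size from an SRM
#'
#' Per-arm sample size for a two-arm trial powered to detect a
#' `delta`-fraction of the observed 1-year progression, treating the SRM
#' as the standardized effect:
#' `n = ceil( 2 * (z_{1-alpha/2} + z_{power})^2 / (delta * SRM)^2 )`
#' for the normal approximation, or the noncentral-t solution via
#' [stats::power.t.test()]. `delta = 1` powers the trial on the full
#' observed progression; `delta = 0.5` on a 50% slowing.
#'
#' @param srm standardized response mean (nonzero).
#' @param alpha two-sided type-I error.
#' @param power target power.
#' @param delta fraction of the observed progression to detect.
#' @param method `"normal"` closed form or `"t"` noncentral-t iteration.
#' @return integer subjects per arm.
#' @examples
#' sample_size_from_srm(1)     # 16
#' sample_size_from_srm(0.09)  # 1938
#' @export
sample_size_from_srm <- function(srm, alpha = 0.05, power = 0.80, delta = 1,
                                 method = c("normal", "t")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, delta > 0)
  if (srm == 0) stop("sample size undefined for SRM = 0", call. = FALSE)
  eff <- abs(delta * srm)
  if (method == "normal") {
    n <- 2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 / eff^2
  } else {
    n <- stats::power.t.test(delta = eff, sd = 1, sig.level = alpha,
                             power = power, type = "two.sample")$n
  }
  as.integer(ceiling(n))
}

#' Responsiveness summary for one measure
#'
#' Bundles the SRM of a change vector with the per-arm sample size at the
#' configured trial design.
#'
#' @param changes within-subject change scores.
#' @inheritParams sample_size_from_srm
#' @return list of class `responsiveness_result`: `srm`, `n_per_arm`,
#'   `alpha`, `power`, `delta`, `n_observed`.
#' @export
responsiveness <- function(changes, alpha = 0.05, power = 0.80, delta = 1,
                           method = c("normal", "t")) {
  s <- srm(changes)
  structure(list(
    srm = s,
    n_per_arm = sample_size_from_srm(s, alpha, power, delta, method),
    alpha = alpha, power = power, delta = delta,
    n_observed = sum(!is.na(changes))
  ), class = "responsiveness_result")
}

#' @export
print.responsiveness_result <- function(x, ...) {
  cat(sprintf("<responsiveness_result> SRM = %.3f, n/arm = %d (alpha %.2f, power %.2f, delta %.2f)\n",
              x$srm, x$n_per_arm, x$alpha, x$power, x$delta))
  invisible(x)
}
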