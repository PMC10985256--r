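test_that("group comparison routes through the normality gate", {
  set.seed(31)
  x <- rnorm(50); y <- rnorm(50, 5)
  r <- compare_groups(x, y)
  expect_equal(r$test, "t")
  expect_lt(r$p, 1e-6)

  # heavy-tailed samples are rejected by Shapiro-Wilk and take Mann-Whitney
  hx <- rcauchy(60); hy <- rcauchy(60)
  expect_equal(compare_groups(hx, hy)$test, "mann-whitney")

  # constant groups always take the rank path; fully tied comparison -> p = 1
  r0 <- compare_groups(rep(1, 5), rep(1, 5))
  expect_equal(r0$test, "mann-whitney")
  expect_equal(r0$p, 1)

  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("group tests hold nominal type-I error under the null", {
  set.seed(32)
  reps <- 2000
  rej <- mean(replicate(reps, compare_groups(rnorm(15), rnorm(15))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.015)  # ~3 MC sds
  rejp <- mean(replicate(reps, {
    b <- rnorm(15)
    paired_change_test(b, b + rnorm(15))$p < 0.05
  }))
  expect_lt(abs(rejp - 0.05), 0.015)
})

test_that("Bonferroni multiplies by the family size and caps at 1", {
  expect_equal(bonferroni(0.01, 7), 0.07)
  expect_equal(bonferroni(0.2, 7), 1)
  set.seed(33)
  p <- runif(20)
  expect_equal(bonferroni(p, 7), vapply(p, function(q) min(1, q * 7), 0))
})

test_that("Spearman matrix recovers monotone association and independence", {
  set.seed(34)
  x <- runif(40)
  r <- spearman_matrix(data.frame(x = x), data.frame(y = exp(3 * x)))
  expect_equal(r$rho, 1)

  big <- spearman_matrix(data.frame(a = runif(1000)),
                         data.frame(b = runif(1000)))
  expect_lt(abs(big$rho), 0.1)

  m <- spearman_matrix(data.frame(a = rnorm(30), b = rnorm(30)),
                       data.frame(u = rnorm(30), v = rnorm(30), w = rnorm(30)))
  expect_equal(nrow(m), 6)
})

test_that("paired change test handles null, shift and missing pairs", {
  set.seed(35)
  b <- rnorm(20)
  same <- paired_change_test(b, b)
  expect_equal(same$mean_change, 0)
  expect_equal(same$p, 1)

  shifted <- paired_change_test(b, b + 1)
  expect_lt(shifted$p, 0.001)
  expect_equal(shifted$mean_change, 1)

  # +1 shift with tiny jitter through the Wilcoxon branch
  fu <- b + 1 + rcauchy(20, scale = 0.01)
  r <- paired_change_test(b, fu)
  expect_equal(r$test, "wilcoxon")
  expect_lt(r$p, 0.001)

  bb <- c(b, NA); ff <- c(b + 1, 5)
  expect_equal(paired_change_test(bb, ff)$n, 20)
})

test_that("ICC matches the ANOVA reference and recovers variance ratios", {
  # hand-sized 6x2 table against the aov-based reference
  x <- c(9, 6, 8, 7, 10, 6); y <- c(2, 1, 4, 0, 7, 2)
  r <- icc21(x, y)
  expect_equal(r$icc, icc_aov_reference(x, y), tolerance = 1e-12)

  set.seed(36)
  n <- 200
  subj <- rnorm(n, sd = 3)                     # between-variance 9
  a <- subj + rnorm(n, sd = 1); b <- subj + rnorm(n, sd = 1)
  r2 <- icc21(a, b)
  expect_lt(abs(r2$icc - 0.9), 0.05)
  expect_equal(r2$icc, icc_aov_reference(a, b), tolerance = 1e-12)

  indep <- icc21(rnorm(n), rnorm(n))
  expect_lt(abs(indep$icc), 0.1)

  dup <- icc21(a, a)
  expect_equal(dup$icc, 1)
  expect_equal(dup$mdc95, 0)

  expect_error(icc21(rep(1, 6), rep(1, 6)), "zero total variance")
  expect_error(icc21(1:4, 1:4 + 0.5), "at least 5")
})

test_that("MDC follows the closed form and is monotone in ICC", {
  expect_equal(mdc_from_icc(10, 0.84), qnorm(0.975) * sqrt(2) * 4)
  expect_equal(mdc_from_icc(10, 1), 0)
  iccs <- seq(0, 1, by = 0.1)
  m <- vapply(iccs, function(i) mdc_from_icc(10, i), 0)
  expect_true(all(diff(m) <= 0))
  # negative ICC is clipped to 0 for the SEM
  expect_equal(mdc_from_icc(10, -0.5), mdc_from_icc(10, 0))
})

test_that("SRM is mean change over SD of change", {
  expect_equal(srm(c(-2, -1, 0, 1, 2)), 0)
  set.seed(37)
  ch <- rnorm(1e5, 1.5, 1.5)
  expect_lt(abs(srm(ch) - 1), 0.02)
  expect_equal(sign(srm(ch)), sign(mean(ch)))
  expect_error(srm(rep(2, 10)), "zero change variance")
})

test_that("sample size from SRM matches the closed form and scaling law", {
  expect_equal(sample_size_from_srm(1), 16L)
  expect_equal(sample_size_from_srm(0.09), 1938L)
  # halving the SRM quadruples n (up to ceiling)
  for (s in c(0.2, 0.4, 0.8)) {
    n1 <- 2 * (qnorm(0.975) + qnorm(0.8))^2 / s^2
    expect_equal(sample_size_from_srm(s / 2), as.integer(ceiling(4 * n1)))
  }
  # delta scales the detectable effect
  expect_equal(sample_size_from_srm(0.5, delta = 0.5),
               sample_size_from_srm(0.25))
  # strictly decreasing in |srm|
  ns <- vapply(seq(0.1, 1.5, by = 0.1), sample_size_from_srm, 1L)
  expect_true(all(diff(ns) < 0))
  expect_error(sample_size_from_srm(0), "SRM = 0")
  # noncentral-t solution is never below the normal approximation
  expect_gte(sample_size_from_srm(0.3, method = "t"),
             sample_size_from_srm(0.3))
})

test_that("odd/even split partitions valid days by weekday and excludes Sunday", {
  # identical Mon..Sun days -> identical summaries
  day <- rep(c(50, 500, 2500), each = 320)
  s <- make_week(rep(list(day), 7), steps = rep(list(rep(6, 960)), 7))
  halves <- odd_even_split(s)
  for (f in c("met_rate", "pct_sedentary", "vm3", "steps_per_min")) {
    expect_equal(halves$odd[[f]], halves$even[[f]])
  }
  expect_equal(halves$odd$wear_days, 3)  # Mon Wed Fri
  expect_equal(halves$even$wear_days, 3) # Tue Thu Sat; Sunday dropped

  # missing all even weekdays -> error
  s2 <- make_week(list(day), start_date = "2022-03-07")  # Monday only
  expect_error(odd_even_split(s2), "each half")

  # randomized days match a manual partition
  set.seed(38)
  days <- lapply(1:7, function(i) sample(c(0, 300, 2200), 960, TRUE))
  s3 <- make_week(days, steps = lapply(1:7, function(i) rep(i, 960)))
  h <- odd_even_split(s3)
  # manual partition: blank the wear flags outside Mon/Wed/Fri
  keep <- rep(1:7, each = 960) %in% c(1, 3, 5)
  s_odd <- s3; s_odd$wear <- s3$wear & keep
  ref <- summarize_subject(s_odd)
  expect_equal(h$odd$vm3, ref$vm3)
  expect_equal(h$odd$steps_per_min, ref$steps_per_min)
  expect_equal(h$odd$pct_mvpa, ref$pct_mvpa)
})
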