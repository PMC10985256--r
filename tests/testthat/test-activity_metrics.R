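# one full wear day built from per-minute CPM values
day_series <- function(cpm, steps = NULL, axis2 = NULL, axis3 = NULL) {
  n <- length(cpm)
  make_series(cpm, axis2 = axis2, axis3 = axis3, steps = steps,
              start = "2022-03-07 00:00:00", wear = rep(TRUE, n))
}

test_that("intensity classification uses the half-open cut-point bins", {
  cp <- cut_points()
  lv <- classify_intensity(c(0, 99, 100, 1951, 1952, 5724, 5725, 9000), cp)
  expect_equal(as.character(lv),
               c("sedentary", "sedentary", "light", "light",
                 "moderate", "moderate", "vigorous", "vigorous"))
  expect_error(cut_points(2000, 1951, 5724))
})

test_that("activity percentages count wear epochs and sum to 100", {
  allzero <- day_series(rep(0, 480))
  expect_equal(unname(activity_percentages(allzero)), c(100, 0, 0))

  thirds <- day_series(rep(c(50, 500, 2500), each = 200))
  expect_equal(unname(activity_percentages(thirds)),
               rep(100 / 3, 3), tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:20) {
    cpm <- sample(c(0:150, 1900:2000, 5000:6000), 600, TRUE)
    s <- day_series(cpm)
    got <- activity_percentages(s)
    lev <- cut(cpm, c(-1, 99, 1951, 5724, Inf),
               labels = c("s", "l", "m", "v"))
    expect_equal(unname(got),
                 100 * c(mean(lev == "s"), mean(lev == "l"),
                         mean(lev %in% c("m", "v"))))
    expect_equal(sum(got), 100)
  }
})

test_that("VM3 is the mean per-epoch triaxial norm and dominates axis1", {
  one <- day_series(rep(3, 480), axis2 = rep(4, 480), axis3 = rep(12, 480))
  expect_equal(vm3_mean(one), 13)
  expect_equal(vm3_mean(day_series(rep(0, 480))), 0)

  set.seed(22)
  for (rep in 1:20) {
    a1 <- sample(0:2000, 480, TRUE)
    a2 <- sample(0:900, 480, TRUE)
    a3 <- sample(0:900, 480, TRUE)
    s <- day_series(a1, axis2 = a2, axis3 = a3)
    expect_equal(vm3_mean(s), mean(sqrt(a1^2 + a2^2 + a3^2)))
    expect_gte(vm3_mean(s), mean(a1))
  }
})

test_that("MET rate floors at 1 and applies the regression above the light cut", {
  expect_equal(met_rate(day_series(rep(50, 480))), 1)
  one <- day_series(c(rep(1952, 1), rep(0, 479)))
  expect_equal(met_rate(one),
               (1.439008 + 0.000795 * 1952 + 479) / 480)
  # single-epoch value itself
  expect_equal(1.439008 + 0.000795 * 1952, 2.990848)

  # monotone under epoch-wise increases of axis1
  set.seed(23)
  cpm <- sample(0:4000, 480, TRUE)
  bumped <- cpm + sample(0:500, 480, TRUE)
  expect_gte(met_rate(day_series(bumped)), met_rate(day_series(cpm)))
})

test_that("bout counting finds maximal MVPA runs of at least 10 minutes", {
  pad <- rep(50, 235)
  expect_equal(count_bouts(day_series(c(pad, rep(2500, 10), pad))), 1)
  expect_equal(count_bouts(day_series(c(pad, rep(2500, 9), pad, rep(0, 1)))), 0)
  expect_equal(count_bouts(day_series(c(pad, rep(2500, 25), pad))), 1)

  set.seed(24)
  for (rep in 1:30) {
    cpm <- sample(c(0, 500, 2500), 960, TRUE, prob = c(0.4, 0.3, 0.3))
    s <- day_series(cpm)
    expect_equal(count_bouts(s), bout_reference(cpm > 1951, 10))
  }
})

test_that("bout drop-tolerance absorbs short sub-threshold dips", {
  pad <- rep(50, 240)
  x <- c(pad, rep(2500, 5), 100, rep(2500, 5), pad)  # 11 min incl. 1 dip
  expect_equal(count_bouts(day_series(x)), 0)
  expect_equal(count_bouts(day_series(x), drop_tolerance = 2), 1)
  # dip at the edge is never absorbed
  y <- c(pad, 100, rep(2500, 10), pad)
  expect_equal(count_bouts(day_series(y), drop_tolerance = 2), 1)
})

test_that("steps per minute is total steps over wear minutes", {
  expect_equal(steps_per_minute(day_series(rep(100, 480),
                                           steps = rep(0, 480))), 0)
  expect_equal(steps_per_minute(day_series(rep(100, 480),
                                           steps = rep(12, 480))), 12)
  set.seed(25)
  st <- sample(0:120, 480, TRUE)
  expect_equal(steps_per_minute(day_series(rep(100, 480), steps = st)),
               sum(st) / 480)
})

test_that("measures ignore non-wear epochs and invalid days entirely", {
  base_day <- rep(c(50, 500, 2500), each = 320)
  st <- rep(5, 960)
  s1 <- make_week(list(base_day), steps = list(st))
  # same day plus an invalid day (only 100 wear minutes) and non-wear tail
  junk <- c(rep(3000, 100), rep(0, 860))
  s2 <- make_week(list(base_day, junk), steps = list(st, rep(50, 960)))
  s2$wear <- c(rep(TRUE, 960), rep(TRUE, 100), rep(FALSE, 860))
  for (f in list(activity_percentages, vm3_mean, met_rate, steps_per_minute)) {
    expect_equal(f(s1), f(s2))
  }
  expect_equal(count_bouts(s1), count_bouts(s2))
})

test_that("summarize_subject composes all measures from one wear mask", {
  set.seed(26)
  cpm <- sample(c(0:99, 100:1951, 1952:6000), 960, TRUE)
  st <- sample(0:60, 960, TRUE)
  s <- make_week(list(cpm), steps = list(st))
  a <- summarize_subject(s)
  expect_s3_class(a, "activity_summary")
  expect_equal(a$pct_sedentary + a$pct_light + a$pct_mvpa, 100)
  expect_equal(a$met_rate, met_rate(s))
  expect_equal(a$n_bouts, count_bouts(s))
  expect_equal(a$vm3, vm3_mean(s))
  expect_equal(a$steps_per_min, steps_per_minute(s))
  expect_equal(a$wear_days, 1)
  expect_equal(a$wear_minutes, 960)
  df <- as.data.frame(a)
  expect_equal(nrow(df), 1)

  # a recording with no valid day reports wear_days = 0 and NA measures
  short <- make_series(rep(100, 60), wear = rep(TRUE, 60))
  a0 <- summarize_subject(short)
  expect_equal(a0$wear_days, 0)
  expect_true(is.na(a0$vm3))
})
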