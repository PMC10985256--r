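small_cfg <- function(...) cohort_config(n_frda = 4, n_ctr = 3, ...)

test_that("step-rate calibration solves the occupancy-weighted target", {
  r <- steps_calibration(0.218, 0.105, 16.0)
  expect_equal(unname(r), c(30, 90), tolerance = 1e-3)
  expect_equal(0.218 * r[["light"]] + 0.105 * r[["mvpa"]], 16.0)

  # zero MVPA occupancy: all steps must come from light activity
  r0 <- steps_calibration(0.25, 0, 10)
  expect_equal(r0[["light"]], 40)

  expect_error(steps_calibration(0, 0, 5), "no admissible")
})

test_that("profile occupancy responds to severity through the logistic link", {
  cfg <- cohort_config()
  p_mean <- build_profile("FRDA", "waist", cfg, z = 0)
  pi_mean <- profile_occupancy(p_mean)
  # population-mean sedentary occupancy (over severity, subject and day
  # effects) sits on the group calibration target
  set.seed(50)
  mean_occ <- function(group) {
    p0 <- build_profile(group, "waist", cfg)
    b <- if (group == "FRDA") cfg$linkage_sed else 0
    s2 <- b^2 + cfg$subject_sd_sed^2 + cfg$day_sd_sed^2
    mean(plogis(p0$logit_sed + rnorm(5e4, 0, sqrt(s2))))
  }
  expect_lt(abs(mean_occ("FRDA") - 0.813), 0.02)
  expect_lt(abs(mean_occ("CTR") - 0.677), 0.02)

  # higher severity -> more sedentary, less MVPA
  pi_hi <- profile_occupancy(build_profile("FRDA", "waist", cfg, z = 2))
  expect_gt(pi_hi[["sedentary"]], pi_mean[["sedentary"]])
  expect_lt(pi_hi[["moderate"]] + pi_hi[["vigorous"]],
            pi_mean[["moderate"]] + pi_mean[["vigorous"]])

  # zero linkage: profiles independent of severity
  cfg0 <- cohort_config(linkage_sed = 0, linkage_mvpa = 0)
  expect_equal(profile_occupancy(build_profile("FRDA", "waist", cfg0, z = 2)),
               profile_occupancy(build_profile("FRDA", "waist", cfg0, z = -2)))

  # transition matrix is row-stochastic with stationary pi
  P <- transition_matrix(p_mean)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
  expect_equal(as.numeric(pi_mean %*% P), unname(pi_mean), tolerance = 1e-12)
})

test_that("generated counts classify back to their generating states exactly", {
  set.seed(51)
  prof <- build_profile("CTR", "waist", cohort_config())
  s <- simulate_epoch_series(prof, days = 3)
  truth <- attr(s, "truth")
  active <- truth$states %in% c("sedentary", "light", "moderate", "vigorous")
  got <- as.character(classify_intensity(s$axis1[active]))
  expect_identical(got, truth$states[active])
  # non-wear epochs are all-zero (spikes excluded by construction label)
  nw <- truth$states == "nonwear"
  expect_true(all(s$axis1[nw] == 0 & s$axis2[nw] == 0 & s$axis3[nw] == 0))
  expect_true(all(s$steps[nw] == 0))
})

test_that("an all-sedentary profile yields sub-cut-point counts and zero steps", {
  set.seed(52)
  prof <- build_profile("FRDA", "waist", cohort_config())
  prof$logit_sed <- 50  # all mass on sedentary
  prof$nonwear$block_prob <- 0
  prof$nonwear$long_prob <- 0
  s <- simulate_epoch_series(prof, days = 1)
  expect_true(all(s$axis1 < 100))
  expect_true(all(s$axis1 > 0))
  expect_true(all(s$steps == 0))
})

test_that("inserted non-wear blocks are recovered by Choi detection with sensitivity 1", {
  set.seed(53)
  prof <- build_profile("FRDA", "wrist", cohort_config(nonwear_block_prob = 1))
  s <- simulate_epoch_series(prof, days = 7)
  truth <- attr(s, "truth")
  expect_gt(nrow(truth$nonwear_blocks), 0)
  s <- detect_nonwear_choi(s)
  inserted <- truth$states %in% c("nonwear", "nonwear_spike")
  expect_true(all(!s$wear[inserted]))          # sensitivity 1.0
  expect_true(all(s$wear[!inserted]))          # no false positives either
})

test_that("identical config and seed give a bit-identical cohort", {
  c1 <- simulate_cohort(small_cfg(seed = 99))
  c2 <- simulate_cohort(small_cfg(seed = 99))
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(lapply(c1$series, function(s) s$axis1),
                   lapply(c2$series, function(s) s$axis1))
  c3 <- simulate_cohort(small_cfg(seed = 100))
  expect_false(identical(c1$series[[1]]$axis1, c3$series[[1]]$axis1))
})

test_that("clinical records respect the inclusion emulation", {
  set.seed(54)
  coh <- simulate_cohort(cohort_config(n_frda = 30, n_ctr = 5, seed = 7))
  frda <- coh$clinical[coh$clinical$group == "FRDA" &
                         coh$clinical$visit == "baseline", ]
  expect_true(all(frda$sara_gait < 8))
  expect_true(all(frda$age >= 18 & frda$age <= 45))
  expect_true(all(frda$disease_duration >= 0, na.rm = TRUE))
  # some but not all patients complete the 8-m walk test
  expect_gt(sum(is.na(frda$t8mwt)), 0)
  expect_gt(sum(!is.na(frda$t8mwt)), 0)
  ctr <- coh$clinical[coh$clinical$group == "CTR", ]
  expect_true(all(ctr$sara <= 1))
})

test_that("decline shifts the patient group and spares controls", {
  coh <- simulate_cohort(cohort_config(n_frda = 12, n_ctr = 8, seed = 61))
  summ <- summarize_cohort(coh)
  waist <- summ[summ$placement == "waist" & summ$wear_days > 0, ]
  grp <- coh$clinical$group[match(waist$subject_id, coh$clinical$subject_id)]
  sed_b <- waist$pct_sedentary[waist$visit == "baseline" & grp == "FRDA"]
  sed_f <- waist$pct_sedentary[waist$visit == "followup" & grp == "FRDA"]
  expect_gt(mean(sed_f) - mean(sed_b), 0)
  # decline = 0 keeps the paired null (mean change small relative to spread)
  coh0 <- simulate_cohort(cohort_config(
    n_frda = 12, n_ctr = 8, seed = 62, decline_sara_mean = 0,
    decline_sara_sd = 0.01, decline_sed_shift = 0, decline_mvpa_shift = 0))
  s0 <- summarize_cohort(coh0)
  w0 <- s0[s0$placement == "waist", ]
  b0 <- w0[w0$visit == "baseline", ]; f0 <- w0[w0$visit == "followup", ]
  common <- intersect(b0$subject_id, f0$subject_id)
  ch <- f0$vm3[match(common, f0$subject_id)] -
    b0$vm3[match(common, b0$subject_id)]
  expect_gt(paired_change_test(b0$vm3[match(common, b0$subject_id)],
                               f0$vm3[match(common, f0$subject_id)])$p, 0.05)
})

test_that("cohort files round-trip through the public interfaces", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(cohort_config(n_frda = 2, n_ctr = 2, days = 3,
                                       seed = 5))
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "diary.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  key <- names(coh$series)[1]
  r <- read_epoch_csv(file.path(dir, paste0(key, ".csv")))
  expect_identical(r$axis1, coh$series[[key]]$axis1)
  cl <- read_clinical_table(file.path(dir, "clinical.csv"))
  expect_equal(nrow(cl), nrow(coh$clinical))
})
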