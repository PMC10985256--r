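# Calibration anchors for the two study groups and two device placements:
# mean occupancy of waking wear time by intensity class, the MVPA share of
# non-sedentary time, the vigorous share of MVPA, and the target mean
# steps/min. Sedentary and MVPA-share values are the group means of the
# emulated study population; the vigorous split and lateral-axis scalings
# are synthetic choices (see the methods vignette).
occupancy_calibration <- list(
  waist = list(
    FRDA = list(sed = 0.813, mvpa_share = 2.7 / (2.7 + 16.0),
                vig_share = 0.07, steps = 7.7),
    CTR = list(sed = 0.677, mvpa_share = 10.5 / (10.5 + 21.8),
               vig_share = 0.15, steps = 16.0)
  ),
  wrist = list(
    FRDA = list(sed = 0.429, mvpa_share = 31.3 / (31.3 + 25.8),
                vig_share = 0.10, steps = 14.0),
    CTR = list(sed = 0.317, mvpa_share = 43.4 / (43.4 + 24.9),
               vig_share = 0.18, steps = 20.2)
  )
)

# Per-state axis1 count model: log-normal (meanlog, sdlog) truncated to the
# cut-point band of the state, drawn by inverse CDF and ceiling-rounded so
# every generated count classifies back to its generating state.
count_model <- function(placement) {
  ml_sed <- if (placement == "wrist") 3.6 else 3.2
  list(
    meanlog = c(sedentary = ml_sed, light = 6.0, moderate = 7.95,
                vigorous = 8.75),
    sdlog = c(sedentary = 0.8, light = 0.7, moderate = 0.35, vigorous = 0.2),
    lo = c(sedentary = 0, light = 99, moderate = 1951, vigorous = 5724),
    hi = c(sedentary = 99, light = 1951, moderate = 5724, vigorous = Inf)
  )
}

#' Configuration of the synthetic two-visit cohort
#'
#' Defaults encode the emulated study conditions: 26 patients and 13
#' controls, 7-day recordings of 60-s epochs during a 16-h waking window
#' at waist and wrist, severity (SARA) distributed N(17.2, 6.0) in the
#' patient group, a logistic severity-to-sedentary linkage, and a 1-year
#' decline of +1.5 +/- 1.5 SARA points with an accompanying shift of the
#' activity-state mix toward sedentary. Controls do not decline.
#'
#' @param n_frda,n_ctr group sizes.
#' @param days recording days per visit (starting on a Monday).
#' @param waking_start hour of day the waking window opens.
#' @param waking_hours length of the waking window, hours.
#' @param start_date first recording day (a Monday keeps the odd/even
#'   weekday split balanced).
#' @param sara_mean,sara_sd patient SARA distribution at baseline, points.
#' @param linkage_sed log-odds of sedentary dwell added per SD of SARA.
#' @param linkage_mvpa log-odds of the MVPA share removed per SD of SARA.
#' @param subject_sd_sed,subject_sd_mvpa between-subject SD of the two
#'   occupancy log-odds.
#' @param day_sd_sed,day_sd_mvpa day-to-day SD of the two occupancy
#'   log-odds (drives split-half reliability below 1).
#' @param persistence probability that a minute keeps the previous
#'   activity state rather than redrawing from the stationary mix.
#' @param decline_sara_mean,decline_sara_sd 1-year SARA change in
#'   patients, points.
#' @param decline_sed_shift,decline_mvpa_shift additional 1-year log-odds
#'   shifts of sedentary dwell and MVPA share beyond the severity-mediated
#'   part.
#' @param nonwear_block_prob per-day probability of one true non-wear
#'   block.
#' @param nonwear_block_min,nonwear_block_max non-wear block length range,
#'   minutes (at least the 90-min detection window).
#' @param long_nonwear_prob per-day probability of a long (10-h) non-wear
#'   block that invalidates the day.
#' @param nonwear_spike_prob probability that a non-wear block contains a
#'   1-2 min movement artifact spike.
#' @param seed integer seed making the cohort fully reproducible.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_frda = 26, n_ctr = 13, days = 7,
                          waking_start = 7, waking_hours = 16,
                          start_date = "2022-03-07",
                          sara_mean = 17.2, sara_sd = 6.0,
                          linkage_sed = 0.49, linkage_mvpa = 0.30,
                          subject_sd_sed = 0.38, subject_sd_mvpa = 0.40,
                          day_sd_sed = 0.35, day_sd_mvpa = 0.30,
                          persistence = 0.85,
                          decline_sara_mean = 1.5, decline_sara_sd = 1.5,
                          decline_sed_shift = 0.08,
                          decline_mvpa_shift = -0.03,
                          nonwear_block_prob = 0.7,
                          nonwear_block_min = 90, nonwear_block_max = 150,
                          long_nonwear_prob = 0.01,
                          nonwear_spike_prob = 0.3,
                          seed = 20220307) {
  stopifnot(n_frda >= 2, n_ctr >= 2, days >= 1, sara_sd > 0,
            subject_sd_sed > 0, subject_sd_mvpa > 0,
            day_sd_sed > 0, day_sd_mvpa > 0,
            persistence >= 0, persistence < 1,
            nonwear_block_min >= 90,
            nonwear_block_max >= nonwear_block_min,
            waking_hours * 60 > nonwear_block_max)
  structure(as.list(environment()), class = "cohort_config")
}

#' Solve per-state step rates against a steps/min target
#'
#' Finds the Poisson step rate of light activity (and `ratio` times that
#' rate for MVPA) such that the expected steps per wear minute at the
#' given state occupancies equals `target`. Sedentary and non-wear
#' minutes contribute no steps.
#'
#' @param p_light,p_mvpa occupancy fractions of wear time.
#' @param target target mean steps per wear minute.
#' @param ratio MVPA-to-light step-rate ratio.
#' @return named vector `c(light =, mvpa =)` of steps/min rates.
#' @examples
#' steps_calibration(0.218, 0.105, 16.0)  # c(light = 30, mvpa = 90)
#' @export
steps_calibration <- function(p_light, p_mvpa, target, ratio = 3) {
  stopifnot(p_light >= 0, p_mvpa >= 0, ratio > 0)
  denom <- p_light + ratio * p_mvpa
  if (target < 0 || denom <= 0 || (target > 0 && denom == 0)) {
    stop("no admissible non-negative step rates for this target", call. = FALSE)
  }
  r <- target / denom
  if (r < 0) stop("negative step rate solution", call. = FALSE)
  c(light = r, mvpa = ratio * r)
}

# Logistic-normal mean correction: choose mu so that E[plogis(mu + e)],
# e ~ N(0, s2), equals the target proportion (solved numerically so the
# population mean sits on the calibration anchor).
logit_adjusted <- function(target, s2) {
  if (s2 == 0) return(stats::qlogis(target))
  mean_p <- function(mu) {
    stats::integrate(function(e) stats::plogis(mu + e) *
                       stats::dnorm(e, 0, sqrt(s2)),
                     -Inf, Inf)$value - target
  }
  stats::uniroot(mean_p, stats::qlogis(target) + c(-2, 3), tol = 1e-8)$root
}

# Build the per-placement activity profile of one subject at one visit.
# z: standardized severity; u_sed/u_mvpa: subject-level log-odds effects
# shared across placements and visits; shift_*: additional visit shifts.
build_profile <- function(group, placement, config, z = 0, u_sed = 0,
                          u_mvpa = 0, shift_sed = 0, shift_mvpa = 0) {
  cal <- occupancy_calibration[[placement]][[group]]
  b_sed <- if (group == "FRDA") config$linkage_sed else 0
  b_mvpa <- if (group == "FRDA") config$linkage_mvpa else 0
  s2_sed <- b_sed^2 + config$subject_sd_sed^2 + config$day_sd_sed^2
  s2_mvpa <- b_mvpa^2 + config$subject_sd_mvpa^2 + config$day_sd_mvpa^2
  lsed <- logit_adjusted(cal$sed, s2_sed) + b_sed * z + u_sed + shift_sed
  lmsh <- logit_adjusted(cal$mvpa_share, s2_mvpa) - b_mvpa * z + u_mvpa +
    shift_mvpa
  rates <- steps_calibration(
    p_light = (1 - cal$sed) * (1 - cal$mvpa_share),
    p_mvpa = (1 - cal$sed) * cal$mvpa_share,
    target = cal$steps
  )
  structure(list(
    group = group, placement = placement,
    logit_sed = lsed, logit_mvpa_share = lmsh, vig_share = cal$vig_share,
    day_sd_sed = config$day_sd_sed, day_sd_mvpa = config$day_sd_mvpa,
    persistence = config$persistence,
    counts = count_model(placement),
    lateral = list(scale2 = 0.55, scale3 = 0.45, sdlog = 0.3),
    step_rates = c(sedentary = 0, light = unname(rates["light"]),
                   moderate = unname(rates["mvpa"]),
                   vigorous = unname(rates["mvpa"])),
    nonwear = list(block_prob = config$nonwear_block_prob,
                   block_min = config$nonwear_block_min,
                   block_max = config$nonwear_block_max,
                   long_prob = config$long_nonwear_prob,
                   spike_prob = config$nonwear_spike_prob),
    waking_start = config$waking_start,
    waking_minutes = config$waking_hours * 60
  ), class = "activity_profile")
}

# Day-noise-free stationary occupancy over the four active states.
profile_occupancy <- function(profile, day_sed = 0, day_mvpa = 0) {
  p_sed <- stats::plogis(profile$logit_sed + day_sed)
  msh <- stats::plogis(profile$logit_mvpa_share + day_mvpa)
  p_mvpa <- (1 - p_sed) * msh
  p_vig <- p_mvpa * profile$vig_share
  c(sedentary = p_sed, light = 1 - p_sed - p_mvpa,
    moderate = p_mvpa - p_vig, vigorous = p_vig)
}

#' Minute-state transition matrix of an activity profile
#'
#' The chain over the four active states is the exchangeable mixture
#' `P = rho * I + (1 - rho) * 1 pi'` (keep the current state with
#' probability `rho`, otherwise redraw from the stationary mix `pi`), so
#' the stationary distribution is `pi` exactly. Non-wear is overlaid as
#' explicit blocks, not a chain state.
#'
#' @param profile an activity profile from [sample_subject()].
#' @return 4x4 row-stochastic matrix over sedentary/light/moderate/vigorous.
#' @export
transition_matrix <- function(profile) {
  pi_ <- profile_occupancy(profile)
  rho <- profile$persistence
  P <- rho * diag(4) + (1 - rho) * matrix(pi_, 4, 4, byrow = TRUE)
  dimnames(P) <- list(names(pi_), names(pi_))
  P
}

#' Draw one synthetic subject
#'
#' Samples demographics, clinical scores and the latent activity
#' disposition of one subject, and builds the four activity profiles
#' (waist/wrist x baseline/follow-up). Patient severity is drawn from the
#' configured SARA distribution (truncated to the ambulatory inclusion
#' range, gait sub-score < 8) and tilts the profiles through the logistic
#' linkage: higher SARA means more sedentary dwell, a smaller MVPA share
#' and consequently fewer steps. Clinical sub-scores (mFARS, FARS part E,
#' ADL, CCFS, 8MWT, gait) are noisy monotone maps of the severity.
#' Follow-up patient profiles add the configured decline; control
#' profiles are unshifted. Uses the session RNG; seed via
#' [simulate_cohort()] or `set.seed()`.
#'
#' @param group `"FRDA"` or `"CTR"`.
#' @param config a [cohort_config()].
#' @param subject_id identifier written into the records.
#' @return list with `record` (clinical rows, one per visit), `latent`
#'   (severity z and subject effects) and `profiles`
#'   (`$baseline$waist`, ... `$followup$wrist`).
#' @export
sample_subject <- function(group, config = cohort_config(),
                           subject_id = "S001") {
  group <- match.arg(group, c("FRDA", "CTR"))
  u_sed <- stats::rnorm(1, 0, config$subject_sd_sed)
  u_mvpa <- stats::rnorm(1, 0, config$subject_sd_mvpa)
  if (group == "FRDA") {
    repeat {
      sara <- stats::rnorm(1, config$sara_mean, config$sara_sd)
      if (sara >= 3 && sara <= 32) break  # ambulatory range
    }
    age_at_onset <- round(min(24, max(7, stats::rnorm(1, 15.4, 4.9))), 1)
    age <- round(min(45, max(18, age_at_onset + max(1, stats::rnorm(1, 11.7, 6.9)))), 1)
    z <- (sara - config$sara_mean) / config$sara_sd
    dsara <- stats::rnorm(1, config$decline_sara_mean, config$decline_sara_sd)
    sara_fu <- min(38, max(0, sara + dsara))
    z_fu <- (sara_fu - config$sara_mean) / config$sara_sd
    gait <- function(s) min(7, max(0, round(0.3 * s + stats::rnorm(1, 0, 1))))
    clin <- function(visit, s) {
      data.frame(
        subject_id = subject_id, visit = visit, group = group,
        sex = sample(c("M", "F"), 1, prob = c(16, 10)),
        age = age + (visit == "followup"),
        bmi = round(stats::rnorm(1, 23, 3), 1),
        sara = round(s, 1), sara_gait = gait(s),
        mfars = round(min(93, max(0, 2.1 * s + 14 + stats::rnorm(1, 0, 5))), 1),
        fars_e = round(min(36, max(0, 1.2 * s + 4 + stats::rnorm(1, 0, 3))), 1),
        adl = round(min(36, max(0, 0.65 * s + 1.1 + stats::rnorm(1, 0, 3.5))), 1),
        ccfs = round(1100 + 7.3 * s + stats::rnorm(1, 0, 110)),
        t8mwt = if (stats::runif(1) < stats::plogis((18 - s) / 3)) {
          round(max(3, 4 + 0.28 * s + stats::rnorm(1, 0, 1.5)), 1)
        } else NA_real_,
        gaa1 = round(min(1100, max(300, stats::rnorm(1, 700, 200)))),
        gaa2 = round(min(1400, max(400, stats::rnorm(1, 900, 250)))),
        age_at_onset = age_at_onset,
        disease_duration = round(age - age_at_onset, 1)
      )
    }
    record <- rbind(clin("baseline", sara), clin("followup", sara_fu))
    record$sex[2] <- record$sex[1]  # identity fields fixed across visits
    record[2, c("bmi", "gaa1", "gaa2")] <- record[1, c("bmi", "gaa1", "gaa2")]
    profiles <- list(
      baseline = list(
        waist = build_profile(group, "waist", config, z, u_sed, u_mvpa),
        wrist = build_profile(group, "wrist", config, z, u_sed, u_mvpa)
      ),
      followup = list(
        waist = build_profile(group, "waist", config, z_fu, u_sed, u_mvpa,
                              config$decline_sed_shift, config$decline_mvpa_shift),
        wrist = build_profile(group, "wrist", config, z_fu, u_sed, u_mvpa,
                              config$decline_sed_shift, config$decline_mvpa_shift)
      )
    )
    latent <- list(z = z, z_followup = z_fu, u_sed = u_sed, u_mvpa = u_mvpa)
  } else {
    age <- round(min(31, max(21, stats::rnorm(1, 25.9, 3.1))), 1)
    clin <- function(visit) {
      data.frame(
        subject_id = subject_id, visit = visit, group = group,
        sex = sample(c("M", "F"), 1, prob = c(6, 7)),
        age = age + (visit == "followup"),
        bmi = round(stats::rnorm(1, 23, 3), 1),
        sara = sample(0:1, 1, prob = c(0.8, 0.2)), sara_gait = 0,
        mfars = sample(0:2, 1, prob = c(0.6, 0.3, 0.1)), fars_e = 0,
        adl = 0,
        ccfs = round(stats::rnorm(1, 947, 282)),
        t8mwt = round(max(3, stats::rnorm(1, 4.2, 0.6)), 1),
        gaa1 = NA_real_, gaa2 = NA_real_,
        age_at_onset = NA_real_, disease_duration = NA_real_
      )
    }
    record <- rbind(clin("baseline"), clin("followup"))
    record$sex[2] <- record$sex[1]
    record$bmi[2] <- record$bmi[1]
    base <- list(
      waist = build_profile(group, "waist", config, 0, u_sed, u_mvpa),
      wrist = build_profile(group, "wrist", config, 0, u_sed, u_mvpa)
    )
    profiles <- list(baseline = base, followup = base)
    latent <- list(z = 0, z_followup = 0, u_sed = u_sed, u_mvpa = u_mvpa)
  }
  list(record = record, latent = latent, profiles = profiles)
}

#' Simulate one epoch-count recording from an activity profile
#'
#' Runs the minute-state chain over the waking window of each day, draws
#' band-truncated log-normal axis1 counts and scaled lateral-axis counts
#' per state, Poisson steps in light and MVPA states, and overlays true
#' non-wear blocks of at least 90 minutes of zeros (optionally containing
#' a 1-2-min artifact spike) so non-wear detection has true positives.
#' No records are emitted outside the waking window. The generating state
#' labels and inserted non-wear blocks are attached as
#' `attr(series, "truth")`.
#'
#' @param profile an activity profile (see [sample_subject()]).
#' @param days number of recording days.
#' @param start_date first day (Date or string).
#' @param subject_id,visit identity fields of the returned series.
#' @return an [epoch_series()] with a `truth` attribute.
#' @export
simulate_epoch_series <- function(profile, days = 7,
                                  start_date = "2022-03-07",
                                  subject_id = "S001", visit = "baseline") {
  n_day <- profile$waking_minutes
  rho <- profile$persistence
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  state_names <- c("sedentary", "light", "moderate", "vigorous")
  all_time <- vector("list", days)
  all_states <- vector("list", days)
  blocks <- list()
  ax1 <- ax2 <- ax3 <- stp <- vector("list", days)
  cm <- profile$counts
  for (d in seq_len(days)) {
    day_start <- t0 + (d - 1) * 86400 + profile$waking_start * 3600
    pi_d <- profile_occupancy(profile,
                              stats::rnorm(1, 0, profile$day_sd_sed),
                              stats::rnorm(1, 0, profile$day_sd_mvpa))
    # exchangeable-mixture chain: redraw from pi_d on switch minutes
    sw <- stats::runif(n_day) < (1 - rho)
    sw[1] <- TRUE
    fresh <- sample.int(4, n_day, replace = TRUE, prob = pi_d)
    st <- fresh[cummax(seq_len(n_day) * sw)]
    # overlay true non-wear blocks (0 = non-wear marker)
    if (stats::runif(1) < profile$nonwear$long_prob) {
      len <- 600L
      from <- sample.int(n_day - len + 1L, 1)
      st[from:(from + len - 1L)] <- 0L
      blocks[[length(blocks) + 1]] <- c(day = d, from = from, len = len)
    } else if (stats::runif(1) < profile$nonwear$block_prob) {
      len <- sample(profile$nonwear$block_min:profile$nonwear$block_max, 1)
      from <- sample.int(n_day - len + 1L, 1)
      st[from:(from + len - 1L)] <- 0L
      blocks[[length(blocks) + 1]] <- c(day = d, from = from, len = len)
    }
    a1 <- numeric(n_day)
    for (s in 1:4) {
      i <- which(st == s)
      if (length(i) == 0) next
      u <- stats::runif(length(i),
                        stats::plnorm(cm$lo[s], cm$meanlog[s], cm$sdlog[s]),
                        stats::plnorm(cm$hi[s], cm$meanlog[s], cm$sdlog[s]))
      a1[i] <- ceiling(stats::qlnorm(u, cm$meanlog[s], cm$sdlog[s]))
    }
    a2 <- round(a1 * profile$lateral$scale2 *
                  exp(stats::rnorm(n_day, 0, profile$lateral$sdlog)))
    a3 <- round(a1 * profile$lateral$scale3 *
                  exp(stats::rnorm(n_day, 0, profile$lateral$sdlog)))
    sp <- stats::rpois(n_day, profile$step_rates[pmax(st, 1L)])
    # an artifact spike inside a non-wear block (flanked by >= 30 min zeros)
    if (length(blocks) > 0) {
      b <- blocks[[length(blocks)]]
      if (b["day"] == d && stats::runif(1) < profile$nonwear$spike_prob) {
        slen <- sample(1:2, 1)
        off <- sample(31:(b["len"] - 30 - slen), 1)
        i <- (b["from"] + off):(b["from"] + off + slen - 1)
        a1[i] <- sample(20:300, slen, replace = TRUE)
        a2[i] <- round(a1[i] * 0.5)
        a3[i] <- round(a1[i] * 0.4)
        st[i] <- -1L  # spike marker inside non-wear
      }
    }
    all_time[[d]] <- day_start + (seq_len(n_day) - 1) * 60
    all_states[[d]] <- st
    ax1[[d]] <- a1; ax2[[d]] <- a2; ax3[[d]] <- a3; stp[[d]] <- sp
  }
  st_all <- unlist(all_states)
  series <- epoch_series(
    time = do.call(c, all_time),
    axis1 = unlist(ax1), axis2 = unlist(ax2), axis3 = unlist(ax3),
    steps = unlist(stp), subject_id = subject_id,
    placement = profile$placement, visit = visit, epoch_length = 60L
  )
  labels <- c("nonwear_spike", "nonwear", state_names)[st_all + 2L]
  attr(series, "truth") <- list(
    states = labels,
    nonwear_blocks = if (length(blocks)) {
      as.data.frame(do.call(rbind, blocks))
    } else data.frame(day = integer(), from = integer(), len = integer())
  )
  series
}

#' Simulate a full two-visit, two-placement cohort
#'
#' Draws every subject, simulates all four recordings per subject, and
#' assembles the clinical table, the diary (worn intervals equal to the
#' waking window of each recording day) and the per-series ground truth.
#' Identical config and seed give a bit-identical cohort.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with `clinical` (data.frame),
#'   `series` (named list, names `subject_placement_visit`), `diary`
#'   (`diary_log`), `truth` (per-subject latents), `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- c(sprintf("FA%03d", seq_len(config$n_frda)),
           sprintf("CT%03d", seq_len(config$n_ctr)))
  groups <- rep(c("FRDA", "CTR"), c(config$n_frda, config$n_ctr))
  clinical <- list()
  series <- list()
  truth <- list()
  for (k in seq_along(ids)) {
    subj <- sample_subject(groups[k], config, ids[k])
    clinical[[k]] <- subj$record
    truth[[ids[k]]] <- subj$latent
    for (visit in c("baseline", "followup")) {
      for (pl in c("waist", "wrist")) {
        key <- paste(ids[k], pl, visit, sep = "_")
        series[[key]] <- simulate_epoch_series(
          subj$profiles[[visit]][[pl]], days = config$days,
          start_date = config$start_date, subject_id = ids[k], visit = visit
        )
      }
    }
  }
  t0 <- as.Date(config$start_date)
  diary <- data.frame(
    subject_id = rep(ids, each = config$days),
    on = as.POSIXct(paste(rep(t0 + seq_len(config$days) - 1, length(ids)),
                          sprintf("%02d:00:00", config$waking_start)),
                    tz = "UTC"),
    off = as.POSIXct(paste(rep(t0 + seq_len(config$days) - 1, length(ids)),
                           "00:00:00"), tz = "UTC") +
      (config$waking_start + config$waking_hours) * 3600
  )
  diary <- diary[order(diary$subject_id, diary$on), ]
  class(diary) <- c("diary_log", "data.frame")
  structure(list(clinical = do.call(rbind, clinical), series = series,
                 diary = diary, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d FRDA + %d CTR, %d days x 2 visits x 2 placements (%d series)\n",
              x$config$n_frda, x$config$n_ctr, x$config$days,
              length(x$series)))
  invisible(x)
}

#' Write a synthetic cohort through the public file interfaces
#'
#' One epoch CSV per recording, plus `diary.csv`, `clinical.csv` and a
#' `truth.json` with the latent severities and generator config, so the
#' pipeline can be exercised end-to-end from files.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort$series)) {
    write_epoch_csv(cohort$series[[key]],
                    file.path(dir, paste0(key, ".csv")))
  }
  write_diary_csv(cohort$diary, file.path(dir, "diary.csv"))
  write_clinical_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg,
         latent = cohort$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
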