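#' Specification of a synthetic wearable cohort
#'
#' Encodes the study conditions the generator emulates: 35 days of data on
#' each side of a self-reported disruption date, irregular heart-rate
#' sampling later averaged into 5-min bins, nightly charging gaps of six or
#' more hours coinciding with sleep, an activity drop of about 18% after the
#' event, and per-age-group post-event phase shifts (means -0.93, +1.26,
#' +0.05 h for under-30, 30-45, over-45). A configurable fraction of
#' subjects (default 51/72) additionally desynchronize: their heart-rate
#' phase drifts away from the activity schedule after the event.
#'
#' @param n_per_group named integer vector over groups
#'   `under30, 30to45, over45`.
#' @param days_pre,days_post window lengths (defaults 35/35).
#' @param start_date Date of the first data day.
#' @param group_shift_mean,group_shift_sd named numeric vectors of the
#'   post-event schedule/phase shift distribution per group, hours.
#' @param desync_fraction fraction of subjects given a nonzero post-event
#'   heart-rate phase drift.
#' @param desync_range range (h/day) the per-subject drift rate is drawn
#'   from (positive = CRHR delaying), capped cumulatively at `desync_cap_h`.
#' @param desync_cap_h cumulative drift cap, hours.
#' @param steps_per_day mean daily step total before the event.
#' @param post_activity_factor multiplier on daily steps after the event.
#' @param sleep_onset_h,sleep_duration_h sleep window (clock hours).
#' @param gap_prob nightly probability of a charging gap.
#' @param gap_min_h,gap_max_h charging-gap length range (>= 6 h).
#' @param dropout daytime probability that an individual HR reading is lost.
#' @param hr_sigma,hr_k_ar AR(1) noise defaults for subjects' heart rate.
#' @param seed mandatory integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(under30 = 4, `30to45` = 5, over45 = 3),
                        days_pre = 35, days_post = 35,
                        start_date = as.Date("2020-02-08"),
                        group_shift_mean = c(under30 = -0.93, `30to45` = 1.26, over45 = 0.05),
                        group_shift_sd = c(under30 = 0.85, `30to45` = 0.45, over45 = 0.53),
                        desync_fraction = 51 / 72,
                        desync_range = c(0.05, 0.25), desync_cap_h = 6,
                        steps_per_day = 7000, post_activity_factor = 0.82,
                        sleep_onset_h = 23.5, sleep_duration_h = 8,
                        gap_prob = 1, gap_min_h = 6, gap_max_h = 8,
                        dropout = 0.1, hr_sigma = 2.5, hr_k_ar = 0.5,
                        seed) {
  if (missing(seed)) stop("cohort_spec requires a seed")
  if (gap_max_h >= 24) stop("charging gap cannot exceed 24 h")
  if (gap_min_h < 6) stop("charging gaps are defined as >= 6 h")
  stopifnot(all(n_per_group >= 0), days_pre > 0, days_post > 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Ground truth for one synthetic subject
#'
#' @param subject_id id string.
#' @param group age-group label.
#' @param true_params a `cosinor_params` (the subject's true HR model).
#' @param post_event_shift_h signed schedule/phase shift after the event, h.
#' @param desync_h_per_day post-event drift of the HR phase only, h/day
#'   (|rate| <= 1).
#' @return a `subject_truth` list.
#' @export
subject_truth <- function(subject_id, group, true_params,
                          post_event_shift_h = 0, desync_h_per_day = 0) {
  if (abs(desync_h_per_day) > 1) stop("desync drift must satisfy |rate| <= 1 h/day")
  structure(list(subject_id = subject_id, group = group,
                 true_params = true_params,
                 post_event_shift_h = post_event_shift_h,
                 desync_h_per_day = desync_h_per_day),
            class = "subject_truth")
}

#' True heart-rate phase on a given day
#'
#' Before the event the phase is the subject's `c`; from the event day on it
#' is `c + post_event_shift_h + min(desync_rate * days_since_event, cap)`.
#'
#' @param truth a `subject_truth`.
#' @param day_index 1-based day index.
#' @param spec the `cohort_spec` (for the event position and drift cap).
#' @return clock hours in `[0, 24)`.
#' @export
true_phase_on_day <- function(truth, day_index, spec) {
  ev <- spec$days_pre + 1L   # first shifted day
  base <- truth$true_params[["c"]]
  if (day_index < ev) return(wrap24(base))
  drift <- truth$desync_h_per_day * (day_index - ev)
  drift <- sign(drift) * min(abs(drift), spec$desync_cap_h)
  wrap24(base + truth$post_event_shift_h + drift)
}

# smooth daytime activity profile for one day; returns steps per 5-min bin
day_activity_profile <- function(spec, shift_h, total_steps) {
  bpd <- 288L
  mid_h <- ((0:(bpd - 1)) + 0.5) * 5 / 60
  onset <- spec$sleep_onset_h + shift_h
  asleep <- in_circular_interval(mid_h, wrap24(onset),
                                 wrap24(onset + spec$sleep_duration_h))
  w <- stats::dnorm(circular_diff(mid_h, wrap24(15 + shift_h)), 0, 3.5)
  w[asleep] <- 0
  if (sum(w) == 0) return(rep(0, bpd))
  round(total_steps * w / sum(w))
}

#' Generate one subject's raw wearable records from known truth
#'
#' Builds a smooth daytime activity bump (zero during the sleep window),
#' samples heart rate on an irregular grid (inter-reading intervals
#' log-uniform between 1 and 10 minutes) from the cosinor model with AR(1)
#' noise at the day's true phase, then applies the schedule shift and
#' heart-rate phase drift after the event, deletes a nightly charging gap of
#' 6+ hours overlapping sleep, and drops daytime readings at random.
#' Deterministic given `seed`.
#'
#' @param truth a `subject_truth`.
#' @param spec a `cohort_spec`.
#' @param seed integer seed for this subject.
#' @return list with `records` (a `wearable_records`), `truth`, and
#'   `true_phase_by_day` (numeric vector, one entry per generated day).
#' @export
generate_subject <- function(truth, spec, seed) {
  set.seed(as.integer(seed))
  n_days <- spec$days_pre + spec$days_post
  ev <- spec$days_pre + 1L
  p <- truth$true_params
  day0 <- as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC")

  ts_all <- list(); hr_all <- list(); st_all <- list()
  phase_by_day <- numeric(n_days)
  gaps <- matrix(NA_real_, n_days, 2)  # absolute hours [start, end)

  for (d in seq_len(n_days)) {
    shift <- if (d >= ev) truth$post_event_shift_h else 0
    phase_by_day[d] <- true_phase_on_day(truth, d, spec)
    total <- spec$steps_per_day * (if (d >= ev) spec$post_activity_factor else 1) *
      exp(stats::rnorm(1, 0, 0.15))
    act_bins <- day_activity_profile(spec, shift, total)

    # steps stream: one record per bin boundary
    st_t <- (d - 1) * 24 + (0:287) * 5 / 60
    # irregular HR sampling: log-uniform inter-reading gaps of 1-10 min
    t <- stats::runif(1, 0, 2 / 60)
    hr_t <- numeric(0)
    while (t < 24) {
      hr_t <- c(hr_t, t)
      t <- t + exp(stats::runif(1, log(1), log(10))) / 60
    }
    act_at <- act_bins[pmin(floor(hr_t / (5 / 60)) + 1L, 288L)]
    mu <- p[["a"]] - p[["b"]] * cos(pi / 12 * (hr_t - phase_by_day[d])) +
      p[["d"]] * act_at
    eps <- numeric(length(hr_t))
    s0 <- p[["sigma"]] / sqrt(1 - p[["k_ar"]]^2)
    eps[1] <- stats::rnorm(1, 0, s0)
    if (length(eps) > 1) {
      inn <- stats::rnorm(length(eps) - 1, 0, p[["sigma"]])
      for (i in 2:length(eps)) eps[i] <- p[["k_ar"]] * eps[i - 1] + inn[i - 1]
    }
    hr_all[[d]] <- mu + eps
    ts_all[[d]] <- (d - 1) * 24 + hr_t
    st_all[[d]] <- st_t

    # nightly charging gap inside the sleep window
    if (stats::runif(1) < spec$gap_prob) {
      len <- stats::runif(1, spec$gap_min_h, spec$gap_max_h)
      onset <- spec$sleep_onset_h + shift
      start <- (d - 1) * 24 + onset + stats::runif(1, 0, 0.5)
      gaps[d, ] <- c(start, start + len)
    }
    attr(st_all[[d]], "steps") <- act_bins
  }

  hr_time <- unlist(ts_all); hr_val <- unlist(hr_all)
  st_time <- unlist(st_all)
  st_val <- unlist(lapply(st_all, attr, "steps"))

  in_gap <- function(th) {
    out <- rep(FALSE, length(th))
    for (d in seq_len(n_days)) {
      if (!is.na(gaps[d, 1])) out <- out | (th >= gaps[d, 1] & th < gaps[d, 2])
    }
    out
  }
  keep_hr <- !in_gap(hr_time) & stats::runif(length(hr_time)) >= spec$dropout
  keep_st <- !in_gap(st_time)

  recs <- rbind(
    data.frame(timestamp = day0 + round(hr_time[keep_hr] * 3600),
               heart_rate = hr_val[keep_hr], steps = NA_real_),
    data.frame(timestamp = day0 + round(st_time[keep_st] * 3600),
               heart_rate = NA_real_, steps = st_val[keep_st])
  )
  records <- wearable_records(recs$timestamp, recs$heart_rate, recs$steps)
  list(records = records, truth = truth, true_phase_by_day = phase_by_day,
       event_date = spec$start_date + spec$days_pre)
}

#' Generate a full cohort with truth table
#'
#' Per-group post-event shifts are drawn from `Normal(mean_g, sd_g)` with the
#' group defaults; a `desync_fraction` of subjects (deterministically the
#' first ones of a seeded permutation) receive a positive heart-rate phase
#' drift after the event. Per-subject cosinor parameters are drawn from
#' physiologic ranges (basal HR ~ N(72, 8), amplitude ~ N(10, 2) truncated
#' above 3 bpm, HR minimum between 03:00 and 07:00).
#'
#' @param spec a `cohort_spec`.
#' @return list with `subjects` (named list of [generate_subject()] outputs),
#'   `truth` (data frame, one row per subject), `meta` (data frame
#'   `subject_id, age_group, event_date`).
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  groups <- rep(names(spec$n_per_group), times = spec$n_per_group)
  n <- length(groups)
  if (n == 0L) {
    return(list(subjects = list(),
                truth = data.frame(), meta = data.frame()))
  }
  ids <- sprintf("S%03d", seq_len(n))
  n_desync <- round(spec$desync_fraction * n)
  desync_flag <- rep(FALSE, n)
  desync_flag[sample.int(n, n_desync)] <- TRUE

  subjects <- list(); truth_rows <- list(); meta_rows <- list()
  for (i in seq_len(n)) {
    g <- groups[i]
    shift <- stats::rnorm(1, spec$group_shift_mean[[g]], spec$group_shift_sd[[g]])
    drift <- if (desync_flag[i]) stats::runif(1, spec$desync_range[1], spec$desync_range[2]) else 0
    pars <- cosinor_params(
      a = stats::rnorm(1, 72, 8),
      b = max(3, stats::rnorm(1, 10, 2)),
      c = stats::runif(1, 3, 7),
      d = max(0, stats::rnorm(1, 0.05, 0.02)),
      k_ar = spec$hr_k_ar, sigma = spec$hr_sigma
    )
    tr <- subject_truth(ids[i], g, pars, post_event_shift_h = shift,
                        desync_h_per_day = drift)
    sub_seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    subjects[[ids[i]]] <- generate_subject(tr, spec, sub_seed)
    truth_rows[[i]] <- data.frame(
      subject_id = ids[i], group = g,
      a = pars[["a"]], b = pars[["b"]], c = pars[["c"]], d = pars[["d"]],
      k_ar = pars[["k_ar"]], sigma = pars[["sigma"]],
      post_event_shift_h = shift, desync_h_per_day = drift,
      desync = desync_flag[i]
    )
    meta_rows[[i]] <- data.frame(subject_id = ids[i], age_group = g,
                                 event_date = spec$start_date + spec$days_pre)
  }
  list(subjects = subjects,
       truth = do.call(rbind, truth_rows),
       meta = do.call(rbind, meta_rows))
}

#' Recovery metrics of a pipeline run against generator truth
#'
#' @param cohort output of [generate_cohort()] (carries the truth table).
#' @param tracks named list of estimated `phase_track`s keyed by subject id.
#' @param spec the `cohort_spec` used.
#' @param desync_rate_threshold estimated post-event phase drift (h/day) above
#'   which a subject is called desynchronizing.
#' @return list with `phase_rmse_h` (per subject, circular), `ci_coverage`
#'   (pooled fraction of days whose interval contains the true phase),
#'   `shift_error_by_group` (recovered minus true group mean shift, hours),
#'   and `desync_confusion` (2x2 table of estimated vs true desync flags).
#' @export
truth_report <- function(cohort, tracks, spec, desync_rate_threshold = 0.025) {
  if (is.null(cohort$truth) || nrow(cohort$truth) == 0L) {
    stop("truth table missing from cohort")
  }
  if (!all(names(tracks) %in% cohort$truth$subject_id)) {
    stop("track subject ids do not match the truth table")
  }
  ev_date <- spec$start_date + spec$days_pre
  rmse <- c(); covered <- c()
  est_shift <- c(); true_shift <- c(); grp <- c()
  est_desync <- c(); true_desync <- c()
  for (sid in names(tracks)) {
    trow <- cohort$truth[cohort$truth$subject_id == sid, ]
    tr_obj <- subject_truth(sid, trow$group,
                            cosinor_params(trow$a, trow$b, trow$c, trow$d,
                                           trow$k_ar, trow$sigma),
                            trow$post_event_shift_h, trow$desync_h_per_day)
    track <- tracks[[sid]]
    track <- track[!track$skipped, , drop = FALSE]
    day_idx <- as.integer(track$date - spec$start_date) + 1L
    truth_phase <- vapply(day_idx, function(d) true_phase_on_day(tr_obj, d, spec),
                          numeric(1))
    err <- circular_diff(track$phase_h, truth_phase)
    rmse[sid] <- sqrt(mean(err^2))
    covered <- c(covered, mapply(function(p, lo, hi) in_circular_interval(p, lo, hi),
                                 truth_phase, track$ci_low_h, track$ci_high_h))

    pre <- track[track$date < ev_date, ]
    post <- track[track$date >= ev_date, ]
    if (nrow(pre) >= 2 && nrow(post) >= 2) {
      est_shift[sid] <- circular_diff(circular_mean(post$phase_h),
                                      circular_mean(pre$phase_h))
      # truth evaluated over the same days, so desync drift is not
      # mistaken for estimator error
      tp_pre <- truth_phase[track$date < ev_date]
      tp_post <- truth_phase[track$date >= ev_date]
      true_shift[sid] <- circular_diff(circular_mean(tp_post),
                                       circular_mean(tp_pre))
      grp[sid] <- trow$group
      # drift rate: slope of unwrapped post-window phase vs day
      dev <- circular_diff(post$phase_h, circular_mean(post$phase_h))
      dd <- as.numeric(post$date - post$date[1])
      est_desync[sid] <- unname(stats::coef(stats::lm(dev ~ dd))[2]) >
        desync_rate_threshold
      true_desync[sid] <- trow$desync_h_per_day > 0
    }
  }
  shift_err <- if (length(est_shift)) {
    vapply(split(est_shift - true_shift, grp), mean, numeric(1))
  } else numeric(0)
  confusion <- if (length(est_desync)) {
    table(estimated = est_desync, truth = true_desync)
  } else NULL
  list(phase_rmse_h = rmse, ci_coverage = mean(covered),
       shift_error_by_group = shift_err, desync_confusion = confusion)
}

#' Simulate one day of binned data directly from the cosinor model
#'
#' Bin-level forward simulation used for calibration studies: a waking
#' window of usable bins with both streams, activity drawn as a non-negative
#' noisy daytime level, heart rate from the cosinor prediction plus
#' stationary AR(1) noise. Unlike [generate_subject()] there is no
#' irregular-sampling layer, so the fitted likelihood is exactly the
#' generating model.
#'
#' @param params a `cosinor_params`.
#' @param seed integer seed.
#' @param wake window of usable bins, clock hours `c(start, end)`.
#' @param date calendar date label.
#' @return a one-day `binned_series`.
#' @export
simulate_cosinor_day <- function(params, seed, wake = c(7.5, 23.5),
                                 date = as.Date("2020-03-01")) {
  set.seed(as.integer(seed))
  bpd <- 288L
  t <- ((0:(bpd - 1)) + 0.5) * 5 / 60
  awake <- t >= wake[1] & t < wake[2]
  act <- ifelse(awake, pmax(0, stats::rnorm(bpd, 40, 25)), 0)
  mu <- hr_model_predict(params, t, act)
  k <- params[["k_ar"]]; s <- params[["sigma"]]
  eps <- numeric(bpd)
  eps[1] <- stats::rnorm(1, 0, s / sqrt(1 - k^2))
  inn <- stats::rnorm(bpd - 1, 0, s)
  for (i in 2:bpd) eps[i] <- k * eps[i - 1] + inn[i - 1]
  df <- data.frame(date = rep(date, bpd), bin_index = 0:(bpd - 1),
                   hr = ifelse(awake, mu + eps, NA_real_), steps = act,
                   wear = awake, sleep = FALSE)
  structure(df, class = c("binned_series", "data.frame"), bin_width = 5L)
}

#' Draw cosinor parameters from the base prior
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @return list of `cosinor_params`.
#' @export
draw_prior_params <- function(n, seed) {
  set.seed(as.integer(seed))
  s <- crhr_base_prior()$sample(n)
  s[, "sigma"] <- pmax(s[, "sigma"], 1e-2)
  s[, "k_ar"] <- pmin(s[, "k_ar"], 0.99)
  lapply(seq_len(n), function(i) {
    cosinor_params(s[i, 1], s[i, 2], s[i, 3], s[i, 4], s[i, 5], s[i, 6])
  })
}
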