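test_that("circular_diff agrees with a brute-force candidate search", {
  expect_equal(circular_diff(5, 5), 0)
  expect_equal(circular_diff(23, 1), -2)
  expect_equal(circular_diff(1, 23), 2)
  set.seed(8)
  t1 <- runif(10000, 0, 24); t2 <- runif(10000, 0, 24)
  got <- circular_diff(t1, t2)
  # oracle: smallest |t1 - t2 + 24k| over k in -1, 0, 1
  cands <- cbind(t1 - t2 - 24, t1 - t2, t1 - t2 + 24)
  oracle <- cands[cbind(seq_len(10000), apply(abs(cands), 1, which.min))]
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got > -12 & got <= 12))
})

test_that("phase arithmetic is invariant under a +24 h relabeling", {
  set.seed(81)
  t1 <- runif(200, 0, 24); t2 <- runif(200, 0, 24)
  expect_equal(circular_diff(wrap24(t1 + 24), t2), circular_diff(t1, t2))
  expect_equal(circular_mean(wrap24(t1 + 24)), circular_mean(t1))
})

test_that("day_alignment handles wrapped intervals and matches oracles", {
  expect_true(day_alignment(5, 4, 6, 0))              # midpoint
  # interval that lands on (23.5, 0.5) after the -4.4 h shift: wraps midnight
  expect_true(day_alignment(23.8, wrap24(23.5 + 4.4), wrap24(0.5 + 4.4), -4.4))
  expect_false(day_alignment(7, 4, 6, 0))
  expect_error(day_alignment(25, 4, 6, 0), "\\[0, 24\\)")

  set.seed(9)
  n <- 10000
  lo <- runif(n, 0, 24)
  width <- runif(n, 0, 12)
  hi <- wrap24(lo + width)
  d <- runif(n, 0, 24)
  sh <- runif(n, -6, 6)
  got <- mapply(function(di, l, h, s) day_alignment(di, l, h, s), d, lo, hi, sh)
  # independent oracle: membership via unwrapped candidates d + 24k
  oracle <- mapply(function(di, l, w, s) {
    lo_s <- (l + s) %% 24
    any(abs(di + c(-24, 0, 24) - lo_s - w / 2) <= w / 2 + 1e-9)
  }, d, lo, width, sh)
  expect_equal(got, oracle)

  # fine-grid membership scan on a subsample
  idx <- sample(n, 200)
  grid_oracle <- mapply(function(di, l, h, s) {
    oracle_in_arc(di, l + s, h + s)
  }, d[idx], lo[idx], hi[idx], sh[idx])
  expect_equal(got[idx], grid_oracle)
})

test_that("percent aligned counts only days where both markers exist", {
  dates <- as.Date("2020-03-01") + 0:9
  dl <- data.frame(day = 1:10, date = dates, cbtmin_h = 5, dlmo_h = rep(22, 10))
  class(dl) <- c("dlmo_track", "data.frame")
  # CRHR interval centered at DLMO + 4.4 so shift -4.4 centers it; 7 of 10 aligned
  ph <- rep(22 + 4.4, 10); ph[8:10] <- wrap24(22 + 4.4 + 5)
  tr <- data.frame(date = dates, phase_h = wrap24(ph),
                   ci_low_h = wrap24(ph - 1), ci_high_h = wrap24(ph + 1),
                   half_width_h = 1, n_bins = 100, skipped = FALSE)
  class(tr) <- c("phase_track", "data.frame")
  res <- percent_days_aligned(dl, tr, dates)
  expect_equal(res$pct, 70)
  expect_equal(res$n_days, 10L)

  # dropping days where a marker is missing leaves the percentage unchanged
  tr2 <- tr; tr2$skipped[3] <- TRUE
  res2 <- percent_days_aligned(dl[-3, ], tr2, dates)
  aligned_kept <- res$flags$aligned[-3]
  expect_equal(res2$pct, 100 * mean(aligned_kept))
  expect_equal(res2$n_days, 9L)

  empty <- percent_days_aligned(dl, tr, as.Date("2021-01-01") + 0:4)
  expect_true(is.na(empty$pct))
})

test_that("self-consistency: zero shift and identical tracks align 100%", {
  dates <- as.Date("2020-03-01") + 0:9
  ph <- wrap24(runif(10, 0, 24))
  dl <- data.frame(day = 1:10, date = dates, cbtmin_h = ph, dlmo_h = ph)
  class(dl) <- c("dlmo_track", "data.frame")
  tr <- data.frame(date = dates, phase_h = ph, ci_low_h = wrap24(ph - 0.5),
                   ci_high_h = wrap24(ph + 0.5), half_width_h = 0.5,
                   n_bins = 100, skipped = FALSE)
  class(tr) <- c("phase_track", "data.frame")
  cfg <- alignment_config(crhr_shift_h = 0)
  expect_equal(percent_days_aligned(dl, tr, dates, cfg)$pct, 100)
})

test_that("the paired pre/post test detects an imposed alignment drop", {
  set.seed(11)
  hits <- 0L
  for (rep in 1:20) {
    results <- lapply(1:50, function(i) {
      pre <- rnorm(1, 78, 8)
      post <- pre - 10 + rnorm(1, 0, 8)
      structure(list(pct_aligned_pre = pre, pct_aligned_post = post),
                class = "alignment_result")
    })
    out <- pre_post_alignment_test(results)
    if (out$p_value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 18L)   # >= 90% power at n = 50, 10-point drop, sd 8
})

test_that("degenerate and undersized paired tests are handled", {
  same <- lapply(1:5, function(i) structure(list(pct_aligned_pre = 70,
                                                 pct_aligned_post = 70),
                                            class = "alignment_result"))
  out <- pre_post_alignment_test(same)
  expect_true(out$degenerate)
  expect_equal(out$p_value, 1)
  one <- same[1]
  expect_error(pre_post_alignment_test(one), "insufficient")
})

test_that("group phase shifts are recovered circularly", {
  dates <- as.Date("2020-03-01") + 0:19
  ev <- as.Date("2020-03-11")
  mk_track <- function(pre_phase, post_phase) {
    ph <- wrap24(c(rep(pre_phase, 10), rep(post_phase, 10)))
    tr <- data.frame(date = dates, phase_h = ph, ci_low_h = wrap24(ph - 1),
                     ci_high_h = wrap24(ph + 1), half_width_h = 1,
                     n_bins = 150, skipped = FALSE)
    class(tr) <- c("phase_track", "data.frame")
    tr
  }
  # phases wrapping midnight: pre 23.5, post 0.5 is a +1 h shift, not -23
  tracks <- list(s1 = mk_track(23.5, 0.5), s2 = mk_track(4, 5.26),
                 s3 = mk_track(6, 6))
  meta <- data.frame(subject_id = c("s1", "s2", "s3"),
                     age_group = c("30to45", "30to45", "over45"),
                     event_date = ev)
  cfg <- alignment_config(pre_window_days = 10, post_window_days = 10)
  out <- phase_shift_by_group(tracks, meta, cfg)
  s <- out$subjects
  expect_equal(s$shift_h[s$subject_id == "s1"], 1, tolerance = 1e-9)
  expect_equal(s$shift_h[s$subject_id == "s2"], 1.26, tolerance = 1e-9)
  expect_equal(s$shift_h[s$subject_id == "s3"], 0, tolerance = 1e-9)
  g <- out$groups
  expect_equal(g$mean_shift_h[g$group == "30to45"], 1.13, tolerance = 1e-9)
  expect_equal(g$n[g$group == "over45"], 1L)
})

test_that("subjects with too few estimated days are excluded", {
  dates <- as.Date("2020-03-01") + 0:19
  ev <- as.Date("2020-03-11")
  ph <- rep(5, 20)
  tr <- data.frame(date = dates, phase_h = ph, ci_low_h = ph - 1,
                   ci_high_h = ph + 1, half_width_h = 1, n_bins = 100,
                   skipped = c(rep(TRUE, 8), rep(FALSE, 12)))
  class(tr) <- c("phase_track", "data.frame")
  meta <- data.frame(subject_id = "s1", age_group = "under30", event_date = ev)
  cfg <- alignment_config(pre_window_days = 10, post_window_days = 10,
                          min_days_per_window = 5)
  expect_error(suppressMessages(phase_shift_by_group(list(s1 = tr), meta, cfg)),
               "no subjects")
})

test_that("the uncertainty-data correlation behaves at its edges", {
  x <- 1:10
  out <- uncertainty_weartime_correlation(10 - x, x)    # exact decreasing line
  expect_equal(out$r, -1)
  expect_error(uncertainty_weartime_correlation(c(1, 2), c(2, 1)), "at least 3")
  expect_error(uncertainty_weartime_correlation(rep(1, 5), 1:5), "zero variance")
  set.seed(3)
  null_r <- replicate(40, uncertainty_weartime_correlation(rnorm(1000), rnorm(1000))$r)
  expect_gte(mean(abs(null_r) < 0.1), 0.95)
})

test_that("cohort mean profiles average days then subjects with SEM", {
  d1 <- make_binned_day(rep(60, 288), rep(10, 288), date = as.Date("2020-03-01"))
  d2 <- make_binned_day(rep(70, 288), rep(20, 288), date = as.Date("2020-03-01"))
  series <- list(s1 = d1, s2 = d2)
  evs <- c(s1 = as.Date("2020-03-05"), s2 = as.Date("2020-03-05"))
  prof <- mean_profiles(series, evs, window_days = 10)
  expect_equal(unique(prof$pre$hr_mean), 65)
  expect_equal(unique(prof$pre$hr_sem), 5)        # sd(60,70)/sqrt(2) = 5
  expect_equal(unique(prof$pre$act_mean), 15)
  expect_equal(nrow(prof$post), 0L)               # empty window -> empty profile

  # single subject, single day: profile equals the day, SEM undefined
  prof1 <- mean_profiles(series["s1"], evs["s1"], window_days = 10)
  expect_equal(unique(prof1$pre$hr_mean), 60)
  expect_true(all(is.na(prof1$pre$hr_sem)))

  # missing bins propagate as missing, not zero
  d3 <- d1; d3$hr[1:10] <- NA
  prof3 <- mean_profiles(list(s1 = d3), evs["s1"], window_days = 10)
  expect_true(all(is.nan(prof3$pre$hr_mean[1:10])))
  expect_equal(unique(prof3$pre$hr_mean[11:288]), 60)
})
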