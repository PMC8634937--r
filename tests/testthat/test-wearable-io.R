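test_that("generic CSV reads in time order and rejects implausible rows", {
  df <- data.frame(
    timestamp = c("2020-03-01 12:03:00", "2020-03-01 12:01:00", "2020-03-01 12:05:00"),
    heart_rate = c(70, 60, 80), steps = c(NA, NA, NA)
  )
  path <- write_generic_csv(df)
  rec <- read_wearable_csv(path)
  expect_equal(nrow(rec), 3L)
  # oracle: an independently scripted sort of the raw rows
  expect_equal(rec$heart_rate, df$heart_rate[order(df$timestamp)])
  expect_true(!is.unsorted(rec$timestamp))

  df$heart_rate[1] <- 300   # physiologically impossible
  path <- write_generic_csv(df)
  expect_message(rec <- read_wearable_csv(path), "1 malformed")
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "n_rejected"), 1L)
})

test_that("unreadable and empty inputs are fatal", {
  expect_error(read_wearable_csv("no/such/file.csv"), "cannot read")
  df <- data.frame(timestamp = "2020-03-01 10:00:00", heart_rate = 300, steps = NA)
  path <- write_generic_csv(df)
  expect_error(suppressMessages(read_wearable_csv(path)), "no valid rows")
})

test_that("alternate dialects map their column names", {
  dir <- withr::local_tempdir()
  df <- data.frame(startDate = c("2020-03-01 08:00:00", "2020-03-01 08:10:00"),
                   heartRate = c(62, 64), stepCount = c(10, 0))
  p <- file.path(dir, "a.csv"); utils::write.csv(df, p, row.names = FALSE)
  rec <- read_wearable_csv(p, dialect = "applehealth_like")
  expect_equal(rec$heart_rate, c(62, 64))
  expect_equal(rec$steps, c(10, 0))
})

test_that("binning averages heart rate and sums steps within half-open bins", {
  ts <- as.POSIXct(c("2020-03-01 12:01:00", "2020-03-01 12:03:00",
                     "2020-03-01 12:04:59", "2020-03-01 12:05:00"), tz = "UTC")
  rec <- wearable_records(ts, heart_rate = c(60, 70, NA, 99),
                          steps = c(NA, 12, 30, NA))
  b <- bin_series(rec)
  i1200 <- which(b$bin_index == 12 * 12)       # 12:00 bin
  expect_equal(b$hr[i1200], 65)                # arithmetic-mean oracle
  expect_equal(b$steps[i1200], 42)             # sum of steps
  expect_equal(b$hr[i1200 + 1], 99)            # 12:05 reading in next bin
  expect_equal(nrow(b), 288L)
  expect_equal(sum(b$wear), 2L)
})

test_that("a single record yields one populated bin among 288", {
  rec <- wearable_records(as.POSIXct("2020-03-01 00:00:00", tz = "UTC"),
                          heart_rate = 55)
  b <- bin_series(rec)
  expect_equal(nrow(b), 288L)
  expect_equal(sum(!is.na(b$hr)), 1L)
  expect_equal(sum(b$wear), 1L)
  expect_error(bin_series(rec[0, ]), "empty")
})

test_that("binning conserves step totals and is idempotent at the same width", {
  set.seed(4)
  n <- 500
  ts <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC") + sort(runif(n, 0, 2 * 86400))
  steps <- rpois(n, 5)
  rec <- wearable_records(ts, steps = steps)
  b <- bin_series(rec)
  expect_equal(sum(b$steps, na.rm = TRUE), sum(steps))  # conservation

  # re-bin the binned values placed at bin starts: identity
  populated <- !is.na(b$steps)
  ts2 <- as.POSIXct(paste(b$date[populated], "00:00:00"), tz = "UTC") +
    b$bin_index[populated] * 300
  rec2 <- wearable_records(ts2, steps = b$steps[populated])
  b2 <- bin_series(rec2)
  expect_equal(b2$steps, b$steps)
})

test_that("sleep detection flags the longest nightly zero-activity run", {
  steps <- rep(20, 288); hr <- rep(70, 288)
  night <- c(1:(7 * 12), (23 * 12 + 1):288)    # 23:00-07:00
  steps[night] <- 0
  b <- rbind(make_binned_day(hr, steps),
             make_binned_day(hr, steps, date = as.Date("2020-03-02")))
  class(b) <- c("binned_series", "data.frame"); attr(b, "bin_width") <- 5L
  b <- detect_sleep(b)
  # the episode straddling midnight (day1 23:00 - day2 07:00, 96 bins) lies
  # in one noon-to-noon window and is flagged whole
  expect_true(all(b$sleep[(23 * 12 + 1):288]))          # day1 23:00-24:00
  expect_true(all(b$sleep[288 + 1:(7 * 12)]))           # day2 00:00-07:00
  # day1's own 00:00-07:00 run (truncated window) is also >= 4 h
  expect_true(all(b$sleep[1:(7 * 12)]))
  # day2 23:00-24:00 alone (12 bins in its truncated window) is below 4 h
  expect_false(any(b$sleep[(288 + 23 * 12 + 1):(2 * 288)]))
  expect_equal(sum(b$sleep), 84 + 96)
})

test_that("no sleep is called without a 4-hour candidate run", {
  steps <- rep(10, 288); steps[seq(1, 288, by = 24)] <- 0   # scattered zeros
  b <- make_binned_day(rep(70, 288), steps)
  expect_true(all(!detect_sleep(b)$sleep))
})

test_that("missing charging bins count toward the sleep run", {
  hr <- rep(70, 288); steps <- rep(15, 288)
  gap <- (1 * 12 + 1):(8 * 12)                 # 01:00-08:00 missing
  hr[gap] <- NA; steps[gap] <- NA
  b <- make_binned_day(hr, steps)
  b <- detect_sleep(b)
  expect_true(all(b$sleep[gap]))
})

test_that("sleep detection matches an exhaustive longest-run scan", {
  # oracle: brute-force longest candidate run within one noon-to-noon window
  brute_longest <- function(cand) {
    best_len <- 0L; best_start <- NA_integer_
    i <- 1L
    while (i <= length(cand)) {
      if (cand[i]) {
        j <- i
        while (j < length(cand) && cand[j + 1]) j <- j + 1L
        if (j - i + 1L > best_len) { best_len <- j - i + 1L; best_start <- i }
        i <- j + 1L
      } else i <- i + 1L
    }
    list(len = best_len, start = best_start)
  }
  set.seed(99)
  for (rep in 1:15) {
    steps <- ifelse(runif(288) < 0.35, 0, rpois(288, 8) + 1)
    # one noon-to-noon window: build two half days around it
    day1 <- make_binned_day(rep(70, 288), steps)
    flagged <- detect_sleep(day1)$sleep
    # windows here: [-12h, noon) and [noon, +12h) each half-day chunk
    w1 <- 1:144; w2 <- 145:288
    for (w in list(w1, w2)) {
      o <- brute_longest(steps[w] == 0)
      if (o$len >= 48) {
        expect_true(all(flagged[w][o$start:(o$start + o$len - 1)]))
        expect_equal(sum(flagged[w]), o$len)
      } else {
        expect_equal(sum(flagged[w]), 0L)
      }
    }
  }
})

test_that("wear time per day counts bins exactly and never exceeds 24 h", {
  b <- make_binned_day(rep(70, 288), rep(1, 288))
  expect_equal(unname(wear_time_per_day(b)), 24)
  hr <- c(rep(70, 144), rep(NA, 144)); st <- c(rep(1, 144), rep(NA, 144))
  b2 <- make_binned_day(hr, st)
  expect_equal(unname(wear_time_per_day(b2)), 12)
  b3 <- make_binned_day(rep(NA_real_, 288), rep(NA_real_, 288))
  expect_equal(unname(wear_time_per_day(b3)), 0)
  set.seed(2)
  hr4 <- ifelse(runif(288) < 0.6, 70, NA)
  b4 <- make_binned_day(hr4, rep(NA_real_, 288))
  expect_equal(unname(wear_time_per_day(b4)), sum(!is.na(hr4)) * 5 / 60)
})

test_that("inclusion policies enforce the published rules", {
  mk_days <- function(n, hr_on = rep(TRUE, n)) {
    do.call(rbind, lapply(seq_len(n), function(d) {
      hr <- if (hr_on[d]) rep(70, 288) else rep(NA_real_, 288)
      make_binned_day(hr, rep(5, 288), date = as.Date("2020-03-01") + d - 1)
    }))
  }
  restore <- function(df) { class(df) <- c("binned_series", "data.frame")
    attr(df, "bin_width") <- 5L; df }

  expect_true(apply_inclusion_filters(restore(mk_days(8)), "dlmo_study")$pass)
  r6 <- apply_inclusion_filters(restore(mk_days(6)), "dlmo_study")
  expect_false(r6$pass)   # boundary of the 7-day rule
  r_gap <- apply_inclusion_filters(restore(mk_days(8, hr_on = c(TRUE, TRUE, TRUE, FALSE,
                                                                TRUE, TRUE, TRUE, TRUE))),
                                   "dlmo_study")
  expect_false(r_gap$pass)

  # social_rhythms: 70 complete days pass; one missing day fails with index
  full <- restore(mk_days(70))
  ev <- as.Date("2020-03-01") + 35
  expect_true(apply_inclusion_filters(full, "social_rhythms", ev)$pass)
  hr_on <- rep(TRUE, 70); hr_on[40] <- FALSE
  broken <- restore(mk_days(70, hr_on))
  res <- apply_inclusion_filters(broken, "social_rhythms", ev)
  expect_false(res$pass)
  expect_match(res$reason, "missing day 40")
  expect_error(apply_inclusion_filters(full, "nonsense"), "unknown inclusion policy")
})

test_that("binned series round-trips through CSV", {
  b <- make_binned_day(rep(c(70, NA), 144), rep(c(0, 5), 144))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "b.csv")
  write_binned_csv(b, p)
  b2 <- read_binned_csv(p)
  expect_equal(b2$hr, b$hr)
  expect_equal(b2$wear, b$wear)
  expect_s3_class(b2, "binned_series")
})
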