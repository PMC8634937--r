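# Shared fixtures: built in code at test time.

# a minimal binned day constructed directly (bypasses bin_series)
make_binned_day <- function(hr, steps, wear = NULL, sleep = NULL,
                            date = as.Date("2020-03-01"), bw = 5L) {
  bpd <- 1440L %/% bw
  stopifnot(length(hr) == bpd, length(steps) == bpd)
  if (is.null(wear)) wear <- !(is.na(hr) & is.na(steps))
  if (is.null(sleep)) sleep <- rep(FALSE, bpd)
  df <- data.frame(date = rep(date, bpd), bin_index = 0:(bpd - 1),
                   hr = hr, steps = steps, wear = wear, sleep = sleep)
  structure(df, class = c("binned_series", "data.frame"), bin_width = bw)
}

# write a generic-dialect CSV and return its path
write_generic_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "wear.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

fast_cfg <- function(seed, evals = 4000, walkers = 20) {
  crhr_config("fast", seed = seed, n_total_evals = evals, n_walkers = walkers)
}

# independent brute-force check of circular membership: does d equal
# low + s (mod 24) for some s in [0, width]?
oracle_in_arc <- function(d, low, high, step = 0.005) {
  width <- (high - low) %% 24
  s <- seq(0, width, by = step)
  any(abs(circular_diff(wrap24(low + s), d)) < step)
}
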