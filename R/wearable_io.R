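#' Read a raw wearable CSV into validated records
#'
#' Parses one-row-per-reading delimited text from a consumer wearable export.
#' Each record carries a local civil timestamp and at least one of a heart-rate
#' reading (bpm) and a step count. Rows failing validation — unparseable
#' timestamp, heart rate outside the (20, 250) bpm plausibility gate, negative
#' or non-integer steps, or neither stream present — are dropped and counted.
#'
#' @param path path to a delimited text file with a header.
#' @param dialect column-naming convention: `"generic"` expects
#'   `timestamp,heart_rate,steps`; `"applehealth_like"` expects
#'   `startDate,heartRate,stepCount`; `"fitbit_like"` expects
#'   `Time,HeartRate,Steps`.
#' @return a `wearable_records` data frame with columns `timestamp`
#'   (POSIXct, local civil time), `heart_rate`, `steps`, sorted ascending in
#'   time, with attribute `n_rejected` (count of dropped rows).
#' @export
read_wearable_csv <- function(path, dialect = c("generic", "applehealth_like", "fitbit_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read wearable file: ", path)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("unreadable wearable file '", path, "': ", conditionMessage(e))
  )
  cols <- switch(dialect,
    generic          = c(ts = "timestamp", hr = "heart_rate", st = "steps"),
    applehealth_like = c(ts = "startDate", hr = "heartRate", st = "stepCount"),
    fitbit_like      = c(ts = "Time", hr = "HeartRate", st = "Steps")
  )
  if (!cols[["ts"]] %in% names(raw)) {
    stop("dialect '", dialect, "' expects a '", cols[["ts"]], "' column")
  }
  get_num <- function(nm) {
    if (nm %in% names(raw)) suppressWarnings(as.numeric(raw[[nm]])) else rep(NA_real_, nrow(raw))
  }
  ts <- parse_civil_time(raw[[cols[["ts"]]]])
  hr <- get_num(cols[["hr"]])
  st <- get_num(cols[["st"]])

  bad_ts <- is.na(ts)
  bad_hr <- !is.na(hr) & (hr <= 20 | hr >= 250)
  bad_st <- !is.na(st) & (st < 0 | st != round(st))
  empty <- is.na(hr) & is.na(st)
  keep <- !(bad_ts | bad_hr | bad_st | empty)
  n_rej <- sum(!keep)
  if (n_rej > 0) message(n_rej, " malformed row(s) skipped in ", basename(path))

  out <- data.frame(timestamp = ts[keep], heart_rate = hr[keep], steps = st[keep])
  if (nrow(out) == 0L) stop("no valid rows in wearable file: ", path)
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("wearable_records", "data.frame"), n_rejected = n_rej)
}

# ISO-8601-ish local timestamps; interpreted as civil clock labels (UTC
# internally so no DST arithmetic is applied to the labels themselves)
parse_civil_time <- function(x) {
  as.POSIXct(as.character(x),
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"),
             tz = "UTC", optional = TRUE)
}

#' Construct wearable records in code
#'
#' Convenience constructor used by the synthetic generator and in tests.
#'
#' @param timestamp POSIXct vector (local civil time).
#' @param heart_rate bpm, `NA` where absent.
#' @param steps non-negative counts, `NA` where absent.
#' @return a `wearable_records` data frame sorted by time.
#' @export
wearable_records <- function(timestamp, heart_rate = NA_real_, steps = NA_real_) {
  out <- data.frame(timestamp = timestamp,
                    heart_rate = as.numeric(heart_rate),
                    steps = as.numeric(steps))
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("wearable_records", "data.frame"), n_rejected = 0L)
}

#' Average raw wearable records onto a uniform bin grid
#'
#' Heart rate is averaged and steps are summed within half-open bins
#' `[start, start + width)`; the default 5-minute width gives 288 bins per
#' civil day. Bins with no data in either stream carry missing values and a
#' false wear mask. The grid spans whole days from the first to the last
#' record.
#'
#' @param records a `wearable_records` data frame.
#' @param bin_width bin width in minutes; must divide 1440.
#' @return a `binned_series` data frame with columns `date` (Date),
#'   `bin_index` (0-based within day), `hr`, `steps`, `wear`, `sleep`, and
#'   attribute `bin_width`.
#' @export
bin_series <- function(records, bin_width = 5) {
  if (is.null(records) || nrow(records) == 0L) stop("empty record list")
  if (1440 %% bin_width != 0) stop("bin_width must divide 1440 minutes")
  bpd <- 1440L %/% as.integer(bin_width)

  day0 <- as.Date(format(min(records$timestamp), "%Y-%m-%d"))
  dayN <- as.Date(format(max(records$timestamp), "%Y-%m-%d"))
  n_days <- as.integer(dayN - day0) + 1L

  # absolute bin index of each record relative to day0 midnight
  mins <- as.numeric(difftime(records$timestamp, as.POSIXct(paste(day0, "00:00:00"), tz = "UTC"),
                              units = "mins"))
  abs_bin <- floor(mins / bin_width)

  total <- n_days * bpd
  hr <- rep(NA_real_, total); st <- rep(NA_real_, total)
  has_hr <- !is.na(records$heart_rate)
  if (any(has_hr)) {
    agg <- tapply(records$heart_rate[has_hr], abs_bin[has_hr], mean)
    hr[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  }
  has_st <- !is.na(records$steps)
  if (any(has_st)) {
    agg <- tapply(records$steps[has_st], abs_bin[has_st], sum)
    st[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  }

  out <- data.frame(
    date = rep(seq(day0, by = "day", length.out = n_days), each = bpd),
    bin_index = rep(seq_len(bpd) - 1L, times = n_days),
    hr = hr, steps = st,
    wear = !(is.na(hr) & is.na(st)),
    sleep = FALSE
  )
  structure(out, class = c("binned_series", "data.frame"), bin_width = as.integer(bin_width))
}

#' Bin width of a binned series, minutes
#' @param series a `binned_series`.
#' @return bin width in minutes.
#' @export
bin_width <- function(series) {
  bw <- attr(series, "bin_width")
  if (is.null(bw)) 5L else bw
}

#' Flag the nightly sleep episode in each noon-to-noon window
#'
#' Sleep is taken as the single longest run of bins that are either missing or
#' have zero activity within each noon-to-noon window, provided the run lasts
#' at least `min_hours`. Noon-to-noon windows keep a sleep episode straddling
#' midnight in one piece. Ties break to the earliest start. Phase fitting
#' excludes flagged bins downstream.
#'
#' @param series a `binned_series`.
#' @param min_hours minimum run length to call sleep (hours).
#' @return the series with `sleep` set.
#' @export
detect_sleep <- function(series, min_hours = 4) {
  bpd <- 1440L %/% bin_width(series)
  half <- bpd %/% 2L
  n <- nrow(series)
  abs_bin <- (as.integer(series$date - series$date[1])) * bpd + series$bin_index
  window <- (abs_bin - half) %/% bpd
  candidate <- is.na(series$steps) | series$steps == 0
  min_bins <- ceiling(min_hours * 60 / bin_width(series))

  sleep <- rep(FALSE, n)
  for (w in unique(window)) {
    idx <- which(window == w)
    r <- rle(candidate[idx])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_bins)
    if (length(runs) == 0L) next
    best <- runs[which.max(r$lengths[runs])]  # which.max takes the earliest tie
    sleep[idx[starts[best]:ends[best]]] <- TRUE
  }
  series$sleep <- sleep
  series
}

#' Hours of device wear per calendar day
#'
#' @param series a `binned_series`.
#' @return named numeric vector, hours per day (names are dates).
#' @export
wear_time_per_day <- function(series) {
  if (nrow(series) == 0L) stop("empty series")
  v <- tapply(series$wear, series$date, sum) * bin_width(series) / 60
  out <- as.numeric(v)
  names(out) <- names(v)
  out
}

#' Apply a study inclusion policy to a subject's binned series
#'
#' `"dlmo_study"` fails a subject with more than one calendar day of zero wear,
#' or without at least 7 consecutive days carrying both heart-rate and step
#' data. `"social_rhythms"` requires every one of the 70 days spanning 35 days
#' before through 34 days after the disruption date to have at least one wear
#' bin in each stream.
#'
#' @param series a `binned_series`.
#' @param policy `"dlmo_study"` or `"social_rhythms"`.
#' @param event_date Date of the disruption onset; required for
#'   `"social_rhythms"`.
#' @return list with `pass` (logical) and `reason` (character, `NA` on pass).
#' @export
apply_inclusion_filters <- function(series, policy, event_date = NULL) {
  if (!policy %in% c("dlmo_study", "social_rhythms")) {
    stop("unknown inclusion policy: ", policy)
  }
  dates <- unique(series$date)
  has_hr <- tapply(!is.na(series$hr), series$date, any)
  has_st <- tapply(!is.na(series$steps), series$date, any)
  any_wear <- tapply(series$wear, series$date, any)

  if (policy == "dlmo_study") {
    if (sum(!any_wear) > 1) {
      return(list(pass = FALSE, reason = sprintf("%d days without wear", sum(!any_wear))))
    }
    complete <- as.logical(has_hr & has_st)
    r <- rle(complete)
    best <- if (any(r$values)) max(r$lengths[r$values]) else 0L
    if (best < 7) {
      return(list(pass = FALSE,
                  reason = sprintf("longest streak of complete days is %d < 7", best)))
    }
    return(list(pass = TRUE, reason = NA_character_))
  }

  # social_rhythms
  if (is.null(event_date)) stop("social_rhythms policy requires event_date")
  required <- seq(event_date - 35, by = "day", length.out = 70L)
  for (i in seq_along(required)) {
    d <- required[i]
    j <- match(d, dates)
    ok <- !is.na(j) && isTRUE(as.logical(has_hr)[j]) && isTRUE(as.logical(has_st)[j])
    if (!ok) {
      return(list(pass = FALSE, reason = sprintf("missing day %d", i)))
    }
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Write / read a binned series as CSV
#'
#' Columns `date,bin_index,hr,steps,wear,sleep`.
#'
#' @param series a `binned_series`.
#' @param path output path.
#' @return `path`, invisibly (writer); a `binned_series` (reader).
#' @export
write_binned_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binned_csv
#' @param bin_width bin width in minutes of the stored grid.
#' @export
read_binned_csv <- function(path, bin_width = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df$wear <- as.logical(df$wear)
  df$sleep <- as.logical(df$sleep)
  structure(df, class = c("binned_series", "data.frame"), bin_width = as.integer(bin_width))
}
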