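#' Alignment analysis configuration
#'
#' `crhr_shift_h` is the fixed population offset added to the CRHR phase
#' (and its interval) before comparing against DLMO; -4.4 h is the mean
#' DLMO-minus-CRHR difference estimated from a laboratory cohort and is not
#' re-estimated here.
#'
#' @param crhr_shift_h hours added to CRHR phases (default -4.4).
#' @param ci_level credible-interval level used for containment (0.8).
#' @param pre_window_days,post_window_days window lengths around the event.
#' @param min_days_per_window minimum estimated days per window for a subject
#'   to enter group-shift summaries.
#' @return an `alignment_config` list.
#' @export
alignment_config <- function(crhr_shift_h = -4.4, ci_level = 0.8,
                             pre_window_days = 35, post_window_days = 35,
                             min_days_per_window = 5) {
  stopifnot(ci_level > 0, ci_level < 1,
            pre_window_days > 0, post_window_days > 0)
  structure(list(crhr_shift_h = crhr_shift_h, ci_level = ci_level,
                 pre_window_days = pre_window_days,
                 post_window_days = post_window_days,
                 min_days_per_window = min_days_per_window),
            class = "alignment_config")
}

#' Does a DLMO time fall inside the shifted CRHR interval?
#'
#' Shifts both interval endpoints by `shift_h` (mod 24) and tests circular
#' containment of the DLMO time, handling intervals that wrap midnight.
#'
#' @param dlmo_h DLMO clock time, hours in `[0, 24)`.
#' @param crhr_low,crhr_high CRHR interval endpoints in `[0, 24)` (the arc
#'   runs clockwise from low to high; wrapping allowed).
#' @param shift_h fixed offset applied to the CRHR interval.
#' @return logical.
#' @export
day_alignment <- function(dlmo_h, crhr_low, crhr_high, shift_h = -4.4) {
  if (any(c(dlmo_h, crhr_low, crhr_high) < 0) ||
      any(c(dlmo_h, crhr_low, crhr_high) >= 24)) {
    stop("times must lie in [0, 24)")
  }
  in_circular_interval(dlmo_h, wrap24(crhr_low + shift_h), wrap24(crhr_high + shift_h))
}

#' Percentage of days on which the two markers align
#'
#' Over the days in `window` where both a DLMO prediction and a CRHR
#' estimate exist, the fraction on which the DLMO time falls within the
#' shifted CRHR credible interval.
#'
#' @param dlmo_track a `dlmo_track` with a `date` column.
#' @param crhr_track a `phase_track`.
#' @param window Date vector of days to consider.
#' @param config an `alignment_config`.
#' @return list with `pct` (0-100), `n_days` (denominator), and `flags`
#'   (per-day data frame `date, aligned`).
#' @export
percent_days_aligned <- function(dlmo_track, crhr_track, window,
                                 config = alignment_config()) {
  ct <- crhr_track[!crhr_track$skipped, , drop = FALSE]
  common <- intersect(intersect(as.character(dlmo_track$date), as.character(ct$date)),
                      as.character(window))
  if (length(common) == 0L) {
    return(list(pct = NA_real_, n_days = 0L,
                flags = data.frame(date = as.Date(character(0)), aligned = logical(0))))
  }
  common <- as.Date(common)
  aligned <- vapply(common, function(d) {
    i <- match(d, dlmo_track$date); j <- match(d, ct$date)
    day_alignment(dlmo_track$dlmo_h[i], ct$ci_low_h[j], ct$ci_high_h[j],
                  config$crhr_shift_h)
  }, logical(1))
  list(pct = 100 * mean(aligned), n_days = length(common),
       flags = data.frame(date = common, aligned = aligned))
}

#' Per-subject alignment before and after the disruption date
#'
#' The pre window is the `pre_window_days` days ending the day before the
#' event; the post window the `post_window_days` days starting the day after
#' (the event day belongs to neither). Reports percent days aligned and the
#' mean circular absolute difference between DLMO and the shifted CRHR phase
#' in each window.
#'
#' @param dlmo_track a `dlmo_track`.
#' @param crhr_track a `phase_track`.
#' @param event_date Date of disruption onset.
#' @param config an `alignment_config`.
#' @return an `alignment_result` list.
#' @export
align_subject <- function(dlmo_track, crhr_track, event_date,
                          config = alignment_config()) {
  pre <- seq(event_date - config$pre_window_days, event_date - 1, by = "day")
  post <- seq(event_date + 1, event_date + config$post_window_days, by = "day")
  a_pre <- percent_days_aligned(dlmo_track, crhr_track, pre, config)
  a_post <- percent_days_aligned(dlmo_track, crhr_track, post, config)

  mad_window <- function(window) {
    ct <- crhr_track[!crhr_track$skipped, , drop = FALSE]
    common <- as.Date(intersect(intersect(as.character(dlmo_track$date), as.character(ct$date)),
                                as.character(window)))
    if (length(common) == 0L) return(NA_real_)
    d <- vapply(common, function(dd) {
      i <- match(dd, dlmo_track$date); j <- match(dd, ct$date)
      abs(circular_diff(dlmo_track$dlmo_h[i],
                        wrap24(ct$phase_h[j] + config$crhr_shift_h)))
    }, numeric(1))
    mean(d)
  }

  structure(list(
    flags = rbind(a_pre$flags, a_post$flags),
    pct_aligned_pre = a_pre$pct, pct_aligned_post = a_post$pct,
    n_days_pre = a_pre$n_days, n_days_post = a_post$n_days,
    mean_abs_diff_pre = mad_window(pre), mean_abs_diff_post = mad_window(post)
  ), class = "alignment_result")
}

#' Paired test of alignment percentage before vs after the event
#'
#' Two-sided paired t-test on per-subject (pre, post) alignment percentages,
#' with the Wilcoxon signed-rank test reported alongside.
#'
#' @param results list of `alignment_result` objects (one per subject).
#' @return list with `mean_pre`, `mean_post`, `p_value` (paired t),
#'   `p_wilcoxon`, `n`, and `degenerate` flag (all differences zero).
#' @export
pre_post_alignment_test <- function(results) {
  pre <- vapply(results, function(r) r$pct_aligned_pre, numeric(1))
  post <- vapply(results, function(r) r$pct_aligned_post, numeric(1))
  ok <- !is.na(pre) & !is.na(post)
  pre <- pre[ok]; post <- post[ok]
  if (length(pre) < 2L) stop("insufficient subjects for a paired test")
  diffs <- post - pre
  if (all(diffs == 0)) {
    return(list(mean_pre = mean(pre), mean_post = mean(post), p_value = 1,
                p_wilcoxon = 1, n = length(pre), degenerate = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE))
  list(mean_pre = mean(pre), mean_post = mean(post),
       p_value = tt$p.value, p_wilcoxon = wt$p.value,
       n = length(pre), degenerate = FALSE)
}

#' Per-subject circular phase shift across the event, summarised by group
#'
#' Each subject's shift is the circular mean of post-window daily phases
#' minus the circular mean of pre-window phases (signed hours on the circle).
#' Subjects with fewer than `min_days_per_window` estimated days in either
#' window are excluded. Groups are summarised by mean, SEM and a one-sample
#' t-test; named group pairs are compared by Welch's t-test.
#'
#' @param tracks named list of `phase_track`s, one per subject id.
#' @param meta data frame with `subject_id`, `age_group`, `event_date`.
#' @param config an `alignment_config`.
#' @param pairs list of 2-vectors of group names to compare (Welch).
#' @return list with `subjects` (per-subject shifts), `groups` (summary data
#'   frame: `group, n, mean_shift_h, sem_h, p_one_sample`), and
#'   `pairwise` (data frame of Welch comparisons).
#' @export
phase_shift_by_group <- function(tracks, meta, config = alignment_config(),
                                 pairs = list(c("under30", "30to45"))) {
  subj <- list()
  for (sid in names(tracks)) {
    mrow <- meta[meta$subject_id == sid, , drop = FALSE]
    if (nrow(mrow) == 0L) next
    ev <- as.Date(mrow$event_date[1])
    tr <- tracks[[sid]]
    tr <- tr[!tr$skipped, , drop = FALSE]
    pre <- tr$phase_h[tr$date >= ev - config$pre_window_days & tr$date <= ev - 1]
    post <- tr$phase_h[tr$date >= ev + 1 & tr$date <= ev + config$post_window_days]
    if (length(pre) < config$min_days_per_window ||
        length(post) < config$min_days_per_window) {
      message("subject ", sid, " excluded: too few estimated days per window")
      next
    }
    subj[[sid]] <- data.frame(
      subject_id = sid, group = mrow$age_group[1],
      shift_h = circular_diff(circular_mean(post), circular_mean(pre))
    )
  }
  if (length(subj) == 0L) stop("no subjects passed the per-window day minimum")
  subjects <- do.call(rbind, subj)
  rownames(subjects) <- NULL

  groups <- do.call(rbind, lapply(split(subjects, subjects$group), function(g) {
    n <- nrow(g)
    p1 <- if (n >= 2 && stats::sd(g$shift_h) > 0)
      stats::t.test(g$shift_h)$p.value else NA_real_
    data.frame(group = g$group[1], n = n,
               mean_shift_h = mean(g$shift_h),
               sem_h = if (n >= 2) stats::sd(g$shift_h) / sqrt(n) else NA_real_,
               p_one_sample = p1)
  }))
  rownames(groups) <- NULL

  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    g1 <- subjects$shift_h[subjects$group == pr[1]]
    g2 <- subjects$shift_h[subjects$group == pr[2]]
    p <- if (length(g1) >= 2 && length(g2) >= 2)
      stats::t.test(g1, g2)$p.value else NA_real_
    data.frame(group1 = pr[1], group2 = pr[2],
               diff_h = mean(g1) - mean(g2), p_welch = p)
  }))

  list(subjects = subjects, groups = groups, pairwise = pairwise)
}

#' Correlation between data quantity and phase uncertainty
#'
#' Pearson correlation (with two-sided p) between a per-day data-quantity
#' metric (usable-bin count, or wear hours) and the credible-interval
#' half-width, pooled over subject-days.
#'
#' @param half_width_h interval half-widths, hours.
#' @param data_quantity matched data-quantity values.
#' @return list `r`, `p`, `n`.
#' @export
uncertainty_weartime_correlation <- function(half_width_h, data_quantity) {
  ok <- is.finite(half_width_h) & is.finite(data_quantity)
  x <- data_quantity[ok]; y <- half_width_h[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cohort mean heart-rate and activity profiles by bin of day
#'
#' Per bin of day: mean over each subject's days, then mean and SEM across
#' subjects, computed separately for the pre- and post-event windows.
#' Missing bins stay missing (they never contribute zeros).
#'
#' @param series_list named list of `binned_series`, one per subject.
#' @param event_dates named Date vector (same names).
#' @param window_days days on each side of the event.
#' @return list of two data frames (`pre`, `post`) with columns `bin_index,
#'   hr_mean, hr_sem, act_mean, act_sem, n_subjects`.
#' @export
mean_profiles <- function(series_list, event_dates, window_days = 35) {
  profile_one <- function(series, days) {
    s <- series[series$date %in% days, , drop = FALSE]
    if (nrow(s) == 0L) return(NULL)
    bpd <- 1440L %/% bin_width(series)
    hr <- tapply(s$hr, factor(s$bin_index, levels = 0:(bpd - 1)),
                 function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    ac <- tapply(s$steps, factor(s$bin_index, levels = 0:(bpd - 1)),
                 function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    cbind(hr = as.numeric(hr), act = as.numeric(ac))
  }
  summarise <- function(which_window) {
    mats <- list()
    for (sid in names(series_list)) {
      ev <- as.Date(event_dates[[sid]])
      days <- if (which_window == "pre") seq(ev - window_days, ev - 1, by = "day")
              else seq(ev + 1, ev + window_days, by = "day")
      p <- profile_one(series_list[[sid]], days)
      if (!is.null(p)) mats[[sid]] <- p
    }
    if (length(mats) == 0L) {
      return(data.frame(bin_index = integer(0), hr_mean = numeric(0),
                        hr_sem = numeric(0), act_mean = numeric(0),
                        act_sem = numeric(0), n_subjects = integer(0)))
    }
    bpd <- nrow(mats[[1]])
    hrs <- sapply(mats, function(m) m[, "hr"])
    acs <- sapply(mats, function(m) m[, "act"])
    hrs <- matrix(hrs, nrow = bpd); acs <- matrix(acs, nrow = bpd)
    sem <- function(m) apply(m, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    })
    data.frame(bin_index = 0:(bpd - 1),
               hr_mean = rowMeans(hrs, na.rm = TRUE),
               hr_sem = sem(hrs),
               act_mean = rowMeans(acs, na.rm = TRUE),
               act_sem = sem(acs),
               n_subjects = length(mats))
  }
  list(pre = summarise("pre"), post = summarise("post"))
}
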