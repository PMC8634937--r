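#' Master configuration for an end-to-end run
#'
#' Bundles every stage's configuration and derives per-stage seeds
#' deterministically from one master seed. The `"full"` profile uses the
#' full 100,000-evaluation sampler budget; `"fast"` the reduced test budget.
#'
#' @param seed master integer seed.
#' @param profile `"fast"` or `"full"`.
#' @param inclusion_policy policy for [apply_inclusion_filters()], or `NA`
#'   to skip filtering.
#' @param crhr a `crhr_config` override (default built from profile/seed).
#' @param clock a `clock_params`.
#' @param alignment an `alignment_config`.
#' @param light_scale,light_cap activity-to-light mapping settings.
#' @param dlmo_offset_h CBTmin-to-DLMO offset, hours.
#' @param out_dir optional directory for per-subject CSV outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, profile = c("fast", "full"),
                       inclusion_policy = "social_rhythms",
                       crhr = NULL, clock = clock_params(),
                       alignment = alignment_config(),
                       light_scale = 1, light_cap = 1000,
                       dlmo_offset_h = 7, out_dir = NULL) {
  profile <- match.arg(profile)
  if (is.null(crhr)) crhr <- crhr_config(profile, seed = seed + 1L)
  structure(list(seed = as.integer(seed), profile = profile,
                 inclusion_policy = inclusion_policy, crhr = crhr,
                 clock = clock, alignment = alignment,
                 light_scale = light_scale, light_cap = light_cap,
                 dlmo_offset_h = dlmo_offset_h, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline for one subject
#'
#' read/bin -> sleep detection -> inclusion filter -> sequential CRHR fit ->
#' activity-to-light -> entrained-start ODE integration -> DLMO track ->
#' alignment against the event date. Intermediate CSVs are written when
#' `config$out_dir` is set.
#'
#' @param records a `wearable_records` (or path to a generic-dialect CSV).
#' @param event_date Date of the disruption onset.
#' @param config a `run_config`.
#' @param subject_id label used for output files and messages.
#' @return a `subject_report` list with `binned`, `crhr` (fit result),
#'   `dlmo_track`, `alignment`, and `included`/`reason`; or, when the
#'   subject fails inclusion, a stub with `included = FALSE`.
#' @export
run_subject <- function(records, event_date, config, subject_id = "subject") {
  if (is.character(records)) records <- read_wearable_csv(records)
  binned <- detect_sleep(bin_series(records))

  if (!is.na(config$inclusion_policy)) {
    ok <- apply_inclusion_filters(binned, config$inclusion_policy,
                                  event_date = event_date)
    if (!ok$pass) {
      message(subject_id, " skipped (inclusion: ", ok$reason, ")")
      return(structure(list(subject_id = subject_id, included = FALSE,
                            reason = paste0("inclusion:", ok$reason)),
                       class = "subject_report"))
    }
  }

  crhr_cfg <- config$crhr
  crhr_cfg$seed <- (config$seed + 100003L) %% .Machine$integer.max
  fit <- sequential_fit(binned, crhr_base_prior(), crhr_cfg)

  lux <- activity_to_light(binned$steps, sleep_mask = binned$sleep,
                           scale = config$light_scale, cap_lux = config$light_cap)
  bpd <- 1440L %/% bin_width(binned)
  template <- rowMeans(matrix(lux, nrow = bpd), na.rm = TRUE)
  ic <- limit_cycle_ic(template, config$clock, bin_width(binned))
  traj <- integrate_clock(as.numeric(ic), lux, config$clock, bin_width(binned))
  dlmo <- predict_dlmo(traj, config$dlmo_offset_h, start_date = binned$date[1])

  alignment <- align_subject(dlmo, fit$track, event_date, config$alignment)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_binned_csv(binned, file.path(config$out_dir, paste0(subject_id, "_binned.csv")))
    write_phase_track_csv(fit$track, file.path(config$out_dir, paste0(subject_id, "_crhr.csv")))
    utils::write.csv(as.data.frame(dlmo),
                     file.path(config$out_dir, paste0(subject_id, "_dlmo.csv")),
                     row.names = FALSE)
  }

  structure(list(subject_id = subject_id, included = TRUE, reason = NA_character_,
                 binned = binned, crhr = fit, dlmo_track = dlmo,
                 alignment = alignment, event_date = event_date),
            class = "subject_report")
}

#' Run the pipeline over a cohort and summarise
#'
#' Applies [run_subject()] to every subject, then computes the cohort-level
#' headline quantities: mean alignment percentage pre/post with the paired
#' test, per-group phase shifts, and the data-quantity vs uncertainty
#' correlation. Failed subjects are recorded and skipped; zero successes is
#' an error.
#'
#' @param cohort output of [generate_cohort()], or a named list of
#'   `list(records, event_date)` plus a `meta` data frame.
#' @param config a `run_config`.
#' @return a `cohort_report` list with `subjects` (reports), `alignment_test`,
#'   `group_shifts`, `correlation`, and `headline` (flat named list, also
#'   written as JSON when `out_dir` is set).
#' @export
run_cohort <- function(cohort, config) {
  if (is.null(cohort$meta) || nrow(cohort$meta) == 0L) {
    stop("cohort metadata missing")
  }
  reports <- list()
  for (sid in names(cohort$subjects)) {
    sub <- cohort$subjects[[sid]]
    ev <- as.Date(cohort$meta$event_date[cohort$meta$subject_id == sid][1])
    reports[[sid]] <- tryCatch(
      run_subject(sub$records, ev, config, subject_id = sid),
      error = function(e) {
        message(sid, " failed: ", conditionMessage(e))
        structure(list(subject_id = sid, included = FALSE,
                       reason = conditionMessage(e)),
                  class = "subject_report")
      })
  }
  ok <- Filter(function(r) isTRUE(r$included), reports)
  if (length(ok) == 0L) stop("no subject completed the pipeline")

  align_results <- lapply(ok, function(r) r$alignment)
  at <- if (length(ok) >= 2) pre_post_alignment_test(align_results) else NULL

  tracks <- lapply(ok, function(r) r$crhr$track)
  gs <- tryCatch(phase_shift_by_group(tracks, cohort$meta, config$alignment),
                 error = function(e) NULL)

  hw <- unlist(lapply(ok, function(r) {
    t <- r$crhr$track; t$half_width_h[!t$skipped]
  }))
  nb <- unlist(lapply(ok, function(r) {
    t <- r$crhr$track; t$n_bins[!t$skipped]
  }))
  corr <- tryCatch(uncertainty_weartime_correlation(hw, nb),
                   error = function(e) NULL)

  headline <- list(
    n_subjects = length(ok),
    pct_aligned_pre = if (!is.null(at)) at$mean_pre else NA,
    pct_aligned_post = if (!is.null(at)) at$mean_post else NA,
    p_paired = if (!is.null(at)) at$p_value else NA,
    r_uncertainty_data = if (!is.null(corr)) corr$r else NA
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(headline, file.path(config$out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(subjects = reports, alignment_test = at, group_shifts = gs,
                 correlation = corr, headline = headline),
            class = "cohort_report")
}
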