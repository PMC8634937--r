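#' Sampler and fitting configuration for the CRHR model
#'
#' The `"full"` profile spends 100,000 target evaluations per day across 50
#' walkers with a burn-in ratio of 0.5; the `"fast"` profile (5,000
#' evaluations, 20 walkers) trades posterior-quantile precision for speed and
#' is intended for tests and exploratory runs.
#'
#' @param profile `"fast"` or `"full"`; sets evaluation budget and walkers.
#' @param seed integer seed; required, every stochastic path derives from it.
#' @param n_total_evals,n_walkers override the profile budget.
#' @param burn_in fraction of sweeps discarded (0.5).
#' @param stretch_a stretch-move scale.
#' @param min_bins minimum usable bins for a day to be fitted.
#' @param ci_level credible-interval level for the phase track.
#' @param prior_inflation s.d. inflation of the day-to-day transferred prior.
#' @return a `crhr_config` list.
#' @export
crhr_config <- function(profile = c("fast", "full"), seed,
                        n_total_evals = NULL, n_walkers = NULL,
                        burn_in = 0.5, stretch_a = 2, min_bins = 24,
                        ci_level = 0.8, prior_inflation = 1.5) {
  profile <- match.arg(profile)
  if (missing(seed)) stop("crhr_config requires a seed")
  defaults <- switch(profile,
    fast  = list(evals = 5000L, walkers = 20L),
    full = list(evals = 100000L, walkers = 50L))
  structure(list(
    profile = profile,
    n_total_evals = if (is.null(n_total_evals)) defaults$evals else as.integer(n_total_evals),
    n_walkers = if (is.null(n_walkers)) defaults$walkers else as.integer(n_walkers),
    burn_in = burn_in, stretch_a = stretch_a, min_bins = min_bins,
    ci_level = ci_level, prior_inflation = prior_inflation,
    seed = as.integer(seed)
  ), class = "crhr_config")
}

param_names <- c("a", "b", "c", "d", "k_ar", "sigma")

# Walker initialization: a small ball around a center (least-squares fit or
# transferred-prior mean), pushed inside the support.
init_walkers <- function(center, n_walkers, prior) {
  jit <- function(n, s) stats::rnorm(n, 0, s)
  X <- cbind(
    a = center[["a"]] + jit(n_walkers, 2),
    b = abs(center[["b"]] + jit(n_walkers, max(0.5, 0.1 * abs(center[["b"]])))),
    c = center[["c"]] + jit(n_walkers, 0.5),
    d = center[["d"]] + jit(n_walkers, max(0.02, 0.1 * abs(center[["d"]]))),
    k_ar = pmin(pmax(center[["k_ar"]] + jit(n_walkers, 0.1), 1e-4), 1 - 1e-4),
    sigma = pmax(abs(center[["sigma"]] * exp(jit(n_walkers, 0.2))), 1e-3)
  )
  X
}

#' Fit one day of heart-rate data
#'
#' Samples the posterior of the six cosinor/AR(1) parameters for a single
#' day, with `log prior + AR(1) log-likelihood` as the target. Walkers start
#' in a small ball around the deterministic cosinor least-squares estimate
#' (or the transferred prior mean for chained days); the first `burn_in`
#' fraction of sweeps is discarded. A day with fewer than `min_bins` usable
#' bins is skipped: the prior is carried forward as the "posterior" and the
#' result is flagged.
#'
#' @param series_day rows of a `binned_series` for one day.
#' @param prior a `crhr_prior` (see [crhr_base_prior()]).
#' @param config a `crhr_config`.
#' @return a `crhr_posterior`: list with `samples` (matrix, post-burn-in),
#'   `date`, `n_data`, `skipped`, `accept_rate`.
#' @export
fit_day <- function(series_day, prior, config) {
  day <- if (nrow(series_day) > 0) series_day$date[1] else as.Date(NA)
  dat <- prepare_day_data(series_day)
  if (dat$n < config$min_bins) {
    message("day ", day, " skipped: ", dat$n, " usable bins < ", config$min_bins)
    set.seed(config$seed)
    s <- prior$sample(2000L)
    colnames(s) <- param_names
    s[, "c"] <- wrap24(s[, "c"])
    return(structure(list(samples = s, date = day, n_data = dat$n,
                          skipped = TRUE, accept_rate = NA_real_),
                     class = "crhr_posterior"))
  }

  log_target <- function(theta) {
    lp <- prior$log_density(theta)
    if (!is.finite(lp)) return(-Inf)
    lp + ar1_log_likelihood(stats::setNames(theta, param_names), dat)
  }

  set.seed(config$seed)
  center <- if (!is.null(prior$mean)) {
    stats::setNames(as.numeric(prior$mean), param_names)
  } else {
    tryCatch(cosinor_lm(dat), error = function(e) {
      stats::setNames(c(mean(dat$hr), 5, 5, 0, 0.5, max(stats::sd(dat$hr), 1)),
                      param_names)
    })
  }
  init <- init_walkers(center, config$n_walkers, prior)
  run <- gw_ensemble_sample(log_target, init, config$n_total_evals,
                            stretch_a = config$stretch_a, seed = config$seed + 1L)
  samples <- flatten_chain(run, config$burn_in)
  colnames(samples) <- param_names
  structure(list(samples = samples, date = day, n_data = dat$n,
                 skipped = FALSE, accept_rate = run$accept_rate),
            class = "crhr_posterior")
}

#' @export
summary.crhr_posterior <- function(object, level = 0.8, ...) {
  s <- object$samples
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- data.frame(parameter = param_names,
                    mean = NA_real_, low = NA_real_, high = NA_real_)
  for (i in seq_along(param_names)) {
    p <- param_names[i]
    if (p == "c") {
      out$mean[i] <- circular_mean(s[, "c"])
      ci <- phase_credible_interval(object, level)
      out$low[i] <- ci[1]; out$high[i] <- ci[2]
    } else {
      out$mean[i] <- mean(s[, p])
      q <- stats::quantile(s[, p], qs, names = FALSE)
      out$low[i] <- q[1]; out$high[i] <- q[2]
    }
  }
  out
}

#' Equal-tailed circular credible interval for the phase
#'
#' Phase samples are unwrapped about their circular mean, the equal-tailed
#' quantile interval is taken on the unwrapped scale, and the endpoints are
#' re-wrapped to `[0, 24)`. The interval may therefore straddle midnight
#' (`low > high` numerically).
#'
#' @param posterior a `crhr_posterior`.
#' @param level interval level in (0, 1); default 0.8.
#' @return numeric `c(low, high)` in hours.
#' @export
phase_credible_interval <- function(posterior, level = 0.8) {
  stopifnot(level > 0, level < 1)
  cs <- posterior$samples[, "c"]
  if (length(cs) == 0L) stop("empty posterior")
  cm <- circular_mean(cs)
  if (is.na(cm)) cm <- wrap24(cs[1])
  dev <- circular_diff(wrap24(cs), cm)
  q <- stats::quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  wrap24(cm + q)
}

#' Sequentially fit a multi-day series, chaining daily priors
#'
#' Day 1 is fitted under `base_prior`; each subsequent day's prior is the
#' moment-matched (and inflated) normal approximation of the previous day's
#' posterior, so information accumulates while the chain can still track
#' phase drift. Emits the list of daily posteriors and a phase track of the
#' daily HR-minimum time `c` with equal-tailed circular credible intervals.
#'
#' @param series a multi-day `binned_series`.
#' @param base_prior a `crhr_prior` for day 1; default [crhr_base_prior()].
#' @param config a `crhr_config`.
#' @return list with `posteriors` (list of `crhr_posterior`) and `track`
#'   (a `phase_track` data frame: `date, phase_h, ci_low_h, ci_high_h,
#'   half_width_h, n_bins, skipped`).
#' @export
sequential_fit <- function(series, base_prior = crhr_base_prior(), config) {
  dates <- unique(series$date)
  if (length(dates) == 0L) stop("empty series")
  prior <- base_prior
  posteriors <- vector("list", length(dates))
  rows <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    day_cfg <- config
    day_cfg$seed <- (config$seed + 1000L * i) %% .Machine$integer.max
    post <- fit_day(series[series$date == dates[i], , drop = FALSE], prior, day_cfg)
    posteriors[[i]] <- post
    rows[[i]] <- phase_track_row(post, config$ci_level)
    if (!post$skipped) {
      prior <- moment_match_prior(post, config$prior_inflation)
    }
  }
  track <- do.call(rbind, rows)
  class(track) <- c("phase_track", "data.frame")
  list(posteriors = posteriors, track = track)
}

phase_track_row <- function(post, level) {
  ci <- phase_credible_interval(post, level)
  est <- circular_mean(post$samples[, "c"])
  hw <- ((ci[2] - ci[1]) %% 24) / 2
  data.frame(date = post$date, phase_h = est,
             ci_low_h = ci[1], ci_high_h = ci[2],
             half_width_h = hw, n_bins = post$n_data,
             skipped = post$skipped)
}

#' Write a phase track as CSV
#' @param track a `phase_track`.
#' @param path output path.
#' @export
write_phase_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}
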