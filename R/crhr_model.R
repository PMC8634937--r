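#' Cosinor heart-rate model parameters
#'
#' The six parameters of the circadian heart-rate model
#' `HR = a - b*cos(pi/12*(t - c)) + d*Activity + eps`, with AR(1) errors
#' `eps_{t+1} = k_ar*eps_t + N(0, sigma^2)`:
#' `a` basal heart rate (bpm), `b` circadian amplitude (bpm, >= 0), `c` clock
#' time of the circadian HR minimum (hours, circular mod 24), `d` bpm per step
#' per bin, `k_ar` AR(1) carryover in `[0, 1)`, `sigma` innovation s.d. (bpm).
#'
#' @param a,b,c,d,k_ar,sigma numeric scalars.
#' @return a named numeric vector of class `cosinor_params`.
#' @export
cosinor_params <- function(a, b, c, d, k_ar, sigma) {
  p <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d),
         k_ar = unname(k_ar), sigma = unname(sigma))
  validate_cosinor_params(p)
  structure(p, class = "cosinor_params")
}

validate_cosinor_params <- function(p) {
  stopifnot(length(p) == 6L, all(is.finite(p)))
  if (p[["b"]] < 0) stop("amplitude b must be >= 0")
  if (p[["sigma"]] <= 0) stop("sigma must be > 0")
  if (p[["k_ar"]] < 0 || p[["k_ar"]] >= 1) stop("k_ar must lie in [0, 1)")
  invisible(p)
}

#' Noise-free cosinor heart-rate prediction
#'
#' Evaluates `a - b*cos(pi/12*(time - c)) + d*activity`. At `time = c` and
#' zero activity this is the circadian minimum `a - b`.
#'
#' @param params a `cosinor_params` vector (or any named numeric with the six
#'   fields).
#' @param time clock time(s) in hours.
#' @param activity steps in the corresponding bin(s).
#' @return predicted heart rate, bpm.
#' @export
hr_model_predict <- function(params, time, activity) {
  params[["a"]] - params[["b"]] * cos(pi / 12 * (time - params[["c"]])) +
    params[["d"]] * activity
}

#' Extract the usable-bin design from one day of binned data
#'
#' Usable bins are worn, not flagged as sleep, and carry both a heart-rate
#' mean and a step count. Contiguity is tracked so the AR(1) chain resets
#' across any gap (missing, sleep, or day boundary).
#'
#' @param series_day rows of a `binned_series` (typically one day).
#' @return list with `t` (hours of day), `hr`, `act`, `run` (integer run id),
#'   and `n` (usable-bin count).
#' @keywords internal
#' @export
prepare_day_data <- function(series_day) {
  bw <- bin_width(series_day)
  bpd <- 1440L %/% bw
  usable <- series_day$wear & !series_day$sleep &
    !is.na(series_day$hr) & !is.na(series_day$steps)
  idx <- which(usable)
  if (length(idx) == 0L) {
    return(list(t = numeric(0), hr = numeric(0), act = numeric(0),
                run = integer(0), n = 0L))
  }
  day_off <- as.integer(series_day$date[idx] - series_day$date[idx[1]])
  abs_bin <- day_off * bpd + series_day$bin_index[idx]
  run <- cumsum(c(1L, as.integer(diff(abs_bin) != 1L)))
  # bin centers: the bin's HR mean represents its midpoint, not its left edge
  list(t = (series_day$bin_index[idx] + 0.5) * bw / 60,
       hr = series_day$hr[idx],
       act = series_day$steps[idx],
       run = run,
       n = length(idx))
}

#' AR(1) cosinor log-likelihood
#'
#' Residuals from the cosinor prediction follow a first-order autoregression
#' within each contiguous run of usable bins: the first residual of a run is
#' scored under the stationary marginal `N(0, sigma^2/(1 - k_ar^2))`, every
#' subsequent innovation `eps_{t+1} - k_ar*eps_t` under `N(0, sigma^2)`.
#' With `k_ar = 0` this reduces exactly to independent Gaussian errors.
#'
#' @param params a `cosinor_params` vector.
#' @param series_day rows of a `binned_series`, or a prepared list from
#'   [prepare_day_data()].
#' @return total log-likelihood (scalar).
#' @export
ar1_log_likelihood <- function(params, series_day) {
  d <- if (is.list(series_day) && !is.data.frame(series_day)) series_day
       else prepare_day_data(series_day)
  if (d$n == 0L) stop("no usable bins: likelihood undefined")
  eps <- d$hr - hr_model_predict(params, d$t, d$act)
  k <- params[["k_ar"]]; s <- params[["sigma"]]
  first <- c(TRUE, diff(d$run) != 0L)
  s0 <- s / sqrt(1 - k^2)
  ll_first <- sum(stats::dnorm(eps[first], 0, s0, log = TRUE))
  if (all(first)) return(ll_first)
  innov <- eps[!first] - k * eps[which(!first) - 1L]
  ll_first + sum(stats::dnorm(innov, 0, s, log = TRUE))
}

#' Deterministic cosinor least-squares fit
#'
#' Linearizes the cosinor term via
#' `-b*cos(w(t - c)) = A*cos(wt) + B*sin(wt)` and fits
#' `hr ~ cos(wt) + sin(wt) + activity` by ordinary least squares, recovering
#' `a, b, c, d` exactly for noise-free model data. The AR parameters are
#' estimated from the residual lag-1 autocorrelation within runs. Used to
#' seed the ensemble sampler and for noiseless round-trip checks.
#'
#' @param series_day rows of a `binned_series`, or a prepared list.
#' @return a `cosinor_params` vector.
#' @export
cosinor_lm <- function(series_day) {
  d <- if (is.list(series_day) && !is.data.frame(series_day)) series_day
       else prepare_day_data(series_day)
  if (d$n < 5L) stop("too few usable bins for a cosinor fit")
  w <- pi / 12
  X <- cbind(1, cos(w * d$t), sin(w * d$t), d$act)
  fit <- stats::lm.fit(X, d$hr)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  a <- cf[1]
  # -b*cos(w(t-c)) = -b*cos(wc)cos(wt) - b*sin(wc)sin(wt)
  b <- sqrt(cf[2]^2 + cf[3]^2)
  cc <- if (b > 0) wrap24(atan2(-cf[3], -cf[2]) / w) else 0
  dd <- cf[4]
  r <- fit$residuals
  contig <- c(FALSE, diff(d$run) == 0L)
  k <- if (sum(contig) >= 3 && stats::sd(r) > 0) {
    num <- sum(r[contig] * r[which(contig) - 1L])
    den <- sum(r[which(contig) - 1L]^2)
    if (den > 0) max(0, min(0.95, num / den)) else 0
  } else 0
  innov <- r[contig] - k * r[which(contig) - 1L]
  s <- if (length(innov) >= 3) stats::sd(innov) else stats::sd(r)
  if (!is.finite(s) || s <= 0) s <- 1e-3
  cosinor_params(a = unname(a), b = unname(b), c = unname(cc), d = unname(dd),
                 k_ar = unname(k), sigma = unname(s))
}
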