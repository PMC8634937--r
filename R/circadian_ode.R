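#' Parameters of the limit-cycle pacemaker model
#'
#' Constants of the light-driven human circadian pacemaker oscillator. The
#' state is `(x, xc, n)`: `x` tracks the core-body-temperature rhythm, `xc`
#' is the complementary oscillator variable, and `n` the fraction of
#' activated photoreceptor. `tau_x` is the intrinsic period in hours; the
#' period correction 0.99729 makes the realized free-running period equal
#' `tau_x`. `q` is not universally printed with this parameter set; the
#' default 1/3 follows the established lineage of the model and is exposed
#' here for explicitness.
#'
#' @param mu,G,alpha0,I0,p_exp,tau_x,k_stiff,beta,q,period_correction numeric
#'   model constants; see field notation in the package vignette.
#' @return a `clock_params` list.
#' @export
clock_params <- function(mu = 0.13, G = 19.875, alpha0 = 0.16, I0 = 9500,
                         p_exp = 0.6, tau_x = 24.2, k_stiff = 0.55,
                         beta = 0.013, q = 1 / 3, period_correction = 0.99729) {
  p <- list(mu = mu, G = G, alpha0 = alpha0, I0 = I0, p_exp = p_exp,
            tau_x = tau_x, k_stiff = k_stiff, beta = beta, q = q,
            period_correction = period_correction)
  stopifnot(all(vapply(p[names(p) != "q"], function(v) v > 0, logical(1))))
  structure(p, class = "clock_params")
}

#' Photic activation rate
#'
#' `alpha = alpha0 * (I / I0)^p`: the rate at which light of illuminance `I`
#' (lux) activates photoreceptor elements. At the reference illuminance
#' `I = I0` it equals `alpha0`; at zero light it is zero.
#'
#' @param illuminance lux, non-negative (vectorized).
#' @param params a `clock_params`.
#' @return activation rate (per minute).
#' @export
alpha_drive <- function(illuminance, params = clock_params()) {
  stopifnot(all(illuminance >= 0))
  params$alpha0 * (illuminance / params$I0)^params$p_exp
}

#' Right-hand side of the pacemaker ODE
#'
#' With photic drive `Bhat = G*alpha*(1 - n)` gated by the oscillator state,
#' `B = (1 - 0.4 x)(1 - 0.4 xc) * Bhat`:
#' \deqn{dx/dt = (\pi/12)[x_c + \mu(x/3 + 4x^3/3 - 256 x^7/105) + B]}
#' \deqn{dx_c/dt = (\pi/12)\{q B x_c - [(24/(0.99729\,\tau_x))^2 + k B] x\}}
#' \deqn{dn/dt = 60[\alpha(1-n) - \beta n]}
#' Time is in hours; the factor 60 converts the per-minute photoreceptor
#' rates onto the hour time base.
#'
#' @param state numeric `c(x, xc, n)`.
#' @param illuminance lux at this instant.
#' @param params a `clock_params`.
#' @return derivative `c(dx, dxc, dn)` per hour.
#' @export
clock_rhs <- function(state, illuminance, params = clock_params()) {
  x <- state[1]; xc <- state[2]; n <- state[3]
  alpha <- alpha_drive(illuminance, params)
  Bhat <- params$G * alpha * (1 - n)
  B <- (1 - 0.4 * x) * (1 - 0.4 * xc) * Bhat
  w <- pi / 12
  dx <- w * (xc + params$mu * (x / 3 + 4 * x^3 / 3 - 256 * x^7 / 105) + B)
  dxc <- w * (params$q * B * xc -
              ((24 / (params$period_correction * params$tau_x))^2 +
               params$k_stiff * B) * x)
  dn <- 60 * (alpha * (1 - n) - params$beta * n)
  c(dx, dxc, dn)
}

#' Integrate the pacemaker under a binned light schedule
#'
#' Fixed-step 4th-order Runge–Kutta with the illuminance held constant within
#' each bin (zero-order hold), so the trajectory aligns exactly with the data
#' grid. `n` is clamped to `[0, 1]` after every step. Deterministic.
#'
#' @param initial state `c(x, xc, n)`.
#' @param lux illuminance per bin (lux), one value per bin.
#' @param params a `clock_params`.
#' @param bin_width_min width of each lux bin, minutes.
#' @param dt integration step in hours; must divide the bin width.
#' @param t0 clock time of the start of the first bin, hours.
#' @return data frame `t_h, x, xc, n, lux` (class `clock_trajectory`),
#'   including the initial state at `t0`.
#' @export
integrate_clock <- function(initial, lux, params = clock_params(),
                            bin_width_min = 5, dt = bin_width_min / 60,
                            t0 = 0) {
  bw_h <- bin_width_min / 60
  sub <- round(bw_h / dt)
  if (abs(sub * dt - bw_h) > 1e-9) stop("dt must divide the bin width")
  n_bins <- length(lux)
  if (n_bins == 0L) {
    out <- data.frame(t_h = t0, x = initial[1], xc = initial[2],
                      n = initial[3], lux = NA_real_)
    class(out) <- c("clock_trajectory", "data.frame")
    return(out)
  }
  n_steps <- n_bins * sub
  traj <- matrix(NA_real_, n_steps + 1L, 3L)
  traj[1L, ] <- initial
  state <- initial
  h <- dt
  for (b in seq_len(n_bins)) {
    I <- lux[b]
    if (is.na(I)) I <- 0
    for (s in seq_len(sub)) {
      k1 <- clock_rhs(state, I, params)
      k2 <- clock_rhs(state + h / 2 * k1, I, params)
      k3 <- clock_rhs(state + h / 2 * k2, I, params)
      k4 <- clock_rhs(state + h * k3, I, params)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      state[3] <- min(max(state[3], 0), 1)
      if (!all(is.finite(state))) {
        stop(sprintf("integration blew up at t = %.3f h",
                     t0 + ((b - 1L) * sub + s) * h))
      }
      traj[(b - 1L) * sub + s + 1L, ] <- state
    }
  }
  out <- data.frame(t_h = t0 + h * (0:n_steps),
                    x = traj[, 1], xc = traj[, 2], n = traj[, 3],
                    lux = c(NA_real_, rep(lux, each = sub)))
  class(out) <- c("clock_trajectory", "data.frame")
  out
}

# upward zero-crossing times of x, linearly interpolated
upward_crossings <- function(t, x) {
  i <- which(x[-length(x)] < 0 & x[-1] >= 0)
  if (length(i) == 0L) return(numeric(0))
  t[i] + (t[i + 1] - t[i]) * (-x[i]) / (x[i + 1] - x[i])
}

# integrate in darkness until the state settles onto the limit cycle
on_cycle_state <- function(params, transient_days = 10) {
  lux <- rep(0, transient_days * 288)
  traj <- integrate_clock(c(1, 0, 0), lux, params)
  as.numeric(traj[nrow(traj), c("x", "xc", "n")])
}

#' Free-running period of the oscillator
#'
#' Integrates in darkness from an on-cycle state for `n_cycles` nominal
#' cycles and returns the mean spacing of the last `measure_cycles` upward
#' zero-crossings of `x`. With default parameters this recovers the intrinsic
#' period `tau_x` (the 0.99729 correction is built to make the realized
#' period equal `tau_x`).
#'
#' @param params a `clock_params`.
#' @param n_cycles cycles to integrate (>= 20).
#' @param measure_cycles trailing cycles over which to average.
#' @return period in hours.
#' @export
free_running_period <- function(params = clock_params(), n_cycles = 25,
                                measure_cycles = 10) {
  init <- on_cycle_state(params)
  n_bins <- ceiling(n_cycles * params$tau_x / 24 * 288)
  traj <- integrate_clock(init, rep(0, n_bins), params)
  cr <- upward_crossings(traj$t_h, traj$x)
  if (length(cr) < measure_cycles + 1L) stop("degenerate oscillation: too few zero crossings")
  iv <- diff(cr)
  mean(utils::tail(iv, measure_cycles))
}

#' Entrained initial condition from a template light day
#'
#' Repeats a 24-h light template until the state at the daily reference time
#' (start of day) changes by less than `tol` in sup-norm between successive
#' cycles, capped at `max_days` days. Because the entrained orbit is a unique
#' attractor, the result is independent of the starting state.
#'
#' @param template_lux illuminance for one 24-h day (one value per bin).
#' @param params a `clock_params`.
#' @param bin_width_min bin width, minutes.
#' @param tol convergence tolerance on the daily state map.
#' @param max_days iteration cap.
#' @param start state to begin from; default an on-cycle dark state.
#' @return converged state `c(x, xc, n)` with attributes `converged`
#'   (logical) and `days` used; warns on non-convergence.
#' @export
limit_cycle_ic <- function(template_lux, params = clock_params(),
                           bin_width_min = 5, tol = 1e-6, max_days = 90,
                           start = NULL) {
  if (length(template_lux) * bin_width_min != 1440) {
    stop("template must cover exactly 24 h")
  }
  state <- if (is.null(start)) on_cycle_state(params) else start
  converged <- FALSE
  d <- 0L
  while (d < max_days) {
    d <- d + 1L
    traj <- integrate_clock(state, template_lux, params, bin_width_min)
    new_state <- as.numeric(traj[nrow(traj), c("x", "xc", "n")])
    if (max(abs(new_state - state)) < tol) {
      state <- new_state
      converged <- TRUE
      break
    }
    state <- new_state
  }
  if (!converged) warning("limit_cycle_ic did not converge within ", max_days, " days")
  structure(state, converged = converged, days = d)
}

#' Map step counts to a light surrogate
#'
#' Activity stands in for the unmeasured light input: illuminance is a
#' linear function of steps per bin, capped, with sleep-flagged bins forced
#' dark and missing bins treated as dark. The mapping is a declared
#' stand-in, configurable and reported with every run.
#'
#' @param steps steps per bin (vector); `NA` treated as 0.
#' @param sleep_mask optional logical vector; `TRUE` bins map to 0 lux.
#' @param scale lux per step (default 1).
#' @param cap_lux saturation level (default 1000 lux).
#' @return illuminance per bin, lux.
#' @export
activity_to_light <- function(steps, sleep_mask = NULL, scale = 1,
                              cap_lux = 1000) {
  s <- steps
  s[is.na(s)] <- 0
  if (any(s < 0)) stop("negative step counts")
  lux <- pmin(scale * s, cap_lux)
  if (!is.null(sleep_mask)) lux[sleep_mask] <- 0
  lux
}

#' Extract daily predicted DLMO times from a trajectory
#'
#' Per simulated day, the core-body-temperature minimum (CBTmin) is the time
#' of the daily minimum of `x`, refined parabolically over the three
#' bracketing samples; predicted DLMO is `CBTmin - offset_h` wrapped to
#' `[0, 24)`. The conventional CBTmin-to-DLMO relation of about 7 h is the
#' default offset. Days whose minimum falls on a day boundary (no interior
#' minimum) are skipped.
#'
#' @param trajectory a `clock_trajectory`.
#' @param offset_h hours subtracted from CBTmin (default 7).
#' @param start_date optional Date of the first trajectory day, used to label
#'   output rows.
#' @return a `dlmo_track` data frame: `day` (1-based index), `date` (if
#'   `start_date` given), `cbtmin_h`, `dlmo_h` (clock hours in `[0, 24)`).
#' @export
predict_dlmo <- function(trajectory, offset_h = 7, start_date = NULL) {
  t <- trajectory$t_h; x <- trajectory$x
  if (max(t) - min(t) < 24 - 1e-9) stop("trajectory must span at least one day")
  day_id <- floor(t / 24)
  rows <- list()
  for (d in unique(day_id)) {
    idx <- which(day_id == d)
    if (length(idx) < 3L) next
    j <- idx[which.min(x[idx])]
    if (j == idx[1] || j == idx[length(idx)] || j == 1L || j == length(x)) next
    # parabolic refinement through (t[j-1], t[j], t[j+1])
    y1 <- x[j - 1]; y2 <- x[j]; y3 <- x[j + 1]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 1e-15) 0.5 * (y1 - y3) / denom else 0
    delta <- min(max(delta, -1), 1)
    tmin <- t[j] + delta * (t[j + 1] - t[j])
    rows[[length(rows) + 1L]] <- data.frame(
      day = d + 1L,
      cbtmin_h = wrap24(tmin),
      dlmo_h = wrap24(tmin - offset_h)
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(day = integer(0), cbtmin_h = numeric(0), dlmo_h = numeric(0))
  if (!is.null(start_date) && nrow(out) > 0) {
    out$date <- start_date + out$day - 1L
    out <- out[, c("day", "date", "cbtmin_h", "dlmo_h")]
  }
  class(out) <- c("dlmo_track", "data.frame")
  out
}
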