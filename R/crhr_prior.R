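#' Weakly informative base prior for the cosinor parameters
#'
#' Scale-matched to human heart rate: `a ~ N(70, 15^2)` bpm,
#' `b ~ HalfNormal(10)` bpm, `c ~ Uniform[0, 24)` (flat on the circle),
#' `d ~ N(0, 0.5^2)` bpm/step, `k_ar ~ Uniform[0, 1)`,
#' `sigma ~ HalfNormal(10)` bpm. Used for the first day of a sequential fit;
#' later days receive a moment-matched approximation of the previous
#' posterior (see [moment_match_prior()]).
#'
#' @return a `crhr_prior` object with `log_density(theta)` and `sample(n)`.
#' @export
crhr_base_prior <- function() {
  ld <- function(theta) {
    b <- theta[2]; d <- theta[4]; k <- theta[5]; s <- theta[6]
    if (b < 0 || s <= 0 || k < 0 || k >= 1) return(-Inf)
    stats::dnorm(theta[1], 70, 15, log = TRUE) +
      stats::dnorm(b, 0, 10, log = TRUE) + log(2) +
      -log(24) +
      stats::dnorm(d, 0, 0.5, log = TRUE) +
      stats::dnorm(s, 0, 10, log = TRUE) + log(2)
  }
  smp <- function(n) {
    cbind(a = stats::rnorm(n, 70, 15),
          b = abs(stats::rnorm(n, 0, 10)),
          c = stats::runif(n, 0, 24),
          d = stats::rnorm(n, 0, 0.5),
          k_ar = stats::runif(n, 0, 1),
          sigma = abs(stats::rnorm(n, 0, 10)))
  }
  structure(list(log_density = ld, sample = smp, mean = NULL, type = "base"),
            class = "crhr_prior")
}

#' Moment-matched multivariate-normal prior from a posterior
#'
#' Approximates a day's posterior by a multivariate normal on
#' `(a, b, c, d, k_ar, sigma)` — with `c` unwrapped about its circular mean —
#' and inflates every standard deviation by `inflate` (correlations kept) so
#' the next day's fit can track genuine phase drift. Support constraints
#' (`b >= 0`, `sigma > 0`, `0 <= k_ar < 1`) are enforced by truncation.
#'
#' @param posterior a `crhr_posterior`.
#' @param inflate multiplicative factor on the standard deviations.
#' @return a `crhr_prior` object.
#' @export
moment_match_prior <- function(posterior, inflate = 1.5) {
  s <- posterior$samples
  cm <- circular_mean(s[, "c"])
  c_work <- cm + circular_diff(s[, "c"], cm)
  m <- cbind(s[, "a"], s[, "b"], c_work, s[, "d"], s[, "k_ar"], s[, "sigma"])
  mu <- colMeans(m)
  sig <- stats::cov(m)
  sds <- sqrt(pmax(diag(sig), 1e-10))
  D <- diag(inflate, 6)
  sig <- D %*% sig %*% D + diag(1e-8 * pmax(sds^2, 1e-6))
  R <- chol(sig)
  Rinv <- backsolve(R, diag(6))
  logdet <- 2 * sum(log(diag(R)))
  names(mu) <- c("a", "b", "c", "d", "k_ar", "sigma")

  ld <- function(theta) {
    b <- theta[2]; k <- theta[5]; sgm <- theta[6]
    if (b < 0 || sgm <= 0 || k < 0 || k >= 1) return(-Inf)
    th <- theta
    th[3] <- mu[3] + circular_diff(theta[3], wrap24(mu[3]))
    z <- crossprod(Rinv, th - mu)
    -0.5 * (logdet + sum(z^2)) - 3 * log(2 * pi)
  }
  smp <- function(n) {
    z <- matrix(stats::rnorm(n * 6), n, 6)
    x <- sweep(z %*% R, 2, mu, "+")
    colnames(x) <- names(mu)
    x[, "b"] <- abs(x[, "b"])
    x[, "sigma"] <- pmax(abs(x[, "sigma"]), 1e-4)
    x[, "k_ar"] <- pmin(pmax(x[, "k_ar"], 0), 1 - 1e-6)
    x
  }
  structure(list(log_density = ld, sample = smp, mean = mu, type = "mvn"),
            class = "crhr_prior")
}
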