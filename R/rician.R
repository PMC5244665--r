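#' Estimate noise sigma from a background region
#'
#' Magnitude MR data in signal-free regions follow a Rayleigh distribution
#' with standard deviation \eqn{\sigma\sqrt{2 - \pi/2}}; the Gaussian noise
#' sigma is recovered by dividing the sample SD of background voxels by that
#' factor.
#'
#' @param background_voxels Numeric vector of magnitude samples from an empty
#'   region (>= 50 samples).
#' @param source Optional descriptor of the background region.
#' @return A `noise_estimate` list with fields `sigma` and `source`.
#' @export
estimate_noise_sigma <- function(background_voxels, source = "background") {
  x <- background_voxels[is.finite(background_voxels)]
  if (length(x) < 50) stop("need at least 50 background samples", call. = FALSE)
  if (all(x == 0)) stop("background region is identically zero", call. = FALSE)
  sigma <- stats::sd(x) / sqrt(2 - pi / 2)
  structure(list(sigma = sigma, source = source), class = "noise_estimate")
}

#' Rician log-likelihood
#'
#' Log-likelihood of observed magnitude signals given predicted noiseless
#' amplitudes under Rician noise:
#' \deqn{\ln L = \sum_i \ln x_i - 2\ln\sigma_i - \frac{x_i^2 + A_i^2}{2\sigma_i^2}
#'   + \ln I_0\!\left(\frac{x_i A_i}{\sigma_i^2}\right)}
#' The Bessel term is evaluated in exponentially scaled form so high-SNR
#' points do not overflow. Non-positive observations are excluded with a
#' warning (magnitude data are positive).
#'
#' @param observed Observed magnitude signals.
#' @param predicted Predicted noiseless amplitudes (same length).
#' @param sigma Noise SD, scalar or per measurement.
#' @return The summed log-likelihood.
#' @export
rician_loglik <- function(observed, predicted, sigma) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  sigma <- rep_len(sigma, length(observed))
  keep <- observed > 0
  if (!all(keep)) {
    warning(sum(!keep), " non-positive observation(s) excluded from the Rician likelihood")
    observed <- observed[keep]; predicted <- predicted[keep]; sigma <- sigma[keep]
  }
  rician_loglik_fast(observed, predicted, sigma)
}

# no-validation inner loop shared with fitting/MCMC
rician_loglik_fast <- function(x, A, sigma) {
  s2 <- sigma^2
  z <- x * A / s2
  sum(log(x) - 2 * log(sigma) - (x^2 + A^2) / (2 * s2) + log_besselI0(z) + z)
}

# log I0(z) - z in two regimes: R's scaled Bessel below z = 50, asymptotic
# expansion above (relative error < 1e-6 at the crossover; besselI itself
# degrades for very large arguments)
log_besselI0 <- function(z) {
  out <- numeric(length(z))
  lo <- z < 50
  if (any(lo)) out[lo] <- log(besselI(z[lo], 0, expon.scaled = TRUE))
  if (!all(lo)) {
    zz <- z[!lo]
    out[!lo] <- -0.5 * log(2 * pi * zz) +
      log1p(1 / (8 * zz) + 9 / (128 * zz^2) + 75 / (1024 * zz^3))
  }
  out
}

# Per-measurement log-likelihood builder handling NEX averaging: single
# acquisitions follow the Rician density; averaged measurements (n_avg > 1)
# are treated as Gaussian about the exact Rician mean with variance
# Var_Rician / n_avg (the average of magnitudes keeps the full noise floor,
# so scaling sigma alone would misplace it).
make_meas_loglik <- function(scheme, sigma) {
  n_avg <- scheme$n_avg
  single <- n_avg == 1
  avg <- !single
  n_av <- n_avg[avg]
  function(x, A) {
    ll <- 0
    if (any(single)) {
      xs <- x[single]; As <- A[single]
      ok <- xs > 0
      ll <- ll + rician_loglik_fast(xs[ok], As[ok], sigma)
    }
    if (any(avg)) {
      mu <- expected_rician_mean(A[avg], sigma)
      v <- pmax((A[avg]^2 + 2 * sigma^2 - mu^2) / n_av, 1e-300)
      ll <- ll + sum(-0.5 * log(2 * pi * v) - (x[avg] - mu)^2 / (2 * v))
    }
    ll
  }
}

#' Expected Rician magnitude
#'
#' Mean of a Rician variate with noiseless amplitude `A` and noise `sigma`:
#' \eqn{\sigma\sqrt{\pi/2}\, L_{1/2}(-A^2/2\sigma^2)}, used to draw fitted
#' curves and residuals on the same (biased) scale as magnitude data.
#'
#' @param A Noiseless amplitude(s), >= 0.
#' @param sigma Noise SD.
#' @return Expected observed magnitude.
#' @export
expected_rician_mean <- function(A, sigma) {
  if (any(A < 0)) stop("A must be non-negative", call. = FALSE)
  n <- max(length(A), length(sigma))
  A <- rep_len(A, n); sigma <- rep_len(sigma, n)
  z <- A^2 / (4 * sigma^2)
  out <- numeric(n)
  lo <- z < 700          # scaled besselI loses accuracy/underflows beyond this
  if (any(lo)) {
    zl <- z[lo]
    # L_{1/2}(-2z) = e^{-z} [(1 + 2z) I0(z) + 2z I1(z)]; scaled Bessels absorb e^{-z}
    lag <- (1 + 2 * zl) * besselI(zl, 0, expon.scaled = TRUE) +
      2 * zl * besselI(zl, 1, expon.scaled = TRUE)
    out[lo] <- sigma[lo] * sqrt(pi / 2) * lag
  }
  if (!all(lo)) {
    # high-SNR expansion: E[x] = A + sigma^2/(2A) - sigma^4/(8A^3) + ...
    Ah <- A[!lo]; sh <- sigma[!lo]
    out[!lo] <- Ah + sh^2 / (2 * Ah) - sh^4 / (8 * Ah^3)
  }
  out
}
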