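#' Default log-spaced T2 grid
#'
#' 120 log-spaced relaxation times spanning 1 ms to 3 s.
#' @param n Number of grid points.
#' @param range Two-element range in seconds.
#' @return Numeric vector of T2 values (s).
#' @export
t2_grid_default <- function(n = 120L, range = c(1e-3, 3)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

#' NNLS T2 spectrum of a multi-echo decay
#'
#' Decomposes a multi-echo signal into a non-negative amplitude spectrum over
#' a grid of relaxation times by non-negative least squares, minimising
#' \eqn{\|s - \sum_j a_j e^{-TE_i/T2_j}\|^2} with optional Tikhonov smoothing.
#' The main peak is the maximal contiguous run of non-negligible amplitudes
#' (> 1e-6 of the maximum) containing the global maximum;
#' `main_peak_fraction` is its share of the total spectral area.
#'
#' @param echo_signals Signal at each echo.
#' @param echo_times Echo times (s), same length, >= 8 echoes.
#' @param t2_grid Relaxation-time grid (s).
#' @param lambda Tikhonov regularisation weight (0 = plain NNLS).
#' @return A `t2_spectrum` list: `t2_grid`, `amplitudes`,
#'   `main_peak_fraction`, `main_peak_t2`, `peaks` (per-peak fractions),
#'   `residual`.
#' @export
nnls_t2_spectrum <- function(echo_signals, echo_times,
                             t2_grid = t2_grid_default(), lambda = 0) {
  if (length(echo_signals) != length(echo_times)) {
    stop("echo_signals and echo_times must have equal length", call. = FALSE)
  }
  if (length(echo_times) < 8) stop("need at least 8 echoes", call. = FALSE)
  if (all(echo_signals == 0)) stop("echo signal is identically zero", call. = FALSE)
  A <- exp(-outer(echo_times, 1 / t2_grid))
  y <- echo_signals
  if (lambda > 0) {
    A <- rbind(A, sqrt(lambda) * diag(length(t2_grid)))
    y <- c(y, rep(0, length(t2_grid)))
  }
  amp <- tryCatch(pracma::lsqnonneg(A, y)$x, error = function(e) NULL)
  if (is.null(amp)) {
    # near-singular active sets on noise-dominated voxels: stabilise with a
    # minimal ridge
    ridge <- 1e-8 * max(abs(y))
    A2 <- rbind(A, sqrt(ridge) * diag(length(t2_grid)))
    amp <- pracma::lsqnonneg(A2, c(y, rep(0, length(t2_grid))))$x
  }
  peaks <- spectrum_peaks(amp)
  main_idx <- which(vapply(peaks, function(p) p$has_max, TRUE))
  mpf <- if (length(main_idx)) peaks[[main_idx]]$fraction else 0
  main_t2 <- if (length(main_idx)) {
    idx <- peaks[[main_idx]]$run
    sum(t2_grid[idx] * amp[idx]) / sum(amp[idx])
  } else NA_real_
  structure(list(
    t2_grid = t2_grid, amplitudes = amp,
    main_peak_fraction = mpf, main_peak_t2 = main_t2,
    peaks = tibble::tibble(
      peak = seq_along(peaks),
      fraction = vapply(peaks, function(p) p$fraction, 0),
      t2_weighted = vapply(peaks, function(p) {
        sum(t2_grid[p$run] * amp[p$run]) / sum(amp[p$run])
      }, 0)),
    residual = sqrt(sum((A %*% amp - y)^2))),
    class = "t2_spectrum")
}

# contiguous runs of amplitude above 1e-6 of the max; fractions sum to 1
spectrum_peaks <- function(amp) {
  thr <- 1e-6 * max(amp)
  on <- amp > thr
  if (!any(on)) return(list())
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  total <- sum(amp[on])
  imax <- which.max(amp)
  out <- list()
  for (q in seq_along(r$values)) {
    if (!r$values[q]) next
    run <- starts[q]:ends[q]
    out[[length(out) + 1]] <- list(run = run, fraction = sum(amp[run]) / total,
                                   has_max = imax %in% run)
  }
  out
}

#' @export
print.t2_spectrum <- function(x, ...) {
  cat(sprintf("<T2 spectrum: %d peaks, main peak %.1f%% of area at T2 = %.1f ms>\n",
              nrow(x$peaks), 100 * x$main_peak_fraction, 1000 * x$main_peak_t2))
  invisible(x)
}

#' Screen voxels on T2 mono-exponentiality
#'
#' A voxel is retained for diffusion fitting when the main T2-spectrum peak
#' holds at least `threshold` (default 90%) of the total spectral area, and
#' the voxel is neither fat nor background. Exclusion reasons are coded
#' 0 = background, 1 = include, 2 = fat, 3 = non-mono-exponential T2.
#'
#' @param main_peak_fraction Numeric vector (or 3-D array) of per-voxel main
#'   peak fractions.
#' @param fat Logical vector/array flagging predominantly fat voxels.
#' @param background Logical vector/array flagging background voxels.
#' @param threshold Main-peak area threshold.
#' @return A `screen_mask` list with logical `include` and integer `reason`
#'   of the same shape as the input.
#' @export
screen_voxels <- function(main_peak_fraction, fat = NULL, background = NULL,
                          threshold = 0.90) {
  dm <- dim(main_peak_fraction)
  if (is.null(fat)) fat <- rep(FALSE, length(main_peak_fraction))
  if (is.null(background)) background <- rep(FALSE, length(main_peak_fraction))
  reason <- integer(length(main_peak_fraction))
  reason[] <- 1L
  reason[main_peak_fraction < threshold] <- 3L
  reason[as.logical(fat)] <- 2L
  reason[as.logical(background)] <- 0L
  include <- reason == 1L
  if (!is.null(dm)) { dim(include) <- dm; dim(reason) <- dm }
  structure(list(include = include, reason = reason, threshold = threshold),
            class = "screen_mask")
}

#' @export
print.screen_mask <- function(x, ...) {
  tab <- table(factor(x$reason, 0:3,
                      c("background", "include", "fat", "non-mono-T2")))
  cat("<screen mask>\n"); print(tab); invisible(x)
}

#' Screen a 4-D multi-echo volume
#'
#' Runs [nnls_t2_spectrum()] in every in-mask voxel and applies the
#' main-peak-area rule.
#'
#' @param echo_4d 4-D array (x, y, z, echo).
#' @param echo_times Echo times (s).
#' @param fat,background Optional 3-D logical arrays.
#' @param threshold Main-peak area threshold.
#' @param t2_grid Relaxation-time grid (s).
#' @return A `screen_mask` whose elements are 3-D arrays, plus the per-voxel
#'   `main_peak_fraction` array.
#' @export
screen_volume <- function(echo_4d, echo_times, fat = NULL, background = NULL,
                          threshold = 0.90, t2_grid = t2_grid_default()) {
  dm <- dim(echo_4d)
  if (length(dm) != 4 || dm[4] != length(echo_times)) {
    stop("echo_4d must be 4-D with 4th dimension matching echo_times", call. = FALSE)
  }
  if (is.null(background)) background <- array(FALSE, dm[1:3])
  background <- array(as.logical(background), dm[1:3])
  if (!is.null(fat)) fat <- array(as.logical(fat), dm[1:3])
  mpf <- array(NA_real_, dm[1:3])
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k3 in seq_len(dm[3])) {
    if (background[i, j, k3]) { mpf[i, j, k3] <- 0; next }
    sig <- echo_4d[i, j, k3, ]
    if (all(sig == 0)) { mpf[i, j, k3] <- 0; next }
    mpf[i, j, k3] <- nnls_t2_spectrum(sig, echo_times, t2_grid)$main_peak_fraction
  }
  out <- screen_voxels(mpf, fat = fat, background = background,
                       threshold = threshold)
  out$main_peak_fraction <- mpf
  out
}
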