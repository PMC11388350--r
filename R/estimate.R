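#' Detrend a signal by moving-average subtraction
#'
#' Subtracts a centered moving average of length `window` (minutes) from the
#' trace; edges are handled by reflecting the signal (mirror padding without
#' repeating the edge sample), so the trend estimate exists at every sample.
#'
#' @param values Intensity trace.
#' @param dt Sampling interval, min.
#' @param window Averaging window, min; must be >= 2 sampling intervals and
#'   <= the trace duration.
#' @return Detrended trace, same length.
#' @export
detrend_signal <- function(values, dt, window) {
  n <- length(values)
  if (!is.numeric(values) || n < 3L || any(!is.finite(values))) {
    stop("`values` must be a finite numeric trace (>= 3 samples)",
         call. = FALSE)
  }
  duration <- (n - 1L) * dt
  if (window < 2 * dt || window > duration) {
    stop(sprintf(
      "`window` = %g min out of range [%g, %g] for this trace",
      window, 2 * dt, duration), call. = FALSE)
  }
  k <- max(3L, round(window / dt))
  if (k %% 2L == 0L) k <- k + 1L
  pad <- (k - 1L) %/% 2L
  if (pad > n - 1L) pad <- n - 1L
  ext <- c(rev(values[2L:(pad + 1L)]), values,
           rev(values[(n - pad):(n - 1L)]))
  trend <- as.numeric(stats::filter(ext, rep(1 / k, k), sides = 2L))
  out <- values - trend[(pad + 1L):(pad + n)]
  out - mean(out)  # exact removal of any residual constant offset
}

# Analytic signal via a Hamming-windowed FIR Hilbert transformer applied to
# the mirror-padded trace. The mirror padding removes the end-point
# discontinuity and the finite windowed kernel keeps boundary leakage from
# bleeding into the interior (unlike a plain FFT Hilbert on a short
# non-periodic segment). `half_len` is the kernel half-length in samples,
# about two oscillation periods.
analytic_signal <- function(x, half_len) {
  n <- length(x)
  K <- max(4L, min(as.integer(half_len), n - 1L))
  k <- -K:K
  hk <- ifelse(k %% 2L != 0L, 2 / (pi * k), 0)
  hk <- hk * (0.54 + 0.46 * cos(pi * k / K))
  padded <- c(rev(x[2L:(K + 1L)]), x, rev(x[(n - K):(n - 1L)]))
  ht <- vapply(seq_len(n), function(i) {
    sum(padded[i:(i + 2L * K)] * rev(hk))
  }, numeric(1L))
  complex(real = x, imaginary = ht)
}

# Smoothed instantaneous phase-advance rate (rad/min); moving average over
# about one mid-band period, which cancels periodic ripple in the phase
# derivative. NA where undefined.
smoothed_rate <- function(phase, dt, period_band) {
  n <- length(phase)
  dphi <- c(NA_real_, diff(phase)) / dt
  dphi[1L] <- dphi[2L]
  span <- max(5L, min(n, 2L * round(sqrt(prod(period_band)) / (2 * dt)) + 1L))
  sm <- as.numeric(stats::filter(dphi, rep(1 / span, span), sides = 2L))
  sm[is.na(sm)] <- stats::median(dphi, na.rm = TRUE)
  sm[sm <= 1e-12] <- NA_real_
  sm
}

#' Estimate instantaneous phase and period from an intensity trace
#'
#' Self-contained reimplementation of ridge-based phase extraction:
#' \describe{
#'   \item{`wavelet_ridge`}{Morlet continuous wavelet transform over a
#'     log-spaced period grid; per time point the ridge is the period of
#'     maximal (scale-normalized) power, the phase is the argument of the
#'     ridge coefficient, and the period is refined by parabolic
#'     interpolation of log-power across neighboring scales.}
#'   \item{`analytic_signal`}{Hilbert-transform phase of the detrended trace
#'     (FFT-based, with reflected extension); instantaneous period from the
#'     smoothed phase derivative. Serves as a cross-check on the ridge.}
#' }
#' Phase is unwrapped (cumulative nearest branch) and phase 0 corresponds to
#' the reporter peak (cosine convention). Samples within one ridge period of
#' either end are flagged with `quality = 0`; quality is never extrapolated
#' beyond the edges.
#'
#' @param times Uniform time grid, min.
#' @param values Intensity trace.
#' @param period_band Search band `(min, max)` in minutes; must satisfy
#'   min > 2 * sampling interval and max <= duration / 2. Default `NULL`
#'   clips the standard 60-300 min segmentation-clock band to validity.
#' @param method `"wavelet_ridge"` (default) or `"analytic_signal"`.
#' @param detrend_window Optional moving-average window, min, applied first;
#'   `NULL` subtracts the mean only.
#' @param omega0 Morlet central frequency parameter (default 6).
#' @param n_periods Number of log-spaced periods in the band (default 150).
#' @return Data frame with columns `time_min`, `phase_rad` (unwrapped),
#'   `period_min`, `amplitude`, `quality`; attribute `method`.
#' @export
estimate_phase <- function(times, values,
                           period_band = NULL,
                           method = c("wavelet_ridge", "analytic_signal"),
                           detrend_window = NULL, omega0 = 6,
                           n_periods = 150L) {
  method <- match.arg(method)
  dt <- check_uniform_times(times)
  n <- length(values)
  if (length(values) != length(times)) {
    stop("`values` must match `times`", call. = FALSE)
  }
  duration <- times[n] - times[1L]
  if (is.null(period_band)) {
    period_band <- c(max(60, 2.5 * dt), min(300, duration / 2))
    if (period_band[1L] >= period_band[2L]) {
      stop("trace too short for the default period band; supply one",
           call. = FALSE)
    }
  }
  if (period_band[1L] <= 2 * dt || period_band[2L] > duration / 2) {
    stop(sprintf(
      "`period_band` must lie within (%.3g, %.3g) min for this trace",
      2 * dt, duration / 2), call. = FALSE)
  }
  x <- if (is.null(detrend_window)) values - mean(values) else {
    detrend_signal(values, dt, detrend_window)
  }
  if (stats::sd(x) < 1e-12) {
    stop("no oscillation detected: trace is constant after detrending",
         call. = FALSE)
  }
  if (method == "wavelet_ridge") {
    npad <- 2^ceiling(log2(2 * n))
    xh <- stats::fft(c(x, rep(0, npad - n)))
    k <- 0:(npad - 1L)
    wk <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
    periods <- exp(seq(log(period_band[1L]), log(period_band[2L]),
                       length.out = n_periods))
    fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
    scales <- periods / fourier_factor
    W <- matrix(0 + 0i, n_periods, n)
    for (j in seq_len(n_periods)) {
      psi <- pi^(-0.25) * exp(-((scales[j] * wk - omega0)^2) / 2) * (wk > 0)
      wj <- stats::fft(xh * psi * sqrt(2 * pi * scales[j] / dt),
                       inverse = TRUE) / npad
      W[j, ] <- wj[seq_len(n)]
    }
    pw <- Mod(W)^2 / scales  # scale-normalized power for an unbiased ridge
    ridge <- apply(pw, 2L, which.max)
    sel <- cbind(ridge, seq_len(n))
    if (max(Mod(W[sel])) < 1e-10) {
      stop("no oscillation detected: no ridge above power threshold",
           call. = FALSE)
    }
    phase <- unwrap_phase(Arg(W[sel]))
    # ridge period, refined parabolically in log-period across scales
    lp <- log(periods)
    ridge_period <- vapply(seq_len(n), function(i) {
      j <- ridge[i]
      if (j <= 1L || j >= n_periods) return(periods[j])
      y <- log(pw[(j - 1L):(j + 1L), i] + .Machine$double.xmin)
      denom <- y[1L] - 2 * y[2L] + y[3L]
      if (abs(denom) < 1e-300) return(periods[j])
      delta <- 0.5 * (y[1L] - y[3L]) / denom
      exp(lp[j] + delta * (lp[2L] - lp[1L]))
    }, numeric(1L))
    # instantaneous period from the (accurate) ridge phase derivative,
    # falling back on the ridge period where the derivative is unusable
    period <- 2 * pi / smoothed_rate(phase, dt, period_band)
    bad <- !is.finite(period) | period <= 0
    period[bad] <- ridge_period[bad]
    amplitude <- Mod(W[sel])
    quality <- pw[sel] / max(pw[sel])
  } else {
    half_len <- round(2 * sqrt(prod(period_band)) / dt)
    a <- analytic_signal(x, half_len)
    phase <- unwrap_phase(Arg(a))
    amplitude <- Mod(a)
    period <- 2 * pi / smoothed_rate(phase, dt, period_band)
    period[!is.finite(period) | period <= 0] <- Inf
    quality <- amplitude / max(amplitude)
  }
  edge <- stats::median(period[is.finite(period)])
  lowq <- times - times[1L] < edge | times[n] - times < edge
  quality[lowq] <- 0
  out <- data.frame(time_min = times, phase_rad = phase,
                    period_min = period, amplitude = amplitude,
                    quality = quality)
  attr(out, "method") <- method
  out
}

#' Circular synchrony statistics of a phase sample
#'
#' Kuramoto order parameter R = |mean(exp(i * phi))|, circular mean (the
#' argument of the resultant, in (-pi, pi]) and circular SD
#' sqrt(-2 * log(R)). R = 1 iff all phases coincide (circular SD 0); R = 0
#' for symmetric configurations (circular SD infinite).
#'
#' @param phases Numeric vector of phases, rad (n >= 1).
#' @return List with `kop`, `circ_mean`, `circ_sd`.
#' @examples
#' circular_stats(c(0.7, 0.7, 0.7))  # kop = 1, circ_sd = 0
#' @export
circular_stats <- function(phases) {
  if (!length(phases)) stop("`phases` must not be empty", call. = FALSE)
  if (any(!is.finite(phases))) stop("`phases` must be finite", call. = FALSE)
  z <- mean(exp(1i * phases))
  kop <- Mod(z)
  if (kop > 1 - 1e-15) kop <- 1  # snap float roundoff at perfect synchrony
  list(kop = kop,
       circ_mean = if (kop == 0) 0 else Arg(z),
       circ_sd = sqrt(-2 * log(kop)))
}

#' Per-time-point synchrony of an ensemble of phase series
#'
#' Applies [circular_stats()] across rows of a time-by-oscillator phase
#' matrix.
#'
#' @param phase_matrix Matrix, rows = time points, columns = oscillators/ROIs.
#' @return Data frame with columns `kop`, `circ_mean`, `circ_sd`, one row per
#'   time point.
#' @export
synchrony_over_time <- function(phase_matrix) {
  stopifnot(is.matrix(phase_matrix))
  out <- t(apply(phase_matrix, 1L, function(p) {
    s <- circular_stats(p)
    c(s$kop, s$circ_mean, s$circ_sd)
  }))
  data.frame(kop = out[, 1L], circ_mean = out[, 2L], circ_sd = out[, 3L])
}
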