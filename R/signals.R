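# Electrophysiology / sensor processing. Filtering goes through the
# `signal` package (Butterworth design, forward-backward filtering); spectra
# are computed on stats::fft with the periodogram normalised so that the
# one-sided power sums to the mean square of the signal (Parseval), which
# makes the normalisation testable.

#' Impose a uniform time base on a trace
#'
#' Replaces the timestamps with `i / fs` for sample index `i = 0, 1, ...`,
#' leaving the values untouched. This is the repair step for sensor exports
#' where time values are missing or unreliable in the raw data but the
#' sampling rate is known.
#'
#' @param s a [signal_trace()].
#' @param fs sampling rate (samples per time unit), positive.
#' @return The trace on the new time base.
#' @export
set_time_base <- function(s, fs) {
  stopifnot(inherits(s, "signal_trace"))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    ma_stop("validation_error", "fs must be a positive number")
  update_trace(s, (seq_along(s$values) - 1L) / fs, s$values,
               history_entry("set_time_base", fs = fs))
}

#' Resample a uniform trace to a new rate
#'
#' Interpolates onto a uniform grid at `new_fs` spanning the same closed
#' time range. The first sample always coincides with the original start;
#' for linear interpolation original endpoint values are preserved whenever
#' the span is an integer number of new sampling intervals.
#'
#' @param s a uniformly sampled [signal_trace()] (use [set_time_base()]
#'   first otherwise).
#' @param new_fs target sampling rate.
#' @param method `"linear"` or `"cubic"` (natural spline).
#' @return The resampled trace.
#' @export
resample_signal <- function(s, new_fs, method = c("linear", "cubic")) {
  stopifnot(inherits(s, "signal_trace"))
  method <- match.arg(method)
  if (!is.numeric(new_fs) || length(new_fs) != 1L || new_fs <= 0)
    ma_stop("validation_error", "new_fs must be a positive number")
  sampling_rate(s)  # raises contract_error on non-uniform input
  t0 <- s$times[1L]
  span <- s$times[length(s$times)] - t0
  m <- floor(span * new_fs + 1e-9) + 1L
  tout <- t0 + (seq_len(m) - 1L) / new_fs
  vout <- if (method == "linear")
    stats::approx(s$times, s$values, xout = tout, rule = 2)$y
  else
    stats::spline(s$times, s$values, xout = tout, method = "natural")$y
  update_trace(s, tout, vout,
               history_entry("resample", new_fs = new_fs, method = method))
}

#' Butterworth filtering
#'
#' Digital Butterworth filter of adjustable order. By default the filter is
#' applied forward and backward (zero-phase, doubling the effective order),
#' so filtered signals keep their phase relationships — essential when the
#' output feeds the phase-lag estimator. Set `zero_phase = FALSE` for a
#' causal single pass.
#'
#' @param s a uniformly sampled [signal_trace()].
#' @param kind `"low"`, `"high"`, `"band"` or `"stop"`.
#' @param cutoffs corner frequency in Hz (one value for low/high, `c(lo,
#'   hi)` for band/stop), strictly below Nyquist.
#' @param order filter order, >= 1 (default 4).
#' @param zero_phase forward-backward filtering (default `TRUE`).
#' @return The filtered trace.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' s <- signal_trace("tone", t, sin(2 * pi * 5 * t))
#' butterworth(s, "low", 100)
butterworth <- function(s, kind = c("low", "high", "band", "stop"),
                        cutoffs, order = 4L, zero_phase = TRUE) {
  stopifnot(inherits(s, "signal_trace"))
  kind <- match.arg(kind)
  fs <- sampling_rate(s)
  nyq <- fs / 2
  nexp <- if (kind %in% c("band", "stop")) 2L else 1L
  if (length(cutoffs) != nexp)
    ma_stop("validation_error", "'%s' filter takes %d cutoff(s)", kind, nexp)
  if (any(cutoffs <= 0) || any(cutoffs >= nyq))
    ma_stop("validation_error",
            "cutoffs must lie strictly between 0 and Nyquist (%g)", nyq)
  if (nexp == 2L && cutoffs[1L] >= cutoffs[2L])
    ma_stop("validation_error", "need f_lo < f_hi")
  if (order < 1L)
    ma_stop("validation_error", "filter order must be >= 1")
  type <- switch(kind, low = "low", high = "high", band = "pass", stop = "stop")
  flt <- signal::butter(order, cutoffs / nyq, type = type)
  v <- if (zero_phase) signal::filtfilt(flt, s$values)
       else as.numeric(signal::filter(flt, s$values))
  update_trace(s, s$times, v,
               history_entry("butterworth", kind = kind, cutoffs = cutoffs,
                             order = order, zero_phase = zero_phase))
}

#' Rectify a signal
#'
#' The usual EMG conditioning variants: `"mean"` removes the DC offset
#' (`x - mean(x)`, the baseline step before full-wave rectification),
#' `"absolute"` takes `|x|`, `"square_root"` takes `sqrt(x^2)` per sample
#' (numerically identical to the absolute value; kept as a distinct named
#' method), and `"half_wave"` clamps negative samples to zero.
#'
#' @param s a [signal_trace()].
#' @param method rectification method.
#' @return The rectified trace.
#' @export
rectify <- function(s, method = c("mean", "absolute", "square_root",
                                  "half_wave")) {
  stopifnot(inherits(s, "signal_trace"))
  method <- match.arg(method)
  v <- switch(method,
              mean = s$values - mean(s$values),
              absolute = abs(s$values),
              square_root = sqrt(s$values^2),
              half_wave = pmax(s$values, 0))
  update_trace(s, s$times, v, history_entry("rectify", method = method))
}

# analytic signal via the FFT construction (doubled positive frequencies)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Signal envelope
#'
#' Extracts the slowly varying amplitude profile of an oscillatory signal.
#' `"lowpass"` is the classic linear-envelope method (Butterworth low-pass
#' of a rectified signal — the history is checked and a contract error is
#' raised if the trace was never rectified, unless `force = TRUE`);
#' `"hilbert"` is the magnitude of the analytic signal; `"moving_mean"` and
#' `"moving_rms"` use centered windows with shrinking edges.
#'
#' @param s a [signal_trace()].
#' @param method envelope method.
#' @param fc low-pass corner frequency (Hz) for `"lowpass"`.
#' @param order Butterworth order for `"lowpass"`.
#' @param w odd window width (samples) for the moving methods.
#' @param force skip the rectification-history check for `"lowpass"`.
#' @return The envelope as a trace.
#' @export
envelope <- function(s, method = c("lowpass", "hilbert", "moving_mean",
                                   "moving_rms"),
                     fc = NULL, order = 4L, w = 5L, force = FALSE) {
  stopifnot(inherits(s, "signal_trace"))
  method <- match.arg(method)
  if (method == "lowpass") {
    if (is.null(fc))
      ma_stop("validation_error", "lowpass envelope needs a corner frequency fc")
    ops <- vapply(s$meta, `[[`, character(1), "op")
    if (!force && !"rectify" %in% ops)
      ma_stop("contract_error",
              "lowpass envelope expects a rectified signal; rectify() first or use force = TRUE")
    out <- butterworth(s, "low", fc, order = order)
    out$meta[[length(out$meta)]] <-
      history_entry("envelope", method = "lowpass", fc = fc, order = order)
    return(out)
  }
  if (method == "hilbert") {
    v <- Mod(analytic_signal(s$values))
    return(update_trace(s, s$times, v,
                        history_entry("envelope", method = "hilbert")))
  }
  if (w %% 2L == 0L || w < 3L)
    ma_stop("validation_error", "window width must be odd and >= 3")
  fun <- if (method == "moving_mean") mean else function(x) sqrt(mean(x^2))
  update_trace(s, s$times, roll_stat(s$values, w, fun),
               history_entry("envelope", method = method, w = w))
}

#' One-sided power spectrum
#'
#' Periodogram of a uniformly sampled trace, normalised as
#' `|X_k|^2 / n^2` with one-sided doubling (except the DC and Nyquist
#' bins) so that the powers sum to the mean square of the signal.
#'
#' @param s a uniformly sampled [signal_trace()] with at least 8 samples.
#' @return A `spectrum_result`: `frequencies` (0 to fs/2), `power`, `n`,
#'   `fs`.
#' @export
power_spectrum <- function(s) {
  stopifnot(inherits(s, "signal_trace"))
  fs <- sampling_rate(s)
  n <- length(s$values)
  if (n < 8L)
    ma_stop("validation_error", "power spectrum needs at least 8 samples")
  X <- stats::fft(s$values)
  half <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(half)])^2 / n^2
  dbl <- 2L:(half - if (n %% 2L == 0L) 1L else 0L)
  p[dbl] <- 2 * p[dbl]
  structure(
    list(frequencies = (seq_len(half) - 1L) * fs / n, power = p,
         n = n, fs = fs, label = s$label),
    class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("<spectrum_result> '%s': %d bins, df %.4g Hz, peak at %.4g Hz\n",
              x$label, length(x$power), x$fs / x$n, peak_frequency(x)))
  invisible(x)
}

#' Peak frequency of a spectrum
#'
#' Frequency of the maximum power bin, excluding DC.
#'
#' @param sp a [power_spectrum()] result.
#' @return Frequency in the spectrum's unit (Hz for seconds-based data).
#' @export
peak_frequency <- function(sp) {
  stopifnot(inherits(sp, "spectrum_result"))
  sp$frequencies[-1L][which.max(sp$power[-1L])]
}

window_fn_values <- function(name, m) {
  switch(name,
         hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1L) / (m - 1L)),
         rect = rep(1, m))
}

#' Spectrogram (short-time Fourier transform)
#'
#' Magnitude-squared STFT over sliding windows. Defaults follow common
#' biosignal practice: Hann window of 256 samples with 50% overlap.
#'
#' @param s a uniformly sampled [signal_trace()].
#' @param window_len window length in samples, `<= n`.
#' @param overlap_frac fractional overlap in `[0, 1)`.
#' @param window_fn `"hann"` or `"rect"`.
#' @return A `spectrogram_result`: `times` (window centers), `frequencies`,
#'   `power` matrix (`n_freqs x n_windows`), window parameters.
#' @export
spectrogram <- function(s, window_len = 256L, overlap_frac = 0.5,
                        window_fn = c("hann", "rect")) {
  stopifnot(inherits(s, "signal_trace"))
  window_fn <- match.arg(window_fn)
  fs <- sampling_rate(s)
  n <- length(s$values)
  w <- as.integer(window_len)
  if (w > n || w < 8L)
    ma_stop("validation_error", "window length must be in [8, %d]", n)
  if (overlap_frac < 0 || overlap_frac >= 1)
    ma_stop("validation_error", "overlap fraction must be in [0, 1)")
  hop <- max(1L, as.integer(round(w * (1 - overlap_frac))))
  starts <- seq(1L, n - w + 1L, by = hop)
  win <- window_fn_values(window_fn, w)
  half <- floor(w / 2) + 1L
  pw <- vapply(starts, function(i) {
    X <- stats::fft(s$values[i:(i + w - 1L)] * win)
    Mod(X[seq_len(half)])^2 / w^2
  }, numeric(half))
  structure(
    list(times = s$times[starts + w %/% 2L],
         frequencies = (seq_len(half) - 1L) * fs / w,
         power = matrix(pw, nrow = half),
         window_len = w, overlap_frac = overlap_frac,
         window_fn = window_fn, label = s$label),
    class = "spectrogram_result")
}

#' Area under the curve
#'
#' Trapezoidal integral of the trace over `[t0, t1]`; the window bounds are
#' reached by linear interpolation when they fall between samples.
#'
#' @param s a [signal_trace()].
#' @param t0,t1 integration bounds within the recorded range.
#' @return The integral (value unit times time unit).
#' @export
area_under_curve <- function(s, t0 = NULL, t1 = NULL) {
  stopifnot(inherits(s, "signal_trace"))
  if (is.null(t0)) t0 <- s$times[1L]
  if (is.null(t1)) t1 <- s$times[length(s$times)]
  if (t0 >= t1)
    ma_stop("validation_error", "need t0 < t1")
  if (t0 < s$times[1L] || t1 > s$times[length(s$times)])
    ma_stop("validation_error", "integration bounds outside the recorded range")
  inside <- s$times > t0 & s$times < t1
  tt <- c(t0, s$times[inside], t1)
  vv <- c(stats::approx(s$times, s$values, xout = t0)$y,
          s$values[inside],
          stats::approx(s$times, s$values, xout = t1)$y)
  pracma::trapz(tt, vv)
}
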