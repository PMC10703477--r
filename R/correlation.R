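# Comparison machinery for signals and kinematic series: normalised auto-
# and cross-correlation, FFT phase lag and amplitude ratio, similarity
# metrics, band-constrained dynamic time warping, cyclograms, and the
# harmonisation step that puts heterogeneously sampled series on a common
# grid before any of the above.

# accept a signal_trace, an angle_series, or a bare numeric vector
as_trace <- function(x, label = "series") {
  if (inherits(x, "signal_trace")) return(x)
  if (inherits(x, "angle_series"))
    return(signal_trace(paste(x$flank[1L], x$vertex, x$flank[2L], sep = "-"),
                        x$times, x$values))
  if (is.numeric(x))
    return(signal_trace(label, seq_along(x) - 1L, x))
  ma_stop("validation_error", "expected a signal_trace, angle_series or numeric vector")
}

#' Harmonize two series onto a common grid
#'
#' Trims both inputs to their overlapping time range and linearly resamples
#' them to the lower of the two sampling rates (downsampling rather than
#' fabricating detail), yielding equal-length series ready for correlation.
#'
#' @param a,b [signal_trace()] or [joint_angle()] series with overlapping
#'   time ranges.
#' @return A list `a`, `b` (harmonized traces) and `report` (common rate,
#'   window, length).
#' @export
harmonize <- function(a, b) {
  a <- as_trace(a, "a"); b <- as_trace(b, "b")
  t0 <- max(a$times[1L], b$times[1L])
  t1 <- min(a$times[length(a$times)], b$times[length(b$times)])
  if (t0 >= t1)
    ma_stop("validation_error", "time ranges do not overlap")
  fs <- min(sampling_rate(a), sampling_rate(b))
  m <- floor((t1 - t0) * fs + 1e-9) + 1L
  tout <- t0 + (seq_len(m) - 1L) / fs
  res <- function(s) update_trace(
    s, tout, stats::approx(s$times, s$values, xout = tout, rule = 2)$y,
    history_entry("harmonize", fs = fs, t0 = t0, t1 = t1))
  list(a = res(a), b = res(b),
       report = list(fs = fs, t0 = t0, t1 = tout[m], n = m))
}

norm_xcorr <- function(x, y, max_lag, dt) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom == 0)
    ma_stop("validation_error", "zero-variance input")
  lags <- seq.int(-max_lag, max_lag)
  r <- vapply(lags, function(l) {
    if (l >= 0) sum(xc[seq_len(n - l)] * yc[seq_len(n - l) + l])
    else        sum(xc[seq_len(n + l) - l] * yc[seq_len(n + l)])
  }, numeric(1)) / denom
  ipk <- which.max(r)
  structure(
    list(lags = lags, lag_times = lags * dt, coefficients = r,
         r0 = r[lags == 0L], peak_lag = lags[ipk], peak_lag_time = lags[ipk] * dt,
         peak_coefficient = r[ipk], max_lag = max_lag),
    class = "correlation_result")
}

#' Auto- and cross-correlation
#'
#' Normalised cross-covariance
#' `r(l) = sum (a_t - mean(a)) (b_(t+l) - mean(b)) / sqrt(sum (a - mean(a))^2 sum (b - mean(b))^2)`
#' over lags `-max_lag ... max_lag`. The autocorrelation is the self case
#' with `r(0) = 1` exactly; for a rhythmic signal it shows a decaying
#' cosine at the signal's period. Inputs must share length and sampling
#' (use [harmonize()] first).
#'
#' @param s,a,b [signal_trace()] objects or numeric vectors.
#' @param max_lag maximum lag in samples (default `n - 1`... capped).
#' @return A `correlation_result`: `lags` (samples), `lag_times`,
#'   `coefficients`, `r0`, `peak_lag`, `peak_coefficient`.
#' @export
autocorrelation <- function(s, max_lag = NULL) {
  s <- as_trace(s)
  n <- length(s$values)
  if (is.null(max_lag)) max_lag <- n %/% 2L
  if (max_lag >= n || max_lag < 0L)
    ma_stop("validation_error", "max_lag must be in [0, n)")
  norm_xcorr(s$values, s$values, max_lag, mean(diff(s$times)))
}

#' @rdname autocorrelation
#' @export
cross_correlation <- function(a, b, max_lag = NULL) {
  a <- as_trace(a, "a"); b <- as_trace(b, "b")
  if (length(a$values) != length(b$values))
    ma_stop("validation_error",
            "inputs differ in length (%d vs %d); harmonize() first",
            length(a$values), length(b$values))
  n <- length(a$values)
  if (is.null(max_lag)) max_lag <- n %/% 2L
  if (max_lag >= n || max_lag < 0L)
    ma_stop("validation_error", "max_lag must be in [0, n)")
  norm_xcorr(a$values, b$values, max_lag, mean(diff(a$times)))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> lags -%d..%d, r(0) = %.4f, peak %.4f at lag %d\n",
              x$max_lag, x$max_lag, x$r0, x$peak_coefficient, x$peak_lag))
  invisible(x)
}

wrap_deg <- function(x) {
  w <- ((x + 180) %% 360) - 180
  ifelse(w <= -180, w + 360, w)
}

#' FFT phase lag and amplitude ratio
#'
#' Identifies the peak frequency of the first signal's FFT magnitude
#' (excluding DC), reads both signals' complex FFT phases at that common
#' frequency, and reports the wrapped phase difference together with the
#' ratio of FFT magnitudes (second over first). Using the first signal's
#' peak for both keeps the phase difference well defined even when the two
#' spectra peak at slightly different bins. Best accuracy is obtained over
#' an integer number of periods (no spectral leakage).
#'
#' @param a reference [signal_trace()] (or numeric vector).
#' @param b probe signal, same length and sampling rate.
#' @return A `phase_amplitude_result`: `peak_frequency`, `phase_a`,
#'   `phase_b` (degrees), `phase_lag` (a minus b, wrapped to (-180, 180]),
#'   `amplitude_ratio` (b over a).
#' @export
phase_amplitude <- function(a, b) {
  a <- as_trace(a, "a"); b <- as_trace(b, "b")
  if (length(a$values) != length(b$values))
    ma_stop("validation_error", "inputs differ in length; harmonize() first")
  n <- length(a$values)
  if (n < 8L)
    ma_stop("validation_error", "need at least 8 samples")
  fs <- sampling_rate(a)
  if (abs(fs - sampling_rate(b)) > 1e-9 * fs)
    ma_stop("validation_error", "inputs differ in sampling rate; harmonize() first")
  A <- stats::fft(a$values); B <- stats::fft(b$values)
  half <- floor(n / 2) + 1L
  magA <- Mod(A[seq_len(half)])
  if (max(magA[-1L]) <= 1e-12 * n)
    ma_stop("validation_error", "flat reference spectrum; no peak frequency")
  k <- which.max(magA[-1L]) + 1L
  ph_a <- Arg(A[k]) * 180 / pi
  ph_b <- Arg(B[k]) * 180 / pi
  structure(
    list(peak_frequency = (k - 1L) * fs / n,
         phase_a = ph_a, phase_b = ph_b,
         phase_lag = wrap_deg(ph_a - ph_b),
         amplitude_ratio = Mod(B[k]) / Mod(A[k])),
    class = "phase_amplitude_result")
}

#' @export
print.phase_amplitude_result <- function(x, ...) {
  cat(sprintf("<phase_amplitude_result> f* = %.4g Hz, phase lag %.2f deg, amplitude ratio %.4f\n",
              x$peak_frequency, x$phase_lag, x$amplitude_ratio))
  invisible(x)
}

#' Similarity between two equal-length series
#'
#' Standard scalar comparisons: Euclidean distance, cosine similarity, and
#' Pearson, Spearman or Kendall (tau-b, tie-corrected) correlation.
#'
#' @param a,b numeric vectors or [signal_trace()] objects of equal length.
#' @param metric one of `"euclidean"`, `"cosine"`, `"pearson"`,
#'   `"spearman"`, `"kendall"`.
#' @return A scalar.
#' @export
similarity <- function(a, b, metric = c("euclidean", "cosine", "pearson",
                                        "spearman", "kendall")) {
  metric <- match.arg(metric)
  av <- as_trace(a, "a")$values; bv <- as_trace(b, "b")$values
  if (length(av) != length(bv))
    ma_stop("validation_error", "inputs differ in length")
  if (length(av) < 2L)
    ma_stop("validation_error", "need at least 2 samples")
  if (metric %in% c("pearson", "spearman", "kendall") &&
      (stats::var(av) == 0 || stats::var(bv) == 0))
    ma_stop("validation_error", "zero-variance input for %s correlation", metric)
  switch(metric,
         euclidean = sqrt(sum((av - bv)^2)),
         cosine = sum(av * bv) / sqrt(sum(av^2) * sum(bv^2)),
         stats::cor(av, bv, method = metric))
}

#' Dynamic time warping with a Sakoe-Chiba band
#'
#' Minimum-cost monotone alignment of two series under per-sample cost
#' `|a_i - b_j|`, symmetric steps (down, right, diagonal) and a diagonal
#' corridor `|i - j| <= band` that bounds the computation. The band must be
#' at least `|n - m|` or no complete path exists.
#'
#' @param a,b numeric vectors or [signal_trace()] objects.
#' @param band non-negative integer half-width of the corridor.
#' @return A `dtw_result`: `distance` (cumulative cost), `path` (two-column
#'   index matrix from `(1, 1)` to `(n, m)`), `band`.
#' @export
dtw_align <- function(a, b, band) {
  av <- as_trace(a, "a")$values; bv <- as_trace(b, "b")$values
  n <- length(av); m <- length(bv)
  band <- as.integer(band)
  if (band < abs(n - m))
    ma_stop("infeasible_band_error",
            "band %d is smaller than the length difference |%d - %d|",
            band, n, m)
  D <- matrix(Inf, n, m)
  for (i in seq_len(n)) {
    jr <- max(1L, i - band):min(m, i + band)
    for (j in jr) {
      cost <- abs(av[i] - bv[j])
      best <- if (i == 1L && j == 1L) 0 else min(
        if (i > 1L) D[i - 1L, j] else Inf,
        if (j > 1L) D[i, j - 1L] else Inf,
        if (i > 1L && j > 1L) D[i - 1L, j - 1L] else Inf)
      D[i, j] <- cost + best
    }
  }
  # backtrack
  path <- matrix(NA_integer_, n + m, 2L)
  k <- n + m
  i <- n; j <- m
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    opts <- rbind(
      if (i > 1L && j > 1L) c(i - 1L, j - 1L, D[i - 1L, j - 1L]),
      if (i > 1L) c(i - 1L, j, D[i - 1L, j]),
      if (j > 1L) c(i, j - 1L, D[i, j - 1L]))
    pick <- opts[which.min(opts[, 3L]), ]
    i <- pick[1L]; j <- pick[2L]
    k <- k - 1L
    path[k, ] <- c(i, j)
  }
  structure(
    list(distance = D[n, m], path = path[k:(n + m), , drop = FALSE],
         band = band),
    class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance %.6g, path length %d, band %d\n",
              x$distance, nrow(x$path), x$band))
  invisible(x)
}

#' Cyclogram of two joint angles
#'
#' Pairs two angle series sample-by-sample into the ordered
#' `(theta1(t), theta2(t))` trajectory used for angle-angle loop plots.
#' The series must share a time base; [harmonize()] heterogeneous inputs
#' first.
#'
#' @param angle1,angle2 [joint_angle()] series (or harmonized traces).
#' @return A `cyclogram`: data frame `t`, `theta1`, `theta2` plus axis
#'   labels.
#' @export
cyclogram <- function(angle1, angle2) {
  a <- as_trace(angle1, "theta1"); b <- as_trace(angle2, "theta2")
  if (length(a$times) != length(b$times) ||
      !common_time_base(a$times, b$times, 1e-9))
    ma_stop("contract_error",
            "angle series are not on a common time base; harmonize() first")
  structure(
    list(pairs = data.frame(t = a$times, theta1 = a$values, theta2 = b$values),
         labels = c(a$label, b$label)),
    class = "cyclogram")
}
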