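# Deterministic generators for the validation fixtures: trajectories,
# angle chains, a dummy gait sequence and sine mixtures with known ground
# truth. Each generator returns a fixture_bundle carrying the generated
# data, the expected analysis results and the exact parameters used, so the
# whole test suite runs from code with no external data.

fixture_bundle <- function(elements = list(), signals = list(), truth = list(),
                           params = list(), seed = NULL) {
  structure(
    list(elements = elements, signals = signals, truth = truth,
         params = params, seed = seed),
    class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %d element(s), %d signal(s), truth: %s\n",
              length(x$elements), length(x$signals),
              paste(names(x$truth), collapse = ", ")))
  invisible(x)
}

eval_poly <- function(coeffs, t) {
  out <- numeric(length(t))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * t^(k - 1L)
  out
}

#' Polynomial trajectory fixture
#'
#' Samples a 2D trajectory with polynomial coordinates (coefficients in
#' ascending order, degree at most 3) and records the exact forward-
#' difference ground truth for speeds and accelerations. The defaults are
#' the kinematic validation case: x linear in time (constant speed, null
#' acceleration) and y quadratic (linearly increasing speed, constant
#' acceleration). An optional outlier is injected into y after the truth is
#' computed, so the truth describes the clean trajectory.
#'
#' @param t0,t1,dt sampling window and interval.
#' @param x_coeffs,y_coeffs polynomial coefficients `c(c0, c1, c2, c3)`.
#' @param outlier optional `list(index, value)` replacing one y sample.
#' @return A `fixture_bundle` with element `"trajectory"` (POI `"p"`) and
#'   truth entries `times`, `vx`, `vy`, `ax`, `ay`, `path_length`,
#'   `outlier`.
#' @export
gen_polynomial_trajectory <- function(t0 = 0, t1 = 10, dt = 1,
                                      x_coeffs = c(0, 2),
                                      y_coeffs = c(0, 0, 1),
                                      outlier = NULL) {
  if (dt <= 0) ma_stop("validation_error", "dt must be positive")
  if (length(x_coeffs) > 4L || length(y_coeffs) > 4L)
    ma_stop("validation_error", "polynomial degree at most 3")
  t <- seq(t0, t1, by = dt)
  x <- eval_poly(x_coeffs, t)
  y <- eval_poly(y_coeffs, t)
  n <- length(t)
  span <- (t[-(1:2)] - t[seq_len(n - 2L)]) / 2
  truth <- list(
    times = t,
    vx = diff(x) / diff(t), vy = diff(y) / diff(t),
    path_length = sum(sqrt(diff(x)^2 + diff(y)^2)),
    outlier = outlier)
  truth$ax <- diff(truth$vx) / span
  truth$ay <- diff(truth$vy) / span
  if (!is.null(outlier)) {
    i <- outlier$index
    if (is.null(i) || i < 1L || i > n)
      ma_stop("validation_error", "outlier index out of range")
    y[i] <- outlier$value
  }
  e <- element("trajectory",
               list(poi_trajectory("p", t, cbind(x = x, y = y))))
  fixture_bundle(elements = list(trajectory = e), truth = truth,
                 params = list(t0 = t0, t1 = t1, dt = dt,
                               x_coeffs = x_coeffs, y_coeffs = y_coeffs,
                               outlier = outlier))
}

#' Known-angle segment chain fixture
#'
#' One frame per requested angle: POIs A = (0,0) and B = (1,0) are fixed
#' and C = B + (cos(180 - theta), sin(180 - theta)) places the interior
#' angle at the vertex B exactly at theta degrees. The angle validation set
#' is 0, 90 and 135 degrees.
#'
#' @param angles vector of angles in `[0, 180]` degrees.
#' @return A `fixture_bundle` with element `"angle_chain"` (POIs A, B, C)
#'   and truth entry `angles`.
#' @export
gen_angle_chain <- function(angles = c(0, 90, 135)) {
  if (any(angles < 0 | angles > 180))
    ma_stop("validation_error", "angles must lie in [0, 180] degrees")
  k <- length(angles)
  t <- seq_len(k) - 1L
  phi <- (180 - angles) * pi / 180
  e <- element("angle_chain", list(
    poi_trajectory("A", t, cbind(x = rep(0, k), y = rep(0, k))),
    poi_trajectory("B", t, cbind(x = rep(1, k), y = rep(0, k))),
    poi_trajectory("C", t, cbind(x = 1 + cos(phi), y = sin(phi)))))
  fixture_bundle(elements = list(angle_chain = e),
                 truth = list(angles = angles),
                 params = list(angles = angles))
}

# smooth swing easing: 0 at s=0, 1 at s=1, zero slope at both ends
swing_ease <- function(s) 0.5 - 0.5 * cos(pi * s)

#' Dummy gait sequence fixture
#'
#' Builds heel, toe and knee trajectories of a leg walking along x with
#' fully known gait parameters. The heel rests at each `hs_positions` value
#' during stance and advances smoothly during swing; the toe leaves the
#' ground at toe-off and follows a half-sine vertical arc peaking at
#' `toe_apex` at mid-swing. The defaults reproduce the printed validation
#' gait: heel-strikes at positions 0, 7, 14 at times 0, 6, 12 s with a 4 s
#' stance, giving a stride length of 7, stance/swing of 4 s / 2 s and a
#' maximum toe-lift of 0.5 (arbitrary units). A contralateral copy offset
#' by half a stride supports bipedal step-parameter tests.
#'
#' @param hs_positions heel-strike progression coordinates (>= 2).
#' @param hs_times heel-strike times, strictly increasing.
#' @param stance_s stance duration, shorter than every stride.
#' @param toe_apex vertical toe peak during swing.
#' @param fps sampling rate; the default grid makes every event time an
#'   exact sample.
#' @param side side label of the generated events.
#' @return A `fixture_bundle` with elements `"leg"` (POIs heel, toe, knee)
#'   and `"legs"` (both sides), the ground-truth [gait_events()] in
#'   `truth$events` / `truth$events_both`, and the expected per-cycle
#'   parameters in `truth$cycles`.
#' @export
gen_dummy_gait <- function(hs_positions = c(0, 7, 14),
                           hs_times = c(0, 6, 12),
                           stance_s = 4, toe_apex = 0.5, fps = 100,
                           side = "left") {
  k <- length(hs_positions)
  if (k < 2L || length(hs_times) != k)
    ma_stop("validation_error",
            "need >= 2 heel strikes with matching positions and times")
  if (any(diff(hs_positions) <= 0) || any(diff(hs_times) <= 0))
    ma_stop("validation_error", "positions and times must be increasing")
  strides <- diff(hs_times)
  if (stance_s >= min(strides))
    ma_stop("validation_error", "stance (%g) must be shorter than every stride",
            stance_s)
  toe_len <- 0.2 * min(diff(hs_positions))
  t <- seq(hs_times[1L], hs_times[k], by = 1 / fps)

  leg_coords <- function(shift_t = 0, shift_x = 0) {
    # piecewise pose as a function of time within the heel-strike schedule
    ht <- hs_times + shift_t
    heel_x <- numeric(length(t)); heel_y <- numeric(length(t))
    toe_x <- numeric(length(t)); toe_y <- numeric(length(t))
    for (i in seq_along(t)) {
      ti <- t[i]
      seg <- findInterval(ti, ht, rightmost.closed = FALSE)
      seg <- min(max(seg, 1L), k - 1L)
      tin <- ti - ht[seg]
      if (ti <= ht[1L]) { seg <- 1L; tin <- 0 }
      if (tin <= stance_s || seg == k) {
        heel_x[i] <- hs_positions[seg]; heel_y[i] <- 0
        toe_x[i] <- hs_positions[seg] + toe_len; toe_y[i] <- 0
      } else {
        s <- (tin - stance_s) / (strides[seg] - stance_s)
        s <- min(max(s, 0), 1)
        heel_x[i] <- hs_positions[seg] +
          diff(hs_positions)[seg] * swing_ease(s)
        heel_y[i] <- 0.6 * toe_apex * sin(pi * s)
        toe_x[i] <- heel_x[i] + toe_len
        toe_y[i] <- toe_apex * sin(pi * s)
      }
    }
    list(heel = cbind(x = heel_x + shift_x, y = heel_y),
         toe = cbind(x = toe_x + shift_x, y = toe_y),
         knee = cbind(x = heel_x + shift_x + 0.5 * toe_len,
                      y = heel_y + 2 * toe_apex + 0.5))
  }

  main <- leg_coords()
  leg <- element("leg", list(
    poi_trajectory("heel", t, main$heel),
    poi_trajectory("toe", t, main$toe),
    poi_trajectory("knee", t, main$knee)))

  other_side <- if (side == "left") "right" else "left"
  half <- strides[1L] / 2
  contra <- leg_coords(shift_t = half, shift_x = diff(hs_positions)[1L] / 2)
  legs <- element("legs", list(
    poi_trajectory(paste0("heel_", side), t, main$heel),
    poi_trajectory(paste0("toe_", side), t, main$toe),
    poi_trajectory(paste0("heel_", other_side), t, contra$heel),
    poi_trajectory(paste0("toe_", other_side), t, contra$toe)))

  frame_of <- function(tt) as.integer(round((tt - t[1L]) * fps)) + 1L
  ev_t <- c(hs_times,
            hs_times[-k] + stance_s,
            hs_times[-k] + stance_s + (strides - stance_s) / 2)
  ev_type <- c(rep("heel_strike", k), rep("toe_off", k - 1L),
               rep("max_toe_lift", k - 1L))
  events <- gait_events(ev_type, side, frame_of(ev_t), element = leg)

  contra_keep <- hs_times[-k] + half  # contralateral strikes inside the record
  contra_to <- contra_keep + stance_s
  contra_to <- contra_to[contra_to <= t[length(t)]]
  events_both <- gait_events(
    c(ev_type, rep("heel_strike", length(contra_keep)),
      rep("toe_off", length(contra_to))),
    c(rep(side, length(ev_type)), rep(other_side,
                                      length(contra_keep) + length(contra_to))),
    c(frame_of(ev_t), frame_of(contra_keep), frame_of(contra_to)),
    element = legs)

  truth_cycles <- data.frame(
    side = side,
    stance_duration = rep(stance_s, k - 1L),
    swing_duration = strides - stance_s,
    stride_duration = strides,
    stride_length = diff(hs_positions),
    toe_lift_height = toe_apex,
    toe_lift_duration = (strides - stance_s) / 2)
  truth_cycles$toe_lift_speed <-
    truth_cycles$toe_lift_height / truth_cycles$toe_lift_duration

  fixture_bundle(
    elements = list(leg = leg, legs = legs),
    truth = list(events = events, events_both = events_both,
                 cycles = truth_cycles,
                 step_duration = half,
                 step_size = diff(hs_positions)[1L] / 2),
    params = list(hs_positions = hs_positions, hs_times = hs_times,
                  stance_s = stance_s, toe_apex = toe_apex, fps = fps,
                  side = side))
}

round_up_periods <- function(duration, freqs) {
  for (rep in 1:8) {
    for (f in freqs) {
      cyc <- duration * f
      if (abs(cyc - round(cyc)) > 1e-9)
        duration <- ceiling(cyc - 1e-9) / f
    }
  }
  duration
}

sample_times <- function(fs, duration) {
  n <- as.integer(round(duration * fs))
  (seq_len(n) - 1L) / fs  # endpoint excluded: exact integer periods
}

#' Sine-mixture signal fixture
#'
#' A sum of sine components with known frequencies, amplitudes and phases.
#' The duration is rounded up so every component completes an integer
#' number of periods (recorded in `params$duration`) and the endpoint
#' sample is excluded, so each component falls exactly on a spectral bin.
#' The defaults are the filtering validation mixture: unit-amplitude tones
#' at 25, 30 and 35 Hz, 1 kHz sampling, 10 s.
#'
#' @param freqs component frequencies (all below Nyquist).
#' @param amps component amplitudes.
#' @param fs sampling rate.
#' @param duration requested duration (possibly rounded up).
#' @param phases component phases in radians.
#' @return A `fixture_bundle` with signal `"mixture"` and truth `peaks`.
#' @export
gen_sine_mixture <- function(freqs = c(25, 30, 35), amps = rep(1, length(freqs)),
                             fs = 1000, duration = 10, phases = NULL) {
  if (length(freqs) == 0L)
    ma_stop("validation_error", "need at least one component frequency")
  if (length(amps) != length(freqs))
    ma_stop("validation_error", "freqs and amps lengths differ")
  if (any(freqs >= fs / 2))
    ma_stop("validation_error", "component frequency at or above Nyquist")
  if (is.null(phases)) phases <- rep(0, length(freqs))
  duration <- round_up_periods(duration, freqs)
  t <- sample_times(fs, duration)
  v <- numeric(length(t))
  for (k in seq_along(freqs))
    v <- v + amps[k] * sin(2 * pi * freqs[k] * t + phases[k])
  s <- signal_trace("mixture", t, v)
  fixture_bundle(signals = list(mixture = s),
                 truth = list(peaks = freqs, amps = amps),
                 params = list(freqs = freqs, amps = amps, fs = fs,
                               duration = duration, phases = phases))
}

#' Antiphase sine-pair fixture
#'
#' Two sines at the same frequency with a known amplitude ratio and phase
#' offset: `a = sin(2 pi f t)` and
#' `b = amp_ratio * sin(2 pi f t + phase_offset)`. The defaults are the
#' correlation validation pair — ratio 2 and a phase shift of pi radians
#' (perfect antiphase), 5 Hz at 1 kHz for 10 s.
#'
#' @param f common frequency (below Nyquist).
#' @param fs sampling rate.
#' @param duration duration, rounded up to integer periods.
#' @param amp_ratio amplitude of `b` relative to `a`.
#' @param phase_offset phase of `b` relative to `a`, radians.
#' @return A `fixture_bundle` with signals `a`, `b` and truth
#'   `amplitude_ratio`, `phase_lag_deg`, `f`.
#' @export
gen_antiphase_pair <- function(f = 5, fs = 1000, duration = 10,
                               amp_ratio = 2, phase_offset = pi) {
  if (f >= fs / 2)
    ma_stop("validation_error", "frequency at or above Nyquist")
  duration <- round_up_periods(duration, f)
  t <- sample_times(fs, duration)
  a <- signal_trace("a", t, sin(2 * pi * f * t))
  b <- signal_trace("b", t, amp_ratio * sin(2 * pi * f * t + phase_offset))
  fixture_bundle(
    signals = list(a = a, b = b),
    truth = list(amplitude_ratio = amp_ratio,
                 phase_lag_deg = wrap_deg(-phase_offset * 180 / pi),
                 f = f),
    params = list(f = f, fs = fs, duration = duration,
                  amp_ratio = amp_ratio, phase_offset = phase_offset))
}

#' Add reproducible Gaussian noise to a fixture
#'
#' Perturbs every signal value and POI coordinate of a bundle with i.i.d.
#' Gaussian noise from an explicitly seeded generator; the ground truth is
#' left untouched. The caller's global random state is preserved.
#'
#' @param bundle a `fixture_bundle`.
#' @param sd noise standard deviation (0 returns the bundle unchanged).
#' @param seed integer seed; required whenever `sd > 0`.
#' @return The noisy `fixture_bundle`.
#' @export
add_noise <- function(bundle, sd, seed = NULL) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  if (sd < 0) ma_stop("validation_error", "sd must be >= 0")
  if (sd == 0) return(bundle)
  if (is.null(seed))
    ma_stop("validation_error", "noise requires an explicit seed")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  bundle$signals <- lapply(bundle$signals, function(s) {
    s$values <- s$values + stats::rnorm(length(s$values), 0, sd)
    s$raw_values <- s$values
    s
  })
  bundle$elements <- lapply(bundle$elements, function(e) {
    e$pois <- lapply(e$pois, function(p) {
      p$coords <- p$coords + stats::rnorm(length(p$coords), 0, sd)
      p
    })
    e
  })
  bundle$seed <- seed
  bundle$params$noise_sd <- sd
  bundle
}
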