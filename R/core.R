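#' motionkit: kinematic, gait and biosignal analysis of tracked motion data
#'
#' motionkit analyses tracked point-of-interest (POI) coordinates — the
#' column-wise tables produced by video tracking and pose-estimation tools —
#' together with electrophysiology and sensor traces recorded alongside the
#' movement. The package is organised around a few light S3 containers:
#'
#' * [poi_trajectory()] — one tracked point through time,
#' * [element()] — an ordered chain of POIs sharing a time base (the unit of
#'   stick diagrams and gait analysis),
#' * [signal_trace()] — one uniformly samplable sensor/EMG channel,
#' * [session()] — everything together, serialisable with [save_session()].
#'
#' All quantities are unit-agnostic: coordinates and times keep the units of
#' the input file, and derived quantities inherit them (millimetres and
#' seconds in give millimetres per second out). Use [rescale_time()] to
#' change the order of magnitude of the time base when mixing sources.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# condition helpers -- every contract violation raises a classed condition so
# callers (and the CLI) can map error families to exit codes.

ma_stop <- function(class, msg, ...) {
  msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "ma_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  ))
}

ma_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

history_entry <- function(op, ...) {
  list(op = op, params = list(...))
}

#' Construct a point trajectory
#'
#' A `poi_trajectory` holds one tracked point-of-interest: a label, a strictly
#' increasing time vector and an `n x d` coordinate matrix with `d` of 2 or 3.
#' Samples flagged in `missing` (tracking dropouts, low-likelihood pose
#' estimates) are excluded from every statistic downstream; their coordinate
#' rows are kept as `NA` sentinels so round trips are lossless.
#'
#' @param label character scalar naming the POI.
#' @param times numeric vector of timestamps in the source time unit.
#' @param coords numeric matrix (`length(times)` rows, 2 or 3 columns) in the
#'   source length unit. A plain vector of `2n`/`3n` values is not accepted.
#' @param missing optional logical vector marking invalid samples. Rows of
#'   `coords` containing non-finite values are flagged missing automatically.
#' @return An object of class `poi_trajectory`.
#' @export
#' @examples
#' p <- poi_trajectory("toe", 0:4, cbind(x = 0:4, y = (0:4)^2))
#' p
poi_trajectory <- function(label, times, coords, missing = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    ma_stop("validation_error", "POI label must be a non-empty string")
  times <- as.numeric(times)
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (!is.matrix(coords)) coords <- matrix(as.numeric(coords), ncol = 1L)
  storage.mode(coords) <- "double"
  d <- ncol(coords)
  if (!d %in% c(2L, 3L))
    ma_stop("validation_error", "coordinates must be 2D or 3D, got %d column(s)", d)
  if (nrow(coords) != length(times))
    ma_stop("validation_error",
            "POI '%s': %d timestamps but %d coordinate rows",
            label, length(times), nrow(coords))
  if (length(times) == 0L)
    ma_stop("validation_error", "POI '%s' has no samples", label)
  if (anyNA(times) || any(diff(times) <= 0))
    ma_stop("time_base_error", "POI '%s': times must be strictly increasing", label)
  miss <- !apply(is.finite(coords), 1L, all)
  if (!is.null(missing)) {
    if (length(missing) != length(times))
      ma_stop("validation_error", "POI '%s': missing mask length mismatch", label)
    miss <- miss | as.logical(missing)
  }
  coords[miss, ] <- NA_real_
  if (is.null(colnames(coords)))
    colnames(coords) <- c("x", "y", "z")[seq_len(d)]
  structure(
    list(label = label, times = times, coords = coords, missing = miss),
    class = "poi_trajectory"
  )
}

#' @export
print.poi_trajectory <- function(x, ...) {
  cat(sprintf("<poi_trajectory> '%s': %d samples, %dD, t in [%g, %g], %d missing\n",
              x$label, length(x$times), ncol(x$coords),
              x$times[1L], x$times[length(x$times)], sum(x$missing)))
  invisible(x)
}

n_dims <- function(p) ncol(p$coords)

#' Assemble POIs into an element
#'
#' An element is a named, ordered chain of point trajectories sharing one
#' time base. The list order defines the stick-figure connectivity used by
#' [stick_diagram()] and the animation exporter, so pass POIs in anatomical
#' order (e.g. hip, knee, ankle, heel, toe). All preprocessing operations
#' return a new element and append one entry to its processing history; the
#' input is never modified.
#'
#' @param name element name (used for labelling exports and plots).
#' @param pois list of [poi_trajectory()] objects with pairwise equal time
#'   vectors (tolerance `tol`) and the same dimension.
#' @param tol absolute tolerance for comparing time bases.
#' @return An object of class `ma_element`.
#' @export
#' @examples
#' heel <- poi_trajectory("heel", 0:3, cbind(0:3, 0))
#' toe  <- poi_trajectory("toe",  0:3, cbind(0:3 + 1, 0))
#' element("leg", list(heel, toe))
element <- function(name, pois, tol = 1e-9) {
  if (!is.character(name) || length(name) != 1L)
    ma_stop("validation_error", "element name must be a string")
  if (!is.list(pois) || length(pois) == 0L)
    ma_stop("validation_error", "an element needs at least one POI")
  if (!all(vapply(pois, inherits, logical(1), "poi_trajectory")))
    ma_stop("validation_error", "all POIs must be poi_trajectory objects")
  labels <- vapply(pois, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    ma_stop("validation_error", "duplicate POI labels: %s",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  d <- n_dims(pois[[1L]])
  ref <- pois[[1L]]$times
  for (p in pois[-1L]) {
    if (n_dims(p) != d)
      ma_stop("validation_error", "POI '%s' is %dD but '%s' is %dD",
              p$label, n_dims(p), labels[1L], d)
    if (!common_time_base(ref, p$times, tol))
      ma_stop("time_base_error",
              "POI '%s' is not on the element time base", p$label)
  }
  names(pois) <- labels
  structure(
    list(name = name, pois = pois, history = list(), display_only = FALSE),
    class = "ma_element"
  )
}

#' @rdname element
#' @param trajectories list of POIs (alias of `pois`).
#' @export
build_element <- function(name, trajectories, tol = 1e-9) {
  element(name, trajectories, tol = tol)
}

#' @export
print.ma_element <- function(x, ...) {
  t <- x$pois[[1L]]$times
  cat(sprintf("<element> '%s': %d POI (%s), %d frames, %dD%s\n",
              x$name, length(x$pois),
              paste(names(x$pois), collapse = "-"),
              length(t), n_dims(x$pois[[1L]]),
              if (isTRUE(x$display_only)) " [display-only]" else ""))
  if (length(x$history))
    cat("  history:", paste(vapply(x$history, `[[`, character(1), "op"),
                            collapse = " -> "), "\n")
  invisible(x)
}

#' Element accessors
#'
#' `element_times` returns the shared time base of an element;
#' `poi_labels` the POI names in stick-connectivity order.
#'
#' @param e an [element()].
#' @return A numeric vector of times, or a character vector of labels.
#' @export
element_times <- function(e) e$pois[[1L]]$times

#' @rdname element_times
#' @export
poi_labels <- function(e) names(e$pois)

# pure-update helper: apply f to every POI coordinate matrix, append history
map_coords <- function(e, f, entry) {
  e$pois <- lapply(e$pois, function(p) {
    p$coords <- f(p$coords, p)
    p$missing <- p$missing | !apply(is.finite(p$coords), 1L, all)
    p$coords[p$missing, ] <- NA_real_
    p
  })
  e$history <- c(e$history, list(entry))
  e
}

assert_not_display_only <- function(e, what) {
  if (isTRUE(e$display_only))
    ma_stop("contract_error",
            "%s must not run on a display-only (downsampled view) element", what)
}

#' Construct a signal trace
#'
#' One electrophysiology or sensor channel: a label, timestamps and scalar
#' values. The original samples are kept in `raw_values` and are never
#' mutated by any processing step, so it is always possible to revert to the
#' original signal with [revert_trace()]. `meta` records the ordered
#' processing history (operation names and parameters).
#'
#' @param label channel name (muscle, sensor, ...).
#' @param times numeric timestamps, strictly increasing.
#' @param values numeric samples, same length as `times`.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(label, times, values) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    ma_stop("validation_error", "signal label must be a non-empty string")
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    ma_stop("validation_error", "signal '%s': %d timestamps but %d values",
            label, length(times), length(values))
  if (length(times) == 0L)
    ma_stop("validation_error", "signal '%s' is empty", label)
  if (anyNA(times) || any(diff(times) <= 0))
    ma_stop("time_base_error", "signal '%s': times must be strictly increasing", label)
  structure(
    list(label = label, times = times, values = values,
         raw_values = values, raw_times = times, meta = list()),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  fs <- if (is_uniform(x$times)) sprintf("%.6g", 1 / mean(diff(x$times))) else "non-uniform"
  cat(sprintf("<signal_trace> '%s': %d samples, t in [%g, %g], fs %s\n",
              x$label, length(x$times), x$times[1L],
              x$times[length(x$times)], fs))
  if (length(x$meta))
    cat("  history:", paste(vapply(x$meta, `[[`, character(1), "op"),
                            collapse = " -> "), "\n")
  invisible(x)
}

# uniformity within relative tolerance on the sampling interval
is_uniform <- function(times, rtol = 1e-9) {
  if (length(times) < 3L) return(TRUE)
  dt <- diff(times)
  m <- mean(dt)
  all(abs(dt - m) <= rtol * max(abs(m), 1e-300) + 1e-12 * m)
}

sampling_rate <- function(s) {
  if (!is_uniform(s$times))
    ma_stop("contract_error",
            "signal '%s' is not uniformly sampled; use set_time_base() or resample_signal() first",
            s$label)
  1 / mean(diff(s$times))
}

# pure-update helper for traces; raw_values always carried over untouched
update_trace <- function(s, times, values, entry) {
  s$times <- times
  s$values <- values
  s$meta <- c(s$meta, list(entry))
  s
}

#' Revert a signal trace to its raw samples
#'
#' Discards every processing step and restores the samples and time base the
#' trace was constructed with.
#'
#' @param s a [signal_trace()].
#' @return The trace as originally constructed (empty history).
#' @export
revert_trace <- function(s) {
  stopifnot(inherits(s, "signal_trace"))
  signal_trace(s$label, s$raw_times, s$raw_values)
}

#' Test whether two time vectors share a common base
#'
#' @param a,b numeric time vectors.
#' @param tol maximum absolute per-sample difference allowed.
#' @return `TRUE` iff the vectors have equal length and agree within `tol`.
#' @export
common_time_base <- function(a, b, tol = 1e-9) {
  if (length(a) == 0L || length(b) == 0L)
    ma_stop("validation_error", "time arrays must be non-empty")
  length(a) == length(b) && max(abs(a - b)) <= tol
}

#' Rescale the time base of an element or signal
#'
#' Multiplies every timestamp by `factor`, leaving coordinates or values
#' untouched. This is the unit-adjustment hook: the package itself never
#' assumes a time unit, so data recorded in milliseconds can be brought to
#' seconds with `factor = 1e-3` before being combined with other sources.
#'
#' @param x an [element()] or [signal_trace()].
#' @param factor positive scale factor applied to all timestamps.
#' @return An object of the same class with rescaled times.
#' @export
rescale_time <- function(x, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0)
    ma_stop("validation_error", "time scale factor must be a positive number")
  UseMethod("rescale_time")
}

#' @export
rescale_time.ma_element <- function(x, factor) {
  x$pois <- lapply(x$pois, function(p) { p$times <- p$times * factor; p })
  x$history <- c(x$history, list(history_entry("rescale_time", factor = factor)))
  x
}

#' @export
rescale_time.signal_trace <- function(x, factor) {
  update_trace(x, x$times * factor, x$values,
               history_entry("rescale_time", factor = factor))
}

#' Bundle data into a session
#'
#' A session is the serialisable container of all inputs and products:
#' elements, signal traces, an optional gait-event annotation and named
#' analysis results. [save_session()] writes it to a single archive file and
#' [load_session()] restores it losslessly.
#'
#' @param elements list of [element()] objects (names taken from the elements).
#' @param signals list of [signal_trace()] objects.
#' @param gait optional gait-event data frame (see [gait_events()]).
#' @param products named list of analysis products (data frames / lists).
#' @param units_note free-text note on the units of measurement of the data.
#' @return An object of class `ma_session`.
#' @export
session <- function(elements = list(), signals = list(), gait = NULL,
                    products = list(), units_note = "") {
  elements <- as.list(elements)
  signals <- as.list(signals)
  if (length(elements)) {
    stopifnot(all(vapply(elements, inherits, logical(1), "ma_element")))
    names(elements) <- vapply(elements, `[[`, character(1), "name")
  }
  if (length(signals)) {
    stopifnot(all(vapply(signals, inherits, logical(1), "signal_trace")))
    names(signals) <- vapply(signals, `[[`, character(1), "label")
  }
  nm <- c(names(elements), names(signals), names(products))
  if (anyDuplicated(nm))
    ma_stop("validation_error", "session names must be unique (duplicated: %s)",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(
    list(elements = elements, signals = signals, gait = gait,
         products = products, units_note = units_note),
    class = "ma_session"
  )
}

#' @export
print.ma_session <- function(x, ...) {
  cat(sprintf("<session> %d element(s), %d signal(s), %d product(s)%s\n",
              length(x$elements), length(x$signals), length(x$products),
              if (!is.null(x$gait)) sprintf(", %d gait event(s)", nrow(x$gait)) else ""))
  if (nzchar(x$units_note)) cat("  units:", x$units_note, "\n")
  invisible(x)
}
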