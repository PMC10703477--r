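# Stride-and-gait analysis from annotated limb-position events. Events are
# first-class inputs (frame indices into an element's time base), mirroring
# interactive marking on a stick diagram; the heuristic detector is a
# programmatic convenience for clean recordings. The cycle decomposition is
# classic: stance from heel-strike to toe-off, swing from toe-off to the
# next ipsilateral heel-strike, and the heel-strike always opens the cycle.

EVENT_TYPES <- c("heel_strike", "toe_off", "heel_off", "max_toe_lift",
                 "cycle_entry", "cycle_mid")
EVENT_SIDES <- c("left", "right", "none")

#' Construct a gait-event annotation
#'
#' A data frame of annotated limb positions: event type, body side, frame
#' index (1-based into the element's samples) and event time. If `element`
#' is given, times are filled in from its time base and checked against it.
#'
#' @param type character vector of event types (`heel_strike`, `toe_off`,
#'   `heel_off`, `max_toe_lift`, `cycle_entry`, `cycle_mid`).
#' @param side `"left"`, `"right"` or `"none"` (recycled).
#' @param frame integer frame indices.
#' @param time event times; derived from `element` when omitted.
#' @param element optional [element()] supplying the time base.
#' @return A `gait_events` data frame sorted by side then time.
#' @export
gait_events <- function(type, side, frame, time = NULL, element = NULL) {
  type <- as.character(type); side <- as.character(side)
  frame <- as.integer(frame)
  if (!all(type %in% EVENT_TYPES))
    ma_stop("validation_error", "unknown event type(s): %s",
            paste(setdiff(type, EVENT_TYPES), collapse = ", "))
  if (!all(side %in% EVENT_SIDES))
    ma_stop("validation_error", "event side must be left, right or none")
  n <- length(type)
  side <- rep_len(side, n)
  if (length(frame) != n)
    ma_stop("validation_error", "type and frame lengths differ")
  if (!is.null(element)) {
    t_el <- element_times(element)
    if (any(frame < 1L | frame > length(t_el)))
      ma_stop("validation_error", "event frame outside the element's record")
    time <- t_el[frame]
  }
  if (is.null(time))
    ma_stop("validation_error", "need event times or an element to derive them")
  ev <- data.frame(type = type, side = side, frame = frame,
                   time = as.numeric(time), stringsAsFactors = FALSE)
  ev <- ev[order(ev$side, ev$time), ]
  rownames(ev) <- NULL
  class(ev) <- c("gait_events", "data.frame")
  ev
}

#' Read or write gait-event annotation files
#'
#' The annotation format is a CSV with columns `type`, `side`, `frame`
#' (and optionally `time`); times can be reconstructed from an element's
#' time base on read.
#'
#' @param path CSV path.
#' @param element optional [element()] to derive event times from frames.
#' @param events a [gait_events()] annotation.
#' @return `read_gait_events` returns a [gait_events()] data frame;
#'   `write_gait_events` returns `path` invisibly.
#' @export
read_gait_events <- function(path, element = NULL) {
  rows <- read_delim_cells(path)
  hdr <- tolower(trimws(rows[[1L]]))
  need <- c("type", "side", "frame")
  if (!all(need %in% hdr))
    ma_stop("format_error", "'%s': event file needs columns type, side, frame", path)
  body <- do.call(rbind, rows[-1L])
  time <- if ("time" %in% hdr) as.numeric(body[, match("time", hdr)]) else NULL
  gait_events(trimws(body[, match("type", hdr)]),
              trimws(body[, match("side", hdr)]),
              as.integer(body[, match("frame", hdr)]),
              time = time, element = element)
}

#' @rdname read_gait_events
#' @export
write_gait_events <- function(events, path) {
  stopifnot(inherits(events, "gait_events"))
  write_ma_csv(as.data.frame(events), path)
  invisible(path)
}

#' Group a side's events into gait cycles
#'
#' Cycles are delimited by successive heel-strikes of the chosen side; the
#' first event must be a heel-strike (the mandated cycle start). Each cycle
#' must contain exactly one toe-off after its opening heel-strike, may
#' contain one heel-off between heel-strike and toe-off and one maximum
#' toe-lift between toe-off and the closing heel-strike.
#'
#' @param events a [gait_events()] annotation.
#' @param side which side to analyse (`"none"` selects unsided events).
#' @return A list of cycles; each holds the rows `hs`, `toe_off`,
#'   `next_hs` and optionally `heel_off`, `max_toe_lift`.
#' @export
validate_events <- function(events, side = c("left", "right", "none")) {
  stopifnot(inherits(events, "gait_events"))
  side <- match.arg(side)
  ev <- events[events$side == side, , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  if (nrow(ev) == 0L)
    ma_stop("validation_error", "no events for side '%s'", side)
  if (ev$type[1L] != "heel_strike")
    ma_stop("ordering_error",
            "the first %s event must be a heel-strike (cycle start), got '%s'",
            side, ev$type[1L])
  hs_idx <- which(ev$type == "heel_strike")
  if (length(hs_idx) < 2L)
    ma_stop("validation_error",
            "side '%s' needs at least two heel-strikes to close a cycle", side)
  cycles <- list()
  for (k in seq_len(length(hs_idx) - 1L)) {
    seg <- ev[(hs_idx[k] + 1L):(hs_idx[k + 1L] - 1L), , drop = FALSE]
    to <- which(seg$type == "toe_off")
    if (length(to) != 1L)
      ma_stop("ordering_error",
              "cycle %d of side '%s' has %d toe-offs; expected exactly one",
              k, side, length(to))
    ho <- which(seg$type == "heel_off")
    mtl <- which(seg$type == "max_toe_lift")
    if (length(ho) > 1L || length(mtl) > 1L)
      ma_stop("ordering_error", "cycle %d: duplicated optional event", k)
    if (length(ho) == 1L && ho > to)
      ma_stop("ordering_error",
              "cycle %d: heel-off must precede toe-off", k)
    if (length(mtl) == 1L && mtl < to)
      ma_stop("ordering_error",
              "cycle %d: maximum toe-lift must follow toe-off", k)
    cycles[[k]] <- list(
      hs = ev[hs_idx[k], ], toe_off = seg[to, ],
      next_hs = ev[hs_idx[k + 1L], ],
      heel_off = if (length(ho)) seg[ho, ] else NULL,
      max_toe_lift = if (length(mtl)) seg[mtl, ] else NULL)
  }
  cycles
}

poi_coord <- function(e, poi, frame, axis) {
  if (!poi %in% poi_labels(e))
    ma_stop("validation_error", "POI '%s' not in element '%s'", poi, e$name)
  e$pois[[poi]]$coords[frame, axis_index(e, axis)]
}

#' Per-cycle gait parameters
#'
#' For every validated cycle of one side: stance duration (heel-strike to
#' toe-off), swing duration (toe-off to next heel-strike), stride duration
#' (their sum) and stride length (progression-axis displacement of the heel
#' POI between successive heel-strikes). When the optional events are
#' annotated it also reports the heel-down duration (heel-strike to
#' heel-off) and the toe-lift height (toe vertical coordinate at maximum
#' toe-lift relative to toe-off), duration and speed.
#'
#' @param e the [element()] the events index into.
#' @param events a [gait_events()] annotation.
#' @param side side to analyse.
#' @param heel_poi,toe_poi POI labels of the heel and toe markers.
#' @param progression_axis axis of travel (default `"x"`).
#' @param vertical_axis up-positive axis (default `"y"`).
#' @return A `gait_cycles` data frame, one row per cycle.
#' @export
compute_cycles <- function(e, events, side = c("left", "right", "none"),
                           heel_poi = "heel", toe_poi = "toe",
                           progression_axis = "x", vertical_axis = "y") {
  stopifnot(inherits(e, "ma_element"))
  side <- match.arg(side)
  cycles <- validate_events(events, side)
  rows <- lapply(cycles, function(cy) {
    stance <- cy$toe_off$time - cy$hs$time
    swing <- cy$next_hs$time - cy$toe_off$time
    out <- data.frame(
      side = side,
      stance_duration = stance,
      swing_duration = swing,
      stride_duration = cy$next_hs$time - cy$hs$time,
      stride_length = abs(
        poi_coord(e, heel_poi, cy$next_hs$frame, progression_axis) -
        poi_coord(e, heel_poi, cy$hs$frame, progression_axis)),
      heel_down_duration = NA_real_,
      toe_lift_height = NA_real_, toe_lift_duration = NA_real_,
      toe_lift_speed = NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(cy$heel_off))
      out$heel_down_duration <- cy$heel_off$time - cy$hs$time
    if (!is.null(cy$max_toe_lift)) {
      h <- poi_coord(e, toe_poi, cy$max_toe_lift$frame, vertical_axis) -
           poi_coord(e, toe_poi, cy$toe_off$frame, vertical_axis)
      dur <- cy$max_toe_lift$time - cy$toe_off$time
      out$toe_lift_height <- h
      out$toe_lift_duration <- dur
      out$toe_lift_speed <- h / dur
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gait_cycles", "data.frame")
  out
}

#' Bipedal step parameters
#'
#' Pairs every heel-strike with the next contralateral heel-strike: the
#' step duration is the time between them and the step size the absolute
#' progression-axis distance between the two heel markers at their
#' respective strikes.
#'
#' @param e the [element()] holding both sides' heel POIs.
#' @param events a [gait_events()] annotation with both sides.
#' @param heel_poi_left,heel_poi_right heel POI labels per side.
#' @param progression_axis axis of travel.
#' @return A data frame with `from_side`, `time`, `step_duration`,
#'   `step_size`.
#' @export
step_parameters <- function(e, events, heel_poi_left = "heel_left",
                            heel_poi_right = "heel_right",
                            progression_axis = "x") {
  stopifnot(inherits(e, "ma_element"), inherits(events, "gait_events"))
  hs <- events[events$type == "heel_strike" &
               events$side %in% c("left", "right"), , drop = FALSE]
  if (length(unique(hs$side)) < 2L)
    ma_stop("validation_error",
            "step parameters need heel-strikes on both sides")
  hs <- hs[order(hs$time), , drop = FALSE]
  heel_of <- function(side) if (side == "left") heel_poi_left else heel_poi_right
  rows <- list()
  for (i in seq_len(nrow(hs) - 1L)) {
    nxt <- which(hs$side[-seq_len(i)] != hs$side[i])
    if (!length(nxt)) break
    j <- i + nxt[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      from_side = hs$side[i], time = hs$time[i],
      step_duration = hs$time[j] - hs$time[i],
      step_size = abs(
        poi_coord(e, heel_of(hs$side[j]), hs$frame[j], progression_axis) -
        poi_coord(e, heel_of(hs$side[i]), hs$frame[i], progression_axis)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

interval_intersections <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1L], b[j, 1L]); hi <- min(a[i, 2L], b[j, 2L])
    if (lo < hi) out <- rbind(out, c(lo, hi))
  }
  if (is.null(out)) matrix(numeric(0), 0L, 2L) else out
}

#' Gait diagram intervals
#'
#' Stance intervals `[heel-strike, toe-off)` per side plus the double-
#' support overlap (both sides in stance, zero-length intersections
#' discarded) — the data behind the classic bar-style gait diagram.
#'
#' @param events a [gait_events()] annotation with both sides.
#' @return A `gait_diagram`: two-column start/end matrices `left`, `right`,
#'   `overlap`.
#' @export
gait_diagram <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  stance_of <- function(side) {
    cy <- validate_events(events, side)
    do.call(rbind, lapply(cy, function(c) c(c$hs$time, c$toe_off$time)))
  }
  left <- stance_of("left")
  right <- stance_of("right")
  structure(
    list(left = left, right = right,
         overlap = interval_intersections(left, right)),
    class = "gait_diagram")
}

#' @export
print.gait_diagram <- function(x, ...) {
  cat(sprintf("<gait_diagram> %d left / %d right stance interval(s), %d overlap(s)\n",
              nrow(x$left), nrow(x$right), nrow(x$overlap)))
  invisible(x)
}

#' Two-phase cycle decomposition
#'
#' Splits a cyclic movement into two phases delimited by alternating entry
#' and mid events — the swim-stroke variant where the entry is the maximal
#' hindlimb extension after the power stroke, phase 1 is the power stroke
#' (entry to mid) and phase 2 the return stroke (mid to next entry).
#'
#' @param events a [gait_events()] annotation with `cycle_entry` and
#'   `cycle_mid` events (side `"none"`).
#' @return A data frame with `phase1_duration`, `phase2_duration` per
#'   complete cycle (empty if no cycle completes).
#' @export
two_phase_cycles <- function(events) {
  stopifnot(inherits(events, "gait_events"))
  ev <- events[events$type %in% c("cycle_entry", "cycle_mid"), , drop = FALSE]
  ev <- ev[order(ev$time), , drop = FALSE]
  if (nrow(ev) == 0L)
    ma_stop("validation_error", "no cycle_entry/cycle_mid events")
  if (ev$type[1L] != "cycle_entry")
    ma_stop("ordering_error", "the first event must be a cycle entry")
  if (any(ev$type[-1L] == ev$type[-nrow(ev)]))
    ma_stop("ordering_error", "entry and mid events must alternate")
  entries <- which(ev$type == "cycle_entry")
  rows <- list()
  for (k in seq_len(length(entries) - 1L)) {
    i <- entries[k]; j <- entries[k + 1L]
    mid <- i + 1L  # alternation guarantees this is the cycle's mid event
    if (mid >= j + 1L) next
    rows[[length(rows) + 1L]] <- data.frame(
      phase1_duration = ev$time[mid] - ev$time[i],
      phase2_duration = ev$time[j] - ev$time[mid])
  }
  if (!length(rows))
    return(data.frame(phase1_duration = numeric(0),
                      phase2_duration = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heuristic gait-event detection
#'
#' A programmatic stand-in for interactive marking, suitable for clean
#' up-positive recordings with at least one full cycle: a frame is a ground
#' candidate when the marker height is within `height_frac` of the height
#' range above its minimum and its progression speed is below `speed_frac`
#' of the maximum speed. Heel-strikes are the onsets of the heel's ground
#' condition, toe-offs the offsets of the toe's, and the maximum toe-lift
#' is the highest toe sample within each swing.
#'
#' @param e an [element()].
#' @param heel_poi,toe_poi marker labels.
#' @param height_frac height tolerance as a fraction of the range.
#' @param speed_frac speed tolerance as a fraction of the maximum.
#' @param side side label attached to the produced events.
#' @param progression_axis,vertical_axis coordinate conventions.
#' @return A [gait_events()] annotation.
#' @export
detect_events_heuristic <- function(e, heel_poi = "heel", toe_poi = "toe",
                                    height_frac = 0.05, speed_frac = 0.1,
                                    side = "none", progression_axis = "x",
                                    vertical_axis = "y") {
  stopifnot(inherits(e, "ma_element"))
  t <- element_times(e)
  n <- length(t)
  ground_mask <- function(poi) {
    y <- e$pois[[poi]]$coords[, axis_index(e, vertical_axis)]
    x <- e$pois[[poi]]$coords[, axis_index(e, progression_axis)]
    sp <- abs(diff(x)) / diff(t)
    sp <- c(sp, sp[n - 1L])          # align speeds with samples
    rng <- max(y) - min(y)
    if (rng == 0)
      ma_stop("detection_error",
              "POI '%s' has constant height; annotate events manually", poi)
    list(mask = y < min(y) + height_frac * rng & sp < speed_frac * max(sp),
         y = y, rng = rng)
  }
  heel_gnd <- ground_mask(heel_poi)
  toe_gnd <- ground_mask(toe_poi)
  runs_of <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    Map(seq.int, starts[r$values], ends[r$values])
  }
  # refine each contact run to the ground plateau: the marker may already
  # satisfy the loose height/speed condition while still descending, so the
  # strike is the first frame at the run's minimum height and the lift-off
  # the last such frame
  refine <- function(g, pick_first) {
    vapply(runs_of(g$mask), function(run) {
      flat <- run[g$y[run] <= min(g$y[run]) + 1e-6 * g$rng]
      if (pick_first) flat[1L] else flat[length(flat)]
    }, integer(1))
  }
  hs <- refine(heel_gnd, pick_first = TRUE)
  to <- refine(toe_gnd, pick_first = FALSE)
  to <- to[to < n]                   # a record-final contact never lifts off
  if (!length(hs) || !length(to))
    ma_stop("detection_error",
            "no gait-event candidates found; annotate events manually")
  if (!length(hs) || !length(to))
    ma_stop("detection_error",
            "no gait-event candidates found; annotate events manually")
  frames <- c(hs, to)
  types <- c(rep("heel_strike", length(hs)), rep("toe_off", length(to)))
  # max toe-lift inside each swing (toe-off to the next heel-strike)
  ytoe <- e$pois[[toe_poi]]$coords[, axis_index(e, vertical_axis)]
  for (f in to) {
    nxt <- hs[hs > f]
    if (!length(nxt)) next
    win <- f:nxt[1L]
    frames <- c(frames, win[which.max(ytoe[win])])
    types <- c(types, "max_toe_lift")
  }
  gait_events(types, side, frames, element = e)
}
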