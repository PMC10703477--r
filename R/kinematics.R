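# Kinematic quantities by forward differencing. Speed over interval i is
# (p[i+1] - p[i]) / (t[i+1] - t[i]) -- the frame-to-frame "instant speed" of
# manual video tracking -- and acceleration is the speed difference over the
# spanned two-interval time. Units are inherited from the input: mm and s in
# give mm/s and mm/s^2 out.

#' Kinematic quantities of an element
#'
#' Computes, per POI: step displacement per sampling interval, cumulative
#' path length, component speeds, speed magnitude, component accelerations
#' and acceleration magnitude. Speeds are forward differences
#' `v_i = (p_(i+1) - p_i) / (t_(i+1) - t_i)` placed at interval midpoints;
#' accelerations are speed differences divided by the half-sum of the two
#' spanned intervals, `a_i = 2 (v_(i+1) - v_i) / (t_(i+2) - t_i)`, placed at
#' the midpoint of the spanned interval. Intervals touching a missing sample
#' yield missing outputs; the path length sums over valid intervals only.
#'
#' @param e an [element()] with at least 3 samples. Display-only
#'   (downsampled-view) elements are refused.
#' @param absolute if `TRUE`, speed and acceleration components are reported
#'   as absolute values (magnitudes are always non-negative).
#' @return A named list of `kinematic_series` objects, one per POI, each
#'   with fields `label`, `speed_times`, `step_disp`, `speeds`, `speed_mag`,
#'   `accel_times`, `accels`, `accel_mag`, `path_length`, `cum_path`,
#'   `absolute`.
#' @export
#' @examples
#' p <- poi_trajectory("p", 0:10, cbind(x = 2 * (0:10), y = (0:10)^2))
#' k <- kinematics(element("demo", list(p)))[["p"]]
#' k$speeds[, "x"]   # constant 2
#' k$accels[, "y"]   # constant 2
kinematics <- function(e, absolute = FALSE) {
  stopifnot(inherits(e, "ma_element"))
  assert_not_display_only(e, "kinematics()")
  t <- element_times(e)
  n <- length(t)
  if (n < 3L)
    ma_stop("validation_error", "kinematics needs at least 3 samples, got %d", n)
  if (any(diff(t) == 0))
    ma_stop("validation_error", "duplicate timestamps")
  dt <- diff(t)
  out <- lapply(e$pois, function(p) {
    dp <- diff(p$coords)                         # (n-1) x d
    bad_int <- p$missing[-n] | p$missing[-1L]
    dp[bad_int, ] <- NA_real_
    step <- sqrt(rowSums(dp^2))
    v <- dp / dt
    vmag <- step / dt
    span <- (t[-(1:2)] - t[seq_len(n - 2L)]) / 2  # half-sum of intervals
    a <- diff(v) / span
    amag_vec <- sqrt(rowSums(a^2))
    if (absolute) {
      v <- abs(v)
      a <- abs(a)
    }
    cum <- cumsum(ifelse(is.na(step), 0, step))
    structure(
      list(label = p$label,
           speed_times = (t[-n] + t[-1L]) / 2,
           step_disp = step,
           speeds = v, speed_mag = vmag,
           accel_times = (t[-(1:2)] + t[seq_len(n - 2L)]) / 2,
           accels = a, accel_mag = amag_vec,
           path_length = sum(step[!is.na(step)]),
           cum_path = cum,
           absolute = absolute),
      class = "kinematic_series")
  })
  names(out) <- poi_labels(e)
  out
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> '%s': %d speed / %d acceleration samples, path length %g%s\n",
              x$label, length(x$speed_mag), length(x$accel_mag),
              x$path_length, if (x$absolute) " [absolute]" else ""))
  invisible(x)
}

angle_at_vertex <- function(A, B, C) {
  u <- A - B
  v <- C - B
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (!is.finite(nu) || !is.finite(nv) || nu == 0 || nv == 0) return(NA_real_)
  cross <- if (length(u) == 2L) abs(u[1L] * v[2L] - u[2L] * v[1L]) else {
    w <- c(u[2L] * v[3L] - u[3L] * v[2L],
           u[3L] * v[1L] - u[1L] * v[3L],
           u[1L] * v[2L] - u[2L] * v[1L])
    sqrt(sum(w^2))
  }
  atan2(cross, sum(u * v))
}

#' Joint angle at a vertex POI
#'
#' The interior (unsigned) angle at POI `b` between the segments `b`–`a` and
#' `b`–`c`, per frame, computed as `atan2(|u x v|, u . v)` — numerically
#' stable near 0 and 180 degrees, unlike the arccosine of the normalised dot
#' product. The range is `[0, 180]` degrees (or `[0, pi]`); frames where a
#' segment has zero length or a missing endpoint give a missing value.
#'
#' @param e an [element()].
#' @param a,b,c POI labels; `b` is the vertex.
#' @param unit `"degrees"` (default) or `"radians"`.
#' @return An `angle_series` with fields `vertex`, `flank`, `times`,
#'   `values`, `unit`.
#' @export
joint_angle <- function(e, a, b, c, unit = c("degrees", "radians")) {
  stopifnot(inherits(e, "ma_element"))
  unit <- match.arg(unit)
  labs <- c(a, b, c)
  if (anyDuplicated(labs) || !all(labs %in% poi_labels(e)))
    ma_stop("validation_error",
            "need three distinct POI labels present in the element (got %s)",
            paste(labs, collapse = ", "))
  t <- element_times(e)
  A <- e$pois[[a]]$coords; B <- e$pois[[b]]$coords; C <- e$pois[[c]]$coords
  vals <- vapply(seq_along(t), function(i)
    angle_at_vertex(A[i, ], B[i, ], C[i, ]), numeric(1))
  if (unit == "degrees") vals <- vals * 180 / pi
  structure(
    list(vertex = b, flank = c(a, c), times = t, values = vals, unit = unit),
    class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %s-%s-%s: %d frames, range [%g, %g] %s\n",
              x$flank[1L], x$vertex, x$flank[2L], length(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              x$unit))
  invisible(x)
}

#' Descriptive statistics of a series
#'
#' Minimum, maximum, their times of occurrence, mean, median, mode and
#' sample standard deviation of a numeric series, missing values excluded.
#' The mode is the most frequent value after rounding to `mode_precision`
#' decimals; ties go to the smallest value. With a single observation the
#' standard deviation is reported as 0 by convention.
#'
#' @param x numeric vector (an angle or kinematic series, a signal, ...).
#' @param times optional timestamps for time-of-extremum (defaults to
#'   indices).
#' @param mode_precision decimals used when binning values for the mode.
#' @return A one-row data frame of class `descriptive_stats`.
#' @export
describe <- function(x, times = NULL, mode_precision = 6L) {
  x <- as.numeric(x)
  if (is.null(times)) times <- seq_along(x)
  ok <- is.finite(x)
  if (!any(ok))
    ma_stop("validation_error", "no finite values to describe")
  v <- x[ok]; tv <- times[ok]
  r <- round(v, mode_precision)
  tab <- table(r)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  out <- data.frame(
    n = length(v),
    min = min(v), max = max(v),
    t_min = tv[which.min(v)], t_max = tv[which.max(v)],
    mean = mean(v), median = stats::median(v),
    mode = min(cand),
    sd = if (length(v) > 1L) stats::sd(v) else 0)
  class(out) <- c("descriptive_stats", "data.frame")
  out
}

#' Stick diagram of an element
#'
#' One polyline per frame connecting the element's POIs in their stored
#' order. With `normalize`, each frame is translated on the selected axes by
#' the displacement of the reference POI since the first frame, anchoring
#' that POI while preserving the initial pose — a display transform only,
#' never used by the kinematic or gait computations.
#'
#' @param e an [element()] with at least 2 POIs.
#' @param normalize optional list `list(poi = <label>, axes = c("x", ...))`.
#' @return A `stick_diagram`: list of per-frame vertex matrices (`n_poi x d`
#'   each), `times`, `labels` and the normalization spec.
#' @export
stick_diagram <- function(e, normalize = NULL) {
  stopifnot(inherits(e, "ma_element"))
  if (length(e$pois) < 2L)
    ma_stop("validation_error", "a stick diagram needs at least 2 POIs")
  t <- element_times(e)
  d <- n_dims(e$pois[[1L]])
  axnames <- colnames(e$pois[[1L]]$coords)
  shiftmat <- matrix(0, length(t), d)
  if (!is.null(normalize)) {
    if (!normalize$poi %in% poi_labels(e))
      ma_stop("validation_error", "reference POI '%s' not in element",
              normalize$poi)
    cols <- match(normalize$axes, axnames)
    if (anyNA(cols))
      ma_stop("validation_error", "unknown normalization axis")
    ref <- e$pois[[normalize$poi]]$coords
    shiftmat[, cols] <- sweep(ref[, cols, drop = FALSE], 2L,
                              ref[1L, cols], `-`)
  }
  frames <- lapply(seq_along(t), function(i) {
    m <- do.call(rbind, lapply(e$pois, function(p) p$coords[i, ]))
    m <- sweep(m, 2L, shiftmat[i, ], `-`)
    rownames(m) <- poi_labels(e)
    m
  })
  structure(
    list(frames = frames, times = t, labels = poi_labels(e),
         normalize = normalize),
    class = "stick_diagram")
}

#' @export
print.stick_diagram <- function(x, ...) {
  cat(sprintf("<stick_diagram> %d frames x %d vertices (%s)%s\n",
              length(x$frames), length(x$labels),
              paste(x$labels, collapse = "-"),
              if (!is.null(x$normalize))
                sprintf(", anchored to '%s'", x$normalize$poi) else ""))
  invisible(x)
}

#' Occupancy heatmap of a trajectory
#'
#' Bins the non-missing samples of one POI on an `nx` by `ny` grid over
#' `extent` (default: the data bounding box; right and top bin edges
#' inclusive) — the standard open-field occupancy map.
#'
#' @param traj a [poi_trajectory()] (2D, or a 3D one with `plane` selecting
#'   two axes).
#' @param nx,ny number of bins per axis.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`.
#' @param plane two axis indices for 3D data (default x, y).
#' @return A `heatmap_grid`: `counts` matrix (`nx` rows, `ny` columns),
#'   `x_edges`, `y_edges`, `extent`, `n_binned`.
#' @export
occupancy_heatmap <- function(traj, nx, ny, extent = NULL, plane = c(1L, 2L)) {
  stopifnot(inherits(traj, "poi_trajectory"))
  if (nx < 1L || ny < 1L)
    ma_stop("validation_error", "nx and ny must be >= 1")
  xy <- traj$coords[!traj$missing, plane, drop = FALSE]
  if (is.null(extent))
    extent <- c(range(xy[, 1L]), range(xy[, 2L]))
  if (extent[2L] <= extent[1L] || extent[4L] <= extent[3L])
    ma_stop("validation_error", "heatmap extent has zero area")
  xe <- seq(extent[1L], extent[2L], length.out = nx + 1L)
  ye <- seq(extent[3L], extent[4L], length.out = ny + 1L)
  ix <- findInterval(xy[, 1L], xe, rightmost.closed = TRUE)
  iy <- findInterval(xy[, 2L], ye, rightmost.closed = TRUE)
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  counts <- matrix(0L, nx, ny)
  for (i in which(ok)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1L
  structure(
    list(counts = counts, x_edges = xe, y_edges = ye, extent = extent,
         n_binned = sum(ok), label = traj$label),
    class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("<heatmap_grid> '%s': %d x %d bins, %d samples binned\n",
              x$label, nrow(x$counts), ncol(x$counts), x$n_binned))
  invisible(x)
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean step displacements over intervals with both endpoints
#' present — the total distance travelled, in the input length unit.
#'
#' @param traj a [poi_trajectory()] with at least 2 samples.
#' @return A scalar.
#' @export
path_length <- function(traj) {
  stopifnot(inherits(traj, "poi_trajectory"))
  if (length(traj$times) < 2L)
    ma_stop("validation_error", "path length needs at least 2 samples")
  dp <- diff(traj$coords)
  n <- length(traj$times)
  ok <- !(traj$missing[-n] | traj$missing[-1L])
  sum(sqrt(rowSums(dp[ok, , drop = FALSE]^2)))
}
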