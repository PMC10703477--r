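# Coordinate cleaning and multi-camera reconciliation. Every operation is
# pure: it returns a new element (input untouched) and appends exactly one
# processing-history entry, so a session records how each trajectory was
# produced without ever altering the raw files.

axis_index <- function(e, axis) {
  ax <- colnames(e$pois[[1L]]$coords)
  j <- match(axis, ax)
  if (is.na(j))
    ma_stop("validation_error", "axis '%s' not present in %dD data",
            axis, length(ax))
  j
}

element_centroid <- function(e) {
  all <- do.call(rbind, lapply(e$pois, `[[`, "coords"))
  colMeans(all, na.rm = TRUE)
}

#' Detect and replace trajectory outliers
#'
#' Flags, per POI and per axis, the samples whose deviation from the axis
#' median exceeds `mad_k` times the scaled median absolute deviation
#' (`1.4826 * MAD`, the robust sigma estimate), then replaces them with the
#' chosen method. Samples already flagged missing (tracking dropouts) are
#' treated as outliers for replacement, so this is also the gap-filling
#' step. Axes with zero MAD (constant signal) are skipped with a warning
#' since the threshold would degenerate.
#'
#' @param e an [element()].
#' @param mad_k threshold multiplier (default 3).
#' @param method `"interpolation"` (linear over the surviving samples),
#'   `"nearest"`, `"previous"` or `"mean_window"`.
#' @param w window width for `mean_window` (odd, default 5).
#' @return A list with the cleaned `element` and a `report` data frame of
#'   class `outlier_report` (POI, axis, index, original and replacement
#'   value, method).
#' @export
#' @examples
#' p <- poi_trajectory("p", 0:4, cbind(x = 0:4, y = c(1, 2, 100, 4, 5)))
#' e <- element("demo", list(p))
#' res <- replace_outliers(e, mad_k = 3, method = "interpolation")
#' res$report
replace_outliers <- function(e, mad_k = 3,
                             method = c("interpolation", "nearest",
                                        "previous", "mean_window"),
                             w = 5L) {
  stopifnot(inherits(e, "ma_element"))
  method <- match.arg(method)
  if (method == "mean_window" && (w %% 2L == 0L || w < 3L))
    ma_stop("validation_error", "mean_window width must be odd and >= 3")
  rep_rows <- list()
  times <- element_times(e)
  e2 <- e
  for (pi in seq_along(e2$pois)) {
    p <- e2$pois[[pi]]
    ax <- colnames(p$coords)
    for (j in seq_along(ax)) {
      v <- p$coords[, j]
      fin <- is.finite(v)
      if (sum(fin) < 3L)
        ma_stop("validation_error",
                "POI '%s' axis %s has fewer than 3 finite samples",
                p$label, ax[j])
      med <- stats::median(v[fin])
      s <- stats::mad(v[fin], constant = 1.4826)
      flag <- rep(FALSE, length(v))
      if (s == 0) {
        if (any(fin & v != med))
          ma_warn("POI '%s' axis %s: MAD is zero, outlier detection skipped",
                  p$label, ax[j])
      } else {
        flag[fin] <- abs(v[fin] - med) > mad_k * s
      }
      bad <- flag | !fin
      if (!any(bad)) next
      good <- which(!bad)
      repl <- switch(method,
        interpolation = stats::approx(times[good], v[good], xout = times[bad],
                                      rule = 2)$y,
        nearest = vapply(which(bad), function(i)
          v[good[which.min(abs(times[good] - times[i]))]], numeric(1)),
        previous = vapply(which(bad), function(i) {
          prev <- good[good < i]
          if (length(prev)) v[max(prev)] else v[min(good)]
        }, numeric(1)),
        mean_window = vapply(which(bad), function(i) {
          win <- max(1L, i - (w - 1L) %/% 2L):min(length(v), i + (w - 1L) %/% 2L)
          win <- setdiff(win, which(bad))
          if (length(win)) mean(v[win]) else stats::approx(
            times[good], v[good], xout = times[i], rule = 2)$y
        }, numeric(1)))
      idx <- which(bad)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        poi = p$label, axis = ax[j], index = idx,
        original = v[idx], replacement = repl, method = method,
        stringsAsFactors = FALSE)
      v[idx] <- repl
      p$coords[, j] <- v
    }
    p$missing <- !apply(is.finite(p$coords), 1L, all)
    e2$pois[[pi]] <- p
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(poi = character(0), axis = character(0), index = integer(0),
               original = numeric(0), replacement = numeric(0),
               method = character(0), stringsAsFactors = FALSE)
  report <- report[order(report$poi, report$axis, report$index), ]
  rownames(report) <- NULL
  class(report) <- c("outlier_report", "data.frame")
  e2$history <- c(e2$history,
                  list(history_entry("replace_outliers", mad_k = mad_k,
                                     method = method, w = w)))
  list(element = e2, report = report)
}

# centered rolling statistic with shrinking windows at the edges
roll_stat <- function(v, w, fun) {
  n <- length(v)
  h <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    win <- v[max(1L, i - h):min(n, i + h)]
    out[i] <- fun(win[is.finite(win)])
  }
  out
}

#' Smooth an element's trajectories
#'
#' Applies a centered rolling statistic per POI and per axis. Edges use
#' shrinking windows (the first and last samples are averaged over the
#' neighbours actually available) rather than padding, so no data is
#' fabricated at the trajectory ends.
#'
#' @param e an [element()].
#' @param method `"moving_mean"`, `"moving_median"` or `"rms"`
#'   (root-mean-square).
#' @param w odd window width, `3 <= w <=` number of samples.
#' @return The smoothed [element()].
#' @export
smooth_element <- function(e, method = c("moving_mean", "moving_median", "rms"),
                           w = 5L) {
  stopifnot(inherits(e, "ma_element"))
  method <- match.arg(method)
  n <- length(element_times(e))
  if (w %% 2L == 0L || w < 3L || w > n)
    ma_stop("validation_error",
            "window width must be odd and between 3 and %d, got %s", n, w)
  fun <- switch(method,
                moving_mean = mean,
                moving_median = stats::median,
                rms = function(x) sqrt(mean(x^2)))
  map_coords(e, function(cm, p) {
    apply(cm, 2L, roll_stat, w = w, fun = fun)
  }, history_entry("smooth", method = method, w = w))
}

#' Invert one coordinate axis
#'
#' Reflects coordinates about a pivot: `x' = 2 * pivot - x`. The default
#' pivot is the midpoint of the axis range over all POIs, so the element
#' stays in place. Use this to convert image coordinates (y increasing
#' downwards) to the Cartesian up-positive convention the gait logic
#' assumes.
#'
#' @param e an [element()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param pivot reflection point; default midpoint of the axis range.
#' @return The reflected [element()].
#' @export
invert_axis <- function(e, axis = "y", pivot = NULL) {
  stopifnot(inherits(e, "ma_element"))
  j <- axis_index(e, axis)
  if (is.null(pivot)) {
    vals <- unlist(lapply(e$pois, function(p) p$coords[, j]))
    pivot <- (min(vals, na.rm = TRUE) + max(vals, na.rm = TRUE)) / 2
  }
  map_coords(e, function(cm, p) { cm[, j] <- 2 * pivot - cm[, j]; cm },
             history_entry("invert_axis", axis = axis, pivot = pivot))
}

#' Rigid and affine element transforms
#'
#' `shift_element` translates all POIs by `offset`; `rotate_element` rotates
#' them by `angle` in the given coordinate plane about `center` (default: the
#' element centroid); `scale_element` applies isotropic scaling about
#' `center`, the plain perspective-size correction for multi-camera setups.
#' Times are untouched.
#'
#' @param e an [element()].
#' @param offset numeric translation vector of length equal to the dimension.
#' @param angle rotation angle.
#' @param unit `"degrees"` (default) or `"radians"`.
#' @param center rotation/scaling center; default element centroid.
#' @param plane rotation plane for 3D data: `"xy"`, `"xz"` or `"yz"`.
#' @param factor positive scale factor.
#' @return The transformed [element()].
#' @export
shift_element <- function(e, offset) {
  stopifnot(inherits(e, "ma_element"))
  d <- n_dims(e$pois[[1L]])
  if (length(offset) != d)
    ma_stop("validation_error", "offset must have length %d", d)
  map_coords(e, function(cm, p) sweep(cm, 2L, offset, `+`),
             history_entry("shift", offset = offset))
}

plane_cols <- function(plane) switch(plane, xy = c(1L, 2L), xz = c(1L, 3L),
                                     yz = c(2L, 3L))

#' @rdname shift_element
#' @export
rotate_element <- function(e, angle, center = NULL, plane = c("xy", "xz", "yz"),
                           unit = c("degrees", "radians")) {
  stopifnot(inherits(e, "ma_element"))
  plane <- match.arg(plane)
  unit <- match.arg(unit)
  th <- if (unit == "degrees") angle * pi / 180 else angle
  cols <- plane_cols(plane)
  d <- n_dims(e$pois[[1L]])
  if (max(cols) > d)
    ma_stop("validation_error", "plane '%s' needs 3D data", plane)
  if (is.null(center)) center <- element_centroid(e)[cols]
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  map_coords(e, function(cm, p) {
    sub <- sweep(cm[, cols, drop = FALSE], 2L, center, `-`)
    cm[, cols] <- sweep(sub %*% t(R), 2L, center, `+`)
    cm
  }, history_entry("rotate", angle = angle, unit = unit, plane = plane,
                   center = center))
}

#' @rdname shift_element
#' @export
scale_element <- function(e, factor, center = NULL) {
  stopifnot(inherits(e, "ma_element"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    ma_stop("validation_error", "scale factor must be positive")
  if (is.null(center)) center <- element_centroid(e)
  map_coords(e, function(cm, p)
    sweep(sweep(cm, 2L, center, `-`) * factor, 2L, center, `+`),
    history_entry("scale", factor = factor, center = center))
}

#' Align one element to another at a reference POI
#'
#' Translates `moving` so that its POI `poi` coincides with the same POI of
#' `reference` at the sample nearest to `at_time` in each element.
#'
#' @param moving,reference [element()] objects sharing the POI label.
#' @param poi POI label present in both elements.
#' @param at_time alignment time (nearest sample used in each element).
#' @return The translated `moving` element.
#' @export
auto_align <- function(moving, reference, poi, at_time) {
  stopifnot(inherits(moving, "ma_element"), inherits(reference, "ma_element"))
  for (e in list(moving, reference))
    if (!poi %in% poi_labels(e))
      ma_stop("validation_error", "POI '%s' not found in element '%s'",
              poi, e$name)
  im <- which.min(abs(element_times(moving) - at_time))
  ir <- which.min(abs(element_times(reference) - at_time))
  offset <- reference$pois[[poi]]$coords[ir, ] - moving$pois[[poi]]$coords[im, ]
  out <- shift_element(moving, offset)
  out$history[[length(out$history)]] <-
    history_entry("auto_align", poi = poi, at_time = at_time, offset = offset)
  out
}

#' Trim to a time window
#'
#' Keeps the samples with `t0 <= t <= t1` (closed interval on time, not on
#' indices, so it behaves identically across sampling rates).
#'
#' @param x an [element()] or [signal_trace()].
#' @param t0,t1 window bounds, `t0 < t1`.
#' @return Same class as `x`, restricted to the window.
#' @export
trim_time <- function(x, t0, t1) {
  if (!is.numeric(t0) || !is.numeric(t1) || t0 >= t1)
    ma_stop("validation_error", "need t0 < t1")
  UseMethod("trim_time")
}

#' @export
trim_time.ma_element <- function(x, t0, t1) {
  keep <- element_times(x) >= t0 & element_times(x) <= t1
  if (!any(keep))
    ma_stop("validation_error", "no samples in [%g, %g]", t0, t1)
  x$pois <- lapply(x$pois, function(p) {
    p$times <- p$times[keep]
    p$coords <- p$coords[keep, , drop = FALSE]
    p$missing <- p$missing[keep]
    p
  })
  x$history <- c(x$history, list(history_entry("trim", t0 = t0, t1 = t1)))
  x
}

#' @export
trim_time.signal_trace <- function(x, t0, t1) {
  keep <- x$times >= t0 & x$times <= t1
  if (!any(keep))
    ma_stop("validation_error", "no samples in [%g, %g]", t0, t1)
  update_trace(x, x$times[keep], x$values[keep],
               history_entry("trim", t0 = t0, t1 = t1))
}

#' Downsample an element for display
#'
#' Returns a derived element keeping every `k`-th sample, tagged
#' display-only. The tag is enforced: kinematic computations refuse
#' display-only elements, since downsampling solely impacts the display and
#' must never alter analysis results.
#'
#' @param e an [element()].
#' @param keep_every positive integer stride.
#' @return A display-only [element()].
#' @export
downsample_view <- function(e, keep_every) {
  stopifnot(inherits(e, "ma_element"))
  k <- as.integer(keep_every)
  if (is.na(k) || k < 1L)
    ma_stop("validation_error", "keep_every must be a positive integer")
  idx <- seq(1L, length(element_times(e)), by = k)
  e$pois <- lapply(e$pois, function(p) {
    p$times <- p$times[idx]
    p$coords <- p$coords[idx, , drop = FALSE]
    p$missing <- p$missing[idx]
    p
  })
  e$display_only <- TRUE
  e$history <- c(e$history, list(history_entry("downsample_view", k = k)))
  e
}

#' Split an element at a time point
#'
#' Convenience inverse of [stitch_elements()]: returns the samples strictly
#' before `t` and those at or after `t` as two elements.
#'
#' @param e an [element()].
#' @param t interior split time.
#' @return A list with elements `before` and `after`.
#' @export
split_element <- function(e, t) {
  stopifnot(inherits(e, "ma_element"))
  times <- element_times(e)
  if (t <= times[1L] || t > times[length(times)])
    ma_stop("validation_error", "split time %g outside the interior of the record", t)
  pick <- function(keep, tag) {
    out <- e
    out$pois <- lapply(out$pois, function(p) {
      p$times <- p$times[keep]
      p$coords <- p$coords[keep, , drop = FALSE]
      p$missing <- p$missing[keep]
      p
    })
    out$history <- c(out$history, list(history_entry("split", t = t, part = tag)))
    out
  }
  list(before = pick(times < t, "before"), after = pick(times >= t, "after"))
}

#' Stitch two camera views into one element
#'
#' Joins a base recording with a patch recording at `transition_time`: the
#' output is the base samples strictly before the transition followed by the
#' patch samples from the transition on. The patch is first rotated by
#' `rotation` about its centroid and then translated by `offset`, the manual
#' reconciliation of two camera frames of reference. No blending is applied;
#' a residual discontinuity larger than twice the median sampling interval
#' triggers a warning.
#'
#' @param base,patch [element()] objects with identical POI labels and
#'   dimension.
#' @param transition_time time at which the output switches from base to
#'   patch samples.
#' @param offset translation applied to the patch after rotation (default
#'   zero).
#' @param rotation rotation angle in degrees applied to the patch about its
#'   centroid (default 0), in the xy plane.
#' @return The stitched [element()].
#' @export
stitch_elements <- function(base, patch, transition_time, offset = NULL,
                            rotation = 0) {
  stopifnot(inherits(base, "ma_element"), inherits(patch, "ma_element"))
  if (!identical(poi_labels(base), poi_labels(patch)) ||
      n_dims(base$pois[[1L]]) != n_dims(patch$pois[[1L]]))
    ma_stop("validation_error",
            "base and patch must share POI labels and dimension")
  tp <- element_times(patch)
  if (max(tp) < transition_time)
    ma_stop("validation_error",
            "patch time range does not reach the transition time %g",
            transition_time)
  d <- n_dims(base$pois[[1L]])
  if (is.null(offset)) offset <- rep(0, d)
  p2 <- patch
  if (rotation != 0) p2 <- rotate_element(p2, rotation)
  if (any(offset != 0)) p2 <- shift_element(p2, offset)
  keep_b <- element_times(base) < transition_time
  keep_p <- element_times(p2) >= transition_time
  if (!any(keep_b) || !any(keep_p))
    ma_stop("validation_error", "transition time leaves one side empty")
  tb <- element_times(base)[keep_b]
  tpk <- element_times(p2)[keep_p]
  newt <- c(tb, tpk)
  if (any(diff(newt) <= 0))
    ma_stop("time_base_error",
            "stitched times are not strictly increasing at the transition")
  dt_med <- stats::median(diff(element_times(base)))
  if (tpk[1L] - tb[length(tb)] > 2 * dt_med)
    ma_warn("stitch gap of %g at the transition exceeds twice the median sampling interval",
            tpk[1L] - tb[length(tb)])
  out <- base
  out$pois <- lapply(poi_labels(base), function(lab) {
    pb <- base$pois[[lab]]; pp <- p2$pois[[lab]]
    poi_trajectory(lab, newt,
                   rbind(pb$coords[keep_b, , drop = FALSE],
                         pp$coords[keep_p, , drop = FALSE]),
                   missing = c(pb$missing[keep_b], pp$missing[keep_p]))
  })
  names(out$pois) <- poi_labels(base)
  out$history <- c(base$history,
                   list(history_entry("stitch", transition_time = transition_time,
                                      offset = offset, rotation = rotation)))
  out
}
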