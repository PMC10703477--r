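# File-based rendering. The correctness surface is the exported geometry,
# so SVG files are written directly (one <polyline> per stick frame, one
# <rect> per gait interval or heatmap bin) with a plain affine viewport
# transform; PNG output goes through the grDevices device. Rendering never
# mutates analysis data.

DEFAULT_PALETTE <- c("#D62728", "#2CA02C", "#1F77B4", "#FF7F0E", "#9467BD",
                     "#8C564B", "#17BECF", "#7F7F7F")

#' Rendering options
#'
#' @param format `"svg"` or `"png"`.
#' @param width,height canvas size in pixels.
#' @param line_width stroke width.
#' @param markers draw vertex markers on stick frames.
#' @param colors colour vector keyed by POI / series order (recycled);
#'   defaults to a fixed documented palette.
#' @param rate animation playback rate, frames per second (> 0).
#' @param azimuth,elevation viewing angles in degrees for 3D projection.
#' @return A `render_spec` list.
#' @export
render_spec <- function(format = c("svg", "png"), width = 640, height = 480,
                        line_width = 1.5, markers = FALSE,
                        colors = DEFAULT_PALETTE, rate = 25,
                        azimuth = 30, elevation = 20) {
  format <- match.arg(format)
  if (rate <= 0) ma_stop("validation_error", "playback rate must be positive")
  structure(list(format = format, width = width, height = height,
                 line_width = line_width, markers = markers, colors = colors,
                 rate = rate, azimuth = azimuth, elevation = elevation),
            class = "render_spec")
}

# affine map from data bbox to the SVG viewport (y axis flipped, 5% margin)
viewport_map <- function(xr, yr, spec) {
  pad <- 0.05
  dx <- diff(xr); dy <- diff(yr)
  if (dx == 0) dx <- 1
  if (dy == 0) dy <- 1
  xr <- xr + c(-pad, pad) * dx
  yr <- yr + c(-pad, pad) * dy
  list(
    x = function(x) (x - xr[1L]) / diff(xr) * spec$width,
    y = function(y) spec$height - (y - yr[1L]) / diff(yr) * spec$height)
}

svg_open <- function(spec) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g" viewBox="0 0 %g %g">',
            spec$width, spec$height, spec$width, spec$height))
}

svg_write <- function(lines, path) {
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

# rotate 3D coordinates by azimuth (about z) then elevation (about x) and
# drop the depth axis; 2D input gets the constant placeholder z first
project_coords <- function(m, spec, third_coord = 0) {
  if (ncol(m) == 2L) m <- cbind(m, third_coord)
  az <- spec$azimuth * pi / 180
  el <- spec$elevation * pi / 180
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3L)
  Rx <- matrix(c(1, 0, 0, 0, cos(el), sin(el), 0, -sin(el), cos(el)), 3L)
  (m %*% Rz %*% Rx)[, c(1L, 3L), drop = FALSE]
}

stick_bbox <- function(frames) {
  all <- do.call(rbind, frames)
  list(x = range(all[, 1L], na.rm = TRUE), y = range(all[, 2L], na.rm = TRUE))
}

#' Render a stick diagram to a file
#'
#' SVG output contains exactly one `<polyline>` per frame, vertices in the
#' element's POI order, mapped by the viewport transform.
#'
#' @param sd a [stick_diagram()].
#' @param path output file.
#' @param spec a [render_spec()].
#' @return `path`, invisibly.
#' @export
render_stick <- function(sd, path, spec = render_spec()) {
  stopifnot(inherits(sd, "stick_diagram"))
  if (!length(sd$frames))
    ma_stop("validation_error", "empty stick diagram")
  frames2d <- lapply(sd$frames, function(m)
    if (ncol(m) == 3L) project_coords(m, spec) else m)
  bb <- stick_bbox(frames2d)
  vm <- viewport_map(bb$x, bb$y, spec)
  if (spec$format == "png") {
    grDevices::png(path, spec$width, spec$height)
    on.exit(grDevices::dev.off())
    plot(NA, xlim = bb$x, ylim = bb$y, xlab = "x", ylab = "y", asp = 1)
    for (m in frames2d) graphics::lines(m[, 1L], m[, 2L],
                                        lwd = spec$line_width)
    return(invisible(path))
  }
  lines <- svg_open(spec)
  for (m in frames2d) {
    pts <- paste(sprintf("%.3f,%.3f", vm$x(m[, 1L]), vm$y(m[, 2L])),
                 collapse = " ")
    lines <- c(lines, sprintf(
      '<polyline points="%s" fill="none" stroke="#333333" stroke-width="%g"/>',
      pts, spec$line_width))
    if (spec$markers)
      lines <- c(lines, sprintf(
        '<circle cx="%.3f" cy="%.3f" r="%g" fill="%s"/>',
        vm$x(m[, 1L]), vm$y(m[, 2L]), 2 * spec$line_width,
        rep_len(spec$colors, nrow(m))))
  }
  svg_write(lines, path)
}

#' Render an occupancy heatmap to a file
#'
#' SVG output contains one `<rect>` per grid bin, shaded by count.
#'
#' @param h a [occupancy_heatmap()] result.
#' @param path output file.
#' @param spec a [render_spec()].
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(h, path, spec = render_spec()) {
  stopifnot(inherits(h, "heatmap_grid"))
  if (sum(h$counts) == 0L)
    ma_stop("validation_error", "empty heatmap")
  if (spec$format == "png") {
    grDevices::png(path, spec$width, spec$height)
    on.exit(grDevices::dev.off())
    graphics::image(h$x_edges, h$y_edges, h$counts,
                    col = grDevices::hcl.colors(64, "inferno"),
                    xlab = "x", ylab = "y", useRaster = TRUE)
    return(invisible(path))
  }
  vm <- viewport_map(range(h$x_edges), range(h$y_edges), spec)
  mx <- max(h$counts)
  lines <- svg_open(spec)
  for (i in seq_len(nrow(h$counts))) for (j in seq_len(ncol(h$counts))) {
    shade <- 255 - as.integer(round(255 * h$counts[i, j] / mx))
    lines <- c(lines, sprintf(
      '<rect x="%.3f" y="%.3f" width="%.3f" height="%.3f" fill="#%02x%02x%02x"/>',
      vm$x(h$x_edges[i]), vm$y(h$y_edges[j + 1L]),
      vm$x(h$x_edges[i + 1L]) - vm$x(h$x_edges[i]),
      vm$y(h$y_edges[j]) - vm$y(h$y_edges[j + 1L]),
      shade, shade, 255L))
  }
  svg_write(lines, path)
}

#' Render a gait diagram to a file
#'
#' One `<rect>` per stance interval (left, right) and per double-support
#' overlap, on three rows.
#'
#' @param gd a [gait_diagram()].
#' @param path output file.
#' @param spec a [render_spec()].
#' @return `path`, invisibly.
#' @export
render_gait <- function(gd, path, spec = render_spec()) {
  stopifnot(inherits(gd, "gait_diagram"))
  rowsets <- list(left = gd$left, right = gd$right, overlap = gd$overlap)
  if (!sum(vapply(rowsets, nrow, integer(1))))
    ma_stop("validation_error", "empty gait diagram")
  tr <- range(unlist(rowsets))
  vm <- viewport_map(tr, c(0, 3), spec)
  fills <- c(left = "#D62728", right = "#2CA02C", overlap = "#7F7F7F")
  lines <- svg_open(spec)
  for (k in seq_along(rowsets)) {
    iv <- rowsets[[k]]
    y0 <- 3 - k + 0.15; y1 <- 3 - k + 0.85
    for (i in seq_len(nrow(iv)))
      lines <- c(lines, sprintf(
        '<rect x="%.3f" y="%.3f" width="%.3f" height="%.3f" fill="%s" class="%s"/>',
        vm$x(iv[i, 1L]), vm$y(y1), vm$x(iv[i, 2L]) - vm$x(iv[i, 1L]),
        vm$y(y0) - vm$y(y1), fills[k], names(rowsets)[k]))
  }
  svg_write(lines, path)
}

#' Render time series to a file
#'
#' One `<polyline>` per series ([signal_trace()], [joint_angle()] series or
#' `list(times, values)`).
#'
#' @param series a list of series.
#' @param path output file.
#' @param spec a [render_spec()].
#' @return `path`, invisibly.
#' @export
render_series <- function(series, path, spec = render_spec()) {
  if (!length(series))
    ma_stop("validation_error", "no series to render")
  ser <- lapply(series, function(s) {
    tr <- as_trace(s)
    list(t = tr$times, v = tr$values)
  })
  tr <- range(unlist(lapply(ser, `[[`, "t")))
  vr <- range(unlist(lapply(ser, `[[`, "v")), finite = TRUE)
  if (spec$format == "png") {
    grDevices::png(path, spec$width, spec$height)
    on.exit(grDevices::dev.off())
    plot(NA, xlim = tr, ylim = vr, xlab = "t", ylab = "value")
    for (k in seq_along(ser))
      graphics::lines(ser[[k]]$t, ser[[k]]$v,
                      col = rep_len(spec$colors, length(ser))[k])
    return(invisible(path))
  }
  vm <- viewport_map(tr, vr, spec)
  lines <- svg_open(spec)
  for (k in seq_along(ser)) {
    ok <- is.finite(ser[[k]]$v)
    pts <- paste(sprintf("%.3f,%.3f", vm$x(ser[[k]]$t[ok]),
                         vm$y(ser[[k]]$v[ok])), collapse = " ")
    lines <- c(lines, sprintf(
      '<polyline points="%s" fill="none" stroke="%s" stroke-width="%g"/>',
      pts, rep_len(spec$colors, length(ser))[k], spec$line_width))
  }
  svg_write(lines, path)
}

#' Export an element as an animation frame sequence
#'
#' Writes one rendered frame per sample (`frame_000001.svg/png` ...) into
#' `dir`, each showing the stick pose at that sample. 2D elements are given
#' a constant placeholder third coordinate for perspective rendering only —
#' it is never fed back into any analysis. Use [downsample_view()] first to
#' reduce the frame count; an accompanying `playback.txt` records the
#' frame rate implied by `spec$rate`.
#'
#' @param e an [element()] with at least 2 POIs and 2 frames.
#' @param dir output directory (created if needed).
#' @param spec a [render_spec()].
#' @param third_coord constant z assigned to 2D data at render time.
#' @param normalize optional normalization passed to [stick_diagram()].
#' @return The vector of frame files, invisibly.
#' @export
export_animation <- function(e, dir, spec = render_spec(), third_coord = 0,
                             normalize = NULL) {
  stopifnot(inherits(e, "ma_element"))
  sd <- stick_diagram(e, normalize = normalize)
  if (length(sd$frames) < 2L)
    ma_stop("validation_error", "an animation needs at least 2 frames")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    ma_stop("io_error", "cannot create directory '%s'", dir)
  frames2d <- lapply(sd$frames, project_coords, spec = spec,
                     third_coord = third_coord)
  bb <- stick_bbox(frames2d)
  vm <- viewport_map(bb$x, bb$y, spec)
  ext <- spec$format
  files <- character(length(frames2d))
  for (i in seq_along(frames2d)) {
    f <- file.path(dir, sprintf("frame_%06d.%s", i, ext))
    m <- frames2d[[i]]
    if (ext == "png") {
      grDevices::png(f, spec$width, spec$height)
      plot(NA, xlim = bb$x, ylim = bb$y, xlab = "", ylab = "", axes = FALSE)
      graphics::lines(m[, 1L], m[, 2L], lwd = spec$line_width)
      grDevices::dev.off()
    } else {
      pts <- paste(sprintf("%.3f,%.3f", vm$x(m[, 1L]), vm$y(m[, 2L])),
                   collapse = " ")
      svg_write(c(svg_open(spec), sprintf(
        '<polyline points="%s" fill="none" stroke="#333333" stroke-width="%g"/>',
        pts, spec$line_width)), f)
    }
    files[i] <- f
  }
  writeLines(sprintf("frames: %d\nrate_fps: %g", length(files), spec$rate),
             file.path(dir, "playback.txt"))
  invisible(files)
}
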