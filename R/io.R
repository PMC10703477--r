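# Readers and writers. All tabular input follows the same column-wise schema:
# timestamps in the first column, data columns after, with a header row used
# to label tables and plots. Text output is written with 17 significant
# digits so numeric round trips are exact for doubles.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

# quote-aware splitter for one delimited line (RFC-4180-style double quotes)
split_delim <- function(line, sep) {
  out <- character(0)
  field <- character(0)
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  in_quote <- FALSE
  buf <- c()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == '"') {
        if (i < n && chars[i + 1L] == '"') { buf <- c(buf, '"'); i <- i + 1L }
        else in_quote <- FALSE
      } else buf <- c(buf, ch)
    } else if (ch == '"') {
      in_quote <- TRUE
    } else if (ch == sep) {
      out <- c(out, paste(buf, collapse = "")); buf <- c()
    } else buf <- c(buf, ch)
    i <- i + 1L
  }
  c(out, paste(buf, collapse = ""))
}

detect_sep <- function(line, decimal = ".") {
  cands <- c(",", ";", "\t")
  if (decimal == ",") cands <- setdiff(cands, ",")
  counts <- vapply(cands, function(s)
    lengths(regmatches(line, gregexpr(s, line, fixed = TRUE))), integer(1))
  if (all(counts == 0L)) " " else cands[which.max(counts)]
}

read_delim_cells <- function(path, sep = NULL, decimal = ".") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    ma_stop("format_error", "'%s' is empty", path)
  if (is.null(sep)) sep <- detect_sep(lines[1L], decimal)
  if (sep == " ") lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1L]])
  else lapply(lines, split_delim, sep = sep)
}

parse_numeric_cells <- function(cells, decimal = ".") {
  if (decimal == ",") cells <- gsub(",", ".", cells, fixed = TRUE)
  suppressWarnings(as.numeric(cells))
}

#' Read a column-wise data table
#'
#' Reads a delimited text file (`.csv`/`.txt`/`.tsv`, delimiter auto-detected
#' among comma, semicolon and tab) or a spreadsheet workbook into a raw
#' table. The first row is treated as the header and is used to label all
#' derived tables and plots; non-numeric cells in the data region become
#' missing values.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"csv"`, `"txt"` or `"xlsx"`.
#' @param decimal decimal mark; set `","` for European exports (then the
#'   field delimiter must be semicolon or tab). Never auto-detected.
#' @param sheet sheet index for xlsx input.
#' @return An object of class `raw_table` with fields `headers`, `columns`
#'   (list of numeric vectors) and `source`.
#' @export
read_table_file <- function(path, dialect = c("auto", "csv", "txt", "xlsx"),
                            decimal = ".", sheet = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    ma_stop("io_error", "cannot read '%s': no such file", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("xlsx", "xls")) "xlsx" else if (ext == "csv") "csv" else "txt"
  }
  if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      ma_stop("io_error", "reading xlsx requires the readxl package")
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                           .name_repair = "minimal"))
    headers <- names(df)
    columns <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  } else {
    rows <- read_delim_cells(path, decimal = decimal)
    headers <- trimws(rows[[1L]])
    ncol_exp <- length(headers)
    body <- rows[-1L]
    widths <- lengths(body)
    bad <- which(widths != ncol_exp)
    if (length(bad))
      ma_stop("format_error",
              "'%s': row %d has %d field(s), expected %d",
              path, bad[1L] + 1L, widths[bad[1L]], ncol_exp)
    mat <- do.call(rbind, body)
    columns <- lapply(seq_len(ncol_exp), function(j)
      parse_numeric_cells(mat[, j], decimal))
  }
  lens <- lengths(columns)
  if (length(unique(lens)) > 1L)
    ma_stop("format_error", "'%s': unequal column lengths", path)
  structure(
    list(headers = headers, columns = columns,
         source = list(path = path, dialect = dialect)),
    class = "raw_table"
  )
}

#' @export
print.raw_table <- function(x, ...) {
  cat(sprintf("<raw_table> %d column(s) x %d row(s) from %s\n",
              length(x$columns), length(x$columns[[1L]]), x$source$path))
  cat("  headers:", paste(x$headers, collapse = ", "), "\n")
  invisible(x)
}

# strip a trailing _x/_y/_z (or .x/.y/.z) axis suffix from a header
strip_axis_suffix <- function(h) sub("[._ ]?[xyzXYZ]$", "", h)

#' Convert a raw table to an element
#'
#' Interprets a raw table as time followed by groups of coordinate columns
#' (x, y for `layout = "xy"`; x, y, z for `"xyz"`), one group per POI.
#' POI labels are taken from the headers of each group's first column
#' (a trailing axis suffix such as `_x` is stripped) unless `poi_labels` is
#' given.
#'
#' @param tbl a [read_table_file()] result.
#' @param layout `"xy"` or `"xyz"`.
#' @param poi_labels optional character vector of POI names.
#' @param name element name; defaults to the source file name.
#' @return An [element()].
#' @export
table_to_element <- function(tbl, layout = c("xy", "xyz"), poi_labels = NULL,
                             name = NULL) {
  layout <- match.arg(layout)
  stopifnot(inherits(tbl, "raw_table"))
  d <- if (layout == "xy") 2L else 3L
  ncoord <- length(tbl$columns) - 1L
  if (ncoord < d || ncoord %% d != 0L)
    ma_stop("layout_error",
            "%d coordinate column(s) not divisible by dimension %d", ncoord, d)
  npoi <- ncoord %/% d
  times <- tbl$columns[[1L]]
  if (is.null(name))
    name <- tools::file_path_sans_ext(basename(tbl$source$path))
  pois <- vector("list", npoi)
  for (k in seq_len(npoi)) {
    idx <- 1L + (k - 1L) * d + seq_len(d)
    lab <- if (!is.null(poi_labels)) poi_labels[k] else {
      h <- strip_axis_suffix(trimws(tbl$headers[idx[1L]]))
      if (nzchar(h)) h else sprintf("poi_%d", k)
    }
    pois[[k]] <- poi_trajectory(lab, times, do.call(cbind, tbl$columns[idx]))
  }
  element(name, pois)
}

#' Read a DeepLabCut pose-estimation CSV
#'
#' Parses the three-row DeepLabCut header (scorer / bodyparts / coords) and
#' builds one POI per bodypart. The first data column is the frame index;
#' timestamps are `frame / fps`. Samples whose likelihood falls below
#' `likelihood_min` are flagged missing (the default 0 keeps everything).
#'
#' @param path CSV path.
#' @param fps video frame rate used to convert frame indices to time.
#' @param likelihood_min likelihood threshold in `[0, 1]`.
#' @param name element name; defaults to the file name.
#' @return An [element()].
#' @export
read_deeplabcut <- function(path, fps, likelihood_min = 0, name = NULL) {
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    ma_stop("validation_error", "fps must be a positive number")
  if (!file.exists(path))
    ma_stop("io_error", "cannot read '%s': no such file", path)
  rows <- read_delim_cells(path)
  if (length(rows) < 4L)
    ma_stop("format_error", "'%s': too short for a DeepLabCut file", path)
  h1 <- tolower(trimws(rows[[1L]][1L]))
  h3 <- tolower(trimws(rows[[3L]]))
  if (!identical(h1, "scorer") || !any(h3 %in% c("x", "y")))
    ma_stop("format_error",
            "'%s': missing DeepLabCut header rows (scorer/bodyparts/coords)", path)
  bodyparts <- trimws(rows[[2L]])[-1L]
  coords <- h3[-1L]
  body <- rows[-(1:3)]
  widths <- lengths(body)
  if (any(widths != length(rows[[1L]])))
    ma_stop("format_error", "'%s': ragged data row %d", path,
            which(widths != length(rows[[1L]]))[1L] + 3L)
  mat <- do.call(rbind, body)
  frames <- parse_numeric_cells(mat[, 1L])
  times <- frames / fps
  parts <- unique(bodyparts)
  pois <- lapply(parts, function(bp) {
    sel <- which(bodyparts == bp) + 1L
    ax <- coords[sel - 1L]
    get_col <- function(a) {
      j <- sel[match(a, ax)]
      if (is.na(j)) NULL else parse_numeric_cells(mat[, j])
    }
    x <- get_col("x"); y <- get_col("y"); z <- get_col("z")
    if (is.null(x) || is.null(y))
      ma_stop("format_error", "bodypart '%s' lacks x/y columns", bp)
    cm <- if (is.null(z)) cbind(x = x, y = y) else cbind(x = x, y = y, z = z)
    lik <- get_col("likelihood")
    miss <- if (is.null(lik)) rep(FALSE, length(x)) else lik < likelihood_min
    poi_trajectory(bp, times, cm, missing = miss)
  })
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  element(name, pois)
}

#' Read signal traces from a column-wise table
#'
#' Time in the first column, one channel per following column, labelled from
#' the header (empty labels become `channel_k`).
#'
#' @inheritParams read_table_file
#' @return A named list of [signal_trace()] objects.
#' @export
read_signal_table <- function(path, dialect = c("auto", "csv", "txt", "xlsx"),
                              decimal = ".") {
  tbl <- read_table_file(path, dialect, decimal = decimal)
  if (length(tbl$columns) < 2L)
    ma_stop("format_error", "'%s': a signal table needs a time column and at least one channel",
            path)
  times <- tbl$columns[[1L]]
  traces <- lapply(seq_along(tbl$columns)[-1L], function(j) {
    lab <- trimws(tbl$headers[j])
    if (!nzchar(lab)) lab <- sprintf("channel_%d", j - 1L)
    signal_trace(lab, times, tbl$columns[[j]])
  })
  names(traces) <- vapply(traces, `[[`, character(1), "label")
  traces
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

write_ma_csv <- function(df, path, sep = ",") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = sep), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col)
      if (is.numeric(col)) fmt_num(col) else as.character(col))
    writeLines(do.call(paste, c(cols, sep = sep)), con)
  }
  invisible(path)
}

element_to_df <- function(e) {
  df <- data.frame(t = element_times(e))
  ax <- colnames(e$pois[[1L]]$coords)
  for (p in e$pois)
    for (j in seq_along(ax))
      df[[paste0(p$label, "_", ax[j])]] <- p$coords[, j]
  df
}

trace_to_df <- function(s) {
  df <- data.frame(t = s$times, v = s$values)
  names(df)[2L] <- s$label   # keep the channel label on re-import
  df
}

#' Export all session data to delimited files
#'
#' Writes one file per element, signal and tabular product into `dir`.
#' Text dialects use 17 significant digits so re-imported values match the
#' originals exactly; missing samples are written as `NA` cells.
#'
#' @param sess a [session()].
#' @param dir output directory (created if needed).
#' @param dialect `"csv"` (comma) or `"txt"` (tab). Spreadsheet output is not
#'   supported by this build and raises an error.
#' @return Invisibly, the vector of files written.
#' @export
write_tables <- function(sess, dir, dialect = c("csv", "txt")) {
  stopifnot(inherits(sess, "ma_session"))
  dialect <- match.arg(dialect[1L], c("csv", "txt", "xlsx"))
  if (dialect == "xlsx")
    ma_stop("validation_error",
            "xlsx export is not supported; use csv or txt")
  if (length(sess$elements) + length(sess$signals) + length(sess$products) == 0L)
    ma_stop("validation_error", "session is empty; nothing to export")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    ma_stop("io_error", "cannot create directory '%s'", dir)
  sep <- if (dialect == "csv") "," else "\t"
  ext <- if (dialect == "csv") ".csv" else ".txt"
  files <- character(0)
  for (e in sess$elements) {
    f <- file.path(dir, paste0(safe_name(e$name), ext))
    write_ma_csv(element_to_df(e), f, sep)
    files <- c(files, f)
  }
  for (s in sess$signals) {
    f <- file.path(dir, paste0(safe_name(s$label), ext))
    write_ma_csv(trace_to_df(s), f, sep)
    files <- c(files, f)
  }
  for (nm in names(sess$products)) {
    pr <- sess$products[[nm]]
    f <- if (is.data.frame(pr)) {
      fp <- file.path(dir, paste0(safe_name(nm), ext))
      write_ma_csv(pr, fp, sep)
      fp
    } else {
      fp <- file.path(dir, paste0(safe_name(nm), ".json"))
      writeLines(jsonlite::serializeJSON(pr, digits = NA), fp)
      fp
    }
    files <- c(files, f)
  }
  invisible(files)
}

SESSION_FORMAT_VERSION <- 1L

#' Save or load a complete session archive
#'
#' The session archive is a single ZIP container holding a JSON manifest
#' (names, types, processing histories, gait annotations) plus one CSV
#' payload per dataset, all text and all written at full double precision:
#' `load_session(save_session(s, f))` reproduces `s` exactly, including
#' missing-sample masks, raw signal copies and processing histories.
#'
#' @param sess a [session()].
#' @param path archive file path (conventionally `.mksession.zip`).
#' @return `save_session` returns `path` invisibly; `load_session` returns
#'   the restored [session()].
#' @export
save_session <- function(sess, path) {
  stopifnot(inherits(sess, "ma_session"))
  stage <- tempfile("mksession")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))
  man <- list(
    version = SESSION_FORMAT_VERSION,
    units_note = sess$units_note,
    elements = lapply(sess$elements, function(e) list(
      name = e$name, file = paste0("elements/", safe_name(e$name), ".csv"),
      pois = names(e$pois), dims = n_dims(e$pois[[1L]]),
      display_only = isTRUE(e$display_only),
      history = as.character(jsonlite::serializeJSON(e$history, digits = NA))
    )),
    signals = lapply(sess$signals, function(s) list(
      label = s$label, file = paste0("signals/", safe_name(s$label), ".csv"),
      raw_file = paste0("signals/", safe_name(s$label), "_raw.csv"),
      meta = as.character(jsonlite::serializeJSON(s$meta, digits = NA))
    )),
    has_gait = !is.null(sess$gait),
    products = names(sess$products)
  )
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, null = "null"),
             file.path(stage, "manifest.json"))
  if (length(sess$elements)) {
    dir.create(file.path(stage, "elements"))
    for (e in sess$elements)
      write_ma_csv(element_to_df(e),
                   file.path(stage, "elements", paste0(safe_name(e$name), ".csv")))
  }
  if (length(sess$signals)) {
    dir.create(file.path(stage, "signals"))
    for (s in sess$signals) {
      write_ma_csv(trace_to_df(s),
                   file.path(stage, "signals", paste0(safe_name(s$label), ".csv")))
      write_ma_csv(data.frame(t = s$raw_times, value = s$raw_values),
                   file.path(stage, "signals", paste0(safe_name(s$label), "_raw.csv")))
    }
  }
  if (!is.null(sess$gait))
    write_ma_csv(sess$gait, file.path(stage, "gait.csv"))
  if (length(sess$products)) {
    dir.create(file.path(stage, "products"))
    for (nm in names(sess$products))
      writeLines(jsonlite::serializeJSON(sess$products[[nm]], digits = NA),
                 file.path(stage, "products", paste0(safe_name(nm), ".json")))
  }
  path <- normalizePath(path, mustWork = FALSE)
  zip::zip(path, files = list.files(stage, recursive = TRUE), root = stage)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  if (!file.exists(path))
    ma_stop("io_error", "cannot read '%s': no such file", path)
  stage <- tempfile("mksession")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE))
  ok <- tryCatch({ zip::unzip(path, exdir = stage); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(file.path(stage, "manifest.json")))
    ma_stop("format_error",
            "'%s' is not a session archive (missing manifest.json)", path)
  man <- jsonlite::fromJSON(file.path(stage, "manifest.json"),
                            simplifyVector = FALSE)
  if (is.null(man$version) || man$version > SESSION_FORMAT_VERSION)
    ma_stop("format_error", "unknown session archive version: %s",
            as.character(man$version))
  read_payload <- function(f) {
    tbl <- read_table_file(file.path(stage, f), dialect = "csv")
    tbl
  }
  elements <- lapply(man$elements, function(em) {
    tbl <- read_payload(em$file)
    d <- em$dims
    e <- table_to_element(tbl, layout = if (d == 2L) "xy" else "xyz",
                          poi_labels = unlist(em$pois), name = em$name)
    e$history <- jsonlite::unserializeJSON(em$history)
    e$display_only <- isTRUE(em$display_only)
    e
  })
  signals <- lapply(man$signals, function(sm) {
    tbl <- read_payload(sm$file)
    s <- signal_trace(sm$label, tbl$columns[[1L]], tbl$columns[[2L]])
    raw <- read_payload(sm$raw_file)
    s$raw_times <- raw$columns[[1L]]
    s$raw_values <- raw$columns[[2L]]
    s$meta <- jsonlite::unserializeJSON(sm$meta)
    s
  })
  gait <- NULL
  if (isTRUE(man$has_gait)) {
    lines <- read_delim_cells(file.path(stage, "gait.csv"), sep = ",")
    hdr <- lines[[1L]]
    body <- do.call(rbind, lines[-1L])
    gait <- data.frame(type = body[, 1L], side = body[, 2L],
                       frame = as.integer(body[, 3L]),
                       time = as.numeric(body[, 4L]),
                       stringsAsFactors = FALSE)
    names(gait) <- hdr
    class(gait) <- c("gait_events", "data.frame")
  }
  products <- list()
  for (nm in unlist(man$products))
    products[[nm]] <- jsonlite::unserializeJSON(
      paste(readLines(file.path(stage, "products", paste0(safe_name(nm), ".json"))),
            collapse = "\n"))
  session(elements = elements, signals = signals, gait = gait,
          products = products, units_note = man$units_note %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
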