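#' Describe the layout of a delimited gaze-sample file
#'
#' Maps file columns onto the fields of a [gaze_trace()]. Eye trackers and
#' EOG/coil exports disagree on column names, time units and missing-data
#' sentinels, so the caller declares them here. For binocular files, map the
#' columns of one eye: the detector is defined on a single eye's trace.
#'
#' @param time,x,y Column names holding the timestamp and gaze position.
#' @param pupil Optional column name for pupil size.
#' @param x_ref,y_ref Optional column names subtracted from `x` / `y` before
#'   use, for bipolar EOG exports with one channel per electrode: the
#'   horizontal trace is right minus left canthus (`x = x - x_ref`), the
#'   vertical one below minus above the eye.
#' @param time_unit `"s"` or `"ms"`; timestamps are converted to seconds.
#' @param units Native gaze units, see [gaze_trace()].
#' @param fs_nominal Nominal sampling rate in Hz; if `NULL`, estimated as
#'   the reciprocal median sample interval.
#' @param pix_per_degree Optional pixels-per-degree calibration.
#' @param modality Recording modality, see [gaze_trace()].
#' @param pupil_missing Numeric sentinel value(s) in the pupil column that
#'   mean "no pupil" (video trackers commonly emit 0 during a blink); such
#'   samples are marked missing. Use `numeric(0)` to disable.
#' @param sep Field separator; `NULL` sniffs tab vs comma from the header.
#'
#' @return A `gaze_format` list, for [read_gaze_samples()].
#' @export
gaze_format <- function(time = "t", x = "x", y = "y", pupil = NULL,
                        x_ref = NULL, y_ref = NULL,
                        time_unit = c("s", "ms"),
                        units = c("pixels", "volts", "arbitrary"),
                        fs_nominal = NULL, pix_per_degree = NULL,
                        modality = NULL, pupil_missing = 0, sep = NULL) {
  structure(
    list(time = time, x = x, y = y, pupil = pupil,
         x_ref = x_ref, y_ref = y_ref,
         time_unit = match.arg(time_unit), units = match.arg(units),
         fs_nominal = fs_nominal, pix_per_degree = pix_per_degree,
         modality = modality, pupil_missing = pupil_missing, sep = sep),
    class = "gaze_format")
}

num_or_na <- function(v) suppressWarnings(as.numeric(as.character(v)))

#' Read gaze samples from a delimited text file
#'
#' Reads a CSV/TSV of gaze samples and returns a validated [gaze_trace()].
#' Timestamps are converted to seconds; rows whose gaze values do not parse
#' as numbers are kept but marked missing (`NA`), never dropped or
#' interpolated, so the sample count always equals the row count.
#'
#' @param path Path to the file.
#' @param format A [gaze_format()] describing the columns.
#' @return A [gaze_trace()].
#' @export
read_gaze_samples <- function(path, format = gaze_format()) {
  if (!inherits(format, "gaze_format")) stop("format must be a gaze_format()")
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- format$sep
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  need <- c(format$time, format$x, format$y, format$pupil,
            format$x_ref, format$y_ref)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mapped column(s) not present in file: ", paste(miss, collapse = ", "))
  if (nrow(df) < 2L) stop("fewer than 2 samples in ", path)

  t <- num_or_na(df[[format$time]])
  if (anyNA(t))
    stop("unparseable timestamp at row ", which(is.na(t))[1L])
  if (format$time_unit == "ms") t <- t / 1000

  x <- num_or_na(df[[format$x]])
  y <- num_or_na(df[[format$y]])
  if (!is.null(format$x_ref)) x <- x - num_or_na(df[[format$x_ref]])
  if (!is.null(format$y_ref)) y <- y - num_or_na(df[[format$y_ref]])

  pupil <- NULL
  if (!is.null(format$pupil)) {
    pupil <- num_or_na(df[[format$pupil]])
    if (length(format$pupil_missing))
      pupil[pupil %in% format$pupil_missing] <- NA_real_
  }
  fs <- format$fs_nominal
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  gaze_trace(t, x, y, pupil = pupil, units = format$units, fs_nominal = fs,
             pix_per_degree = format$pix_per_degree,
             modality = format$modality)
}

fmt_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "NA" else sprintf("%.17g", z)
  }, character(1L))
  out
}

#' Write a detected event list to a tab-separated file
#'
#' Writes one row per event with columns `onset`, `duration`, `label`,
#' `amplitude`, `peak_velocity`, `overshoot` (0/1) and `truncated` (0/1),
#' preceded by a comment line recording the trace extent. Numbers are
#' written with full double precision so that [read_events()] reproduces
#' the event list exactly.
#'
#' @param events An [event_list()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "safide_events"))
  ext <- attr(events, "extent")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# extent\t", sprintf("%.17g", ext[1L]), "\t",
                    sprintf("%.17g", ext[2L])), con)
  writeLines(paste(c("onset", "duration", "label", "amplitude",
                     "peak_velocity", "overshoot", "truncated"),
                   collapse = "\t"), con)
  if (nrow(events)) {
    lines <- paste(fmt_num(events$onset), fmt_num(events$duration),
                   events$label, fmt_num(events$amplitude),
                   fmt_num(events$peak_velocity),
                   as.integer(events$overshoot),
                   as.integer(events$truncated), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an event list written by [write_events()]
#'
#' @param path Path to the tab-separated event file.
#' @return An [event_list()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  ext <- c(NA_real_, NA_real_)
  if (startsWith(first, "# extent")) {
    parts <- strsplit(first, "\t", fixed = TRUE)[[1L]]
    ext <- as.numeric(parts[2:3])
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = "NA")
  if (!nrow(df)) {
    ev <- empty_events()
  } else {
    ev <- data.frame(onset = as.numeric(df$onset),
                     offset = as.numeric(df$onset) + as.numeric(df$duration),
                     label = as.character(df$label),
                     amplitude = as.numeric(df$amplitude),
                     duration = as.numeric(df$duration),
                     peak_velocity = as.numeric(df$peak_velocity),
                     overshoot = as.logical(df$overshoot),
                     truncated = as.logical(df$truncated),
                     stringsAsFactors = FALSE)
  }
  if (anyNA(ext)) ext <- if (nrow(ev)) c(min(ev$onset), max(ev$offset)) else c(0, 0)
  event_list(ev, extent = ext)
}

#' Read / write a flat key-value parameter file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers or logicals where possible. Every parameter of
#' [safide_params()] can be named.
#'
#' @param path File path.
#' @return `read_config()`: a named list. `write_config()`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    parsed <- suppressWarnings(as.numeric(val))
    if (!is.na(parsed)) val <- parsed
    else if (toupper(val) %in% c("TRUE", "FALSE")) val <- as.logical(val)
    else if (toupper(val) == "NA") val <- NA
    out[[key]] <- val
  }
  out
}

#' @rdname read_config
#' @param config Named list of parameter values.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, " = ", if (is.na(v)) "NA" else as.character(v))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
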