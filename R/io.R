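# On-disk format: CSV with header `time,pressure,label`, UTF-8, decimal
# point. The time column is either numeric seconds or an ISO-8601 timestamp
# with milliseconds; both are normalized to seconds since series start.

parse_time_column <- function(tt) {
  suppressWarnings(num <- as.numeric(tt))
  if (!anyNA(num)) return(num)
  # ISO-8601 with fractional seconds, 'T' or space separator
  clean <- sub("T", " ", tt, fixed = TRUE)
  op <- options(digits.secs = 6); on.exit(options(op))
  ts <- as.POSIXct(clean, format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("cannot parse time value '%s' (data line %d): expected numeric seconds or ISO-8601",
                 tt[bad], bad), call. = FALSE)
  }
  # POSIXct doubles carry ~0.2 us jitter at epoch scale; snap to 1 us
  round(as.numeric(ts) - as.numeric(ts[1L]), 6)
}

#' Read a noseband pressure CSV
#'
#' Reads the annotation record format: one row per 50 Hz sample with columns
#' \code{time} (numeric seconds or ISO-8601 with milliseconds),
#' \code{pressure} (grams) and \code{label}. Column matching and label
#' matching are case-insensitive. Timestamps must form a uniform grid; the
#' sampling rate is inferred from the median step unless given.
#'
#' @param path CSV file path.
#' @param sampling_rate expected sampling rate in Hz, or \code{NULL} to infer.
#' @param animal_id identifier for the series; defaults to the file name.
#' @return A \code{\link{pressure_series}}.
#' @export
read_pressure_csv <- function(path, sampling_rate = NULL, animal_id = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (is.null(animal_id))
    animal_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  nm <- tolower(trimws(names(df)))
  need <- c("time", "pressure", "label")
  miss <- setdiff(need, nm)
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  names(df) <- nm
  if (nrow(df) == 0L)
    return(pressure_series(numeric(0),
                           sampling_rate = if (is.null(sampling_rate)) 50
                                           else sampling_rate,
                           labels = character(0), animal_id = animal_id))

  suppressWarnings(p <- as.numeric(df$pressure))
  if (anyNA(p)) {
    bad <- which(is.na(p))[1L]
    stop(sprintf("non-numeric pressure value '%s' at data line %d of %s",
                 df$pressure[bad], bad, path), call. = FALSE)
  }
  tt <- parse_time_column(df$time)
  tt <- tt - tt[1L]
  if (length(tt) > 1L) {
    steps <- diff(tt)
    step <- stats::median(steps)
    if (step <= 0 || any(abs(steps - step) > step * 1e-3 + 1e-9)) {
      bad <- which(abs(steps - step) > step * 1e-3 + 1e-9)[1L] + 1L
      stop(sprintf("non-uniform timestamps in %s near data line %d (expected step %.6g s)",
                   path, bad, step), call. = FALSE)
    }
    fs <- 1 / step
  } else {
    fs <- if (is.null(sampling_rate)) 50 else sampling_rate
  }
  if (!is.null(sampling_rate)) {
    if (abs(fs - sampling_rate) > sampling_rate * 1e-3)
      stop(sprintf("timestamps of %s imply %.3f Hz, expected %g Hz",
                   path, fs, sampling_rate), call. = FALSE)
    fs <- sampling_rate
  } else {
    fs <- round(fs, 6)
  }
  labels <- tryCatch(normalize_labels(df$label), error = function(e) {
    stop(conditionMessage(e), " in ", path, call. = FALSE)
  })
  pressure_series(p, sampling_rate = fs, labels = labels,
                  animal_id = animal_id)
}

#' Write a pressure series to CSV
#'
#' One row per sample with header \code{time,pressure,label}; time and
#' pressure are printed with 3 decimal places (the sensor's 0.001 g
#' resolution), so output is byte-stable and diffable. Series whose pressure
#' values are representable at 3 decimals round-trip exactly through
#' \code{\link{read_pressure_csv}}.
#'
#' @param series a \code{\link{pressure_series}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pressure_csv <- function(series, path) {
  stopifnot(inherits(series, "pressure_series"))
  lab <- if (is.null(series$label))
    rep("", length(series$pressure)) else as.character(series$label)
  lines <- c("time,pressure,label",
             sprintf("%.3f,%.3f,%s", series$time, series$pressure, lab))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Segment a labeled series into fixed-duration single-label windows
#'
#' Cuts the series into non-overlapping, contiguous windows of
#' \code{window_seconds}, aligned to the series start. Windows whose samples
#' do not all carry the same label are discarded (a window is the unit of
#' classification and carries exactly one label), as is any trailing partial
#' window. No sample appears in two windows.
#'
#' @param series a labeled \code{\link{pressure_series}}.
#' @param window_seconds window duration in seconds (study sizes: 5, 10, 15,
#'   20, 30; default 10).
#' @return List of \code{\link{window_sample}} objects (possibly empty).
#' @export
segment_windows <- function(series, window_seconds = 10) {
  stopifnot(inherits(series, "pressure_series"))
  if (!is.numeric(window_seconds) || window_seconds <= 0)
    stop("window_seconds must be > 0", call. = FALSE)
  if (is.null(series$label))
    stop("series must be labeled to segment into classification windows",
         call. = FALSE)
  wlen <- round(window_seconds * series$sampling_rate)
  n <- length(series$pressure)
  n_win <- n %/% wlen
  if (n_win == 0L) return(list())
  out <- vector("list", n_win)
  keep <- logical(n_win)
  for (i in seq_len(n_win)) {
    idx <- ((i - 1L) * wlen + 1L):(i * wlen)
    labs <- series$label[idx]
    if (length(unique(labs)) == 1L) {
      keep[i] <- TRUE
      out[[i]] <- window_sample(series$pressure[idx], labs[1L],
                                animal_id = series$animal_id,
                                start_time = series$time[idx[1L]],
                                sampling_rate = series$sampling_rate)
    }
  }
  out[keep]
}

#' Segment several series at once
#'
#' Windows never span animals or files: each series is segmented
#' independently with \code{\link{segment_windows}} and the results
#' concatenated.
#'
#' @param series_list list of labeled \code{\link{pressure_series}}.
#' @param window_seconds window duration, seconds.
#' @return Flat list of \code{\link{window_sample}} objects.
#' @export
segment_windows_multi <- function(series_list, window_seconds = 10) {
  do.call(c, lapply(series_list, segment_windows,
                    window_seconds = window_seconds))
}
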