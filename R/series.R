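#' Behavior label vocabulary
#'
#' The three-class ethogram used throughout the package: \code{RUMINATION}
#' (regurgitation and remastication with a steady chew rhythm), \code{EATING}
#' (prehension and chewing of fresh feed, faster and more irregular), and
#' \code{OTHER} (all remaining behaviors).
#'
#' @return Character vector of the three canonical label strings.
#' @export
behavior_labels <- function() c("RUMINATION", "EATING", "OTHER")

#' Normalize behavior label strings
#'
#' Maps free-form label strings case-insensitively onto the canonical
#' three-value vocabulary. Common synonyms from annotation files
#' ("ruminating", "eating", "other") are accepted.
#'
#' @param x character vector of labels.
#' @return factor with levels \code{behavior_labels()}.
#' @keywords internal
normalize_labels <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  out[key %in% c("RUMINATION", "RUMINATING", "RUMINATE")] <- "RUMINATION"
  out[key %in% c("EATING", "EAT", "GRAZING_EATING")] <- "EATING"
  out[key %in% c("OTHER", "OTHERS")] <- "OTHER"
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("unknown behavior label '%s' (entry %d); expected one of %s",
                 x[bad], bad, paste(behavior_labels(), collapse = ", ")),
         call. = FALSE)
  }
  factor(out, levels = behavior_labels())
}

#' Construct a pressure series
#'
#' A \code{pressure_series} is a uniformly sampled single-channel noseband
#' pressure trace in grams, with optional per-sample behavior labels. The
#' sensor's physical range is 0--2000 g.
#'
#' @param pressure numeric vector of pressure values in grams.
#' @param sampling_rate sampling frequency in Hz (default 50).
#' @param labels optional vector of behavior labels, one per sample.
#' @param animal_id identifier of the animal/recording.
#' @param start_time time of the first sample in seconds (default 0).
#' @return An object of class \code{pressure_series}: a list with elements
#'   \code{time}, \code{pressure}, \code{label}, \code{animal_id},
#'   \code{sampling_rate}.
#' @export
pressure_series <- function(pressure, sampling_rate = 50, labels = NULL,
                            animal_id = "animal", start_time = 0) {
  pressure <- as.numeric(pressure)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number", call. = FALSE)
  if (any(!is.finite(pressure)))
    stop("pressure values must be finite", call. = FALSE)
  if (any(pressure < 0 | pressure > 2000))
    stop("pressure values must lie within the sensor range [0, 2000] g",
         call. = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != length(pressure))
      stop("labels must have one entry per pressure sample", call. = FALSE)
    labels <- normalize_labels(labels)
  }
  structure(
    list(
      time = start_time + (seq_along(pressure) - 1) / sampling_rate,
      pressure = pressure,
      label = labels,
      animal_id = as.character(animal_id),
      sampling_rate = sampling_rate
    ),
    class = "pressure_series"
  )
}

#' @export
length.pressure_series <- function(x) length(x$pressure)

#' @export
print.pressure_series <- function(x, ...) {
  n <- length(x$pressure)
  dur <- n / x$sampling_rate
  cat(sprintf("<pressure_series> animal '%s': %d samples @ %g Hz (%.1f s)\n",
              x$animal_id, n, x$sampling_rate, dur))
  if (n == 0L) return(invisible(x))
  cat(sprintf("  pressure: %.3f .. %.3f g (mean %.3f)\n",
              min(x$pressure), max(x$pressure), mean(x$pressure)))
  if (!is.null(x$label)) {
    tb <- table(x$label)
    cat("  labels:  ", paste(sprintf("%s=%d", names(tb), tb), collapse = "  "),
        "\n")
  } else {
    cat("  labels:   <none>\n")
  }
  invisible(x)
}

#' Construct a window sample
#'
#' A \code{window_sample} is a fixed-duration, single-label signal segment:
#' the unit of classification.
#'
#' @param values numeric vector of pressure values (grams).
#' @param label a single behavior label.
#' @param animal_id animal identifier.
#' @param start_time start of the window in seconds since series start.
#' @param sampling_rate sampling frequency in Hz.
#' @return An object of class \code{window_sample}.
#' @export
window_sample <- function(values, label, animal_id = "animal",
                          start_time = 0, sampling_rate = 50) {
  label <- normalize_labels(label)
  if (length(label) != 1L)
    stop("a window carries exactly one label", call. = FALSE)
  structure(
    list(values = as.numeric(values), label = label,
         animal_id = as.character(animal_id),
         start_time = start_time, sampling_rate = sampling_rate),
    class = "window_sample"
  )
}

#' @export
print.window_sample <- function(x, ...) {
  cat(sprintf("<window_sample> %s, %d samples @ %g Hz, animal '%s', t0=%.2f s\n",
              as.character(x$label), length(x$values), x$sampling_rate,
              x$animal_id, x$start_time))
  invisible(x)
}
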