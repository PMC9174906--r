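# Synthetic jaw-pressure simulator.
#
# Emulates the statistical structure a noseband pressure recording is assumed
# to have: a constant per-wearing initial pressure offset, quasi-periodic chew
# bursts during rumination (slow, regular) and eating (faster, irregular),
# low-amplitude aperiodic activity during "other" behavior, Gaussian baseline
# noise, and sparse mechanical-noise impulses.

#' Build a simulation configuration
#'
#' All parameters of one simulated animal-day. Defaults encode the study
#' conditions the pipeline assumes: 50 Hz sampling, rumination chews in
#' 0.6--0.9 Hz with small period jitter (the regular behavior), eating chews
#' in 1.0--1.5 Hz with larger jitter, chew amplitudes of 150--350 g on top of
#' a constant strap-on offset, 5 g baseline noise, and 2 mechanical spikes
#' per minute of 100--300 g over 1--3 samples.
#'
#' @param sampling_rate sampling frequency, Hz.
#' @param initial_offset constant strap-on pressure in grams; stable for the
#'   whole wearing.
#' @param behavior_bouts data.frame with columns \code{label} and
#'   \code{duration} (seconds), in temporal order.
#' @param chew_freq_rumination,chew_freq_eating length-2 numeric: chew
#'   frequency range (Hz) sampled per bout.
#' @param freq_jitter_rumination,freq_jitter_eating relative SD of per-chew
#'   period jitter; rumination must be the more regular (smaller) one.
#' @param chew_amplitude length-2 numeric: per-chew peak amplitude range, grams.
#' @param active_rumination,pause_rumination length-2 numeric ranges
#'   (seconds): rumination proceeds in bolus cycles, chewing for
#'   \code{active_rumination} then pausing (swallowing/regurgitation) for
#'   \code{pause_rumination}.
#' @param active_eating,pause_eating length-2 numeric ranges (seconds):
#'   eating alternates chewing bursts with prehension pauses (gathering
#'   feed).
#' @param baseline_noise_sd Gaussian sensor noise SD, grams.
#' @param spike_rate mechanical-noise impulses per minute.
#' @param spike_amplitude length-2 numeric: impulse magnitude range, grams.
#' @param other_noise_sd broadband activity SD during OTHER bouts, grams.
#' @param other_bump_rate isolated pressure bumps per minute during OTHER
#'   bouts (head movement, grass pulls).
#' @param other_bump_amplitude length-2 numeric: bump peak range, grams.
#' @param waveform chew pulse shape: \code{"pulse"} (rectified half-sine per
#'   chew period; pressure rises on each jaw closure) or \code{"sine"}
#'   (zero-mean sinusoid, useful for spectral calibration).
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   output.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(sampling_rate = 50,
                              initial_offset = 200,
                              behavior_bouts = data.frame(
                                label = c("RUMINATION", "EATING", "OTHER"),
                                duration = c(120, 120, 120)),
                              chew_freq_rumination = c(0.6, 0.9),
                              chew_freq_eating = c(1.0, 1.5),
                              freq_jitter_rumination = 0.03,
                              freq_jitter_eating = 0.15,
                              chew_amplitude = c(150, 350),
                              active_rumination = c(35, 60),
                              pause_rumination = c(3, 6),
                              active_eating = c(5, 20),
                              pause_eating = c(1, 4),
                              baseline_noise_sd = 5,
                              spike_rate = 2,
                              spike_amplitude = c(100, 300),
                              other_noise_sd = 8,
                              other_bump_rate = 6,
                              other_bump_amplitude = c(20, 80),
                              waveform = c("pulse", "sine"),
                              seed = 1L) {
  waveform <- match.arg(waveform)
  cfg <- structure(
    list(sampling_rate = sampling_rate, initial_offset = initial_offset,
         behavior_bouts = behavior_bouts,
         chew_freq_rumination = sort(chew_freq_rumination),
         chew_freq_eating = sort(chew_freq_eating),
         freq_jitter_rumination = freq_jitter_rumination,
         freq_jitter_eating = freq_jitter_eating,
         chew_amplitude = sort(chew_amplitude),
         active_rumination = sort(active_rumination),
         pause_rumination = sort(pause_rumination),
         active_eating = sort(active_eating),
         pause_eating = sort(pause_eating),
         baseline_noise_sd = baseline_noise_sd,
         spike_rate = spike_rate, spike_amplitude = sort(spike_amplitude),
         other_noise_sd = other_noise_sd, other_bump_rate = other_bump_rate,
         other_bump_amplitude = sort(other_bump_amplitude),
         waveform = waveform, seed = as.integer(seed)),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  fail <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (!is.numeric(cfg$sampling_rate) || cfg$sampling_rate <= 0)
    fail("sampling_rate must be > 0")
  b <- cfg$behavior_bouts
  if (!is.data.frame(b) || nrow(b) == 0L ||
      !all(c("label", "duration") %in% names(b)))
    fail("behavior_bouts must be a non-empty data.frame with columns label, duration")
  if (any(!is.finite(b$duration)) || any(b$duration <= 0))
    fail("all bout durations must be > 0")
  normalize_labels(b$label)  # errors on unknown labels
  nyq <- cfg$sampling_rate / 2
  for (nm in c("chew_freq_rumination", "chew_freq_eating")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(r <= 0) || any(r >= nyq))
      fail(sprintf("%s must lie within (0, %g) Hz", nm, nyq))
  }
  if (cfg$initial_offset < 0)
    fail("initial_offset must be >= 0")
  if (cfg$initial_offset + max(cfg$chew_amplitude) +
      max(cfg$spike_amplitude) > 2000)
    fail("initial_offset plus maximum amplitudes exceeds the 2000 g sensor range")
  if (cfg$freq_jitter_rumination >= cfg$freq_jitter_eating)
    fail("freq_jitter_rumination must be < freq_jitter_eating (rumination is the regular behavior)")
  if (cfg$baseline_noise_sd < 0 || cfg$spike_rate < 0)
    fail("noise parameters must be nonnegative")
  for (nm in c("active_rumination", "pause_rumination", "active_eating",
               "pause_eating")) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(r < 0))
      fail(sprintf("%s must be a nonnegative range", nm))
  }
  if (min(cfg$active_rumination) <= 0 || min(cfg$active_eating) <= 0)
    fail("active chewing durations must be > 0")
  invisible(cfg)
}

# Evaluate code under a temporary RNG state so simulation does not disturb
# (and is not disturbed by) the caller's random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Alternating active/pause mask of n samples: chewing proceeds in segments
# of U(active) seconds separated by U(pause) second gaps (bolus cycles in
# rumination, prehension pauses in eating). A zero-width pause range
# disables the structure.
activity_mask <- function(n, fs, active, pause) {
  if (max(pause) <= 0) return(rep(TRUE, n))
  mask <- logical(0)
  while (length(mask) < n) {
    a <- round(stats::runif(1, active[1], active[2]) * fs)
    p <- round(stats::runif(1, pause[1], pause[2]) * fs)
    mask <- c(mask, rep(TRUE, a), rep(FALSE, p))
  }
  mask[seq_len(n)]
}

# One chew train of the given duration: successive chews with jittered periods
# and per-chew amplitude; returns a vector of n samples (zero baseline).
chew_train <- function(n, fs, freq_range, rel_jitter, amp_range, waveform,
                       active = c(1, 1), pause = c(0, 0)) {
  f0 <- stats::runif(1, freq_range[1], freq_range[2])
  base_period <- 1 / f0
  # draw enough chew periods to cover the bout
  n_chews <- ceiling(n / fs / base_period * 1.6) + 4L
  periods <- base_period * pmax(0.3, 1 + stats::rnorm(n_chews, 0, rel_jitter))
  amps <- stats::runif(n_chews, amp_range[1], amp_range[2])
  starts <- c(0, cumsum(periods))
  t <- (seq_len(n) - 1) / fs
  idx <- findInterval(t, starts)            # which chew each sample is in
  phase <- (t - starts[idx]) / periods[idx] # in [0, 1)
  x <- if (waveform == "pulse") {
    amps[idx] * sin(pi * phase)             # rectified half-sine per period
  } else {
    amps[idx] * sin(2 * pi * phase)         # zero-mean sinusoid
  }
  x * activity_mask(n, fs, active, pause)
}

# Aperiodic "other" activity: broadband noise plus rare isolated bumps.
other_activity <- function(n, fs, noise_sd, bump_rate, bump_amp) {
  x <- stats::rnorm(n, 0, noise_sd)
  n_bumps <- stats::rpois(1, bump_rate * n / fs / 60)
  if (n_bumps > 0) {
    for (k in seq_len(n_bumps)) {
      width <- round(stats::runif(1, 0.3, 0.8) * fs)
      pos <- sample.int(max(1L, n - width), 1L)
      amp <- stats::runif(1, bump_amp[1], bump_amp[2])
      seg <- pos:min(n, pos + width - 1L)
      x[seg] <- x[seg] + amp * sin(pi * seq_along(seg) / length(seg))
    }
  }
  x
}

#' Simulate a labeled noseband pressure series
#'
#' Generates \code{sampling_rate * sum(durations)} samples. Each sample is
#' \code{initial_offset + behavior waveform + baseline noise (+ spikes)},
#' clipped to the 0--2000 g sensor range, and labeled with its bout's
#' behavior. All randomness is drawn from \code{config$seed}, so identical
#' (config, seed) pairs give bit-identical series, and configs differing only
#' in \code{initial_offset} differ sample-wise by exactly the offset
#' difference (before clipping).
#'
#' @param config a \code{\link{simulation_config}}.
#' @param animal_id identifier attached to the series.
#' @return A \code{\link{pressure_series}} with per-sample labels.
#' @export
simulate_series <- function(config, animal_id = "sim") {
  validate_simulation_config(config)
  fs <- config$sampling_rate
  bouts <- config$behavior_bouts
  bouts$label <- as.character(normalize_labels(bouts$label))
  n_per_bout <- round(bouts$duration * fs)

  with_seed(config$seed, {
    parts <- vector("list", nrow(bouts))
    for (i in seq_len(nrow(bouts))) {
      n <- n_per_bout[i]
      parts[[i]] <- switch(
        bouts$label[i],
        RUMINATION = chew_train(n, fs, config$chew_freq_rumination,
                                config$freq_jitter_rumination,
                                config$chew_amplitude, config$waveform,
                                config$active_rumination,
                                config$pause_rumination),
        EATING = chew_train(n, fs, config$chew_freq_eating,
                            config$freq_jitter_eating,
                            config$chew_amplitude, config$waveform,
                            config$active_eating, config$pause_eating),
        OTHER = other_activity(n, fs, config$other_noise_sd,
                               config$other_bump_rate,
                               config$other_bump_amplitude))
    }
    x <- unlist(parts, use.names = FALSE)
    ntot <- length(x)
    if (config$baseline_noise_sd > 0)
      x <- x + stats::rnorm(ntot, 0, config$baseline_noise_sd)
    if (config$spike_rate > 0) {
      n_spikes <- stats::rpois(1, config$spike_rate * ntot / fs / 60)
      if (n_spikes > 0) {
        pos <- sample.int(ntot, n_spikes)
        for (p in pos) {
          width <- sample.int(3L, 1L)
          amp <- stats::runif(1, config$spike_amplitude[1],
                              config$spike_amplitude[2]) *
            sample(c(-1, 1), 1)
          seg <- p:min(ntot, p + width - 1L)
          x[seg] <- x[seg] + amp
        }
      }
    }
    pressure <- pmin(2000, pmax(0, config$initial_offset + x))
    labels <- rep(bouts$label, times = n_per_bout)
    pressure_series(pressure, sampling_rate = fs, labels = labels,
                    animal_id = animal_id)
  })
}

#' Simulate a herd of animals
#'
#' Each animal receives an independent constant strap-on offset drawn
#' uniformly from \code{offset_range} and its own random bout realization.
#' Per-animal seeds are derived deterministically from \code{seed}
#' (\code{seed + 10007 * animal index}), so a fixed seed reproduces the herd.
#'
#' @param n_animals number of animals (>= 1).
#' @param config base \code{\link{simulation_config}} shared by all animals;
#'   its \code{initial_offset} and \code{seed} are overridden per animal.
#' @param offset_range length-2 numeric: range (grams) the per-animal offsets
#'   are drawn from.
#' @param overrides optional list (one element per animal) of named config
#'   fields to override for that animal, e.g. distinct bout schedules.
#' @param seed integer master seed.
#' @return List of \code{\link{pressure_series}}, one per animal, named
#'   \code{animal_1 ... animal_n}.
#' @export
simulate_herd <- function(n_animals, config = simulation_config(),
                          offset_range = c(30, 400), overrides = NULL,
                          seed = 1L) {
  if (!is.numeric(n_animals) || n_animals < 1)
    stop("n_animals must be >= 1", call. = FALSE)
  n_animals <- as.integer(n_animals)
  offsets <- with_seed(seed,
                       stats::runif(n_animals, offset_range[1], offset_range[2]))
  out <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    cfg <- config
    cfg$initial_offset <- offsets[i]
    cfg$seed <- as.integer((seed + 10007 * i) %% .Machine$integer.max)
    if (!is.null(overrides) && length(overrides) >= i &&
        !is.null(overrides[[i]]))
      cfg[names(overrides[[i]])] <- overrides[[i]]
    validate_simulation_config(cfg)
    out[[i]] <- simulate_series(cfg, animal_id = paste0("animal_", i))
  }
  names(out) <- paste0("animal_", seq_len(n_animals))
  out
}
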