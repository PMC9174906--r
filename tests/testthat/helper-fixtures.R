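# Shared fixtures, generated in code at test time.

# One bout of each behavior per wearing; several wearings emulate the daily
# re-strapping that gives every series its own offset.
test_bouts <- function(duration = 60) {
  data.frame(label = c("RUMINATION", "EATING", "OTHER"),
             duration = rep(duration, 3))
}

test_config <- function(duration = 60, ...) {
  simulation_config(behavior_bouts = test_bouts(duration), ...)
}

# Small deterministic herd for harness tests: n_wearings series, each with an
# independent offset.
test_herd <- function(n_wearings = 6, duration = 60, seed = 42) {
  simulate_herd(n_wearings, test_config(duration), seed = seed)
}

# The end-to-end herd: 3 animals x 5 daily wearings, one 120 s bout per
# behavior per wearing (180 pure 10 s windows per class herd-wide), noise and
# mechanical spikes at their defaults. Cached per session because several
# tests share it.
end_to_end_herd <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_herd(15, test_config(120), seed = 7)
    cache
  }
})
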