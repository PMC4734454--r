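# Shared fixtures: tiny and scaled runs, memoised per test session so
# several test files can reuse the same simulations.

run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, fn) {
  if (is.null(run_cache[[key]])) run_cache[[key]] <- fn()
  run_cache[[key]]
}

# a very short run with full event logging (minutes, not months)
tiny_run <- function(seed = 42, lhw = 720, lps = 0.5, ...) {
  p <- preset_params("smoke", lhw = lhw, lps = lps, ...)
  p$record_minutes <- 1440
  p$stab_minutes <- 120
  emo_run(p, seed = seed, log_events = TRUE)
}

# one-week scaled run (the "smoke" tier)
smoke_run <- function(seed, lhw = 720, lps = 0.5, ...) {
  p <- preset_params("smoke", lhw = lhw, lps = lps, ...)
  emo_run(p, seed = seed)
}

# two-month scaled run (the "desk" tier)
desk_run <- function(seed, lhw = 720, lps = 0.5, ...) {
  p <- preset_params("desk", lhw = lhw, lps = lps, ...)
  emo_run(p, seed = seed)
}
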