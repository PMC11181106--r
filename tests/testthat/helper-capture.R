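# Shared fixtures for the capture tests. All fixtures are built in code at
# test time; pipeline outputs that several test files need are computed
# once and cached for the session.

# Restore global settings (and any dangling session) when the calling
# test finishes.
local_clean_capture <- function(env = parent.frame()) {
  old <- provtrace_settings()
  withr::defer({
    if (session_active()) deactivate()
    assign("settings", old, envir = provtrace:::.provtrace)
  }, envir = env)
}

# Deterministic identifier / clock sources: uuid-shaped counters and a
# fixed clock advancing one second per call.
deterministic_sources <- function() {
  id_n <- 0L
  clock_n <- 0L
  list(
    id_source = function() {
      id_n <<- id_n + 1L
      sprintf("00000000-0000-4000-8000-%012d", id_n)
    },
    clock = function() {
      clock_n <<- clock_n + 1L
      as.POSIXct("2024-06-07 12:00:00", tz = "UTC") + clock_n
    })
}

use_deterministic_sources <- function(env = parent.frame()) {
  local_clean_capture(env)
  src <- deterministic_sources()
  provtrace_settings(id_source = src$id_source, clock = src$clock)
}

new_test_script <- function(lines = "x <- 1") {
  path <- tempfile(fileext = ".R")
  writeLines(lines, path)
  path
}

# Run `fn(tracked_function_list)` inside a fresh session and return the
# finished session.
with_session <- function(fn, script_lines = "x <- 1") {
  activate(new_test_script(script_lines))
  on.exit(if (session_active()) deactivate(), add = TRUE)
  fn()
  deactivate()
}

# --- cached pipeline fixtures ----------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

# Scaled-down demo run: 6 channels (2 excluded), 2 trials per type, the
# timing-critical parameters (30 kHz, 500 ms epochs, factor-60
# downsampling, 2 Hz Welch resolution) at study scale.
demo_fixture <- function() {
  if (is.null(.fixture_cache$demo)) {
    cfg <- demo_config(channels = 6L, trials_per_type = 2L,
                       exclude_channels = c("chan 2", "chan 4"))
    rec <- generate_recording(cfg, seed = 42L, subject = "subject_N")
    res <- run_demo_pipeline(rec, cfg,
                             output_dir = tempfile("demo_fixture"))
    res$config <- cfg
    .fixture_cache$demo <- res
  }
  .fixture_cache$demo
}

split_fixture <- function(mode) {
  key <- paste0("split_", mode)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- demo_config(channels = 4L, trials_per_type = 1L,
                       exclude_channels = "chan 2")
    recs <- list(generate_recording(cfg, seed = 1L, subject = "subject_N"),
                 generate_recording(cfg, seed = 2L, subject = "subject_L"))
    .fixture_cache[[key]] <-
      run_split_pipeline(recs, mode, cfg,
                         output_dir = tempfile(paste0("split_", mode)))
  }
  .fixture_cache[[key]]
}

# Minimal one-record session: welch_psd-style call, one object input, one
# multi-array output.
single_record_session <- function() {
  with_session(function() {
    wl <- track(welch_psd, inputs = "sig", name = "welch_psd")
    sig <- analog_signal(matrix(sin(seq_len(500) / 5), ncol = 2),
                         sampling_rate = 100)
    wl(sig, frequency_resolution = 2)
  })
}
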