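# End-to-end demo: a synthetic analogue of a multichannel LFP spectral
# analysis, run under provenance capture. Defaults reproduce the study
# conditions of the reach-to-grasp-style recording: 96 channels sampled at
# 30 kHz, four trial types (side/precision grip x low/high force), 500 ms
# epochs after the CUE-OFF event, 250 Hz low-pass, factor-60 downsampling,
# and a Welch PSD at 2 Hz resolution with a Hanning window and 50% overlap.

#' Demo pipeline configuration
#'
#' @param ... overrides for any of the defaults (see Details).
#' @details Recording: `channels` (96), `sampling_rate` (30000 Hz),
#' `trials_per_type` (4), `trial_spacing` (1.25 s), `lead_in`
#' (0.5 s), `signal_frequency` (20 Hz ground-truth sinusoid),
#' `signal_amplitude` (10), `noise_sd` (2). Analysis:
#' `epoch_pre` (0 s), `epoch_post` (0.5 s), `exclude_channels`
#' ("chan 2", "chan 4"), `lowpass_frequency` (250 Hz),
#' `filter_order` (4), `downsample_factor` (60),
#' `frequency_resolution` (2 Hz), `window` ("hanning"),
#' `overlap` (0.5).
#' @return named list of configuration values.
#' @export
demo_config <- function(...) {
  cfg <- list(
    channels = 96L,
    sampling_rate = 30000,
    trials_per_type = 4L,
    trial_spacing = 1.25,
    lead_in = 0.5,
    signal_frequency = 20,
    signal_amplitude = 10,
    noise_sd = 2,
    epoch_pre = 0,
    epoch_post = 0.5,
    exclude_channels = c("chan 2", "chan 4"),
    lowpass_frequency = 250,
    filter_order = 4L,
    downsample_factor = 60L,
    frequency_resolution = 2,
    window = "hanning",
    overlap = 0.5)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  modifyList(cfg, overrides)
}

#' Read a demo configuration from a key-value file
#'
#' Plain `key = value` lines (or `key: value`); values are parsed
#' as numbers where possible, comma-separated lists become vectors.
#'
#' @param path configuration file.
#' @return configuration list as from [demo_config()].
#' @export
read_demo_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$",
                                ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln,
                              call. = FALSE)
    vals <- trimws(strsplit(m[[3L]], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[m[[2L]]]] <- if (!anyNA(num)) num else vals
  }
  do.call(demo_config, out)
}

#' Generate a synthetic multichannel recording
#'
#' Builds a block with one segment holding a channels x time analog
#' signal (a known-frequency sinusoid, common to all channels, plus
#' Gaussian noise -- so the PSD stage has a predictable spectral peak) and
#' a CUE-OFF event series cycling through the four trial types, each
#' marked as a correct trial.
#'
#' @param config from [demo_config()].
#' @param seed RNG seed; fixed seed, identical recording.
#' @param subject subject name annotation.
#' @return a [block()].
#' @export
generate_recording <- function(config = demo_config(), seed = NULL,
                               subject = "subject_N") {
  if (config$channels <= 0 || config$trials_per_type <= 0 ||
      config$sampling_rate <= 0) {
    stop("channels, sampling_rate and trials_per_type must be positive",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_trials <- 4L * as.integer(config$trials_per_type)
  event_times <- config$lead_in + (seq_len(n_trials) - 1L) *
    config$trial_spacing
  trial_types <- rep(TRIAL_TYPES, length.out = n_trials)
  duration <- max(event_times) + config$epoch_post + 0.25
  n_samples <- ceiling(duration * config$sampling_rate)
  t <- (seq_len(n_samples) - 1L) / config$sampling_rate
  base <- config$signal_amplitude * sin(2 * pi * config$signal_frequency * t)
  dat <- matrix(stats::rnorm(n_samples * config$channels,
                             sd = config$noise_sd),
                nrow = n_samples, ncol = config$channels)
  dat <- dat + base
  sig <- analog_signal(dat, sampling_rate = config$sampling_rate,
                       t_start = 0,
                       annotations = list(subject_name = subject))
  evt <- event_series(
    event_times,
    labels = rep("CUE-OFF", n_trials),
    array_annotations = list(
      belongs_to_trialtype = trial_types,
      performance_in_trial_str = rep("correct_trial", n_trials)),
    annotations = list(subject_name = subject))
  block(segments = list(segment(analogsignals = list(sig),
                                events = list(evt),
                                t_start = 0, t_stop = duration)),
        annotations = list(subject_name = subject))
}

# Wrap every stage once per session run.
demo_tracked_functions <- function() {
  list(
    load_recording = track(load_recording, file_inputs = "path",
                           name = "load_recording"),
    get_events = track(get_events, inputs = "seg", name = "get_events"),
    add_epoch = track(add_epoch, inputs = c("seg", "evt"),
                      name = "add_epoch"),
    cut_segment_by_epoch = track(cut_segment_by_epoch,
                                 inputs = c("seg", "epo"),
                                 name = "cut_segment_by_epoch"),
    select_channels = track(select_channels, inputs = "sig",
                            name = "select_channels"),
    butter_filter = track(butter_filter, inputs = "sig",
                          name = "butter_filter"),
    downsample_signal = track(downsample_signal, inputs = "sig",
                              name = "downsample_signal"),
    welch_psd = track(welch_psd, inputs = "sig", name = "welch_psd"),
    average_channels = track(average_channels, inputs = "psd",
                             name = "average_channels"),
    append_trial = track(append_trial, inputs = c("acc", "trial_psd"),
                         name = "append_trial"),
    trial_statistics = track(trial_statistics, inputs = "trials",
                             name = "trial_statistics"),
    add_result = track(add_result,
                       inputs = c("bundle", "mean_psd", "sem", "freqs"),
                       name = "add_result"),
    create_figure = track(create_figure, name = "create_figure"),
    plot_lfp_psd = track(plot_lfp_psd,
                         inputs = c("fig", "freqs", "mean_psd", "sem"),
                         name = "plot_lfp_psd"),
    save_plot = track(save_plot, inputs = "fig", file_outputs = "path",
                      name = "save_plot"),
    save_intermediate = track(save_intermediate, inputs = "obj",
                              file_outputs = "path",
                              name = "save_intermediate"),
    load_intermediate = track(load_intermediate, file_inputs = "path",
                              name = "load_intermediate"))
}

# One subject: load the data file and compute per-trial-type PSD
# statistics, accumulating them in a ResultBundle.
demo_compute_subject <- function(tf, data_path, config) {
  blk <- tf$load_recording(data_path)
  bundle <- new_result_bundle()
  for (tt in TRIAL_TYPES) {
    evt <- tf$get_events(blk$segments[[1]],
                         properties = list(
                           trial_event_labels = "CUE-OFF",
                           performance_in_trial_str = "correct_trial",
                           belongs_to_trialtype = tt))
    epo <- tf$add_epoch(blk$segments[[1]], evt,
                        pre = config$epoch_pre, post = config$epoch_post)
    trial_segs <- tf$cut_segment_by_epoch(blk$segments[[1]], epo,
                                          reset_time = FALSE)
    stacked <- NULL
    freqs <- NULL
    for (i in seq_along(trial_segs)) {
      sig <- tf$select_channels(trial_segs[[i]]$analogsignals[[1]],
                                exclude = config$exclude_channels)
      filt <- tf$butter_filter(sig,
                               lowpass_frequency = config$lowpass_frequency,
                               order = config$filter_order)
      ds <- tf$downsample_signal(filt, factor = config$downsample_factor)
      wp <- tf$welch_psd(ds,
                         frequency_resolution = config$frequency_resolution,
                         window = config$window, overlap = config$overlap)
      freqs <- wp[[1]]
      avg <- tf$average_channels(wp[[2]])
      stacked <- if (is.null(stacked)) avg else
        tf$append_trial(stacked, avg)
    }
    stats <- tf$trial_statistics(stacked)
    subject <- attr(blk, "annotations")$subject_name %||% "subject"
    bundle <- tf$add_result(bundle, stats[[1]], stats[[2]], freqs,
                            label = paste(subject, tt))
  }
  bundle
}

demo_plot_bundles <- function(tf, bundles, png_path) {
  fig <- tf$create_figure()
  for (b in bundles) {
    for (i in seq_along(b$results)) {
      fig <- tf$plot_lfp_psd(fig,
                             b$results[[i]]$freqs,
                             b$results[[i]]$mean,
                             b$results[[i]]$sem,
                             label = b$results[[i]]$label)
    }
  }
  tf$save_plot(fig, path = png_path)
  invisible(fig)
}

write_stage_script <- function(dir, name, body) {
  path <- file.path(dir, name)
  writeLines(body, path)
  path
}

write_recordings <- function(recordings, output_dir) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  paths <- character(length(recordings))
  for (i in seq_along(recordings)) {
    subject <- attr(recordings[[i]], "annotations")$subject_name %||%
      paste0("subject", i)
    paths[[i]] <- file.path(output_dir, paste0(subject, ".rds"))
    saveRDS(recordings[[i]], paths[[i]])
  }
  paths
}

#' Run the demo analysis pipeline under provenance capture
#'
#' Writes the recording(s) to data files, activates a capture session,
#' runs every analysis stage as a tracked call (the outer loop iterates
#' over subjects, the inner loop over the four trial types, cutting and
#' processing each trial), renders the PSD summary figure, and saves the
#' captured provenance as a Turtle sidecar file next to the image.
#'
#' @param recordings a [block()] or list of blocks (one per subject).
#' @param config from [demo_config()].
#' @param output_dir directory for data files, image and sidecar.
#' @param name basename for the image/sidecar pair.
#' @return list with elements `png`, `ttl`, `data_files`, and
#'   `n_records` (tracked executions).
#' @export
run_demo_pipeline <- function(recordings, config = demo_config(),
                              output_dir = tempfile("provtrace_demo"),
                              name = "demo_psd") {
  if (inherits(recordings, "Block")) recordings <- list(recordings)
  if (session_active()) {
    stop("a capture session is already active", call. = FALSE)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  data_files <- write_recordings(recordings, output_dir)
  script <- write_stage_script(
    output_dir, paste0(name, ".R"),
    c("# demo pipeline driver",
      sprintf("provtrace::run_demo_pipeline(recordings, output_dir = \"%s\")",
              output_dir)))
  activate(script)
  on.exit(if (session_active()) deactivate(), add = TRUE)
  tf <- demo_tracked_functions()
  bundles <- lapply(data_files, demo_compute_subject, tf = tf,
                    config = config)
  png_path <- file.path(output_dir, paste0(name, ".png"))
  demo_plot_bundles(tf, bundles, png_path)
  ttl_path <- file.path(output_dir, paste0(name, ".ttl"))
  save_provenance(ttl_path)
  session <- deactivate()
  list(png = png_path, ttl = ttl_path, data_files = data_files,
       n_records = session$counter)
}

#' Run the demo pipeline as a split workflow
#'
#' Emulates the distributed-capture scenarios: `"single"` runs
#' everything in one session (1 RDF file); `"two_process"` computes
#' one subject per independent session, the second session also plotting
#' the in-memory results of both (2 RDF files, as with message-passing
#' parallelization); `"two_stage"` computes each subject in its own
#' session, saving the PSD statistics to an intermediate file, and a
#' third session loads both files and plots (3 RDF files). The resulting
#' files can be concatenated with [read_provenance()]; shared
#' content/file identifiers make the merged graph connected.
#'
#' @param recordings list of two [block()] objects.
#' @param mode `"single"`, `"two_process"`, or `"two_stage"`.
#' @param config from [demo_config()].
#' @param output_dir working directory for all artifacts.
#' @return list with `rdf` (character vector of RDF file paths) and
#'   `png`.
#' @export
run_split_pipeline <- function(recordings,
                               mode = c("single", "two_process",
                                        "two_stage"),
                               config = demo_config(),
                               output_dir = tempfile("provtrace_split")) {
  mode <- match.arg(mode)
  if (inherits(recordings, "Block")) recordings <- list(recordings)
  if (session_active()) {
    stop("a capture session is already active", call. = FALSE)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  data_files <- write_recordings(recordings, output_dir)
  png_path <- file.path(output_dir, "split_psd.png")

  run_stage <- function(stage_name, fn) {
    script <- write_stage_script(output_dir, paste0(stage_name, ".R"),
                                 c(sprintf("# stage: %s", stage_name),
                                   sprintf("provtrace::run_split_pipeline(mode = \"%s\")",
                                           mode)))
    activate(script)
    on.exit(if (session_active()) deactivate(), add = TRUE)
    tf <- demo_tracked_functions()
    value <- fn(tf)
    ttl <- file.path(output_dir, paste0(stage_name, ".ttl"))
    save_provenance(ttl)
    deactivate()
    list(value = value, ttl = ttl)
  }

  if (mode == "single") {
    st <- run_stage("single_run", function(tf) {
      bundles <- lapply(data_files, demo_compute_subject, tf = tf,
                        config = config)
      demo_plot_bundles(tf, bundles, png_path)
      bundles
    })
    return(list(rdf = st$ttl, png = png_path))
  }

  if (mode == "two_process") {
    # rank 1: computes the second subject only; results stay in memory
    st1 <- run_stage("rank1", function(tf) {
      demo_compute_subject(tf, data_files[[2L]], config)
    })
    # rank 0: computes the first subject and plots both
    st0 <- run_stage("rank0", function(tf) {
      b0 <- demo_compute_subject(tf, data_files[[1L]], config)
      demo_plot_bundles(tf, list(b0, st1$value), png_path)
      b0
    })
    return(list(rdf = c(st1$ttl, st0$ttl), png = png_path))
  }

  # two_stage: per-subject compute stages write intermediate files; the
  # plot stage reads them back
  inter <- file.path(output_dir, sprintf("psd_stage%d.rds", 1:2))
  st1 <- run_stage("stage1", function(tf) {
    bundle <- demo_compute_subject(tf, data_files[[1L]], config)
    tf$save_intermediate(bundle, path = inter[[1L]])
  })
  st2 <- run_stage("stage2", function(tf) {
    bundle <- demo_compute_subject(tf, data_files[[2L]], config)
    tf$save_intermediate(bundle, path = inter[[2L]])
  })
  st3 <- run_stage("plot_stage", function(tf) {
    if (!all(file.exists(inter))) {
      stop("intermediate PSD files are missing", call. = FALSE)
    }
    b1 <- tf$load_intermediate(inter[[1L]])
    b2 <- tf$load_intermediate(inter[[2L]])
    demo_plot_bundles(tf, list(b1, b2), png_path)
  })
  list(rdf = c(st1$ttl, st2$ttl, st3$ttl), png = png_path)
}
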