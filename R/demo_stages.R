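# Analysis stages of the demo pipeline. Each is an ordinary function; the
# pipeline drivers wrap them with track() so every call becomes one
# provenance record. The chain mirrors a standard LFP spectral analysis:
# event selection -> epoch definition -> trial cutting -> channel
# exclusion -> Butterworth low-pass -> downsampling -> Welch PSD ->
# channel / trial aggregation -> plotting.

#' @rdname demo_stages
#' @export
load_recording <- function(path) readRDS(path)

#' Demo analysis stages
#'
#' `get_events` selects the timestamps of an event series whose
#' per-event annotations match every entry of `properties` (e.g. the
#' CUE-OFF events of correct trials of one trial type).
#'
#' @param seg a [segment()].
#' @param properties named list of annotation values to match.
#' @name demo_stages
#' @export
get_events <- function(seg, properties = list()) {
  evt <- seg$events[[1L]]
  ann <- attr(evt, "array_annotations")
  keep <- rep(TRUE, length(evt))
  for (nm in names(properties)) {
    vals <- ann[[nm]]
    keep <- keep & (!is.null(vals) & vals == properties[[nm]])
  }
  event_series(unclass(evt)[keep],
               labels = ann$trial_event_labels[keep],
               array_annotations = lapply(ann[setdiff(names(ann),
                                                      "trial_event_labels")],
                                          function(v) v[keep]),
               annotations = attr(evt, "annotations") %||% list())
}

#' @rdname demo_stages
#' @param evt an [event_series()] with the selected trigger times.
#' @param pre,post window relative to each trigger (s); the default cuts
#'   0--500 ms after the event.
#' @export
add_epoch <- function(seg, evt, pre = 0, post = 0.5) {
  times <- unclass(evt) + pre
  epoch(times, durations = post - pre,
        labels = attr(evt, "array_annotations")$belongs_to_trialtype)
}

#' @rdname demo_stages
#' @param epo an [epoch()] with the cutting windows.
#' @param reset_time shift each cut segment's clock to zero?
#' @return `cut_segment_by_epoch` returns a plain list of
#'   [segment()] objects, one per window (enumerated as separate outputs
#'   by the tracker).
#' @export
cut_segment_by_epoch <- function(seg, epo, reset_time = FALSE) {
  sig <- seg$analogsignals[[1L]]
  rate <- attr(sig, "sampling_rate")
  t0 <- attr(sig, "t_start")
  durations <- attr(epo, "durations")
  out <- vector("list", length(epo))
  for (i in seq_along(epo)) {
    start <- unclass(epo)[[i]]
    n <- round(durations[[i]] * rate)
    i0 <- round((start - t0) * rate) + 1L
    if (i0 < 1L || i0 + n - 1L > nrow(sig)) {
      stop("epoch window outside the recorded signal", call. = FALSE)
    }
    dat <- unclass(sig)[i0:(i0 + n - 1L), , drop = FALSE]
    attributes(dat) <- list(dim = dim(dat))
    new_t0 <- if (reset_time) 0 else start
    cut_sig <- analog_signal(
      dat, sampling_rate = rate, t_start = new_t0,
      units = attr(sig, "units"),
      channel_names = attr(sig, "array_annotations")$channel_names,
      annotations = attr(sig, "annotations"))
    out[[i]] <- segment(analogsignals = list(cut_sig),
                        t_start = new_t0, t_stop = new_t0 + n / rate,
                        annotations = attr(seg, "annotations"))
  }
  out
}

#' @rdname demo_stages
#' @param sig an [analog_signal()].
#' @param exclude channel names to drop (failed electrodes).
#' @export
select_channels <- function(sig, exclude = character()) {
  names_all <- attr(sig, "array_annotations")$channel_names
  keep <- !(names_all %in% exclude)
  dat <- unclass(sig)[, keep, drop = FALSE]
  attributes(dat) <- list(dim = dim(dat))
  analog_signal(dat, sampling_rate = attr(sig, "sampling_rate"),
                t_start = attr(sig, "t_start"), units = attr(sig, "units"),
                channel_names = names_all[keep],
                annotations = attr(sig, "annotations"))
}

#' @rdname demo_stages
#' @param lowpass_frequency low-pass cutoff (Hz).
#' @param order Butterworth filter order.
#' @export
butter_filter <- function(sig, lowpass_frequency = 250, order = 4) {
  rate <- attr(sig, "sampling_rate")
  bf <- signal::butter(order, lowpass_frequency / (rate / 2), type = "low")
  dat <- unclass(sig)
  attributes(dat) <- list(dim = dim(dat))
  for (ch in seq_len(ncol(dat))) {
    dat[, ch] <- signal::filtfilt(bf, dat[, ch])
  }
  analog_signal(dat, sampling_rate = rate, t_start = attr(sig, "t_start"),
                units = attr(sig, "units"),
                channel_names = attr(sig, "array_annotations")$channel_names,
                annotations = attr(sig, "annotations"))
}

#' @rdname demo_stages
#' @param factor integer decimation factor; the signal must already be
#'   band-limited below the new Nyquist frequency (the pipeline low-passes
#'   first).
#' @export
downsample_signal <- function(sig, factor = 60) {
  rate <- attr(sig, "sampling_rate")
  dat <- unclass(sig)
  attributes(dat) <- list(dim = dim(dat))
  idx <- seq(1L, nrow(dat), by = factor)
  dat <- dat[idx, , drop = FALSE]
  analog_signal(dat, sampling_rate = rate / factor,
                t_start = attr(sig, "t_start"), units = attr(sig, "units"),
                channel_names = attr(sig, "array_annotations")$channel_names,
                annotations = attr(sig, "annotations"))
}

hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))

#' @rdname demo_stages
#' @param frequency_resolution spectral resolution (Hz); the Welch segment
#'   length is `sampling_rate / frequency_resolution` samples.
#' @param window taper applied to each Welch segment (only
#'   `"hanning"` is provided).
#' @param overlap fractional overlap between consecutive segments.
#' @return `welch_psd` returns a plain list of two arrays: the
#'   frequency bins (Hz) and the per-channel power densities
#'   (channels x frequencies).
#' @export
welch_psd <- function(sig, frequency_resolution = 2, window = "hanning",
                      overlap = 0.5) {
  rate <- attr(sig, "sampling_rate")
  dat <- unclass(sig)
  attributes(dat) <- list(dim = dim(dat))
  nper <- round(rate / frequency_resolution)
  if (nper > nrow(dat)) nper <- nrow(dat)
  step <- max(1L, round(nper * (1 - overlap)))
  win <- switch(window, hanning = hanning_window(nper),
                stop("unsupported window: ", window, call. = FALSE))
  starts <- seq(1L, nrow(dat) - nper + 1L, by = step)
  nfreq <- nper %/% 2L + 1L
  scale <- rate * sum(win^2)
  psd <- matrix(0, nrow = ncol(dat), ncol = nfreq)
  for (ch in seq_len(ncol(dat))) {
    acc <- numeric(nfreq)
    for (s0 in starts) {
      x <- dat[s0:(s0 + nper - 1L), ch]
      x <- (x - mean(x)) * win
      spec <- abs(fft(x))^2 / scale
      half <- spec[seq_len(nfreq)]
      # one-sided density: double all bins except DC (and Nyquist when the
      # segment length is even)
      dbl <- rep(2, nfreq)
      dbl[1L] <- 1
      if (nper %% 2L == 0L) dbl[nfreq] <- 1
      acc <- acc + half * dbl
    }
    psd[ch, ] <- acc / length(starts)
  }
  freqs <- (seq_len(nfreq) - 1L) * rate / nper
  list(structure(freqs, units = "Hz"),
       structure(psd, units = paste0(attr(sig, "units"), "**2/Hz")))
}

#' @rdname demo_stages
#' @param psd channels x frequencies power array.
#' @return `average_channels` returns a 1 x frequencies matrix (the
#'   channel mean for one trial).
#' @export
average_channels <- function(psd) {
  m <- matrix(colMeans(unclass(psd)), nrow = 1L)
  structure(m, units = attr(psd, "units"))
}

#' @rdname demo_stages
#' @param acc trials x frequencies matrix accumulated so far.
#' @param trial_psd 1 x frequencies matrix for the next trial.
#' @export
append_trial <- function(acc, trial_psd) {
  units <- attr(trial_psd, "units")
  out <- rbind(if (is.null(acc)) NULL else unclass(acc),
               unclass(trial_psd))
  structure(out, units = units)
}

#' @rdname demo_stages
#' @param trials trials x frequencies matrix.
#' @return `trial_statistics` returns a plain list holding the
#'   across-trial mean and the standard error of the mean.
#' @export
trial_statistics <- function(trials) {
  m <- unclass(trials)
  attributes(m) <- list(dim = dim(m))
  mean_psd <- colMeans(m)
  sem <- if (nrow(m) > 1L) {
    apply(m, 2L, stats::sd) / sqrt(nrow(m))
  } else {
    numeric(ncol(m))   # a single trial has no across-trial spread
  }
  list(structure(mean_psd, units = attr(trials, "units")),
       structure(sem, units = attr(trials, "units")))
}

#' @rdname demo_stages
#' @return `create_figure` returns a `PSDFigure`: an
#'   environment-backed accumulator with reference semantics, so every
#'   plotting call works on (and regenerates) one and the same figure
#'   entity, as a plotting toolkit's figure object would.
#' @export
create_figure <- function() {
  fig <- new.env(parent = emptyenv())
  fig$layers <- list()
  class(fig) <- "PSDFigure"
  fig
}

#' @rdname demo_stages
#' @param fig a `PSDFigure` accumulator, updated in place and
#'   returned.
#' @param freqs frequency bins (Hz).
#' @param mean_psd,sem across-trial mean and standard error.
#' @param label legend label (subject / trial type).
#' @export
plot_lfp_psd <- function(fig, freqs, mean_psd, sem, label = "") {
  fig$layers[[length(fig$layers) + 1L]] <-
    list(freqs = as.numeric(freqs), mean = as.numeric(mean_psd),
         sem = as.numeric(sem), label = label)
  fig
}

#' @rdname demo_stages
#' @param path output image file (PNG).
#' @return `save_plot` renders the figure to `path` and returns
#'   `NULL` (its output entity in the provenance is therefore the null
#'   object, plus the file descriptor of the written image).
#' @export
save_plot <- function(fig, path) {
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  layers <- fig$layers
  if (length(layers) == 0L) {
    graphics::plot.new()
    return(invisible(NULL))
  }
  xr <- range(unlist(lapply(layers, `[[`, "freqs")))
  yr <- range(unlist(lapply(layers, function(l) {
    c(l$mean - 1.96 * l$sem, l$mean + 1.96 * l$sem)
  })), finite = TRUE)
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "Frequency (Hz)",
                 ylab = "Power density", main = "Mean PSD by trial type")
  cols <- grDevices::hcl.colors(length(layers), "Dark 3")
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    graphics::polygon(c(l$freqs, rev(l$freqs)),
                      c(l$mean - 1.96 * l$sem,
                        rev(l$mean + 1.96 * l$sem)),
                      col = grDevices::adjustcolor(cols[[i]], 0.2),
                      border = NA)
    graphics::lines(l$freqs, l$mean, col = cols[[i]])
  }
  graphics::legend("topright", legend = vapply(layers, `[[`, "", "label"),
                   col = cols, lty = 1, cex = 0.7)
  invisible(NULL)
}

#' @rdname demo_stages
#' @return `new_result_bundle` returns an empty `ResultBundle`,
#'   an environment-backed accumulator like the figure object.
#' @export
new_result_bundle <- function() {
  b <- new.env(parent = emptyenv())
  b$results <- list()
  class(b) <- "ResultBundle"
  b
}

#' @rdname demo_stages
#' @param bundle a `ResultBundle` accumulator, updated in place and
#'   returned.
#' @export
add_result <- function(bundle, mean_psd, sem, freqs, label) {
  bundle$results[[length(bundle$results) + 1L]] <-
    list(mean = mean_psd, sem = sem, freqs = freqs, label = label)
  bundle
}

#' @rdname demo_stages
#' @param obj object written to the intermediate file.
#' @export
save_intermediate <- function(obj, path) {
  saveRDS(obj, path)
  invisible(NULL)
}

#' @rdname demo_stages
#' @export
load_intermediate <- function(path) readRDS(path)
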