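# Lightweight electrophysiology container model for the demo pipeline:
# a Block holds Segments; a Segment groups an AnalogSignal (sampled
# multichannel time series) and an EventSeries (labeled timestamps).
# Metadata lives in `annotations` (whole-object) and `array_annotations`
# (one value per element / channel) attributes, which the capture layer
# records on every descriptor.

TRIAL_TYPES <- c("SGLF", "SGHF", "PGLF", "PGHF")

#' Construct a sampled multichannel signal
#'
#' @param data numeric matrix, first dimension time, second channels.
#' @param sampling_rate samples per second (Hz).
#' @param t_start recording time of the first sample (s).
#' @param units physical unit of the samples.
#' @param channel_names per-channel labels (array annotation).
#' @param annotations named list of whole-signal metadata.
#' @return an `AnalogSignal`: the data matrix with the metadata attached
#'   as attributes.
#' @export
analog_signal <- function(data, sampling_rate, t_start = 0,
                          units = "uV", channel_names = NULL,
                          annotations = list()) {
  stopifnot(is.matrix(data), sampling_rate > 0)
  if (is.null(channel_names)) {
    channel_names <- paste("chan", seq_len(ncol(data)))
  }
  structure(data,
            class = "AnalogSignal",
            sampling_rate = sampling_rate,
            t_start = t_start,
            t_stop = t_start + nrow(data) / sampling_rate,
            units = units,
            annotations = annotations,
            array_annotations = list(channel_names = channel_names))
}

#' Construct a labeled event series
#'
#' @param times event timestamps (s).
#' @param labels event label per timestamp (array annotation
#'   `trial_event_labels`).
#' @param array_annotations additional per-event annotations (e.g.
#'   `belongs_to_trialtype`, `performance_in_trial_str`).
#' @param annotations whole-object metadata.
#' @export
event_series <- function(times, labels,
                         array_annotations = list(),
                         annotations = list()) {
  stopifnot(length(labels) == length(times))
  array_annotations$trial_event_labels <- labels
  structure(as.numeric(times),
            class = "EventSeries",
            units = "s",
            annotations = annotations,
            array_annotations = array_annotations)
}

#' Construct a segment (time-windowed group of data objects)
#'
#' @param analogsignals list of [analog_signal()] objects.
#' @param events list of [event_series()] objects.
#' @param t_start,t_stop time window covered by the segment (s).
#' @param annotations named metadata list.
#' @export
segment <- function(analogsignals = list(), events = list(),
                    t_start = 0, t_stop = NULL, annotations = list()) {
  if (is.null(t_stop)) {
    t_stop <- if (length(analogsignals) > 0L) {
      attr(analogsignals[[1L]], "t_stop")
    } else 0
  }
  structure(list(analogsignals = analogsignals, events = events),
            class = "Segment",
            t_start = t_start, t_stop = t_stop,
            annotations = annotations)
}

#' Construct a block (top-level container)
#'
#' @param segments list of [segment()] objects.
#' @param annotations named metadata list (e.g. `subject_name`).
#' @export
block <- function(segments = list(), annotations = list()) {
  structure(list(segments = segments),
            class = "Block",
            annotations = annotations)
}

#' Construct an epoch (windows for cutting trials)
#'
#' @param times window start times (s).
#' @param durations window durations (s), recycled.
#' @param labels optional window labels.
#' @export
epoch <- function(times, durations, labels = NULL) {
  durations <- rep_len(durations, length(times))
  structure(as.numeric(times),
            class = "Epoch",
            units = "s",
            durations = durations,
            array_annotations =
              if (!is.null(labels)) list(labels = labels) else list())
}

demo_classes <- c("AnalogSignal", "EventSeries", "Segment", "Block",
                  "Epoch", "PSDFigure", "ResultBundle")
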