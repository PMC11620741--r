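#' Stimulus events and protocols
#'
#' A stimulus protocol is an ordered set of timed pulse events, each tagged with
#' a modality (`"auditory"`, `"tectal"` or `"antidromic"`) and a dimensionless
#' drive amplitude (1 = reference intensity). Protocols define both the drive of
#' the simulator and the anchor times of all quantification windows; trial time
#' zero is the first stimulus event.
#'
#' @param time_ms event onset in ms relative to trial start (>= 0).
#' @param modality one of `"auditory"`, `"tectal"`, `"antidromic"`.
#' @param amplitude relative drive strength (>= 0), 1 = reference intensity.
#' @return `stimulus_event()` returns a one-row data frame; `stimulus_protocol()`
#'   returns an object of class `stimulus_protocol` with elements `events`
#'   (data frame with columns `time_ms`, `modality`, `amplitude`), `label`,
#'   `train_freq_hz`, `train_duration_ms`.
#' @export
stimulus_event <- function(time_ms, modality, amplitude = 1) {
  modality <- match.arg(modality, c("auditory", "tectal", "antidromic"))
  if (!is.finite(time_ms) || time_ms < 0)
    stop("invalid protocol: event time_ms must be finite and >= 0", call. = FALSE)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("invalid protocol: amplitude must be finite and >= 0", call. = FALSE)
  data.frame(time_ms = as.numeric(time_ms), modality = modality,
             amplitude = as.numeric(amplitude), stringsAsFactors = FALSE)
}

#' @rdname stimulus_event
#' @param events data frame of events as produced by [stimulus_event()].
#' @param label condition tag, e.g. `"T60Hz_100ms"`, `"A"`, `"M"`, `"AT"`.
#' @param train_freq_hz nominal train frequency (NA for single pulses/pips).
#' @param train_duration_ms nominal train duration (NA when not applicable).
#' @export
stimulus_protocol <- function(events, label,
                              train_freq_hz = NA_real_,
                              train_duration_ms = NA_real_) {
  stopifnot(is.data.frame(events),
            all(c("time_ms", "modality", "amplitude") %in% names(events)))
  if (nrow(events) > 0) {
    if (any(events$time_ms < 0) || any(events$amplitude < 0))
      stop("invalid protocol: negative event time or amplitude", call. = FALSE)
    if (is.unsorted(events$time_ms))
      events <- events[order(events$time_ms), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(list(events = events, label = as.character(label),
                 train_freq_hz = as.numeric(train_freq_hz),
                 train_duration_ms = as.numeric(train_duration_ms)),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol '%s'> %d event(s)\n", x$label, nrow(x$events)))
  if (!is.na(x$train_freq_hz))
    cat(sprintf("  nominal train: %g Hz, %g ms\n",
                x$train_freq_hz, x$train_duration_ms))
  if (nrow(x$events) > 0) {
    show <- utils::head(x$events, 8L)
    cat(sprintf("  %7.2f ms  %-10s amp %.3g\n",
                show$time_ms, show$modality, show$amplitude), sep = "")
    if (nrow(x$events) > 8L) cat(sprintf("  ... %d more\n", nrow(x$events) - 8L))
  }
  invisible(x)
}

#' Build a tectal stimulation train
#'
#' Pulses are placed at `0, 1000/f, 2000/f, ...` up to and including
#' `duration_ms` (closed endpoint). A duration of 0 or 1 ms yields exactly one
#' pulse at t = 0, so the event count is `floor(duration_ms * freq_hz / 1000) + 1`.
#'
#' @param freq_hz pulse rate in Hz (> 0).
#' @param duration_ms train duration in ms (>= 0).
#' @param amplitude relative drive per pulse.
#' @return a [stimulus_protocol()] labelled `"T<freq>Hz_<duration>ms"`.
#' @export
build_tectal_train <- function(freq_hz, duration_ms, amplitude = 1) {
  if (!is.finite(freq_hz) || freq_hz <= 0)
    stop("invalid protocol: freq_hz must be > 0", call. = FALSE)
  if (!is.finite(duration_ms) || duration_ms < 0)
    stop("invalid protocol: duration_ms must be >= 0", call. = FALSE)
  n_pulses <- floor(duration_ms * freq_hz / 1000 + 1e-9) + 1L
  times <- (seq_len(n_pulses) - 1L) * (1000 / freq_hz)
  events <- do.call(rbind, lapply(times, stimulus_event,
                                  modality = "tectal", amplitude = amplitude))
  stimulus_protocol(events,
                    label = sprintf("T%gHz_%gms", freq_hz, duration_ms),
                    train_freq_hz = freq_hz, train_duration_ms = duration_ms)
}

#' Build a single auditory pip
#'
#' One auditory event (a single-cycle sound pip in the experiments this
#' emulates) at `t_onset_ms`.
#'
#' @param t_onset_ms onset time in ms (>= 0).
#' @param amplitude relative drive.
#' @return a [stimulus_protocol()] labelled `"A"`.
#' @export
build_auditory_pip <- function(t_onset_ms = 0, amplitude = 1) {
  if (!is.finite(t_onset_ms) || t_onset_ms < 0)
    stop("invalid protocol: t_onset_ms must be >= 0", call. = FALSE)
  stimulus_protocol(stimulus_event(t_onset_ms, "auditory", amplitude),
                    label = "A")
}

#' Combine two protocols with a temporal offset
#'
#' Events of `second` are shifted by `offset_ms` and merged with those of
#' `first`, preserving per-event modality and amplitude; the merged event list
#' is sorted by time (stable, so simultaneous events keep first-before-second
#' order). The default label is the concatenation of the two labels.
#'
#' @param first,second [stimulus_protocol()] objects.
#' @param offset_ms shift applied to `second`'s events (>= 0).
#' @param label optional label override (e.g. `"M"` for a multisensory
#'   train + pip combination).
#' @return a [stimulus_protocol()].
#' @export
combine_protocols <- function(first, second, offset_ms = 0, label = NULL) {
  stopifnot(inherits(first, "stimulus_protocol"),
            inherits(second, "stimulus_protocol"))
  if (!is.finite(offset_ms) || offset_ms < 0)
    stop("invalid protocol: offset_ms must be >= 0", call. = FALSE)
  ev2 <- second$events
  if (nrow(ev2) > 0) ev2$time_ms <- ev2$time_ms + offset_ms
  events <- rbind(first$events, ev2)
  if (nrow(events) > 0) {
    events <- events[order(events$time_ms), , drop = FALSE]
    rownames(events) <- NULL
  }
  if (is.null(label)) label <- paste0(first$label, second$label)
  stimulus_protocol(events, label = label,
                    train_freq_hz = first$train_freq_hz,
                    train_duration_ms = first$train_duration_ms)
}

#' Multisensory train + pip protocol
#'
#' Convenience constructor for the multisensory condition: an auditory pip whose
#' onset coincides with the last pulse of a tectal train, so the 12-ms
#' quantification windows of the tectal-only and multisensory conditions
#' coincide.
#'
#' @param train a tectal [stimulus_protocol()] (as from [build_tectal_train()]).
#' @param pip_amplitude auditory drive amplitude.
#' @return a [stimulus_protocol()] labelled `"M"`.
#' @export
build_multisensory <- function(train, pip_amplitude = 1) {
  last_t <- max(train$events$time_ms)
  combine_protocols(train, build_auditory_pip(0, pip_amplitude),
                    offset_ms = last_t, label = "M")
}

#' Serialize / read a protocol as JSON
#'
#' Round-trip lossless (event times, modalities, amplitudes, label and nominal
#' train parameters, including unicode labels).
#'
#' @param protocol a [stimulus_protocol()].
#' @param path file path.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  doc <- list(label = protocol$label,
              train_freq_hz = protocol$train_freq_hz,
              train_duration_ms = protocol$train_duration_ms,
              events = protocol$events)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  events <- as.data.frame(doc$events, stringsAsFactors = FALSE)
  if (nrow(events) == 0)
    events <- data.frame(time_ms = numeric(), modality = character(),
                         amplitude = numeric(), stringsAsFactors = FALSE)
  stimulus_protocol(events, label = doc$label,
                    train_freq_hz = if (is.null(doc$train_freq_hz)) NA_real_ else doc$train_freq_hz,
                    train_duration_ms = if (is.null(doc$train_duration_ms)) NA_real_ else doc$train_duration_ms)
}

#' Per-cell recording metadata
#'
#' Carries the inclusion rule used for the intracellular data set: a trial is
#' included only when the resting membrane potential lies in the closed
#' interval \[-90, -70\] mV.
#'
#' @param fish_id identifier string.
#' @param cell_side `"left"` or `"right"`.
#' @param resting_potential_mV pre-trial resting membrane potential (mV).
#' @return an object of class `cell_meta` with an `included` flag.
#' @export
cell_meta <- function(fish_id, cell_side = c("left", "right"),
                      resting_potential_mV = NA_real_) {
  cell_side <- match.arg(cell_side)
  rp <- as.numeric(resting_potential_mV)
  structure(list(fish_id = as.character(fish_id), cell_side = cell_side,
                 resting_potential_mV = rp,
                 included = if (is.na(rp)) NA else (rp >= -90 & rp <= -70)),
            class = "cell_meta")
}
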