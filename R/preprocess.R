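#' Band-pass filter a session
#'
#' 5th-order Butterworth band-pass (default 8-30 Hz) applied zero-phase
#' (forward-backward, so the effective magnitude response is squared) to the
#' continuous recording, before epoching, so filter transients stay away
#' from epoch windows. Any channel labelled "EMG" is passed through
#' untouched.
#'
#' @param session An `eeg_session`.
#' @param low,high Band edges in Hz (0 < low < high < fs/2).
#' @param order Butterworth order (default 5).
#' @return The filtered `eeg_session`.
#' @export
bandpass <- function(session, low = 8, high = 30, order = 5) {
  stopifnot(inherits(session, "eeg_session"))
  fs <- session$fs
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- session
  for (ch in seq_len(nrow(session$signal))) {
    if (session$channel_labels[ch] == "EMG") next
    out$signal[ch, ] <- signal::filtfilt(bf, session$signal[ch, ])
  }
  out
}

#' Construct an epoch set
#'
#' @param data trials x channels x samples array.
#' @param labels Per-trial labels in {"KMI", "REST"}.
#' @param fs Sampling rate (Hz).
#' @param channel_labels EEG channel names (EMG excluded).
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, channel_labels) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(labels))
  structure(list(data = data, labels = labels, fs = fs,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%s) x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1],
              paste(names(table(x$labels)), table(x$labels), sep = ":", collapse = ", "),
              dim(x$data)[2], dim(x$data)[3], x$fs))
  invisible(x)
}

#' Extract classification epochs from a session
#'
#' Cuts one kinesthetic epoch (KTC) per GREEN cue, starting 0.5 s after the
#' cue, and one rest epoch (RTC) per RED cue, starting 2.5 s after it, each
#' lasting `dur` seconds (default 3.5 s, i.e. T = round(3.5 * fs) samples;
#' 896 at 256 Hz). Windows are half-open in samples, `[floor(t * fs),
#' floor(t * fs) + T)`, so every epoch has exactly T samples. Epochs
#' exceeding the recording are dropped with a warning; the EMG channel is
#' excluded from epoch data.
#'
#' @param session An `eeg_session` with RED/GREEN events.
#' @param kmi_offset,rest_offset Start of the window after the GREEN / RED
#'   cue, seconds.
#' @param dur Epoch duration in seconds.
#' @return An `epoch_set` with labels "KMI" and "REST", in event order
#'   (all KMI epochs first, then all REST epochs).
#' @export
extract_epochs <- function(session, kmi_offset = 0.5, rest_offset = 2.5, dur = 3.5) {
  stopifnot(inherits(session, "eeg_session"))
  fs <- session$fs
  T_ <- round(dur * fs)
  ev <- session$events
  if (!any(ev$code == "GREEN") || !any(ev$code == "RED"))
    stop("events must contain GREEN and RED codes")
  eeg <- which(session$channel_labels != "EMG")
  n_samp <- ncol(session$signal)

  cut_one <- function(onset, offset) {
    start <- floor((onset + offset) * fs) + 1
    if (start < 1 || start + T_ - 1 > n_samp) return(NULL)
    session$signal[eeg, start:(start + T_ - 1), drop = FALSE]
  }
  grab <- function(code, offset, label) {
    ons <- ev$onset_s[ev$code == code]
    eps <- lapply(ons, cut_one, offset = offset)
    drop <- vapply(eps, is.null, TRUE)
    if (any(drop))
      warning(sum(drop), " ", label, " epoch(s) dropped: window outside recording")
    eps[!drop]
  }
  kmi <- grab("GREEN", kmi_offset, "KMI")
  rest <- grab("RED", rest_offset, "REST")
  n <- length(kmi) + length(rest)
  if (n == 0) stop("no usable trials: all epoch windows fall outside the recording")
  data <- array(0, dim = c(n, length(eeg), T_))
  for (i in seq_along(kmi)) data[i, , ] <- kmi[[i]]
  for (i in seq_along(rest)) data[length(kmi) + i, , ] <- rest[[i]]
  epoch_set(data,
            c(rep("KMI", length(kmi)), rep("REST", length(rest))),
            fs, session$channel_labels[eeg])
}
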