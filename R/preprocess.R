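## Preprocessing of continuous recordings: EOG channel removal, zero-phase
## 8-30 Hz band-pass, and extraction of the 0.5-3.5 s post-cue window.
## Stage order follows the standard pipeline: channels -> filter -> epochs.

#' Drop non-EEG channels
#'
#' Returns a recording containing only the channels whose kind is `"EEG"`
#' (order preserved); EOG channels are removed before any filtering.
#'
#' @param rec a [RawRecording-class].
#' @return A [RawRecording-class] with only EEG channels.
#' @export
selectChannels <- function(rec) {
  stopifnot(is(rec, "RawRecording"))
  keep <- rec@channelKinds == "EEG"
  if (!any(keep))
    stop("no EEG channels remain after channel selection (empty montage)")
  RawRecording(rec@data[keep, , drop = FALSE], rec@fs,
               channelLabels = rec@channelLabels[keep],
               channelKinds = rec@channelKinds[keep],
               events = rec@events)
}

#' Zero-phase band-pass filter
#'
#' Filters every channel with a 4th-order Butterworth band-pass applied
#' forward and backward ([signal::filtfilt()]), so the pass band is preserved
#' with zero phase shift and cue timing stays meaningful. Defaults to the
#' 8-30 Hz sensorimotor band covering the mu and beta rhythms.
#'
#' @param rec a [RawRecording-class].
#' @param lowHz,highHz band edges in Hz; `0 < lowHz < highHz < fs/2`.
#' @param order Butterworth order (per pass).
#' @return The filtered [RawRecording-class], same shape.
#' @export
bandpass <- function(rec, lowHz = 8, highHz = 30, order = 4) {
  stopifnot(is(rec, "RawRecording"))
  if (lowHz <= 0 || highHz <= lowHz || highHz >= rec@fs / 2)
    stop("band edges must satisfy 0 < lowHz < highHz < fs/2")
  bf <- signal::butter(order, c(lowHz, highHz) / (rec@fs / 2), type = "pass")
  out <- rec@data
  for (c in seq_len(nrow(out)))
    out[c, ] <- signal::filtfilt(bf, rec@data[c, ])
  RawRecording(out, rec@fs, channelLabels = rec@channelLabels,
               channelKinds = rec@channelKinds, events = rec@events)
}

#' Cut cue-locked epochs from a recording
#'
#' Extracts one epoch per event over the half-open window
#' `[cue + startOffset, cue + endOffset)`, so every epoch has exactly
#' `round((endOffset - startOffset) * fs)` samples. The default 0.5-3.5 s
#' window captures the 3 s motor-imagery period after the cue.
#'
#' @param rec a [RawRecording-class] with populated events.
#' @param startOffset,endOffset window offsets in seconds relative to the cue.
#' @return An [EpochSet-class]; empty (0 trials) when the recording has no
#'   events.
#' @export
extractEpochs <- function(rec, startOffset = 0.5, endOffset = 3.5) {
  stopifnot(is(rec, "RawRecording"))
  if (endOffset <= startOffset)
    stop("endOffset must exceed startOffset")
  nSamp <- round((endOffset - startOffset) * rec@fs)
  k <- nrow(rec@data)
  nEv <- nrow(rec@events)
  data <- array(0, dim = c(nEv, k, nSamp))
  for (i in seq_len(nEv)) {
    from <- rec@events$sample[i] + round(startOffset * rec@fs)
    to <- from + nSamp - 1L
    if (from < 1 || to > ncol(rec@data))
      stop(sprintf("epoch window for event %d ([%d, %d]) exceeds recording bounds",
                   i, from, to))
    data[i, , ] <- rec@data[, from:to]
  }
  EpochSet(data, rec@events$label, rec@fs,
           channelLabels = rec@channelLabels,
           window = c(startOffset, endOffset))
}

#' Full preprocessing pipeline
#'
#' Channel selection, zero-phase band-pass and cue-locked windowing, composed
#' in that order. Accepts continuous recordings only; already-epoched data is
#' rejected rather than silently re-filtered.
#'
#' @param rec a [RawRecording-class].
#' @param band (low, high) Hz band-pass edges.
#' @param window (start, end) seconds relative to the cue.
#' @return An [EpochSet-class].
#' @examples
#' fs <- 250
#' sig <- matrix(rnorm(2 * 5 * fs), 2)
#' rec <- RawRecording(sig, fs, events = data.frame(sample = 250, label = 1))
#' preprocessRecording(rec)
#' @export
preprocessRecording <- function(rec, band = c(8, 30), window = c(0.5, 3.5)) {
  if (is(rec, "EpochSet"))
    stop("input is already epoched; preprocessing applies to RawRecording objects")
  stopifnot(is(rec, "RawRecording"))
  rec <- selectChannels(rec)
  rec <- bandpass(rec, band[1L], band[2L])
  extractEpochs(rec, window[1L], window[2L])
}
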