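## Plain-text array container: one CSV of flattened signal values plus a JSON
## metadata sidecar. One container per recording or epoch set; row blocks are
## channels (recordings) or trial-channel pairs (epochs), columns are samples.

.metaPath <- function(prefix) paste0(prefix, "_meta.json")
.dataPath <- function(prefix) paste0(prefix, "_data.csv")

#' Write an EpochSet to the plain-text array container
#'
#' Produces `<prefix>_data.csv` (rows = trial-channel pairs in trial-major
#' order, columns = samples) and `<prefix>_meta.json` (dims, labels, sampling
#' rate, channel labels, window).
#'
#' @param epochs an [EpochSet-class].
#' @param prefix file path prefix.
#' @return `prefix`, invisibly.
#' @export
writeEpochSet <- function(epochs, prefix) {
  stopifnot(is(epochs, "EpochSet"))
  d <- dim(epochs@data)
  flat <- matrix(aperm(epochs@data, c(3L, 2L, 1L)), ncol = d[3L],
                 byrow = TRUE)
  utils::write.table(flat, .dataPath(prefix), sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(kind = "epochs", dim = d, labels = epochs@labels, fs = epochs@fs,
         channel_labels = epochs@channelLabels, window = epochs@window),
    .metaPath(prefix), auto_unbox = FALSE, digits = NA)
  invisible(prefix)
}

#' Read an EpochSet from the plain-text array container
#'
#' @param prefix file path prefix used by [writeEpochSet()].
#' @return An [EpochSet-class].
#' @export
readEpochSet <- function(prefix) {
  meta <- jsonlite::read_json(.metaPath(prefix), simplifyVector = TRUE)
  if (!identical(meta$kind, "epochs"))
    stop("container at '", prefix, "' does not hold epochs")
  d <- as.integer(meta$dim)
  flat <- as.matrix(utils::read.table(.dataPath(prefix), sep = ","))
  dimnames(flat) <- NULL
  data <- aperm(array(t(flat), dim = c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
  EpochSet(data, meta$labels, meta$fs, channelLabels = meta$channel_labels,
           window = meta$window)
}

#' Write a RawRecording to the plain-text array container
#'
#' Produces `<prefix>_data.csv` (rows = channels, columns = samples) and
#' `<prefix>_meta.json` (sampling rate, channel labels and kinds, events).
#'
#' @param rec a [RawRecording-class].
#' @param prefix file path prefix.
#' @return `prefix`, invisibly.
#' @export
writeRawRecording <- function(rec, prefix) {
  stopifnot(is(rec, "RawRecording"))
  utils::write.table(rec@data, .dataPath(prefix), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(kind = "raw", fs = rec@fs, channel_labels = rec@channelLabels,
         channel_kinds = rec@channelKinds,
         events = list(sample = rec@events$sample,
                       label = rec@events$label)),
    .metaPath(prefix), auto_unbox = FALSE, digits = NA)
  invisible(prefix)
}

#' Read a RawRecording from the plain-text array container
#'
#' @param prefix file path prefix used by [writeRawRecording()].
#' @return A [RawRecording-class].
#' @export
readRawRecording <- function(prefix) {
  meta <- jsonlite::read_json(.metaPath(prefix), simplifyVector = TRUE)
  if (!identical(meta$kind, "raw"))
    stop("container at '", prefix, "' does not hold a raw recording")
  data <- as.matrix(utils::read.table(.dataPath(prefix), sep = ","))
  dimnames(data) <- NULL
  RawRecording(data, meta$fs, channelLabels = meta$channel_labels,
               channelKinds = meta$channel_kinds,
               events = data.frame(sample = meta$events$sample,
                                   label = meta$events$label))
}
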