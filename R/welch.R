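## Welch power spectral density: segmentation, tapered periodograms with
## window-power normalization, segment averaging, and band-power reduction.
## PSD values are one-sided densities (power per Hz), so summing bins times
## the bin width recovers the signal's mean power.

.welchWindow <- function(kind, n) {
  switch(kind,
    rectangular = rep(1, n),
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L)),
    hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L)),
    stop("unknown window kind: ", kind))
}

#' Split a signal into Welch segments
#'
#' Cuts a single-channel signal into segments of exactly `segmentLength`
#' samples whose starts advance by `round(segmentLength * (1 - overlap))`;
#' a trailing partial segment is discarded.
#'
#' @param x numeric signal vector, at least one segment long.
#' @param cfg a [WelchConfig-class].
#' @return A list of numeric segments.
#' @export
segmentSignal <- function(x, cfg = WelchConfig()) {
  stopifnot(is(cfg, "WelchConfig"))
  N <- as.integer(cfg@segmentLength)
  if (length(x) < N)
    stop(sprintf("signal (%d samples) is shorter than one segment (%d)",
                 length(x), N))
  step <- max(1L, as.integer(round(N * (1 - cfg@overlap))))
  starts <- seq.int(1L, length(x) - N + 1L, by = step)
  lapply(starts, function(s) x[s:(s + N - 1L)])
}

#' Tapered periodogram of one segment
#'
#' Computes the one-sided windowed periodogram
#' `P(lambda_j) = |DFT(x * w)|^2 / (N * U * fs)` at frequencies
#' `lambda_j = fs * j / N`, where `U = mean(w^2)` normalizes the window power
#' so the white-noise PSD level is independent of the taper. Interior bins are
#' doubled to fold negative frequencies into the one-sided density.
#'
#' @param segment numeric vector of exactly `cfg@segmentLength` samples.
#' @param cfg a [WelchConfig-class].
#' @return A list with `freq` (Hz) and `power` (density, per Hz).
#' @export
windowedPeriodogram <- function(segment, cfg = WelchConfig()) {
  stopifnot(is(cfg, "WelchConfig"))
  N <- as.integer(cfg@segmentLength)
  if (length(segment) != N)
    stop("segment length must equal cfg@segmentLength")
  w <- .welchWindow(cfg@windowKind, N)
  U <- mean(w^2)
  X <- stats::fft(segment * w)
  nb <- N %/% 2L + 1L
  p <- Mod(X[seq_len(nb)])^2 / (N * U * cfg@fs)
  # fold the negative-frequency half into interior bins
  hi <- nb - if (N %% 2L == 0L) 1L else 0L
  if (hi >= 2L) p[2L:hi] <- 2 * p[2L:hi]
  list(freq = cfg@fs * (seq_len(nb) - 1L) / N, power = p)
}

#' Welch power spectral density estimate
#'
#' Arithmetic mean of the tapered periodograms of all segments; averaging over
#' `R` segments reduces estimator variance by about `1/R` at the cost of
#' frequency resolution `fs / segmentLength`.
#'
#' @param x numeric signal vector.
#' @param cfg a [WelchConfig-class].
#' @return A list with `freq` (Hz) and `power` (density, per Hz).
#' @examples
#' x <- sin(2 * pi * 10 * (0:749) / 250)
#' psd <- welchPsd(x, WelchConfig(windowKind = "rectangular"))
#' psd$freq[which.max(psd$power)]  # 10 Hz
#' @export
welchPsd <- function(x, cfg = WelchConfig()) {
  segs <- segmentSignal(x, cfg)
  per <- lapply(segs, windowedPeriodogram, cfg = cfg)
  list(freq = per[[1L]]$freq,
       power = Reduce(`+`, lapply(per, `[[`, "power")) / length(per))
}

#' Band-power spectral features for epoched trials
#'
#' For every trial, channel and frequency band, averages the Welch PSD over
#' the bins with `low <= lambda <= high`. Columns are ordered channel-major
#' then band (all bands of channel 1, then channel 2, ...). Defaults cover the
#' mu (8-12 Hz) and beta (13-30 Hz) sensorimotor rhythms.
#'
#' @param epochs an [EpochSet-class].
#' @param cfg a [WelchConfig-class]; its `fs` is overridden by the epochs'.
#' @param bands list of `(low, high)` Hz pairs within `(0, fs/2)`.
#' @return A [SpectralFeatureBlock-class], trials x (channels * bands).
#' @export
bandFeatures <- function(epochs, cfg = WelchConfig(),
                         bands = list(c(8, 12), c(13, 30))) {
  stopifnot(is(epochs, "EpochSet"), is(cfg, "WelchConfig"))
  cfg@fs <- epochs@fs
  for (b in bands)
    if (b[1L] <= 0 || b[2L] <= b[1L] || b[2L] >= cfg@fs / 2)
      stop("each band must satisfy 0 < low < high < fs/2")
  n <- nTrials(epochs)
  k <- nChannels(epochs)
  nb <- length(bands)
  # resolve band bin masks once from the shared frequency grid
  freq <- windowedPeriodogram(numeric(cfg@segmentLength), cfg)$freq
  masks <- lapply(bands, function(b) freq >= b[1L] & freq <= b[2L])
  empty <- vapply(masks, function(m) !any(m), logical(1))
  if (any(empty))
    stop("band [", paste(bands[[which(empty)[1L]]], collapse = ", "),
         "] Hz contains no frequency bins; lengthen the Welch segments")
  vals <- matrix(0, n, k * nb)
  for (i in seq_len(n)) {
    for (c in seq_len(k)) {
      p <- welchPsd(epochs@data[i, c, ], cfg)$power
      for (j in seq_len(nb))
        vals[i, (c - 1L) * nb + j] <- mean(p[masks[[j]]])
    }
  }
  colnames(vals) <- as.vector(vapply(epochs@channelLabels, function(ch)
    vapply(bands, function(b)
      sprintf("%s.%g-%gHz", ch, b[1L], b[2L]), character(1)),
    character(nb)))
  new("SpectralFeatureBlock", values = vals, bands = bands,
      channelLabels = epochs@channelLabels)
}
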