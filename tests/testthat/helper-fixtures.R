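# Small fixture builders shared across test files.

# EpochSet from a list of channels x samples trial matrices
epochsFromTrials <- function(trials, labels, fs = 250) {
  k <- nrow(trials[[1]]); s <- ncol(trials[[1]])
  data <- array(0, dim = c(length(trials), k, s))
  for (i in seq_along(trials)) data[i, , ] <- trials[[i]]
  EpochSet(data, labels, fs)
}

# trials drawn as X = A %*% white-noise, labels alternating
mixedNoiseEpochs <- function(n, A, samples = 200, fs = 250,
                             labels = rep(c(1, 2), length.out = n)) {
  k <- nrow(A)
  epochsFromTrials(lapply(seq_len(n), function(i)
    A %*% matrix(rnorm(k * samples), k)), labels, fs)
}

smallConfig <- function(...) {
  args <- list(nSubjects = 2, nTrialsPerClass = 6, nChannels = 8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(SyntheticConfig, args)
}
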