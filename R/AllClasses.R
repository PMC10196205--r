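#' @import methods
NULL

## ---------------------------------------------------------------------------
## Recordings and epochs
## ---------------------------------------------------------------------------

#' Continuous multi-channel EEG recording
#'
#' Container for a continuous labeled recording: a channels x samples signal
#' matrix, per-channel kind (\code{"EEG"} or \code{"EOG"}), and a table of cue
#' events from which epochs are cut.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of channel names.
#' @slot channelKinds character vector, \code{"EEG"} or \code{"EOG"} per channel.
#' @slot events data.frame with columns \code{sample} (1-based cue sample
#'   index, sorted increasing) and \code{label} (class in \{1, 2\}).
#'
#' @seealso [RawRecording()] for the validating constructor,
#'   [selectChannels()], [bandpass()], [extractEpochs()].
#' @export
setClass("RawRecording",
  representation(
    data          = "matrix",
    fs            = "numeric",
    channelLabels = "character",
    channelKinds  = "character",
    events        = "data.frame"
  )
)

setValidity("RawRecording", function(object) {
  msg <- character()
  k <- nrow(object@data)
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelLabels) != k)
    msg <- c(msg, "channelLabels length must match channel count")
  if (length(object@channelKinds) != k)
    msg <- c(msg, "channelKinds length must match channel count")
  if (!all(object@channelKinds %in% c("EEG", "EOG")))
    msg <- c(msg, "channelKinds must be 'EEG' or 'EOG'")
  if (!all(c("sample", "label") %in% names(object@events)))
    msg <- c(msg, "events must have columns 'sample' and 'label'")
  else {
    if (is.unsorted(object@events$sample))
      msg <- c(msg, "events must be sorted by sample index")
    if (!all(object@events$label %in% c(1, 2)))
      msg <- c(msg, "event labels must be 1 or 2")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RawRecording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param channelLabels channel names; defaults to \code{ch1, ch2, ...}.
#' @param channelKinds \code{"EEG"}/\code{"EOG"} per channel; defaults to all EEG.
#' @param events data.frame with columns \code{sample} and \code{label}.
#' @return A [RawRecording-class] object.
#' @export
RawRecording <- function(data, fs, channelLabels = NULL, channelKinds = NULL,
                         events = data.frame(sample = integer(), label = integer())) {
  data <- as.matrix(data)
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(nrow(data)))
  if (is.null(channelKinds)) channelKinds <- rep("EEG", nrow(data))
  new("RawRecording", data = data, fs = as.numeric(fs),
      channelLabels = channelLabels, channelKinds = channelKinds,
      events = events)
}

#' Labeled epoched EEG trials
#'
#' The common currency between preprocessing, feature extraction and
#' classification: a trials x channels x samples tensor with per-trial class
#' labels and the epoch window relative to the cue.
#'
#' @slot data numeric array, trials x channels x samples.
#' @slot labels numeric vector of class labels in \{1, 2\} (left, right).
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector of channel names.
#' @slot window numeric length-2: (start, end) offsets in seconds relative to
#'   the cue; samples per trial equal \code{round((end - start) * fs)}.
#'
#' @seealso [EpochSet()], [extractEpochs()], [spatialFeatures()], [bandFeatures()].
#' @export
setClass("EpochSet",
  representation(
    data          = "array",
    labels        = "numeric",
    fs            = "numeric",
    channelLabels = "character",
    window        = "numeric"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x channels x samples array")
  else {
    if (length(object@labels) != d[1L])
      msg <- c(msg, "labels length must equal trial count")
    if (length(object@channelLabels) != d[2L])
      msg <- c(msg, "channelLabels length must equal channel count")
    if (length(object@window) == 2L &&
        d[3L] != round(diff(object@window) * object@fs))
      msg <- c(msg, "samples must equal round((end - start) * fs)")
  }
  if (length(object@labels) && !all(object@labels %in% c(1, 2)))
    msg <- c(msg, "labels must take values in {1, 2}")
  if (length(object@window) != 2L || object@window[2L] <= object@window[1L])
    msg <- c(msg, "window must be (start, end) with end > start")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param data trials x channels x samples numeric array.
#' @param labels per-trial class labels in \{1, 2\}.
#' @param fs sampling rate (Hz).
#' @param channelLabels channel names; defaults to \code{ch1, ch2, ...}.
#' @param window (start, end) seconds relative to the cue.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(data, labels, fs, channelLabels = NULL,
                     window = c(0, dim(data)[3L] / fs)) {
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(dim(data)[2L]))
  new("EpochSet", data = data, labels = as.numeric(labels), fs = as.numeric(fs),
      channelLabels = channelLabels, window = as.numeric(window))
}

## ---------------------------------------------------------------------------
## Synthetic cohort
## ---------------------------------------------------------------------------

#' Configuration of the synthetic motor-imagery EEG generator
#'
#' Defines the study conditions emulated by [generateSubject()] and
#' [generateCohort()]: montage size, trial counts, the mu and beta rhythm
#' bands, the depth of the class-dependent event-related desynchronization
#' (ERD), broadband noise level, and the spread of per-subject channel-mixing
#' perturbations that create cross-subject covariate shift.
#'
#' @slot nSubjects number of subjects in a cohort.
#' @slot nTrialsPerClass trials per class per subject.
#' @slot nChannels montage size.
#' @slot fs sampling rate (Hz); must exceed twice the beta-band upper edge.
#' @slot trialDuration epoch length in seconds.
#' @slot muBand,betaBand (low, high) Hz of the two sensorimotor rhythms.
#' @slot erdDepth fraction in [0, 1): relative mu-amplitude attenuation on the
#'   class-matched channel subset (power attenuates by \code{(1 - erdDepth)^2}).
#' @slot noiseSd standard deviation of additive white noise.
#' @slot subjectShiftSd scale of the per-subject mixing perturbation.
#' @slot seed integer master seed; identical seed + config regenerates the
#'   cohort bit-exactly.
#' @export
setClass("SyntheticConfig",
  representation(
    nSubjects       = "numeric",
    nTrialsPerClass = "numeric",
    nChannels       = "numeric",
    fs              = "numeric",
    trialDuration   = "numeric",
    muBand          = "numeric",
    betaBand        = "numeric",
    erdDepth        = "numeric",
    noiseSd         = "numeric",
    subjectShiftSd  = "numeric",
    seed            = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  chk1 <- function(x, nm, pos = TRUE) {
    if (length(slot(object, x)) != 1L || (pos && slot(object, x) <= 0))
      c(sprintf("%s must be a single positive number", nm)) else character()
  }
  msg <- c(msg,
    chk1("nSubjects", "nSubjects"), chk1("nTrialsPerClass", "nTrialsPerClass"),
    chk1("nChannels", "nChannels"), chk1("fs", "fs"),
    chk1("trialDuration", "trialDuration"))
  if (object@erdDepth < 0 || object@erdDepth >= 1)
    msg <- c(msg, "erdDepth must lie in [0, 1)")
  if (object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be > 0")
  if (object@subjectShiftSd < 0)
    msg <- c(msg, "subjectShiftSd must be >= 0")
  for (b in c("muBand", "betaBand")) {
    v <- slot(object, b)
    if (length(v) != 2L || v[1L] <= 0 || v[2L] <= v[1L])
      msg <- c(msg, sprintf("%s must be (low, high) with 0 < low < high", b))
  }
  if (length(object@betaBand) == 2L && object@fs <= 2 * object@betaBand[2L])
    msg <- c(msg, "fs must exceed twice the beta-band upper edge (Nyquist)")
  if (object@nChannels < 4)
    msg <- c(msg, "nChannels must be at least 4 (two disjoint ERD subsets)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticConfig-class Constructor with the default study
#'   conditions: 9 subjects, 72 trials per class, 8 channels, 250 Hz, 3 s
#'   trials, mu 8-12 Hz, beta 13-30 Hz, ERD depth 0.5, noise SD 4, subject
#'   shift SD 0.6 (chosen so the pooled cross-subject baseline degrades
#'   markedly relative to within-subject classification, the covariate-shift
#'   regime instance transfer addresses).
#' @param nSubjects,nTrialsPerClass,nChannels,fs,trialDuration,muBand,betaBand
#'   see slots.
#' @param erdDepth,noiseSd,subjectShiftSd,seed see slots.
#' @export
SyntheticConfig <- function(nSubjects = 9, nTrialsPerClass = 72, nChannels = 8,
                            fs = 250, trialDuration = 3,
                            muBand = c(8, 12), betaBand = c(13, 30),
                            erdDepth = 0.5, noiseSd = 4,
                            subjectShiftSd = 0.6, seed = 1L) {
  new("SyntheticConfig", nSubjects = nSubjects, nTrialsPerClass = nTrialsPerClass,
      nChannels = nChannels, fs = fs, trialDuration = trialDuration,
      muBand = as.numeric(muBand), betaBand = as.numeric(betaBand),
      erdDepth = erdDepth, noiseSd = noiseSd, subjectShiftSd = subjectShiftSd,
      seed = as.numeric(seed))
}

#' Multi-subject synthetic cohort
#'
#' @slot subjects named list of [EpochSet-class] objects, one per subject.
#' @slot config the [SyntheticConfig-class] that produced it.
#' @seealso [generateCohort()]
#' @export
setClass("Cohort",
  representation(subjects = "list", config = "SyntheticConfig"))

setValidity("Cohort", function(object) {
  msg <- character()
  if (!length(object@subjects))
    msg <- c(msg, "cohort must contain at least one subject")
  if (!all(vapply(object@subjects, is, logical(1), "EpochSet")))
    msg <- c(msg, "all subjects must be EpochSet objects")
  else {
    fs <- vapply(object@subjects, function(e) e@fs, numeric(1))
    nc <- vapply(object@subjects, function(e) dim(e@data)[2L], numeric(1))
    ns <- vapply(object@subjects, function(e) dim(e@data)[3L], numeric(1))
    if (length(unique(fs)) > 1L || length(unique(nc)) > 1L ||
        length(unique(ns)) > 1L)
      msg <- c(msg, "all subjects must share fs, channel count and samples")
    bal <- vapply(object@subjects, function(e)
      sum(e@labels == 1) == sum(e@labels == 2), logical(1))
    if (!all(bal)) msg <- c(msg, "labels must be balanced per subject")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CSP
## ---------------------------------------------------------------------------

#' Learned CSP spatial filter bank
#'
#' Common-spatial-pattern projection learned from two-class epochs: the
#' retained filter rows, their class-1 share of whitened variance (paired
#' eigenvalues summing to 1 across classes), and the whitening transform.
#'
#' @slot filters m x channels projection matrix (rows are spatial filters,
#'   sorted by decreasing discriminability |lambda - 0.5|).
#' @slot eigenvalues class-1 whitened-variance share per retained filter,
#'   in [0, 1].
#' @slot whitener channels x channels whitening matrix R with R Hc R' = I.
#' @slot m number of retained filters (even).
#' @seealso [fitFilters()], [spatialFeatures()]
#' @export
setClass("SpatialFilterBank",
  representation(filters = "matrix", eigenvalues = "numeric",
                 whitener = "matrix", m = "numeric"))

setValidity("SpatialFilterBank", function(object) {
  msg <- character()
  if (nrow(object@filters) != object@m)
    msg <- c(msg, "filters must have m rows")
  if (length(object@eigenvalues) != object@m)
    msg <- c(msg, "eigenvalues length must equal m")
  if (any(object@eigenvalues < -1e-8 | object@eigenvalues > 1 + 1e-8))
    msg <- c(msg, "eigenvalues must lie in [0, 1]")
  dsc <- abs(object@eigenvalues - 0.5)
  if (length(dsc) && is.unsorted(rev(dsc)))
    msg <- c(msg, "filters must be sorted by descending |eigenvalue - 0.5|")
  if (length(msg)) msg else TRUE
})

#' CSP variance-ratio feature block
#'
#' Per-trial normalized variance shares along the retained spatial filters;
#' each row sums to 1 and is invariant to per-trial gain.
#'
#' @slot values trials x m matrix.
#' @slot m number of filters.
#' @export
setClass("SpatialFeatureBlock",
  representation(values = "matrix", m = "numeric"))

setValidity("SpatialFeatureBlock", function(object) {
  msg <- character()
  if (ncol(object@values) != object@m)
    msg <- c(msg, "values must have m columns")
  if (nrow(object@values) &&
      max(abs(rowSums(object@values) - 1)) > 1e-8)
    msg <- c(msg, "feature rows must sum to 1")
  if (nrow(object@values) && any(object@values < 0 | object@values > 1 + 1e-12))
    msg <- c(msg, "entries must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Welch PSD
## ---------------------------------------------------------------------------

#' Welch periodogram-averaging configuration
#'
#' @slot segmentLength segment length N in samples.
#' @slot overlap fraction in [0, 1); segment starts advance by
#'   \code{round(N * (1 - overlap))}.
#' @slot windowKind taper name: \code{"hamming"} (default), \code{"hann"} or
#'   \code{"rectangular"}.
#' @slot fs sampling rate (Hz).
#' @seealso [welchPsd()], [bandFeatures()]
#' @export
setClass("WelchConfig",
  representation(segmentLength = "numeric", overlap = "numeric",
                 windowKind = "character", fs = "numeric"))

setValidity("WelchConfig", function(object) {
  msg <- character()
  if (object@segmentLength < 2)
    msg <- c(msg, "segmentLength must be at least 2")
  if (object@overlap < 0 || object@overlap >= 1)
    msg <- c(msg, "overlap must lie in [0, 1)")
  if (!object@windowKind %in% c("hamming", "hann", "rectangular"))
    msg <- c(msg, "windowKind must be 'hamming', 'hann' or 'rectangular'")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn WelchConfig-class Constructor. Defaults give 1 s non-overlapping
#'   Hamming segments at 250 Hz (1 Hz bin resolution on 750-sample epochs).
#' @param segmentLength,overlap,windowKind,fs see slots.
#' @export
WelchConfig <- function(segmentLength = 250, overlap = 0,
                        windowKind = "hamming", fs = 250) {
  new("WelchConfig", segmentLength = segmentLength, overlap = overlap,
      windowKind = windowKind, fs = fs)
}

#' Band-power spectral feature block
#'
#' Per-trial mean Welch power in each requested frequency band for each
#' channel; columns ordered channel-major then band.
#'
#' @slot values trials x (channels * n_bands) non-negative matrix.
#' @slot bands list of (low, high) Hz pairs.
#' @slot channelLabels channel names, in column-block order.
#' @export
setClass("SpectralFeatureBlock",
  representation(values = "matrix", bands = "list",
                 channelLabels = "character"))

setValidity("SpectralFeatureBlock", function(object) {
  msg <- character()
  if (nrow(object@values) && min(object@values) < 0)
    msg <- c(msg, "power values must be non-negative")
  if (ncol(object@values) !=
      length(object@bands) * length(object@channelLabels))
    msg <- c(msg, "column count must equal channels x bands")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## KMM
## ---------------------------------------------------------------------------

#' Kernel mean matching configuration
#'
#' @slot sigma Gaussian kernel width; \code{NA} requests the median heuristic
#'   on the pooled source + target features.
#' @slot B upper box bound on each weight (>= 1).
#' @slot eps slack on the mean-weight constraint: \code{|sum(beta) - n| <= n * eps}.
#'   \code{Inf} drops the constraint, leaving the literal [0, B] box.
#' @slot ridge diagonal loading added to the kernel matrix in the quadratic
#'   program. The unregularized program is degenerate whenever many weight
#'   vectors achieve near-zero discrepancy; the ridge selects the smooth
#'   representative (and, with the mean constraint, never worsens the achieved
#'   discrepancy relative to uniform weights).
#' @seealso [solveWeights()]
#' @export
setClass("KernelConfig",
  representation(sigma = "numeric", B = "numeric", eps = "numeric",
                 ridge = "numeric"))

setValidity("KernelConfig", function(object) {
  msg <- character()
  if (!is.na(object@sigma) && object@sigma <= 0)
    msg <- c(msg, "sigma must be positive (or NA for the median heuristic)")
  if (object@B < 1) msg <- c(msg, "B must be >= 1")
  if (object@eps < 0) msg <- c(msg, "eps must be >= 0")
  if (object@ridge < 0) msg <- c(msg, "ridge must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn KernelConfig-class Constructor; defaults: median-heuristic
#'   sigma, box bound B = 10, mean-weight slack eps = 0.01, ridge 0.1.
#' @param sigma,B,eps,ridge see slots.
#' @export
KernelConfig <- function(sigma = NA_real_, B = 10, eps = 0.01, ridge = 0.1) {
  new("KernelConfig", sigma = as.numeric(sigma), B = B, eps = eps,
      ridge = ridge)
}

#' Per-source-trial importance weights from kernel mean matching
#'
#' @slot weights length-n weight vector (uniform weight corresponds to 1).
#' @slot objective achieved squared maximum mean discrepancy at the optimum,
#'   including the weight-independent target-target term.
#' @slot sigma resolved kernel width.
#' @slot config the [KernelConfig-class] used.
#' @export
setClass("SourceWeightVector",
  representation(weights = "numeric", objective = "numeric",
                 sigma = "numeric", config = "KernelConfig"))

setValidity("SourceWeightVector", function(object) {
  msg <- character()
  B <- object@config@B
  if (any(object@weights < -1e-6) || any(object@weights > B + 1e-6))
    msg <- c(msg, "weights must lie in [0, B]")
  eps <- object@config@eps
  if (is.finite(eps) &&
      abs(mean(object@weights) - 1) > eps + 1e-6)
    msg <- c(msg, "mean weight must satisfy |mean - 1| <= eps")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TrAdaBoost
## ---------------------------------------------------------------------------

#' TrAdaBoost configuration
#'
#' @slot nIterations boosting iterations N (>= 1).
#' @slot weakLearner weak-learner preset: \code{"tree"} (depth-2 decision
#'   tree, default), \code{"stump"} (depth-1) or \code{"logistic"} (weighted
#'   logistic regression). All honor per-sample weights; the contract is
#'   probed at fit time.
#' @slot initMode \code{"uniform"} (1/n source, 1/m target) or \code{"kmm"}
#'   (KMM-seeded source weights).
#' @slot seed integer seed controlling any stochastic step.
#' @export
setClass("BoostConfig",
  representation(nIterations = "numeric", weakLearner = "character",
                 initMode = "character", seed = "numeric"))

setValidity("BoostConfig", function(object) {
  msg <- character()
  if (object@nIterations < 1) msg <- c(msg, "nIterations must be >= 1")
  if (!object@weakLearner %in% c("tree", "stump", "logistic"))
    msg <- c(msg, "weakLearner must be 'tree', 'stump' or 'logistic'")
  if (!object@initMode %in% c("uniform", "kmm"))
    msg <- c(msg, "initMode must be 'uniform' or 'kmm'")
  if (length(msg)) msg else TRUE
})

#' @describeIn BoostConfig-class Constructor; defaults: 20 iterations, depth-2
#'   tree weak learner, uniform initialization.
#' @param nIterations,weakLearner,initMode,seed see slots.
#' @export
BoostConfig <- function(nIterations = 20, weakLearner = "tree",
                        initMode = "uniform", seed = 1L) {
  new("BoostConfig", nIterations = nIterations, weakLearner = weakLearner,
      initMode = initMode, seed = as.numeric(seed))
}

#' Boosted instance-transfer strong classifier
#'
#' The ensemble assembled by [fitTrAdaBoost()]: the recorded weak hypotheses,
#' their error ratios beta_t = eps_t / (1 - eps_t), and the second-half
#' weighted-vote decision rule. Predicts 1 when the ln(1/beta_t)-weighted vote
#' over the second half of iterations reaches half its total mass (ties
#' resolve to 1); predictions are mapped back to class labels \{1, 2\}.
#'
#' @slot hypotheses list of fitted weak learners.
#' @slot betas per-iteration beta_t values in (0, 1).
#' @slot epsilons per-iteration weighted target error rates, each < 0.5.
#' @slot nIterations iterations actually completed.
#' @slot weakLearner weak-learner preset name.
#' @slot underTrained TRUE when early stopping left fewer than half the
#'   requested iterations.
#' @seealso [fitTrAdaBoost()], [predict,StrongClassifier-method]
#' @export
setClass("StrongClassifier",
  representation(hypotheses = "list", betas = "numeric", epsilons = "numeric",
                 nIterations = "numeric", weakLearner = "character",
                 underTrained = "logical"))

setValidity("StrongClassifier", function(object) {
  msg <- character()
  if (length(object@hypotheses) != object@nIterations)
    msg <- c(msg, "one hypothesis per completed iteration required")
  if (length(object@betas) != object@nIterations)
    msg <- c(msg, "one beta_t per completed iteration required")
  if (object@nIterations >= 1 && any(object@epsilons >= 0.5))
    msg <- c(msg, "every recorded error rate must be < 0.5")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Pipeline
## ---------------------------------------------------------------------------

#' Joint spatial-spectral feature matrix
#'
#' Concatenation of the CSP variance block and the Welch band-power block,
#' z-scored per column with training-set statistics; the block map names which
#' columns are spatial and which are spectral.
#'
#' @slot values trials x p standardized feature matrix.
#' @slot blockMap named list of column index vectors (\code{spatial},
#'   \code{frequency}); spatial columns precede frequency columns and the
#'   blocks tile all columns exactly once.
#' @slot center,scale per-column standardization parameters (training set).
#' @seealso [buildJointFeatures()]
#' @export
setClass("JointFeatureMatrix",
  representation(values = "matrix", blockMap = "list",
                 center = "numeric", scale = "numeric"))

setValidity("JointFeatureMatrix", function(object) {
  msg <- character()
  idx <- sort(unlist(object@blockMap, use.names = FALSE))
  if (!identical(as.integer(idx), seq_len(ncol(object@values))))
    msg <- c(msg, "block map must tile all columns exactly once")
  if (all(c("spatial", "frequency") %in% names(object@blockMap)) &&
      length(object@blockMap$spatial) && length(object@blockMap$frequency) &&
      max(object@blockMap$spatial) > min(object@blockMap$frequency))
    msg <- c(msg, "spatial columns must precede frequency columns")
  if (length(object@center) != ncol(object@values) ||
      length(object@scale) != ncol(object@values))
    msg <- c(msg, "center/scale must have one entry per column")
  if (length(msg)) msg else TRUE
})

#' Transfer-experiment evaluation report
#'
#' Accuracy of one feature/classifier configuration for one target subject,
#' aggregated over seeded repetitions, with summed confusion counts.
#'
#' @slot subject target subject identifier.
#' @slot featureMode \code{"csp"}, \code{"psd"} or \code{"joint"}.
#' @slot classifierMode \code{"svm"}, \code{"kmm_weighted"},
#'   \code{"tradaboost_uniform"} or \code{"kt_full"}.
#' @slot accuracies per-seed accuracies in [0, 1].
#' @slot meanAccuracy,sdAccuracy aggregate over seeds.
#' @slot confusion named numeric (TP, TN, FP, FN), summed over seeds.
#' @slot seeds the seeds used.
#' @seealso [runTransferExperiment()], [runLoso()]
#' @export
setClass("EvaluationReport",
  representation(subject = "character", featureMode = "character",
                 classifierMode = "character", accuracies = "numeric",
                 meanAccuracy = "numeric", sdAccuracy = "numeric",
                 confusion = "numeric", seeds = "numeric"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  cf <- object@confusion
  if (!all(c("TP", "TN", "FP", "FN") %in% names(cf)))
    msg <- c(msg, "confusion must name TP, TN, FP, FN")
  else if (sum(cf) > 0) {
    # seeds share one test-set size, so the pooled confusion accuracy must
    # reproduce the mean of per-seed accuracies
    acc <- (cf[["TP"]] + cf[["TN"]]) / sum(cf)
    if (abs(acc - object@meanAccuracy) > 1e-12)
      msg <- c(msg, "confusion counts inconsistent with accuracy")
  }
  if (length(object@accuracies) &&
      abs(mean(object@accuracies) - object@meanAccuracy) > 1e-12)
    msg <- c(msg, "meanAccuracy must equal mean(accuracies)")
  if (length(msg)) msg else TRUE
})

#' Experiment configuration for transfer evaluation
#'
#' Bundles the feature mode, classifier mode and all stage sub-configurations
#' for [runTransferExperiment()] and [runLoso()]; the mode grid spans the
#' standard ablations (single-domain vs joint features; plain SVM vs
#' KMM-weighted learner vs uniformly initialized TrAdaBoost vs the full
#' KMM-seeded TrAdaBoost).
#'
#' @slot featureMode \code{"csp"}, \code{"psd"} or \code{"joint"}.
#' @slot classifierMode \code{"svm"}, \code{"kmm_weighted"},
#'   \code{"tradaboost_uniform"} or \code{"kt_full"}.
#' @slot targetTrainFraction fraction of target trials available for training
#'   (stratified, seeded split); remainder is the test set.
#' @slot m number of CSP filters retained.
#' @slot bands list of (low, high) Hz band pairs for the spectral block.
#' @slot welch [WelchConfig-class].
#' @slot kernel [KernelConfig-class].
#' @slot boost [BoostConfig-class].
#' @slot seeds seeds over which each evaluation is repeated.
#' @export
setClass("ExperimentConfig",
  representation(featureMode = "character", classifierMode = "character",
                 targetTrainFraction = "numeric", m = "numeric",
                 bands = "list", welch = "WelchConfig",
                 kernel = "KernelConfig", boost = "BoostConfig",
                 seeds = "numeric"))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (!object@featureMode %in% c("csp", "psd", "joint"))
    msg <- c(msg, "featureMode must be 'csp', 'psd' or 'joint'")
  if (!object@classifierMode %in%
      c("svm", "kmm_weighted", "tradaboost_uniform", "kt_full"))
    msg <- c(msg, "unknown classifierMode")
  if (object@targetTrainFraction <= 0 || object@targetTrainFraction >= 1)
    msg <- c(msg, "targetTrainFraction must lie in (0, 1)")
  if (object@m < 2 || object@m %% 2 != 0)
    msg <- c(msg, "m must be an even count >= 2")
  if (!length(object@seeds)) msg <- c(msg, "at least one seed required")
  if (length(msg)) msg else TRUE
})

#' @describeIn ExperimentConfig-class Constructor. Defaults: joint features,
#'   full KMM-seeded TrAdaBoost, 20\% target training fraction, m = 6 CSP
#'   filters, mu + beta bands, 10 seeds.
#' @param featureMode,classifierMode,targetTrainFraction,m,bands see slots.
#' @param welch,kernel,boost,seeds see slots.
#' @export
ExperimentConfig <- function(featureMode = "joint", classifierMode = "kt_full",
                             targetTrainFraction = 0.2, m = 6,
                             bands = list(c(8, 12), c(13, 30)),
                             welch = WelchConfig(), kernel = KernelConfig(),
                             boost = BoostConfig(), seeds = 1:10) {
  new("ExperimentConfig", featureMode = featureMode,
      classifierMode = classifierMode,
      targetTrainFraction = targetTrainFraction, m = m, bands = bands,
      welch = welch, kernel = kernel, boost = boost,
      seeds = as.numeric(seeds))
}
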