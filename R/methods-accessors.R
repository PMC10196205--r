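#' Accessors for the package's data containers
#'
#' Slot access for [EpochSet-class], [Cohort-class], [SpatialFilterBank-class],
#' feature blocks, [SourceWeightVector-class] and [EvaluationReport-class]
#' objects.
#'
#' @param x an object of the documented classes.
#' @return The corresponding component: counts, label/channel vectors, the
#'   trial tensor, feature matrices, filter rows, eigenvalues, weights, the
#'   subject list, or a mean accuracy.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2L])
#' @rdname accessors
setMethod("nChannels", "RawRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "RawRecording", function(x) x@fs)
#' @rdname accessors
setMethod("trialLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "RawRecording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname accessors
setMethod("featureValues", "SpatialFeatureBlock", function(x) x@values)
#' @rdname accessors
setMethod("featureValues", "SpectralFeatureBlock", function(x) x@values)
#' @rdname accessors
setMethod("featureValues", "JointFeatureMatrix", function(x) x@values)

#' @rdname accessors
setMethod("spatialFilters", "SpatialFilterBank", function(x) x@filters)
#' @rdname accessors
setMethod("filterEigenvalues", "SpatialFilterBank", function(x) x@eigenvalues)

#' @rdname accessors
setMethod("importanceWeights", "SourceWeightVector", function(x) x@weights)

#' @rdname accessors
setMethod("subjects", "Cohort", function(x) x@subjects)
#' @rdname accessors
setMethod("nTrials", "Cohort", function(x)
  sum(vapply(x@subjects, nTrials, numeric(1))))

#' @rdname accessors
setMethod("meanAccuracy", "EvaluationReport", function(x) x@meanAccuracy)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], object@fs))
  cat(sprintf("  window: [%g, %g) s; labels: %d class-1, %d class-2\n",
              object@window[1L], object@window[2L],
              sum(object@labels == 1), sum(object@labels == 2)))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort of %d subjects (%s)\n", length(object@subjects),
              paste(names(object@subjects), collapse = ", ")))
  cat(sprintf("  ERD depth %g, noise SD %g, subject shift SD %g, seed %d\n",
              object@config@erdDepth, object@config@noiseSd,
              object@config@subjectShiftSd, as.integer(object@config@seed)))
})

setMethod("show", "SpatialFilterBank", function(object) {
  cat(sprintf("SpatialFilterBank: %d filters over %d channels\n",
              object@m, ncol(object@filters)))
  cat("  eigenvalues:", paste(sprintf("%.3f", object@eigenvalues),
                              collapse = " "), "\n")
})

setMethod("show", "SourceWeightVector", function(object) {
  cat(sprintf(
    "SourceWeightVector: n = %d, mean = %.4f, range = [%.4f, %.4f]\n",
    length(object@weights), mean(object@weights), min(object@weights),
    max(object@weights)))
  cat(sprintf("  squared MMD at optimum: %.6g (sigma = %.4g)\n",
              object@objective, object@sigma))
})

setMethod("show", "StrongClassifier", function(object) {
  cat(sprintf(
    "StrongClassifier: %d %s hypotheses; voting over iterations %d..%d\n",
    object@nIterations, object@weakLearner,
    ceiling(object@nIterations / 2), object@nIterations))
  if (object@underTrained)
    cat("  warning: early stopping left the ensemble under-trained\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport [%s | %s] target %s\n", object@featureMode,
              object@classifierMode, object@subject))
  cat(sprintf("  accuracy %.1f%% +/- %.1f%% over %d seeds\n",
              100 * object@meanAccuracy, 100 * object@sdAccuracy,
              length(object@seeds)))
})
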