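## Orchestration: joint spatial-spectral features (CSP fit on training epochs
## only, per-column z-scoring with training statistics), the four classifier
## modes of the ablation grid, single-target transfer experiments and
## leave-one-subject-out evaluation.

.zscoreParams <- function(M) {
  ctr <- colMeans(M)
  scl <- apply(M, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.applyZ <- function(M, p) sweep(sweep(M, 2, p$center), 2, p$scale, `/`)

#' Build joint spatial-spectral feature matrices
#'
#' Fits the CSP filter bank on the training epochs only, computes the CSP
#' variance block and the Welch band-power block for both the training and
#' apply sets, z-scores every column with training-set statistics (the CSP
#' ratios live in (0, 1) while band powers are unbounded, so unstandardized
#' concatenation would let one block dominate), and concatenates spatial
#' before spectral columns.
#'
#' @param epochsTrain training [EpochSet-class] (must contain both classes).
#' @param epochsApply epochs to transform with the fitted bank and training
#'   statistics (may be the training set itself).
#' @param m number of CSP filters.
#' @param welch a [WelchConfig-class].
#' @param bands list of (low, high) Hz band pairs.
#' @param featureMode `"joint"`, `"csp"` or `"psd"`.
#' @param logVariance apply `log` to the CSP variance ratios before
#'   standardization.
#' @param spectralTrain,spectralApply optional precomputed
#'   [SpectralFeatureBlock-class]s for the two sets (cache for repeated
#'   splits); computed from the epochs when `NULL`.
#' @return A list with [JointFeatureMatrix-class]es `train` and `apply`, and
#'   the fitted [SpatialFilterBank-class] `bank` (`NULL` in `"psd"` mode).
#' @export
buildJointFeatures <- function(epochsTrain, epochsApply, m = 6,
                               welch = WelchConfig(),
                               bands = list(c(8, 12), c(13, 30)),
                               featureMode = c("joint", "csp", "psd"),
                               logVariance = FALSE,
                               spectralTrain = NULL, spectralApply = NULL) {
  featureMode <- match.arg(featureMode)
  if (!all(c(1, 2) %in% epochsTrain@labels))
    stop("training epochs must contain both classes")
  bank <- NULL
  spTr <- spAp <- NULL
  if (featureMode != "psd") {
    cc <- classCovariances(epochsTrain)
    bank <- fitFilters(cc$C1, cc$C2, m)
    spTr <- featureValues(spatialFeatures(bank, epochsTrain))
    spAp <- featureValues(spatialFeatures(bank, epochsApply))
    if (logVariance) { spTr <- log(spTr); spAp <- log(spAp) }
  }
  fqTr <- fqAp <- NULL
  if (featureMode != "csp") {
    if (is.null(spectralTrain))
      spectralTrain <- bandFeatures(epochsTrain, welch, bands)
    if (is.null(spectralApply))
      spectralApply <- bandFeatures(epochsApply, welch, bands)
    fqTr <- featureValues(spectralTrain)
    fqAp <- featureValues(spectralApply)
  }
  tr <- cbind(spTr, fqTr)
  ap <- cbind(spAp, fqAp)
  blockMap <- switch(featureMode,
    joint = list(spatial = seq_len(ncol(spTr)),
                 frequency = ncol(spTr) + seq_len(ncol(fqTr))),
    csp = list(spatial = seq_len(ncol(tr))),
    psd = list(frequency = seq_len(ncol(tr))))
  zp <- .zscoreParams(tr)
  mk <- function(M) new("JointFeatureMatrix", values = .applyZ(M, zp),
                        blockMap = blockMap, center = zp$center,
                        scale = zp$scale)
  list(train = mk(tr), apply = mk(ap), bank = bank)
}

#' Classification accuracy from confusion counts
#'
#' `Acc = (TP + TN) / (TP + TN + FP + FN)`, returned as a fraction in [0, 1].
#'
#' @param TP,TN,FP,FN non-negative confusion counts with positive total.
#' @return The accuracy.
#' @examples
#' accuracyFromCounts(45, 40, 5, 10)  # 0.85
#' @export
accuracyFromCounts <- function(TP, TN, FP, FN) {
  counts <- c(TP, TN, FP, FN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("accuracy is undefined for zero total count")
  unname((TP + TN) / sum(counts))
}

# confusion counts with class 2 ("right") as the positive label
.confusion <- function(predicted, actual) {
  c(TP = sum(predicted == 2 & actual == 2),
    TN = sum(predicted == 1 & actual == 1),
    FP = sum(predicted == 2 & actual == 1),
    FN = sum(predicted == 1 & actual == 2))
}

# stratified seeded index split; returns train indices
.stratifiedTrain <- function(labels, fraction) {
  unlist(lapply(c(1, 2), function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1L, round(fraction * length(idx))))
  }), use.names = FALSE)
}

.bindEpochs <- function(sets) {
  d1 <- dim(sets[[1L]]@data)
  n <- sum(vapply(sets, nTrials, numeric(1)))
  data <- array(0, dim = c(n, d1[2L], d1[3L]))
  labels <- numeric(n)
  at <- 0L
  for (s in sets) {
    ns <- nTrials(s)
    data[at + seq_len(ns), , ] <- s@data
    labels[at + seq_len(ns)] <- s@labels
    at <- at + ns
  }
  EpochSet(data, labels, sets[[1L]]@fs,
           channelLabels = sets[[1L]]@channelLabels,
           window = sets[[1L]]@window)
}

.subsetEpochs <- function(es, idx) {
  EpochSet(es@data[idx, , , drop = FALSE], es@labels[idx], es@fs,
           channelLabels = es@channelLabels, window = es@window)
}

#' Precompute per-subject spectral feature blocks
#'
#' Welch band-power features do not depend on the train/test split or the
#' target subject, so repeated evaluations over seeds and targets can share
#' one cache.
#'
#' @param cohort a [Cohort-class].
#' @param welch a [WelchConfig-class].
#' @param bands list of (low, high) Hz band pairs.
#' @return A named list of [SpectralFeatureBlock-class]s, one per subject.
#' @export
cohortSpectralCache <- function(cohort, welch = WelchConfig(),
                                bands = list(c(8, 12), c(13, 30))) {
  lapply(cohort@subjects, bandFeatures, cfg = welch, bands = bands)
}

.svmBaseline <- function(Xtr, ytr, Xte) {
  gamma <- 1 / (ncol(Xtr) * stats::var(as.vector(Xtr)))
  fit <- e1071::svm(x = Xtr, y = factor(ytr, levels = c(1, 2)),
                    kernel = "radial", cost = 1, gamma = gamma, scale = FALSE)
  as.numeric(as.character(stats::predict(fit, Xte)))
}

#' Run one cross-subject transfer experiment
#'
#' Pools all non-target subjects as the source domain, splits the target
#' subject's trials into a small labeled training fraction and a held-out
#' test set (stratified, per-seed), builds features with fits on source +
#' target-train only, applies the configured classifier mode, and scores
#' accuracy on the target test trials. Repeated over `cfg@seeds` and
#' aggregated. The test partition is only ever transformed and predicted,
#' never fit on.
#'
#' Classifier modes: `"svm"` is the weight-free RBF-SVM baseline on the
#' pooled training rows; `"kmm_weighted"` feeds the KMM importance weights to
#' a single weight-sensitive weak learner; `"tradaboost_uniform"` boosts from
#' the uniform initialization; `"kt_full"` boosts from the KMM-seeded
#' initialization.
#'
#' @param cohort a [Cohort-class] with at least two subjects.
#' @param targetSubject name (e.g. `"S3"`) or index of the target subject.
#' @param cfg an [ExperimentConfig-class].
#' @param spectralCache optional [cohortSpectralCache()] result.
#' @return An [EvaluationReport-class].
#' @export
runTransferExperiment <- function(cohort, targetSubject,
                                  cfg = ExperimentConfig(),
                                  spectralCache = NULL) {
  stopifnot(is(cohort, "Cohort"), is(cfg, "ExperimentConfig"))
  validObject(cfg)
  if (length(cohort@subjects) < 2L)
    stop("cohort must contain at least two subjects")
  if (is.numeric(targetSubject))
    targetSubject <- names(cohort@subjects)[targetSubject]
  if (!targetSubject %in% names(cohort@subjects))
    stop("target subject '", targetSubject, "' is not in the cohort")
  if (is.null(spectralCache) && cfg@featureMode != "csp")
    spectralCache <- cohortSpectralCache(cohort, cfg@welch, cfg@bands)

  target <- cohort@subjects[[targetSubject]]
  sourceNames <- setdiff(names(cohort@subjects), targetSubject)
  sourceEpochs <- .bindEpochs(cohort@subjects[sourceNames])
  nSrc <- nTrials(sourceEpochs)
  srcSpectral <- if (!is.null(spectralCache))
    do.call(rbind, lapply(spectralCache[sourceNames], featureValues))

  accs <- numeric(length(cfg@seeds))
  confTotal <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (s in seq_along(cfg@seeds)) {
    seed <- cfg@seeds[s]
    old <- .Random.seed_save()
    set.seed(as.integer(seed %% .Machine$integer.max))
    trIdx <- .stratifiedTrain(target@labels, cfg@targetTrainFraction)
    teIdx <- setdiff(seq_len(nTrials(target)), trIdx)
    if (!length(teIdx)) { .Random.seed_restore(old); stop("degenerate split: no test trials") }
    tgtTrain <- .subsetEpochs(target, trIdx)
    tgtTest <- .subsetEpochs(target, teIdx)

    spectralTrain <- spectralApply <- NULL
    if (!is.null(spectralCache)) {
      tv <- featureValues(spectralCache[[targetSubject]])
      spectralTrain <- new("SpectralFeatureBlock",
                           values = rbind(srcSpectral, tv[trIdx, , drop = FALSE]),
                           bands = cfg@bands,
                           channelLabels = target@channelLabels)
      spectralApply <- new("SpectralFeatureBlock",
                           values = tv[teIdx, , drop = FALSE],
                           bands = cfg@bands,
                           channelLabels = target@channelLabels)
    }
    trainEpochs <- .bindEpochs(list(sourceEpochs, tgtTrain))
    fts <- buildJointFeatures(trainEpochs, tgtTest, m = cfg@m,
                              welch = cfg@welch, bands = cfg@bands,
                              featureMode = cfg@featureMode,
                              spectralTrain = spectralTrain,
                              spectralApply = spectralApply)
    Xtr <- featureValues(fts$train)
    Xte <- featureValues(fts$apply)
    ytr <- trainEpochs@labels
    srcRows <- seq_len(nSrc)
    tgtRows <- nSrc + seq_len(nTrials(tgtTrain))

    kmmW <- NULL
    if (cfg@classifierMode %in% c("kmm_weighted", "kt_full"))
      kmmW <- solveWeights(Xtr[srcRows, , drop = FALSE],
                           Xtr[tgtRows, , drop = FALSE], cfg@kernel)

    pred <- switch(cfg@classifierMode,
      svm = .svmBaseline(Xtr, ytr, Xte),
      kmm_weighted = {
        # single weight-sensitive classifier (weighted logistic regression)
        # taking the KMM importance weights as per-sample weights
        w <- c(importanceWeights(kmmW), rep(1, length(tgtRows)))
        colnames(Xtr) <- colnames(Xte) <- paste0("f", seq_len(ncol(Xtr)))
        h <- .fitWeak("logistic", Xtr, ytr - 1, w)
        .predictWeak("logistic", h, Xte) + 1
      },
      tradaboost_uniform = {
        bc <- cfg@boost; bc@initMode <- "uniform"; bc@seed <- seed
        predict(fitTrAdaBoost(Xtr[srcRows, , drop = FALSE], ytr[srcRows],
                              Xtr[tgtRows, , drop = FALSE], ytr[tgtRows], bc),
                Xte)
      },
      kt_full = {
        bc <- cfg@boost; bc@initMode <- "kmm"; bc@seed <- seed
        predict(fitTrAdaBoost(Xtr[srcRows, , drop = FALSE], ytr[srcRows],
                              Xtr[tgtRows, , drop = FALSE], ytr[tgtRows], bc,
                              kmmWeights = kmmW),
                Xte)
      })
    cf <- .confusion(pred, tgtTest@labels)
    confTotal <- confTotal + cf
    accs[s] <- accuracyFromCounts(cf["TP"], cf["TN"], cf["FP"], cf["FN"])
    .Random.seed_restore(old)
  }
  new("EvaluationReport", subject = targetSubject,
      featureMode = cfg@featureMode, classifierMode = cfg@classifierMode,
      accuracies = accs, meanAccuracy = mean(accs),
      sdAccuracy = if (length(accs) > 1) stats::sd(accs) else 0,
      confusion = confTotal, seeds = cfg@seeds)
}

#' Leave-one-subject-out evaluation
#'
#' Runs [runTransferExperiment()] once with every subject as the target and
#' the remaining subjects pooled as the source domain.
#'
#' @param cohort a [Cohort-class] with at least two subjects.
#' @param cfg an [ExperimentConfig-class].
#' @param spectralCache optional [cohortSpectralCache()] result; computed once
#'   here when needed.
#' @return A named list of [EvaluationReport-class]s, one per target subject.
#' @seealso [losoSummary()]
#' @export
runLoso <- function(cohort, cfg = ExperimentConfig(), spectralCache = NULL) {
  stopifnot(is(cohort, "Cohort"))
  if (length(cohort@subjects) < 2L)
    stop("LOSO needs at least two subjects")
  if (is.null(spectralCache) && cfg@featureMode != "csp")
    spectralCache <- cohortSpectralCache(cohort, cfg@welch, cfg@bands)
  reports <- lapply(names(cohort@subjects), function(sj)
    runTransferExperiment(cohort, sj, cfg, spectralCache))
  names(reports) <- names(cohort@subjects)
  reports
}

#' Summarize LOSO reports
#'
#' Per-subject mean and SD accuracy plus an aggregate `Mean` row (mean and SD
#' across subjects), mirroring the usual per-subject accuracy tables.
#'
#' @param reports list of [EvaluationReport-class]s from [runLoso()].
#' @return A data.frame with columns `subject`, `meanAccuracy`, `sdAccuracy`.
#' @export
losoSummary <- function(reports) {
  mns <- vapply(reports, meanAccuracy, numeric(1))
  sds <- vapply(reports, function(r) r@sdAccuracy, numeric(1))
  rbind(
    data.frame(subject = names(reports), meanAccuracy = unname(mns),
               sdAccuracy = unname(sds)),
    data.frame(subject = "Mean", meanAccuracy = mean(mns),
               sdAccuracy = stats::sd(mns)))
}
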