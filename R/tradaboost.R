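## TrAdaBoost instance transfer: source samples misclassified by the current
## weak hypothesis are down-weighted by the fixed Hedge rate beta (they look
## unlike the target domain), misclassified target samples are up-weighted by
## 1/beta_t (AdaBoost style), and the strong classifier votes with weights
## ln(1/beta_t) over the second half of iterations. Initial weights are
## either the uniform 1/n (source), 1/m (target) scheme or KMM-seeded.

.BETA_T_FLOOR <- 1e-10

## ---- weak learners --------------------------------------------------------

.fitWeak <- function(kind, X, y01, w) {
  df <- data.frame(y = factor(y01, levels = c(0, 1)), X)
  switch(kind,
    tree = rpart::rpart(y ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = 2, minsplit = 5,
                                     minbucket = 2, cp = 1e-4, xval = 0)),
    stump = rpart::rpart(y ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = 1, minsplit = 5,
                                     minbucket = 2, cp = 1e-4, xval = 0)),
    logistic = suppressWarnings(
      stats::glm(y ~ ., data = df, weights = w, family = stats::quasibinomial())),
    stop("unknown weak learner: ", kind))
}

.predictWeak <- function(kind, fit, X) {
  df <- data.frame(X)
  if (kind == "logistic")
    as.numeric(stats::predict(fit, newdata = df, type = "response") >= 0.5)
  else
    as.numeric(as.character(stats::predict(fit, newdata = df, type = "class")))
}

# the weak learner must honor per-sample weights: at duplicated feature
# locations carrying conflicting labels, the heavily weighted label must win
.checkWeightContract <- function(kind) {
  X <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), 4, 2)
  colnames(X) <- c("f1", "f2")
  y <- c(0, 1, 0, 1)
  pr <- .predictWeak(kind, .fitWeak(kind, X, y, c(1, 1e-8, 1, 1e-8)), X)
  if (!all(pr == 0))
    stop("weak learner '", kind, "' does not honor per-sample weights")
  invisible(TRUE)
}

## ---- boosting primitives --------------------------------------------------

#' Initial TrAdaBoost sample weights
#'
#' Uniform mode assigns `1/n` to each of the `n` source samples and `1/m` to
#' each of the `m` target samples. KMM mode replaces the source entries with
#' the KMM importance weights normalized to unit total mass (so source and
#' target carry one unit of mass each); with all-equal KMM weights it
#' reproduces the uniform scheme exactly.
#'
#' @param n,m source and target sample counts (>= 1).
#' @param mode `"uniform"` or `"kmm"`.
#' @param kmmWeights a [SourceWeightVector-class] or numeric vector of length
#'   `n`; required iff `mode = "kmm"`.
#' @return A numeric weight vector of length `n + m` (source entries first).
#' @export
initWeights <- function(n, m, mode = c("uniform", "kmm"), kmmWeights = NULL) {
  mode <- match.arg(mode)
  if (n < 1 || m < 1) stop("n and m must be at least 1")
  if (mode == "uniform")
    return(c(rep(1 / n, n), rep(1 / m, m)))
  if (is.null(kmmWeights))
    stop("mode = 'kmm' requires kmmWeights")
  b <- if (is(kmmWeights, "SourceWeightVector"))
    kmmWeights@weights else as.numeric(kmmWeights)
  if (length(b) != n) stop("kmmWeights must have length n")
  c(b / sum(b), rep(1 / m, m))
}

#' Hedge down-weighting rate for source samples
#'
#' `beta = 1 / (1 + sqrt(2 ln(n) / N))`: the fixed factor by which a
#' misclassified source sample's weight shrinks. Lies in (0, 1], decreasing
#' in the source count `n` and increasing in the iteration budget `N`.
#'
#' @param n source sample count (>= 1).
#' @param N boosting iterations (>= 1).
#' @return The rate beta.
#' @examples
#' betaSource(100, 10)  # ~0.51028
#' @export
betaSource <- function(n, N) {
  if (n < 1 || N < 1) stop("n and N must be at least 1")
  1 / (1 + sqrt(2 * log(n) / N))
}

#' Weighted target-domain error rate
#'
#' `eps_t = sum_i w_i |h(x_i) - c(x_i)| / sum_i w_i` over the target-domain
#' training samples only.
#'
#' @param predicted,actual 0/1 hypothesis outputs and true labels on the
#'   target training samples.
#' @param weights current positive target-sample weights.
#' @return The error rate in [0, 1].
#' @export
weightedError <- function(predicted, actual, weights) {
  if (any(weights < 0) || sum(weights) <= 0)
    stop("target weights must be positive with positive total mass")
  sum(weights * abs(predicted - actual)) / sum(weights)
}

#' One TrAdaBoost weight update
#'
#' Source sample `i` is multiplied by `beta^{err_i}` (misclassified source
#' weights shrink, since `beta < 1`); target sample `i` is multiplied by
#' `betaT^{-err_i}` (misclassified target weights grow, since `betaT < 1`).
#' Correctly classified samples are unchanged.
#'
#' @param weights length `n + m` weight vector, source entries first.
#' @param n source sample count.
#' @param errors 0/1 misclassification indicators, aligned with `weights`.
#' @param beta Hedge rate from [betaSource()].
#' @param betaT iteration rate `eps_t / (1 - eps_t)`.
#' @return The updated weight vector.
#' @export
updateWeights <- function(weights, n, errors, beta, betaT) {
  if (length(errors) != length(weights))
    stop("errors must align with weights")
  src <- seq_len(n)
  tgt <- setdiff(seq_along(weights), src)
  weights[src] <- weights[src] * beta^errors[src]
  weights[tgt] <- weights[tgt] * betaT^(-errors[tgt])
  weights
}

## ---- fitting and prediction ----------------------------------------------

#' Fit the TrAdaBoost instance-transfer ensemble
#'
#' Runs up to `cfg@nIterations` boosting rounds over the pooled source +
#' target training samples: normalize weights, fit the weak learner with the
#' current weights, measure the weighted error on the target portion, then
#' shrink misclassified source weights by the fixed Hedge rate and grow
#' misclassified target weights by `1/beta_t`. Rounds whose target error
#' reaches 0.5 trigger early stopping (the ensemble keeps the completed
#' rounds); a zero error floors `beta_t` at a small constant. Deterministic
#' given `cfg@seed`.
#'
#' @param Xs,ys source features (n x d) and labels in \{1, 2\}.
#' @param Xt,yt target training features (m x d) and labels in \{1, 2\}.
#' @param cfg a [BoostConfig-class].
#' @param init optional length `n + m` initial weight vector; defaults to
#'   [initWeights()] under `cfg@initMode`.
#' @param kmmWeights KMM weights forwarded to [initWeights()] when
#'   `cfg@initMode = "kmm"` and `init` is not given.
#' @return A [StrongClassifier-class].
#' @examples
#' set.seed(1)
#' Xs <- matrix(rnorm(80), 40); ys <- rep(1:2, 20)
#' Xs[ys == 2, 1] <- Xs[ys == 2, 1] + 2
#' Xt <- Xs + 0.2; yt <- ys
#' model <- fitTrAdaBoost(Xs, ys, Xt, yt, BoostConfig(nIterations = 5))
#' table(predict(model, Xt), yt)
#' @export
fitTrAdaBoost <- function(Xs, ys, Xt, yt, cfg = BoostConfig(), init = NULL,
                          kmmWeights = NULL) {
  stopifnot(is(cfg, "BoostConfig"))
  validObject(cfg)
  Xs <- as.matrix(Xs); Xt <- as.matrix(Xt)
  n <- nrow(Xs); m <- nrow(Xt)
  if (!setequal(unique(c(ys, yt)), c(1, 2)) ||
      !all(c(ys, yt) %in% c(1, 2)))
    stop("source and target labels must share the two classes {1, 2}")
  .checkWeightContract(cfg@weakLearner)
  if (is.null(init))
    init <- if (n > 0) initWeights(n, m, cfg@initMode, kmmWeights)
            else rep(1 / m, m)
  if (length(init) != n + m)
    stop("init must have length n + m")

  X <- rbind(Xs, Xt)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  y01 <- c(ys, yt) - 1
  tgt <- n + seq_len(m)
  N <- as.integer(cfg@nIterations)
  # degenerate n = 0 reduces the loop to target-only AdaBoost; beta is unused
  beta <- if (n > 0) betaSource(n, N) else 1

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(cfg@seed %% .Machine$integer.max))

  w <- init
  hyps <- list(); betas <- numeric(); epss <- numeric()
  for (t in seq_len(N)) {
    w <- w / sum(w)
    h <- .fitWeak(cfg@weakLearner, X, y01, w)
    pr <- .predictWeak(cfg@weakLearner, h, X)
    err <- abs(pr - y01)
    epsT <- weightedError(pr[tgt], y01[tgt], w[tgt])
    if (epsT >= 0.5) {
      if (!length(hyps))
        stop("first weak hypothesis is no better than chance on the target ",
             "portion; cannot boost")
      warning(sprintf(
        "target error reached %.3f at iteration %d; stopping early with %d rounds",
        epsT, t, t - 1L))
      break
    }
    betaT <- if (epsT == 0) .BETA_T_FLOOR else epsT / (1 - epsT)
    w <- updateWeights(w, n, err, beta, betaT)
    hyps[[t]] <- h; betas[t] <- betaT; epss[t] <- epsT
  }
  completed <- length(hyps)
  under <- completed < ceiling(N / 2)
  if (under)
    warning("ensemble is under-trained: ", completed, " of ", N,
            " iterations completed")
  new("StrongClassifier", hypotheses = hyps, betas = betas, epsilons = epss,
      nIterations = as.numeric(completed), weakLearner = cfg@weakLearner,
      underTrained = under)
}

#' Predict with the boosted strong classifier
#'
#' Weighted vote over the second half of the completed iterations
#' (`t = ceiling(N/2) .. N`): output 1 when
#' `sum_t ln(1/beta_t) h_t(x) >= 1/2 sum_t ln(1/beta_t)`, ties resolving to
#' 1; the 0/1 outputs are mapped back to class labels \{1, 2\}.
#'
#' @param object a [StrongClassifier-class].
#' @param newdata feature matrix with the training dimensionality.
#' @param ... ignored.
#' @return Numeric class labels in \{1, 2\}.
#' @export
setMethod("predict", "StrongClassifier", function(object, newdata, ...) {
  N <- as.integer(object@nIterations)
  if (N < 1) stop("the voting set is empty; the model has no hypotheses")
  newdata <- as.matrix(newdata)
  colnames(newdata) <- paste0("f", seq_len(ncol(newdata)))
  voters <- seq.int(ceiling(N / 2), N)
  alpha <- log(1 / object@betas[voters])
  score <- numeric(nrow(newdata))
  for (t in voters)
    score <- score + log(1 / object@betas[t]) *
      .predictWeak(object@weakLearner, object@hypotheses[[t]], newdata)
  as.numeric(score >= sum(alpha) / 2) + 1
})
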