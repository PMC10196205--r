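## Common spatial patterns: trace-normalized class covariances, whitening of
## the composite covariance, simultaneous diagonalization, and normalized
## variance-ratio features along the retained filters.

#' Trace-normalized class covariance matrices
#'
#' For each class, averages the per-trial spatial covariance
#' `X X' / trace(X X')` over trials. Trace normalization removes per-trial
#' gain, so each class average is symmetric positive semidefinite with unit
#' trace.
#'
#' @param epochs an [EpochSet-class] containing both classes.
#' @return A list with SPD matrices `C1` and `C2` (channels x channels).
#' @export
classCovariances <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  labs <- epochs@labels
  if (!all(c(1, 2) %in% labs))
    stop("both class labels (1 and 2) must be present")
  k <- nChannels(epochs)
  avg <- function(idx) {
    C <- matrix(0, k, k)
    for (i in idx) {
      X <- epochs@data[i, , , drop = TRUE]
      if (k == 1L) X <- matrix(X, 1L)
      S <- tcrossprod(X)
      tr <- sum(diag(S))
      if (tr <= 0)
        stop(sprintf("trial %d has zero trace (degenerate all-zero trial)", i))
      C <- C + S / tr
    }
    C / length(idx)
  }
  list(C1 = avg(which(labs == 1)), C2 = avg(which(labs == 2)))
}

#' Whitening transform of a covariance matrix
#'
#' Builds the symmetric whitener `R = U Lambda^{-1/2} U'` from the
#' eigendecomposition `Hc = U Lambda U'`, so that `R Hc R' = I`. The
#' symmetric form is used (rather than `Lambda^{-1/2} U'`) because it is
#' canonical: it returns the identity for `Hc = I` and does not depend on the
#' arbitrary eigenbasis chosen within degenerate eigenvalue blocks.
#'
#' @param Hc symmetric positive definite matrix.
#' @param tol relative eigenvalue tolerance below which the matrix is treated
#'   as rank deficient.
#' @return The whitening matrix `R`.
#' @export
whitenCovariance <- function(Hc, tol = 1e-10) {
  Hc <- (Hc + t(Hc)) / 2
  eg <- eigen(Hc, symmetric = TRUE)
  if (any(eg$values < tol * max(eg$values)))
    stop("covariance is rank deficient; remove redundant channels or add ",
         "diagonal shrinkage (gamma > 0)")
  eg$vectors %*% diag(1 / sqrt(eg$values), nrow(Hc)) %*% t(eg$vectors)
}

#' Fit CSP spatial filters from two class covariances
#'
#' Whitens the composite covariance `Hc = C1 + C2`, eigendecomposes the
#' whitened class-1 covariance `R C1 R' = Q P Q'`, and takes the filter rows
#' `W = Q' R`. In this basis the two class covariances are simultaneously
#' diagonal with eigenvalue pairs summing to 1, so filters at the extremes of
#' the spectrum maximize the between-class variance ratio. The `m/2` filters
#' with the largest and `m/2` with the smallest eigenvalues are retained and
#' sorted by decreasing discriminability `|lambda - 0.5|`.
#'
#' @param C1,C2 class covariance matrices (see [classCovariances()]).
#' @param m even number of filters to retain, `2 <= m <= channels`.
#' @param gamma optional diagonal-loading shrinkage added to `Hc` (fraction of
#'   its mean diagonal), for rank-deficient montages.
#' @return A [SpatialFilterBank-class].
#' @examples
#' C1 <- diag(c(0.9, 0.1)); C2 <- diag(c(0.1, 0.9))
#' fitFilters(C1 / sum(diag(C1)), C2 / sum(diag(C2)), m = 2)
#' @export
fitFilters <- function(C1, C2, m, gamma = 0) {
  k <- nrow(C1)
  if (m %% 2 != 0 || m < 2 || m > k)
    stop("m must be even with 2 <= m <= channels")
  Hc <- C1 + C2
  if (gamma > 0) Hc <- Hc + diag(gamma * mean(diag(Hc)), k)
  R <- whitenCovariance(Hc)
  S1 <- R %*% C1 %*% t(R)
  eg <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)  # descending eigenvalues
  W <- t(eg$vectors) %*% R
  lambda <- pmin(pmax(eg$values, 0), 1)
  keep <- c(seq_len(m / 2), k - seq_len(m / 2) + 1L)
  ord <- keep[order(abs(lambda[keep] - 0.5), decreasing = TRUE)]
  new("SpatialFilterBank", filters = W[ord, , drop = FALSE],
      eigenvalues = lambda[ord], whitener = R, m = as.numeric(m))
}

#' CSP variance-ratio features
#'
#' Projects each trial onto the retained spatial filters, computes the
#' per-filter variance over samples, and normalizes by the sum over filters:
#' `f_j = var(Z_j) / sum_j var(Z_j)`. Rows sum to 1 and are invariant to
#' per-trial gain.
#'
#' @param bank a [SpatialFilterBank-class].
#' @param epochs an [EpochSet-class] with the bank's channel count.
#' @return A [SpatialFeatureBlock-class] (trials x m).
#' @export
spatialFeatures <- function(bank, epochs) {
  stopifnot(is(bank, "SpatialFilterBank"), is(epochs, "EpochSet"))
  if (ncol(bank@filters) != nChannels(epochs))
    stop("filter bank channel count does not match the epochs")
  n <- nTrials(epochs)
  vals <- matrix(0, n, bank@m)
  for (i in seq_len(n)) {
    X <- epochs@data[i, , , drop = TRUE]
    if (nChannels(epochs) == 1L) X <- matrix(X, 1L)
    Z <- bank@filters %*% X
    v <- rowSums((Z - rowMeans(Z))^2) / (ncol(Z) - 1L)
    vals[i, ] <- v / sum(v)
  }
  new("SpatialFeatureBlock", values = vals, m = bank@m)
}
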