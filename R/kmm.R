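## Kernel mean matching: importance weights for source-domain trials chosen
## so the re-weighted source mean embedding approaches the target mean
## embedding in the RKHS of a Gaussian kernel. The quadratic program
##   min 1/2 b' K b - kappa' b,  0 <= b <= B,  |sum(b) - n| <= n * eps
## (K = k(Xs, Xs), kappa_i = (n/p) sum_j k(x_i, x_j^t)) is solved with the
## interior-point solver kernlab::ipop.

#' Gaussian kernel matrix
#'
#' `K(x, y) = exp(-||x - y||^2 / (2 sigma^2))`; symmetric with unit diagonal
#' when `X` and `Y` coincide, entries in (0, 1].
#'
#' @param X,Y numeric feature matrices (rows = samples) with equal column
#'   count; vectors are treated as single-column matrices.
#' @param sigma kernel width, > 0.
#' @return The `nrow(X) x nrow(Y)` kernel matrix.
#' @export
gaussianKernel <- function(X, Y, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y))
    stop("X and Y must have the same feature dimension")
  if (sigma <= 0) stop("sigma must be positive")
  d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Median-heuristic kernel width
#'
#' The median of the pairwise Euclidean distances over a (seeded) subsample of
#' at most `maxRows` rows, excluding zero distances, a standard default for
#' Gaussian-kernel methods.
#'
#' @param X pooled feature matrix (rows = samples), at least two distinct rows.
#' @param maxRows subsample cap for the pairwise-distance computation.
#' @param seed seed for the subsample draw.
#' @return A strictly positive width.
#' @export
medianHeuristicSigma <- function(X, maxRows = 1000L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("at least two rows required")
  if (nrow(X) > maxRows) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    X <- X[sample.int(nrow(X), maxRows), , drop = FALSE]
  }
  d <- as.numeric(stats::dist(X))
  d <- d[d > 0]
  if (!length(d))
    stop("all rows are identical; the kernel width is undefined")
  stats::median(d)
}

#' Squared maximum mean discrepancy at given weights
#'
#' Direct kernel-sum evaluation of
#' `|| (1/n) sum_i beta_i Phi(x_i^s) - (1/p) sum_j Phi(x_j^t) ||^2`,
#' the objective that [solveWeights()] minimizes; non-negative up to solver
#' tolerance since it is an RKHS norm.
#'
#' @param Xs,Xt source and target feature matrices.
#' @param weights length-`nrow(Xs)` weight vector (uniform = all 1).
#' @param sigma Gaussian kernel width.
#' @return The squared MMD (a single non-negative number).
#' @export
mmdSquared <- function(Xs, Xt, weights, sigma) {
  Xs <- as.matrix(Xs); Xt <- as.matrix(Xt)
  n <- nrow(Xs); p <- nrow(Xt)
  if (length(weights) != n)
    stop("weights must have one entry per source row")
  Kss <- gaussianKernel(Xs, Xs, sigma)
  Kst <- gaussianKernel(Xs, Xt, sigma)
  Ktt <- gaussianKernel(Xt, Xt, sigma)
  drop(crossprod(weights, Kss %*% weights)) / n^2 -
    2 * sum(weights * rowSums(Kst)) / (n * p) +
    sum(Ktt) / p^2
}

#' Kernel mean matching weights
#'
#' Solves the KMM quadratic program for per-source-trial importance weights:
#' minimize `1/2 beta' K beta - kappa' beta` over the box `0 <= beta_i <= B`
#' with the mean-preservation constraint `|sum(beta) - n| <= n * eps`
#' (dropped when `eps = Inf`, leaving the literal `[0, B]` box). A diagonal
#' ridge (see [KernelConfig-class]) regularizes the degenerate program toward
#' its smooth solution. The achieved squared MMD
#' (including the weight-independent target term) is recomputed from the
#' returned weights by [mmdSquared()].
#'
#' @param Xs,Xt source (n x d) and target (p x d) feature matrices, n, p >= 2.
#' @param cfg a [KernelConfig-class]; `sigma = NA` resolves to
#'   [medianHeuristicSigma()] on the pooled rows.
#' @return A [SourceWeightVector-class].
#' @examples
#' set.seed(1)
#' Xs <- matrix(rnorm(100), 50); Xt <- matrix(rnorm(100, 0.5), 50)
#' w <- solveWeights(Xs, Xt, KernelConfig(sigma = 1))
#' mean(importanceWeights(w))
#' @export
solveWeights <- function(Xs, Xt, cfg = KernelConfig()) {
  stopifnot(is(cfg, "KernelConfig"))
  Xs <- as.matrix(Xs); Xt <- as.matrix(Xt)
  n <- nrow(Xs); p <- nrow(Xt)
  if (n < 2L || p < 2L) stop("need at least two source and two target rows")
  if (!all(is.finite(Xs)) || !all(is.finite(Xt)))
    stop("features must be finite")
  sigma <- if (is.na(cfg@sigma))
    medianHeuristicSigma(rbind(Xs, Xt)) else cfg@sigma

  K0 <- gaussianKernel(Xs, Xs, sigma)
  kappa <- (n / p) * rowSums(gaussianKernel(Xs, Xt, sigma))
  if (is.finite(cfg@eps)) {
    b <- n * (1 - cfg@eps); r <- 2 * n * cfg@eps
  } else {
    b <- 0; r <- n * cfg@B  # sum(beta) is free inside [0, n B]
  }
  # the ridge regularizes the (often degenerate) program toward the smooth
  # solution; if the solve still fails numerically, escalate the loading
  sol <- NULL
  for (jitter in unique(pmax(cfg@ridge, c(1e-8, 1e-6, 1e-4, 1e-2, 1)))) {
    sol <- tryCatch(
      kernlab::ipop(c = matrix(-kappa, ncol = 1), H = K0 + diag(jitter, n),
                    A = matrix(1, 1, n), b = b, r = r,
                    l = matrix(0, n, 1), u = matrix(cfg@B, n, 1),
                    sigf = 9, maxiter = 100),
      error = function(e) NULL)
    if (!is.null(sol) &&
        kernlab::how(sol) %in% c("converged", "sigf and maxiter exceeded"))
      break
    sol <- NULL
  }
  if (is.null(sol))
    stop("KMM quadratic program did not converge even with diagonal loading")
  beta <- pmin(pmax(drop(kernlab::primal(sol)), 0), cfg@B)
  new("SourceWeightVector", weights = beta,
      objective = mmdSquared(Xs, Xt, beta, sigma),
      sigma = sigma, config = cfg)
}
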