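# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive and separate from the implementation paths they check.

# Averaged one-sided tapered periodogram, coded directly from the definition:
# mean over segments of |FFT(x * w)|^2 / (N * U * fs), interior bins doubled.
oracleWelch <- function(x, N, fs, window = rep(1, N), overlap = 0) {
  U <- mean(window^2)
  step <- round(N * (1 - overlap))
  starts <- seq(1, length(x) - N + 1, by = step)
  nb <- N %/% 2 + 1
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + N - 1)] * window
    sp <- Mod(fft(seg)[1:nb])^2 / (N * U * fs)
    hi <- nb - if (N %% 2 == 0) 1 else 0
    if (hi >= 2) sp[2:hi] <- 2 * sp[2:hi]
    acc <- acc + sp
  }
  acc / length(starts)
}

# Variance-ratio spectrum of the generalized eigenproblem C1 v = lambda (C1+C2) v,
# solved by brute force on the non-symmetric matrix solve(C1+C2) %*% C1.
oracleGeneralizedEigenvalues <- function(C1, C2) {
  ev <- eigen(solve(C1 + C2) %*% C1, only.values = TRUE)$values
  sort(Re(ev), decreasing = TRUE)
}

# Squared MMD from first principles: explicit double sums over kernel entries.
oracleMmd <- function(Xs, Xt, beta, sigma) {
  n <- nrow(Xs); p <- nrow(Xt)
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  s1 <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s1 <- s1 + beta[i] * beta[j] * k(Xs[i, ], Xs[j, ])
  s2 <- 0
  for (i in seq_len(n)) for (j in seq_len(p))
    s2 <- s2 + beta[i] * k(Xs[i, ], Xt[j, ])
  s3 <- 0
  for (i in seq_len(p)) for (j in seq_len(p))
    s3 <- s3 + k(Xt[i, ], Xt[j, ])
  s1 / n^2 - 2 * s2 / (n * p) + s3 / p^2
}

# random SPD matrix with unit trace
randomSpd <- function(k) {
  A <- matrix(rnorm(k * k), k)
  S <- crossprod(A) + diag(0.1, k)
  S / sum(diag(S))
}

# target-only AdaBoost reference (stump weak learner), mirroring the boosting
# loop with no source samples: error and update computed on all (= target)
# samples, vote over the second half of iterations
referenceAdaBoost <- function(X, y01, N) {
  w <- rep(1 / nrow(X), nrow(X))
  hyps <- list(); betas <- numeric()
  df <- data.frame(y = factor(y01, levels = c(0, 1)), X)
  for (t in seq_len(N)) {
    w <- w / sum(w)
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = 1, minsplit = 5,
                                     minbucket = 2, cp = 1e-4, xval = 0))
    pr <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- abs(pr - y01)
    eps <- sum(w * err) / sum(w)
    if (eps >= 0.5) break
    bt <- if (eps == 0) 1e-10 else eps / (1 - eps)
    w <- w * bt^(-err)
    hyps[[t]] <- fit; betas[t] <- bt
  }
  list(hypotheses = hyps, betas = betas)
}

referenceAdaBoostPredict <- function(model, X) {
  N <- length(model$hypotheses)
  voters <- seq(ceiling(N / 2), N)
  alpha <- log(1 / model$betas[voters])
  df <- data.frame(X)
  score <- numeric(nrow(df))
  for (t in voters)
    score <- score + log(1 / model$betas[t]) *
      as.numeric(as.character(predict(model$hypotheses[[t]], df,
                                      type = "class")))
  as.numeric(score >= sum(alpha) / 2)
}
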