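test_that("class covariances are trace-normalized per-trial averages", {
  set.seed(1)
  # single trial per class: exactly X X' / trace
  X1 <- matrix(rnorm(8), 2); X2 <- matrix(rnorm(8), 2)
  es <- epochsFromTrials(list(X1, X2), c(1, 2))
  cc <- classCovariances(es)
  expect_equal(cc$C1, tcrossprod(X1) / sum(diag(tcrossprod(X1))),
               tolerance = 1e-12)
  expect_equal(sum(diag(cc$C2)), 1, tolerance = 1e-12)

  # per-trial gain invariance
  es2 <- epochsFromTrials(list(10 * X1, X2), c(1, 2))
  expect_equal(classCovariances(es2)$C1, cc$C1, tolerance = 1e-12)

  # white noise through identity mixing tends to I/k
  esw <- mixedNoiseEpochs(400, diag(4), samples = 100)
  ccw <- classCovariances(esw)
  expect_lt(max(abs(ccw$C1 - diag(4) / 4)), 0.02)
  expect_lt(max(abs(ccw$C2 - diag(4) / 4)), 0.02)

  # degenerate inputs
  es1 <- epochsFromTrials(list(X1, X2), c(1, 1))
  expect_error(classCovariances(es1), "both class labels")
  esz <- epochsFromTrials(list(X1, matrix(0, 2, 4)), c(1, 2))
  expect_error(classCovariances(esz), "zero trace")
})

test_that("whitening satisfies R Hc R' = I and matches closed forms", {
  expect_equal(whitenCovariance(diag(2)), diag(2), tolerance = 1e-12)
  expect_equal(whitenCovariance(diag(c(4, 1))), diag(c(0.5, 1)),
               tolerance = 1e-12)
  set.seed(2)
  for (k in c(2, 5, 9)) {
    Hc <- randomSpd(k)
    R <- whitenCovariance(Hc)
    expect_lt(max(abs(R %*% Hc %*% t(R) - diag(k))), 1e-10)
  }
  singular <- tcrossprod(c(1, 1))
  expect_error(whitenCovariance(singular), "rank deficient")
})

test_that("CSP filters simultaneously diagonalize and match the 2x2 closed form", {
  C1 <- diag(c(0.9, 0.1)); C2 <- diag(c(0.1, 0.9))
  bank <- fitFilters(C1, C2, 2)
  expect_equal(sort(filterEigenvalues(bank)), c(0.1, 0.9), tolerance = 1e-10)
  # filters align with the coordinate axes
  W <- spatialFilters(bank)
  expect_equal(abs(W) / max(abs(W)), rbind(c(1, 0), c(0, 1)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # equal covariances: nothing is discriminative
  bankEq <- fitFilters(diag(3) / 3, diag(3) / 3, 2)
  expect_equal(filterEigenvalues(bankEq), c(0.5, 0.5), tolerance = 1e-8)

  expect_error(fitFilters(C1, C2, 3), "even")
  expect_error(fitFilters(C1, C2, 8), "channels")
})

test_that("CSP agrees with the generalized-eigendecomposition oracle", {
  set.seed(3)
  for (rep in 1:100) {
    k <- 2 * sample(1:6, 1)          # channels in 2..12
    C1 <- randomSpd(k); C2 <- randomSpd(k)
    bank <- fitFilters(C1, C2, k)    # full spectrum
    lam <- sort(filterEigenvalues(bank), decreasing = TRUE)
    expect_equal(lam, oracleGeneralizedEigenvalues(C1, C2), tolerance = 1e-8)

    # simultaneous diagonalization with complementary unit sums
    W <- spatialFilters(bank)
    D1 <- W %*% C1 %*% t(W); D2 <- W %*% C2 %*% t(W)
    expect_lt(max(abs(D1 - diag(diag(D1)))), 1e-8)
    expect_lt(max(abs(D2 - diag(diag(D2)))), 1e-8)
    expect_equal(diag(D1) + diag(D2), rep(1, k), tolerance = 1e-8)
    expect_equal(filterEigenvalues(bank),
                 diag(D1) / (diag(D1) + diag(D2)), tolerance = 1e-8)
  }
})

test_that("variance-ratio features sum to one, ignore gain, and discriminate", {
  set.seed(4)
  A1 <- diag(c(3, 1)); A2 <- diag(c(1, 3))   # class-dependent channel power
  trials <- c(lapply(1:100, function(i) A1 %*% matrix(rnorm(400), 2)),
              lapply(1:100, function(i) A2 %*% matrix(rnorm(400), 2)))
  es <- epochsFromTrials(trials, rep(c(1, 2), each = 100))
  cc <- classCovariances(es)
  bank <- fitFilters(cc$C1, cc$C2, 2)
  f <- featureValues(spatialFeatures(bank, es))
  expect_equal(rowSums(f), rep(1, 200), tolerance = 1e-12)

  # per-trial gain invariance
  esScaled <- epochsFromTrials(lapply(trials, function(x) 7 * x),
                               rep(c(1, 2), each = 100))
  expect_equal(featureValues(spatialFeatures(bank, esScaled)), f,
               tolerance = 1e-10)

  # the class-1-dominant filter (largest eigenvalue) separates the classes
  j1 <- which.max(filterEigenvalues(bank))
  j2 <- which.min(filterEigenvalues(bank))
  expect_gt(mean(f[1:100, j1]), mean(f[1:100, j2]))
  expect_lt(mean(f[101:200, j1]), mean(f[101:200, j2]))

  # channel-count mismatch
  es3 <- mixedNoiseEpochs(4, diag(3))
  expect_error(spatialFeatures(bank, es3), "channel count")
})
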