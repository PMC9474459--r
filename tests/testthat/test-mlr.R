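# The pseudo-inverse oracle: every quantity recomputed independently from
# first principles (MASS::ginv), against which fitMlr must agree.
mlrOracle <- function(X, y) {
  Z <- cbind(1, X)
  beta <- drop(MASS::ginv(t(Z) %*% Z) %*% t(Z) %*% y)
  yhat <- drop(Z %*% beta)
  n <- nrow(X); m <- ncol(X)
  ssreg <- sum((yhat - mean(y))^2)
  s <- sqrt(sum((y - yhat)^2) / (n - m - 1))
  Xc <- sweep(X, 2, colMeans(X))
  pjj <- diag(MASS::ginv(t(Xc) %*% Xc))
  vif <- vapply(seq_len(m), function(j) {
    if (m == 1) return(1)
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  list(beta = beta, R = sqrt(ssreg / sum((y - mean(y))^2)), s = s,
       seSlope = sqrt(pjj) * s, F = ssreg / (m * s^2), vif = vif)
}

test_that("fitMlr matches the pseudo-inverse oracle on random instances", {
  set.seed(20)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    m <- sample(1:5, 1)
    if (n <= m + 2) next
    X <- matrix(rnorm(n * m), n, m)
    y <- drop(X %*% rnorm(m)) + rnorm(n)
    fit <- fitMlr(X, y)
    orc <- mlrOracle(X, y)
    expect_equal(unname(coef(fit)), orc$beta, tolerance = 1e-8)
    expect_equal(fit@R, orc$R, tolerance = 1e-8)
    expect_equal(fit@s, orc$s, tolerance = 1e-8)
    expect_equal(unname(fit@se[-1]), orc$seSlope, tolerance = 1e-8)
    expect_equal(fit@F, orc$F, tolerance = 1e-8)
    expect_equal(unname(fit@vif), orc$vif, tolerance = 1e-6)
  }
})

test_that("fitMlr agrees with lm's coefficient table", {
  set.seed(7)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + drop(X %*% c(1, -1, 0.5)) + rnorm(40, sd = 0.3)
  fit <- fitMlr(X, y)
  lmf <- summary(lm(y ~ X))
  expect_equal(unname(coef(fit)), unname(coef(lmf)[, 1]), tolerance = 1e-10)
  expect_equal(unname(fit@se), unname(coef(lmf)[, 2]), tolerance = 1e-10)
  expect_equal(unname(fit@tValues), unname(coef(lmf)[, 3]), tolerance = 1e-10)
  expect_equal(fit@R2, lmf$r.squared, tolerance = 1e-12)
  expect_equal(fit@F, unname(lmf$fstatistic[1]), tolerance = 1e-10)
})

test_that("perfect fits, orthogonal designs and collinearity are flagged", {
  X <- matrix(c(1, 2, 3, 4, 5, 1, 0, 1, 0, 1), 5, 2,
              dimnames = list(NULL, c("u", "v")))
  y <- drop(X %*% c(2, -1)) + 3
  fit <- fitMlr(X, y)
  expect_equal(fit@R, 1)
  expect_equal(fit@s, 0)
  expect_true(all(is.infinite(fit@tValues[2:3])))

  # orthogonal centred predictors: VIF exactly 1
  Xo <- cbind(a = c(-1, -1, 1, 1, 0, 0), b = c(0, 0, 0, 0, -1, 1))
  yo <- rnorm(6)
  expect_equal(unname(fitMlr(Xo, yo)@vif), c(1, 1), tolerance = 1e-12)

  Xc <- cbind(p = 1:8, q = 2 * (1:8))
  expect_error(fitMlr(Xc, rnorm(8)), "collinear")
  expect_error(fitMlr(matrix(rnorm(6), 3, 2), rnorm(3)), "n > m \\+ 1")
})

test_that("calibration objects plug into fitMlr with default features", {
  sim <- simulateCalibration(n = 60, seed = 31)
  fit <- fitMlr(sim$dataset)
  expect_equal(fit@m, 8L)
  expect_identical(names(coef(fit))[-1], defaultMapFeatures())
  pred <- predictMlr(fit, sim$dataset)
  expect_equal(length(pred), 60L)
  expect_equal(unname(pred), unname(fit@fitted), tolerance = 1e-12)
})

test_that("evaluateFit reports the closed-form degenerate cases", {
  y <- c(1, 2, 3, 4)
  perf <- evaluateFit(y, y)
  expect_equal(perf$R2, 1)
  expect_equal(perf$RMSE, 0)
  flat <- evaluateFit(rep(mean(y), 4), y)
  expect_true(is.na(flat$R2))  # zero prediction variance flags NA
  expect_equal(flat$RMSE, sqrt(mean((y - mean(y))^2)))
  m <- evaluateFit(c(2, 2, 5), c(1, 2, 3))
  expect_equal(m$MAE, 1)
  expect_error(evaluateFit(1:3, 1:4), "equal length")
})

test_that("splitDataset is disjoint, exhaustive and seed-stable", {
  sim <- simulateCalibration(n = 712, seed = 12)
  sp <- splitDataset(sim$dataset, 179 / 712, seed = 3)
  expect_equal(ncol(sp$training), 533L)
  expect_equal(ncol(sp$validation), 179L)
  expect_length(intersect(colnames(sp$training), colnames(sp$validation)), 0)
  expect_setequal(c(colnames(sp$training), colnames(sp$validation)),
                  colnames(sim$dataset))
  sp2 <- splitDataset(sim$dataset, 179 / 712, seed = 3)
  expect_identical(colnames(sp2$validation), colnames(sp$validation))
  sp3 <- splitDataset(sim$dataset[, 1:10], 0.5, seed = 1)
  expect_equal(ncol(sp3$training), 5L)
})
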