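test_that("the Morlet transform localizes a pure sinusoid's period", {
  age <- 0:430
  x <- sin(2 * pi * age / 23)
  w <- cwtMorlet(x, step = 1)
  pw <- rowMeans(Mod(w$coef)^2 * !w$inCoi)
  peak <- w$period[which.max(pw)]
  # peak within one dyadic scale step of the true period
  expect_lt(abs(log2(peak / 23)), 0.11)

  const <- cwtMorlet(rep(3, 64), step = 1)
  expect_lt(max(Mod(const$coef)), 1e-10)

  expect_error(cwtMorlet(rnorm(8)), "too short")
  expect_error(crossWavelet(data.frame(age = c(0, 1, 3), value = 1:3),
                            data.frame(age = c(0, 1, 3), value = 1:3)),
               "uniform grid")
})

test_that("self-, flipped and lagged spectra give phases 0, pi, 2*pi*lag/P", {
  age <- 0:430
  s1 <- data.frame(age = age, value = sin(2 * pi * age / 23))
  cs <- crossWavelet(s1, s1)
  bp <- bandPhase(cs, 23)
  expect_equal(bp$meanPhase, 0, tolerance = 1e-10)
  expect_false(bp$antiPhase)
  # self-spectrum is real non-negative and equals the wavelet power
  expect_true(all(abs(Im(cs$cs)) < 1e-10))
  expect_equal(cs$amplitude, Mod(cs$w1$coef)^2, tolerance = 1e-12)

  s2 <- data.frame(age = age, value = -s1$value)
  bpf <- bandPhase(crossWavelet(s1, s2), 23)
  expect_equal(abs(bpf$meanPhase), pi, tolerance = 1e-6)
  expect_true(bpf$antiPhase)

  lag <- 5.75  # quarter period
  s3 <- data.frame(age = age, value = sin(2 * pi * (age - lag) / 23))
  bpl <- bandPhase(crossWavelet(s1, s3), 23)
  expect_equal(bpl$meanPhase, 2 * pi * lag / 23, tolerance = 0.1)
})

test_that("cross spectra are Hermitian and amplitude-linear", {
  set.seed(9)
  age <- 0:127
  s1 <- data.frame(age = age, value = sin(2 * pi * age / 16) + rnorm(128, 0, 0.2))
  s2 <- data.frame(age = age, value = cos(2 * pi * age / 16) + rnorm(128, 0, 0.2))
  ab <- crossWavelet(s1, s2)
  ba <- crossWavelet(s2, s1)
  expect_equal(ab$cs, Conj(ba$cs), tolerance = 1e-12)
  s1c <- s1; s1c$value <- -2.5 * s1$value
  sc <- crossWavelet(s1c, s2)
  expect_equal(sc$amplitude, 2.5 * ab$amplitude, tolerance = 1e-9)
})

test_that("bandPhase rejects unresolved or fully-masked bands", {
  age <- 0:430
  s <- data.frame(age = age, value = sin(2 * pi * age / 23))
  cs <- crossWavelet(s, s)
  expect_error(bandPhase(cs, 500), "outside the resolved range")
  # the longest resolved periods are entirely inside the cone
  long <- max(cs$period)
  expect_error(bandPhase(cs, long, bandTolerance = 0.01), "cone of influence")
})

test_that("planted anti-phase pairs are detected end to end", {
  ps <- simulatePairedSeries(periodKa = 23, phaseOffset = pi, seed = 3)
  bp <- bandPhase(crossWavelet(ps$s1, ps$s2), 23)
  expect_true(bp$antiPhase)
  ps0 <- simulatePairedSeries(periodKa = 23, phaseOffset = 0, noiseSd = 0,
                              seed = 3)
  bp0 <- bandPhase(crossWavelet(ps0$s1, ps0$s2), 23)
  expect_false(bp0$antiPhase)
  expect_equal(bp0$meanPhase, 0, tolerance = 1e-8)
})

test_that("pcaSummary reports variance fractions, loadings and errors", {
  set.seed(10)
  z <- rnorm(50)
  two <- cbind(a = z, b = 2 * z + 1)  # perfectly correlated pair
  res <- pcaSummary(two)
  expect_equal(res$varianceFraction[1], 1, tolerance = 1e-12)

  orth <- cbind(a = rep(c(-1, 1), 25), b = rep(c(-1, -1, 1, 1), length.out = 50))
  ro <- pcaSummary(orth)
  expect_equal(ro$varianceFraction, c(0.5, 0.5), tolerance = 0.05)

  # planted 2-factor structure in 4 observed factors
  f1 <- rnorm(80); f2 <- rnorm(80)
  X <- cbind(f1 + 0.05 * rnorm(80), f2 + 0.05 * rnorm(80),
             f1 - f2 + 0.05 * rnorm(80), f1 + f2 + 0.05 * rnorm(80))
  rx <- pcaSummary(X)
  expect_gt(sum(rx$varianceFraction[1:2]), 0.95)
  expect_equal(sum(rx$varianceFraction), 1, tolerance = 1e-12)
  expect_true(all(diff(rx$varianceFraction) <= 1e-12))
  expect_equal(crossprod(rx$loadings), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(pcaSummary(cbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance")
  expect_error(pcaSummary(matrix(1:4, 2, 2)), "at least 3 samples")
})
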