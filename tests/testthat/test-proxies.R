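test_that("methylation indices reproduce hand-computed values", {
  expect_equal(mbtPrime(c(Ia = 1)), 1)
  expect_equal(mbtPrime(c(IIIa = 1)), 0)
  expect_equal(mbtPrime(c(Ia = 0.2, IIa = 0.3, IIIa = 0.5)), 0.2)
  # IIIb/IIIc series sit outside the printed denominator
  expect_equal(mbtPrime(c(Ia = 0.5, "IIIb'" = 0.5)), 1)

  expect_equal(mbtPrime6Me(c(Ib = 1)), 1)
  expect_equal(mbtPrime6Me(c("IIa'" = 1)), 0)
  expect_equal(mbtPrime6Me(c(Ia = 0.4, "IIa'" = 0.4, IIIa = 0.2)), 0.5)

  expect_equal(ir6Me(c("IIa'" = 1)), 1)
  expect_equal(ir6Me(c(IIa = 0.5, "IIa'" = 0.5)), 0.5)
  expect_equal(ir6Me(c(Ia = 0.5, "IIa'" = 0.25, "IIIb'" = 0.25)), 0.5)
  # penta+hexa convention drops the tetramethylated pool
  expect_equal(ir6Me(c(Ia = 0.5, "IIa'" = 0.25, "IIIb'" = 0.25),
                     convention = "pentaHexa"), 1)
  expect_true(is.na(mbtPrime(c("IIIb'" = 1))))  # zero denominator flags NA
})

test_that("cyclization indices and pH follow the printed forms", {
  expect_equal(cbtPrime(c(Ia = 0.3, Ib = 0.1, Ic = 0.1, "IIa'" = 0.4)), 0,
               tolerance = 1e-12)  # numerator (Ic+IIa') == denominator
  expect_equal(cbtPrime(c(Ia = 0.5, Ib = 0.3, Ic = 0.2)),
               -log10(0.2 / 1.0), tolerance = 1e-12)
  # a ratio of one decade moves CBT' by -1 and pH by -1.59
  fa10 <- c(Ia = 1, "IIa'" = 10)
  expect_equal(cbtPrime(fa10), -1)
  expect_equal(phFromCbtPrime(cbtPrime(fa10)), 7.15 - 1.59)
  expect_equal(phFromCbtPrime(0), 7.15)
  expect_equal(phFromCbtPrime(1), 8.74)
  expect_equal(phFromCbtPrime(-1), 5.56)
  expect_true(is.na(cbtPrime(c(Ia = 1))))  # no cyclic/6-methyl numerator
  expect_equal(cbt(c(Ib = 0.5, IIb = 0.5, Ia = 0.5, IIa = 0.5)), 0)
})

test_that("temperature calibrations evaluate as printed", {
  zero <- c(IIIc = 1)  # none of the regression compounds present
  expect_equal(matMr(zero), 7.17)
  expect_equal(matMr(c(Ia = 1)), 7.17 + 17.1)
  expect_equal(matMr(c(Ia = 0.5, Ib = 0.1, Ic = 0.05, IIa = 0.2)), 14.31,
               tolerance = 1e-12)
  expect_equal(matMrSimple(zero), 5.58)
  expect_equal(matMrSimple(c(Ia = 1)), 23.49)
  expect_equal(matMrSimple(c(IIa = 1)), -13.19)
  expect_equal(matSsm(zero), 20.9)
  expect_equal(matSsm(c(Ib = 1)), 32.1)
  expect_equal(matSsm(c(IIa = 0.5, "IIa'" = 0.5)), 7.5)
  expect_equal(maatFromIndices(0, 0), 0.81)
  expect_equal(maatFromIndices(0, 1), 31.81)
  expect_equal(maatFromIndices(1, 0.5), 10.64)
  # CBT = 0 and MBT' = 0 simultaneously: IIa = IIb = 0.5
  expect_equal(maatWeijers(c(IIa = 0.5, IIb = 0.5)), 0.81)
})

test_that("n-alkane CPI and ACL behave on flat and skewed profiles", {
  flat <- setNames(rep(2, 12), paste0("C", 23:34))
  expect_equal(cpi(flat, 1), 1)
  expect_equal(cpi(flat, 2), 1)
  expect_equal(acl(flat), mean(c(23, 25, 27, 29, 31, 33)))
  oddOnly <- setNames(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
                      paste0("C", 23:34))
  expect_true(is.na(cpi(oddOnly, 1)))
  odd2 <- setNames(c(2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1), paste0("C", 23:34))
  expect_equal(cpi(odd2, 1), 2)
  expect_equal(acl(c(C29 = 5)), 29)
  expect_equal(acl(c(C31 = 3, C27 = 1)), 30)
})

test_that("ratio indices stay in [0,1] and respect invariances on random draws", {
  fa <- randomSimplex(500, seed = 42)
  for (f in list(mbtPrime, mbtPrime6Me, ir6Me)) {
    v <- f(fa)
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  }
  # CBT' is invariant under joint rescaling; pH strictly increasing in CBT'
  expect_equal(cbtPrime(fa * 37), cbtPrime(fa), tolerance = 1e-12)
  cb <- seq(-2, 2, length.out = 50)
  expect_true(all(diff(phFromCbtPrime(cb)) > 0))
  # MAT_mr strictly increasing in Ia at fixed other fractions
  base <- fullAbundanceVector()
  up <- base; up["Ia"] <- up["Ia"] + 0.1
  expect_gt(matMr(up), matMr(base))
})

test_that("the proxy suite aggregates with flags and alkane columns", {
  fa <- fullAbundanceVector()
  suite <- computeProxySuite(rbind(fa))
  expect_true(suite$swcInterpretable[1] == (suite$IR6ME[1] > 0.5))
  expect_false(any(is.na(suite[1, c("MBTp", "CBTp", "pH", "MATmr")])))

  # no 6-methyls: CBT' undefined propagates to pH, the rest computes
  no6 <- c(Ia = 0.5, Ib = 0.2, IIa = 0.3)
  s2 <- computeProxySuite(rbind(no6))
  expect_true(is.na(s2$CBTp) && is.na(s2$pH))
  expect_false(is.na(s2$MATmr))
  expect_false(s2$swcInterpretable)

  sim <- simulateDowncoreProfile(lengthKa = 80, seed = 11)
  s3 <- computeProxySuite(sim$profile)
  expect_true(all(c("CPI1", "CPI2", "ACL") %in% colnames(s3)))
  expect_equal(nrow(s3), 80L)
  expect_false(anyNA(s3$ACL))
})
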