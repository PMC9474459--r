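test_that("registry partitions the 15 compounds by methyl position", {
  reg <- compoundRegistry()
  expect_equal(nrow(reg), 15L)
  expect_identical(rownames(reg), gdgtCompounds())
  five <- fiveMethylCompounds()
  six <- sixMethylCompounds()
  tetra <- tetraCompounds()
  expect_setequal(c(five, six, tetra), gdgtCompounds())
  expect_length(intersect(five, six), 0)
  expect_length(intersect(five, tetra), 0)
  expect_identical(sort(six),
                   sort(c("IIa'", "IIb'", "IIc'", "IIIa'", "IIIb'", "IIIc'")))
  # positional isomers share the parent's ion mass; series masses step by 2
  expect_equal(unname(reg["IIa'", "ionMass"]), unname(reg["IIa", "ionMass"]))
  expect_equal(unname(reg["Ia", "ionMass"]) - unname(reg["Ib", "ionMass"]), 2L)
  expect_true(all(reg$ionMass[reg$methylation == "hexa"] %in%
                    c(1050L, 1048L, 1046L)))
})

test_that("prime and apostrophe spellings normalize to one canon", {
  expect_identical(normalizeCompoundNames(c("IIa′", "IIa'", " IIIc' ")),
                   c("IIa'", "IIa'", "IIIc'"))
  expect_identical(normalizeCompoundNames("depth"), "depth")
})

test_that("fractional abundances normalize areas and flag bad input", {
  one <- computeFractionalAbundances(c(Ia = 10), missingAsZero = TRUE)
  expect_equal(unname(one["Ia"]), 1)
  expect_equal(sum(one), 1)

  eq <- computeFractionalAbundances(setNames(rep(3, 15), gdgtCompounds()))
  expect_equal(unname(eq), rep(1 / 15, 15))

  tri <- computeFractionalAbundances(c(Ia = 3, IIa = 1, "IIIa'" = 1),
                                     missingAsZero = TRUE)
  expect_equal(unname(tri[c("Ia", "IIa", "IIIa'")]), c(0.6, 0.2, 0.2))

  expect_error(computeFractionalAbundances(c(Ia = 0), missingAsZero = TRUE),
               "empty sample")
  expect_error(computeFractionalAbundances(c(Ia = -1), missingAsZero = TRUE),
               "non-negative")
  # missing compounds are an error unless explicitly zeroed
  expect_error(computeFractionalAbundances(c(Ia = 1)), "missing compound")
})

test_that("fractional abundances are scale invariant", {
  areas <- setNames(runif(15, 1, 100), gdgtCompounds())
  base <- computeFractionalAbundances(areas)
  for (c0 in c(1e-6, 0.3, 7, 1e8)) {
    expect_equal(computeFractionalAbundances(areas * c0), base,
                 tolerance = 1e-12)
  }
})

test_that("internal-standard quantification follows the area ratio", {
  expect_equal(quantifyCompound(c(Ia = 50), "Ia", standardArea = 50,
                                missingAsZero = TRUE), 0.01157)
  expect_equal(quantifyCompound(c(Ia = 100), "Ia", standardArea = 50,
                                missingAsZero = TRUE), 0.02314)
  expect_equal(quantifyCompound(c(Ia = 0, Ib = 5), "Ia", standardArea = 10,
                                missingAsZero = TRUE), 0)
  expect_error(quantifyCompound(c(Ia = 1), "Ia", standardArea = 0,
                                missingAsZero = TRUE), "internal standard")
  expect_error(quantifyCompound(c(Ia = 1), "Ia", missingAsZero = TRUE),
               "internal standard")
})
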