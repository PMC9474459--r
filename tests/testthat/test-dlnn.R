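test_that("relu and its derivative follow the printed case split", {
  expect_equal(relu(c(-3, 0, 5)), c(0, 0, 5))
  expect_equal(reluGrad(c(-3, 0, 5)), c(0, 0, 1))  # x = 0 on the zero branch
  expect_equal(relu(matrix(c(-1, 2), 1)), matrix(c(0, 2), 1))
})

test_that("maeLoss is the mean absolute deviation", {
  expect_equal(maeLoss(1:4, 1:4), 0)
  expect_equal(maeLoss(0, 3), 3)
  expect_equal(maeLoss(c(1, 2, 3), c(2, 2, 5)), 1)
  expect_error(maeLoss(1:3, 1:2), "equal length")
})

test_that("adam steps have magnitude ~lambda under constant gradient", {
  st <- adamInit(1)
  s1 <- adamStep(st, 1)
  expect_equal(s1$delta, -0.001 / (1 + 1e-8), tolerance = 1e-12)
  expect_equal(abs(abs(s1$delta) - 0.001) < 1e-6, TRUE)
  s2 <- adamStep(adamInit(1), -2)
  expect_equal(s2$delta, 0.001 * 2 / (2 + 1e-8), tolerance = 1e-9)
  # closed-form recursion: every step under g = 1 keeps magnitude ~lambda
  st <- adamInit(1)
  for (k in 1:20) {
    out <- adamStep(st, 1)
    st <- out$state
    expect_lt(abs(abs(out$delta) - 0.001), 1e-6)
  }
  # elementwise on tensors
  stm <- adamInit(c(2, 2))
  om <- adamStep(stm, matrix(c(1, -1, 2, -2), 2))
  expect_equal(dim(om$delta), c(2, 2))
  expect_equal(sign(om$delta), -sign(matrix(c(1, -1, 2, -2), 2)))
})

test_that("training is deterministic and epoch-0 yields the raw network", {
  sim <- simulateCalibration(n = 40, seed = 6)
  sp0 <- networkSpec(neurons = 8, epochs = 0, seed = 9)
  m0 <- trainDlnn(sim$dataset, sp0)
  m0b <- trainDlnn(sim$dataset, sp0)
  expect_identical(m0@weights, m0b@weights)
  expect_length(m0@lossHistory, 0)

  sp <- networkSpec(neurons = 8, epochs = 30, seed = 9, batchSize = 8)
  m1 <- trainDlnn(sim$dataset, sp)
  m2 <- trainDlnn(sim$dataset, sp)
  expect_identical(m1@weights, m2@weights)
  expect_false(identical(m0@weights$W[[1]], m1@weights$W[[1]]))
  # duplicate inputs give identical outputs (pure function)
  X <- fractionalAbundances(sim$dataset)[c(1, 1, 2), ]
  p <- predictMap(m1, X)
  expect_identical(p[1], p[2])
})

test_that("training loss decreases on a noiseless in-class target", {
  set.seed(13)
  X <- randomSimplex(120, seed = 13)
  y <- 300 + 2500 * X[, "Ia"]  # noiseless, single-layer-learnable
  sp <- networkSpec(hiddenLayers = 2, neurons = 16, epochs = 300,
                    batchSize = 16, seed = 4)
  m <- trainDlnn(X, sp, y = y)
  lh <- m@lossHistory
  # after warm-up the logged epoch loss trends down
  expect_lt(lh[300], lh[20])
  expect_lt(min(lh[250:300]), min(lh[20:40]))
  expect_gt(m@trainMetrics$R2, 0.8)
})

test_that("parameter recovery on a linear synthetic link", {
  # MAP = 300 + 2500*Ia + noise(sd = 50): the recovery contract at small n
  set.seed(17)
  fa <- randomSimplex(500, seed = 17)
  y <- 300 + 2500 * fa[, "Ia"] + rnorm(500, 0, 50)
  tr <- 1:350; va <- 351:500
  sp <- networkSpec(hiddenLayers = 2, neurons = 32, epochs = 300,
                    batchSize = 32, seed = 5)
  m <- trainDlnn(fa[tr, ], sp, features = c("Ia", "Ic"), y = y[tr],
                 validation = fa[va, ], validationY = y[va])
  expect_gt(m@valMetrics$R2, 0.9)
})

test_that("predictMap validates features and honours the clamp flag", {
  sim <- simulateCalibration(n = 30, seed = 8)
  m <- trainDlnn(sim$dataset, networkSpec(neurons = 4, epochs = 5, seed = 1))
  bad <- fractionalAbundances(sim$dataset)[, 1:3]
  expect_error(predictMap(m, bad), "feature")
  p <- predictMap(m, sim$dataset)
  expect_length(p, 30L)
  expect_true(all(is.finite(p)))
  expect_true(all(predictMap(m, sim$dataset, clampNonnegative = TRUE) >= 0))
})

test_that("model serialization round-trips predictions to near machine precision", {
  sim <- simulateCalibration(n = 25, seed = 14)
  m <- trainDlnn(sim$dataset, networkSpec(neurons = 6, epochs = 20, seed = 3))
  path <- tempfile(fileext = ".json")
  writeMapModel(m, path)
  m2 <- readMapModel(path)
  expect_equal(predictMap(m2, sim$dataset), predictMap(m, sim$dataset),
               tolerance = 1e-12)
  expect_identical(m2@features, m@features)
})

test_that("grid search selects by validation R2 with deterministic ties", {
  sim <- simulateCalibration(n = 80, seed = 21)
  sp <- splitDataset(sim$dataset, 0.3, seed = 2)
  base <- networkSpec(hiddenLayers = 2, neurons = 8, epochs = 20, seed = 2)
  single <- gridSearch(sp$training, sp$validation, epochGrid = 20,
                       neuronGrid = 8, baseSpec = base)
  expect_equal(nrow(single$scores), 1L)
  expect_equal(single$bestSpec$neurons, 8L)

  gs <- gridSearch(sp$training, sp$validation, epochGrid = c(10, 20),
                   neuronGrid = c(4, 8), baseSpec = base)
  expect_equal(nrow(gs$scores), 4L)
  best <- gs$scores[which.max(gs$scores$valR2), ]
  expect_equal(gs$bestSpec$epochs, best$epochs)
  gs2 <- gridSearch(sp$training, sp$validation, epochGrid = c(10, 20),
                    neuronGrid = c(4, 8), baseSpec = base)
  expect_identical(gs$bestSpec, gs2$bestSpec)
  expect_equal(gs$scores$valR2, gs2$scores$valR2, tolerance = 1e-15)
})

test_that("ablation ranks a planted dominant feature worst to remove", {
  # y depends strongly on IIa' and not at all on IIIc'
  set.seed(23)
  fa <- randomSimplex(300, seed = 23)
  y <- 500 + 4000 * fa[, "IIa'"] + rnorm(300, 0, 60)
  tr <- 1:200; va <- 201:300
  feats <- c("Ia", "IIa'", "IIIc'")
  sp <- networkSpec(hiddenLayers = 2, neurons = 16, epochs = 150,
                    batchSize = 32, seed = 6)
  calTr <- GdgtCalibration(fa = fa[tr, ], MAP = pmax(0, y[tr]))
  calVa <- GdgtCalibration(fa = fa[va, ], MAP = pmax(0, y[va]))
  tab <- ablateFeatures(calTr, calVa, baseFeatures = feats,
                        candidates = c("IIa'", "IIIc'"), spec = sp)
  expect_equal(nrow(tab), 2L)
  d <- setNames(tab$deltaR2, tab$compound)
  expect_lt(d[["IIa'"]], 0)                       # dominant feature hurts
  expect_lt(d[["IIa'"]], d[["IIIc'"]])            # and hurts most
  expect_lt(abs(d[["IIIc'"]]), 0.3)               # null feature ~noise
  expect_error(ablateFeatures(calTr, calVa, baseFeatures = "Ia",
                              candidates = "Ia", spec = sp), "all features")
})
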