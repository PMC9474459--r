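test_that("printed GRU forward matches the hand-computed step", {
  p <- baselineCellParams("GRU", hiddenSize = 1, seed = 1)
  p$Wr[] <- 0; p$Wz[] <- 0; p$Wh[] <- 0
  # all-zero weights, h0 = 1: r = z = 0.5, htil = 0,
  # printed update h1 = (1-z)*r*h0 + z*htil = 0.25
  fw <- baselineCellForward(p, x = 0, h0 = 1)
  expect_equal(drop(fw$h), 0.25)
  expect_equal(drop(fw$states[[1]]$r), 0.5)
  expect_equal(drop(fw$states[[1]]$z), 0.5)
  # conventional update keeps (1-z)*h0 + z*htil = 0.5
  fw2 <- baselineCellForward(p, x = 0, h0 = 1, standardGru = TRUE)
  expect_equal(drop(fw2$h), 0.5)
})

test_that("zero-weight RNN and gate-limit LSTM behave as closed forms", {
  p <- baselineCellParams("RNN", hiddenSize = 3, seed = 2)
  p$U[] <- 0; p$W[] <- 0
  fw <- baselineCellForward(p, x = c(1, -2, 3))
  expect_equal(unname(fw$h), matrix(tanh(0), 1, 3))  # h_t = f(0) always
  # printed softmax output over the readout row
  expect_equal(dim(fw$o), c(1L, 1L))
  expect_equal(drop(fw$o), 1)  # softmax of a length-1 vector

  # LSTM with forget gate ~1 and input gate ~0 carries C unchanged
  q <- baselineCellParams("LSTM", hiddenSize = 2, seed = 3)
  q$Wf[] <- 0; q$bf[] <- 50     # f ~ 1
  q$Wi[] <- 0; q$bi[] <- -50    # i ~ 0
  fw2 <- baselineCellForward(q, x = c(0.3, -0.1, 0.7))
  C <- fw2$states[[3]]$C
  expect_equal(unname(C), matrix(0, 1, 2), tolerance = 1e-12)  # C0 = 0 kept
})

test_that("BPTT gradients match finite differences for every cell", {
  set.seed(31)
  X <- matrix(runif(4 * 6), 4, 6)
  y <- runif(4, -1, 1)
  for (kind in c("RNN", "LSTM", "GRU")) {
    for (std in if (kind == "GRU") c(FALSE, TRUE) else FALSE) {
      p <- baselineCellParams(kind, hiddenSize = 3, seed = 7)
      g <- paleoGDGT:::.baselineGrad(p, X, y, standardGru = std)$grads
      lossAt <- function(pp) {
        fw <- baselineCellForward(pp, X, standardGru = std)
        mean(abs(y - paleoGDGT:::.baselineReadout(pp, fw$h)))
      }
      for (nm in setdiff(names(g), "V")) {
        pv <- p[[nm]]
        idx <- seq_len(min(4L, length(pv)))
        for (i in idx) {
          eps <- 1e-6
          p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
          p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
          fd <- (lossAt(p1) - lossAt(p2)) / (2 * eps)
          expect_equal(g[[nm]][i], fd, tolerance = 1e-5)
        }
      }
    }
  }
})

test_that("baseline training is seed-deterministic and fits its metrics", {
  sim <- simulateCalibration(n = 60, seed = 41)
  sp <- splitDataset(sim$dataset, 0.5, seed = 4)
  m1 <- trainBaseline("GRU", sp$training, sp$validation, hiddenSize = 8,
                      epochs = 50, seed = 2)
  m2 <- trainBaseline("GRU", sp$training, sp$validation, hiddenSize = 8,
                      epochs = 50, seed = 2)
  expect_identical(m1@trainMetrics, m2@trainMetrics)
  expect_identical(m1@valMetrics, m2@valMetrics)
  expect_length(m1@lossHistory, 50L)
  # losses are reported in mm (unstandardized scale)
  expect_gt(m1@lossHistory[1], 100)
  p <- predictBaseline(m1, sp$validation)
  expect_length(p, ncol(sp$validation))

  # epochs = 0: the untrained forward pass still yields finite metrics
  m0 <- trainBaseline("RNN", sp$training, sp$validation, hiddenSize = 8,
                      epochs = 0, seed = 2)
  expect_true(is.finite(m0@trainMetrics$RMSE))
})

test_that("sustained training drives the training loss down", {
  sim <- simulateCalibration(n = 50, seed = 42)
  m <- trainBaseline("LSTM", sim$dataset, hiddenSize = 16, epochs = 400,
                     seed = 3)
  lh <- m@lossHistory
  expect_lt(lh[400], 0.5 * lh[1])
  expect_gt(m@trainMetrics$R2, 0.3)
})
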