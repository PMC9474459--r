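## Deep feed-forward calibration of brGDGT compositions to mean annual
## precipitation: a from-scratch multilayer perceptron (ReLU hidden layers,
## single linear output in mm) trained by minibatch Adam on the mean
## absolute error, plus the grid-search and compound-ablation protocol
## around it.

#' Default brGDGT-MAP feature set
#'
#' The eight compounds entered into the precipitation models: Ia, Ic and all
#' six 6-methyl isomers (the compounds most responsive to soil moisture and
#' pH).  `includeIb = TRUE` gives the nine-compound variant that retains Ib.
#'
#' @param includeIb include Ib as a ninth feature.
#' @return character vector of compound names in registry order.
#' @export
defaultMapFeatures <- function(includeIb = FALSE) {
  f <- c("Ia", if (includeIb) "Ib", "Ic", sixMethylCompounds())
  intersect(gdgtCompounds(), f)  # registry order
}

#' Rectified linear unit and its derivative
#'
#' `relu(x) = max(0, x)`; `reluGrad(x)` is 1 for x > 0 and 0 for x <= 0
#' (the x = 0 point sits on the zero branch, as printed).
#'
#' @param x numeric vector/matrix.
#' @return numeric of the same shape.
#' @export
relu <- function(x) pmax(x, 0)

#' @rdname relu
#' @export
reluGrad <- function(x) (x > 0) * 1

#' Mean absolute error
#'
#' `MAE = (1/N) sum |T - Y|`, the training loss of the precipitation
#' network.
#'
#' @param targets,predictions numeric vectors of equal length (N >= 1).
#' @return non-negative scalar in target units.
#' @export
maeLoss <- function(targets, predictions) {
  if (length(targets) != length(predictions))
    stop("targets and predictions must have equal length")
  if (length(targets) < 1L) stop("need at least one value")
  mean(abs(targets - predictions))
}

#' Adam optimizer state and step
#'
#' One parameter tensor's adaptive-moment state.  `adamInit()` starts both
#' moments at zero with step counter t = 0; `adamStep()` advances one step:
#' `a <- rho1*a + (1-rho1)*g`, `b <- rho2*b + (1-rho2)*g*g`, bias
#' corrections `a_c = a/(1-rho1^t)`, `b_c = b/(1-rho2^t)`, and update
#' `delta = -lambda * a_c / (sqrt(b_c) + epsilon)` (to be *added* to the
#' weights).  With zero initial moments and a constant gradient every step
#' has magnitude ~lambda.
#'
#' @param shape dimensions of the parameter tensor (vector length or
#'   `dim()`); moments start as zeros of that shape.
#' @param state list from `adamInit()`/a previous `adamStep()`.
#' @param g gradient tensor of the state's shape.
#' @param learningRate step size lambda (default 0.001).
#' @param rho1,rho2 exponential decay rates (defaults 0.9 and 0.999).
#' @param epsilon numerical-stability constant (default 1e-8).
#' @return `adamInit()`: list with `a`, `b`, `t`.  `adamStep()`: list with
#'   `state` (advanced) and `delta` (the weight increment).
#' @examples
#' st <- adamInit(1)
#' adamStep(st, g = 1)$delta  # ~ -0.001
#' @export
adamInit <- function(shape = 1L) {
  z <- if (length(shape) > 1L) array(0, dim = shape) else numeric(shape)
  list(a = z, b = z, t = 0L)
}

#' @rdname adamInit
#' @export
adamStep <- function(state, g, learningRate = 0.001, rho1 = 0.9,
                     rho2 = 0.999, epsilon = 1e-8) {
  stopifnot(is.list(state), all(c("a", "b", "t") %in% names(state)))
  if (rho1 <= 0 || rho1 >= 1 || rho2 <= 0 || rho2 >= 1)
    stop("decay rates must lie strictly between 0 and 1")
  t <- state$t + 1L
  a <- rho1 * state$a + (1 - rho1) * g
  b <- rho2 * state$b + (1 - rho2) * g * g
  ac <- a / (1 - rho1^t)
  bc <- b / (1 - rho2^t)
  delta <- -learningRate * ac / (sqrt(bc) + epsilon)
  list(state = list(a = a, b = b, t = t), delta = delta)
}

#' Network hyperparameter specification
#'
#' @param hiddenLayers number of hidden layers (default 4).
#' @param neurons neurons per hidden layer (default 160).
#' @param epochs training epochs, one full pass each (default 1000).
#' @param learningRate Adam step size lambda (default 0.001).
#' @param rho1,rho2,epsilon Adam constants (defaults 0.9, 0.999, 1e-8).
#' @param batchSize minibatch size (default 32; the loss gradient is the
#'   minibatch mean).  `NULL` trains full-batch.  Either way training is
#'   deterministic: the per-epoch shuffle is seeded from `seed`.
#' @param seed integer RNG seed for weight initialization and minibatch
#'   shuffling.
#' @return list of class `networkSpec`.
#' @export
networkSpec <- function(hiddenLayers = 4L, neurons = 160L, epochs = 1000L,
                        learningRate = 0.001, rho1 = 0.9, rho2 = 0.999,
                        epsilon = 1e-8, batchSize = 32L, seed = 1L) {
  stopifnot(hiddenLayers >= 1L, neurons >= 1L, epochs >= 0L,
            learningRate > 0, rho1 > 0, rho1 < 1, rho2 > 0, rho2 < 1,
            epsilon > 0)
  structure(list(hiddenLayers = as.integer(hiddenLayers),
                 neurons = as.integer(neurons),
                 epochs = as.integer(epochs),
                 learningRate = learningRate, rho1 = rho1, rho2 = rho2,
                 epsilon = epsilon,
                 batchSize = if (!is.null(batchSize)) as.integer(batchSize),
                 seed = as.integer(seed)),
            class = "networkSpec")
}

## He-style scaled normal initialization of all layers, seeded.
.initWeights <- function(sizes, seed) {
  .withSeed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                    sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- numeric(sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

## forward pass; returns list(yhat, Z = pre-activations, A = activations)
.mlpForward <- function(X, W, b, keep = FALSE) {
  L <- length(W)
  A <- X
  Zs <- if (keep) vector("list", L)
  As <- if (keep) vector("list", L + 1L)
  if (keep) As[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% W[[l]]
    Z <- sweep(Z, 2L, b[[l]], "+")
    A <- if (l < L) relu(Z) else Z
    if (keep) { Zs[[l]] <- Z; As[[l + 1L]] <- A }
  }
  if (keep) list(yhat = drop(A), Z = Zs, A = As) else drop(A)
}

#' MapModel: trained brGDGT-MAP network
#'
#' S4 container for a trained precipitation network: the feature order, the
#' hyperparameter spec, the learned weight tensors, the per-epoch training
#' loss history and fit metrics.  A model is reproducible bit-for-bit from
#' (data, spec, seed).
#'
#' @aliases MapModel-class
#' @export
setClass("MapModel", representation(
  features = "character", spec = "list", weights = "list",
  lossHistory = "numeric", trainMetrics = "list", valMetrics = "list",
  version = "character"))

setMethod("show", "MapModel", function(object) {
  sp <- object@spec
  cat(sprintf("MapModel: %d features -> %d x %d ReLU -> 1 (mm/yr)\n",
              length(object@features), sp$hiddenLayers, sp$neurons))
  cat(sprintf("trained %d epochs (Adam, MAE loss), seed %d\n",
              sp$epochs, sp$seed))
  tm <- object@trainMetrics
  if (length(tm))
    cat(sprintf("training:   R2 = %.3f, RMSE = %.0f mm, n = %d\n",
                tm$R2, tm$RMSE, tm$n))
  vm <- object@valMetrics
  if (length(vm))
    cat(sprintf("validation: R2 = %.3f, RMSE = %.0f mm, n = %d\n",
                vm$R2, vm$RMSE, vm$n))
  invisible(NULL)
})

## resolve (X, y) from a calibration object or matrix input
.calibXY <- function(data, features, y = NULL) {
  if (is(data, "GdgtSet")) {
    X <- fractionalAbundances(data)[, features, drop = FALSE]
    if (is.null(y) && is(data, "GdgtCalibration")) y <- mapObserved(data)
  } else {
    X <- as.matrix(data)
    missing <- setdiff(features, colnames(X))
    if (length(missing))
      stop("input lacks feature column(s): ", paste(missing, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  if (!is.null(y) && length(y) != nrow(X))
    stop("target length does not match sample count")
  list(X = X, y = y)
}

#' Train the brGDGT-MAP deep network
#'
#' Feed-forward network (feature fractions in, `hiddenLayers` ReLU layers of
#' `neurons` units, one linear output = MAP in mm) trained by minibatch Adam
#' on the MAE loss.  Full-batch by default; weights are He-initialized from
#' the spec seed, so training is deterministic given (data, spec).
#'
#' @param training a [GdgtCalibration], or a samples-by-compounds matrix
#'   (then supply `y`).
#' @param spec a [networkSpec()].
#' @param features ordered compound names fed to the input layer; default
#'   [defaultMapFeatures()].
#' @param validation optional held-out [GdgtCalibration] (or matrix, with
#'   `validationY`) whose metrics are stored on the model.
#' @param y,validationY targets (mm/yr) when matrices are given.
#' @return A [MapModel-class].  Training stops with an error naming the
#'   epoch if the loss diverges to a non-finite value.
#' @examples
#' sim <- simulateCalibration(n = 80, seed = 2)
#' m <- trainDlnn(sim$dataset, networkSpec(neurons = 8, epochs = 50, seed = 2))
#' m
#' @export
trainDlnn <- function(training, spec = networkSpec(),
                      features = defaultMapFeatures(), validation = NULL,
                      y = NULL, validationY = NULL) {
  xy <- .calibXY(training, features, y)
  X <- xy$X; yv <- xy$y
  if (is.null(yv)) stop("training targets are required")
  n <- nrow(X)
  if (n < 1L) stop("training data are empty")
  sizes <- c(ncol(X), rep(spec$neurons, spec$hiddenLayers), 1L)
  init <- .initWeights(sizes, spec$seed)
  W <- init$W; b <- init$b
  L <- length(W)
  optW <- lapply(W, function(w) adamInit(dim(w)))
  optB <- lapply(b, function(v) adamInit(length(v)))
  batch <- if (is.null(spec$batchSize)) n else min(spec$batchSize, n)
  lossHist <- numeric(0)

  runEpochs <- function() {
    for (epoch in seq_len(spec$epochs)) {
      ord <- if (batch < n)
        .withSeed(spec$seed + epoch, sample.int(n)) else seq_len(n)
      starts <- seq(1L, n, by = batch)
      epochAbs <- 0
      for (s0 in starts) {
        rows <- ord[s0:min(s0 + batch - 1L, n)]
        m <- length(rows)
        fw <- .mlpForward(X[rows, , drop = FALSE], W, b, keep = TRUE)
        err <- fw$yhat - yv[rows]
        epochAbs <- epochAbs + sum(abs(err))
        ## MAE gradient at the linear output, minibatch mean
        delta <- matrix(sign(err) / m, ncol = 1L)
        for (l in rev(seq_len(L))) {
          gW <- crossprod(fw$A[[l]], delta)
          gB <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(W[[l]])) * reluGrad(fw$Z[[l - 1L]])
          stW <- adamStep(optW[[l]], gW, spec$learningRate, spec$rho1,
                          spec$rho2, spec$epsilon)
          optW[[l]] <<- stW$state
          W[[l]] <<- W[[l]] + stW$delta
          stB <- adamStep(optB[[l]], gB, spec$learningRate, spec$rho1,
                          spec$rho2, spec$epsilon)
          optB[[l]] <<- stB$state
          b[[l]] <<- b[[l]] + drop(stB$delta)
        }
      }
      loss <- epochAbs / n
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      lossHist[epoch] <<- loss
    }
  }
  runEpochs()

  weights <- list(W = W, b = b, sizes = sizes)
  yhatTr <- .mlpForward(X, W, b)
  model <- new("MapModel",
               features = features, spec = unclass(spec), weights = weights,
               lossHistory = lossHist,
               trainMetrics = evaluateFit(yhatTr, yv),
               valMetrics = list(), version = "1")
  if (!is.null(validation)) {
    vxy <- .calibXY(validation, features, validationY)
    if (is.null(vxy$y)) stop("validation targets are required")
    model@valMetrics <- evaluateFit(predictMap(model, validation), vxy$y)
  }
  model
}

#' Predict precipitation from abundances
#'
#' @param model a trained [MapModel-class].
#' @param newdata a [GdgtSet] or samples-by-compounds matrix containing the
#'   model's feature columns.
#' @param clampNonnegative truncate negative estimates at 0 mm (off by
#'   default: the raw network output is reported).
#' @return numeric MAP estimates in mm/yr, one per sample.
#' @export
predictMap <- function(model, newdata, clampNonnegative = FALSE) {
  stopifnot(is(model, "MapModel"))
  xy <- .calibXY(newdata, model@features)
  out <- .mlpForward(xy$X, model@weights$W, model@weights$b)
  if (clampNonnegative) out <- pmax(out, 0)
  out
}

#' Grid search over epochs and network width
#'
#' Trains one network per (epochs, neurons) cell and selects the cell with
#' the highest validation R^2 (ties: lower validation RMSE, then fewer
#' neurons, then fewer epochs).  Default grids are epochs 1000..1500 by 100
#' and neurons 160..260 by 20 (36 cells).
#'
#' @param training,validation [GdgtCalibration] objects.
#' @param epochGrid,neuronGrid numeric grids.
#' @param features input compounds; default [defaultMapFeatures()].
#' @param baseSpec spec whose other fields (layers, rates, seed) every cell
#'   inherits.
#' @param seed overrides `baseSpec$seed` when given.
#' @return list with `scores` (one row per cell: epochs, neurons, training
#'   and validation R2/RMSE), `bestSpec`, and `bestModel` (retrained at the
#'   selected cell).
#' @export
gridSearch <- function(training, validation,
                       epochGrid = seq(1000L, 1500L, by = 100L),
                       neuronGrid = seq(160L, 260L, by = 20L),
                       features = defaultMapFeatures(),
                       baseSpec = networkSpec(), seed = NULL) {
  if (length(epochGrid) == 0L || length(neuronGrid) == 0L)
    stop("grids must be non-empty")
  if (!is.null(seed)) baseSpec$seed <- as.integer(seed)
  cells <- expand.grid(epochs = as.integer(epochGrid),
                       neurons = as.integer(neuronGrid))
  models <- vector("list", nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sp <- baseSpec
    sp$epochs <- cells$epochs[i]
    sp$neurons <- cells$neurons[i]
    m <- trainDlnn(training, sp, features = features,
                   validation = validation)
    models[[i]] <<- m
    data.frame(epochs = sp$epochs, neurons = sp$neurons,
               trainR2 = m@trainMetrics$R2, trainRMSE = m@trainMetrics$RMSE,
               valR2 = m@valMetrics$R2, valRMSE = m@valMetrics$RMSE)
  })
  scores <- do.call(rbind, rows)
  ord <- order(-scores$valR2, scores$valRMSE, scores$neurons, scores$epochs)
  bestModel <- models[[ord[1L]]]
  bestSpec <- baseSpec
  bestSpec$epochs <- scores$epochs[ord[1L]]
  bestSpec$neurons <- scores$neurons[ord[1L]]
  list(scores = scores, bestSpec = bestSpec, bestModel = bestModel)
}

#' Single-compound ablation importance
#'
#' Retrains the network with each candidate compound removed from the input
#' layer and reports the change in validation metrics; the drop in
#' validation R^2 when a compound is removed ranks its importance.  Default
#' candidates are the seven removable inputs of the eight-compound model
#' (Ic and the six 6-methyl isomers; Ia anchors the set).
#'
#' @param training,validation [GdgtCalibration] objects.
#' @param baseFeatures full feature set; default [defaultMapFeatures()].
#' @param candidates compounds to ablate, each a member of `baseFeatures`.
#' @param spec a [networkSpec()] shared by every fit.
#' @return data.frame with one row per candidate: validation R2/RMSE without
#'   it and `deltaR2`/`deltaRMSE` relative to the full model (negative
#'   `deltaR2` = removing the compound hurts).
#' @export
ablateFeatures <- function(training, validation,
                           baseFeatures = defaultMapFeatures(),
                           candidates = setdiff(baseFeatures, "Ia"),
                           spec = networkSpec()) {
  if (!all(candidates %in% baseFeatures))
    stop("every candidate must be in baseFeatures")
  if (any(vapply(candidates, function(cc)
    length(setdiff(baseFeatures, cc)) == 0L, logical(1))))
    stop("cannot ablate away all features")
  full <- trainDlnn(training, spec, features = baseFeatures,
                    validation = validation)
  rows <- lapply(candidates, function(cc) {
    m <- trainDlnn(training, spec,
                   features = setdiff(baseFeatures, cc),
                   validation = validation)
    data.frame(compound = cc,
               valR2 = m@valMetrics$R2, valRMSE = m@valMetrics$RMSE,
               deltaR2 = m@valMetrics$R2 - full@valMetrics$R2,
               deltaRMSE = m@valMetrics$RMSE - full@valMetrics$RMSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fullModel") <- list(valR2 = full@valMetrics$R2,
                                 valRMSE = full@valMetrics$RMSE)
  out
}

#' Portable model serialization
#'
#' Writes/reads a [MapModel-class] as a versioned JSON container (weights,
#' spec, feature order, seed, metrics), so trained calibrations can move
#' between machines as plain text.
#'
#' @param model a [MapModel-class].
#' @param path file path (.json).
#' @return `writeMapModel()` returns `path` invisibly; `readMapModel()` the
#'   reconstructed model.
#' @export
writeMapModel <- function(model, path) {
  stopifnot(is(model, "MapModel"))
  payload <- list(
    container = "paleoGDGT-MapModel", version = model@version,
    features = model@features, spec = model@spec,
    sizes = model@weights$sizes,
    W = lapply(model@weights$W, function(w) as.vector(w)),
    b = model@weights$b,
    lossHistory = model@lossHistory,
    trainMetrics = model@trainMetrics, valMetrics = model@valMetrics)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeMapModel
#' @export
readMapModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$container, "paleoGDGT-MapModel"))
    stop(path, " is not a MapModel container")
  sizes <- as.integer(p$sizes)
  W <- lapply(seq_len(length(sizes) - 1L), function(l)
    matrix(as.numeric(p$W[[l]]), sizes[l], sizes[l + 1L]))
  b <- lapply(seq_len(length(sizes) - 1L), function(l)
    as.numeric(if (is.list(p$b)) p$b[[l]] else p$b[l, ]))
  spec <- p$spec
  spec$batchSize <- if (!is.null(spec$batchSize)) as.integer(spec$batchSize)
  new("MapModel", features = as.character(p$features), spec = spec,
      weights = list(W = W, b = b, sizes = sizes),
      lossHistory = as.numeric(p$lossHistory),
      trainMetrics = as.list(p$trainMetrics),
      valMetrics = as.list(p$valMetrics),
      version = as.character(p$version))
}
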