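## Recurrent baselines (RNN / LSTM / GRU) for the composition-to-MAP task.
##
## The feature vector (default 8 compounds, registry order) is presented to
## the cell as a length-8 sequence of scalars; the final hidden state feeds
## a linear readout to MAP in mm.  Forward recursions follow the printed
## equations: the LSTM adds the conventional output gate (the printed system
## stops at the cell state), and the GRU state update is implemented as
## printed, h_t = (1-z_t)*r_t*h_{t-1} + z_t*htilde_t, with the reset gate
## inside the carry-over term; `standardGru = TRUE` selects the conventional
## h_t = (1-z_t)*h_{t-1} + z_t*htilde_t.  Training is backpropagation
## through time with the same Adam/MAE machinery as the deep network.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize recurrent-cell parameters
#'
#' Creates seeded random parameters for one cell operating on a scalar-per-
#' step input.  Gate weights act on the concatenation `[h_{t-1}, x_t]`
#' (h + 1 columns).  RNN: `U` (input weights, length h), `W` (h x h
#' recurrence), `V` (readout row used by the printed softmax output).
#' LSTM: `Wf`, `Wi`, `Wc`, `Wo` ((h+1) x h) with biases `bf`, `bi`, `bc`,
#' `bo`.  GRU: `Wr`, `Wz`, `Wh` ((h+1) x h), no gate biases (as printed).
#' All kinds carry a linear regression readout (`v`, `c`).
#'
#' @param kind `"RNN"`, `"LSTM"` or `"GRU"`.
#' @param hiddenSize hidden-state width h.
#' @param seed integer seed.
#' @return list of class `baselineCellParams`.
#' @export
baselineCellParams <- function(kind = c("RNN", "LSTM", "GRU"),
                               hiddenSize = 16L, seed = 1L) {
  kind <- match.arg(kind)
  h <- as.integer(hiddenSize)
  stopifnot(h >= 1L)
  .withSeed(seed, {
    sdw <- sqrt(1 / (h + 1))
    rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sdw), nr, nc)
    p <- switch(kind,
      RNN = list(U = stats::rnorm(h, sd = sdw), W = rmat(h, h),
                 V = rmat(1L, h)),
      LSTM = list(Wf = rmat(h + 1L, h), bf = numeric(h),
                  Wi = rmat(h + 1L, h), bi = numeric(h),
                  Wc = rmat(h + 1L, h), bc = numeric(h),
                  Wo = rmat(h + 1L, h), bo = numeric(h)),
      GRU = list(Wr = rmat(h + 1L, h), Wz = rmat(h + 1L, h),
                 Wh = rmat(h + 1L, h)))
    p$v <- stats::rnorm(h, sd = sdw)
    p$c <- 0
    structure(c(list(kind = kind, hiddenSize = h, seed = as.integer(seed)),
                p),
              class = "baselineCellParams")
  })
}

#' Recurrent cell forward pass
#'
#' Runs the printed forward recursion over a scalar input sequence
#' (or a samples-by-steps matrix), returning all intermediate states.
#' For the RNN, `activation` selects the hidden nonlinearity (`"tanh"`
#' default; `"softmax"` normalizes each hidden vector as printed) and the
#' per-step output `o_t = softmax(V h_t)` is also returned.  For the GRU the
#' printed state update is used unless `standardGru = TRUE`.
#'
#' @param params a [baselineCellParams()] list.
#' @param x numeric vector (one sequence) or matrix (samples x steps).
#' @param h0 initial hidden state (default zeros; recycled across samples).
#' @param standardGru use the conventional GRU update instead of the
#'   printed one.
#' @param activation RNN hidden nonlinearity, `"tanh"` or `"softmax"`.
#' @return list with `h` (samples x hiddenSize final state), `states`
#'   (per-step list of gate/state matrices) and, for the RNN, `o` (printed
#'   softmax outputs per step).
#' @examples
#' p <- baselineCellParams("GRU", hiddenSize = 1, seed = 1)
#' p$Wr[] <- 0; p$Wz[] <- 0; p$Wh[] <- 0
#' baselineCellForward(p, x = 0, h0 = 1)$h  # 0.25 as printed
#' @export
baselineCellForward <- function(params, x, h0 = NULL,
                                standardGru = FALSE,
                                activation = c("tanh", "softmax")) {
  stopifnot(inherits(params, "baselineCellParams"))
  activation <- match.arg(activation)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n <- nrow(x); Tn <- ncol(x); h <- params$hiddenSize
  H <- matrix(0, n, h)
  if (!is.null(h0)) H[] <- if (length(h0) == h) rep(h0, each = n) else h0
  C <- matrix(0, n, h)
  states <- vector("list", Tn)
  o <- NULL
  for (t in seq_len(Tn)) {
    xt <- x[, t]
    concat <- cbind(H, xt)
    if (params$kind == "RNN") {
      a <- outer(xt, params$U) + H %*% params$W
      H <- if (activation == "tanh") tanh(a)
      else {
        e <- exp(a - apply(a, 1L, max))
        e / rowSums(e)
      }
      ot <- {
        z <- H %*% t(params$V)
        ez <- exp(z - apply(z, 1L, max))
        ez / rowSums(ez)
      }
      states[[t]] <- list(a = a, h = H, o = ot)
      o <- ot
    } else if (params$kind == "LSTM") {
      f <- .sigmoid(sweep(concat %*% params$Wf, 2L, params$bf, "+"))
      i <- .sigmoid(sweep(concat %*% params$Wi, 2L, params$bi, "+"))
      ctil <- tanh(sweep(concat %*% params$Wc, 2L, params$bc, "+"))
      Cnew <- f * C + i * ctil
      og <- .sigmoid(sweep(concat %*% params$Wo, 2L, params$bo, "+"))
      Hnew <- og * tanh(Cnew)
      states[[t]] <- list(f = f, i = i, ctil = ctil, C = Cnew, o = og,
                          h = Hnew, hPrev = H, CPrev = C, concat = concat)
      H <- Hnew; C <- Cnew
    } else {  # GRU
      r <- .sigmoid(concat %*% params$Wr)
      z <- .sigmoid(concat %*% params$Wz)
      rh <- r * H
      pre <- cbind(rh, xt) %*% params$Wh
      htil <- tanh(pre)
      Hnew <- if (standardGru) (1 - z) * H + z * htil
      else (1 - z) * rh + z * htil
      states[[t]] <- list(r = r, z = z, htil = htil, h = Hnew, hPrev = H,
                          rh = rh, concat = concat)
      H <- Hnew
    }
  }
  out <- list(h = H, states = states)
  if (!is.null(o)) out$o <- o
  out
}

## linear readout used for regression training
.baselineReadout <- function(params, H) drop(H %*% params$v + params$c)

## Full forward + BPTT gradient of the MAE loss wrt every parameter.
## Returns list(yhat, grads).  Derivations follow the recursions above.
.baselineGrad <- function(params, x, y, standardGru = FALSE) {
  n <- nrow(x); Tn <- ncol(x); h <- params$hiddenSize
  fw <- baselineCellForward(params, x, standardGru = standardGru)
  yhat <- .baselineReadout(params, fw$h)
  dy <- sign(yhat - y) / n                       # MAE gradient
  g <- lapply(params[!(names(params) %in% c("kind", "hiddenSize", "seed"))],
              function(p) p * 0)
  g$v <- drop(crossprod(fw$h, dy))
  g$c <- sum(dy)
  G <- dy %o% params$v                           # dL/dh_T, n x h
  if (params$kind == "RNN") {
    for (t in rev(seq_len(Tn))) {
      st <- fw$states[[t]]
      da <- G * (1 - st$h^2)                     # tanh hidden
      g$U <- g$U + drop(crossprod(da, x[, t]))
      hPrev <- if (t > 1L) fw$states[[t - 1L]]$h else matrix(0, n, h)
      g$W <- g$W + crossprod(hPrev, da)
      G <- da %*% t(params$W)
    }
  } else if (params$kind == "LSTM") {
    GC <- matrix(0, n, h)
    for (t in rev(seq_len(Tn))) {
      st <- fw$states[[t]]
      tC <- tanh(st$C)
      dog <- G * tC
      dpo <- dog * st$o * (1 - st$o)
      GC <- GC + G * st$o * (1 - tC^2)
      df <- GC * st$CPrev
      dpf <- df * st$f * (1 - st$f)
      di <- GC * st$ctil
      dpi <- di * st$i * (1 - st$i)
      dct <- GC * st$i
      dpc <- dct * (1 - st$ctil^2)
      g$Wf <- g$Wf + crossprod(st$concat, dpf); g$bf <- g$bf + colSums(dpf)
      g$Wi <- g$Wi + crossprod(st$concat, dpi); g$bi <- g$bi + colSums(dpi)
      g$Wc <- g$Wc + crossprod(st$concat, dpc); g$bc <- g$bc + colSums(dpc)
      g$Wo <- g$Wo + crossprod(st$concat, dpo); g$bo <- g$bo + colSums(dpo)
      dcat <- dpf %*% t(params$Wf) + dpi %*% t(params$Wi) +
        dpc %*% t(params$Wc) + dpo %*% t(params$Wo)
      G <- dcat[, seq_len(h), drop = FALSE]
      GC <- GC * st$f
    }
  } else {  # GRU
    for (t in rev(seq_len(Tn))) {
      st <- fw$states[[t]]
      if (standardGru) {
        dz <- G * (st$htil - st$hPrev)
        dhtil <- G * st$z
        dhPrev <- G * (1 - st$z)
        drh <- matrix(0, n, h)
      } else {
        dz <- G * (st$htil - st$rh)
        dhtil <- G * st$z
        drh <- G * (1 - st$z)
        dhPrev <- matrix(0, n, h)
      }
      dpre <- dhtil * (1 - st$htil^2)
      g$Wh <- g$Wh + crossprod(cbind(st$rh, x[, t]), dpre)
      dcatH <- dpre %*% t(params$Wh)
      drh <- drh + dcatH[, seq_len(h), drop = FALSE]
      dr <- drh * st$hPrev
      dhPrev <- dhPrev + drh * st$r
      dpr <- dr * st$r * (1 - st$r)
      g$Wr <- g$Wr + crossprod(st$concat, dpr)
      dcatR <- dpr %*% t(params$Wr)
      dhPrev <- dhPrev + dcatR[, seq_len(h), drop = FALSE]
      dpz <- dz * st$z * (1 - st$z)
      g$Wz <- g$Wz + crossprod(st$concat, dpz)
      dcatZ <- dpz %*% t(params$Wz)
      dhPrev <- dhPrev + dcatZ[, seq_len(h), drop = FALSE]
      G <- dhPrev
    }
  }
  list(yhat = yhat, grads = g)
}

#' BaselineModel: trained recurrent baseline
#'
#' S4 container for a trained RNN/LSTM/GRU regression baseline: cell kind,
#' parameters, loss history and training/validation metrics (kept side by
#' side to expose the overfitting gap).
#'
#' @aliases BaselineModel-class
#' @export
setClass("BaselineModel", representation(
  kind = "character", params = "ANY", features = "character",
  standardGru = "logical", yCenter = "numeric", yScale = "numeric",
  lossHistory = "numeric", trainMetrics = "list", valMetrics = "list"))

setMethod("show", "BaselineModel", function(object) {
  cat(sprintf("BaselineModel (%s, h = %d) on %d-step feature sequence\n",
              object@kind, object@params$hiddenSize,
              length(object@features)))
  tm <- object@trainMetrics; vm <- object@valMetrics
  if (length(tm))
    cat(sprintf("training:   R2 = %.3f, RMSE = %.0f mm\n", tm$R2, tm$RMSE))
  if (length(vm))
    cat(sprintf("validation: R2 = %.3f, RMSE = %.0f mm\n", vm$R2, vm$RMSE))
  invisible(NULL)
})

#' Train a recurrent baseline on composition sequences
#'
#' Presents each sample's feature vector as an ordered scalar sequence
#' (registry order) to the chosen cell, reads MAP in mm off the final
#' hidden state through a linear head, and trains everything by
#' backpropagation through time with full-batch Adam on the MAE loss.
#' Training and validation metrics are both reported so the training-minus-
#' validation gap (overfitting) can be compared against the deep network's.
#'
#' @param kind `"RNN"`, `"LSTM"` or `"GRU"`.
#' @param training,validation [GdgtCalibration] objects (validation
#'   optional).
#' @param features ordered compounds forming the sequence; default
#'   [defaultMapFeatures()].
#' @param hiddenSize hidden width (default 16).
#' @param epochs full-batch Adam steps (default 300).
#' @param learningRate,rho1,rho2,epsilon Adam constants as in
#'   [networkSpec()].
#' @param seed integer seed (initialization).
#' @param standardGru use the conventional GRU update.
#' @return A [BaselineModel-class].
#' @export
trainBaseline <- function(kind, training, validation = NULL,
                          features = defaultMapFeatures(),
                          hiddenSize = 16L, epochs = 300L,
                          learningRate = 0.001, rho1 = 0.9, rho2 = 0.999,
                          epsilon = 1e-8, seed = 1L, standardGru = FALSE) {
  kind <- match.arg(kind, c("RNN", "LSTM", "GRU"))
  xy <- .calibXY(training, features)
  X <- xy$X; y <- xy$y
  if (is.null(y)) stop("training targets are required")
  ## z-score the targets for the bounded-state readout (restored on predict)
  yCenter <- mean(y)
  yScale <- stats::sd(y)
  if (!is.finite(yScale) || yScale <= 0) yScale <- 1
  ys <- (y - yCenter) / yScale
  params <- baselineCellParams(kind, hiddenSize, seed)
  pn <- setdiff(names(params), c("kind", "hiddenSize", "seed"))
  opt <- lapply(params[pn], function(p)
    adamInit(if (is.matrix(p)) dim(p) else length(p)))
  lossHist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    bg <- .baselineGrad(params, X, ys, standardGru = standardGru)
    loss <- yScale * mean(abs(ys - bg$yhat))
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at epoch ", ep)
    lossHist[ep] <- loss
    for (nm in pn) {
      st <- adamStep(opt[[nm]], bg$grads[[nm]], learningRate, rho1, rho2,
                     epsilon)
      opt[[nm]] <- st$state
      params[[nm]] <- params[[nm]] + st$delta
    }
  }
  predict1 <- function(dat) {
    Xd <- .calibXY(dat, features)$X
    yCenter + yScale *
      .baselineReadout(params,
                       baselineCellForward(params, Xd,
                                           standardGru = standardGru)$h)
  }
  model <- new("BaselineModel", kind = kind, params = params,
               features = features, standardGru = standardGru,
               yCenter = yCenter, yScale = yScale,
               lossHistory = lossHist,
               trainMetrics = evaluateFit(predict1(training), y),
               valMetrics = list())
  if (!is.null(validation)) {
    vy <- .calibXY(validation, features)$y
    model@valMetrics <- evaluateFit(predict1(validation), vy)
  }
  model
}

#' Predict from a trained recurrent baseline
#'
#' @param model a [BaselineModel-class].
#' @param newdata [GdgtSet] or samples-by-compounds matrix.
#' @return numeric MAP estimates (mm/yr).
#' @export
predictBaseline <- function(model, newdata) {
  stopifnot(is(model, "BaselineModel"))
  X <- .calibXY(newdata, model@features)$X
  model@yCenter + model@yScale *
    .baselineReadout(model@params,
                     baselineCellForward(model@params, X,
                                         standardGru = model@standardGru)$h)
}
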