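## Multiple-linear-regression baseline with the full printed diagnostic
## suite (multiple correlation R, per-coefficient t, residual scale s, F,
## VIF), plus the shared fit-metric helper and the random training/
## validation splitter.

## Evaluate expr under a local RNG seed, restoring global RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Random training/validation split
#'
#' Uniformly random, disjoint and exhaustive split of a calibration set, in
#' the spirit of the 533/179 partition of the 712-soil compilation.
#'
#' @param ds a [GdgtCalibration] (or any object subsettable by column with
#'   `ncol()`), n >= 2.
#' @param validationFraction fraction of samples held out (0 < f < 1).
#' @param seed integer seed; the same seed reproduces the same membership.
#' @return list with elements `training` and `validation`.
#' @examples
#' sim <- simulateCalibration(n = 20, seed = 1)
#' sp <- splitDataset(sim$dataset, 0.25, seed = 7)
#' ncol(sp$validation)  # 5
#' @export
splitDataset <- function(ds, validationFraction, seed = NULL) {
  n <- ncol(ds)
  if (is.null(n) || n < 2L) stop("need at least 2 samples to split")
  if (!is.numeric(validationFraction) || validationFraction <= 0 ||
      validationFraction >= 1)
    stop("validationFraction must lie strictly between 0 and 1")
  nval <- round(n * validationFraction)
  nval <- max(1L, min(n - 1L, as.integer(nval)))
  pick <- .withSeed(seed, sample.int(n, nval))
  list(training = ds[, setdiff(seq_len(n), pick)],
       validation = ds[, sort(pick)])
}

#' Fit metrics for a prediction/observation pair
#'
#' R^2 is the squared Pearson correlation between predictions and
#' observations (the squared-multiple-correlation form; for a linear fit on
#' its own training data this equals the regression R^2).  RMSE and MAE are
#' in the target's units.
#'
#' @param predictions,observations numeric vectors of equal length.
#' @return list with `R2` (NA when the observations have zero variance),
#'   `RMSE`, `MAE` and `n`.
#' @export
evaluateFit <- function(predictions, observations) {
  if (length(predictions) != length(observations))
    stop("predictions and observations must have equal length")
  n <- length(observations)
  if (n < 1L) stop("need at least one observation")
  e <- observations - predictions
  r2 <- if (stats::var(observations) <= 0 || stats::var(predictions) <= 0)
    NA_real_
  else unname(stats::cor(predictions, observations)^2)
  list(R2 = r2,
       RMSE = sqrt(mean(e^2)),
       MAE = mean(abs(e)),
       n = n)
}

#' MlrFit: multiple linear regression with printed diagnostics
#'
#' S4 container returned by [fitMlr()].  Slots: `coefficients` (intercept
#' first), `se` and `tValues` (same order; the slope standard errors follow
#' `s_bj = sqrt(p_jj) * s` with `p_jj` the diagonal of the inverted centred
#' normal matrix), `R` (multiple correlation), `R2`, `s` (residual scale on
#' n - m - 1 df), `F`, `vif` (from auxiliary regressions of each predictor
#' on the others), `fitted`, `residuals`, `n`, `m`.
#'
#' @aliases MlrFit-class
#' @export
setClass("MlrFit", representation(
  coefficients = "numeric", se = "numeric", tValues = "numeric",
  R = "numeric", R2 = "numeric", s = "numeric", F = "numeric",
  vif = "numeric", fitted = "numeric", residuals = "numeric",
  n = "integer", m = "integer"))

#' Multiple linear regression with full diagnostics
#'
#' Ordinary least squares of a target (MAP, mm/yr) on a feature matrix,
#' assembled from the printed formulas: coefficients by QR least squares,
#' multiple correlation `R = sqrt(SSreg/SStot)`, residual scale
#' `s = sqrt(RSS/(n-m-1))`, per-slope `t = b_j / (sqrt(p_jj) * s)` with
#' `p_jj` from the inverse centred cross-product matrix, overall
#' `F = SSreg / (m * s^2)`, and `VIF_j = 1/(1-R2_j)` from auxiliary
#' regressions.  The intercept's standard error comes from the full
#' (uncentred) normal-matrix inverse.
#'
#' @param X numeric feature matrix (n samples x m predictors) or a
#'   [GdgtCalibration] (in which case `features` selects compounds and `y`
#'   defaults to observed MAP).
#' @param y numeric target vector.
#' @param features compound names when `X` is a calibration set; default
#'   [defaultMapFeatures()].
#' @return An [MlrFit-class] object.  With an exactly collinear design an
#'   error lists the offending columns; with a perfect fit (`s = 0`) the t
#'   statistics are infinite.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' fit <- fitMlr(X, drop(X %*% c(1, -2, 0.5)) + rnorm(20, sd = 0.1))
#' coef(fit)
#' @export
fitMlr <- function(X, y = NULL, features = defaultMapFeatures()) {
  if (is(X, "GdgtCalibration")) {
    if (is.null(y)) y <- mapObserved(X)
    X <- fractionalAbundances(X)[, features, drop = FALSE]
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); m <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n <= m + 1L)
    stop(sprintf("need n > m + 1 samples (n = %d, m = %d)", n, m))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(m))
  Z <- cbind("(Intercept)" = 1, X)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    drop <- colnames(Z)[qz$pivot[(qz$rank + 1L):ncol(Z)]]
    stop("collinear design; offending column(s): ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qz, y)
  fitted <- drop(Z %*% beta)
  res <- y - fitted
  ybar <- mean(y)
  ssreg <- sum((fitted - ybar)^2)
  sstot <- sum((y - ybar)^2)
  R <- if (sstot > 0) min(1, sqrt(ssreg / sstot)) else NA_real_
  rss <- sum(res^2)
  ## an interpolating fit leaves only float dust in the residuals; treat it
  ## as exact so the t statistics flag as infinite rather than astronomical
  if (sstot > 0 && rss <= 1e-20 * sstot) rss <- 0
  s <- sqrt(rss / (n - m - 1L))
  ## slope SEs from the inverted centred normal matrix
  Xc <- sweep(X, 2L, colMeans(X))
  Pinv <- solve(crossprod(Xc))
  seSlope <- sqrt(diag(Pinv)) * s
  ## intercept SE from the full design inverse
  ZtZinv <- chol2inv(qr.R(qz))
  seInt <- sqrt(ZtZinv[1L, 1L]) * s
  se <- c(seInt, seSlope)
  tval <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  Fstat <- if (s > 0) ssreg / (m * s^2) else Inf
  vif <- vapply(seq_len(m), function(j) {
    if (m == 1L) return(1)
    fitj <- stats::lsfit(X[, -j, drop = FALSE], X[, j])
    rj <- X[, j] - mean(X[, j])
    r2j <- 1 - sum(fitj$residuals^2) / sum(rj^2)
    if (r2j >= 1) Inf else 1 / (1 - r2j)
  }, numeric(1))
  names(vif) <- colnames(X)
  new("MlrFit",
      coefficients = beta, se = se, tValues = tval,
      R = R, R2 = R^2, s = s, F = Fstat, vif = vif,
      fitted = fitted, residuals = res, n = as.integer(n), m = as.integer(m))
}

#' @describeIn fitMlr coefficients (intercept first).
#' @param object,... standard S4 method arguments.
#' @export
setMethod("coef", "MlrFit", function(object, ...) object@coefficients)

#' @describeIn fitMlr predictions for a new feature matrix (or
#'   [GdgtCalibration]).
#' @param newdata feature matrix with the fitted columns.
#' @export
setGeneric("predictMlr", function(object, newdata, ...)
  standardGeneric("predictMlr"))

#' @rdname fitMlr
#' @export
setMethod("predictMlr", "MlrFit", function(object, newdata, ...) {
  nm <- names(object@coefficients)[-1L]
  if (is(newdata, "GdgtSet"))
    newdata <- fractionalAbundances(newdata)
  newdata <- as.matrix(newdata)
  if (!all(nm %in% colnames(newdata)))
    stop("newdata lacks fitted feature column(s): ",
         paste(setdiff(nm, colnames(newdata)), collapse = ", "))
  drop(cbind(1, newdata[, nm, drop = FALSE]) %*% object@coefficients)
})

setMethod("show", "MlrFit", function(object) {
  cat(sprintf("MlrFit: n = %d, m = %d, R = %.4f, R2 = %.4f, s = %.4g, F = %.4g\n",
              object@n, object@m, object@R, object@R2, object@s, object@F))
  print(data.frame(coefficient = object@coefficients,
                   se = object@se, t = object@tValues,
                   VIF = c(NA, object@vif)))
  invisible(NULL)
})
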