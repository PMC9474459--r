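## Continuous and cross wavelet analysis on uniform age grids, plus a PCA
## summary for environmental factor matrices.
##
## The mother wavelet is the Morlet with center frequency omega0 = 6, the
## standard choice in paleoclimate wavelet practice; the transform follows
## the classical FFT formulation (zero padding to the next power of two,
## dyadic scale set, cone-of-influence masking at the sqrt(2)*scale
## e-folding distance).  The cross spectrum of two series is
## CS = W1 * Conj(W2); its modulus locates shared periodicity and its
## argument the phase relation.  Sign convention: a *positive* phase at a
## band means series 1 leads series 2 (s2 lagged by `lag` gives phase
## +2*pi*lag/period); phase +/- pi is anti-phase ("arrows left").

#' Continuous Morlet wavelet transform
#'
#' @param values numeric series on a uniform grid, length >= 16.
#' @param step grid step (ka per sample).
#' @param omega0 Morlet center frequency (default 6).
#' @param dj scale resolution in octaves (default 0.1); scales are dyadic
#'   from 2*step up to half the series span.
#' @return list of class `cwt`: `coef` (complex, scales x times), `period`
#'   (ka per scale), `scale`, `time` (ka offsets), `coi` (per-time maximum
#'   reliable period, ka), `inCoi` (logical matrix, TRUE where the
#'   coefficient lies inside the cone of influence, i.e. is edge-affected),
#'   `step`, `omega0`.
#' @export
cwtMorlet <- function(values, step = 1, omega0 = 6, dj = 0.1) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 16L) stop("series too short: need at least 16 samples")
  if (any(!is.finite(values))) stop("series values must be finite")
  if (step <= 0) stop("step must be positive")
  ## zero-pad to next power of two
  npad <- 2^ceiling(log2(n))
  x <- c(values - mean(values), numeric(npad - n))
  xf <- stats::fft(x)
  ## angular frequencies of the padded grid
  k <- c(seq(0, floor(npad / 2)), seq(-(ceiling(npad / 2) - 1), -1))
  w <- 2 * pi * k / (npad * step)
  ## dyadic scales spanning periods [2*step, span/2]
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))  # Fourier factor
  s0 <- 2 * step / ff
  J <- floor(log2(n * step / (2 * s0)) / dj)
  scale <- s0 * 2^(dj * seq(0, max(J, 0)))
  coef <- matrix(0i, length(scale), n)
  norm0 <- pi^(-1 / 4)
  for (j in seq_along(scale)) {
    s <- scale[j]
    psi <- norm0 * sqrt(2 * pi * s / step) *
      exp(-0.5 * (s * w - omega0)^2) * (w > 0)
    wave <- stats::fft(xf * psi, inverse = TRUE) / npad
    coef[j, ] <- wave[seq_len(n)]
  }
  period <- ff * scale
  tgrid <- (seq_len(n) - 1L) * step
  edge <- pmin(tgrid, (n - 1L) * step - tgrid)
  coi <- ff / sqrt(2) * pmax(edge, 1e-12)
  inCoi <- outer(period, coi, ">")
  structure(list(coef = coef, period = period, scale = scale, time = tgrid,
                 coi = coi, inCoi = inCoi, step = step, omega0 = omega0),
            class = "cwt")
}

#' @export
print.cwt <- function(x, ...) {
  cat(sprintf("Morlet CWT: %d times x %d scales, periods %.3g - %.3g ka\n",
              ncol(x$coef), nrow(x$coef), min(x$period), max(x$period)))
  invisible(x)
}

.asGridded <- function(s) {
  if (is.list(s) && !is.null(s$age) && !is.null(s$value))
    s <- data.frame(age = s$age, value = s$value)
  if (is.data.frame(s)) {
    st <- diff(s$age)
    if (length(st) < 1L) stop("series needs at least 2 samples")
    if (max(abs(st - st[1L])) > 1e-6 * abs(st[1L]))
      stop("series is not on a uniform grid; resample with resampleToAgeGrid()")
    list(values = s$value, step = st[1L], start = s$age[1L])
  } else stop("series must be a data.frame with 'age' and 'value'")
}

#' Cross wavelet spectrum of two gridded series
#'
#' Computes `CS = W1 * Conj(W2)` on the common Morlet scale set and
#' decomposes it into amplitude `|CS|` and phase `arg(CS)` (radians in
#' (-pi, pi]).  The two series must share the same uniform grid (resample
#' first; a 1-ka grid is the conventional choice).
#'
#' @param s1,s2 data.frames with `age` and `value` on identical uniform
#'   grids.
#' @param omega0,dj as in [cwtMorlet()].
#' @return list of class `crossSpectrum`: `cs` (complex, scales x times),
#'   `amplitude`, `phase`, `period`, `time`, `coi`, `inCoi`, plus the two
#'   component transforms `w1`, `w2`.
#' @export
crossWavelet <- function(s1, s2, omega0 = 6, dj = 0.1) {
  g1 <- .asGridded(s1); g2 <- .asGridded(s2)
  if (length(g1$values) != length(g2$values) ||
      abs(g1$step - g2$step) > 1e-9 * g1$step ||
      abs(g1$start - g2$start) > 1e-9 * max(1, abs(g1$start)))
    stop("series grids differ; resample both onto a common grid first")
  w1 <- cwtMorlet(g1$values, g1$step, omega0 = omega0, dj = dj)
  w2 <- cwtMorlet(g2$values, g2$step, omega0 = omega0, dj = dj)
  cs <- w1$coef * Conj(w2$coef)
  structure(list(cs = cs, amplitude = Mod(cs), phase = Arg(cs),
                 period = w1$period, time = w1$time + g1$start,
                 coi = w1$coi, inCoi = w1$inCoi, w1 = w1, w2 = w2),
            class = "crossSpectrum")
}

#' @export
print.crossSpectrum <- function(x, ...) {
  cat(sprintf("cross-wavelet spectrum: %d times x %d scales (%.3g - %.3g ka)\n",
              ncol(x$cs), nrow(x$cs), min(x$period), max(x$period)))
  invisible(x)
}

#' Band-averaged phase and anti-phase verdict
#'
#' Power-weighted circular mean of the cross-wavelet phase over the scales
#' whose period lies within `bandTolerance` (fractional) of the target
#' period, excluding coefficients inside the cone of influence.  The
#' anti-phase verdict is TRUE when the circular distance of the mean phase
#' from pi is below `phaseTolerance`.
#'
#' @param cs a [crossWavelet()] result.
#' @param period target period (ka); must lie inside the resolved range.
#' @param bandTolerance half-width of the period band as a fraction of
#'   `period` (default 0.2).
#' @param phaseTolerance radians for the anti-phase verdict (default 0.5).
#' @param excludeCoi drop in-cone coefficients (default TRUE).
#' @return list with `meanPhase` (radians), `antiPhase` (logical), `power`
#'   (summed band amplitude) and `nUsed`.
#' @export
bandPhase <- function(cs, period, bandTolerance = 0.2,
                      phaseTolerance = 0.5, excludeCoi = TRUE) {
  stopifnot(inherits(cs, "crossSpectrum"))
  if (period < min(cs$period) || period > max(cs$period))
    stop(sprintf("period %g ka outside the resolved range [%.3g, %.3g]",
                 period, min(cs$period), max(cs$period)))
  rows <- which(abs(cs$period - period) <= bandTolerance * period)
  if (length(rows) == 0L)
    rows <- which.min(abs(cs$period - period))
  use <- matrix(TRUE, nrow(cs$cs), ncol(cs$cs))
  if (excludeCoi) use <- !cs$inCoi
  use <- use[rows, , drop = FALSE]
  if (!any(use))
    stop("insufficient coverage: the band lies entirely inside the cone of influence")
  amp <- cs$amplitude[rows, , drop = FALSE][use]
  ph <- cs$phase[rows, , drop = FALSE][use]
  meanPhase <- atan2(sum(amp * sin(ph)), sum(amp * cos(ph)))
  dist <- abs(atan2(sin(meanPhase - pi), cos(meanPhase - pi)))
  list(meanPhase = meanPhase, antiPhase = dist < phaseTolerance,
       power = sum(amp), nUsed = sum(use))
}

#' PCA summary of an environmental factor matrix
#'
#' Thin wrapper around [stats::prcomp()] for samples-by-factors matrices
#' (e.g. reconstructed MAP, MAT, SWC and pH down a profile): reports the
#' fraction of variance per axis, the loadings and the scores.
#'
#' @param x numeric matrix or data.frame, >= 3 samples by >= 2 factors, no
#'   missing cells.
#' @param standardize scale each factor to unit variance (default TRUE,
#'   appropriate for mixed-unit matrices).
#' @return list with `varianceFraction` (sums to 1, non-increasing),
#'   `loadings` (orthonormal columns), `scores` and `center`/`scale`.
#' @export
pcaSummary <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3L || ncol(x) < 2L)
    stop("need at least 3 samples and 2 factors")
  if (any(!is.finite(x))) stop("missing or non-finite cells are not allowed")
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance column(s) cannot be standardized: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  v <- pc$sdev^2
  list(varianceFraction = v / sum(v),
       loadings = pc$rotation,
       scores = pc$x,
       center = pc$center,
       scale = if (standardize) pc$scale else NULL)
}

#' Shapiro-Wilk normality screen
#'
#' Convenience utility applying [stats::shapiro.test()] to each column of a
#' factor matrix (the PCA itself does not require normality).
#'
#' @param x numeric matrix or data.frame.
#' @return data.frame with columns `factor`, `W`, `pValue`.
#' @export
normalityCheck <- function(x) {
  x <- as.matrix(x)
  res <- lapply(seq_len(ncol(x)), function(j) {
    t <- stats::shapiro.test(x[, j])
    data.frame(factor = colnames(x)[j] %||% paste0("V", j),
               W = unname(t$statistic), pValue = t$p.value)
  })
  do.call(rbind, res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
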