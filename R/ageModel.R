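## Susceptibility-weighted age-depth modelling for loess-paleosol profiles.
##
## Between two chronological control points the accumulated age is allocated
## in proportion to the cumulative thickness-times-susceptibility of the
## layers above the sample (magnetic susceptibility is used as a proxy for
## accumulated pedogenic time per unit thickness):
##
##   T_m = T1 + (sum_{i<=m} a_i s_i) * (T2 - T1) / (sum_{i<=n} a_i s_i)
##
## A "layer" is one sampling interval (10 cm in the canonical scheme); the
## sample's nominal position is the base of its layer, so layers 1..m lie at
## or above the dated sample.  Depths are metres below the profile top; ages
## are ka BP, increasing downward.

#' Susceptibility-weighted age assignment
#'
#' Assigns an age to each layer base by susceptibility-weighted
#' interpolation between consecutive control points (see the formula above).
#' With constant susceptibility this reduces exactly to linear depth-age
#' interpolation; multiplying all susceptibilities by a constant leaves the
#' ages unchanged.
#'
#' @param layers data.frame with columns `depth` (layer-base depth, m,
#'   strictly increasing) and `susceptibility` (>= 0); layer thickness is
#'   taken as the spacing between successive bases (the first layer extends
#'   up to the shallowest control point).  Alternatively a [GdgtProfile]
#'   whose `colData` has `depth` and `susceptibility`.
#' @param controls data.frame with columns `depth` (m) and `age` (ka BP);
#'   ages must strictly increase with depth.  Every layer must lie within
#'   the control span (no extrapolation).
#' @param uniformFallback if every layer inside a control interval has zero
#'   susceptibility the interval's weights are degenerate; with
#'   `uniformFallback = TRUE` thickness-only (uniform-accumulation) weights
#'   are used there instead of raising an error.
#' @return An object of class `ageModel`: a list with `age` (ka per layer
#'   base), `depth`, `controls`, `cumulativeWeight` and `uniformIntervals`
#'   (indices of intervals where the fallback fired).  If `layers` was a
#'   [GdgtProfile], use [applyAgeModel()] to attach the ages.
#' @examples
#' lay <- data.frame(depth = seq(0.1, 10, 0.1), susceptibility = 1)
#' ctl <- data.frame(depth = c(0, 10), age = c(0, 100))
#' am <- assignAges(lay, ctl)
#' am$age[50]  # 50 ka: constant susceptibility = linear interpolation
#' @export
assignAges <- function(layers, controls, uniformFallback = FALSE) {
  if (is(layers, "GdgtProfile"))
    layers <- data.frame(depth = depths(layers),
                         susceptibility = susceptibility(layers))
  stopifnot(is.data.frame(layers),
            all(c("depth", "susceptibility") %in% colnames(layers)))
  d <- as.numeric(layers$depth)
  s <- as.numeric(layers$susceptibility)
  if (any(diff(d) <= 0)) stop("layer depths must be strictly increasing")
  if (any(!is.finite(s)) || any(s < 0))
    stop("susceptibilities must be finite and non-negative")
  controls <- controls[order(controls$depth), , drop = FALSE]
  cd <- as.numeric(controls$depth)
  ca <- as.numeric(controls$age)
  if (length(cd) < 2L) stop("need at least two control points")
  if (any(diff(cd) <= 0)) stop("control depths must be strictly increasing")
  if (any(diff(ca) <= 0)) stop("control ages must strictly increase with depth")
  ## snap depths that sit within float noise of a control point onto it,
  ## so interval assignment is stable under inexact grid spacing
  for (k in seq_along(cd)) {
    hit <- abs(d - cd[k]) < 1e-9 * max(1, abs(cd[k]))
    d[hit] <- cd[k]
  }
  if (min(d) <= cd[1L] - 1e-12 || max(d) > cd[length(cd)] + 1e-12)
    stop(sprintf(paste0("sample depths [%g, %g] fall outside the control ",
                        "span [%g, %g]; extrapolation is not supported"),
         min(d), max(d), cd[1L], cd[length(cd)]))

  ## thickness of each layer: spacing between bases; first layer reaches up
  ## to the top control point
  a <- diff(c(cd[1L], d))

  age <- numeric(length(d))
  cumw <- numeric(length(d))
  uniform <- integer()
  ## interval k spans (cd[k], cd[k+1]]
  idx <- findInterval(d, cd, left.open = TRUE, rightmost.closed = TRUE)
  for (k in seq_len(length(cd) - 1L)) {
    in.k <- which(idx == k)
    if (length(in.k) == 0L) next
    ## thickness of the first layer of the interval restarts at the control
    first <- in.k[1L]
    ak <- a[in.k]
    ak[1L] <- d[first] - cd[k]
    wk <- ak * s[in.k]
    tot <- sum(wk)
    if (tot <= 0) {
      if (!uniformFallback)
        stop(sprintf(paste0("all-zero susceptibility weights in control ",
                            "interval %d (%g-%g m); pass uniformFallback = ",
                            "TRUE for thickness-only interpolation"),
                     k, cd[k], cd[k + 1L]))
      wk <- ak
      tot <- sum(wk)
      uniform <- c(uniform, k)
    }
    cw <- cumsum(wk)
    ## a layer base exactly on the lower control point gets the control age
    age[in.k] <- ca[k] + cw / tot * (ca[k + 1L] - ca[k])
    cumw[in.k] <- cw
  }
  ## exact boundary identity at control depths
  at.ctl <- match(round(d, 12), round(cd, 12))
  hit <- !is.na(at.ctl)
  age[hit] <- ca[at.ctl[hit]]
  structure(list(age = age, depth = d,
                 controls = data.frame(depth = cd, age = ca),
                 cumulativeWeight = cumw, uniformIntervals = uniform),
            class = "ageModel")
}

#' @export
print.ageModel <- function(x, ...) {
  cat(sprintf("ageModel: %d layers, %d control points, %g - %g ka\n",
              length(x$age), nrow(x$controls), min(x$age), max(x$age)))
  invisible(x)
}

#' Attach model ages to a profile
#'
#' @param profile a [GdgtProfile].
#' @param controls control points (see [assignAges()]).
#' @param uniformFallback see [assignAges()].
#' @return the profile with an `age` column in `colData`.
#' @export
applyAgeModel <- function(profile, controls, uniformFallback = FALSE) {
  stopifnot(is(profile, "GdgtProfile"))
  am <- assignAges(profile, controls, uniformFallback = uniformFallback)
  ages(profile) <- am$age
  profile
}

#' Resample a dated series onto a uniform age grid
#'
#' Linear interpolation of (age, value) samples onto a uniform grid (default
#' 1-ka step) spanning only the sampled age range, the common pre-processing
#' step before wavelet comparison of two records.
#'
#' @param age numeric ages (ka), strictly increasing; at least 2.
#' @param values numeric values at those ages.
#' @param step grid step in ka (default 1).
#' @param start optional grid start; default the first multiple of `step` at
#'   or above `min(age)`.
#' @return data.frame with columns `age` and `value` on the uniform grid.
#' @examples
#' resampleToAgeGrid(c(0, 2), c(0, 2), step = 1)$value  # 0 1 2
#' @export
resampleToAgeGrid <- function(age, values, step = 1, start = NULL) {
  stopifnot(length(age) == length(values))
  if (length(age) < 2L)
    stop("insufficient data: need at least 2 samples to interpolate")
  if (any(diff(age) <= 0)) stop("ages must be strictly increasing")
  if (step <= 0) stop("step must be positive")
  if (is.null(start)) start <- ceiling(age[1L] / step) * step
  grid <- seq(start, max(age), by = step)
  grid <- grid[grid >= age[1L] - 1e-9]
  data.frame(age = grid,
             value = stats::approx(age, values, xout = grid)$y)
}
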