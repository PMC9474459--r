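## Synthetic-data generators with known truth, emulating (i) a global
## surface-soil calibration compilation (compositional lipid vectors
## responding to latent climate), (ii) a 430-ka loess-paleosol downcore
## profile with 100-ka and 23-ka cyclicity, and (iii) paired gridded series
## for cross-wavelet tests.  Every generator is deterministic given its
## seed and returns the latent truth alongside the observables.

## Linear response of compound logits to standardized climate drivers.
## 5-methyl/tetra compounds load mainly on temperature (methylation degree
## falls as MAT rises), cyclized compounds on pH, and the 6-methyl isomers
## mainly on moisture (drier -> more 6-methyl), echoing the empirical
## behaviour of soils.  Columns: intercept, MAT, MAP (moisture), pH.
.GDGT_LOGIT_LOADINGS <- matrix(c(
  ## alpha   tm     pm     hm
   1.2,  1.8,  0.8,  0.0,   # Ia
  -0.5,  1.2,  0.0,  0.8,   # Ib
  -1.2,  0.8, -0.6,  1.0,   # Ic
   1.0, -1.6,  0.0,  0.0,   # IIa
   2.4,  0.0, -2.8,  1.2,   # IIa'
  -0.6, -1.0,  0.0,  0.6,   # IIb
   1.0,  0.0, -1.6,  1.0,   # IIb'
  -1.8, -0.8,  0.0,  0.8,   # IIc
   0.0,  0.0, -1.0,  0.8,   # IIc'
   0.6, -2.2,  0.0,  0.0,   # IIIa
   2.2,  0.0, -3.4,  1.0,   # IIIa'
  -1.6, -1.4,  0.0,  0.0,   # IIIb
   0.2,  0.0, -2.0,  0.8,   # IIIb'
  -2.4, -1.2,  0.0,  0.0,   # IIIc
  -0.6,  0.0, -1.4,  0.6),  # IIIc'
  nrow = 15L, byrow = TRUE,
  dimnames = list(.GDGT_COMPOUNDS, c("alpha", "tm", "pm", "hm")))

## mean compositions from latent drivers via a normalized-exponential map
.meanComposition <- function(MAT, MAP, pH, link = "mixed") {
  tm <- (MAT + 5) / 33
  hm <- (pH - 4) / 5
  pmLin <- (MAP - 50) / 2950
  ## the saturating channel plateaus above ~1500 mm, the regime where
  ## linear composition-precipitation transfer functions break down
  pmSat <- tanh(MAP / 1500) / tanh(2)
  pm <- switch(link,
               linear = pmLin,
               saturating = pmSat,
               mixed = 0.5 * (pmLin + pmSat),
               stop("link must be 'linear', 'saturating' or 'mixed'"))
  Z <- cbind(1, tm, pm, hm)
  eta <- Z %*% t(.GDGT_LOGIT_LOADINGS)
  mu <- exp(eta)
  mu / rowSums(mu)
}

## Dirichlet draw around mean composition with concentration kappa
.rdirichlet <- function(mu, kappa) {
  g <- matrix(stats::rgamma(length(mu), shape = mu * kappa),
              nrow(mu), ncol(mu), dimnames = dimnames(mu))
  zero <- rowSums(g) <= 0
  if (any(zero)) g[zero, ] <- mu[zero, , drop = FALSE]  # kappa -> Inf limit
  g / rowSums(g)
}

#' Simulate a surface-soil calibration compilation
#'
#' Draws latent climate (MAT, MAP, pH) uniformly over realistic global
#' ranges, maps it to mean brGDGT compositions through a
#' normalized-exponential (softmax) response in which 5-methyl compounds
#' load mainly on temperature and 6-methyl compounds on moisture and pH,
#' adds Dirichlet compositional noise with concentration `kappa`, and
#' records MAP with additive observation noise — a desk-scale emulation of
#' a multi-laboratory 712-soil compilation.
#'
#' @param n number of samples (default 712).
#' @param seed integer seed; identical seeds give identical datasets.
#' @param link shape of the moisture channel: `"linear"`, `"saturating"`
#'   (plateaus above ~1500 mm) or `"mixed"` (default; mean of the two).
#' @param kappa Dirichlet concentration of compositional measurement noise
#'   (default 200; larger = cleaner compositions).
#' @param mapNoise sd of additive MAP observation noise in mm (default 100).
#' @param matRange,mapRange,phRange latent climate ranges (defaults
#'   -5..28 C, 50..3000 mm, pH 4..9).
#' @return list with `dataset` (a [GdgtCalibration]; `colData` holds the
#'   noisy `MAP` plus latent `MAT` and `pH`) and `truth` (data.frame of
#'   latent per-sample MAT/MAP/pH and the link name).
#' @examples
#' sim <- simulateCalibration(n = 10, seed = 1)
#' sim$dataset
#' @export
simulateCalibration <- function(n = 712L, seed = 1L, link = "mixed",
                                kappa = 200, mapNoise = 100,
                                matRange = c(-5, 28),
                                mapRange = c(50, 3000),
                                phRange = c(4, 9)) {
  stopifnot(n >= 1L, kappa > 0, mapNoise >= 0,
            diff(matRange) > 0, diff(mapRange) > 0, diff(phRange) > 0)
  .withSeed(seed, {
    MAT <- stats::runif(n, matRange[1L], matRange[2L])
    MAP <- stats::runif(n, mapRange[1L], mapRange[2L])
    pH <- stats::runif(n, phRange[1L], phRange[2L])
    mu <- .meanComposition(MAT, MAP, pH, link)
    fa <- .rdirichlet(mu, kappa)
    mapObs <- pmax(0, MAP + stats::rnorm(n, 0, mapNoise))
    rownames(fa) <- sprintf("s%03d", seq_len(n))
    ds <- GdgtCalibration(
      fa = fa,
      colData = S4Vectors::DataFrame(MAP = mapObs, MAT = MAT, pH = pH,
                                     row.names = rownames(fa)))
    truth <- data.frame(MAT = MAT, MAP = MAP, pH = pH,
                        row.names = rownames(fa))
    attr(truth, "link") <- link
    list(dataset = ds, truth = truth)
  })
}

#' Simulate a downcore loess-paleosol profile
#'
#' Builds a synthetic profile with the cyclic structure of late-Pleistocene
#' loess records: the latent temperature / soil-water signal follows a
#' 100-ka glacial-interglacial sawtooth (slow cooling, fast termination),
#' latent precipitation follows a 23-ka precessional sinusoid plus noise,
#' magnetic susceptibility covaries with the 100-ka component (pedogenic
#' enhancement in interglacials), and layer thickness shrinks when
#' susceptibility is high, so that thickness-times-susceptibility tracks
#' elapsed time and the susceptibility-weighted age model can recover the
#' true chronology from the end-point controls alone.  Compositions follow
#' the same climate-to-logit response as [simulateCalibration()].
#'
#' @param lengthKa time span in ka (default 430).
#' @param stepKa true time per layer in ka (default 1); `lengthKa/stepKa`
#'   must give at least 64 layers.
#' @param amplitude100,amplitude23 peak amplitudes of the 100-ka MAT
#'   component (degrees C, default 5, i.e. ~10 C glacial-interglacial range)
#'   and of the 23-ka MAP component (mm, default 300).
#' @param seed integer seed.
#' @param kappa,mapNoise compositional and precipitation noise as in
#'   [simulateCalibration()].
#' @return list with `profile` (a [GdgtProfile] whose `colData` carries
#'   `depth`, `susceptibility`, `grainSize` and n-alkane homolog columns),
#'   `controls` (end-point control data.frame) and `truth` (data.frame with
#'   true `age`, `MAT`, `MAP`, `pH` per layer).
#' @export
simulateDowncoreProfile <- function(lengthKa = 430, stepKa = 1,
                                    amplitude100 = 5, amplitude23 = 300,
                                    seed = 1L, kappa = 200, mapNoise = 50) {
  nlay <- floor(lengthKa / stepKa)
  if (nlay < 64L) stop("length/step must yield at least 64 layers")
  .withSeed(seed, {
    age <- seq(stepKa, by = stepKa, length.out = nlay)  # layer-base ages
    ## 100-ka sawtooth in [-1, 1]: slow glacial cooling, abrupt termination
    phase <- (age %% 100) / 100
    saw <- 1 - 2 * phase
    MAT <- 9 + amplitude100 * saw + stats::rnorm(nlay, 0, 0.4)
    MAP <- 600 + amplitude23 * sin(2 * pi * age / 23) +
      stats::rnorm(nlay, 0, mapNoise)
    MAP <- pmax(50, MAP)
    pH <- 7.6 - 0.15 * saw + stats::rnorm(nlay, 0, 0.05)
    ## susceptibility high in warm (interglacial) layers; SI-instrument-like
    susc <- 60 + 45 * saw + stats::rnorm(nlay, 0, 3)
    susc <- pmax(5, susc)
    ## equal time per layer; thickness inversely tracks susceptibility so
    ## that a_i * s_i ~ elapsed time (loess accumulates fast, soils slowly)
    thick <- 0.1 * mean(susc) / susc
    depth <- cumsum(thick)
    mu <- .meanComposition(MAT, MAP, pH, link = "mixed")
    fa <- .rdirichlet(mu, kappa)
    rownames(fa) <- sprintf("d%04d", seq_len(nlay))
    ## leaf-wax homologs: odd dominance rises with moisture, ACL with warmth
    cpiTrue <- 4 + 2 * (MAP - 600) / 600
    homologs <- t(vapply(seq_len(nlay), function(i) {
      ns <- 23:34
      center <- 28.5 + 1.2 * saw[i]
      base <- exp(-((ns - center)^2) / 18)
      odd <- ns %% 2 == 1
      base[odd] <- base[odd] * pmax(1.5, cpiTrue[i])
      base * stats::rlnorm(12, 0, 0.05)
    }, numeric(12)))
    colnames(homologs) <- paste0("C", 23:34)
    cd <- S4Vectors::DataFrame(
      depth = depth, susceptibility = susc,
      grainSize = 20 - 6 * saw + stats::rnorm(nlay, 0, 0.8),
      homologs, row.names = rownames(fa))
    profile <- GdgtProfile(fa = fa, colData = cd)
    controls <- data.frame(depth = c(0, max(depth)),
                           age = c(0, max(age)))
    truth <- data.frame(age = age, MAT = MAT, MAP = MAP, pH = pH,
                        row.names = rownames(fa))
    list(profile = profile, controls = controls, truth = truth)
  })
}

#' Simulate a phase-lagged pair of gridded series
#'
#' Two unit sinusoids of the given period on a uniform age grid, the second
#' shifted by `phaseOffset` radians (pi = anti-phase), each with independent
#' Gaussian noise — the planted-truth input for cross-wavelet phase tests.
#'
#' @param periodKa common period in ka (default 23).
#' @param phaseOffset phase shift of series 2 relative to series 1, radians.
#' @param noiseSd sd of the additive noise (default 0.1).
#' @param lengthKa grid span in ka (default 430); `stepKa` grid step
#'   (default 1).
#' @param seed integer seed.
#' @return list of two data.frames `s1`, `s2` (columns `age`, `value`) plus
#'   the generation parameters in `truth`.
#' @export
simulatePairedSeries <- function(periodKa = 23, phaseOffset = pi,
                                 noiseSd = 0.1, lengthKa = 430, stepKa = 1,
                                 seed = 1L) {
  if (periodKa < 2 * stepKa) stop("period is not resolvable on the grid")
  .withSeed(seed, {
    age <- seq(0, lengthKa, by = stepKa)
    w <- 2 * pi / periodKa
    v1 <- sin(w * age) + stats::rnorm(length(age), 0, noiseSd)
    v2 <- sin(w * age - phaseOffset) + stats::rnorm(length(age), 0, noiseSd)
    list(s1 = data.frame(age = age, value = v1),
         s2 = data.frame(age = age, value = v2),
         truth = list(periodKa = periodKa, phaseOffset = phaseOffset,
                      noiseSd = noiseSd))
  })
}
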