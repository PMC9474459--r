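# Shared fixtures, built in code at test time.

# a named abundance vector covering all 15 compounds, summing to 1
fullAbundanceVector <- function() {
  v <- c(Ia = 0.22, Ib = 0.05, Ic = 0.03,
         IIa = 0.10, "IIa'" = 0.16, IIb = 0.04, "IIb'" = 0.06,
         IIc = 0.01, "IIc'" = 0.02,
         IIIa = 0.08, "IIIa'" = 0.14, IIIb = 0.02, "IIIb'" = 0.04,
         IIIc = 0.01, "IIIc'" = 0.02)
  stopifnot(abs(sum(v) - 1) < 1e-12)
  v
}

# random points on the 15-part simplex, named by registry compounds
randomSimplex <- function(n, seed = 1) {
  set.seed(seed)
  g <- matrix(rgamma(n * 15L, shape = 0.7), n, 15L)
  fa <- g / rowSums(g)
  colnames(fa) <- gdgtCompounds()
  fa
}

# small calibration table file on disk; returns its path
writeTempCalibration <- function(n = 4, dir = tempdir(), delim = ",") {
  sim <- simulateCalibration(n = n, seed = 99)
  path <- file.path(dir, paste0("cal-", n, ".csv"))
  writeCalibrationTable(sim$dataset, path, delim = delim)
  path
}
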