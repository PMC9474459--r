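## Closed-form lipid indices and calibrations.
##
## All index functions accept a GdgtSet, a samples-by-compounds matrix /
## data.frame, or a single named abundance vector, and are vectorized over
## samples.  Compounds not mentioned in an input vector are taken as absent
## (zero) for index algebra; strictness about missing columns lives in the
## ingestion layer.  Ratio indices are scale-invariant, so inputs need not
## be normalized.  Undefined ratios (zero numerator or denominator of a
## logarithm, zero denominator of a ratio) return NA rather than raising, so
## batch runs over degenerate downcore horizons survive; definedness is
## simply !is.na() of the result.

## coerce to samples x 15 matrix, canonical column order, absent -> 0
.faInput <- function(x) {
  if (is(x, "GdgtSet")) return(fractionalAbundances(x))
  if (is.numeric(x) && is.null(dim(x))) x <- t(as.matrix(x))
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    stop("abundance input must have compound names")
  colnames(x) <- normalizeCompoundNames(colnames(x))
  m <- matrix(0, nrow(x), 15L, dimnames = list(rownames(x), .GDGT_COMPOUNDS))
  keep <- intersect(colnames(x), .GDGT_COMPOUNDS)
  m[, keep] <- x[, keep, drop = FALSE]
  if (any(!is.finite(m)) || any(m < 0))
    stop("abundances must be finite and non-negative")
  m
}

.rowSum <- function(m, cols) rowSums(m[, cols, drop = FALSE])

.safeRatio <- function(num, den) {
  out <- ifelse(den > 0, num / den, NA_real_)
  unname(out)
}

#' Methylation index of branched tetraethers (MBT')
#'
#' `MBT' = (Ia+Ib+Ic) / (Ia+Ib+Ic+IIa+IIa'+IIb+IIb'+IIc+IIc'+IIIa+IIIa')`.
#' The denominator set is exactly the printed one (the IIIb/IIIb'/IIIc/IIIc'
#' series is excluded).  In (semi)arid settings where the 6-methyl isomers
#' dominate (IR6ME > 0.5), MBT' tracks relative soil water content rather
#' than temperature.
#'
#' @param x GdgtSet, samples-by-compounds matrix, or named abundance vector.
#' @return numeric vector in [0, 1]; NA where the denominator is zero.
#' @examples
#' mbtPrime(c(Ia = 0.2, IIa = 0.3, IIIa = 0.5))  # 0.2
#' @export
mbtPrime <- function(x) {
  m <- .faInput(x)
  num <- .rowSum(m, c("Ia", "Ib", "Ic"))
  den <- num + .rowSum(m, c("IIa", "IIa'", "IIb", "IIb'", "IIc", "IIc'",
                            "IIIa", "IIIa'"))
  .safeRatio(num, den)
}

#' 6-methyl variant of MBT'
#'
#' `MBT'6ME = (Ia+Ib+Ic) / (Ia+Ib+Ic+IIa'+IIb'+IIc'+IIIa')` — the
#' methylation index computed against the 6-methyl isomers only, per the
#' printed compound set.
#'
#' @inheritParams mbtPrime
#' @return numeric vector in [0, 1]; NA where the denominator is zero.
#' @export
mbtPrime6Me <- function(x) {
  m <- .faInput(x)
  num <- .rowSum(m, c("Ia", "Ib", "Ic"))
  den <- num + .rowSum(m, c("IIa'", "IIb'", "IIc'", "IIIa'"))
  .safeRatio(num, den)
}

#' Isomer ratio of 6-methyl brGDGTs (IR6ME)
#'
#' Default (as printed): the summed 6-methyl isomers over the summed
#' abundance of all 15 brGDGTs.  `convention = "pentaHexa"` restricts the
#' denominator to the penta- plus hexamethylated compounds (the literature
#' convention, in which 5- and 6-methyl isomers partition the denominator).
#'
#' @inheritParams mbtPrime
#' @param convention `"all"` (printed formula, default) or `"pentaHexa"`.
#' @return numeric vector in [0, 1]; NA for empty samples.
#' @export
ir6Me <- function(x, convention = c("all", "pentaHexa")) {
  convention <- match.arg(convention)
  m <- .faInput(x)
  num <- .rowSum(m, sixMethylCompounds())
  den <- if (convention == "all") rowSums(m)
         else num + .rowSum(m, fiveMethylCompounds())
  .safeRatio(num, den)
}

#' Cyclization indices CBT' and CBT
#'
#' `cbtPrime()` computes
#' `CBT' = -log10((Ic+IIa'+IIb'+IIc'+IIIa'+IIIb'+IIIc') / (Ia+Ib+Ic))`,
#' the 6-methyl-based cyclization/pH index.  `cbt()` computes the classical
#' `CBT = -log10((Ib+IIb) / (Ia+IIa))` needed by [maatWeijers()].
#' Both return NA where the numerator or denominator of the log is zero.
#'
#' @inheritParams mbtPrime
#' @return numeric vector (dimensionless, log10 scale).
#' @examples
#' cbtPrime(c(Ia = 0.5, Ib = 0.3, Ic = 0.2))  # -log10(0.2 / 1) = 0.69897
#' @export
cbtPrime <- function(x) {
  m <- .faInput(x)
  num <- .rowSum(m, c("Ic", "IIa'", "IIb'", "IIc'", "IIIa'", "IIIb'",
                      "IIIc'"))
  den <- .rowSum(m, c("Ia", "Ib", "Ic"))
  unname(ifelse(num > 0 & den > 0, -log10(num / den), NA_real_))
}

#' @rdname cbtPrime
#' @export
cbt <- function(x) {
  m <- .faInput(x)
  num <- .rowSum(m, c("Ib", "IIb"))
  den <- .rowSum(m, c("Ia", "IIa"))
  unname(ifelse(num > 0 & den > 0, -log10(num / den), NA_real_))
}

#' Soil pH from CBT'
#'
#' Linear calibration `pH = 7.15 + 1.59 * CBT'` (global soil calibration,
#' n = 221, R^2 = 0.85, RMSE = 0.52 pH units).  `soilPH()` composes it with
#' [cbtPrime()].
#'
#' @param cbtPrime numeric CBT' value(s); NA propagates.
#' @return pH units.
#' @examples
#' phFromCbtPrime(0)   # 7.15
#' phFromCbtPrime(-1)  # 5.56
#' @export
phFromCbtPrime <- function(cbtPrime) 7.15 + 1.59 * cbtPrime

#' @rdname phFromCbtPrime
#' @inheritParams mbtPrime
#' @export
soilPH <- function(x) phFromCbtPrime(cbtPrime(x))

#' Temperature calibrations from brGDGT fractional abundances
#'
#' Four mean-annual-(air-)temperature transfer functions:
#' \describe{
#'   \item{`matMr()`}{`7.17 + 17.1*Ia + 25.9*Ib + 34.4*Ic - 28.6*IIa`
#'     (multiple regression on global soils, n = 222, R^2 = 0.68,
#'     RMSE = 4.6 C).}
#'   \item{`matMrSimple()`}{`5.58 + 17.91*Ia - 18.77*IIa`.}
#'   \item{`matSsm()`}{`20.9 - 13.4*(IIa+IIa') - 17.2*(IIIa+IIIa') -
#'     17.5*(IIb+IIb') + 11.2*Ib` (surface-soil model over pooled 5-/6-methyl
#'     pairs).}
#'   \item{`maatWeijers()`}{`0.81 - 5.67*CBT + 31.0*MBT'`, composing
#'     [cbt()] and [mbtPrime()]; `maatFromIndices()` exposes the same linear
#'     form on explicit index values.}
#' }
#' Inputs are fractional abundances (the linear calibrations are not
#' scale-invariant, unlike the ratio indices).
#'
#' @inheritParams mbtPrime
#' @return degrees Celsius; `maatWeijers()` is NA where CBT or MBT' is
#'   undefined.
#' @examples
#' matMr(c(Ia = 0.5, Ib = 0.1, Ic = 0.05, IIa = 0.2))  # 14.31
#' @export
matMr <- function(x) {
  m <- .faInput(x)
  unname(7.17 + 17.1 * m[, "Ia"] + 25.9 * m[, "Ib"] + 34.4 * m[, "Ic"] -
           28.6 * m[, "IIa"])
}

#' @rdname matMr
#' @export
matMrSimple <- function(x) {
  m <- .faInput(x)
  unname(5.58 + 17.91 * m[, "Ia"] - 18.77 * m[, "IIa"])
}

#' @rdname matMr
#' @export
matSsm <- function(x) {
  m <- .faInput(x)
  unname(20.9 - 13.4 * (m[, "IIa"] + m[, "IIa'"]) -
           17.2 * (m[, "IIIa"] + m[, "IIIa'"]) -
           17.5 * (m[, "IIb"] + m[, "IIb'"]) + 11.2 * m[, "Ib"])
}

#' @rdname matMr
#' @param cbt,mbtPrime numeric index values for `maatFromIndices()`.
#' @export
maatFromIndices <- function(cbt, mbtPrime) 0.81 - 5.67 * cbt + 31.0 * mbtPrime

#' @rdname matMr
#' @export
maatWeijers <- function(x) maatFromIndices(cbt(x), mbtPrime(x))

## coerce alkane input to samples x homolog matrix (C23..C34), absent -> 0
.alkaneInput <- function(a) {
  if (is(a, "GdgtSet")) {
    a <- alkaneProfile(a)
    if (is.null(a)) stop("object carries no n-alkane homolog columns")
    return(a)
  }
  if (is.numeric(a) && is.null(dim(a))) a <- t(as.matrix(a))
  a <- as.matrix(a)
  if (is.null(colnames(a))) stop("alkane input must have homolog names C23..C34")
  m <- matrix(0, nrow(a), length(.ALKANE_HOMOLOGS),
              dimnames = list(rownames(a), .ALKANE_HOMOLOGS))
  keep <- intersect(colnames(a), .ALKANE_HOMOLOGS)
  m[, keep] <- a[, keep, drop = FALSE]
  if (any(!is.finite(m)) || any(m < 0))
    stop("alkane abundances must be finite and non-negative")
  m
}

#' Carbon preference index of leaf-wax n-alkanes
#'
#' Odd-over-even preference of the C23-C34 homologs, two printed variants:
#' \describe{
#'   \item{variant 1}{`((C23+C25+C27+C29+C31) + (C25+C27+C29+C31+C33)) /
#'     (2*(C24+C26+C28+C30+C32))`}
#'   \item{variant 2}{`0.5 * ((C25+...+C33)/(C24+...+C32) +
#'     (C25+...+C33)/(C26+...+C34))`}
#' }
#' Both equal 1 for a profile with no odd/even preference; higher values
#' indicate stronger (fresher, more arid-climate) leaf-wax input.
#'
#' @param alkanes GdgtSet with homolog columns, samples-by-homolog matrix, or
#'   named vector with names among `C23`..`C34`.
#' @param variant 1 or 2.
#' @return dimensionless; NA where an even-homolog denominator is zero.
#' @examples
#' eq <- setNames(rep(1, 12), paste0("C", 23:34))
#' cpi(eq, 1); cpi(eq, 2)  # both 1
#' @export
cpi <- function(alkanes, variant = 1L) {
  m <- .alkaneInput(alkanes)
  odd23_31 <- .rowSum(m, paste0("C", c(23, 25, 27, 29, 31)))
  odd25_33 <- .rowSum(m, paste0("C", c(25, 27, 29, 31, 33)))
  even24_32 <- .rowSum(m, paste0("C", c(24, 26, 28, 30, 32)))
  even26_34 <- .rowSum(m, paste0("C", c(26, 28, 30, 32, 34)))
  if (variant == 1L)
    .safeRatio(odd23_31 + odd25_33, 2 * even24_32)
  else if (variant == 2L)
    unname(0.5 * (ifelse(even24_32 > 0, odd25_33 / even24_32, NA_real_) +
                  ifelse(even26_34 > 0, odd25_33 / even26_34, NA_real_)))
  else stop("variant must be 1 or 2")
}

#' Average chain length of odd n-alkanes
#'
#' Abundance-weighted mean carbon number over the odd homologs C23-C33:
#' `ACL = sum(n * Cn) / sum(Cn)`, n in {23, 25, 27, 29, 31, 33}.  Lower
#' values track cooler conditions in loess-paleosol records.
#'
#' @inheritParams cpi
#' @return carbon number; NA where no odd homolog is present.
#' @examples
#' acl(c(C31 = 3, C27 = 1))  # 30
#' @export
acl <- function(alkanes) {
  m <- .alkaneInput(alkanes)
  ns <- c(23, 25, 27, 29, 31, 33)
  odd <- m[, paste0("C", ns), drop = FALSE]
  .safeRatio(drop(odd %*% ns), rowSums(odd))
}

#' Compute the full proxy suite
#'
#' One-pass evaluation of every index for each sample: MBT', MBT'6ME, IR6ME,
#' CBT', CBT, pH, the four temperature calibrations and (when homolog data
#' are present) CPI variants and ACL.  Undefined indices are NA; the logical
#' `swcInterpretable` column records whether IR6ME > 0.5, the regime in which
#' MBT' is read as a relative soil-water-content indicator rather than a
#' thermometer.
#'
#' @inheritParams mbtPrime
#' @param alkanes optional n-alkane input (see [cpi()]); taken from `x`
#'   automatically when `x` is a GdgtSet carrying homolog columns.
#' @return data.frame with one row per sample.
#' @export
computeProxySuite <- function(x, alkanes = NULL) {
  m <- .faInput(x)
  if (is.null(alkanes) && is(x, "GdgtSet")) {
    alk <- tryCatch(alkaneProfile(x), error = function(e) NULL)
    if (!is.null(alk) && any(alk > 0)) alkanes <- alk
  }
  out <- data.frame(
    MBTp = mbtPrime(m),
    MBTp6ME = mbtPrime6Me(m),
    IR6ME = ir6Me(m),
    CBTp = cbtPrime(m),
    CBT = cbt(m),
    pH = soilPH(m),
    MATmr = matMr(m),
    MATmrSimple = matMrSimple(m),
    MATssm = matSsm(m),
    MAAT = maatWeijers(m),
    row.names = rownames(m))
  out$swcInterpretable <- !is.na(out$IR6ME) & out$IR6ME > 0.5
  if (!is.null(alkanes)) {
    out$CPI1 <- cpi(alkanes, 1L)
    out$CPI2 <- cpi(alkanes, 2L)
    out$ACL <- acl(alkanes)
  }
  out
}
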