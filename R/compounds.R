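## Compound registry for the 15 separated 5-/6-methyl brGDGTs.
##
## Naming: roman numeral = number of methyl branches (I = tetra-, II = penta-,
## III = hexamethylated); letter = number of cyclopentane moieties (a = 0,
## b = 1, c = 2); a prime marks the 6-methyl positional isomer of the II/III
## series.  Canonical spelling uses the ASCII apostrophe ("IIa'"); readers
## also accept the typographic prime (U+2032).

.GDGT_COMPOUNDS <- c("Ia", "Ib", "Ic",
                     "IIa", "IIa'", "IIb", "IIb'", "IIc", "IIc'",
                     "IIIa", "IIIa'", "IIIb", "IIIb'", "IIIc", "IIIc'")

## Protonated-molecular-ion masses ([M+H]+) monitored in SIM mode.  The
## tetramethylated series is 1022/1020/1018, the pentamethylated 1036/1034/
## 1032 and the hexamethylated 1050/1048/1046; positional isomers share a
## mass.  744 is the C46 GTGT internal standard.
.GDGT_ION_MASS <- c(
  "Ia" = 1022L, "Ib" = 1020L, "Ic" = 1018L,
  "IIa" = 1036L, "IIa'" = 1036L, "IIb" = 1034L, "IIb'" = 1034L,
  "IIc" = 1032L, "IIc'" = 1032L,
  "IIIa" = 1050L, "IIIa'" = 1050L, "IIIb" = 1048L, "IIIb'" = 1048L,
  "IIIc" = 1046L, "IIIc'" = 1046L)

.STANDARD_ION_MASS <- 744L

## Default internal-standard amount: 10 uL of a 0.001157 ug/uL C46 GTGT
## solution added to every polar fraction.
.DEFAULT_STANDARD_UG <- 10 * 0.001157

#' The brGDGT compound registry
#'
#' Returns the fixed registry of the 15 branched glycerol dialkyl glycerol
#' tetraethers (brGDGTs) with separated 5- and 6-methyl positional isomers,
#' annotated with their methylation class, cyclopentane count, methyl
#' position and protonated-ion mass.
#'
#' @return A [S4Vectors::DataFrame] with one row per compound (rownames are
#'   the canonical compound names) and columns:
#'   \describe{
#'     \item{compound}{canonical name, e.g. \code{"IIa'"}}
#'     \item{methylation}{\code{"tetra"}, \code{"penta"} or \code{"hexa"}}
#'     \item{cyclization}{number of cyclopentane moieties (0, 1 or 2)}
#'     \item{methylPosition}{5 or 6 for the penta/hexa series; \code{NA} for
#'       the tetramethylated series, which has no positional isomerism}
#'     \item{ionMass}{integer [M+H]+ m/z monitored in SIM mode}
#'   }
#' @examples
#' compoundRegistry()
#' @export
compoundRegistry <- function() {
  cmp <- .GDGT_COMPOUNDS
  meth <- c(rep("tetra", 3), rep("penta", 6), rep("hexa", 6))
  cyc <- c(0L, 1L, 2L, 0L, 0L, 1L, 1L, 2L, 2L, 0L, 0L, 1L, 1L, 2L, 2L)
  pos <- ifelse(meth == "tetra", NA_integer_,
                ifelse(grepl("'", cmp, fixed = TRUE), 6L, 5L))
  S4Vectors::DataFrame(
    compound = cmp,
    methylation = factor(meth, levels = c("tetra", "penta", "hexa")),
    cyclization = cyc,
    methylPosition = pos,
    ionMass = unname(.GDGT_ION_MASS[cmp]),
    row.names = cmp)
}

#' @rdname compoundRegistry
#' @return `gdgtCompounds()` returns the 15 canonical compound names in
#'   registry order.
#' @export
gdgtCompounds <- function() .GDGT_COMPOUNDS

#' @rdname compoundRegistry
#' @return `sixMethylCompounds()`, `fiveMethylCompounds()` and
#'   `tetraCompounds()` return the corresponding name subsets.
#' @export
sixMethylCompounds <- function() {
  reg <- compoundRegistry()
  rownames(reg)[!is.na(reg$methylPosition) & reg$methylPosition == 6L]
}

#' @rdname compoundRegistry
#' @export
fiveMethylCompounds <- function() {
  reg <- compoundRegistry()
  rownames(reg)[!is.na(reg$methylPosition) & reg$methylPosition == 5L]
}

#' @rdname compoundRegistry
#' @export
tetraCompounds <- function() {
  reg <- compoundRegistry()
  rownames(reg)[is.na(reg$methylPosition)]
}

#' Normalize compound column/element names
#'
#' Maps user spellings of the 15 compound names onto the canonical registry
#' spelling: the typographic prime (U+2032) and the ASCII apostrophe are
#' interchangeable, and surrounding whitespace is ignored.  Non-compound
#' names are returned unchanged.
#'
#' @param x character vector of names.
#' @return character vector of the same length with compound names in
#'   canonical spelling.
#' @examples
#' normalizeCompoundNames(c("IIa′", "IIa'", "depth"))
#' @export
normalizeCompoundNames <- function(x) {
  y <- trimws(x)
  y <- gsub("′", "'", y)
  y <- gsub("´", "'", y)  # acute accent occasionally used as a prime
  ifelse(y %in% .GDGT_COMPOUNDS, y, x)
}

## Coerce a record (named numeric vector, 1-row data.frame, or list) into a
## full-length named area vector in registry order.  Missing compounds are an
## error unless missingAsZero = TRUE (silent zeros bias every index).
.asAreaVector <- function(record, missingAsZero = FALSE) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- unlist(record[1L, , drop = TRUE])
  }
  if (is.list(record)) record <- unlist(record)
  if (is.null(names(record)))
    stop("peak-area record must be named by compound")
  names(record) <- normalizeCompoundNames(names(record))
  record <- record[names(record) %in% .GDGT_COMPOUNDS]
  absent <- setdiff(.GDGT_COMPOUNDS, names(record))
  if (length(absent) > 0L && !missingAsZero)
    stop("missing compound value(s): ", paste(absent, collapse = ", "),
         " (set missingAsZero = TRUE to treat absent compounds as zero)")
  out <- stats::setNames(numeric(15L), .GDGT_COMPOUNDS)
  out[names(record)] <- as.numeric(record)
  if (any(!is.finite(out)))
    stop("peak areas must be finite")
  if (any(out < 0))
    stop("peak areas must be non-negative; offending compound(s): ",
         paste(names(out)[out < 0], collapse = ", "))
  out
}

#' Fractional abundances from peak areas
#'
#' Converts per-compound peak areas into fractional abundances over all 15
#' brGDGTs (each compound's share of the summed brGDGT signal), the
#' compositional representation that every index and calibration in the
#' package consumes.
#'
#' @param record named numeric vector (or 1-row data.frame) of non-negative
#'   peak areas; names are compound names in either prime spelling.
#' @param missingAsZero treat absent compounds as zero area instead of
#'   raising an error.  Default `FALSE`: silently zeroing a compound biases
#'   every downstream index.
#' @return Named numeric vector of 15 fractions in registry order, summing
#'   to 1.
#' @examples
#' computeFractionalAbundances(c(Ia = 3, IIa = 1, "IIIa'" = 1),
#'                             missingAsZero = TRUE)
#' @export
computeFractionalAbundances <- function(record, missingAsZero = FALSE) {
  areas <- .asAreaVector(record, missingAsZero = missingAsZero)
  total <- sum(areas)
  if (total <= 0)
    stop("empty sample: all compound areas are zero")
  areas / total
}

#' Absolute quantification against the internal standard
#'
#' Converts a compound's peak area into micrograms by reference to the C46
#' GTGT internal standard co-injected with every polar fraction:
#' `mass = area / standardArea * standardAmount`.
#'
#' @param record named numeric vector of peak areas (see
#'   [computeFractionalAbundances()]).
#' @param compound canonical (or prime-spelled) compound name to quantify.
#' @param standardArea internal-standard peak area (> 0).
#' @param standardAmount micrograms of standard added; default
#'   `r .DEFAULT_STANDARD_UG` ug (10 uL of a 0.001157 ug/uL solution).
#' @param missingAsZero passed to the area parser.
#' @return mass in micrograms.
#' @examples
#' quantifyCompound(c(Ia = 50), "Ia", standardArea = 50,
#'                  missingAsZero = TRUE)  # 0.01157 ug
#' @export
quantifyCompound <- function(record, compound, standardArea,
                             standardAmount = .DEFAULT_STANDARD_UG,
                             missingAsZero = FALSE) {
  if (missing(standardArea) || is.null(standardArea) || is.na(standardArea))
    stop("no internal standard: provide standardArea")
  if (!is.numeric(standardArea) || standardArea <= 0)
    stop("no internal standard: standardArea must be > 0")
  if (is.null(standardAmount) || !is.finite(standardAmount) ||
      standardAmount <= 0)
    stop("standardAmount must be a positive mass in micrograms")
  compound <- normalizeCompoundNames(compound)
  if (!compound %in% .GDGT_COMPOUNDS)
    stop("unknown compound: ", compound)
  areas <- .asAreaVector(record, missingAsZero = missingAsZero)
  unname(areas[compound] / standardArea * standardAmount)
}
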