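#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData `colData<-` rowData
NULL

.FA_SUM_TOL <- 1e-9

#' GdgtSet: brGDGT abundance container
#'
#' `GdgtSet` extends [SummarizedExperiment::SummarizedExperiment] with the 15
#' registry compounds as rows (features) and samples as columns.  Recognised
#' assays are `"areas"` (raw peak areas, arbitrary units) and `"fa"`
#' (fractional abundances; every column sums to 1 within 1e-9).  `rowData`
#' carries the compound registry.  Two subclasses add sample-metadata
#' contracts:
#' \describe{
#'   \item{`GdgtCalibration`}{modern surface-soil calibration sets; `colData`
#'     must contain a non-negative numeric `MAP` column (mm/yr); `MAT`,
#'     `pH`, `MAPalt` and `source` are optional.}
#'   \item{`GdgtProfile`}{downcore profiles; `colData` must contain a
#'     strictly increasing numeric `depth` column (m, 0 at the top);
#'     `susceptibility`, `grainSize`, `age` and n-alkane homolog columns
#'     `C23`..`C34` are optional.}
#' }
#'
#' @aliases GdgtSet-class GdgtCalibration-class GdgtProfile-class
#' @name GdgtSet
NULL

#' @rdname GdgtSet
#' @export
setClass("GdgtSet", contains = "SummarizedExperiment")

#' @rdname GdgtSet
#' @export
setClass("GdgtCalibration", contains = "GdgtSet")

#' @rdname GdgtSet
#' @export
setClass("GdgtProfile", contains = "GdgtSet")

.validGdgtSet <- function(object) {
  msg <- character()
  if (!identical(rownames(object), .GDGT_COMPOUNDS))
    msg <- c(msg, "rows must be the 15 registry compounds in registry order")
  known <- assayNames(object) %in% c("areas", "fa")
  if (length(assayNames(object)) == 0L || !any(known))
    msg <- c(msg, "need an 'areas' or 'fa' assay")
  if ("fa" %in% assayNames(object) && ncol(object) > 0L) {
    fa <- assay(object, "fa")
    if (any(!is.finite(fa)) || any(fa < 0) || any(fa > 1))
      msg <- c(msg, "'fa' entries must be finite fractions in [0, 1]")
    else if (any(abs(colSums(fa) - 1) > .FA_SUM_TOL))
      msg <- c(msg, sprintf("'fa' columns must sum to 1 within %g",
                            .FA_SUM_TOL))
  }
  if ("areas" %in% assayNames(object)) {
    ar <- assay(object, "areas")
    if (any(!is.finite(ar)) || any(ar < 0))
      msg <- c(msg, "'areas' entries must be finite and non-negative")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GdgtSet", .validGdgtSet)

setValidity("GdgtCalibration", function(object) {
  msg <- character()
  if (!"MAP" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'MAP' column (mm/yr)")
  else {
    map <- colData(object)$MAP
    if (!is.numeric(map) || any(!is.finite(map)) || any(map < 0))
      msg <- c(msg, "'MAP' must be finite, non-negative mm/yr")
  }
  if (!"fa" %in% assayNames(object))
    msg <- c(msg, "calibration sets need the 'fa' assay")
  if (length(msg)) msg else TRUE
})

setValidity("GdgtProfile", function(object) {
  msg <- character()
  if (!"depth" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'depth' column (m)")
  else {
    d <- colData(object)$depth
    if (!is.numeric(d) || any(!is.finite(d)))
      msg <- c(msg, "'depth' must be finite numeric")
    else if (length(d) > 1L && any(diff(d) <= 0))
      msg <- c(msg, "'depth' must be strictly increasing (top to bottom)")
  }
  if (length(msg)) msg else TRUE
})

## Shared constructor engine: accepts samples-in-rows matrices/data.frames
## keyed by compound column names, converts areas to fractional abundances.
.buildGdgtSE <- function(class, fa = NULL, areas = NULL, colData = NULL,
                         renormalize = FALSE, missingAsZero = FALSE) {
  toMat <- function(x) {
    if (is.null(x)) return(NULL)
    x <- as.data.frame(x)
    colnames(x) <- normalizeCompoundNames(colnames(x))
    absent <- setdiff(.GDGT_COMPOUNDS, colnames(x))
    if (length(absent) > 0L && !missingAsZero)
      stop("missing compound column(s): ", paste(absent, collapse = ", "))
    m <- matrix(0, nrow(x), 15L, dimnames = list(rownames(x), .GDGT_COMPOUNDS))
    keep <- intersect(colnames(x), .GDGT_COMPOUNDS)
    m[, keep] <- as.matrix(x[, keep, drop = FALSE])
    t(m)  # compounds x samples
  }
  faM <- toMat(fa)
  arM <- toMat(areas)
  if (is.null(faM) && !is.null(arM)) {
    tot <- colSums(arM)
    if (any(tot <= 0))
      stop("empty sample(s) at column ", paste(which(tot <= 0), collapse = ", "))
    faM <- sweep(arM, 2L, tot, "/")
  } else if (!is.null(faM)) {
    tot <- colSums(faM)
    off <- abs(tot - 1) > .FA_SUM_TOL
    if (any(off)) {
      if (renormalize) {
        bad <- abs(tot - 1) > 0.02 + 1e-9
        if (any(bad))
          stop("abundance row(s) ", paste(which(bad), collapse = ", "),
               " sum to ", paste(signif(tot[bad], 4), collapse = ", "),
               "; outside the +/-0.02 renormalization band")
        faM <- sweep(faM, 2L, tot, "/")
      } else {
        stop("abundance row(s) ", paste(which(off), collapse = ", "),
             " do not sum to 1 (set renormalize = TRUE to rescale sums ",
             "within +/-0.02)")
      }
    }
  }
  al <- SimpleList()
  if (!is.null(arM)) al$areas <- arM
  if (!is.null(faM)) al$fa <- faM
  n <- ncol(al[[1L]])
  if (is.null(colData)) colData <- DataFrame(row.names = colnames(al[[1L]]))
  se <- SummarizedExperiment(assays = al,
                             rowData = compoundRegistry(),
                             colData = colData)
  new(class, se)
}

#' Construct a GdgtSet / GdgtCalibration / GdgtProfile
#'
#' @param fa samples-in-rows matrix or data.frame of fractional abundances
#'   with compound column names (either prime spelling); alternative to
#'   `areas`.
#' @param areas samples-in-rows matrix or data.frame of raw peak areas;
#'   converted to fractional abundances automatically.
#' @param colData sample metadata ([S4Vectors::DataFrame] or data.frame).
#' @param renormalize accept pre-normalized abundance rows whose sums fall
#'   within 1 +/- 0.02 and rescale them to exactly 1; sums further from 1
#'   are always rejected.
#' @param missingAsZero treat absent compound columns as zero (default:
#'   error).
#' @return A `GdgtSet` (or subclass) object.
#' @examples
#' fa <- matrix(1/15, 2, 15, dimnames = list(c("s1", "s2"), gdgtCompounds()))
#' GdgtSet(fa = fa)
#' @rdname GdgtSet
#' @export
GdgtSet <- function(fa = NULL, areas = NULL, colData = NULL,
                    renormalize = FALSE, missingAsZero = FALSE) {
  .buildGdgtSE("GdgtSet", fa = fa, areas = areas, colData = colData,
               renormalize = renormalize, missingAsZero = missingAsZero)
}

#' @param MAP numeric vector of observed mean annual precipitation (mm/yr),
#'   one per sample (alternatively supply it inside `colData`).
#' @rdname GdgtSet
#' @export
GdgtCalibration <- function(fa = NULL, areas = NULL, MAP = NULL,
                            colData = NULL, renormalize = FALSE,
                            missingAsZero = FALSE) {
  if (!is.null(MAP)) {
    if (is.null(colData)) colData <- DataFrame(MAP = as.numeric(MAP))
    else colData$MAP <- as.numeric(MAP)
  }
  .buildGdgtSE("GdgtCalibration", fa = fa, areas = areas, colData = colData,
               renormalize = renormalize, missingAsZero = missingAsZero)
}

#' @param depth numeric vector of sample depths (m, strictly increasing
#'   downward); alternatively supply it inside `colData`.
#' @rdname GdgtSet
#' @export
GdgtProfile <- function(fa = NULL, areas = NULL, depth = NULL,
                        colData = NULL, renormalize = FALSE,
                        missingAsZero = FALSE) {
  if (!is.null(depth)) {
    if (is.null(colData)) colData <- DataFrame(depth = as.numeric(depth))
    else colData$depth <- as.numeric(depth)
  }
  .buildGdgtSE("GdgtProfile", fa = fa, areas = areas, colData = colData,
               renormalize = renormalize, missingAsZero = missingAsZero)
}

#' Accessors for GdgtSet objects
#'
#' `fractionalAbundances()` returns the samples-by-compounds fractional
#' abundance matrix (the orientation the index and calibration functions
#' consume); `peakAreas()` the raw area matrix; `mapObserved()`, `depths()`,
#' `susceptibility()`, `ages()` the corresponding `colData` columns; and
#' `alkaneProfile()` the `C23`..`C34` homolog columns as a matrix.
#'
#' @param x a `GdgtSet` (or subclass).
#' @return See each description.
#' @name gdgt-accessors
NULL

#' @rdname gdgt-accessors
#' @export
fractionalAbundances <- function(x) {
  stopifnot(is(x, "GdgtSet"))
  if (!"fa" %in% assayNames(x)) stop("object has no 'fa' assay")
  t(assay(x, "fa"))
}

#' @rdname gdgt-accessors
#' @export
peakAreas <- function(x) {
  stopifnot(is(x, "GdgtSet"))
  if (!"areas" %in% assayNames(x)) stop("object has no 'areas' assay")
  t(assay(x, "areas"))
}

#' @rdname gdgt-accessors
#' @export
mapObserved <- function(x) {
  stopifnot(is(x, "GdgtSet"))
  colData(x)$MAP
}

#' @rdname gdgt-accessors
#' @export
depths <- function(x) {
  stopifnot(is(x, "GdgtSet"))
  colData(x)$depth
}

#' @rdname gdgt-accessors
#' @export
susceptibility <- function(x) {
  stopifnot(is(x, "GdgtSet"))
  colData(x)$susceptibility
}

#' @rdname gdgt-accessors
#' @export
ages <- function(x) {
  stopifnot(is(x, "GdgtSet"))
  colData(x)$age
}

#' @param value replacement ages (ka BP), one per sample.
#' @rdname gdgt-accessors
#' @export
`ages<-` <- function(x, value) {
  stopifnot(is(x, "GdgtSet"))
  colData(x)$age <- as.numeric(value)
  validObject(x)
  x
}

.ALKANE_HOMOLOGS <- paste0("C", 23:34)

#' @rdname gdgt-accessors
#' @export
alkaneProfile <- function(x) {
  stopifnot(is(x, "GdgtSet"))
  cd <- colData(x)
  have <- intersect(.ALKANE_HOMOLOGS, colnames(cd))
  if (length(have) == 0L) return(NULL)
  m <- matrix(0, ncol(x), length(.ALKANE_HOMOLOGS),
              dimnames = list(colnames(x), .ALKANE_HOMOLOGS))
  m[, have] <- as.matrix(cd[, have, drop = FALSE])
  m
}

setMethod("show", "GdgtSet", function(object) {
  cat(sprintf("%s with %d compounds x %d samples\n",
              class(object), nrow(object), ncol(object)))
  cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
  cd <- colnames(colData(object))
  if (length(cd)) cat("colData:", paste(cd, collapse = ", "), "\n")
  if (is(object, "GdgtProfile") && ncol(object) > 0L) {
    d <- depths(object)
    cat(sprintf("depth span: %.3g - %.3g m\n", min(d), max(d)))
  }
  if (is(object, "GdgtCalibration") && ncol(object) > 0L) {
    m <- mapObserved(object)
    cat(sprintf("MAP range: %.0f - %.0f mm/yr\n", min(m), max(m)))
  }
  invisible(NULL)
})
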