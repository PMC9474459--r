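## Delimited-text readers/writers for the tabular formats the toolkit
## exchanges: calibration tables, downcore profile tables, age-model control
## points and (age, value) reference series.  All formats are plain text with
## a header; comma and tab delimiters are auto-detected.  The column schema
## is documented in inst/extdata/table-schemas.md.

.detectDelim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.readDelim <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- .detectDelim(path)
  ## quote = '"' only: the apostrophe is part of compound names (IIa')
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  colnames(df) <- trimws(colnames(df))
  df
}

.numericColumn <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v)) {
    suppressWarnings(num <- as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
    if (length(bad))
      stop(sprintf("%s: non-numeric value '%s' in column '%s', data row %d",
                   path, v[bad[1L]], col, bad[1L]))
    v <- num
  }
  v
}

#' Read a surface-soil calibration table
#'
#' Reads a delimited text file whose header names the 15 brGDGT compounds
#' (fractional abundances; prime or apostrophe spellings) and a `MAP` column
#' in mm/yr, producing a [GdgtCalibration] object.  Optional columns `site`,
#' `MAT`, `pH`, `MAPalt` and `source` are carried into `colData`.
#'
#' @param path file path.
#' @param delim field delimiter; default auto-detect (comma or tab).
#' @param renormalize accept abundance rows summing to 1 +/- 0.02 and
#'   rescale them; otherwise any row off by more than 1e-9 is an error that
#'   names the offending row numbers.
#' @param missingAsZero treat absent compound columns as zero fraction.
#' @return A [GdgtCalibration].
#' @seealso [writeCalibrationTable()]
#' @export
readCalibrationTable <- function(path, delim = NULL, renormalize = FALSE,
                                 missingAsZero = FALSE) {
  df <- .readDelim(path, delim)
  colnames(df) <- normalizeCompoundNames(colnames(df))
  absent <- setdiff(gdgtCompounds(), colnames(df))
  if (length(absent) > 0L && !missingAsZero)
    stop(path, ": missing compound column(s): ",
         paste(absent, collapse = ", "))
  if (!"MAP" %in% colnames(df))
    stop(path, ": missing required 'MAP' column")
  compCols <- intersect(gdgtCompounds(), colnames(df))
  for (col in c(compCols, "MAP")) df[[col]] <- .numericColumn(df, col, path)
  meta <- intersect(c("site", "MAT", "pH", "MAPalt", "source"), colnames(df))
  cd <- S4Vectors::DataFrame(df[, meta, drop = FALSE])
  cd$MAP <- df$MAP
  if ("site" %in% meta && !anyDuplicated(df$site))
    rownames(cd) <- df$site
  GdgtCalibration(fa = df[, compCols, drop = FALSE], colData = cd,
                  renormalize = renormalize, missingAsZero = missingAsZero)
}

#' Write a calibration table
#'
#' Inverse of [readCalibrationTable()]: writes fractional abundances plus
#' `colData` columns as delimited text at full precision, so a write/read
#' round trip reproduces the object.
#'
#' @param x a [GdgtCalibration].
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
writeCalibrationTable <- function(x, path, delim = ",") {
  stopifnot(is(x, "GdgtCalibration"))
  df <- as.data.frame(fractionalAbundances(x), check.names = FALSE)
  cd <- as.data.frame(colData(x))
  df <- cbind(df, cd)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a downcore profile table
#'
#' Reads a delimited profile table with a strictly increasing `depth` column
#' (m) plus per-sample compound abundances (or peak areas) and optional
#' `susceptibility`, `grainSize`, `age` and n-alkane homolog columns
#' `C23`..`C34`, producing a [GdgtProfile].
#'
#' @param path file path.
#' @param delim field delimiter; default auto-detect.
#' @param areas logical: compound columns are raw peak areas rather than
#'   fractional abundances.
#' @param renormalize,missingAsZero as in [readCalibrationTable()].
#' @return A [GdgtProfile].
#' @export
readProfileTable <- function(path, delim = NULL, areas = FALSE,
                             renormalize = FALSE, missingAsZero = FALSE) {
  df <- .readDelim(path, delim)
  colnames(df) <- normalizeCompoundNames(colnames(df))
  if (!"depth" %in% colnames(df))
    stop(path, ": missing required 'depth' column")
  df$depth <- .numericColumn(df, "depth", path)
  if (any(diff(df$depth) <= 0)) {
    i <- which(diff(df$depth) <= 0)[1L]
    stop(sprintf("%s: depth not strictly increasing at data row %d (%g then %g)",
                 path, i + 1L, df$depth[i], df$depth[i + 1L]))
  }
  compCols <- intersect(gdgtCompounds(), colnames(df))
  if (length(compCols) == 0L && !missingAsZero)
    stop(path, ": no compound columns found")
  for (col in compCols) df[[col]] <- .numericColumn(df, col, path)
  meta <- setdiff(colnames(df), compCols)
  cd <- S4Vectors::DataFrame(df[, meta, drop = FALSE])
  comp <- df[, compCols, drop = FALSE]
  if (areas)
    GdgtProfile(areas = comp, colData = cd, missingAsZero = missingAsZero)
  else
    GdgtProfile(fa = comp, colData = cd, renormalize = renormalize,
                missingAsZero = missingAsZero)
}

#' Write a profile table
#'
#' @param x a [GdgtProfile].
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(x, path, delim = ",") {
  stopifnot(is(x, "GdgtProfile"))
  df <- cbind(as.data.frame(colData(x)),
              as.data.frame(fractionalAbundances(x), check.names = FALSE))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read age-model control points
#'
#' Two-column delimited text: depth (m) and age (ka BP).  Ages must
#' strictly increase with depth.
#'
#' @param path file path.
#' @param delim field delimiter; default auto-detect.
#' @return data.frame with columns `depth` and `age`.
#' @export
readControlPoints <- function(path, delim = NULL) {
  df <- .readDelim(path, delim)
  colnames(df) <- tolower(colnames(df))
  if (!all(c("depth", "age") %in% colnames(df)))
    stop(path, ": control-point file needs 'depth' and 'age' columns")
  df <- df[order(df$depth), c("depth", "age")]
  if (any(diff(df$age) <= 0))
    stop(path, ": control-point ages must strictly increase with depth")
  df
}

#' Read a reference time series
#'
#' Two-column delimited text: age (ka) and value, e.g. a speleothem
#' oxygen-isotope record.
#'
#' @param path file path.
#' @param delim field delimiter; default auto-detect.
#' @return data.frame with columns `age` and `value`, sorted by age.
#' @export
readSeriesTable <- function(path, delim = NULL) {
  df <- .readDelim(path, delim)
  if (ncol(df) < 2L)
    stop(path, ": series file needs two columns (age, value)")
  colnames(df)[1:2] <- c("age", "value")
  df$age <- .numericColumn(df, "age", path)
  df$value <- .numericColumn(df, "value", path)
  df[order(df$age), c("age", "value")]
}
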