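.TRUTH_COLUMNS <- c("gene", "class", "true_rna_wbs", "true_rna_dup",
                    "true_te_wbs", "true_te_dup", "is_top", "regulon_of")

## Full-precision numeric formatting so that write -> read round-trips are
## bit-exact on the defined columns (17 significant digits suffice for IEEE
## doubles).
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  out <- df
  for (nm in names(df)[num]) out[[nm]] <- .fmt_num(df[[nm]])
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8"),
    error = function(e) stop(sprintf("I/O error writing '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Read a differential-statistics table from TSV
#'
#' Expects the canonical tab-separated schema with header columns
#' \code{gene, layer, contrast, dataset, logfc, se, pvalue, fdr}; missing
#' values are the literal \code{NA}. Rows failing validation are reported
#' with their row numbers. If the \code{fdr} column is entirely missing
#' values, FDR is recomputed by Benjamini-Hochberg within each
#' (layer, contrast, dataset) stratum; a supplied \code{fdr} column is
#' trusted otherwise.
#'
#' @param path path to the TSV file.
#' @param expected_layer optional layer name; if given, an error is raised
#'   when the file contains any other layer.
#' @return a \linkS4class{MultiLayerTable}.
#' @seealso [writeDifferentialTable()]
#' @export
readDifferentialTable <- function(path, expected_layer = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character")
  missing <- setdiff(.DIFF_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("schema error: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- df[, .DIFF_COLUMNS]
  for (nm in c("logfc", "se", "pvalue", "fdr")) {
    parsed <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(parsed) & !is.na(df[[nm]]))
    if (length(bad))
      stop(sprintf("parse error: non-numeric '%s' at row(s) %s", nm,
                   paste(utils::head(bad, 5L), collapse = ",")), call. = FALSE)
    df[[nm]] <- parsed
  }
  if (!is.null(expected_layer)) {
    expected_layer <- match.arg(expected_layer, .LAYERS)
    off <- setdiff(unique(df$layer), expected_layer)
    if (length(off))
      stop(sprintf("expected layer %s but found: %s", expected_layer,
                   paste(off, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) && all(is.na(df$fdr))) {
    tlLog("INFO", "no fdr values supplied in %s; recomputing by BH per stratum",
          path)
    strata <- paste(df$layer, df$contrast, df$dataset)
    for (s in unique(strata)) {
      i <- strata == s
      df$fdr[i] <- bhAdjust(df$pvalue[i])
    }
  }
  MultiLayerTable(df)
}

#' Write a differential-statistics table to TSV
#'
#' Serializes the canonical column set at full precision so that
#' \code{readDifferentialTable(writeDifferentialTable(x, f))} reproduces
#' \code{x} bit-exactly. Missing values are written as the literal
#' \code{NA}; the decimal separator is \code{.}; the encoding is UTF-8.
#'
#' @param table a non-empty \linkS4class{MultiLayerTable}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeDifferentialTable <- function(table, path) {
  stopifnot(methods::is(table, "MultiLayerTable"))
  if (!nrow(table@records))
    stop("refusing to write an empty differential table", call. = FALSE)
  .write_tsv(table@records, path)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around \code{stats::p.adjust(method = "BH")}:
#' output preserves length and order, enforces step-up monotonicity, and is
#' clipped at 1. Used wherever the pipeline recomputes FDR within a
#' (layer, contrast, dataset) stratum.
#'
#' @param pvalues numeric vector with all values in [0, 1] (NA allowed).
#' @return adjusted values, same length and order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pvalues) {
  if (!is.numeric(pvalues))
    stop("pvalues must be numeric", call. = FALSE)
  bad <- which(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))
  if (length(bad))
    stop(sprintf("pvalues outside [0,1] at position(s) %s",
                 paste(utils::head(bad, 5L), collapse = ",")), call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Write a synthetic ground-truth table to TSV
#'
#' Columns: \code{gene, class, true_rna_wbs, true_rna_dup, true_te_wbs,
#' true_te_dup, is_top, regulon_of}. The class is serialized as its exact
#' enum string; \code{is_top} as TRUE/FALSE.
#'
#' @param truth truth data.frame as returned by [simulateMultiomics()].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTruthTable <- function(truth, path) {
  if (!nrow(truth)) stop("refusing to write an empty truth table", call. = FALSE)
  missing <- setdiff(.TRUTH_COLUMNS, names(truth))
  if (length(missing))
    stop(sprintf("truth table missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  .write_tsv(truth[, .TRUTH_COLUMNS], path)
}

#' Read a synthetic ground-truth table from TSV
#'
#' @param path path written by [writeTruthTable()].
#' @return truth data.frame with validated class labels.
#' @export
readTruthTable <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  missing <- setdiff(.TRUTH_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("schema error: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad <- which(!df$class %in% .TRUTH_CLASSES)
  if (length(bad))
    stop(sprintf("parse error: unknown class at row(s) %s",
                 paste(utils::head(bad, 5L), collapse = ",")), call. = FALSE)
  df$is_top <- as.logical(df$is_top)
  df
}

#' Read a one-column gene list (e.g. TOP-mRNA genes)
#'
#' @param path text file with one gene identifier per line; blank lines and
#'   lines starting with '#' are ignored.
#' @return character vector of gene identifiers.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
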