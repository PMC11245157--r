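#' @include trilayer-package.R
NULL

## Enum alphabets shared by validators across the package.
.LAYERS <- c("RNA", "RPF", "PROTEIN")
.CONTRASTS <- c("WBS_VS_CTL", "DUP_VS_CTL", "CN_REGRESSION")
.DATASETS <- c("ISOGENIC", "PATIENT", "MERGED")
.TRUTH_CLASSES <- c("FORWARDED_OPPOSITE", "BUFFERED_WBS", "BUFFERED_DUP",
                    "BUFFERED_BOTH", "TRANSLATION_OFFSET", "NULL")
.CATEGORIES <- c("FORWARDED", "TRANSLATION_REGULATED",
                 "OTHER_POSTTRANSCRIPTIONAL", "UNCLASSIFIED")
.GROUP_LABELS <- c("FORWARDED_OPPOSITE", "BUFFERED_WBS", "BUFFERED_DUP",
                   "BUFFERED_BOTH", "OTHER")
.DIFF_COLUMNS <- c("gene", "layer", "contrast", "dataset",
                   "logfc", "se", "pvalue", "fdr")

#' MultiLayerTable: per-gene differential statistics across molecular layers
#'
#' An S4 container holding one row per (gene, layer, contrast, dataset)
#' combination of differential statistics: log2 fold change, its standard
#' error, p-value and FDR. All downstream stages (dataset merging, candidate
#' selection, forwarded/buffered classification, clustering, TOP-mRNA shift
#' analysis) consume this container.
#'
#' Layers are \code{RNA} (transcriptome), \code{RPF} (ribosome-protected
#' fragments, i.e. translatome) and \code{PROTEIN}; contrasts compare the
#' hemideletion (\code{WBS_VS_CTL}) and hemiduplication (\code{DUP_VS_CTL})
#' conditions to control, or regress on copy number (\code{CN_REGRESSION}).
#'
#' @slot records data.frame with columns \code{gene}, \code{layer},
#'   \code{contrast}, \code{dataset}, \code{logfc}, \code{se}, \code{pvalue},
#'   \code{fdr}.
#'
#' @seealso [readDifferentialTable()], [mergeDatasets()], [geneUniverse()]
#' @export
setClass("MultiLayerTable", representation(records = "data.frame"))

.validate_records <- function(df) {
  missing <- setdiff(.DIFF_COLUMNS, names(df))
  if (length(missing))
    return(sprintf("missing required column(s): %s",
                   paste(missing, collapse = ", ")))
  probs <- character(0)
  bad_enum <- function(col, alphabet) {
    bad <- which(!df[[col]] %in% alphabet)
    if (length(bad))
      probs <<- c(probs, sprintf(
        "invalid %s at row(s) %s (allowed: %s)", col,
        paste(utils::head(bad, 5L), collapse = ","),
        paste(alphabet, collapse = "/")))
  }
  bad_enum("layer", .LAYERS)
  bad_enum("contrast", .CONTRASTS)
  bad_enum("dataset", .DATASETS)
  for (col in c("logfc", "se", "pvalue", "fdr"))
    if (!is.numeric(df[[col]]))
      probs <- c(probs, sprintf("column '%s' must be numeric", col))
  if (is.numeric(df$pvalue)) {
    bad <- which(!is.na(df$pvalue) & (df$pvalue < 0 | df$pvalue > 1))
    if (length(bad))
      probs <- c(probs, sprintf("pvalue outside [0,1] at row(s) %s",
                                paste(utils::head(bad, 5L), collapse = ",")))
  }
  if (is.numeric(df$fdr)) {
    bad <- which(!is.na(df$fdr) & (df$fdr < 0 | df$fdr > 1))
    if (length(bad))
      probs <- c(probs, sprintf("fdr outside [0,1] at row(s) %s",
                                paste(utils::head(bad, 5L), collapse = ",")))
  }
  if (is.numeric(df$se)) {
    bad <- which(!is.na(df$se) & df$se <= 0)
    if (length(bad))
      probs <- c(probs, sprintf("se must be > 0 at row(s) %s",
                                paste(utils::head(bad, 5L), collapse = ",")))
  }
  key <- paste(df$gene, df$layer, df$contrast, df$dataset, sep = "\r")
  if (anyDuplicated(key))
    probs <- c(probs, sprintf(
      "duplicate (gene, layer, contrast, dataset) key at row(s) %s",
      paste(utils::head(which(duplicated(key)), 5L), collapse = ",")))
  if (length(probs)) probs else TRUE
}

setValidity("MultiLayerTable", function(object) .validate_records(object@records))

#' Construct a MultiLayerTable from a data.frame of differential records
#'
#' @param records data.frame carrying the canonical columns (see
#'   \linkS4class{MultiLayerTable}). Extra columns are dropped; character
#'   columns are kept as character (no factors).
#' @return A validated \linkS4class{MultiLayerTable}.
#' @examples
#' df <- data.frame(gene = "g1", layer = "RNA", contrast = "WBS_VS_CTL",
#'                  dataset = "ISOGENIC", logfc = 0.5, se = 0.1,
#'                  pvalue = 1e-6, fdr = 1e-5)
#' MultiLayerTable(df)
#' @export
MultiLayerTable <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  res <- .validate_records(records)
  if (!isTRUE(res)) stop(paste(res, collapse = "; "), call. = FALSE)
  records <- records[, .DIFF_COLUMNS]
  rownames(records) <- NULL
  methods::new("MultiLayerTable", records = records)
}

#' @describeIn MultiLayerTable number of records
#' @param x,object a MultiLayerTable
#' @export
setMethod("length", "MultiLayerTable", function(x) nrow(x@records))

setMethod("show", "MultiLayerTable", function(object) {
  df <- object@records
  cat(sprintf("MultiLayerTable: %d records, %d genes\n",
              nrow(df), length(unique(df$gene))))
  cat(sprintf("  layers:    %s\n", paste(sort(unique(df$layer)), collapse = ", ")))
  cat(sprintf("  contrasts: %s\n", paste(sort(unique(df$contrast)), collapse = ", ")))
  cat(sprintf("  datasets:  %s\n", paste(sort(unique(df$dataset)), collapse = ", ")))
  miss <- missingLayerGenes(object)
  if (length(miss))
    cat(sprintf("  %d gene(s) missing at least one layer/contrast combination\n",
                length(miss)))
  invisible(object)
})

#' Extract the record data.frame from a MultiLayerTable
#' @param x a \linkS4class{MultiLayerTable}
#' @return data.frame of differential records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "MultiLayerTable", function(x) x@records)

#' Genes present in every layer/contrast combination of a table
#'
#' The gene universe is the intersection of gene sets across all
#' (layer, contrast) combinations present; genes missing a combination are
#' reported by [missingLayerGenes()] rather than silently dropped.
#' @param x a \linkS4class{MultiLayerTable}
#' @return character vector of gene identifiers.
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname geneUniverse
#' @export
setMethod("geneUniverse", "MultiLayerTable", function(x) {
  df <- x@records
  if (!nrow(df)) return(character(0))
  combos <- split(df$gene, paste(df$layer, df$contrast, df$dataset))
  Reduce(intersect, combos)
})

#' @rdname geneUniverse
#' @return for \code{missingLayerGenes}, genes absent from at least one
#'   observed layer/contrast/dataset combination.
#' @export
missingLayerGenes <- function(x) {
  stopifnot(methods::is(x, "MultiLayerTable"))
  setdiff(unique(x@records$gene), geneUniverse(x))
}

#' RegulonSet: transcription factors with mode- and likelihood-annotated targets
#'
#' Each regulon is a transcription factor (TF) together with its curated
#' target genes; every target carries a regulation mode (+1 activation,
#' -1 repression) and an interaction-likelihood weight in (0, 1] used to
#' weight the enrichment score.
#'
#' @slot regulons named list (by TF) of data.frames with columns
#'   \code{target}, \code{mode}, \code{likelihood}.
#' @seealso [readRegulons()], [scoreRegulon()]
#' @export
setClass("RegulonSet", representation(regulons = "list"))

setValidity("RegulonSet", function(object) {
  regs <- object@regulons
  if (length(regs) && is.null(names(regs)))
    return("regulons list must be named by TF")
  for (tf in names(regs)) {
    df <- regs[[tf]]
    if (!all(c("target", "mode", "likelihood") %in% names(df)))
      return(sprintf("regulon '%s' lacks target/mode/likelihood columns", tf))
    if (!all(df$mode %in% c(-1, 1)))
      return(sprintf("regulon '%s': mode must be -1 or +1", tf))
    if (any(df$likelihood <= 0 | df$likelihood > 1))
      return(sprintf("regulon '%s': likelihood must be in (0,1]", tf))
    if (anyDuplicated(df$target))
      return(sprintf("regulon '%s': duplicate target(s)", tf))
  }
  TRUE
})

#' Construct a RegulonSet
#' @param regulons named list of data.frames with columns \code{target},
#'   \code{mode}, \code{likelihood} (one list element per TF).
#' @return a validated \linkS4class{RegulonSet}
#' @export
RegulonSet <- function(regulons = list()) {
  methods::new("RegulonSet", regulons = regulons)
}

#' @describeIn RegulonSet number of regulons
#' @param x,object a RegulonSet
#' @export
setMethod("length", "RegulonSet", function(x) length(x@regulons))

#' @describeIn RegulonSet TF identifiers
#' @export
setMethod("names", "RegulonSet", function(x) names(x@regulons))

setMethod("show", "RegulonSet", function(object) {
  sizes <- vapply(object@regulons, nrow, integer(1))
  cat(sprintf("RegulonSet: %d TF(s), %s targets per TF\n",
              length(object@regulons),
              if (length(sizes)) sprintf("%d-%d", min(sizes), max(sizes)) else "0"))
  invisible(object)
})

#' Extract the target table of one regulon
#' @param x a \linkS4class{RegulonSet}
#' @param tf TF identifier
#' @return data.frame with columns \code{target}, \code{mode}, \code{likelihood}
#' @export
regulonTargets <- function(x, tf) {
  stopifnot(methods::is(x, "RegulonSet"))
  if (!tf %in% names(x@regulons))
    stop(sprintf("no regulon for TF '%s'", tf), call. = FALSE)
  x@regulons[[tf]]
}
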