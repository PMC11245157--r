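#' Distribution shift between TOP-mRNA and background fold changes
#'
#' Two-sample, two-sided Kolmogorov-Smirnov comparison (asymptotic
#' p-values) of the fold-change distributions of a gene group (e.g.
#' 5' TOP-motif mRNAs) against all other genes, with the shift direction
#' taken from the difference of medians. ECDF coordinates for cumulative
#' distribution plots are attached as the \code{"ecdf"} attribute.
#'
#' @param top_values,other_values numeric fold-change vectors for the two
#'   groups (both non-empty).
#' @return one-row data.frame with \code{ks_d}, \code{ks_p},
#'   \code{shift_direction} (-1/0/+1), \code{n_top}, \code{n_other};
#'   attribute \code{"ecdf"} holds per-group sorted values and cumulative
#'   fractions.
#' @export
ecdfShift <- function(top_values, other_values) {
  top_values <- top_values[is.finite(top_values)]
  other_values <- other_values[is.finite(other_values)]
  if (!length(top_values) || !length(other_values))
    stop("ecdfShift: both groups must be non-empty", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(top_values, other_values,
                                        alternative = "two.sided",
                                        exact = FALSE))
  out <- data.frame(
    ks_d = unname(ks$statistic),
    ks_p = ks$p.value,
    shift_direction = sign(stats::median(top_values) -
                           stats::median(other_values)),
    n_top = length(top_values),
    n_other = length(other_values))
  attr(out, "ecdf") <- list(
    top = list(x = sort(top_values),
               y = seq_along(top_values) / length(top_values)),
    other = list(x = sort(other_values),
                 y = seq_along(other_values) / length(other_values)))
  out
}

#' TOP-mRNA distribution shifts per layer and contrast
#'
#' Runs [ecdfShift()] for the RNA, RPF, TE and protein fold changes in each
#' contrast, comparing the supplied TOP genes to all other genes, and flags
#' compensation where the RNA and TE shift directions are opposite within a
#' contrast (transcriptional change counteracted at the level of
#' translation efficiency).
#'
#' @param table \linkS4class{MultiLayerTable} with RNA, RPF and PROTEIN
#'   layers.
#' @param te data.frame from [teInteraction()].
#' @param top_genes character vector of TOP gene identifiers (must
#'   intersect the gene universe).
#' @param dataset dataset stratum (default MERGED).
#' @return data.frame with one row per (layer, contrast): \code{layer},
#'   \code{contrast}, \code{ks_d}, \code{ks_p}, \code{shift_direction},
#'   \code{n_top}, \code{n_other}, \code{compensation}.
#' @export
topReport <- function(table, te, top_genes, dataset = "MERGED") {
  df <- records(table)
  universe <- unique(df$gene[df$dataset == dataset])
  top_genes <- intersect(top_genes, universe)
  if (!length(top_genes))
    stop("topReport: TOP list does not intersect the gene universe",
         call. = FALSE)
  contrasts <- unique(df$contrast[df$dataset == dataset])
  rows <- list()
  for (ct in contrasts) {
    vals <- list()
    for (ly in .LAYERS) {
      d <- .slice(table, ly, ct, dataset)
      vals[[ly]] <- stats::setNames(d$logfc, d$gene)
    }
    te_ct <- te[te$contrast == ct, , drop = FALSE]
    vals[["TE"]] <- stats::setNames(te_ct$te_logfc, te_ct$gene)
    for (ly in c("RNA", "RPF", "TE", "PROTEIN")) {
      v <- vals[[ly]]
      is_top <- names(v) %in% top_genes
      shift <- ecdfShift(v[is_top], v[!is_top])
      rows[[paste(ly, ct)]] <- cbind(
        data.frame(layer = ly, contrast = ct, stringsAsFactors = FALSE),
        shift)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$compensation <- FALSE
  for (ct in contrasts) {
    rna_dir <- out$shift_direction[out$layer == "RNA" & out$contrast == ct]
    te_dir <- out$shift_direction[out$layer == "TE" & out$contrast == ct]
    comp <- length(rna_dir) == 1L && length(te_dir) == 1L &&
      rna_dir != 0 && te_dir == -rna_dir
    out$compensation[out$contrast == ct] <- comp
  }
  out
}
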