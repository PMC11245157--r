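## Wide extraction helper: one row per gene with logfc/se/pvalue/fdr columns
## for a given layer/contrast/dataset slice.
.slice <- function(table, layer, contrast, dataset) {
  df <- records(table)
  df[df$layer == layer & df$contrast == contrast & df$dataset == dataset,
     c("gene", "logfc", "se", "pvalue", "fdr"), drop = FALSE]
}

#' Combine p-values across layers by Fisher's method
#'
#' Aggregates significance across the molecular layers for one gene:
#' \eqn{\chi^2 = -2 \sum_i \ln p_i} with \eqn{2k} degrees of freedom, where
#' k is the number of (non-missing) p-values. Missing layers are dropped
#' with the degrees of freedom reduced accordingly. Exact zeros are clamped
#' to 1e-300 with a warning (the logarithm is otherwise undefined).
#'
#' @param pvalues numeric vector of per-layer p-values in (0, 1]; NAs are
#'   dropped.
#' @return list with \code{chi2}, \code{df} and \code{combined_p}.
#' @examples
#' fisherCombine(c(0.05, 0.05))$combined_p  # ~0.0175
#' @export
fisherCombine <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues))
    stop("fisherCombine: no non-missing p-values to combine", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1))
    stop("fisherCombine: p-values must be in [0,1]", call. = FALSE)
  if (any(pvalues == 0)) {
    tlLog("WARN", "fisherCombine: %d zero p-value(s) clamped to 1e-300",
          sum(pvalues == 0))
    pvalues[pvalues == 0] <- 1e-300
  }
  chi2 <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(chi2 = chi2, df = df,
       combined_p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Fisher-combined significance across layers for every gene
#'
#' Runs [fisherCombine()] on the RNA, RPF and protein p-values of each gene
#' within each contrast of one dataset, then adjusts the combined p-values
#' by Benjamini-Hochberg within the contrast.
#'
#' @param table a \linkS4class{MultiLayerTable}.
#' @param dataset which dataset stratum to combine (default MERGED).
#' @return data.frame with columns \code{gene}, \code{contrast},
#'   \code{chi2}, \code{df}, \code{combined_p}, \code{combined_fdr}.
#' @export
combineLayerSignificance <- function(table, dataset = "MERGED") {
  df <- records(table)
  df <- df[df$dataset == dataset, , drop = FALSE]
  if (!nrow(df))
    stop(sprintf("no records for dataset %s", dataset), call. = FALSE)
  out <- list()
  for (ct in unique(df$contrast)) {
    sub <- df[df$contrast == ct, , drop = FALSE]
    sp <- split(sub$pvalue, sub$gene)
    res <- lapply(sp, function(p) fisherCombine(p))
    genes <- names(sp)
    comb <- data.frame(
      gene = genes, contrast = ct,
      chi2 = vapply(res, `[[`, numeric(1), "chi2"),
      df = vapply(res, `[[`, integer(1), "df"),
      combined_p = vapply(res, `[[`, numeric(1), "combined_p"),
      stringsAsFactors = FALSE, row.names = NULL)
    comb$combined_fdr <- bhAdjust(comb$combined_p)
    out[[ct]] <- comb
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Meta-analytic merge of isogenic and patient-derived datasets
#'
#' Combines the two datasets' statistics per (gene, layer, contrast) by
#' inverse-variance weighting: the merged log2FC is the precision-weighted
#' mean, the merged SE is \eqn{1/\sqrt{\sum 1/se_i^2}}, the p-value is the
#' two-sided normal tail of the merged z, and FDR is recomputed by
#' Benjamini-Hochberg within each (layer, contrast) stratum. Genes present
#' in only one dataset are excluded from the merge and reported in the
#' \code{"skipped"} attribute.
#'
#' @param isogenic,patient \linkS4class{MultiLayerTable} for each dataset.
#' @return a \linkS4class{MultiLayerTable} with \code{dataset = "MERGED"};
#'   attribute \code{"skipped"} lists genes dropped for being absent from
#'   one dataset.
#' @export
mergeDatasets <- function(isogenic, patient) {
  a <- records(isogenic); b <- records(patient)
  key <- function(d) paste(d$gene, d$layer, d$contrast, sep = "\r")
  ka <- key(a); kb <- key(b)
  shared <- intersect(ka, kb)
  if (!length(shared))
    stop("mergeDatasets: no shared (gene, layer, contrast) records", call. = FALSE)
  skipped <- union(a$gene[!ka %in% shared], b$gene[!kb %in% shared])
  a <- a[match(shared, ka), ]; b <- b[match(shared, kb), ]
  wa <- 1 / a$se^2; wb <- 1 / b$se^2
  logfc <- (wa * a$logfc + wb * b$logfc) / (wa + wb)
  se <- 1 / sqrt(wa + wb)
  p <- 2 * stats::pnorm(-abs(logfc / se))
  m <- data.frame(gene = a$gene, layer = a$layer, contrast = a$contrast,
                  dataset = "MERGED", logfc = logfc, se = se, pvalue = p,
                  fdr = NA_real_, stringsAsFactors = FALSE)
  strata <- paste(m$layer, m$contrast)
  for (s in unique(strata)) {
    i <- strata == s
    m$fdr[i] <- bhAdjust(m$pvalue[i])
  }
  if (length(skipped))
    tlLog("INFO", "mergeDatasets: %d gene(s) skipped (absent from one dataset)",
          length(skipped))
  out <- MultiLayerTable(m)
  attr(out, "skipped") <- skipped
  out
}

#' Differential-expression filter on the merged RNA analysis
#'
#' A gene is a DEG if, in any contrast, its merged RNA |log2FC| exceeds
#' \code{log2(1 + merged_min_change)} with merged FDR below
#' \code{merged_fdr}, and it additionally replicates in both datasets with
#' per-dataset FDR below \code{per_dataset_fdr} in that contrast. The
#' HIGH_CONFIDENCE tier additionally requires |log2FC| above
#' \code{log2(1 + highconf_min_change)} at the same FDR. All comparisons
#' are strict.
#'
#' @param merged merged \linkS4class{MultiLayerTable} (from
#'   [mergeDatasets()]).
#' @param isogenic,patient the per-dataset tables supplying the replication
#'   FDRs.
#' @param config a [pipelineConfig()] list.
#' @param layer layer on which the filter operates (default RNA).
#' @return data.frame with columns \code{gene} and \code{tier}
#'   (\code{"DEG"} or \code{"HIGH_CONFIDENCE"}).
#' @export
mergedDegFilter <- function(merged, isogenic, patient,
                            config = pipelineConfig(), layer = "RNA") {
  mdf <- records(merged)
  mdf <- mdf[mdf$layer == layer & mdf$dataset == "MERGED", , drop = FALSE]
  if (!nrow(mdf))
    stop(sprintf("merged table has no %s layer", layer), call. = FALSE)
  thr_deg <- log2(1 + config$merged_min_change)
  thr_hc <- log2(1 + config$highconf_min_change)
  per_ds <- list(ISOGENIC = isogenic, PATIENT = patient)
  deg <- character(0); hc <- character(0)
  for (ct in unique(mdf$contrast)) {
    sub <- mdf[mdf$contrast == ct, , drop = FALSE]
    fdr_ds <- lapply(names(per_ds), function(ds) {
      d <- .slice(per_ds[[ds]], layer, ct, ds)
      if (!nrow(d))
        stop(sprintf("missing per-dataset FDR for dataset %s (%s, %s)",
                     ds, layer, ct), call. = FALSE)
      d$fdr[match(sub$gene, d$gene)]
    })
    replicated <- fdr_ds[[1]] < config$per_dataset_fdr &
      fdr_ds[[2]] < config$per_dataset_fdr
    replicated[is.na(replicated)] <- FALSE
    pass_deg <- abs(sub$logfc) > thr_deg & sub$fdr < config$merged_fdr &
      replicated
    pass_hc <- pass_deg & abs(sub$logfc) > thr_hc
    deg <- union(deg, sub$gene[pass_deg])
    hc <- union(hc, sub$gene[pass_hc])
  }
  if (!length(deg)) return(data.frame(gene = character(0), tier = character(0)))
  data.frame(gene = sort(deg),
             tier = ifelse(sort(deg) %in% hc, "HIGH_CONFIDENCE", "DEG"),
             stringsAsFactors = FALSE)
}

#' Candidate genes for the layer-integration procedure
#'
#' A gene is a candidate in a contrast if any route passes: RNA FDR below
#' \code{candidate_fdr} with |RNA log2FC| above \code{candidate_abs_logfc};
#' the same at the protein layer; or Fisher-combined FDR across the three
#' layers below \code{candidate_fdr}.
#'
#' @param table \linkS4class{MultiLayerTable} containing RNA and PROTEIN
#'   layers for the chosen dataset.
#' @param combined data.frame from [combineLayerSignificance()].
#' @param config a [pipelineConfig()] list.
#' @param dataset dataset stratum to select within (default MERGED).
#' @return data.frame with columns \code{gene}, \code{contrast},
#'   \code{route} (comma-separated routes that fired).
#' @export
selectCandidateGenes <- function(table, combined, config = pipelineConfig(),
                                 dataset = "MERGED") {
  out <- list()
  for (ct in unique(combined$contrast)) {
    rna <- .slice(table, "RNA", ct, dataset)
    prot <- .slice(table, "PROTEIN", ct, dataset)
    if (!nrow(rna) || !nrow(prot))
      stop(sprintf("RNA and PROTEIN layers required for contrast %s", ct),
           call. = FALSE)
    comb <- combined[combined$contrast == ct, , drop = FALSE]
    genes <- union(union(rna$gene, prot$gene), comb$gene)
    r_i <- match(genes, rna$gene); p_i <- match(genes, prot$gene)
    c_i <- match(genes, comb$gene)
    via_rna <- !is.na(r_i) & rna$fdr[r_i] < config$candidate_fdr &
      abs(rna$logfc[r_i]) > config$candidate_abs_logfc
    via_prot <- !is.na(p_i) & prot$fdr[p_i] < config$candidate_fdr &
      abs(prot$logfc[p_i]) > config$candidate_abs_logfc
    via_comb <- !is.na(c_i) & comb$combined_fdr[c_i] < config$candidate_fdr
    keep <- via_rna | via_prot | via_comb
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) next
    route <- apply(cbind(RNA = via_rna, PROTEIN = via_prot,
                         COMBINED = via_comb)[keep, , drop = FALSE], 1L,
                   function(z) paste(names(z)[which(z)], collapse = ","))
    out[[ct]] <- data.frame(gene = genes[keep], contrast = ct, route = route,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(out))
    return(data.frame(gene = character(0), contrast = character(0),
                      route = character(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Translation-efficiency interaction contrast on summary statistics
#'
#' The TE log2FC is the RPF log2FC minus the RNA log2FC; under independent
#' errors its SE is \eqn{\sqrt{se_{rna}^2 + se_{rpf}^2}}, giving a z
#' statistic and a two-sided normal p-value, with FDR by Benjamini-Hochberg
#' within each contrast.
#'
#' @param table \linkS4class{MultiLayerTable} with RNA and RPF layers.
#' @param dataset dataset stratum (default MERGED).
#' @return data.frame with columns \code{gene}, \code{contrast},
#'   \code{te_logfc}, \code{te_se}, \code{te_z}, \code{te_pvalue},
#'   \code{te_fdr}.
#' @export
teInteraction <- function(table, dataset = "MERGED") {
  df <- records(table)
  df <- df[df$dataset == dataset, , drop = FALSE]
  out <- list()
  for (ct in unique(df$contrast)) {
    rna <- .slice(table, "RNA", ct, dataset)
    rpf <- .slice(table, "RPF", ct, dataset)
    if (!nrow(rna) || !nrow(rpf)) next
    genes <- intersect(rna$gene, rpf$gene)
    if (!length(genes))
      stop(sprintf("teInteraction: no genes with both RNA and RPF in %s", ct),
           call. = FALSE)
    r <- rna[match(genes, rna$gene), ]; f <- rpf[match(genes, rpf$gene), ]
    if (any(r$se <= 0 | f$se <= 0, na.rm = TRUE))
      stop("teInteraction: standard errors must be positive", call. = FALSE)
    te <- f$logfc - r$logfc
    se <- sqrt(r$se^2 + f$se^2)
    z <- te / se
    res <- data.frame(gene = genes, contrast = ct, te_logfc = te, te_se = se,
                      te_z = z, te_pvalue = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE, row.names = NULL)
    res$te_fdr <- bhAdjust(res$te_pvalue)
    out[[ct]] <- res
  }
  if (!length(out))
    stop("teInteraction: RNA and RPF layers required", call. = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fraction of genes with opposite-direction fold changes across conditions
#'
#' Among a gene set with log2FCs in both the hemideletion and
#' hemiduplication contrasts, the fraction whose signs are opposite
#' (\code{sign(wbs) == -sign(dup)}). Genes with a zero fold change in
#' either contrast are excluded from numerator and denominator; their count
#' is reported in the \code{"n_zero"} attribute.
#'
#' @param genes character vector of gene identifiers (e.g. the DEG set).
#' @param wbs_logfc,dup_logfc named numeric vectors of log2FCs (names are
#'   genes) for the two contrasts.
#' @return fraction in [0,1]; attributes \code{"n"} (genes counted) and
#'   \code{"n_zero"} (excluded zeros).
#' @export
oppositeDirectionFraction <- function(genes, wbs_logfc, dup_logfc) {
  if (!length(genes))
    stop("oppositeDirectionFraction: empty gene set", call. = FALSE)
  w <- wbs_logfc[genes]; d <- dup_logfc[genes]
  if (anyNA(w) || anyNA(d))
    stop("oppositeDirectionFraction: both contrasts required for all genes",
         call. = FALSE)
  nz <- sign(w) != 0 & sign(d) != 0
  n_zero <- sum(!nz)
  if (!any(nz))
    stop("oppositeDirectionFraction: all fold changes are zero", call. = FALSE)
  frac <- mean(sign(w[nz]) == -sign(d[nz]))
  attr(frac, "n") <- sum(nz)
  attr(frac, "n_zero") <- n_zero
  frac
}
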