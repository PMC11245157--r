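#' Robust no-intercept regression (Huber M-estimation through the origin)
#'
#' Iteratively reweighted least squares for the slope of \code{y ~ 0 + x}
#' with Huber weights (default tuning 1.345, the 95%-efficiency constant),
#' vertical residuals, and a MAD scale (centered at zero) re-estimated each
#' iteration. Iteration stops when the slope changes by less than \code{tol}
#' or after \code{max_iter} iterations. \code{residual_sd} is the SD of the
#' vertical residuals over the fitted points and \code{r} the Pearson
#' correlation of (x, y).
#'
#' @param x,y numeric vectors (RNA and protein log2FCs, say); non-finite
#'   pairs are dropped.
#' @param tuning Huber tuning constant.
#' @param psi weight function: \code{"huber"} (default) or
#'   \code{"bisquare"} (Tukey, tuning typically 4.685).
#' @param max_iter,tol IRLS iteration cap and slope-change tolerance.
#' @return list of class \code{"originFit"} with \code{slope},
#'   \code{residual_sd}, \code{n_genes}, \code{r}, \code{iterations},
#'   \code{converged}.
#' @examples
#' f <- fitOriginRobust(1:10, 0.8 * (1:10))
#' f$slope  # 0.8
#' @export
fitOriginRobust <- function(x, y, tuning = 1.345,
                            psi = c("huber", "bisquare"),
                            max_iter = 50L, tol = 1e-8) {
  psi <- match.arg(psi)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("fitOriginRobust: need at least 3 finite (x, y) pairs", call. = FALSE)
  if (all(x == 0))
    stop("fitOriginRobust: x is degenerate (all zero)", call. = FALSE)
  nz <- x != 0
  slope <- stats::median(y[nz] / x[nz])
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- y - slope * x
    s <- stats::mad(r, center = 0)
    if (s == 0) { converged <- TRUE; break }  # exact fit (up to MAD)
    if (psi == "huber") {
      u <- abs(r) / (s * tuning)
      w <- pmin(1, 1 / pmax(u, .Machine$double.eps))
    } else {
      ub <- abs(r) / (s * 4.685)
      w <- ifelse(ub < 1, (1 - ub^2)^2, 0)
    }
    new_slope <- sum(w * x * y) / sum(w * x^2)
    if (!is.finite(new_slope))
      stop("fitOriginRobust: weighted fit degenerate", call. = FALSE)
    if (abs(new_slope - slope) < tol) { slope <- new_slope; converged <- TRUE; break }
    slope <- new_slope
  }
  res <- y - slope * x
  structure(list(slope = slope,
                 residual_sd = stats::sd(res),
                 n_genes = length(x),
                 r = if (stats::sd(x) > 0 && stats::sd(y) > 0)
                   stats::cor(x, y) else NA_real_,
                 iterations = iter, converged = converged),
            class = "originFit")
}

#' @export
print.originFit <- function(x, ...) {
  cat(sprintf(
    "robust origin fit: slope %.4f, residual SD %.4f, r %.3f, n = %d\n",
    x$slope, x$residual_sd, x$r, x$n_genes))
  invisible(x)
}

#' Classify candidate genes as forwarded via the RNA-protein residual band
#'
#' Establishes the normal RNA-to-protein relationship by a robust
#' no-intercept fit restricted to genes that are significant (FDR below
#' \code{candidate_fdr}) and in the same direction at both the
#' transcriptome and the proteome, pooling the contrasts' points. The
#' spread of those diagonal genes sets the forwarded band: every candidate
#' whose vertical residual \eqn{|protein - slope \cdot rna|} lies within
#' \code{forward_band_sd} residual-SDs is labeled FORWARDED; all other
#' candidates carry their residual forward to [classifyTranslation()].
#'
#' @param candidates data.frame from [selectCandidateGenes()] (columns
#'   \code{gene}, \code{contrast}).
#' @param table \linkS4class{MultiLayerTable} with RNA and PROTEIN layers.
#' @param config a [pipelineConfig()] list.
#' @param dataset dataset stratum (default MERGED).
#' @return list with \code{fit} (the \code{"originFit"}) and
#'   \code{classification}, a data.frame with columns \code{gene},
#'   \code{contrast}, \code{category}, \code{rna_logfc},
#'   \code{protein_logfc}, \code{residual}, \code{te_explained}.
#' @export
classifyForwarded <- function(candidates, table, config = pipelineConfig(),
                              dataset = "MERGED") {
  if (!nrow(candidates))
    stop("classifyForwarded: empty candidate set", call. = FALSE)
  pts <- list(); fitpts <- list()
  for (ct in unique(candidates$contrast)) {
    rna <- .slice(table, "RNA", ct, dataset)
    prot <- .slice(table, "PROTEIN", ct, dataset)
    if (!nrow(rna) || !nrow(prot))
      stop("classifyForwarded: RNA and PROTEIN layers required", call. = FALSE)
    genes <- intersect(rna$gene, prot$gene)
    r <- rna[match(genes, rna$gene), ]; p <- prot[match(genes, prot$gene), ]
    both_sig <- r$fdr < config$candidate_fdr & p$fdr < config$candidate_fdr &
      sign(r$logfc) == sign(p$logfc) & sign(r$logfc) != 0
    both_sig[is.na(both_sig)] <- FALSE
    fitpts[[ct]] <- data.frame(x = r$logfc[both_sig], y = p$logfc[both_sig])
    cand <- candidates$gene[candidates$contrast == ct]
    keep <- genes %in% cand
    pts[[ct]] <- data.frame(gene = genes[keep], contrast = ct,
                            rna_logfc = r$logfc[keep],
                            protein_logfc = p$logfc[keep],
                            stringsAsFactors = FALSE)
  }
  fitdf <- do.call(rbind, fitpts)
  if (nrow(fitdf) < 3L)
    stop(paste("classifyForwarded: fewer than 3 genes significant and",
               "same-direction at both layers; supply a larger input"),
         call. = FALSE)
  fit <- fitOriginRobust(fitdf$x, fitdf$y)
  tlLog("INFO", "RNA-protein origin fit: slope %.3f, residual SD %.3f, r %.3f (n=%d)",
        fit$slope, fit$residual_sd, fit$r, fit$n_genes)
  cls <- do.call(rbind, c(pts, list(make.row.names = FALSE)))
  cls$residual <- cls$protein_logfc - fit$slope * cls$rna_logfc
  band <- config$forward_band_sd * fit$residual_sd
  cls$category <- ifelse(abs(cls$residual) <= band, "FORWARDED", "UNCLASSIFIED")
  cls$te_explained <- FALSE
  list(fit = fit, classification = cls)
}

#' Attribute non-forwarded residuals to translation-efficiency changes
#'
#' Repeats the origin-fit procedure on the residuals of
#' [classifyForwarded()] against the TE log2FC, restricted to genes with a
#' TE p-value below \code{te_pvalue}. Non-forwarded candidates whose
#' second-stage residual lies within the central
#' \code{translation_band_quantile} band (half-width
#' \code{qnorm((1+q)/2)} times the second residual SD) are labeled
#' TRANSLATION_REGULATED — their TE pattern explains the RNA-protein
#' discrepancy; remaining non-forwarded candidates become
#' OTHER_POSTTRANSCRIPTIONAL. With fewer than 3 genes passing the TE
#' filter, all non-forwarded genes are labeled OTHER_POSTTRANSCRIPTIONAL
#' with a warning.
#'
#' @param classified the list returned by [classifyForwarded()].
#' @param te data.frame from [teInteraction()].
#' @param config a [pipelineConfig()] list.
#' @return list with \code{fit} (first-stage), \code{te_fit} (second-stage
#'   \code{"originFit"} or NULL) and the updated \code{classification}.
#' @export
classifyTranslation <- function(classified, te, config = pipelineConfig()) {
  cls <- classified$classification
  key <- paste(cls$gene, cls$contrast)
  te_key <- paste(te$gene, te$contrast)
  idx <- match(key, te_key)
  cls$te_logfc <- te$te_logfc[idx]
  cls$te_pvalue <- te$te_pvalue[idx]
  open <- cls$category != "FORWARDED"
  fit_sub <- open & !is.na(cls$te_pvalue) & cls$te_pvalue < config$te_pvalue
  te_fit <- NULL
  if (sum(fit_sub) < 3L) {
    tlLog("WARN", paste("classifyTranslation: <3 genes pass the TE p filter;",
                        "labeling all non-forwarded as OTHER_POSTTRANSCRIPTIONAL"))
    cls$category[open] <- "OTHER_POSTTRANSCRIPTIONAL"
  } else {
    te_fit <- fitOriginRobust(cls$te_logfc[fit_sub], cls$residual[fit_sub])
    tlLog("INFO", "residual-TE origin fit: slope %.3f, residual SD %.3f, r %.3f (n=%d)",
          te_fit$slope, te_fit$residual_sd, te_fit$r, te_fit$n_genes)
    zq <- stats::qnorm((1 + config$translation_band_quantile) / 2)
    band2 <- zq * te_fit$residual_sd
    res2 <- cls$residual - te_fit$slope * cls$te_logfc
    inside <- open & !is.na(res2) & abs(res2) <= band2
    cls$category[inside] <- "TRANSLATION_REGULATED"
    cls$te_explained[inside] <- TRUE
    cls$category[open & !inside] <- "OTHER_POSTTRANSCRIPTIONAL"
  }
  list(fit = classified$fit, te_fit = te_fit, classification = cls)
}

#' Buffering coefficient of a gene set
#'
#' One minus the robust no-intercept slope of protein log2FC on RNA log2FC
#' over the set: 0 means full forwarding (protein tracks RNA), 1 complete
#' buffering (protein flat), negative values amplification.
#'
#' @param genes character vector of gene identifiers (>= 3 with both layers).
#' @param table \linkS4class{MultiLayerTable}.
#' @param contrast contrast to evaluate.
#' @param dataset dataset stratum (default MERGED).
#' @return list with \code{buffering_coefficient}, \code{n_genes},
#'   \code{contrast} and the underlying \code{fit}.
#' @export
bufferingCoefficient <- function(genes, table, contrast, dataset = "MERGED") {
  rna <- .slice(table, "RNA", contrast, dataset)
  prot <- .slice(table, "PROTEIN", contrast, dataset)
  genes <- intersect(genes, intersect(rna$gene, prot$gene))
  if (length(genes) < 3L)
    stop("bufferingCoefficient: need >= 3 genes with both layers", call. = FALSE)
  x <- rna$logfc[match(genes, rna$gene)]
  y <- prot$logfc[match(genes, prot$gene)]
  fit <- fitOriginRobust(x, y)
  list(buffering_coefficient = 1 - fit$slope, n_genes = length(genes),
       contrast = contrast, fit = fit)
}
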