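#' Scale fold-change columns to unit variance without centering
#'
#' Divides each column of a log2FC matrix by its SD; no mean subtraction,
#' so signs and relative magnitudes across genes are preserved.
#'
#' @param m numeric matrix (genes x layer/contrast columns).
#' @return matrix of the same shape with unit-SD columns.
#' @export
scaleUnitVariance <- function(m) {
  m <- as.matrix(m)
  sds <- apply(m, 2L, stats::sd)
  zero <- which(sds == 0 | is.na(sds))
  if (length(zero))
    stop(sprintf("scaleUnitVariance: zero-SD column(s): %s",
                 paste(colnames(m)[zero], collapse = ", ")), call. = FALSE)
  sweep(m, 2L, sds, "/")
}

#' Discretize a gene's scaled fold changes to a five-level score
#'
#' Given the per-dataset scaled log2FCs of one gene in one layer/contrast:
#' score 1 if the median exceeds the threshold and all values are positive,
#' 0.5 if the median exceeds it but signs are mixed, and symmetrically -1 /
#' -0.5 for downregulation; 0 when the median is within the threshold.
#'
#' @param values numeric vector of scaled log2FCs (one per dataset).
#' @param threshold median threshold (default 0.2).
#' @return a score in \{-1, -0.5, 0, 0.5, 1\}.
#' @examples
#' discretizeGene(c(0.5, 0.6))    # 1
#' discretizeGene(c(0.9, -0.1))   # 0.5
#' discretizeGene(c(0.1, 0.15))   # 0
#' @export
discretizeGene <- function(values, threshold = 0.2) {
  values <- values[is.finite(values)]
  if (!length(values))
    stop("discretizeGene: no finite values", call. = FALSE)
  m <- stats::median(values)
  if (m > threshold) {
    if (all(values > 0)) 1 else 0.5
  } else if (m < -threshold) {
    if (all(values < 0)) -1 else -0.5
  } else 0
}

#' Discretized cross-layer profiles for a gene set
#'
#' For each of RNA and protein in each contrast, scales the per-dataset
#' log2FC columns to unit variance (computed over the supplied gene set)
#' and discretizes each gene's pair of dataset values with
#' [discretizeGene()]. The resulting four-score profile (RNA and protein
#' by WBS and DUP) is the clustering input.
#'
#' @param isogenic,patient per-dataset \linkS4class{MultiLayerTable}s.
#' @param genes genes to profile (e.g. the DEG set).
#' @param config a [pipelineConfig()] list (supplies
#'   \code{discretize_median}).
#' @return data.frame with columns \code{gene}, \code{score_rna_wbs},
#'   \code{score_rna_dup}, \code{score_prot_wbs}, \code{score_prot_dup}.
#' @export
discretizeProfiles <- function(isogenic, patient, genes,
                               config = pipelineConfig()) {
  if (!length(genes))
    stop("discretizeProfiles: empty gene set", call. = FALSE)
  combos <- list(score_rna_wbs = c("RNA", "WBS_VS_CTL"),
                 score_rna_dup = c("RNA", "DUP_VS_CTL"),
                 score_prot_wbs = c("PROTEIN", "WBS_VS_CTL"),
                 score_prot_dup = c("PROTEIN", "DUP_VS_CTL"))
  tabs <- list(ISOGENIC = isogenic, PATIENT = patient)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(combos)) {
    ly <- combos[[nm]][1]; ct <- combos[[nm]][2]
    m <- vapply(names(tabs), function(ds) {
      d <- .slice(tabs[[ds]], ly, ct, ds)
      v <- d$logfc[match(genes, d$gene)]
      if (anyNA(v))
        stop(sprintf("discretizeProfiles: missing %s/%s values in %s",
                     ly, ct, ds), call. = FALSE)
      v
    }, numeric(length(genes)))
    m <- scaleUnitVariance(m)
    out[[nm]] <- apply(m, 1L, discretizeGene,
                       threshold = config$discretize_median)
  }
  out
}

#' k-means clustering of discretized cross-layer profiles
#'
#' Clusters the concatenated RNA and protein score vectors with k-means
#' (Euclidean distance, 10 seeded restarts, best by within-cluster sum of
#' squares). Deterministic given the seed.
#'
#' @param profiles data.frame from [discretizeProfiles()] (first column
#'   \code{gene}, remaining columns scores).
#' @param k number of centers (default 8).
#' @param seed integer seed.
#' @return list with \code{assignments} (data.frame \code{gene},
#'   \code{cluster_id} in [0, k)) and \code{centroids} (k x score matrix).
#' @export
clusterProfiles <- function(profiles, k = 8L, seed = 42L) {
  score_cols <- setdiff(names(profiles), "gene")
  m <- as.matrix(profiles[, score_cols, drop = FALSE])
  rownames(m) <- profiles$gene
  n_distinct <- nrow(unique(m))
  if (n_distinct < k)
    stop(sprintf(
      "clusterProfiles: only %d distinct profiles for k = %d; use a smaller k",
      n_distinct, k), call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = 10L, iter.max = 100L)
  list(assignments = data.frame(gene = profiles$gene,
                                cluster_id = km$cluster - 1L,
                                stringsAsFactors = FALSE),
       centroids = km$centers,
       tot_withinss = km$tot.withinss)
}

#' Label clusters by their centroid's cross-layer pattern
#'
#' Deterministic replacement for manual cluster grouping. With centroid
#' entries (RNA_WBS, RNA_DUP, PROT_WBS, PROT_DUP) and \code{|entry| <
#' near_zero} counting as zero: opposite-signed RNA with matching
#' non-zero protein signs is FORWARDED_OPPOSITE; non-zero RNA with protein
#' near zero in exactly one contrast is BUFFERED_WBS or BUFFERED_DUP (for
#' the contrast whose protein is flat); protein near zero in both with
#' non-zero RNA is BUFFERED_BOTH; anything else is OTHER.
#'
#' @param centroids k x 4 matrix from [clusterProfiles()] with columns
#'   ordered RNA_WBS, RNA_DUP, PROT_WBS, PROT_DUP.
#' @param near_zero magnitude below which a centroid entry counts as zero.
#' @return character vector of group labels, one per cluster (names are
#'   cluster ids starting at 0).
#' @export
groupClusters <- function(centroids, near_zero = 0.25) {
  labels <- apply(centroids, 1L, function(ce) {
    rw <- ce[1]; rd <- ce[2]; pw <- ce[3]; pd <- ce[4]
    rna_nz <- abs(rw) >= near_zero && abs(rd) >= near_zero
    pw0 <- abs(pw) < near_zero; pd0 <- abs(pd) < near_zero
    if (rna_nz && sign(rw) == -sign(rd) && !pw0 && !pd0 &&
        sign(pw) == sign(rw) && sign(pd) == sign(rd)) {
      "FORWARDED_OPPOSITE"
    } else if (rna_nz && xor(pw0, pd0)) {
      if (pw0) "BUFFERED_WBS" else "BUFFERED_DUP"
    } else if (rna_nz && pw0 && pd0) {
      "BUFFERED_BOTH"
    } else "OTHER"
  })
  stats::setNames(labels, as.character(seq_len(nrow(centroids)) - 1L))
}
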