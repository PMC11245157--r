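## expected integration category per truth class and contrast
.expected_category <- function(klass, contrast) {
  wbs <- contrast == "WBS_VS_CTL"
  switch(klass,
         FORWARDED_OPPOSITE = "FORWARDED",
         BUFFERED_WBS = if (wbs) "TRANSLATION_REGULATED" else "FORWARDED",
         BUFFERED_DUP = if (wbs) "FORWARDED" else "TRANSLATION_REGULATED",
         BUFFERED_BOTH = "TRANSLATION_REGULATED",
         TRANSLATION_OFFSET = "TRANSLATION_REGULATED",
         "NULL" = "UNCLASSIFIED")
}

## expected cluster group label per truth class
.expected_group <- function(klass) {
  switch(klass,
         FORWARDED_OPPOSITE = "FORWARDED_OPPOSITE",
         BUFFERED_WBS = "BUFFERED_WBS",
         BUFFERED_DUP = "BUFFERED_DUP",
         BUFFERED_BOTH = "BUFFERED_BOTH",
         "OTHER")
}

#' Compare pipeline outputs to synthetic ground truth
#'
#' Builds confusion tables between ground-truth classes and (i) the
#' per-contrast integration categories and (ii) the cluster group labels,
#' together with per-class recall against the expected label. Genes absent
#' from the classification table count as UNCLASSIFIED; the clustering
#' confusion covers only clustered genes.
#'
#' @param classification data.frame from [classifyTranslation()]
#'   (\code{$classification}).
#' @param clusters data.frame with columns \code{gene},
#'   \code{group_label} (from the clustering stage); may be NULL.
#' @param truth ground-truth data.frame from [simulateMultiomics()].
#' @return list with \code{confusion} (stage, contrast, truth_class,
#'   predicted, n) and \code{recall} (stage, contrast, truth_class,
#'   expected, n, n_match, recall).
#' @export
evaluateAgainstTruth <- function(classification, clusters = NULL, truth) {
  if (!all(classification$gene %in% truth$gene))
    stop("evaluateAgainstTruth: classification genes missing from truth",
         call. = FALSE)
  conf <- list(); rec <- list()
  for (ct in unique(classification$contrast)) {
    sub <- classification[classification$contrast == ct, , drop = FALSE]
    pred <- stats::setNames(sub$category, sub$gene)
    all_pred <- pred[truth$gene]
    all_pred[is.na(all_pred)] <- "UNCLASSIFIED"
    for (kl in unique(truth$class)) {
      p <- all_pred[truth$class == kl]
      tab <- table(p)
      conf[[paste("integration", ct, kl)]] <- data.frame(
        stage = "integration", contrast = ct, truth_class = kl,
        predicted = names(tab), n = as.integer(tab),
        stringsAsFactors = FALSE)
      expected <- .expected_category(kl, ct)
      rec[[paste("integration", ct, kl)]] <- data.frame(
        stage = "integration", contrast = ct, truth_class = kl,
        expected = expected, n = length(p),
        n_match = sum(p == expected),
        recall = mean(p == expected), stringsAsFactors = FALSE)
    }
  }
  if (!is.null(clusters) && nrow(clusters)) {
    kl_of <- stats::setNames(truth$class, truth$gene)
    cl_class <- kl_of[clusters$gene]
    for (kl in unique(cl_class)) {
      p <- clusters$group_label[cl_class == kl]
      tab <- table(p)
      conf[[paste("clustering", kl)]] <- data.frame(
        stage = "clustering", contrast = NA_character_, truth_class = kl,
        predicted = names(tab), n = as.integer(tab),
        stringsAsFactors = FALSE)
      expected <- .expected_group(kl)
      rec[[paste("clustering", kl)]] <- data.frame(
        stage = "clustering", contrast = NA_character_, truth_class = kl,
        expected = expected, n = length(p), n_match = sum(p == expected),
        recall = mean(p == expected), stringsAsFactors = FALSE)
    }
  }
  list(confusion = do.call(rbind, c(conf, list(make.row.names = FALSE))),
       recall = do.call(rbind, c(rec, list(make.row.names = FALSE))))
}

#' Run the full integration pipeline on synthetic data
#'
#' Orchestrates simulate -> merge -> TE/DEG -> candidate selection ->
#' forwarded/translation classification -> cross-layer clustering ->
#' TOP-mRNA shift analysis -> regulon activity scoring -> truth evaluation,
#' writing every stage output as TSV into \code{out_dir} plus a
#' \code{manifest.json} recording the configuration, seed and MD5 digest of
#' each output. Fully deterministic given the configuration seeds.
#'
#' @param config a [pipelineConfig()] list.
#' @param sim_config a [simulationConfig()]; its seed defaults to the
#'   pipeline seed.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the manifest list. Stage outputs:
#'   \code{isogenic.tsv}, \code{patient.tsv}, \code{truth.tsv},
#'   \code{regulons.tsv}, \code{merged.tsv}, \code{te.tsv},
#'   \code{deg.tsv}, \code{classified.tsv}, \code{fit_summary.json},
#'   \code{clusters.tsv}, \code{buffering.tsv}, \code{top.tsv},
#'   \code{tf_activity.tsv}, \code{metrics.tsv}, \code{recall.tsv}.
#' @examples
#' \donttest{
#' out <- runAll(pipelineConfig(seed = 1),
#'               simulationConfig(n_genes = 500, seed = 1),
#'               out_dir = tempfile("run"))
#' }
#' @export
runAll <- function(config = pipelineConfig(),
                   sim_config = simulationConfig(seed = config$seed),
                   out_dir = "trilayer_run") {
  .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tlLog("INFO", "stage: %s", name)
    tryCatch(force(expr),
             error = function(e) stop(sprintf("stage '%s' failed: %s", name,
                                              conditionMessage(e)),
                                      call. = FALSE))
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    .write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  sim <- stage("simulate", simulateMultiomics(sim_config))
  iso <- sim$tables$ISOGENIC; pat <- sim$tables$PATIENT
  emit(records(iso), "isogenic.tsv")
  emit(records(pat), "patient.tsv")
  stage("simulate", writeTruthTable(sim$truth, file.path(out_dir, "truth.tsv")))
  outputs <- c(outputs, file.path(out_dir, "truth.tsv"))
  stage("simulate", writeRegulons(sim$regulons,
                                  file.path(out_dir, "regulons.tsv")))
  outputs <- c(outputs, file.path(out_dir, "regulons.tsv"))

  merged <- stage("merge", mergeDatasets(iso, pat))
  emit(records(merged), "merged.tsv")

  te <- stage("te", teInteraction(merged))
  emit(te, "te.tsv")

  deg <- stage("deg", mergedDegFilter(merged, iso, pat, config))
  emit(deg, "deg.tsv")

  combined <- stage("integrate", combineLayerSignificance(merged))
  candidates <- stage("integrate",
                      selectCandidateGenes(merged, combined, config))
  cls <- stage("integrate", {
    fwd <- classifyForwarded(candidates, merged, config)
    classifyTranslation(fwd, te, config)
  })
  emit(cls$classification[, c("gene", "contrast", "category", "rna_logfc",
                              "protein_logfc", "residual", "te_explained")],
       "classified.tsv")
  fit_summary <- list(
    rna_protein = cls$fit[c("slope", "residual_sd", "r", "n_genes")],
    residual_te = if (is.null(cls$te_fit)) NULL else
      cls$te_fit[c("slope", "residual_sd", "r", "n_genes")])
  jsonlite::write_json(fit_summary, file.path(out_dir, "fit_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  outputs <- c(outputs, file.path(out_dir, "fit_summary.json"))

  clus <- stage("cluster", {
    if (nrow(deg) < config$kmeans_k)
      stop(sprintf("only %d DEGs for k = %d", nrow(deg), config$kmeans_k))
    profiles <- discretizeProfiles(iso, pat, deg$gene, config)
    km <- clusterProfiles(profiles, k = config$kmeans_k,
                          seed = config$seed + 1L)
    labels <- groupClusters(km$centroids)
    out <- profiles
    out$cluster_id <- km$assignments$cluster_id
    out$group_label <- unname(labels[as.character(out$cluster_id)])
    out
  })
  emit(clus, "clusters.tsv")

  buf <- stage("buffering", {
    rows <- list()
    for (gl in setdiff(unique(clus$group_label), NA)) {
      genes <- clus$gene[clus$group_label == gl]
      if (length(genes) < 3L) next
      for (ct in c("WBS_VS_CTL", "DUP_VS_CTL")) {
        bc <- bufferingCoefficient(genes, merged, ct)
        rows[[paste(gl, ct)]] <- data.frame(
          group_label = gl, contrast = ct,
          buffering_coefficient = bc$buffering_coefficient,
          n_genes = bc$n_genes, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  emit(buf, "buffering.tsv")

  top <- stage("top", topReport(merged, te, sim$truth$gene[sim$truth$is_top]))
  emit(top, "top.tsv")

  tfa <- stage("regulon", {
    rows <- list()
    for (ct in c("WBS_VS_CTL", "DUP_VS_CTL")) {
      sigs <- lapply(list(ISOGENIC = iso, PATIENT = pat), function(tb) {
        d <- .slice(tb, "RNA", ct,
                    records(tb)$dataset[1])
        stats::setNames(d$logfc / d$se, d$gene)
      })
      sa <- scoreRegulons(sim$regulons, sigs$ISOGENIC)
      sb <- scoreRegulons(sim$regulons, sigs$PATIENT)
      cf <- consistencyFilter(sa, sb)
      cf$contrast <- ct
      rows[[ct]] <- cf
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
  emit(tfa, "tf_activity.tsv")

  metrics <- stage("evaluate",
                   evaluateAgainstTruth(cls$classification, clus, sim$truth))
  emit(metrics$confusion, "metrics.tsv")
  emit(metrics$recall, "recall.tsv")

  manifest <- list(
    tool = "trilayer",
    version = as.character(utils::packageVersion("trilayer")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    sim_config = unclass(sim_config)[setdiff(names(sim_config),
                                             "class_proportions")],
    class_proportions = as.list(sim_config$class_proportions),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  tlLog("INFO", "run complete: %d output file(s) in %s", length(outputs),
        out_dir)
  invisible(manifest)
}
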