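#' Pipeline configuration with the study's thresholds as defaults
#'
#' Collects every tunable threshold of the integration pipeline. Defaults
#' encode the analysis' published filtering rules: candidate genes need
#' FDR < 0.05 and |log2FC| > 0.25 at the transcriptome or proteome (or
#' combined Fisher significance); the forwarded band is 2 residual-SDs wide;
#' translation-level calls use a TE p-value filter of 0.01 and a central 95%
#' residual band; merged differentially expressed genes (DEGs) need a >30%
#' change at FDR < 0.01 plus FDR < 0.5 in both datasets, with the
#' high-confidence tier at >40%; discretization thresholds the scaled median
#' at 0.2; cross-layer clustering uses k-means with 8 centers.
#'
#' Percent-change thresholds are converted to the log2 scale as
#' \code{log2(1 + pct)}; all comparisons are strict.
#'
#' @param candidate_fdr FDR cutoff for the candidate-selection routes.
#' @param candidate_abs_logfc |log2FC| cutoff for the candidate routes.
#' @param te_pvalue TE p-value filter for the residual-on-TE fit.
#' @param forward_band_sd half-width (in residual SDs) of the forwarded band.
#' @param translation_band_quantile central coverage of the translation band
#'   (in (0,1)); 0.95 gives a \code{qnorm(0.975)}-SD half-width.
#' @param merged_min_change minimum proportional change for the DEG filter
#'   (0.30 = 30%).
#' @param merged_fdr merged-analysis FDR cutoff for DEGs.
#' @param per_dataset_fdr both-dataset FDR replication cutoff.
#' @param highconf_min_change proportional change for the high-confidence tier.
#' @param discretize_median threshold on the scaled median for discretization.
#' @param kmeans_k number of k-means centers (>= 2).
#' @param seed integer seed from which all pipeline randomness flows.
#' @return a validated list of class \code{"trilayerConfig"}.
#' @examples
#' cfg <- pipelineConfig(seed = 7)
#' cfg$kmeans_k
#' @export
pipelineConfig <- function(candidate_fdr = 0.05,
                           candidate_abs_logfc = 0.25,
                           te_pvalue = 0.01,
                           forward_band_sd = 2.0,
                           translation_band_quantile = 0.95,
                           merged_min_change = 0.30,
                           merged_fdr = 0.01,
                           per_dataset_fdr = 0.5,
                           highconf_min_change = 0.40,
                           discretize_median = 0.2,
                           kmeans_k = 8L,
                           seed = 42L) {
  cfg <- list(candidate_fdr = candidate_fdr,
              candidate_abs_logfc = candidate_abs_logfc,
              te_pvalue = te_pvalue,
              forward_band_sd = forward_band_sd,
              translation_band_quantile = translation_band_quantile,
              merged_min_change = merged_min_change,
              merged_fdr = merged_fdr,
              per_dataset_fdr = per_dataset_fdr,
              highconf_min_change = highconf_min_change,
              discretize_median = discretize_median,
              kmeans_k = as.integer(kmeans_k),
              seed = as.integer(seed))
  .validate_config(cfg)
  class(cfg) <- "trilayerConfig"
  cfg
}

.validate_config <- function(cfg) {
  thresholds <- c("candidate_fdr", "candidate_abs_logfc", "te_pvalue",
                  "forward_band_sd", "merged_min_change", "merged_fdr",
                  "per_dataset_fdr", "highconf_min_change",
                  "discretize_median")
  for (nm in thresholds) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("config error: '%s' must be a single value > 0", nm),
           call. = FALSE)
  }
  q <- cfg$translation_band_quantile
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    stop("config error: 'translation_band_quantile' must be in (0,1)",
         call. = FALSE)
  if (is.na(cfg$kmeans_k) || cfg$kmeans_k < 2L)
    stop("config error: 'kmeans_k' must be >= 2", call. = FALSE)
  if (is.na(cfg$seed))
    stop("config error: 'seed' must be an integer", call. = FALSE)
  invisible(TRUE)
}

#' Read a pipeline configuration from a flat YAML file
#'
#' All keys are optional; absent keys fall back to the defaults of
#' [pipelineConfig()]. Unknown keys raise an error rather than being ignored.
#'
#' @param path path to a YAML file of flat key-value pairs.
#' @return a validated \code{"trilayerConfig"} list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("config error: unknown key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(pipelineConfig, raw)
}

#' @export
print.trilayerConfig <- function(x, ...) {
  cat("trilayer pipeline configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
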