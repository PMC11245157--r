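## Quiet logger during tests; individual tests re-enable as needed.
options(trilayer.loglevel = "ERROR")

## Build a differential-record data.frame with sensible defaults; pvalue
## defaults to the two-sided z tail of logfc/se and fdr to pvalue.
mkRecords <- function(gene, layer = "RNA", contrast = "WBS_VS_CTL",
                      dataset = "MERGED", logfc = 0, se = 0.1,
                      pvalue = NULL, fdr = NULL) {
  df <- data.frame(gene = gene, layer = layer, contrast = contrast,
                   dataset = dataset, logfc = logfc, se = se,
                   stringsAsFactors = FALSE)
  df$pvalue <- if (is.null(pvalue)) 2 * pnorm(-abs(df$logfc / df$se)) else pvalue
  df$fdr <- if (is.null(fdr)) df$pvalue else fdr
  df
}

mkTable <- function(...) MultiLayerTable(rbind(...))

## Small simulation shared by several tests (fast, deterministic).
smallSim <- function(seed = 42L, n_genes = 600L) {
  simulateMultiomics(simulationConfig(
    n_genes = n_genes, seed = seed,
    n_tfs = 2L, targets_per_tf = 20L))
}

## Independent brute-force BH step-up oracle (kept deliberately naive).
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    tail_idx <- o[i:n]
    rank_tail <- i:n
    adj[o[i]] <- min(1, min(p[tail_idx] * n / rank_tail))
  }
  adj
}
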