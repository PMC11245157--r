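test_that("same config and seed give bit-identical simulations", {
  a <- smallSim(seed = 11)
  b <- smallSim(seed = 11)
  expect_identical(records(a$tables$ISOGENIC), records(b$tables$ISOGENIC))
  expect_identical(records(a$tables$PATIENT), records(b$tables$PATIENT))
  expect_identical(a$truth, b$truth)
})

test_that("class counts follow the largest-remainder allocation exactly", {
  cfg <- simulationConfig(n_genes = 997, seed = 3, n_tfs = 2,
                          targets_per_tf = 20)
  sim <- simulateMultiomics(cfg)
  p <- cfg$class_proportions
  raw <- p * 997
  counts <- floor(raw)
  left <- 997 - sum(counts)
  frac <- raw - counts
  take <- order(frac, decreasing = TRUE)[seq_len(left)]
  counts[take] <- counts[take] + 1
  got <- table(factor(sim$truth$class, levels = names(p)))
  expect_equal(as.integer(got), as.integer(counts))
})

test_that("with b = 1 and vanishing protein noise, buffered protein logFCs vanish", {
  cfg <- simulationConfig(
    n_genes = 300, buffering_strength = 1,
    measurement_sd = c(RNA = 0.1, RPF = 0.1, PROTEIN = 1e-12),
    class_proportions = c(FORWARDED_OPPOSITE = 0, BUFFERED_WBS = 0.5,
                          BUFFERED_DUP = 0.5, BUFFERED_BOTH = 0,
                          TRANSLATION_OFFSET = 0, "NULL" = 0),
    n_top = 0, n_tfs = 0, seed = 5)
  sim <- simulateMultiomics(cfg)
  df <- records(sim$tables$ISOGENIC)
  buf_wbs <- sim$truth$gene[sim$truth$class == "BUFFERED_WBS"]
  prot <- df[df$layer == "PROTEIN" & df$contrast == "WBS_VS_CTL" &
               df$gene %in% buf_wbs, ]
  expect_lt(max(abs(prot$logfc)), 1e-9)
})

test_that("the generative identity protein = rna + te holds per class", {
  sim <- simulateMultiomics(simulationConfig(n_genes = 2000, seed = 8,
                                             n_tfs = 2, targets_per_tf = 30))
  df <- records(sim$tables$ISOGENIC)
  for (ct in c("WBS_VS_CTL", "DUP_VS_CTL")) {
    rna <- df[df$layer == "RNA" & df$contrast == ct, ]
    prot <- df[df$layer == "PROTEIN" & df$contrast == ct, ]
    te_true <- if (ct == "WBS_VS_CTL") sim$truth$true_te_wbs else
      sim$truth$true_te_dup
    diffs <- prot$logfc[match(sim$truth$gene, prot$gene)] -
      rna$logfc[match(sim$truth$gene, rna$gene)] - te_true
    ## diff of two noise draws: mean 0, sd sqrt(2)*0.1
    for (kl in unique(sim$truth$class)) {
      d <- diffs[sim$truth$class == kl]
      se <- sqrt(2) * 0.1 / sqrt(length(d))
      expect_lt(abs(mean(d)), 3 * se)
    }
  }
})

test_that("null-gene p-values are uniform", {
  cfg <- simulationConfig(
    n_genes = 5000,
    class_proportions = c(FORWARDED_OPPOSITE = 0, BUFFERED_WBS = 0,
                          BUFFERED_DUP = 0, BUFFERED_BOTH = 0,
                          TRANSLATION_OFFSET = 0, "NULL" = 1),
    n_top = 0, n_tfs = 0, seed = 17)
  sim <- simulateMultiomics(cfg)
  df <- records(sim$tables$ISOGENIC)
  p <- df$pvalue[df$layer == "RNA" & df$contrast == "WBS_VS_CTL"]
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.25)
})

test_that("truth tables round-trip and reject unknown classes", {
  sim <- smallSim(seed = 2, n_genes = 200)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTruthTable(sim$truth, path)
  back <- readTruthTable(path)
  expect_identical(back, sim$truth)
  expect_true(all(back$class %in% c("FORWARDED_OPPOSITE", "BUFFERED_WBS",
                                    "BUFFERED_DUP", "BUFFERED_BOTH",
                                    "TRANSLATION_OFFSET", "NULL")))
  raw <- readLines(path)
  raw[2] <- sub("\t[A-Z_]+\t", "\tNOT_A_CLASS\t", raw[2])
  writeLines(raw, path)
  expect_error(readTruthTable(path), "unknown class")
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulationConfig(class_proportions = c(
    FORWARDED_OPPOSITE = 0.6, BUFFERED_WBS = 0.1, BUFFERED_DUP = 0.1,
    BUFFERED_BOTH = 0.1, TRANSLATION_OFFSET = 0.1, "NULL" = 0.2)),
    "sum to 1")
  expect_error(simulationConfig(buffering_strength = 1.2), "\\[0,1\\]")
  expect_error(simulationConfig(effect_sd = 0), "effect_sd")
})
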