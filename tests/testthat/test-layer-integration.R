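test_that("the robust origin fit recovers exact lines and resists outliers", {
  x <- seq(0.1, 2, length.out = 20)
  f <- fitOriginRobust(x, 0.8 * x)
  expect_equal(f$slope, 0.8)
  expect_equal(f$residual_sd, 0)
  # gross outlier: oracle is the median of y/x ratios, which is 2
  xo <- c(x, 1); yo <- c(2 * x, 50)
  fo <- fitOriginRobust(xo, yo)
  expect_lt(abs(fo$slope - 2), 0.1)
  # antisymmetry
  fn <- fitOriginRobust(x, -(2 * x + rnorm(20, 0, 1e-3)))
  fp <- fitOriginRobust(x, -fn$slope * x)
  expect_equal(fp$slope, -fn$slope)
  expect_error(fitOriginRobust(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fitOriginRobust(rep(0, 5), 1:5), "degenerate")
})

test_that("the Huber origin fit agrees with an independent M-estimator", {
  skip_if_not_installed("MASS")
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(200)
    y <- 1.3 * x + rnorm(200, 0, 0.3)
    y[1:10] <- y[1:10] + 8  # contamination
    mine <- fitOriginRobust(x, y)$slope
    ref <- unname(coef(MASS::rlm(y ~ x + 0, psi = MASS::psi.huber,
                                 k = 1.345, maxit = 50)))
    expect_equal(mine, ref, tolerance = 0.02)
  }
})

## Small deterministic integration fixture: forwarded genes on the diagonal
## plus buffered genes whose protein change is absent.
.integration_fixture <- function() {
  set.seed(5)
  n_fwd <- 30
  fwd <- sprintf("fwd%02d", seq_len(n_fwd))
  rna_f <- seq(-1.5, 1.5, length.out = n_fwd)
  rna_f <- rna_f[abs(rna_f) > 0.3]
  fwd <- fwd[seq_along(rna_f)]
  buf <- c("bufA", "bufB", "bufC", "bufD")
  rna_b <- c(1.0, -1.2, 0.8, 1.4)
  # bufA/B/D are TE-compensated (RPF flat); bufC has no TE change at all
  rpf_b <- c(0, 0, 0.8, 0)
  # deterministic +-0.015 residuals: well inside the 2-SD band by design
  small_noise <- rep(c(-0.015, 0.015), length.out = length(rna_f))
  tab <- MultiLayerTable(rbind(
    mkRecords(gene = fwd, layer = "RNA", logfc = rna_f, se = 0.05),
    mkRecords(gene = fwd, layer = "RPF", logfc = rna_f, se = 0.05),
    mkRecords(gene = fwd, layer = "PROTEIN", logfc = rna_f + small_noise,
              se = 0.05),
    mkRecords(gene = buf, layer = "RNA", logfc = rna_b, se = 0.05),
    mkRecords(gene = buf, layer = "RPF", logfc = rpf_b, se = 0.05),
    mkRecords(gene = buf, layer = "PROTEIN",
              logfc = c(0.01, -0.02, 0.02, -0.01), se = 0.05)))
  cand <- data.frame(gene = c(fwd, buf), contrast = "WBS_VS_CTL",
                     stringsAsFactors = FALSE)
  list(tab = tab, cand = cand, fwd = fwd, buf = buf)
}

test_that("forwarded genes stay in the band; buffered genes leave it", {
  fx <- .integration_fixture()
  res <- classifyForwarded(fx$cand, fx$tab)
  cls <- res$classification
  expect_equal(res$fit$slope, 1, tolerance = 0.05)
  expect_true(all(cls$category[cls$gene %in% fx$fwd] == "FORWARDED"))
  expect_true(all(cls$category[cls$gene %in% fx$buf] == "UNCLASSIFIED"))
})

test_that("TE explains buffered residuals; unexplained residuals go to OTHER", {
  fx <- .integration_fixture()
  res <- classifyForwarded(fx$cand, fx$tab)
  te <- teInteraction(fx$tab)
  out <- classifyTranslation(res, te, pipelineConfig())$classification
  # bufA/B/D: protein ~ 0 and TE ~ -rna with tiny se => explained
  expect_equal(out$category[out$gene == "bufA"], "TRANSLATION_REGULATED")
  expect_equal(out$category[out$gene == "bufB"], "TRANSLATION_REGULATED")
  expect_equal(out$category[out$gene == "bufD"], "TRANSLATION_REGULATED")
  # bufC: protein ~ 0 but TE ~ 0 => nothing explains the residual
  expect_equal(out$category[out$gene == "bufC"], "OTHER_POSTTRANSCRIPTIONAL")
  expect_true(all(out$te_explained[out$category == "TRANSLATION_REGULATED"]))
})

test_that("every candidate receives exactly one category", {
  sim <- smallSim(seed = 23)
  merged <- mergeDatasets(sim$tables$ISOGENIC, sim$tables$PATIENT)
  comb <- combineLayerSignificance(merged)
  cand <- selectCandidateGenes(merged, comb)
  te <- teInteraction(merged)
  cls <- classifyTranslation(classifyForwarded(cand, merged), te)$classification
  expect_equal(nrow(cls), nrow(cand))
  expect_true(all(cls$category %in% c("FORWARDED", "TRANSLATION_REGULATED",
                                      "OTHER_POSTTRANSCRIPTIONAL",
                                      "UNCLASSIFIED")))
  expect_false(any(duplicated(paste(cls$gene, cls$contrast))))
})

test_that("classification labels are invariant under a common rescaling", {
  sim <- smallSim(seed = 29)
  merged <- mergeDatasets(sim$tables$ISOGENIC, sim$tables$PATIENT)
  comb <- combineLayerSignificance(merged)
  cand <- selectCandidateGenes(merged, comb)
  te <- teInteraction(merged)
  base <- classifyTranslation(classifyForwarded(cand, merged), te)$classification

  scaled_df <- records(merged)
  scaled_df$logfc <- 3 * scaled_df$logfc
  scaled_df$se <- 3 * scaled_df$se
  scaled <- MultiLayerTable(scaled_df)
  te_s <- teInteraction(scaled)
  # candidate |logfc| threshold is not scale-free, so reuse the same set
  scl <- classifyTranslation(classifyForwarded(cand, scaled), te_s)$classification
  key <- paste(base$gene, base$contrast)
  expect_identical(base$category,
                   scl$category[match(key, paste(scl$gene, scl$contrast))])
})

test_that("buffering coefficients hit their defining limits", {
  x <- seq(-1, 1, length.out = 10); x <- x[x != 0]
  tab <- MultiLayerTable(rbind(
    mkRecords(gene = paste0("flat", seq_along(x)), layer = "RNA", logfc = x),
    mkRecords(gene = paste0("flat", seq_along(x)), layer = "PROTEIN",
              logfc = 0)))
  bc <- bufferingCoefficient(paste0("flat", seq_along(x)), tab, "WBS_VS_CTL")
  expect_identical(bc$buffering_coefficient, 1)  # complete buffering

  tab2 <- MultiLayerTable(rbind(
    mkRecords(gene = paste0("fw", seq_along(x)), layer = "RNA", logfc = x),
    mkRecords(gene = paste0("fw", seq_along(x)), layer = "PROTEIN",
              logfc = x)))
  bc2 <- bufferingCoefficient(paste0("fw", seq_along(x)), tab2, "WBS_VS_CTL")
  expect_identical(bc2$buffering_coefficient, 0)  # full forwarding

  tab3 <- MultiLayerTable(rbind(
    mkRecords(gene = paste0("am", seq_along(x)), layer = "RNA", logfc = x),
    mkRecords(gene = paste0("am", seq_along(x)), layer = "PROTEIN",
              logfc = 1.5 * x)))
  bc3 <- bufferingCoefficient(paste0("am", seq_along(x)), tab3, "WBS_VS_CTL")
  expect_equal(bc3$buffering_coefficient, -0.5)  # amplification
})

test_that("buffering is condition-specific for single-condition buffered genes", {
  sim <- simulateMultiomics(simulationConfig(seed = 42))
  merged <- mergeDatasets(sim$tables$ISOGENIC, sim$tables$PATIENT)
  comb <- combineLayerSignificance(merged)
  cand <- selectCandidateGenes(merged, comb)
  te <- teInteraction(merged)
  cls <- classifyTranslation(classifyForwarded(cand, merged), te)$classification
  lab <- function(g, ct) {
    v <- cls$category[cls$gene == g & cls$contrast == ct]
    if (length(v)) v else "UNCLASSIFIED"
  }
  bw <- sim$truth$gene[sim$truth$class == "BUFFERED_WBS"]
  ok <- vapply(bw, function(g) {
    wbs <- lab(g, "WBS_VS_CTL"); dup <- lab(g, "DUP_VS_CTL")
    (wbs %in% c("TRANSLATION_REGULATED", "UNCLASSIFIED")) &&
      (dup %in% c("FORWARDED", "UNCLASSIFIED"))
  }, logical(1))
  expect_gte(mean(ok), 0.75)
})
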