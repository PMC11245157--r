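test_that("fisherCombine matches its boundary and closed-form cases", {
  r <- fisherCombine(c(1, 1, 1))
  expect_equal(r$chi2, 0)
  expect_equal(r$combined_p, 1)
  expect_equal(fisherCombine(0.03)$combined_p, 0.03)  # k = 1 identity
  q <- 0.05 * 0.05
  expect_equal(fisherCombine(c(0.05, 0.05))$combined_p, q * (1 - log(q)),
               tolerance = 1e-12)
  expect_equal(fisherCombine(c(0.05, 0.05))$combined_p, 0.0175,
               tolerance = 1e-2)
  expect_error(fisherCombine(numeric(0)), "no non-missing")
})

test_that("fisherCombine clamps zero p-values instead of failing", {
  r <- fisherCombine(c(0, 0.5))
  expect_true(is.finite(r$chi2))
  expect_gt(r$chi2, -2 * log(1e-299))
})

test_that("mergeDatasets performs inverse-variance weighting", {
  iso <- mkRecords(gene = c("g1", "g2"), dataset = "ISOGENIC",
                   logfc = c(1, 1), se = 0.2)
  pat <- mkRecords(gene = c("g1", "g2"), dataset = "PATIENT",
                   logfc = c(1, -1), se = 0.2)
  m <- records(mergeDatasets(MultiLayerTable(iso), MultiLayerTable(pat)))
  expect_equal(m$logfc[m$gene == "g1"], 1)            # identical inputs
  expect_equal(m$se, rep(0.2 / sqrt(2), 2))            # equal-weight case
  expect_equal(m$logfc[m$gene == "g2"], 0)             # symmetric cancel
})

test_that("mergeDatasets excludes genes present in one dataset only", {
  iso <- mkRecords(gene = c("g1", "g2"), dataset = "ISOGENIC")
  pat <- mkRecords(gene = "g1", dataset = "PATIENT")
  m <- mergeDatasets(MultiLayerTable(iso), MultiLayerTable(pat))
  expect_setequal(records(m)$gene, "g1")
  expect_true("g2" %in% attr(m, "skipped"))
  pat2 <- mkRecords(gene = "g9", dataset = "PATIENT")
  expect_error(mergeDatasets(MultiLayerTable(iso), MultiLayerTable(pat2)),
               "no shared")
})

test_that("merging with a near-infinite-variance dataset converges to the other", {
  iso <- mkRecords(gene = "g1", dataset = "ISOGENIC", logfc = 0.8, se = 0.1)
  pat <- mkRecords(gene = "g1", dataset = "PATIENT", logfc = -5, se = 1e6)
  m <- records(mergeDatasets(MultiLayerTable(iso), MultiLayerTable(pat)))
  expect_equal(m$logfc, 0.8, tolerance = 1e-6)
  expect_equal(m$se, 0.1, tolerance = 1e-6)
})

.deg_fixture <- function(logfc, merged_fdr, fdr_iso, fdr_pat) {
  merged <- MultiLayerTable(mkRecords(
    gene = "g1", dataset = "MERGED", logfc = logfc,
    pvalue = merged_fdr, fdr = merged_fdr))
  iso <- MultiLayerTable(mkRecords(gene = "g1", dataset = "ISOGENIC",
                                   pvalue = fdr_iso, fdr = fdr_iso))
  pat <- MultiLayerTable(mkRecords(gene = "g1", dataset = "PATIENT",
                                   pvalue = fdr_pat, fdr = fdr_pat))
  mergedDegFilter(merged, iso, pat)
}

test_that("the merged DEG filter applies the 30%/40% and FDR rules strictly", {
  # passes DEG (0.40 > log2 1.3) but not high confidence (0.40 < log2 1.4)
  r <- .deg_fixture(0.40, 0.005, 0.2, 0.3)
  expect_equal(r$tier, "DEG")
  # second dataset fails the FDR < 0.5 replication rule
  expect_equal(nrow(.deg_fixture(0.60, 0.005, 0.2, 0.6)), 0)
  # exactly at the log2(1.3) boundary: excluded (strict inequality)
  expect_equal(nrow(.deg_fixture(log2(1.3), 0.005, 0.2, 0.3)), 0)
  # high-confidence tier
  expect_equal(.deg_fixture(0.60, 0.005, 0.2, 0.3)$tier, "HIGH_CONFIDENCE")
})

test_that("the DEG filter is monotone in FDR and |logfc|", {
  set.seed(21)
  for (i in 1:20) {
    # start from a configuration guaranteed inside the DEG set ...
    lf <- runif(1, 0.40, 0.8); mf <- runif(1, 0.001, 0.009)
    f1 <- runif(1, 0.01, 0.45); f2 <- runif(1, 0.01, 0.45)
    expect_gt(nrow(.deg_fixture(lf, mf, f1, f2)), 0)
    # ... then improving every statistic must never remove the gene
    expect_gt(nrow(.deg_fixture(lf + 0.2, mf / 2, f1 / 2, f2 / 2)), 0)
  }
})

test_that("candidate selection fires on any of its three routes", {
  mk <- function(rna_lf, rna_fdr, prot_lf, prot_fdr) {
    MultiLayerTable(rbind(
      mkRecords(gene = "g1", layer = "RNA", logfc = rna_lf,
                pvalue = rna_fdr, fdr = rna_fdr),
      mkRecords(gene = "g1", layer = "RPF", logfc = 0,
                pvalue = 0.9, fdr = 0.9),
      mkRecords(gene = "g1", layer = "PROTEIN", logfc = prot_lf,
                pvalue = prot_fdr, fdr = prot_fdr)))
  }
  comb <- function(fdr) data.frame(gene = "g1", contrast = "WBS_VS_CTL",
                                   chi2 = 1, df = 6, combined_p = fdr,
                                   combined_fdr = fdr)
  # RNA route
  r <- selectCandidateGenes(mk(0.5, 0.01, 0, 0.9), comb(0.8))
  expect_equal(r$gene, "g1")
  expect_match(r$route, "RNA")
  # nothing fires
  expect_equal(nrow(selectCandidateGenes(mk(0.5, 0.2, 0.1, 0.9), comb(0.8))), 0)
  # aggregation route alone
  r <- selectCandidateGenes(mk(0.1, 0.2, 0.1, 0.2), comb(0.01))
  expect_equal(r$route, "COMBINED")
})

test_that("the TE interaction contrast matches its normal-theory oracle", {
  tab <- MultiLayerTable(rbind(
    mkRecords(gene = c("null", "down"), layer = "RNA",
              logfc = c(0.5, 0.5), se = 0.1),
    mkRecords(gene = c("null", "down"), layer = "RPF",
              logfc = c(0.5, 0.1), se = 0.1)))
  te <- teInteraction(tab)
  null_row <- te[te$gene == "null", ]
  expect_equal(null_row$te_logfc, 0)
  expect_equal(null_row$te_pvalue, 1)
  down <- te[te$gene == "down", ]
  expect_equal(down$te_logfc, -0.4)
  expect_equal(down$te_z, -0.4 / sqrt(0.02))
  expect_equal(down$te_pvalue, 2 * pnorm(-0.4 / sqrt(0.02)), tolerance = 1e-12)
  expect_equal(down$te_pvalue, 0.0047, tolerance = 2e-2)
})

test_that("swapping RNA and RPF layers negates the TE log-fold change", {
  a <- MultiLayerTable(rbind(
    mkRecords(gene = "g1", layer = "RNA", logfc = -0.7),
    mkRecords(gene = "g1", layer = "RPF", logfc = 0.7)))
  b <- MultiLayerTable(rbind(
    mkRecords(gene = "g1", layer = "RNA", logfc = 0.7),
    mkRecords(gene = "g1", layer = "RPF", logfc = -0.7)))
  expect_equal(teInteraction(a)$te_logfc, 1.4)
  expect_equal(teInteraction(a)$te_logfc, -teInteraction(b)$te_logfc)
})

test_that("opposite-direction fraction counts signs and excludes zeros", {
  w <- c(g1 = 1, g2 = 1, g3 = 0)
  d <- c(g1 = -1, g2 = 1, g3 = -1)
  f <- oppositeDirectionFraction(c("g1", "g2"), w, d)
  expect_equal(as.numeric(f), 0.5)
  expect_equal(as.numeric(oppositeDirectionFraction("g1", w, d)), 1)
  f3 <- oppositeDirectionFraction(c("g1", "g2", "g3"), w, d)
  expect_equal(attr(f3, "n_zero"), 1)
  expect_equal(attr(f3, "n"), 2)
  expect_error(oppositeDirectionFraction(character(0), w, d), "empty")
})

test_that("the DEG opposite-direction fraction tracks the truth proportion", {
  sim <- simulateMultiomics(simulationConfig(seed = 42))
  merged <- mergeDatasets(sim$tables$ISOGENIC, sim$tables$PATIENT)
  deg <- mergedDegFilter(merged, sim$tables$ISOGENIC, sim$tables$PATIENT)
  df <- records(merged)
  rna_w <- df[df$layer == "RNA" & df$contrast == "WBS_VS_CTL", ]
  rna_d <- df[df$layer == "RNA" & df$contrast == "DUP_VS_CTL", ]
  obs <- oppositeDirectionFraction(
    deg$gene, setNames(rna_w$logfc, rna_w$gene),
    setNames(rna_d$logfc, rna_d$gene))
  tr <- sim$truth[match(deg$gene, sim$truth$gene), ]
  truth_frac <- mean(sign(tr$true_rna_wbs) == -sign(tr$true_rna_dup) &
                       sign(tr$true_rna_wbs) != 0)
  expect_equal(as.numeric(obs), truth_frac, tolerance = 0.05)
})
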