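#' Configuration for the synthetic multi-omics generator
#'
#' Defines the generative conditions under which the pipeline is
#' benchmarked. Each gene belongs to one ground-truth class:
#' \describe{
#'   \item{FORWARDED_OPPOSITE}{RNA effect of opposite sign in the two CNV
#'     conditions, propagated unchanged to RPF and protein (TE effect 0).}
#'   \item{BUFFERED_WBS / BUFFERED_DUP}{RNA effects as above, but in the
#'     affected condition a compensating TE effect of \code{-b * rna}
#'     attenuates the protein change.}
#'   \item{BUFFERED_BOTH}{TE compensation in both conditions.}
#'   \item{TRANSLATION_OFFSET}{no RNA effect; a pure TE effect shifts RPF
#'     and protein only.}
#'   \item{NULL}{no true effect on any layer.}
#' }
#' The generative identity is \code{protein = rna + te} on the log2 scale.
#'
#' @param n_genes number of genes.
#' @param class_proportions named fractions over the six classes, summing
#'   to 1 (within 1e-9). The default puts 85% of the non-null mass in
#'   FORWARDED_OPPOSITE, mirroring the predominantly symmetric-opposite
#'   dysregulation the analysis targets.
#' @param effect_sd SD of true RNA (and translation-offset TE) effects.
#' @param buffering_strength fraction b in [0,1] of the RNA log2FC cancelled
#'   by TE in buffered classes.
#' @param measurement_sd named per-layer observation noise SD; also reported
#'   as the record's standard error (known-variance z model, keeping
#'   p-values exactly calibrated).
#' @param patient_attenuation multiplier on true effects in the
#'   patient-derived dataset, mimicking its slightly weaker effect sizes.
#' @param n_top number of TOP-mRNA genes, drawn from BUFFERED_DUP with the
#'   RNA sign forced negative in the duplication condition.
#' @param n_tfs,targets_per_tf,tf_activity regulon structure: each TF shifts
#'   its targets' RNA effect by \code{mode * tf_activity} in WBS and by the
#'   opposite amount in DUP. Targets are drawn from FORWARDED_OPPOSITE genes.
#' @param tf_mode_pos_frac fraction of activating (+1) target modes.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return validated list of class \code{"trilayerSimConfig"}.
#' @seealso [simulateMultiomics()]
#' @export
simulationConfig <- function(n_genes = 2000L,
                             class_proportions = c(
                               FORWARDED_OPPOSITE = 0.51,
                               BUFFERED_WBS = 0.03,
                               BUFFERED_DUP = 0.03,
                               BUFFERED_BOTH = 0.02,
                               TRANSLATION_OFFSET = 0.01,
                               "NULL" = 0.40),
                             effect_sd = 0.5,
                             buffering_strength = 0.9,
                             measurement_sd = c(RNA = 0.1, RPF = 0.1,
                                                PROTEIN = 0.1),
                             patient_attenuation = 0.9,
                             n_top = 40L,
                             n_tfs = 3L,
                             targets_per_tf = 40L,
                             tf_activity = 0.25,
                             tf_mode_pos_frac = 0.8,
                             seed = 42L) {
  cfg <- list(n_genes = as.integer(n_genes),
              class_proportions = class_proportions,
              effect_sd = effect_sd,
              buffering_strength = buffering_strength,
              measurement_sd = measurement_sd,
              patient_attenuation = patient_attenuation,
              n_top = as.integer(n_top),
              n_tfs = as.integer(n_tfs),
              targets_per_tf = as.integer(targets_per_tf),
              tf_activity = tf_activity,
              tf_mode_pos_frac = tf_mode_pos_frac,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("config error: n_genes must be >= 1", call. = FALSE)
  p <- cfg$class_proportions
  if (is.null(names(p)) || !setequal(names(p), .TRUTH_CLASSES))
    stop(sprintf("config error: class_proportions must be named over: %s",
                 paste(.TRUTH_CLASSES, collapse = ", ")), call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("config error: class_proportions must sum to 1 (within 1e-9)",
         call. = FALSE)
  if (any(p < 0)) stop("config error: negative class proportion", call. = FALSE)
  b <- cfg$buffering_strength
  if (!is.numeric(b) || b < 0 || b > 1)
    stop("config error: buffering_strength must be in [0,1]", call. = FALSE)
  if (cfg$effect_sd <= 0) stop("config error: effect_sd must be > 0", call. = FALSE)
  sds <- cfg$measurement_sd
  if (is.null(names(sds)) || !setequal(names(sds), .LAYERS) || any(sds <= 0))
    stop("config error: measurement_sd must be positive and named RNA/RPF/PROTEIN",
         call. = FALSE)
  if (cfg$patient_attenuation <= 0)
    stop("config error: patient_attenuation must be > 0", call. = FALSE)
  class(cfg) <- "trilayerSimConfig"
  cfg
}

## Largest-remainder allocation of n among proportions p (named).
.largest_remainder <- function(p, n) {
  raw <- p * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- raw - counts
    take <- order(frac, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1L
  }
  stats::setNames(as.integer(counts), names(p))
}

#' Simulate three-layer differential tables with known ground truth
#'
#' Generates, for each of two datasets (isogenic and patient-derived, sharing
#' the same gene-level truth but with independent measurement noise and an
#' attenuation factor on the patient effects), differential statistics for
#' the RNA, RPF and protein layers in the hemideletion (WBS) and
#' hemiduplication (DUP) contrasts. For every gene, contrast and dataset the
#' observed log2FCs are
#' \deqn{RNA = t_{rna} + \epsilon,\quad RPF = t_{rna} + t_{te} + \epsilon,
#'   \quad PROTEIN = t_{rna} + t_{te} + \epsilon}
#' with independent Gaussian noise per layer; the reported standard error is
#' the known noise SD, p-values are two-sided normal tails of
#' \code{logfc/se}, and FDR is Benjamini-Hochberg within each
#' (layer, contrast, dataset) stratum. Class counts follow the
#' largest-remainder allocation of the configured proportions.
#'
#' @param config a \code{"trilayerSimConfig"} from [simulationConfig()].
#' @return list with elements \code{tables} (named list of
#'   \linkS4class{MultiLayerTable}: ISOGENIC, PATIENT), \code{truth}
#'   (ground-truth data.frame) and \code{regulons}
#'   (\linkS4class{RegulonSet}).
#' @examples
#' sim <- simulateMultiomics(simulationConfig(n_genes = 200, seed = 1))
#' table(sim$truth$class)
#' @export
simulateMultiomics <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "trilayerSimConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  counts <- .largest_remainder(config$class_proportions[.TRUTH_CLASSES], n)
  klass <- rep(names(counts), counts)
  gene <- sprintf("g%05d", seq_len(n))

  ## true RNA effects: symmetric-opposite across contrasts for all classes
  ## with a transcriptional component
  has_rna <- klass %in% c("FORWARDED_OPPOSITE", "BUFFERED_WBS",
                          "BUFFERED_DUP", "BUFFERED_BOTH")
  rna_wbs <- ifelse(has_rna, stats::rnorm(n, 0, config$effect_sd), 0)

  ## TOP genes: BUFFERED_DUP, transcriptionally down in DUP (up in WBS)
  is_top <- rep(FALSE, n)
  dup_idx <- which(klass == "BUFFERED_DUP")
  if (config$n_top > 0L) {
    if (length(dup_idx) < config$n_top)
      tlLog("WARN", "only %d BUFFERED_DUP genes available for %d TOP flags",
            length(dup_idx), config$n_top)
    top_idx <- dup_idx[seq_len(min(config$n_top, length(dup_idx)))]
    is_top[top_idx] <- TRUE
    rna_wbs[top_idx] <- abs(rna_wbs[top_idx])
  }

  ## regulons: targets among forwarded genes; antisymmetric activity shift
  regulon_of <- rep(NA_character_, n)
  regs <- list()
  fwd_idx <- which(klass == "FORWARDED_OPPOSITE")
  if (config$n_tfs > 0L && config$targets_per_tf > 0L) {
    need <- config$n_tfs * config$targets_per_tf
    if (length(fwd_idx) < need)
      stop(sprintf("config error: %d regulon targets requested but only %d forwarded genes",
                   need, length(fwd_idx)), call. = FALSE)
    pool <- sample(fwd_idx, need)
    for (t in seq_len(config$n_tfs)) {
      tf <- sprintf("TF%02d", t)
      tgt <- pool[((t - 1L) * config$targets_per_tf + 1L):(t * config$targets_per_tf)]
      mode <- ifelse(stats::runif(length(tgt)) < config$tf_mode_pos_frac, 1, -1)
      regulon_of[tgt] <- tf
      rna_wbs[tgt] <- rna_wbs[tgt] + mode * config$tf_activity
      regs[[tf]] <- data.frame(target = gene[tgt], mode = mode,
                               likelihood = 1.0, stringsAsFactors = FALSE)
    }
  }

  rna_dup <- -rna_wbs

  b <- config$buffering_strength
  te_wbs <- rep(0, n)
  te_dup <- rep(0, n)
  buf_w <- klass %in% c("BUFFERED_WBS", "BUFFERED_BOTH")
  buf_d <- klass %in% c("BUFFERED_DUP", "BUFFERED_BOTH")
  te_wbs[buf_w] <- -b * rna_wbs[buf_w]
  te_dup[buf_d] <- -b * rna_dup[buf_d]
  off <- klass == "TRANSLATION_OFFSET"
  te_wbs[off] <- stats::rnorm(sum(off), 0, config$effect_sd)
  te_dup[off] <- -te_wbs[off]

  truth <- data.frame(gene = gene, class = klass,
                      true_rna_wbs = rna_wbs, true_rna_dup = rna_dup,
                      true_te_wbs = te_wbs, true_te_dup = te_dup,
                      is_top = is_top, regulon_of = regulon_of,
                      stringsAsFactors = FALSE)

  sds <- config$measurement_sd
  atten <- c(ISOGENIC = 1, PATIENT = config$patient_attenuation)
  tables <- list()
  for (ds in names(atten)) {
    f <- atten[[ds]]
    rows <- list()
    for (ct in c("WBS_VS_CTL", "DUP_VS_CTL")) {
      t_rna <- if (ct == "WBS_VS_CTL") rna_wbs else rna_dup
      t_te <- if (ct == "WBS_VS_CTL") te_wbs else te_dup
      means <- list(RNA = f * t_rna,
                    RPF = f * (t_rna + t_te),
                    PROTEIN = f * (t_rna + t_te))
      for (ly in .LAYERS) {
        s <- sds[[ly]]
        obs <- means[[ly]] + stats::rnorm(n, 0, s)
        p <- 2 * stats::pnorm(-abs(obs / s))
        rows[[paste(ds, ct, ly)]] <- data.frame(
          gene = gene, layer = ly, contrast = ct, dataset = ds,
          logfc = obs, se = s, pvalue = p, fdr = bhAdjust(p),
          stringsAsFactors = FALSE)
      }
    }
    tables[[ds]] <- MultiLayerTable(do.call(rbind, rows))
  }

  list(tables = tables, truth = truth, regulons = RegulonSet(regs))
}
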