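#' Read regulons from a TSV file
#'
#' Expects columns \code{tf}, \code{target}, \code{mode} (-1 or +1) and
#' \code{likelihood} in (0, 1]; a missing likelihood column defaults to 1.
#' Regulons with fewer than \code{min_targets} targets are dropped with a
#' warning.
#'
#' @param path TSV file path.
#' @param min_targets minimum regulon size retained (default 5).
#' @return a \linkS4class{RegulonSet}.
#' @export
readRegulons <- function(path, min_targets = 5L) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("tf", "target", "mode")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("schema error: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!"likelihood" %in% names(df)) df$likelihood <- 1.0
  df$likelihood[is.na(df$likelihood)] <- 1.0
  bad <- which(!df$mode %in% c(-1, 1))
  if (length(bad))
    stop(sprintf("parse error: mode must be -1 or +1 at row(s) %s",
                 paste(utils::head(bad, 5L), collapse = ",")), call. = FALSE)
  bad <- which(df$likelihood <= 0 | df$likelihood > 1)
  if (length(bad))
    stop(sprintf("parse error: likelihood outside (0,1] at row(s) %s",
                 paste(utils::head(bad, 5L), collapse = ",")), call. = FALSE)
  dup <- duplicated(paste(df$tf, df$target))
  if (any(dup))
    stop(sprintf("duplicate target(s) for TF(s): %s",
                 paste(unique(df$tf[dup]), collapse = ", ")), call. = FALSE)
  regs <- lapply(split(df[, c("target", "mode", "likelihood")], df$tf),
                 function(d) { rownames(d) <- NULL; d })
  small <- names(regs)[vapply(regs, nrow, integer(1)) < min_targets]
  if (length(small)) {
    tlLog("WARN", "dropping %d undersized regulon(s): %s", length(small),
          paste(small, collapse = ", "))
    regs <- regs[setdiff(names(regs), small)]
  }
  RegulonSet(regs)
}

#' Write a RegulonSet to TSV
#' @param regulons a \linkS4class{RegulonSet}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeRegulons <- function(regulons, path) {
  stopifnot(methods::is(regulons, "RegulonSet"))
  rows <- lapply(names(regulons), function(tf) {
    cbind(data.frame(tf = tf, stringsAsFactors = FALSE),
          regulonTargets(regulons, tf))
  })
  .write_tsv(do.call(rbind, rows), path)
}

## rank-transform a signature to normal quantiles (average ties)
.rank_normal <- function(signature) {
  n <- length(signature)
  q <- stats::qnorm((rank(signature, ties.method = "average") - 0.5) / n)
  stats::setNames(q, names(signature))
}

#' Likelihood-weighted regulon enrichment score
#'
#' A simplified analytic normalized enrichment score (NES) for
#' transcription-factor activity: the signature (a signed per-gene
#' differential statistic) is rank-transformed to normal quantiles
#' \eqn{q_g}, and
#' \deqn{NES = \frac{\sum_i \ell_i m_i q_{t_i}}{\sqrt{\sum_i \ell_i^2}}}
#' over the regulon's targets \eqn{t_i} with modes \eqn{m_i} (+1
#' activation, -1 repression) and likelihood weights \eqn{\ell_i}. Under a
#' random signature the NES is approximately standard normal, giving a
#' two-sided normal p-value.
#'
#' @param regulon data.frame with columns \code{target}, \code{mode},
#'   \code{likelihood} (one regulon), or a \linkS4class{RegulonSet} plus
#'   \code{tf}.
#' @param signature named numeric vector: gene -> signed statistic (e.g.
#'   the RNA z statistic).
#' @param min_targets minimum targets that must be present in the
#'   signature (default 5); below this the score is skipped with a warning
#'   and NA is returned.
#' @param tf TF identifier when \code{regulon} is a RegulonSet.
#' @return list with \code{tf}, \code{nes}, \code{pvalue},
#'   \code{n_targets}.
#' @export
scoreRegulon <- function(regulon, signature, min_targets = 5L, tf = NULL) {
  if (methods::is(regulon, "RegulonSet")) {
    stopifnot(!is.null(tf))
    regulon <- regulonTargets(regulon, tf)
  }
  if (is.null(names(signature)))
    stop("scoreRegulon: signature must be a named vector", call. = FALSE)
  hit <- regulon$target %in% names(signature)
  if (sum(hit) < min_targets) {
    tlLog("WARN", "regulon %s: only %d target(s) in signature; score skipped",
          if (is.null(tf)) "?" else tf, sum(hit))
    return(list(tf = tf, nes = NA_real_, pvalue = NA_real_,
                n_targets = sum(hit)))
  }
  reg <- regulon[hit, , drop = FALSE]
  q <- .rank_normal(signature)
  nes <- sum(reg$likelihood * reg$mode * q[reg$target]) /
    sqrt(sum(reg$likelihood^2))
  list(tf = tf, nes = unname(nes), pvalue = 2 * stats::pnorm(-abs(nes)),
       n_targets = nrow(reg))
}

#' Score every regulon of a RegulonSet against a signature
#'
#' @param regulons a \linkS4class{RegulonSet}.
#' @param signature named numeric vector (gene -> signed statistic).
#' @param min_targets minimum targets present required per regulon.
#' @return data.frame with columns \code{tf}, \code{nes}, \code{pvalue},
#'   \code{n_targets}.
#' @export
scoreRegulons <- function(regulons, signature, min_targets = 5L) {
  stopifnot(methods::is(regulons, "RegulonSet"))
  rows <- lapply(names(regulons), function(tf)
    as.data.frame(scoreRegulon(regulonTargets(regulons, tf), signature,
                               min_targets = min_targets, tf = tf),
                  stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Permutation null for a regulon score
#'
#' Empirical calibration of the analytic NES null: gene labels of the
#' signature are permuted B times and the two-sided permutation p-value is
#' \eqn{(1 + \#\{|NES_{perm}| \ge |NES_{obs}|\}) / (B + 1)}.
#'
#' @param regulon one regulon data.frame (\code{target}, \code{mode},
#'   \code{likelihood}).
#' @param signature named numeric vector.
#' @param B number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with \code{nes}, \code{permutation_p}, \code{B}.
#' @export
permutationNull <- function(regulon, signature, B = 1000L, seed = 42L) {
  if (B < 100L)
    stop("permutationNull: B must be >= 100", call. = FALSE)
  obs <- scoreRegulon(regulon, signature)
  if (is.na(obs$nes))
    stop("permutationNull: observed score undefined", call. = FALSE)
  set.seed(seed)
  genes <- names(signature)
  exceed <- 0L
  for (i in seq_len(B)) {
    perm <- signature
    names(perm) <- sample(genes)
    nes_p <- scoreRegulon(regulon, perm)$nes
    if (abs(nes_p) >= abs(obs$nes)) exceed <- exceed + 1L
  }
  list(nes = obs$nes, permutation_p = (1 + exceed) / (B + 1), B = B)
}

#' Two-analysis consistency filter for regulon scores
#'
#' A TF is consistent when it is significant (p below \code{alpha}) in both
#' analyses (here: the isogenic and patient-derived datasets) with the same
#' NES sign. Symmetric in its two arguments.
#'
#' @param scores_a,scores_b data.frames from [scoreRegulons()] covering a
#'   shared TF set.
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns \code{tf}, \code{nes_a}, \code{p_a},
#'   \code{nes_b}, \code{p_b}, \code{consistent}.
#' @export
consistencyFilter <- function(scores_a, scores_b, alpha = 0.05) {
  shared <- intersect(scores_a$tf, scores_b$tf)
  if (!length(shared))
    stop("consistencyFilter: disjoint TF sets", call. = FALSE)
  a <- scores_a[match(shared, scores_a$tf), ]
  b <- scores_b[match(shared, scores_b$tf), ]
  consistent <- !is.na(a$nes) & !is.na(b$nes) &
    a$pvalue < alpha & b$pvalue < alpha & sign(a$nes) == sign(b$nes)
  data.frame(tf = shared, nes_a = a$nes, p_a = a$pvalue,
             nes_b = b$nes, p_b = b$pvalue, consistent = consistent,
             stringsAsFactors = FALSE, row.names = NULL)
}
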