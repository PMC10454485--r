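# Cis-window methQTL testing.
#
# Each CpG is tested against nearby SNPs with a one-way ANOVA of its beta
# values across genotype groups (AA / AB / BB). The cis window is +/- 18 kb
# (closed bounds) by default; per-CpG multiple testing across its window is
# Bonferroni-corrected.

#' SNPs within the cis window of a CpG
#'
#' Same chromosome and `|pos_snp - pos_cpg| <= half_width`, bounds
#' inclusive.
#'
#' @param cpg One-row probe annotation (`chromosome`, `position`).
#' @param snps A [genotype_table()].
#' @param half_width Window half-width in bp (default 18000).
#' @return Data frame of SNP info with a `distance` column (possibly empty).
#' @export
cis_window <- function(cpg, snps, half_width = 18000) {
  stopifnot(inherits(snps, "genotype_table"))
  info <- snps$info
  dist <- abs(info$position - cpg$position)
  keep <- info$chromosome == cpg$chromosome & dist <= half_width
  out <- info[keep, , drop = FALSE]
  out$distance <- dist[keep]
  rownames(out) <- NULL
  out
}

#' One-way methQTL ANOVA at one CpG
#'
#' Beta values are compared across genotype groups; groups with a single
#' sample are dropped (flagged) and at least two groups of two or more
#' samples are required. Zero within-group variance with unequal means
#' yields the smallest representable p, flagged.
#'
#' @param beta_i Per-sample beta values at one CpG.
#' @param dosage Per-sample genotype group (0/1/2 dosages; `NA` excluded).
#' @return One-row data frame: `F`, `df1`, `df2`, `p`, `n_groups`, flags.
#' @export
metqtl_anova <- function(beta_i, dosage) {
  keep <- !is.na(dosage) & !is.na(beta_i)
  b <- beta_i[keep]; g <- factor(dosage[keep])
  sizes <- table(g)
  dropped_singleton <- any(sizes < 2)
  use <- g %in% names(sizes)[sizes >= 2]
  b <- b[use]; g <- droplevels(g[use])
  k <- nlevels(g)
  if (k < 2) stop("need at least two genotype groups with >= 2 samples")
  n <- length(b)
  means <- tapply(b, g, mean)
  grand <- mean(b)
  ssb <- sum(table(g) * (means - grand)^2)
  ssw <- sum((b - means[g])^2)
  df1 <- k - 1; df2 <- n - k
  degenerate <- ssw == 0 && ssb > 0
  if (degenerate) {
    f <- Inf
    p <- .Machine$double.xmin
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  data.frame(F = f, df1 = df1, df2 = df2, p = p, n_groups = k,
             degenerate = degenerate, dropped_singleton = dropped_singleton)
}

#' Cis-window methQTL scan for a set of CpGs
#'
#' Tests every CpG against all SNPs in its cis window; within each CpG's
#' window, significance is Bonferroni-corrected (`alpha / m` for `m` window
#' SNPs) by default, or nominal with `correction = "none"`.
#'
#' @param beta Beta matrix.
#' @param annotation Probe annotation covering the CpGs.
#' @param genotypes A [genotype_table()].
#' @param cpg_ids CpGs to test (default: all rows of `beta`).
#' @param half_width Cis window half-width in bp (default 18000).
#' @param alpha Significance level (default 0.05).
#' @param correction `"bonferroni"` (within window) or `"none"`.
#' @return Data frame: one row per testable (CpG, SNP) pair with distance,
#'   F, p and significance flag.
#' @export
run_metqtl <- function(beta, annotation, genotypes,
                       cpg_ids = rownames(beta), half_width = 18000,
                       alpha = 0.05, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  out <- lapply(cpg_ids, function(cpg) {
    ann <- annotation[annotation$cpg_id == cpg, , drop = FALSE]
    if (nrow(ann) != 1) stop("annotation missing for ", cpg)
    win <- cis_window(ann, genotypes, half_width)
    if (!nrow(win)) return(NULL)
    cut <- if (correction == "bonferroni") alpha / nrow(win) else alpha
    rows <- lapply(seq_len(nrow(win)), function(j) {
      res <- tryCatch(
        metqtl_anova(beta[cpg, ], genotypes$dosages[win$snp_id[j], ]),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(cpg_id = cpg, snp_id = win$snp_id[j],
                 distance = win$distance[j], F = res$F, p = res$p,
                 significant = res$p < cut, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(cpg_id = character(), snp_id = character(),
                      distance = numeric(), F = numeric(), p = numeric(),
                      significant = logical())
  rownames(out) <- NULL
  out
}

#' Fraction of DMPs modulated by genotype
#'
#' A DMP counts as modulated when at least one tested SNP passes the
#' significance policy in the methQTL results.
#'
#' @param dmp_ids CpG ids of the (significant) DMP set.
#' @param metqtl_results Output of [run_metqtl()] (or any data frame with
#'   `cpg_id` and `significant`).
#' @return List with `count` (modulated DMPs), `total` and `fraction`.
#' @export
proportion_modulated <- function(dmp_ids, metqtl_results) {
  modulated <- unique(
    metqtl_results$cpg_id[metqtl_results$significant])
  count <- sum(dmp_ids %in% modulated)
  total <- length(dmp_ids)
  list(count = count, total = total,
       fraction = if (total > 0) count / total else 0)
}

#' Fisher-exact SNP association from a 2x2 allele-count table
#'
#' Two-sided exact p by hypergeometric enumeration; the odds ratio is the
#' sample cross-product ratio with the Haldane 0.5 correction when any cell
#' is zero.
#'
#' @param counts 2x2 matrix: rows = case/control, columns = allele counts.
#' @return List with `odds_ratio` and `p`.
#' @export
snp_association <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in the 2x2 table")
  p <- fisher.test(counts)$p.value
  x <- counts
  if (any(x == 0)) x <- x + 0.5
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  list(odds_ratio = or, p = p)
}
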