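# Whole-blood per-CpG EWAS.
#
# Each CpG is tested with a logistic regression of case/control status on its
# beta value plus covariates (age, sex, region, cell fractions with one type
# dropped to break the sum-to-one collinearity; optionally haplotype dosage
# and a polygenic score for the genotype-risk-corrected model). The Wald test
# on the beta coefficient gives the DMP p-value; the effect size is the plain
# case-minus-control mean beta difference.

# Build the shared covariate design matrix. One cell fraction (neutrophils by
# default, the largest) is dropped; single-level factors are omitted.
covariate_design <- function(meta, fractions = NULL, drop_fraction = "Neu",
                             include_batch = FALSE, extra = NULL) {
  df <- data.frame(age = as.numeric(meta$age))
  if (length(unique(meta$sex)) > 1) df$sex <- factor(meta$sex)
  if (length(unique(meta$region)) > 1) df$region <- factor(meta$region)
  if (include_batch && !is.null(meta$batch) &&
      length(unique(meta$batch)) > 1)
    df$batch <- factor(meta$batch)
  X <- model.matrix(~ ., df)
  if (!is.null(fractions)) {
    f <- as.matrix(fractions)
    keep <- setdiff(colnames(f), drop_fraction)
    X <- cbind(X, f[, keep, drop = FALSE])
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (is.null(colnames(extra)))
      colnames(extra) <- paste0("extra", seq_len(ncol(extra)))
    X <- cbind(X, extra)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[-qx$pivot[seq_len(qx$rank)]]
    warning("dropping collinear covariates: ",
            paste(aliased, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  X
}

# Logistic fit with a Wald test on the last column of the design.
# Returns coefficient, SE, z, p and an estimability flag; never errors on
# separation or collinearity of the target column.
logistic_wald_last <- function(X, y) {
  out <- list(coefficient = NA_real_, se = NA_real_, z = NA_real_,
              p = NA_real_, estimable = FALSE)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  k <- ncol(X)
  rank <- fit$rank
  piv <- fit$qr$pivot[seq_len(rank)]
  if (!(k %in% piv)) return(out)            # target aliased
  R <- qr.R(fit$qr)[seq_len(rank), seq_len(rank), drop = FALSE]
  cov <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(cov)) return(out)
  se_piv <- sqrt(diag(cov))
  se <- se_piv[match(k, piv)]
  b <- fit$coefficients[k]
  if (!fit$converged || !is.finite(se) || se > 100) {
    out$coefficient <- unname(b)
    return(out)                              # separation / unstable
  }
  z <- unname(b / se)
  list(coefficient = unname(b), se = unname(se), z = z,
       p = 2 * pnorm(-abs(z)), estimable = TRUE)
}

#' Fit the whole-blood DMP model at one CpG
#'
#' Logistic regression of phenotype on the CpG beta value, age, sex, region
#' and cell fractions (one type dropped); Wald test on the beta coefficient.
#'
#' @param beta_i Per-sample beta values at one CpG.
#' @param meta Sample metadata data frame (`phenotype`, `age`, `sex`,
#'   `region`).
#' @param fractions Optional sample x cell-type proportion matrix.
#' @param extra_covariates Optional additional covariate matrix (e.g.
#'   haplotype dosage and polygenic score).
#' @param drop_fraction Cell-fraction column dropped for identifiability.
#' @return One-row data frame: coefficient (log-odds per unit beta), se, p,
#'   delta_beta, estimable flag.
#' @export
fit_dmp <- function(beta_i, meta, fractions = NULL, extra_covariates = NULL,
                    drop_fraction = "Neu") {
  y <- as_case(meta$phenotype)
  if (!any(y) || all(y)) stop("need at least one case and one control")
  X <- covariate_design(meta, fractions, drop_fraction,
                        extra = extra_covariates)
  w <- logistic_wald_last(cbind(X, cpg = beta_i), as.numeric(y))
  db <- mean(beta_i[y]) - mean(beta_i[!y])
  data.frame(coefficient = w$coefficient, se = w$se, p = w$p,
             delta_beta = db, estimable = w$estimable)
}

#' Run the whole-blood EWAS over all CpGs
#'
#' One logistic DMP model per CpG (see [fit_dmp()]); a failing CpG is flagged
#' non-estimable and never aborts the scan.
#'
#' @param beta Beta matrix (CpG x sample).
#' @param meta Sample metadata.
#' @param fractions Sample x cell-type proportions used as covariates.
#' @param p_threshold Genome-wide significance threshold
#'   (default `9.8e-8`).
#' @param delta_beta_cut Large-effect threshold on |delta beta|
#'   (default `0.02`).
#' @param extra_covariates Optional additional covariates (see
#'   [run_grc_ewas()]).
#' @param drop_fraction Cell-fraction column dropped for identifiability.
#' @return Data frame of class `ewas_result`: one row per CpG with
#'   coefficient, se, p, delta_beta, significant and large_effect flags.
#' @export
run_ewas <- function(beta, meta, fractions = NULL,
                     p_threshold = 9.8e-8, delta_beta_cut = 0.02,
                     extra_covariates = NULL, drop_fraction = "Neu") {
  y <- as.numeric(as_case(meta$phenotype))
  if (!any(y == 1) || !any(y == 0))
    stop("need at least one case and one control")
  X <- covariate_design(meta, fractions, drop_fraction,
                        extra = extra_covariates)
  db <- delta_beta(beta, meta$phenotype)
  n <- nrow(beta)
  coefficient <- se <- p <- rep(NA_real_, n)
  estimable <- logical(n)
  Xi <- cbind(X, cpg = 0)
  k <- ncol(Xi)
  for (i in seq_len(n)) {
    Xi[, k] <- beta[i, ]
    w <- logistic_wald_last(Xi, y)
    coefficient[i] <- w$coefficient
    se[i] <- w$se
    p[i] <- w$p
    estimable[i] <- w$estimable
  }
  res <- data.frame(cpg_id = rownames(beta), coefficient = coefficient,
                    se = se, p = p, delta_beta = db,
                    significant = !is.na(p) & p < p_threshold,
                    large_effect = abs(db) > delta_beta_cut,
                    estimable = estimable,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "p_threshold") <- p_threshold
  attr(res, "delta_beta_cut") <- delta_beta_cut
  class(res) <- c("ewas_result", "data.frame")
  res
}

#' Run the genotype-risk-corrected EWAS
#'
#' Identical to [run_ewas()] with two additional covariates: the risk
#' haplotype tag-SNP dosage and the polygenic risk score. CpGs whose
#' whole-blood association is driven by genotype lose significance here.
#'
#' @inheritParams run_ewas
#' @param hla_dosage Per-sample risk-haplotype dosage (0/1/2).
#' @param prs_score Per-sample polygenic risk score.
#' @return An `ewas_result` data frame.
#' @export
run_grc_ewas <- function(beta, meta, fractions, hla_dosage, prs_score,
                         p_threshold = 9.8e-8, delta_beta_cut = 0.02,
                         drop_fraction = "Neu") {
  run_ewas(beta, meta, fractions, p_threshold, delta_beta_cut,
           extra_covariates = cbind(hla = hla_dosage, prs = prs_score),
           drop_fraction = drop_fraction)
}

#' @export
print.ewas_result <- function(x, ...) {
  cat("ewas_result:", nrow(x), "CpGs;",
      sum(x$significant), "significant at p <",
      format(attr(x, "p_threshold")), ";",
      sum(x$significant & x$large_effect),
      "also with |delta beta| >", attr(x, "delta_beta_cut"), "\n")
  invisible(x)
}

#' Per-covariate sensitivity scan
#'
#' Assesses a single covariate's marginal influence on methylation: numeric
#' covariates by simple linear regression (slope t-test), categorical ones by
#' one-way ANOVA; R-squared is reported either way.
#'
#' @param beta Beta matrix.
#' @param covariate Per-sample numeric vector or factor (>= 2 levels).
#' @return Data frame with per-CpG statistic, p and variance explained.
#' @export
sensitivity_scan <- function(beta, covariate) {
  n <- ncol(beta)
  if (is.numeric(covariate)) {
    if (var(covariate) == 0) stop("covariate has zero variance")
    r <- as.vector(cor(t(beta), covariate))
    r[is.na(r)] <- 0                         # zero-variance CpGs
    stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(stat), df = n - 2)
    r2 <- r^2
  } else {
    g <- droplevels(as.factor(covariate))
    k <- nlevels(g)
    if (k < 2) stop("categorical covariate needs at least two levels")
    G <- model.matrix(~ g - 1)
    ng <- colSums(G)
    gmeans <- (beta %*% G) / matrix(ng, nrow(beta), k, byrow = TRUE)
    grand <- rowMeans(beta)
    ssb <- rowSums(sweep(gmeans, 1, grand)^2 %*% diag(ng, k))
    sst <- rowSums((beta - grand)^2)
    ssw <- pmax(sst - ssb, 0)
    stat <- (ssb / (k - 1)) / (ssw / (n - k))
    p <- pf(stat, k - 1, n - k, lower.tail = FALSE)
    r2 <- ifelse(sst > 0, ssb / sst, NA_real_)
  }
  data.frame(cpg_id = rownames(beta), statistic = stat, p = p,
             variance_explained = r2, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Combine DMP p-values into differentially methylated regions
#'
#' Candidate regions are maximal runs of CpGs on one chromosome with
#' inter-CpG gaps of at most `max_gap` bp and at least `min_cpgs` members.
#' Each region is scored three ways: Fisher's combination
#' (chi-square `-2 * sum(log p)` on 2k df), Stouffer's Z from one-sided
#' normal transforms, and the harmonic mean of the members' BH-adjusted
#' p-values (adjustment over the full DMP set). A region is significant only
#' if all three are at or below `alpha`.
#'
#' @param dmps Data frame with `cpg_id` and `p` (e.g. an `ewas_result`).
#' @param annotation Probe annotation covering all CpGs (`cpg_id`,
#'   `chromosome`, `position`).
#' @param max_gap Maximum intra-region gap in bp (default 1000).
#' @param min_cpgs Minimum CpGs per region (default 3).
#' @param alpha Region significance level (default 0.05).
#' @return Data frame of regions (1-based closed coordinates) with the three
#'   combined statistics and a significance flag.
#' @export
combine_dmr <- function(dmps, annotation, max_gap = 1000, min_cpgs = 3,
                        alpha = 0.05) {
  idx <- match(dmps$cpg_id, annotation$cpg_id)
  if (anyNA(idx)) stop("annotation does not cover all CpGs")
  d <- data.frame(cpg_id = dmps$cpg_id, p = dmps$p,
                  chromosome = annotation$chromosome[idx],
                  position = annotation$position[idx],
                  stringsAsFactors = FALSE)
  d <- d[!is.na(d$p), , drop = FALSE]
  d$q <- p.adjust(d$p, method = "BH")
  d <- d[order(d$chromosome, d$position), , drop = FALSE]
  new_run <- c(TRUE, d$chromosome[-1] != d$chromosome[-nrow(d)] |
                 diff(d$position) > max_gap)
  d$run <- cumsum(new_run)
  out <- lapply(split(d, d$run), function(g) {
    k <- nrow(g)
    if (k < min_cpgs) return(NULL)
    p <- g$p
    zero_p <- any(p <= 0)
    p <- pmax(p, .Machine$double.xmin)
    x2 <- -2 * sum(log(p))
    fisher_p <- pchisq(x2, df = 2 * k, lower.tail = FALSE)
    z <- sum(qnorm(1 - p)) / sqrt(k)
    stouffer_p <- pnorm(z, lower.tail = FALSE)
    hm <- k / sum(1 / g$q)
    data.frame(chromosome = g$chromosome[1], start = min(g$position),
               end = max(g$position), n_cpgs = k,
               cpg_ids = paste(g$cpg_id, collapse = ","),
               fisher_chisq = x2, fisher_p = fisher_p,
               stouffer_z = z, stouffer_p = stouffer_p,
               harmonic_mean_fdr = hm,
               significant = fisher_p <= alpha & stouffer_p <= alpha &
                 hm <= alpha,
               zero_p_clipped = zero_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chromosome = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      cpg_ids = character(), fisher_chisq = numeric(),
                      fisher_p = numeric(), stouffer_z = numeric(),
                      stouffer_p = numeric(), harmonic_mean_fdr = numeric(),
                      significant = logical(), zero_p_clipped = logical())
  rownames(out) <- NULL
  out[order(out$chromosome, out$start), , drop = FALSE]
}

#' Write DMRs as a BED file
#'
#' Internal coordinates are 1-based closed; BED is written 0-based half-open.
#'
#' @param dmrs Output of [combine_dmr()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- data.frame(dmrs$chromosome, dmrs$start - 1L, dmrs$end,
                    paste0("DMR", seq_len(nrow(dmrs))))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Correlate gene expression with methylation
#'
#' Pearson correlation of one gene's expression against the beta values of
#' each CpG of interest, with a two-sided t-based p-value.
#'
#' @param expression Per-sample expression values for one gene.
#' @param beta_block Beta matrix (CpGs of interest x sample) or a single
#'   per-sample beta vector.
#' @return Data frame with per-CpG Pearson `r` and `p`.
#' @export
expr_meth_correlation <- function(expression, beta_block) {
  if (is.null(dim(beta_block)))
    beta_block <- matrix(beta_block, nrow = 1,
                         dimnames = list("cpg", names(beta_block)))
  n <- ncol(beta_block)
  if (n < 3) stop("need at least 3 paired samples")
  if (length(expression) != n)
    stop("expression and beta have different sample counts")
  if (var(expression) == 0) stop("expression has zero variance")
  res <- lapply(seq_len(nrow(beta_block)), function(i) {
    b <- beta_block[i, ]
    if (var(b) == 0)
      stop("zero variance in methylation at ", rownames(beta_block)[i])
    ct <- cor.test(expression, b, method = "pearson")
    data.frame(cpg_id = rownames(beta_block)[i], r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
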