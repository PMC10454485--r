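# Methylation and genetic risk scores, logistic combination, ROC/AUC.
#
# The genotype-risk-corrected methylation score is the weighted sum
# score_s = sum_i beta_si * delta_beta_i over the DMPs surviving the
# genotype-corrected EWAS, with the corrected-EWAS delta-beta values as
# weights. Genetic risk is summarised by the tag-SNP haplotype dosage and a
# polygenic score (weighted allele-dosage sum). Scores are compared as
# classifiers by AUC (Mann-Whitney pair statistic, ties counted 1/2) with a
# DeLong or bootstrap confidence interval.

#' Genotype-risk-corrected methylation score
#'
#' @param beta Beta matrix containing every weighted CpG.
#' @param weights Named per-CpG weight vector (the delta-beta values of the
#'   genotype-corrected EWAS DMPs).
#' @return Named per-sample score vector.
#' @export
grc_meth_score <- function(beta, weights) {
  if (is.null(names(weights))) stop("weights must be named by CpG id")
  if (any(!is.finite(weights))) stop("weights must be finite")
  missing_cpg <- setdiff(names(weights), rownames(beta))
  if (length(missing_cpg))
    stop("beta matrix lacks weighted CpGs: ",
         paste(head(missing_cpg, 5), collapse = ", "))
  b <- beta[names(weights), , drop = FALSE]
  if (anyNA(b)) stop("missing beta value at a weighted CpG")
  drop(crossprod(b, weights))[colnames(beta)]
}

#' Polygenic risk score
#'
#' Weighted sum of effect-allele dosages. Missing dosages are mean-imputed
#' per SNP (the mean of the observed dosages).
#'
#' @param genotypes A [genotype_table()].
#' @param effects Named per-SNP weight vector, or a data frame with `snp_id`
#'   and `weight` columns.
#' @return Named per-sample score vector.
#' @export
prs_score <- function(genotypes, effects) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (is.data.frame(effects))
    effects <- setNames(effects$weight, effects$snp_id)
  absent <- setdiff(names(effects), rownames(genotypes$dosages))
  if (length(absent))
    stop("SNPs absent from genotype table: ",
         paste(head(absent, 5), collapse = ", "))
  d <- genotypes$dosages[names(effects), , drop = FALSE]
  if (anyNA(d)) {
    for (i in seq_len(nrow(d))) {
      miss <- is.na(d[i, ])
      if (any(miss)) d[i, miss] <- mean(d[i, !miss])
    }
  }
  drop(crossprod(d, effects))
}

#' Risk-haplotype score from the tag SNP
#'
#' Identity extraction of the tag-SNP effect-allele dosage (0, 1 or 2).
#' Missing dosages stay `NA` (flagged, never coerced to 0).
#'
#' @param genotypes A [genotype_table()].
#' @param tag_snp Tag-SNP identifier.
#' @return Named per-sample dosage vector, `NA` where missing.
#' @export
hla_score <- function(genotypes, tag_snp) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (!tag_snp %in% rownames(genotypes$dosages))
    stop("tag SNP not present: ", tag_snp)
  genotypes$dosages[tag_snp, ]
}

#' Combine risk scores in a logistic model
#'
#' Logistic regression of phenotype on one or more per-sample scores;
#' fitted probabilities are returned for ROC analysis. Complete separation
#' is flagged rather than silently reported.
#'
#' @param predictors Per-sample score vector, matrix or data frame (one
#'   column per score).
#' @param phenotype Case/control labels.
#' @return List of class `score_model`: `fitted` probabilities,
#'   `coefficients`, `separation` flag.
#' @export
combine_scores <- function(predictors, phenotype) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("score", seq_len(ncol(X)))
  y <- as.numeric(as_case(phenotype))
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  qx <- qr(cbind(1, X))
  if (qx$rank < ncol(X) + 1) {
    keep <- qx$pivot[seq_len(qx$rank)]
    keep <- setdiff(keep, 1) - 1
    warning("dropping collinear predictors: ",
            paste(setdiff(colnames(X), colnames(X)[keep]), collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), y,
                                  family = binomial()))
  eps <- 1e-8
  separation <- !fit$converged ||
    all(abs(fit$fitted.values - y) < eps)
  structure(list(fitted = setNames(fit$fitted.values, rownames(X)),
                 coefficients = fit$coefficients,
                 separation = separation),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("score_model: logistic combination of",
      length(x$coefficients) - 1, "score(s)\n")
  print(x$coefficients)
  if (x$separation) cat("  WARNING: complete separation\n")
  invisible(x)
}

# AUC as the Mann-Whitney pair statistic (ties 1/2), via midranks.
auc_stat <- function(scores, case) {
  n1 <- sum(case); n0 <- sum(!case)
  r <- rank(scores)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC area under the curve with confidence interval
#'
#' AUC is the probability that a random case outranks a random control
#' (ties counted 1/2). The confidence interval is DeLong's (default) or a
#' seeded stratified bootstrap.
#'
#' @param scores Per-sample scores (higher = more case-like).
#' @param phenotype Case/control labels.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param conf Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Bootstrap seed.
#' @return Object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_cases`, `n_controls`, `ci_method`.
#' @export
roc_auc <- function(scores, phenotype, ci_method = c("delong", "bootstrap"),
                    conf = 0.95, n_boot = 2000, seed = 1) {
  ci_method <- match.arg(ci_method)
  case <- as_case(phenotype)
  if (!any(case) || all(case)) stop("both classes must be present")
  drop_na <- is.na(scores)
  if (any(drop_na)) {
    scores <- scores[!drop_na]
    case <- case[!drop_na]
  }
  auc <- auc_stat(scores, case)
  n1 <- sum(case); n0 <- sum(!case)
  z <- qnorm(1 - (1 - conf) / 2)
  if (ci_method == "delong") {
    x <- scores[case]; y0 <- scores[!case]
    # placements: per-case fraction of controls it beats (ties 1/2), and
    # the control-side mirror
    v10 <- vapply(x, function(s) mean((s > y0) + 0.5 * (s == y0)),
                  numeric(1))
    v01 <- vapply(y0, function(s) mean((x > s) + 0.5 * (x == s)),
                  numeric(1))
    se <- sqrt(var(v10) / n1 + var(v01) / n0)
    lo <- auc - z * se; hi <- auc + z * se
  } else {
    set.seed(seed)
    idx1 <- which(case); idx0 <- which(!case)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx1, n1, replace = TRUE),
             sample(idx0, n0, replace = TRUE))
      auc_stat(scores[i], case[i])
    }, numeric(1))
    qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  structure(list(auc = auc, ci_low = max(min(lo, auc), 0),
                 ci_high = min(max(hi, auc), 1),
                 n_cases = n1, n_controls = n0, ci_method = ci_method),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f; %d cases / %d controls; %s)\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls,
              x$ci_method))
  invisible(x)
}

#' ROC curve points
#'
#' @param scores Per-sample scores.
#' @param phenotype Case/control labels.
#' @return Data frame of (threshold, fpr, tpr), one row per distinct score.
#' @export
roc_points <- function(scores, phenotype) {
  case <- as_case(phenotype)
  thr <- sort(unique(scores), decreasing = TRUE)
  out <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[!case] >= t),
                      numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(scores[case] >= t),
                      numeric(1))))
  out
}

#' Correlate two risk scores
#'
#' Pearson correlation with a Fisher-z confidence interval and a t-based
#' two-sided p-value.
#'
#' @param score_a,score_b Aligned per-sample score vectors (>= 4 samples).
#' @param conf Confidence level (default 0.95).
#' @return List with `r`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
correlate_scores <- function(score_a, score_b, conf = 0.95) {
  if (length(score_a) != length(score_b)) stop("scores must be aligned")
  keep <- !is.na(score_a) & !is.na(score_b)
  a <- score_a[keep]; b <- score_b[keep]
  if (length(a) < 4) stop("need at least 4 samples")
  if (var(a) == 0 || var(b) == 0) stop("zero variance in a score")
  ct <- cor.test(a, b, method = "pearson", conf.level = conf)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], p = ct$p.value, n = length(a))
}
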