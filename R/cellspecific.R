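# Per-cell-type interaction models for cell-type-specific DMPs (csDMPs).
#
# For each cell type k the model is an ordinary least-squares fit of the
# CpG's M-value on the cell fraction, the fraction x phenotype interaction,
# and covariates (age + sex by default):
#
#     M_i ~ f_k + f_k:phenotype + covariates
#
# The interaction coefficient measures the case/control methylation
# difference attributed to that cell type, on the M scale per unit fraction;
# no phenotype main effect is included, so the term also carries the group
# contrast scaled by 1/fraction, which is what makes the +/-2 estimate cut
# discriminate the source cell type. One model per cell type per CpG.

csdmp_design <- function(cell_type, fractions, meta,
                         include_phenotype_main = FALSE,
                         include_region = FALSE) {
  if (!cell_type %in% colnames(fractions))
    stop("unknown cell type: ", cell_type)
  f <- fractions[, cell_type]
  if (var(f) == 0) stop("zero-variance fraction for ", cell_type)
  ph <- as.numeric(as_case(meta$phenotype))
  df <- data.frame(age = as.numeric(meta$age))
  if (length(unique(meta$sex)) > 1) df$sex <- factor(meta$sex)
  if (include_region && length(unique(meta$region)) > 1)
    df$region <- factor(meta$region)
  X <- cbind(model.matrix(~ ., df), frac = f, frac_pheno = f * ph)
  if (include_phenotype_main) X <- cbind(X, phenotype = ph)
  X
}

# OLS of (possibly many) responses on a shared design; t-test on the named
# column. Returns per-response estimate, se, t, p.
ols_wald_column <- function(X, Y, column) {
  qx <- qr(X)
  n <- nrow(X)
  if (qx$rank < ncol(X))
    return(list(estimate = rep(NA_real_, ncol(Y)),
                se = rep(NA_real_, ncol(Y)), p = rep(NA_real_, ncol(Y)),
                estimable = rep(FALSE, ncol(Y))))
  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  dfree <- n - ncol(X)
  sigma2 <- colSums(res^2) / dfree
  xtx_inv <- chol2inv(qr.R(qx))
  j <- match(column, colnames(X))
  se <- sqrt(xtx_inv[j, j] * sigma2)
  est <- coefs[j, ]
  tt <- est / se
  list(estimate = unname(est), se = unname(se),
       p = unname(2 * pt(-abs(tt), df = dfree)),
       estimable = rep(TRUE, ncol(Y)))
}

#' Fit the per-cell-type interaction model at one CpG
#'
#' @param m_i Per-sample M-values at one CpG.
#' @param cell_type Cell-type label (a column of `fractions`).
#' @param fractions Sample x cell-type proportion matrix.
#' @param meta Sample metadata (`phenotype`, `age`, `sex`).
#' @param include_phenotype_main Add a phenotype main effect (off by
#'   default, following the interaction-only formulation).
#' @param include_region Add region dummies.
#' @return One-row data frame: cell_type, interaction estimate (M-units per
#'   unit fraction), se, p, direction, estimable.
#' @export
fit_csdmp <- function(m_i, cell_type, fractions, meta,
                      include_phenotype_main = FALSE,
                      include_region = FALSE) {
  ph <- as_case(meta$phenotype)
  if (!any(ph) || all(ph)) stop("need at least one case and one control")
  X <- csdmp_design(cell_type, fractions, meta, include_phenotype_main,
                    include_region)
  w <- ols_wald_column(X, matrix(m_i, ncol = 1), "frac_pheno")
  data.frame(cell_type = cell_type, estimate = w$estimate, se = w$se,
             p = w$p,
             direction = ifelse(w$estimate > 0, "hyper", "hypo"),
             estimable = w$estimable, stringsAsFactors = FALSE)
}

#' Scan all CpGs and cell types for cell-type-specific DMPs
#'
#' Runs the per-cell-type interaction model for every (CpG, cell type) pair
#' and classifies with the default cut-offs (|estimate| > 2 and
#' p < 9.8e-8).
#'
#' @param m M-value matrix (CpG x sample); see [beta_to_m()].
#' @param fractions Sample x cell-type proportions.
#' @param meta Sample metadata.
#' @param cell_types Cell types to model (default: all fraction columns).
#' @param estimate_cut,p_cut Significance cut-offs (defaults 2 and 9.8e-8).
#' @inheritParams fit_csdmp
#' @return Data frame of class `csdmp_result`: one row per (CpG, cell type).
#' @export
run_csdmp <- function(m, fractions, meta, cell_types = colnames(fractions),
                      estimate_cut = 2, p_cut = 9.8e-8,
                      include_phenotype_main = FALSE,
                      include_region = FALSE) {
  Y <- t(m)
  res <- lapply(cell_types, function(ct) {
    X <- csdmp_design(ct, fractions, meta, include_phenotype_main,
                      include_region)
    w <- ols_wald_column(X, Y, "frac_pheno")
    data.frame(cpg_id = rownames(m), cell_type = ct, estimate = w$estimate,
               se = w$se, p = w$p, estimable = w$estimable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res <- classify_csdmp(res, estimate_cut, p_cut)
  class(res) <- c("csdmp_result", "data.frame")
  res
}

#' Classify csDMP results with the printed cut-offs
#'
#' A (CpG, cell type) pair is significant when the interaction estimate is
#' above `estimate_cut` or below `-estimate_cut` and its p-value is under
#' `p_cut`. Direction is hyper for positive estimates.
#'
#' @param results Data frame with `estimate` and `p` columns.
#' @param estimate_cut Magnitude cut on the interaction estimate (default 2).
#' @param p_cut P-value cut (default 9.8e-8).
#' @return The input with `direction` and `significant` columns set.
#' @export
classify_csdmp <- function(results, estimate_cut = 2, p_cut = 9.8e-8) {
  results$direction <- ifelse(results$estimate > 0, "hyper", "hypo")
  results$significant <- !is.na(results$p) &
    abs(results$estimate) > estimate_cut & results$p < p_cut
  attr(results, "estimate_cut") <- estimate_cut
  attr(results, "p_cut") <- p_cut
  results
}

#' @export
print.csdmp_result <- function(x, ...) {
  tab <- table(x$cell_type[x$significant])
  cat("csdmp_result:", length(unique(x$cpg_id)), "CpGs x",
      length(unique(x$cell_type)), "cell types;",
      sum(x$significant), "significant pairs\n")
  if (length(tab)) print(tab)
  invisible(x)
}

#' Summarise csDMP counts and cross-cell-type overlap
#'
#' Counts significant csDMPs (and their hyper/hypo breakdown) per cell type,
#' and for the chosen cell types reports the CpGs unique to each, shared by
#' all, and shared by all with the same direction in every one.
#'
#' @param results A `csdmp_result` (or compatible data frame with `cpg_id`,
#'   `cell_type`, `direction`, `significant`).
#' @param cell_types Cell types entering the overlap comparison (default:
#'   all present).
#' @return List with `counts` (per-cell-type data frame), `unique` (named
#'   list of CpGs unique to each chosen type), `shared` (CpGs significant in
#'   every chosen type) and `shared_same_direction`.
#' @export
summarize_csdmp <- function(results, cell_types = unique(results$cell_type)) {
  sig <- results[results$significant, , drop = FALSE]
  counts <- do.call(rbind, lapply(unique(results$cell_type), function(ct) {
    s <- sig[sig$cell_type == ct, , drop = FALSE]
    data.frame(cell_type = ct, n_significant = nrow(s),
               n_hyper = sum(s$direction == "hyper"),
               n_hypo = sum(s$direction == "hypo"),
               stringsAsFactors = FALSE)
  }))
  sets <- lapply(cell_types, function(ct)
    sig$cpg_id[sig$cell_type == ct])
  names(sets) <- cell_types
  shared <- Reduce(intersect, sets)
  uniq <- lapply(cell_types, function(ct) {
    others <- unlist(sets[setdiff(cell_types, ct)])
    setdiff(sets[[ct]], others)
  })
  names(uniq) <- cell_types
  same_dir <- Filter(function(cpg) {
    dirs <- sig$direction[sig$cpg_id == cpg & sig$cell_type %in% cell_types]
    length(unique(dirs)) == 1
  }, shared)
  list(counts = counts, unique = uniq, shared = shared,
       shared_same_direction = as.character(same_dir))
}
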