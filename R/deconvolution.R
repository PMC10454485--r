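# Reference-based immune-cell deconvolution.
#
# Fractions are estimated per sample by least squares of the sample's beta
# values at the signature CpGs onto the reference profiles with the
# sum-to-one equality imposed in the solve; negative coefficients are then
# truncated to zero and the result renormalised (the projection flavour of
# reference-based deconvolution). When no non-negativity constraint binds --
# the typical case with a well-separated reference -- this IS the fully
# constrained quadratic-programming solution; the QP with explicit
# non-negativity is kept as an oracle in the test suite.

#' Estimate immune-cell fractions from a beta matrix
#'
#' @param beta Beta matrix (CpG x sample); must contain every reference CpG.
#' @param reference Signature CpG x cell-type beta matrix.
#' @param intercept Include an intercept column in the fit (excluded from the
#'   returned fractions). Default `FALSE`: reference and sample betas share
#'   the same scale.
#' @return Sample x cell-type matrix of proportions; non-negative rows
#'   summing to 1.
#' @export
estimate_fractions <- function(beta, reference, intercept = FALSE) {
  reference <- as.matrix(reference)
  if (ncol(reference) < 2) stop("need at least two cell types")
  missing_cpg <- setdiff(rownames(reference), rownames(beta))
  if (length(missing_cpg))
    stop("beta matrix lacks reference CpGs: ",
         paste(head(missing_cpg, 5), collapse = ", "))
  y <- beta[rownames(reference), , drop = FALSE]
  x <- if (intercept) cbind(`(Intercept)` = 1, reference) else reference
  qx <- qr(x)
  if (qx$rank < ncol(x))
    stop("reference profiles are collinear (rank ", qx$rank, " < ",
         ncol(x), ")")
  coefs <- qr.coef(qx, y)                       # (types [+1]) x samples
  if (intercept) coefs <- coefs[-1, , drop = FALSE]
  # impose the sum-to-one equality on the least-squares solution:
  # f = f_u + (X'X)^-1 1 (1 - 1'f_u) / (1'(X'X)^-1 1), restricted to the
  # cell-type block when an intercept is present
  xtx_inv <- solve(crossprod(x))
  k <- ncol(reference)
  sel <- if (intercept) 1 + seq_len(k) else seq_len(k)
  a1 <- rowSums(xtx_inv[, sel, drop = FALSE])[sel]
  denom <- sum(xtx_inv[sel, sel])
  coefs <- coefs + outer(a1 / denom, 1 - colSums(coefs))
  coefs[coefs < 0] <- 0
  tot <- colSums(coefs)
  if (any(tot <= 0)) stop("degenerate fit: all coefficients non-positive")
  out <- t(coefs) / tot
  dimnames(out) <- list(colnames(beta), colnames(reference))
  out
}

#' Compare estimated cell fractions between cases and controls
#'
#' Two-sided two-sample test per cell type (Welch's t by default, Wilcoxon
#' rank-sum selectable).
#'
#' @param fractions Sample x cell-type proportion matrix.
#' @param phenotype Case/control labels (see [delta_beta()] for coding).
#' @param method `"welch"` or `"wilcoxon"`.
#' @return Data frame with per-cell-type case/control means, difference,
#'   p-value and a flag for degenerate (zero-variance) cell types.
#' @export
compare_fractions <- function(fractions, phenotype,
                              method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  ph <- as_case(phenotype)
  if (!any(ph) || all(ph)) stop("both phenotype groups must be non-empty")
  res <- lapply(colnames(fractions), function(ct) {
    a <- fractions[ph, ct]
    b <- fractions[!ph, ct]
    degenerate <- (var(a) + var(b)) == 0
    p <- if (degenerate) NA_real_
    else if (method == "welch") t.test(a, b)$p.value
    else wilcox.test(a, b, exact = FALSE)$p.value
    data.frame(cell_type = ct, mean_case = mean(a), mean_control = mean(b),
               difference = mean(a) - mean(b), p = p,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
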