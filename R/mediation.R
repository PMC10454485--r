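# Causal inference test (CIT) for genotype -> methylation -> trait
# mediation, and chi-square risk-haplotype selection.
#
# The CIT asks whether a genotype L, a methylation mediator G and a binary
# trait T are consistent with the causal chain L -> G -> T, against the
# alternatives of independent effects (L -> T with G passive) and reverse
# causation (L -> T -> G). Four component conditions are tested and the
# omnibus p-value is their maximum, so every condition must hold:
#   (1) L is associated with T;
#   (2) L is associated with G given T;
#   (3) G is associated with T given L;
#   (4) L is independent of T given G.
# Condition (4) is an equivalence test: its null hypothesis is *dependence*.
# The no-mediation null is simulated by reconstituting the mediator as
# fitted(G | L) plus permuted residuals -- preserving the L-G association
# while severing any G-T link -- and recomputing the conditional L-T score
# statistic; the p-value is the fraction of null statistics at or below the
# observed one. Under full mediation the observed conditional association is
# smaller than essentially every null draw and the p-value is small.

# Rao score chi-square for adding column z to a logistic model with design X0.
logistic_score_stat <- function(X0, y, z) {
  fit <- suppressWarnings(glm.fit(X0, y, family = binomial()))
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  u <- sum(z * (y - mu))
  xw <- crossprod(X0, w * X0)
  b <- crossprod(X0, w * z)
  v <- sum(z * w * z) - drop(crossprod(b, solve(xw, b)))
  if (v <= 0) return(NA_real_)
  u^2 / v
}

#' Causal inference test for mediation
#'
#' Tests whether methylation `G` mediates the effect of genotype `L` on a
#' binary trait `T` (see the module description above for the four component
#' conditions). Binary-trait components use logistic models; the mediator is
#' modelled linearly.
#'
#' @param L Per-sample genotype dosage (at least two distinct values).
#' @param G Per-sample mediator methylation (beta values).
#' @param T_trait Per-sample binary trait (0/1, logical, or two-level
#'   factor).
#' @param n_permutations Permutations for the equivalence component
#'   (default 500; fewer than 100 is recorded as a warning).
#' @param seed Seed for the permutation draws.
#' @return Object of class `cit_result`: the four component p-values, the
#'   omnibus p (their maximum), permutation count, seed and warnings.
#' @export
cit_test <- function(L, G, T_trait, n_permutations = 500, seed = 1) {
  y <- as.numeric(as_case(T_trait))
  if (length(L) != length(G) || length(G) != length(y))
    stop("L, G and T must be aligned")
  if (length(unique(L)) < 2) stop("L is constant")
  if (var(G) == 0) stop("G is constant")
  warnings <- character(0)
  if (n_permutations < 100)
    warnings <- c(warnings, "fewer than 100 permutations")
  if (length(y) < 30)
    warnings <- c(warnings, "fewer than 30 samples")

  # canonical sample order: makes the permutation component (and thus the
  # omnibus p) invariant to the input ordering of samples
  ord <- order(L, G, y)
  L <- L[ord]; G <- G[ord]; y <- y[ord]
  n <- length(y)

  p1 <- logistic_wald_last(cbind(1, L = L), y)$p
  p2 <- ols_wald_column(cbind(1, trait = y, L = L),
                        matrix(G, ncol = 1), "L")$p
  p3 <- logistic_wald_last(cbind(1, L = L, G = G), y)$p

  s_obs <- logistic_score_stat(cbind(1, G), y, L)
  g_fit <- cbind(1, L) %*% qr.coef(qr(cbind(1, L)), G)
  g_res <- G - g_fit
  set.seed(seed)
  s_null <- vapply(seq_len(n_permutations), function(b) {
    g_star <- g_fit + g_res[sample.int(n)]
    logistic_score_stat(cbind(1, g_star), y, L)
  }, numeric(1))
  p4 <- (1 + sum(s_null <= s_obs, na.rm = TRUE)) / (n_permutations + 1)

  structure(list(p_assoc_LT = p1, p_assoc_LG_given_T = p2,
                 p_assoc_GT_given_L = p3, p_indep_LT_given_G = p4,
                 omnibus_p = max(p1, p2, p3, p4),
                 n_permutations = n_permutations, seed = seed,
                 warnings = warnings),
            class = "cit_result")
}

#' @export
print.cit_result <- function(x, ...) {
  cat("Causal inference test\n")
  cat(sprintf("  T ~ L            p = %.4g\n", x$p_assoc_LT))
  cat(sprintf("  L ~ G | T        p = %.4g\n", x$p_assoc_LG_given_T))
  cat(sprintf("  T ~ G | L        p = %.4g\n", x$p_assoc_GT_given_L))
  cat(sprintf("  L indep T | G    p = %.4g  (%d permutations)\n",
              x$p_indep_LT_given_G, x$n_permutations))
  cat(sprintf("  omnibus          p = %.4g\n", x$omnibus_p))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Select the risk haplotype by chi-square association
#'
#' For each haplotype, a 2x2 chi-square of (this haplotype vs all others) x
#' (case vs control); the haplotype minimising the p-value is selected.
#' Tables with an expected cell below 5 use the continuity correction and
#' are flagged. Exact ties are broken lexicographically by id and flagged.
#'
#' @param haplotype_counts Data frame with columns `haplotype_id`, `n_case`,
#'   `n_control`.
#' @return List with `haplotype_id`, `chi_square`, `p`, `corrected`, `tie`
#'   and the per-haplotype table.
#' @export
select_risk_haplotype <- function(haplotype_counts) {
  hc <- haplotype_counts
  stopifnot(all(c("haplotype_id", "n_case", "n_control") %in% names(hc)))
  if (nrow(hc) < 2) stop("need at least two haplotypes")
  tot_case <- sum(hc$n_case); tot_ctrl <- sum(hc$n_control)
  if (tot_case <= 0 || tot_ctrl <= 0) stop("empty case or control margin")
  rows <- lapply(seq_len(nrow(hc)), function(i) {
    a <- hc$n_case[i]; b <- tot_case - a
    cc <- hc$n_control[i]; d <- tot_ctrl - cc
    n <- a + b + cc + d
    expected <- outer(c(a + cc, b + d), c(tot_case, tot_ctrl)) / n
    corrected <- any(expected < 5)
    num <- abs(a * d - b * cc)
    if (corrected) num <- max(num - n / 2, 0)
    denom <- as.numeric(a + b) * (cc + d) * (a + cc) * (b + d)
    chi <- if (denom == 0) 0 else n * num^2 / denom
    data.frame(haplotype_id = hc$haplotype_id[i], chi_square = chi,
               p = pchisq(chi, df = 1, lower.tail = FALSE),
               corrected = corrected, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  best_p <- min(tab$p)
  hits <- which(abs(tab$p - best_p) < 1e-12)
  tie <- length(hits) > 1
  pick <- hits[order(tab$haplotype_id[hits])][1]
  list(haplotype_id = tab$haplotype_id[pick],
       chi_square = tab$chi_square[pick], p = tab$p[pick],
       corrected = tab$corrected[pick], tie = tie, table = tab)
}
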