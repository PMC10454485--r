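test_that("the DMP model recovers the closed-form log odds ratio", {
  # binary pseudo-CpG: P(case | x=1) = 0.8, P(case | x=0) = 0.2
  x <- rep(c(1, 0), each = 10)
  ph <- c(rep("case", 8), rep("control", 2),
          rep("case", 2), rep("control", 8))
  meta <- make_meta(20, phenotype = ph)
  meta$age <- 40                       # constant -> dropped as collinear
  res <- suppressWarnings(fit_dmp(x, meta))
  expect_equal(res$coefficient, log(16), tolerance = 1e-6)
  expect_equal(res$delta_beta, 0.8 - 0.2)
})

test_that("constant methylation is flagged non-estimable, never p = 0", {
  meta <- make_meta(20)
  res <- fit_dmp(rep(0.5, 20), meta)
  expect_false(res$estimable)
  expect_true(is.na(res$p))
})

test_that("Wald machinery agrees with the glm formula interface", {
  set.seed(14)
  n <- 80
  meta <- make_meta(n, phenotype = sample(c("case", "control"), n, TRUE))
  b <- runif(n, 0.2, 0.8)
  f <- matrix(runif(n * 3, 0.1, 0.5), n, 3,
              dimnames = list(meta$sample_id, c("B", "NK", "Neu")))
  f <- f / rowSums(f)
  res <- fit_dmp(b, meta, fractions = f)
  oracle <- glm(I(phenotype == "case") ~ age + sex + b + f[, "B"] +
                  f[, "NK"], binomial(), data = meta)
  os <- coef(summary(oracle))["b", ]
  expect_equal(res$coefficient, unname(os["Estimate"]), tolerance = 1e-8)
  expect_equal(res$se, unname(os["Std. Error"]), tolerance = 1e-8)
  expect_equal(res$p, unname(os["Pr(>|z|)"]), tolerance = 1e-8)
})

test_that("label swap flips delta-beta and leaves p unchanged", {
  beta <- make_beta(25, 60, seed = 15)
  ph <- rep(c("case", "control"), 30)
  meta <- make_meta(60, phenotype = ph)
  e1 <- run_ewas(beta, meta)
  meta2 <- meta
  meta2$phenotype <- ifelse(ph == "case", "control", "case")
  e2 <- run_ewas(beta, meta2)
  expect_equal(e2$delta_beta, -e1$delta_beta, tolerance = 1e-10)
  expect_equal(e2$p, e1$p, tolerance = 1e-7)
})

test_that("null CpGs yield calibrated p-values and survive failures", {
  cfg <- sim_config(n_cases = 100, n_controls = 100, n_cpgs = 500,
                    fraction_means_case = c(B = 0.060, NK = 0.031,
                                            CD4T = 0.071, CD8T = 0.106,
                                            Mono = 0.090, Neu = 0.642),
                    n_signature_cpgs_per_type = 8, n_effect_cpgs = 0,
                    n_methqtl_cpgs = 0, n_direct_cpgs = 0, n_prs_snps = 0,
                    seed = 16)
  co <- generate_cohort(cfg)
  fr <- estimate_fractions(co$beta,
                           co$reference[unlist(co$truth$signature_cpgs), ])
  beta <- co$beta
  beta[3, ] <- 0.5                      # degenerate CpG must not abort
  e <- run_ewas(beta, co$meta, fr)
  expect_equal(nrow(e), 500)
  expect_false(e$estimable[3])
  frac05 <- mean(e$p < 0.05, na.rm = TRUE)
  expect_gt(frac05, 0.02)
  expect_lt(frac05, 0.09)
  expect_false(any(e$significant, na.rm = TRUE))
})

test_that("sensitivity scan matches lm/aov and the F = t^2 identity", {
  beta <- make_beta(10, 50, seed = 17)
  covar <- beta[4, ] * 3 + 1
  res <- sensitivity_scan(beta, covar)
  expect_equal(res$variance_explained[4], 1, tolerance = 1e-10)

  set.seed(18)
  z <- rnorm(50)
  res2 <- sensitivity_scan(beta, z)
  for (i in c(1, 5, 9)) {
    fit <- summary(lm(beta[i, ] ~ z))
    expect_equal(res2$statistic[i], unname(coef(fit)[2, "t value"]),
                 tolerance = 1e-8)
    expect_equal(res2$p[i], unname(coef(fit)[2, "Pr(>|t|)"]),
                 tolerance = 1e-8)
  }

  g2 <- rep(c("a", "b"), 25)
  res3 <- sensitivity_scan(beta, factor(g2))
  tt <- t.test(beta[2, g2 == "a"], beta[2, g2 == "b"], var.equal = TRUE)
  expect_equal(res3$statistic[2], unname(tt$statistic)^2, tolerance = 1e-8)
  g3 <- factor(rep(c("a", "b", "c"), length.out = 50))
  res4 <- sensitivity_scan(beta, g3)
  a <- anova(lm(beta[7, ] ~ g3))
  expect_equal(res4$statistic[7], a$`F value`[1], tolerance = 1e-8)

  expect_error(sensitivity_scan(beta, factor(rep("a", 50))), "two levels")
})

test_that("DMR combination reduces to closed forms", {
  ann <- data.frame(cpg_id = paste0("cg", 1:6),
                    chromosome = rep(c("chr1", "chr2"), each = 3),
                    position = c(100, 200, 300, 100, 200, 5000))
  # single-member region: all three statistics reduce to the member p
  d1 <- data.frame(cpg_id = "cg1", p = 0.01)
  r1 <- combine_dmr(d1, ann, max_gap = 1000, min_cpgs = 1)
  expect_equal(r1$fisher_p, 0.01, tolerance = 1e-12)
  expect_equal(r1$stouffer_p, 0.01, tolerance = 1e-12)
  expect_equal(r1$harmonic_mean_fdr, 0.01, tolerance = 1e-12)

  # two members at p = 0.05: hand-evaluated Fisher and Stouffer
  d2 <- data.frame(cpg_id = c("cg1", "cg2"), p = c(0.05, 0.05))
  r2 <- combine_dmr(d2, ann, max_gap = 1000, min_cpgs = 2)
  x2 <- -2 * (2 * log(0.05))
  expect_equal(r2$fisher_chisq, x2, tolerance = 1e-10)
  expect_equal(r2$fisher_p, exp(-x2 / 2) * (1 + x2 / 2), # chi2 df 4 tail
               tolerance = 1e-10)
  z <- 2 * qnorm(0.95) / sqrt(2)
  expect_equal(r2$stouffer_z, z, tolerance = 1e-10)
  expect_equal(r2$stouffer_p, pnorm(z, lower.tail = FALSE),
               tolerance = 1e-10)

  # all member p = 1: Fisher chi-square 0, not significant
  d3 <- data.frame(cpg_id = paste0("cg", 1:3), p = 1)
  r3 <- combine_dmr(d3, ann, min_cpgs = 3)
  expect_equal(r3$fisher_chisq, 0)
  expect_equal(r3$fisher_p, 1)
  expect_false(r3$significant)

  # regioning: the chr2 run breaks at the 4800 bp gap
  d4 <- data.frame(cpg_id = paste0("cg", 1:6), p = 0.001)
  r4 <- combine_dmr(d4, ann, max_gap = 1000, min_cpgs = 2)
  expect_equal(nrow(r4), 2)
  expect_equal(r4$n_cpgs, c(3, 2))

  # zero p is clipped, flagged
  d5 <- data.frame(cpg_id = paste0("cg", 1:3), p = c(0, 0.01, 0.01))
  r5 <- combine_dmr(d5, ann, min_cpgs = 3)
  expect_true(r5$zero_p_clipped)
  expect_true(is.finite(r5$fisher_chisq))
})

test_that("BED export converts to 0-based half-open coordinates", {
  dmr <- data.frame(chromosome = "chr1", start = 100L, end = 300L)
  p <- tempfile(fileext = ".bed")
  write_dmr_bed(dmr, p)
  bed <- read.delim(p, header = FALSE)
  expect_equal(bed$V2, 99)
  expect_equal(bed$V3, 300)
})

test_that("expression-methylation correlation matches the covariance oracle", {
  b <- c(0.2, 0.4, 0.5, 0.7, 0.9)
  expect_equal(expr_meth_correlation(-b, b)$r, -1, tolerance = 1e-12)

  bc <- b - mean(b)
  e_orth <- c(1, -1, 1, -1, 1)
  e_orth <- e_orth - mean(e_orth)
  e_orth <- e_orth - sum(e_orth * bc) / sum(bc^2) * bc
  expect_equal(expr_meth_correlation(e_orth, b)$r, 0, tolerance = 1e-12)

  set.seed(19)
  expr <- rnorm(5)
  r_oracle <- sum((expr - mean(expr)) * bc) /
    sqrt(sum((expr - mean(expr))^2) * sum(bc^2))
  expect_equal(expr_meth_correlation(expr, b)$r, r_oracle,
               tolerance = 1e-12)

  expect_error(expr_meth_correlation(rep(1, 5), b), "zero variance")
  expect_error(expr_meth_correlation(expr[1:2], b[1:2]), "at least 3")
})
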