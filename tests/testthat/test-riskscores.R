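test_that("grcMethScore is the weighted beta sum and is linear in weights", {
  beta <- beta_matrix(matrix(0.5, 1, 2, dimnames = list("cg1",
                                                        c("s1", "s2"))))
  expect_equal(unname(grc_meth_score(beta, c(cg1 = 0.02))), c(0.01, 0.01))

  b <- make_beta(50, 20, seed = 33)
  set.seed(34)
  w1 <- setNames(rnorm(50, 0, 0.02), rownames(b))
  w2 <- setNames(rnorm(50, 0, 0.02), rownames(b))
  s <- grc_meth_score(b, w1)
  oracle <- sapply(colnames(b), function(sm)
    sum(b[names(w1), sm] * w1))
  expect_equal(s, oracle, tolerance = 1e-12)
  expect_equal(grc_meth_score(b, w1 + w2),
               grc_meth_score(b, w1) + grc_meth_score(b, w2),
               tolerance = 1e-12)
  expect_equal(unname(grc_meth_score(b, w1 * 0)), rep(0, 20))

  expect_error(grc_meth_score(b, c(missing_cpg = 0.1)), "lacks")
  b_na <- b; b_na[1, 1] <- NA
  expect_error(grc_meth_score(b_na, w1), "missing beta")
})

test_that("PRS is the weighted dosage sum with per-SNP mean imputation", {
  info <- data.frame(snp_id = c("s1", "s2"), chromosome = "chr1",
                     position = c(100L, 200L))
  g <- genotype_table(info, rbind(s1 = c(1, 0), s2 = c(2, 2)))
  expect_equal(unname(prs_score(g, c(s1 = 0.1, s2 = -0.2))[1]), -0.3)

  gg <- make_genotypes(10, 15, seed = 35)
  set.seed(36)
  w <- setNames(rnorm(10, 0, 0.1), rownames(gg$dosages))
  oracle <- sapply(colnames(gg$dosages), function(sm)
    sum(gg$dosages[names(w), sm] * w))
  expect_equal(prs_score(gg, w), oracle, tolerance = 1e-12)
  expect_equal(unname(prs_score(gg, w * 0)),
               rep(0, ncol(gg$dosages)))

  gg$dosages["snp001", 1] <- NA
  imputed <- prs_score(gg, w)
  manual <- mean(gg$dosages["snp001", -1]) * w["snp001"] +
    sum(gg$dosages[names(w)[-1], 1] * w[-1])
  expect_equal(unname(imputed[1]), unname(manual), tolerance = 1e-12)

  expect_error(prs_score(gg, c(nope = 0.1)), "absent")
})

test_that("the HLA tag score is an identity extraction keeping NA", {
  g <- make_genotypes(3, 4, seed = 37)
  g$dosages["snp002", ] <- c(2, 0, 1, NA)
  s <- hla_score(g, "snp002")
  expect_equal(unname(s), c(2, 0, 1, NA))
  expect_error(hla_score(g, "rs_none"), "not present")
})

test_that("logistic score combination flags separation, matches glm", {
  ph <- rep(c("case", "control"), each = 6)
  perfect <- rep(c(1, 0), each = 6)
  expect_true(combine_scores(perfect, ph)$separation)

  set.seed(38)
  x <- cbind(a = rnorm(12), b = rnorm(12))
  m <- combine_scores(x, ph)
  oracle <- glm(I(ph == "case") ~ x[, "a"] + x[, "b"], binomial())
  expect_equal(unname(m$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)
  expect_false(m$separation)

  expect_warning(combine_scores(cbind(a = x[, 1], b = x[, 1]), ph),
                 "collinear")
})

test_that("a null predictor's CI covers zero at the nominal rate", {
  cover <- 0L
  for (s in 1:40) {
    set.seed(400 + s)
    ph <- rep(c("case", "control"), each = 50)
    x <- rnorm(100)
    fit <- glm(I(ph == "case") ~ x, binomial())
    est <- coef(summary(fit))["x", ]
    ci <- est["Estimate"] + c(-1.96, 1.96) * est["Std. Error"]
    m <- combine_scores(x, ph)
    expect_equal(unname(m$coefficients[2]), unname(est["Estimate"]),
                 tolerance = 1e-6)
    if (ci[1] <= 0 && 0 <= ci[2]) cover <- cover + 1L
  }
  expect_gte(cover, 33)  # ~95% nominal with binomial slack
})

test_that("AUC equals exhaustive pair counting with half-weight ties", {
  pair_auc <- function(s, case) {
    x <- s[case]; y <- s[!case]
    tot <- 0
    for (a in x) for (b in y)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(x) * length(y))
  }
  s <- c(0.9, 0.6, 0.8, 0.5)
  case <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_auc(s, case)
  expect_equal(r$auc, 3 / 4, tolerance = 1e-12)
  expect_equal(r$auc, pair_auc(s, case), tolerance = 1e-12)

  expect_equal(roc_auc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)

  set.seed(39)
  s2 <- sample(round(rnorm(40), 1))       # includes ties
  case2 <- rep(c(TRUE, FALSE), 20)
  expect_equal(roc_auc(s2, case2)$auc, pair_auc(s2, case2),
               tolerance = 1e-12)
  # invariance under strictly increasing transform; complement rule
  expect_equal(roc_auc(exp(s2), case2)$auc, roc_auc(s2, case2)$auc)
  expect_equal(roc_auc(-s2, case2)$auc, 1 - roc_auc(s2, case2)$auc,
               tolerance = 1e-12)

  expect_error(roc_auc(s2, rep(TRUE, 40)), "both classes")
})

test_that("DeLong intervals agree with pROC and bootstrap is seeded", {
  set.seed(40)
  case <- rep(c(TRUE, FALSE), each = 60)
  s <- rnorm(120) + case * 0.8
  r <- roc_auc(s, case, ci_method = "delong")
  pr <- pROC::ci.auc(pROC::roc(case, s, quiet = TRUE), method = "delong")
  expect_equal(r$auc, as.numeric(pr[2]), tolerance = 1e-10)
  expect_equal(r$ci_low, as.numeric(pr[1]), tolerance = 1e-6)
  expect_equal(r$ci_high, as.numeric(pr[3]), tolerance = 1e-6)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)

  b1 <- roc_auc(s, case, ci_method = "bootstrap", n_boot = 200, seed = 4)
  b2 <- roc_auc(s, case, ci_method = "bootstrap", n_boot = 200, seed = 4)
  expect_identical(b1$ci_low, b2$ci_low)
})

test_that("score correlation matches the covariance formula and Fisher z", {
  a <- c(1.2, 0.8, 1.5, 2.0, 0.3, 1.1)
  b <- c(0.9, 1.1, 1.4, 1.8, 0.5, 0.8)
  r <- correlate_scores(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r$r, r_oracle, tolerance = 1e-12)
  z <- atanh(r_oracle)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(6 - 3))
  expect_equal(c(r$ci_low, r$ci_high), ci, tolerance = 1e-9)

  expect_equal(correlate_scores(a, a)$r, 1)
  expect_error(correlate_scores(a, rep(1, 6)), "zero variance")
  expect_error(correlate_scores(a[1:3], b[1:3]), "at least 4")
})
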