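test_that("beta/M transform hits the logit2 anchor points and inverts", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  expect_equal(m_to_beta(0), 0.5)
  expect_equal(m_to_beta(2), 0.8)
  expect_equal(m_to_beta(beta_to_m(0.37)), 0.37, tolerance = 1e-12)

  # antisymmetry and round trip away from the clip bounds
  set.seed(1)
  b <- runif(500, 1e-3, 1 - 1e-3)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b), tolerance = 1e-10)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-10)
})

test_that("beta_to_m validates epsilon and names the offending cell", {
  expect_error(beta_to_m(0.5, epsilon = 0.6), "epsilon")
  bad <- matrix(c(0.1, NaN, 0.2, 0.3), 2,
                dimnames = list(c("cgA", "cgB"), c("s1", "s2")))
  expect_error(beta_to_m(bad), "cgB.*s1")
})

test_that("beta_matrix rejects out-of-range values and duplicate ids", {
  m <- matrix(runif(4), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_silent(beta_matrix(m))
  m2 <- m; m2[1, 1] <- 1.2
  expect_error(beta_matrix(m2), "\\[0, 1\\]")
  expect_error(beta_matrix(m, cpg_ids = c("a", "a")), "duplicated")
})

test_that("probe filtering removes exactly the implanted failures", {
  beta <- make_beta(20, 40)
  detp <- matrix(0, 20, 40, dimnames = dimnames(beta))
  implanted <- c("cg003", "cg011", "cg017")
  detp[implanted, 1:4] <- 0.5            # 10% of samples failing

  res <- filter_probes(beta, detp, p_cut = 0.01, max_fail_fraction = 0.05)
  # enumeration oracle: recompute failing fractions by direct loop
  expected_removed <- character(0)
  for (i in rownames(beta)) {
    frac <- sum(detp[i, ] > 0.01) / ncol(beta)
    if (frac > 0.05) expected_removed <- c(expected_removed, i)
  }
  expect_setequal(res$report$cpg_id, expected_removed)
  expect_setequal(res$report$cpg_id, implanted)
  expect_equal(nrow(res$beta), 17)

  # all detection p zero -> identity; filtering is idempotent
  id <- filter_probes(beta, matrix(0, 20, 40))
  expect_identical(id$beta, beta)
  twice <- filter_probes(res$beta, detp[rownames(res$beta), ],
                         p_cut = 0.01, max_fail_fraction = 0.05)
  expect_identical(twice$beta, res$beta)

  expect_error(filter_probes(beta, matrix(1, 20, 40)), "all probes")
})

test_that("sample filtering matches a direct-enumeration oracle", {
  beta <- make_beta(20, 10)
  expect_identical(filter_samples(beta)$beta, beta)   # no missingness

  beta[1:10, "S003"] <- NA                            # 50% missing
  beta[1, "S007"] <- NA                               # 5% missing
  res <- filter_samples(beta, max_fail_fraction = 0.1)
  oracle <- colnames(beta)[sapply(colnames(beta), function(s)
    mean(is.na(beta[, s])) > 0.1)]
  expect_setequal(res$report$sample_id, oracle)
  expect_identical(res$report$sample_id, "S003")
  expect_identical(filter_samples(res$beta, 0.1)$beta, res$beta)
})

test_that("genotype QC applies call-rate and HWE filters in order", {
  n <- 100
  info <- data.frame(snp_id = c("hw_ok", "hw_bad", "lowcall", "mono"),
                     chromosome = "chr1", position = 1:4 * 1000L)
  dos <- rbind(
    hw_ok = c(rep(0, 25), rep(1, 50), rep(2, 25)),     # exact HW
    hw_bad = c(rep(0, 50), rep(2, 50)),                # no hets
    lowcall = c(rep(NA, 3), rep(1, 97)),               # 97% call rate
    mono = rep(0, n))
  g <- genotype_table(info, dos)
  res <- genotype_qc(g, min_snp_call = 0.98, min_sample_call = 0.5,
                     hwe_alpha = 1e-6)
  kept <- res$genotypes$info$snp_id
  expect_true("hw_ok" %in% kept)
  expect_false("hw_bad" %in% kept)
  expect_false("lowcall" %in% kept)
  expect_true("mono" %in% kept)

  # hand-computed 1-df chi-square for the no-het SNP: 100
  hwe_row <- res$report[res$report$id == "hw_bad", ]
  expect_equal(hwe_row$value, pchisq(100, 1, lower.tail = FALSE))
  expect_equal(res$report$action[res$report$id == "lowcall"], "removed")
  expect_equal(res$report$action[res$report$id == "mono"],
               "retained_monomorphic")
})

test_that("HWE decisions match a brute-force chi-square on random SNPs", {
  g <- make_genotypes(50, 200, seed = 9, maf = 0.4)
  res <- genotype_qc(g, hwe_alpha = 0.05)
  kept <- res$genotypes$info$snp_id
  for (s in rownames(g$dosages)) {
    x <- g$dosages[s, ]
    cnt <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    p <- (2 * cnt[3] + cnt[2]) / (2 * sum(cnt))
    if (p == 0 || p == 1) next
    e <- sum(cnt) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi <- sum((cnt - e)^2 / e)
    expect_equal(s %in% kept, pchisq(chi, 1, lower.tail = FALSE) >= 0.05,
                 info = s)
  }
  # idempotence
  again <- genotype_qc(res$genotypes, hwe_alpha = 0.05)
  expect_identical(again$genotypes$dosages, res$genotypes$dosages)
})

test_that("delta_beta is the case-minus-control mean and antisymmetric", {
  beta <- beta_matrix(matrix(c(0.6, 0.8, 0.5, 0.7), 1,
                             dimnames = list("cg1", paste0("s", 1:4))))
  ph <- c("case", "case", "control", "control")
  expect_equal(unname(delta_beta(beta, ph)), 0.1)
  expect_equal(unname(delta_beta(beta, rev(ph))), -0.1)

  same <- beta_matrix(matrix(rep(c(0.4, 0.6), 2), 1,
                             dimnames = list("cg1", paste0("s", 1:4))))
  expect_equal(unname(delta_beta(same, c(1, 1, 0, 0))), 0)

  # random fixture against a loop-based oracle
  b <- make_beta(30, 24, seed = 4)
  ph <- rep(c(TRUE, FALSE), 12)
  db <- delta_beta(b, ph)
  for (i in sample(rownames(b), 10)) {
    expect_equal(unname(db[i]),
                 mean(b[i, ph]) - mean(b[i, !ph]), tolerance = 1e-12)
  }
  expect_equal(delta_beta(b, !ph), -db)
  expect_error(delta_beta(b, rep(TRUE, 24)), "non-empty")
})
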