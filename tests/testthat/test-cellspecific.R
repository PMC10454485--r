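frac_fixture <- function(n, seed = 1) {
  set.seed(seed)
  f <- matrix(rgamma(n * 6, shape = rep(c(12, 6, 14, 21, 18, 128), each = n)),
              n, 6, dimnames = list(sprintf("s%03d", seq_len(n)),
                                    c("B", "NK", "CD4T", "CD8T", "Mono",
                                      "Neu")))
  f / rowSums(f)
}

test_that("interaction coefficients equal the normal-equations oracle", {
  n <- 10
  meta <- make_meta(n, seed = 20)
  f <- frac_fixture(n, seed = 20)
  set.seed(21)
  m <- rnorm(n, 0, 1)
  res <- fit_csdmp(m, "B", f, meta)

  ph <- as.numeric(meta$phenotype == "case")
  X <- cbind(1, meta$age, as.numeric(meta$sex == "M"), f[, "B"],
             f[, "B"] * ph)
  bhat <- solve(crossprod(X), crossprod(X, m))
  expect_equal(res$estimate, bhat[5], tolerance = 1e-10)

  # and the full inference matches the lm formula interface
  fit <- summary(lm(m ~ meta$age + meta$sex + f[, "B"] + f[, "B"]:ph))
  row <- coef(fit)[nrow(coef(fit)), ]
  expect_equal(res$estimate, unname(row["Estimate"]), tolerance = 1e-10)
  expect_equal(res$se, unname(row["Std. Error"]), tolerance = 1e-10)
  expect_equal(res$p, unname(row["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("an implanted B-cell interaction is recovered and attributed", {
  n <- 600
  meta <- make_meta(n, seed = 22)
  f <- frac_fixture(n, seed = 22)
  ph <- as.numeric(meta$phenotype == "case")
  set.seed(23)
  m <- 5 + 3 * f[, "B"] * ph + rnorm(n, 0, 0.1)
  res_b <- fit_csdmp(m, "B", f, meta)
  expect_true(abs(res_b$estimate - 3) < 3 * res_b$se)
  # without a phenotype main effect the neutrophil model absorbs the group
  # shift scaled by 1/mean fraction -- far from 3 and below the +/-2 cut,
  # which is what keeps the attribution correct
  res_n <- fit_csdmp(m, "Neu", f, meta)
  expect_lt(abs(res_n$estimate), 1)
  expect_lt(abs(res_n$estimate), abs(res_b$estimate) / 3)
})

test_that("label swap negates the interaction estimate", {
  n <- 60
  meta <- make_meta(n, seed = 24)
  f <- frac_fixture(n, seed = 24)
  set.seed(25)
  m <- rnorm(n)
  a <- fit_csdmp(m, "Mono", f, meta)
  meta2 <- meta
  meta2$phenotype <- ifelse(meta$phenotype == "case", "control", "case")
  b <- fit_csdmp(m, "Mono", f, meta2)
  # with no main effect, the swapped model shifts the fraction slope;
  # the interaction changes sign exactly
  expect_equal(b$estimate, -a$estimate, tolerance = 1e-9)
})

test_that("phenotype-free methylation gives calibrated interaction tests", {
  n <- 200
  meta <- make_meta(n, seed = 26)
  f <- frac_fixture(n, seed = 26)
  set.seed(27)
  m <- matrix(rnorm(200 * n), 200, n,
              dimnames = list(sprintf("cg%03d", 1:200), meta$sample_id))
  cs <- run_csdmp(m, f, meta, cell_types = "CD4T")
  frac05 <- mean(cs$p < 0.05)
  expect_gt(frac05, 0.02)
  expect_lt(frac05, 0.09)
  expect_false(any(cs$significant))
})

test_that("with a phenotype main effect, attribution is clean across all types", {
  # the interaction-only formula scales the shared group contrast by
  # 1/mean-fraction, so low-abundance cell types can clear the magnitude
  # cut on signal they do not carry; the main-effect variant absorbs the
  # contrast and attributes purely on fraction-dependence
  hits <- other <- total <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_cases = 300, n_controls = 300, n_cpgs = 300,
                      n_signature_cpgs_per_type = 20, n_effect_cpgs = 20,
                      effect_cell_types = "B", effect_delta_beta = 0.15,
                      n_methqtl_cpgs = 0, n_mediator_cpgs = 0,
                      n_direct_cpgs = 0, noise_sd = 0.004, seed = 50 + s)
    co <- generate_cohort(cfg)
    fr <- estimate_fractions(
      co$beta, co$reference[unlist(co$truth$signature_cpgs), ])
    cs <- run_csdmp(beta_to_m(co$beta), fr, co$meta,
                    include_phenotype_main = TRUE)
    eff <- co$truth$effect$cpg_id
    hits <- hits + sum(cs$significant[cs$cell_type == "B" &
                                        cs$cpg_id %in% eff])
    other <- other + sum(cs$significant[cs$cell_type != "B" &
                                          cs$cpg_id %in% eff])
    total <- total + length(eff)
  }
  expect_gte(hits / total, 0.6)
  expect_lte(other / (5 * total), 0.01)
})

test_that("zero-variance fractions and rank deficiency are handled", {
  n <- 30
  meta <- make_meta(n, seed = 28)
  f <- frac_fixture(n, seed = 28)
  f[, "NK"] <- 0.05
  expect_error(fit_csdmp(rnorm(n), "NK", f, meta), "zero-variance")
  expect_error(fit_csdmp(rnorm(n), "Xcell", f, meta), "unknown cell type")
})

test_that("classification follows the printed estimate/p rule exactly", {
  fix <- data.frame(cpg_id = paste0("cg", 1:3), cell_type = "B",
                    estimate = c(2.5, -2.5, 1.5),
                    p = c(1e-9, 1e-9, 1e-12))
  out <- classify_csdmp(fix)
  expect_equal(out$significant, c(TRUE, TRUE, FALSE))
  expect_equal(out$direction, c("hyper", "hypo", "hyper"))
  # idempotent pure threshold function
  expect_equal(classify_csdmp(out)$significant, out$significant)
  # monotone in |estimate| and -log p
  expect_true(classify_csdmp(data.frame(estimate = 3, p = 1e-9))$significant)
  expect_false(classify_csdmp(data.frame(estimate = 3, p = 1e-3))$significant)
})

test_that("overlap summaries match brute-force set algebra", {
  fix <- data.frame(
    cpg_id = c("a", "b", "c", "b", "c", "d"),
    cell_type = rep(c("B", "Mono"), each = 3),
    estimate = c(3, 3, -3, 3, 3, 3),
    p = 1e-10, stringsAsFactors = FALSE)
  out <- summarize_csdmp(classify_csdmp(fix))
  expect_equal(sort(out$unique$B), "a")
  expect_equal(sort(out$unique$Mono), "d")
  expect_setequal(out$shared, c("b", "c"))
  expect_setequal(out$shared_same_direction, "b")   # c flips direction

  empty <- summarize_csdmp(classify_csdmp(
    data.frame(cpg_id = "a", cell_type = "B", estimate = 0.1, p = 0.5)))
  expect_equal(empty$counts$n_significant, 0)
  expect_equal(length(empty$shared), 0)

  # randomized fixture against an explicit set oracle
  set.seed(29)
  rnd <- expand.grid(cpg_id = paste0("cg", 1:40),
                     cell_type = c("B", "Mono", "CD4T"),
                     stringsAsFactors = FALSE)
  rnd$estimate <- sample(c(-3, 3, 0.5), nrow(rnd), replace = TRUE)
  rnd$p <- sample(c(1e-10, 0.5), nrow(rnd), replace = TRUE)
  cl <- classify_csdmp(rnd)
  sm <- summarize_csdmp(cl, cell_types = c("B", "Mono"))
  sets <- lapply(c("B", "Mono"), function(ct)
    cl$cpg_id[cl$significant & cl$cell_type == ct])
  expect_setequal(sm$shared, intersect(sets[[1]], sets[[2]]))
  expect_setequal(sm$unique$B, setdiff(sets[[1]], sets[[2]]))
  expect_setequal(sm$unique$Mono, setdiff(sets[[2]], sets[[1]]))
  expect_equal(sm$counts$n_significant[sm$counts$cell_type == "B"],
               length(sets[[1]]))
})
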