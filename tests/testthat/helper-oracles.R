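# Shared fixtures and independent oracles used across the suite.

# Exact solver for min ||y - X f||^2 subject to f >= 0, sum(f) = 1,
# by enumeration of active sets (global optimum of the convex QP is the
# feasible KKT point with minimal objective; with <= 6 cell types the 2^k
# subsets are cheap). Used as the constrained-deconvolution oracle.
qp_fractions_oracle <- function(y, X) {
  k <- ncol(X)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^k - 2)) {
    zero <- which(bitwAnd(mask, 2^(0:(k - 1))) > 0)
    free <- setdiff(seq_len(k), zero)
    Xf <- X[, free, drop = FALSE]
    A <- crossprod(Xf)
    b <- crossprod(Xf, y)
    kkt <- rbind(cbind(2 * A, 1), c(rep(1, length(free)), 0))
    sol <- tryCatch(solve(kkt, c(2 * b, 1)), error = function(e) NULL)
    if (is.null(sol)) next
    f <- sol[seq_along(free)]
    if (any(f < -1e-9)) next
    full <- numeric(k)
    full[free] <- pmax(f, 0)
    obj <- sum((y - X %*% full)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- full
    }
  }
  best
}

# Minimal metadata builder: balanced or custom phenotype, varying age,
# both sexes, one region (dropped from designs automatically).
make_meta <- function(n, phenotype = rep(c("case", "control"), length.out = n),
                      seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             phenotype = phenotype,
             age = round(runif(n, 20, 60)),
             sex = rep(c("F", "M"), length.out = n),
             region = "R1", stringsAsFactors = FALSE)
}

# Random beta matrix fixture.
make_beta <- function(n_cpg, n_sample, seed = 1) {
  set.seed(seed)
  beta_matrix(matrix(runif(n_cpg * n_sample, 0.05, 0.95), n_cpg,
                     dimnames = list(sprintf("cg%03d", seq_len(n_cpg)),
                                     sprintf("S%03d", seq_len(n_sample)))))
}

# Small genotype table fixture.
make_genotypes <- function(n_snp, n_sample, seed = 1, maf = 0.3) {
  set.seed(seed)
  info <- data.frame(snp_id = sprintf("snp%03d", seq_len(n_snp)),
                     chromosome = "chr1",
                     position = 1000L + seq_len(n_snp) * 1000L,
                     stringsAsFactors = FALSE)
  dos <- matrix(rbinom(n_snp * n_sample, 2, maf), n_snp,
                dimnames = list(info$snp_id,
                                sprintf("S%03d", seq_len(n_sample))))
  genotype_table(info, dos)
}
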