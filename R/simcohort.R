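# Synthetic-cohort generator.
#
# A cohort is built as a six-cell-type mixture: a cell-type reference beta
# matrix with signature CpGs, per-sample Dirichlet cell fractions with
# group-specific means, and implanted signals -- cell-specific case/control
# effects, cis-methQTLs, a tag-SNP risk haplotype acting through mediator
# CpGs, direct (genotype-independent) disease-associated CpGs, and a small
# polygenic background. Phenotype is drawn from a logistic model and sampled
# retrospectively to fixed case/control quotas. The ground truth of every
# implanted signal is returned for recovery testing.

SIM_CELL_TYPES <- c("B", "NK", "CD4T", "CD8T", "Mono", "Neu")

#' Simulation configuration
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults encode
#' a blood-like study: six immune cell types with case/control differences in
#' NK, CD8+ and CD4+ T-cell proportions, tight (concentration 200) Dirichlet
#' variability, a tag-SNP risk haplotype of 3x odds acting through mediator
#' CpG methylation, weak polygenic SNP effects, cis-methQTLs, and
#' cell-specific case effects in B cells and monocytes.
#'
#' @param n_cases,n_controls Group sizes (default 208 / 402).
#' @param n_cpgs Total CpGs simulated.
#' @param fraction_means_control,fraction_means_case Named per-cell-type mean
#'   proportions; each must sum to 1.
#' @param dirichlet_concentration Dirichlet concentration (sum of the
#'   parameter vector); larger is tighter.
#' @param n_signature_cpgs_per_type Signature CpGs per cell type for the
#'   deconvolution reference.
#' @param signature_margin Minimum beta separation between a cell type and all
#'   others at its signature CpGs.
#' @param n_effect_cpgs Number of cell-specific case-effect CpGs.
#' @param effect_cell_types Cell types receiving the implanted effects
#'   (cycled over CpGs).
#' @param effect_delta_beta Within-cell-type case/control beta difference at
#'   effect CpGs (alternating hyper/hypo).
#' @param effect_baseline Baseline beta of hypermethylation-effect CpGs
#'   (hypomethylation effects use `1 - effect_baseline`).
#' @param n_methqtl_cpgs Number of cis-methQTL CpGs (one SNP each).
#' @param methqtl_delta Beta shift per effect allele at methQTL CpGs.
#' @param n_mediator_cpgs Mediator CpGs carrying the haplotype's effect.
#' @param mediator_delta Beta shift per haplotype allele at mediator CpGs.
#' @param mediator_sd Per-sample biological SD of mediator methylation beyond
#'   genotype (the variation the trait responds to in chain mode).
#' @param mediator_baseline Baseline beta of mediator CpGs.
#' @param risk_haplotype_or Marginal odds ratio per haplotype allele
#'   (default 3).
#' @param risk_haplotype_freq Haplotype tag-SNP allele frequency.
#' @param n_direct_cpgs Genotype-independent disease-effect CpGs.
#' @param direct_gamma Log-odds of disease per unit beta at direct CpGs.
#' @param direct_sd Per-sample biological SD at direct CpGs.
#' @param n_prs_snps,n_null_snps Polygenic and null background SNP counts.
#' @param prs_effect_sd SD of polygenic log-odds weights (truncated at 0.2).
#' @param mediation_mode One of `"chain"` (haplotype -> methylation ->
#'   disease), `"independent"` (haplotype -> disease, methylation passive), or
#'   `"reverse"` (disease -> methylation).
#' @param noise_sd Beta-scale measurement noise SD.
#' @param noise_model `"gaussian"` (clipped) or `"beta"`.
#' @param prevalence Baseline disease probability of the generative logistic
#'   model (retrospective sampling makes quotas exact regardless).
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 208, n_controls = 402, n_cpgs = 2000,
                       fraction_means_control = c(B = 0.060, NK = 0.031,
                                                  CD4T = 0.071, CD8T = 0.106,
                                                  Mono = 0.090, Neu = 0.642),
                       fraction_means_case = c(B = 0.060, NK = 0.021,
                                               CD4T = 0.081, CD8T = 0.095,
                                               Mono = 0.090, Neu = 0.653),
                       dirichlet_concentration = 200,
                       n_signature_cpgs_per_type = 33,
                       signature_margin = 0.65,
                       n_effect_cpgs = 20,
                       effect_cell_types = c("B", "Mono"),
                       effect_delta_beta = 0.15,
                       effect_baseline = 0.10,
                       n_methqtl_cpgs = 20, methqtl_delta = 0.10,
                       n_mediator_cpgs = 1, mediator_delta = 0.20,
                       mediator_sd = 0.05, mediator_baseline = 0.30,
                       risk_haplotype_or = 3, risk_haplotype_freq = 0.15,
                       n_direct_cpgs = 10, direct_gamma = 10, direct_sd = 0.05,
                       n_prs_snps = 20, n_null_snps = 20, prs_effect_sd = 0.1,
                       mediation_mode = c("chain", "independent", "reverse"),
                       noise_sd = 0.02,
                       noise_model = c("gaussian", "beta"),
                       prevalence = 0.35, seed = 1) {
  cfg <- list(
    n_cases = n_cases, n_controls = n_controls, n_cpgs = n_cpgs,
    cell_types = SIM_CELL_TYPES,
    fraction_means_control = fraction_means_control[SIM_CELL_TYPES],
    fraction_means_case = fraction_means_case[SIM_CELL_TYPES],
    dirichlet_concentration = dirichlet_concentration,
    n_signature_cpgs_per_type = n_signature_cpgs_per_type,
    signature_margin = signature_margin,
    n_effect_cpgs = n_effect_cpgs,
    effect_cell_types = effect_cell_types,
    effect_delta_beta = effect_delta_beta,
    effect_baseline = effect_baseline,
    n_methqtl_cpgs = n_methqtl_cpgs, methqtl_delta = methqtl_delta,
    n_mediator_cpgs = n_mediator_cpgs, mediator_delta = mediator_delta,
    mediator_sd = mediator_sd, mediator_baseline = mediator_baseline,
    risk_haplotype_or = risk_haplotype_or,
    risk_haplotype_freq = risk_haplotype_freq,
    n_direct_cpgs = n_direct_cpgs, direct_gamma = direct_gamma,
    direct_sd = direct_sd,
    n_prs_snps = n_prs_snps, n_null_snps = n_null_snps,
    prs_effect_sd = prs_effect_sd,
    mediation_mode = match.arg(mediation_mode),
    noise_sd = noise_sd, noise_model = match.arg(noise_model),
    prevalence = prevalence, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (gm in list(cfg$fraction_means_control, cfg$fraction_means_case)) {
    if (any(is.na(gm)) || any(gm < 0))
      stop("fraction means must be non-negative and cover all six cell types")
    if (abs(sum(gm) - 1) > 1e-8)
      stop("fraction means must sum to 1 per group")
  }
  n_special <- 6 * cfg$n_signature_cpgs_per_type + cfg$n_mediator_cpgs +
    cfg$n_direct_cpgs + cfg$n_methqtl_cpgs + cfg$n_effect_cpgs
  if (n_special > cfg$n_cpgs)
    stop("n_cpgs too small for the requested signature and effect CpGs")
  if (cfg$signature_margin <= 0 || cfg$signature_margin > 0.8)
    stop("signature_margin must be in (0, 0.8]")
  if (cfg$effect_baseline + abs(cfg$effect_delta_beta) > 1 ||
      cfg$effect_baseline - 0 < 0)
    stop("infeasible effect delta-beta: beta would leave [0, 1]")
  if (cfg$mediator_baseline + 2 * cfg$mediator_delta > 1)
    stop("infeasible mediator delta: beta would leave [0, 1]")
  if (!all(cfg$effect_cell_types %in% SIM_CELL_TYPES))
    stop("unknown cell type in effect_cell_types")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cases, "cases /", x$n_controls, "controls,",
      x$n_cpgs, "CpGs, mode =", x$mediation_mode, ", seed =", x$seed, "\n")
  invisible(x)
}

# CpG role layout and genomic annotation; deterministic (no RNG).
sim_layout <- function(cfg) {
  ids <- sprintf("cg%06d", seq_len(cfg$n_cpgs))
  roles <- rep("background", cfg$n_cpgs)
  pos <- 1L
  take <- function(n) {
    idx <- seq.int(pos, length.out = n)
    pos <<- pos + n
    idx
  }
  signature <- lapply(seq_along(SIM_CELL_TYPES), function(k)
    take(cfg$n_signature_cpgs_per_type))
  names(signature) <- SIM_CELL_TYPES
  roles[unlist(signature)] <- "signature"
  mediator <- take(cfg$n_mediator_cpgs); roles[mediator] <- "mediator"
  direct <- take(cfg$n_direct_cpgs); roles[direct] <- "direct"
  methqtl <- take(cfg$n_methqtl_cpgs); roles[methqtl] <- "methqtl"
  effect <- take(cfg$n_effect_cpgs); roles[effect] <- "effect"

  # CpGs are laid out in blocks of 5 probes 400 bp apart (blocks 20 kb apart)
  # across 22 autosomes; mediator CpGs are relocated to chromosome 6 next to
  # the haplotype tag SNP.
  chrom_of <- rep(paste0("chr", 1:22),
                  length.out = ceiling(cfg$n_cpgs / 50))[
                    ceiling(seq_len(cfg$n_cpgs) / 50)]
  within <- (seq_len(cfg$n_cpgs) - 1) %% 50
  position <- 100000L + (within %/% 5) * 20000L + (within %% 5) * 400L
  ann <- data.frame(cpg_id = ids, chromosome = chrom_of, position = position,
                    gene = paste0("GENE", ceiling(seq_len(cfg$n_cpgs) / 5)),
                    stringsAsFactors = FALSE)
  if (length(mediator)) {
    ann$chromosome[mediator] <- "chr6"
    ann$position[mediator] <- 32500000L + seq_along(mediator) * 400L
    ann$gene[mediator] <- "HLA_LIKE"
  }
  list(ids = ids, roles = roles, signature = signature, mediator = mediator,
       direct = direct, methqtl = methqtl, effect = effect, annotation = ann)
}

# Reference construction (consumes RNG; callers handle seeding).
build_reference <- function(cfg, layout) {
  baseline <- runif(cfg$n_cpgs, 0.1, 0.9)
  low <- 0.15
  high <- min(low + cfg$signature_margin + 0.0, 0.95)
  if (high - low < cfg$signature_margin)
    stop("signature margin infeasible")
  ref <- matrix(rep(baseline, 6), ncol = 6,
                dimnames = list(layout$ids, SIM_CELL_TYPES))
  for (k in seq_along(SIM_CELL_TYPES)) {
    idx <- layout$signature[[k]]
    ref[idx, ] <- low
    ref[idx, k] <- high
  }
  if (length(layout$mediator)) ref[layout$mediator, ] <- cfg$mediator_baseline
  if (length(layout$direct))
    ref[layout$direct, ] <- runif(length(layout$direct), 0.3, 0.7)
  if (length(layout$methqtl))
    ref[layout$methqtl, ] <- runif(length(layout$methqtl), 0.2, 0.6)
  if (length(layout$effect)) {
    sign_v <- rep(c(1, -1), length.out = length(layout$effect))
    base_v <- ifelse(sign_v > 0, cfg$effect_baseline, 1 - cfg$effect_baseline)
    ref[layout$effect, ] <- base_v
  }
  ref
}

#' Generate the cell-type reference beta matrix
#'
#' For each cell type, its signature CpGs are separated from all other types
#' by at least `signature_margin` on the beta scale; non-signature CpGs share
#' a common baseline drawn once. Deterministic under the configured seed.
#'
#' @param config A [sim_config()].
#' @return CpG x cell-type beta matrix.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- sim_layout(config)
  set.seed(config$seed)
  build_reference(config, layout)
}

#' Mix cell-type profiles into whole-blood samples
#'
#' `beta_sample = reference %*% fractions + Gaussian noise`, clipped to
#' \[0, 1\].
#'
#' @param reference CpG x cell-type beta matrix.
#' @param fractions Sample x cell-type proportion matrix; rows must be
#'   non-negative and sum to 1.
#' @param noise_sd Beta-scale noise SD (default 0).
#' @param seed Optional seed for the noise draw.
#' @return CpG x sample beta matrix.
#' @export
mix_profiles <- function(reference, fractions, noise_sd = 0, seed = NULL) {
  fractions <- as.matrix(fractions)
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (any(abs(rowSums(fractions) - 1) > 1e-8))
    stop("fraction rows must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  beta <- reference %*% t(fractions)
  if (noise_sd > 0)
    beta <- beta + matrix(rnorm(length(beta), 0, noise_sd), nrow(beta))
  beta <- pmin(pmax(beta, 0), 1)
  if (!is.null(rownames(fractions))) colnames(beta) <- rownames(fractions)
  beta
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  x / rowSums(x)
}

#' Generate a full synthetic cohort
#'
#' Draws genotypes, mediator/direct CpG signals and a phenotype from the
#' configured causal mode, samples retrospectively to the case/control
#' quotas, draws group-specific cell fractions, mixes cell profiles with the
#' implanted cell-specific case effects, and returns the data with complete
#' ground truth.
#'
#' In `chain` mode the haplotype influences disease only through mediator CpG
#' methylation (per-CpG log-odds `log(risk_haplotype_or) /
#' (n_mediator_cpgs * mediator_delta)` per beta unit); in `independent` mode
#' the haplotype acts on disease directly and mediator methylation is a
#' passive methQTL; in `reverse` mode disease shifts mediator methylation by
#' `mediator_delta`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort` with elements `beta`, `genotypes`,
#'   `meta`, `fractions` (true sample x cell-type), `reference`,
#'   `reference_case`, `annotation` and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  layout <- sim_layout(cfg)
  set.seed(cfg$seed)
  ref <- build_reference(cfg, layout)

  # SNP panel frequencies and weights
  n_q <- cfg$n_methqtl_cpgs
  qtl_freq <- if (n_q) runif(n_q, 0.2, 0.8) else numeric(0)
  prs_freq <- if (cfg$n_prs_snps) runif(cfg$n_prs_snps, 0.1, 0.9) else numeric(0)
  prs_w <- if (cfg$n_prs_snps)
    pmax(pmin(rnorm(cfg$n_prs_snps, 0, cfg$prs_effect_sd), 0.2), -0.2) else
      numeric(0)
  null_freq <- if (cfg$n_null_snps) runif(cfg$n_null_snps, 0.1, 0.9) else
    numeric(0)

  n_med <- cfg$n_mediator_cpgs
  gamma_med <- if (n_med > 0 && cfg$mediation_mode == "chain")
    log(cfg$risk_haplotype_or) / (n_med * cfg$mediator_delta) else 0
  direct_base <- ref[layout$direct, 1]
  alpha0 <- qlogis(cfg$prevalence)
  hap_direct <- if (cfg$mediation_mode == "chain") 0 else
    log(cfg$risk_haplotype_or)

  draw_batch <- function(n) {
    hap <- rbinom(n, 2, cfg$risk_haplotype_freq)
    prs_dos <- if (cfg$n_prs_snps)
      matrix(rbinom(n * cfg$n_prs_snps, 2, rep(prs_freq, each = n)), nrow = n)
    else matrix(0, n, 0)
    qtl_dos <- if (n_q)
      matrix(rbinom(n * n_q, 2, rep(qtl_freq, each = n)), nrow = n) else
        matrix(0, n, 0)
    null_dos <- if (cfg$n_null_snps)
      matrix(rbinom(n * cfg$n_null_snps, 2, rep(null_freq, each = n)),
             nrow = n) else matrix(0, n, 0)
    med <- if (n_med)
      matrix(cfg$mediator_baseline, n, n_med) +
        (if (cfg$mediation_mode == "reverse") 0 else
           cfg$mediator_delta * hap) +
        matrix(rnorm(n * n_med, 0, cfg$mediator_sd), n) else matrix(0, n, 0)
    dir <- if (cfg$n_direct_cpgs)
      matrix(rep(direct_base, each = n), n) +
        matrix(rnorm(n * cfg$n_direct_cpgs, 0, cfg$direct_sd), n) else
          matrix(0, n, 0)
    prs_lin <- if (cfg$n_prs_snps)
      drop(prs_dos %*% prs_w) - sum(prs_w * 2 * prs_freq) else rep(0, n)
    eta <- alpha0 + prs_lin + hap_direct * (hap - 2 * cfg$risk_haplotype_freq)
    if (n_med && cfg$mediation_mode == "chain") {
      med_expect <- cfg$mediator_baseline +
        cfg$mediator_delta * 2 * cfg$risk_haplotype_freq
      eta <- eta + gamma_med * rowSums(med - med_expect)
    }
    if (cfg$n_direct_cpgs)
      eta <- eta + cfg$direct_gamma *
        drop((dir - matrix(rep(direct_base, each = n), n)) %*%
               rep(1, cfg$n_direct_cpgs)) / 1
    y <- rbinom(n, 1, plogis(eta))
    if (n_med && cfg$mediation_mode == "reverse")
      med <- med + cfg$mediator_delta * y
    list(hap = hap, prs = prs_dos, qtl = qtl_dos, null = null_dos,
         med = med, dir = dir, y = y)
  }

  n_total <- cfg$n_cases + cfg$n_controls
  acc <- NULL
  batch_n <- max(1000L, 2L * n_total)
  got_case <- 0L; got_ctrl <- 0L
  while (got_case < cfg$n_cases || got_ctrl < cfg$n_controls) {
    b <- draw_batch(batch_n)
    keep_case <- which(b$y == 1)[seq_len(min(cfg$n_cases - got_case,
                                             sum(b$y == 1)))]
    keep_ctrl <- which(b$y == 0)[seq_len(min(cfg$n_controls - got_ctrl,
                                             sum(b$y == 0)))]
    keep <- c(keep_case, keep_ctrl)
    sel <- list(hap = b$hap[keep], prs = b$prs[keep, , drop = FALSE],
                qtl = b$qtl[keep, , drop = FALSE],
                null = b$null[keep, , drop = FALSE],
                med = b$med[keep, , drop = FALSE],
                dir = b$dir[keep, , drop = FALSE], y = b$y[keep])
    acc <- if (is.null(acc)) sel else
      list(hap = c(acc$hap, sel$hap), prs = rbind(acc$prs, sel$prs),
           qtl = rbind(acc$qtl, sel$qtl), null = rbind(acc$null, sel$null),
           med = rbind(acc$med, sel$med), dir = rbind(acc$dir, sel$dir),
           y = c(acc$y, sel$y))
    got_case <- got_case + length(keep_case)
    got_ctrl <- got_ctrl + length(keep_ctrl)
  }
  ord <- order(acc$y, decreasing = TRUE)  # cases first, stable
  acc <- list(hap = acc$hap[ord], prs = acc$prs[ord, , drop = FALSE],
              qtl = acc$qtl[ord, , drop = FALSE],
              null = acc$null[ord, , drop = FALSE],
              med = acc$med[ord, , drop = FALSE],
              dir = acc$dir[ord, , drop = FALSE], y = acc$y[ord])
  sample_ids <- sprintf("S%04d", seq_len(n_total))

  # Group-specific cell fractions
  is_case <- acc$y == 1
  frac <- matrix(NA_real_, n_total, 6,
                 dimnames = list(sample_ids, SIM_CELL_TYPES))
  conc <- cfg$dirichlet_concentration
  frac[is_case, ] <- rdirichlet(sum(is_case),
                                conc * cfg$fraction_means_case)
  frac[!is_case, ] <- rdirichlet(sum(!is_case),
                                 conc * cfg$fraction_means_control)

  # Case reference (cell-specific effects applied within the assigned type)
  ref_case <- ref
  effect_truth <- NULL
  if (cfg$n_effect_cpgs) {
    e_cell <- rep(cfg$effect_cell_types,
                  length.out = cfg$n_effect_cpgs)
    e_sign <- rep(c(1, -1), length.out = cfg$n_effect_cpgs)
    e_db <- e_sign * cfg$effect_delta_beta
    for (j in seq_len(cfg$n_effect_cpgs)) {
      i <- layout$effect[j]
      ref_case[i, e_cell[j]] <- ref_case[i, e_cell[j]] + e_db[j]
      if (ref_case[i, e_cell[j]] < 0 || ref_case[i, e_cell[j]] > 1)
        stop("infeasible delta-beta at ", layout$ids[i])
    }
    effect_truth <- data.frame(cpg_id = layout$ids[layout$effect],
                               cell_type = e_cell, delta_beta = e_db,
                               stringsAsFactors = FALSE)
  }

  # Mixture (case samples use the case reference)
  beta <- matrix(NA_real_, cfg$n_cpgs, n_total,
                 dimnames = list(layout$ids, sample_ids))
  beta[, is_case] <- ref_case %*% t(frac[is_case, , drop = FALSE])
  beta[, !is_case] <- ref %*% t(frac[!is_case, , drop = FALSE])

  # Overlay sample-level CpG signals (flat across cell types by construction)
  if (n_med) beta[layout$mediator, ] <- t(acc$med)
  if (cfg$n_direct_cpgs) beta[layout$direct, ] <- t(acc$dir)
  if (n_q)
    beta[layout$methqtl, ] <- ref[layout$methqtl, 1] +
      cfg$methqtl_delta * t(acc$qtl)

  # Measurement noise
  if (cfg$noise_sd > 0) {
    if (cfg$noise_model == "gaussian") {
      beta <- beta + matrix(rnorm(length(beta), 0, cfg$noise_sd), nrow(beta))
    } else {
      mu <- pmin(pmax(beta, 1e-3), 1 - 1e-3)
      nu <- pmax(mu * (1 - mu) / cfg$noise_sd^2 - 1, 2)
      beta <- matrix(rbeta(length(beta), mu * nu, (1 - mu) * nu), nrow(beta),
                     dimnames = dimnames(beta))
    }
  }
  beta <- pmin(pmax(beta, 0), 1)

  # Genotype table
  snp_info <- list()
  dosages <- list()
  if (n_med || TRUE) {
    snp_info$tag <- data.frame(snp_id = "rs_tag", chromosome = "chr6",
                               position = 32500000L, stringsAsFactors = FALSE)
    dosages$tag <- matrix(acc$hap, nrow = 1)
  }
  if (n_q) {
    snp_info$qtl <- data.frame(
      snp_id = sprintf("qtl_snp%03d", seq_len(n_q)),
      chromosome = layout$annotation$chromosome[layout$methqtl],
      position = layout$annotation$position[layout$methqtl] + 5000L,
      stringsAsFactors = FALSE)
    dosages$qtl <- t(acc$qtl)
  }
  if (cfg$n_prs_snps) {
    snp_info$prs <- data.frame(
      snp_id = sprintf("prs_snp%03d", seq_len(cfg$n_prs_snps)),
      chromosome = "chr2",
      position = 10000000L + seq_len(cfg$n_prs_snps) * 100000L,
      stringsAsFactors = FALSE)
    dosages$prs <- t(acc$prs)
  }
  if (cfg$n_null_snps) {
    snp_info$null <- data.frame(
      snp_id = sprintf("null_snp%03d", seq_len(cfg$n_null_snps)),
      chromosome = "chr3",
      position = 10000000L + seq_len(cfg$n_null_snps) * 100000L,
      stringsAsFactors = FALSE)
    dosages$null <- t(acc$null)
  }
  info <- do.call(rbind, unname(snp_info))
  dos <- do.call(rbind, unname(dosages))
  colnames(dos) <- sample_ids
  genotypes <- genotype_table(info, dos)

  meta <- data.frame(
    sample_id = sample_ids,
    phenotype = ifelse(is_case, "case", "control"),
    age = round(runif(n_total, 18, 59)),
    sex = sample(c("F", "M"), n_total, replace = TRUE),
    region = sample(c("R1", "R2", "R3"), n_total, replace = TRUE),
    batch = "B1", stringsAsFactors = FALSE)

  truth <- list(
    mode = cfg$mediation_mode,
    effect = effect_truth,
    methqtl = if (n_q) data.frame(
      cpg_id = layout$ids[layout$methqtl],
      snp_id = sprintf("qtl_snp%03d", seq_len(n_q)),
      delta_per_allele = cfg$methqtl_delta, stringsAsFactors = FALSE),
    mediator = if (n_med) data.frame(
      cpg_id = layout$ids[layout$mediator], snp_id = "rs_tag",
      delta_per_allele = if (cfg$mediation_mode == "reverse") 0 else
        cfg$mediator_delta,
      gamma = gamma_med, stringsAsFactors = FALSE),
    direct = if (cfg$n_direct_cpgs) data.frame(
      cpg_id = layout$ids[layout$direct], gamma = cfg$direct_gamma,
      stringsAsFactors = FALSE),
    prs = if (cfg$n_prs_snps) data.frame(
      snp_id = sprintf("prs_snp%03d", seq_len(cfg$n_prs_snps)),
      weight = prs_w, freq = prs_freq, stringsAsFactors = FALSE),
    haplotype = list(snp_id = "rs_tag", freq = cfg$risk_haplotype_freq,
                     or = cfg$risk_haplotype_or),
    roles = layout$roles,
    signature_cpgs = lapply(layout$signature, function(i) layout$ids[i])
  )

  structure(list(beta = beta, genotypes = genotypes, meta = meta,
                 fractions = frac, reference = ref, reference_case = ref_case,
                 annotation = layout$annotation, truth = truth,
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$beta), "CpGs x", ncol(x$beta), "samples (",
      sum(x$meta$phenotype == "case"), "cases ), mode =", x$truth$mode, "\n")
  invisible(x)
}

#' Write all cohort components to TSV files
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             genotypes = file.path(dir, "dosages.tsv"),
             meta = file.path(dir, "meta.tsv"),
             fractions = file.path(dir, "true_fractions.tsv"),
             reference = file.path(dir, "reference.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_beta_tsv(cohort$beta, paths["beta"])
  write_dosage_tsv(cohort$genotypes, paths["genotypes"])
  write_tsv(cohort$meta, paths["meta"])
  write_beta_tsv(t(cohort$fractions), paths["fractions"],
                 id_column = "cell_type")
  write_beta_tsv(cohort$reference, paths["reference"], id_column = "cpg_id")
  write_tsv(cohort$annotation, paths["annotation"])
  truth_rows <- rbind(
    if (!is.null(cohort$truth$effect))
      data.frame(kind = "effect", id = cohort$truth$effect$cpg_id,
                 partner = cohort$truth$effect$cell_type,
                 value = cohort$truth$effect$delta_beta),
    if (!is.null(cohort$truth$methqtl))
      data.frame(kind = "methqtl", id = cohort$truth$methqtl$cpg_id,
                 partner = cohort$truth$methqtl$snp_id,
                 value = cohort$truth$methqtl$delta_per_allele),
    if (!is.null(cohort$truth$mediator))
      data.frame(kind = "mediator", id = cohort$truth$mediator$cpg_id,
                 partner = cohort$truth$mediator$snp_id,
                 value = cohort$truth$mediator$delta_per_allele),
    if (!is.null(cohort$truth$direct))
      data.frame(kind = "direct", id = cohort$truth$direct$cpg_id,
                 partner = "", value = cohort$truth$direct$gamma),
    if (!is.null(cohort$truth$prs))
      data.frame(kind = "prs", id = cohort$truth$prs$snp_id,
                 partner = "", value = cohort$truth$prs$weight))
  if (is.null(truth_rows))
    truth_rows <- data.frame(kind = character(), id = character(),
                             partner = character(), value = numeric())
  write_tsv(truth_rows, paths["truth"])
  invisible(paths)
}
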