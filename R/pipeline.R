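# Orchestration: configuration, the full analysis chain, and the run report.
#
# Stage order: simulate (or load) -> QC -> deconvolution -> EWAS (+ DMR) ->
# genotype-risk-corrected EWAS -> scores + ROC -> csDMP -> CIT -> methQTL ->
# report. Every stage writes TSV outputs into the run directory; a manifest
# records the md5 of every file plus the seed and package version, so a
# rerun with the same configuration and seed is byte-identical.

RUN_CONFIG_FIELDS <- c(
  "sim", "inputs", "p_threshold", "delta_beta_cut", "estimate_cut",
  "csdmp_p_cut", "dmr_max_gap", "dmr_min_cpgs", "dmr_alpha",
  "metqtl_half_width", "metqtl_alpha", "score_train_fraction",
  "cit_permutations", "cit_top_k", "tag_snp", "seed", "output_dir")

#' Build a validated run configuration
#'
#' Either `sim` (a [sim_config()] or a list of its arguments) or `inputs`
#' (named file paths: `beta`, `annotation`, `meta`, `dosages`, `reference`,
#' `prs_weights`) must be supplied. All thresholds default to the package's
#' standard values.
#'
#' @param sim Simulation block; its seed is overridden by `seed` so that one
#'   seed governs the whole run.
#' @param inputs Named list of input file paths.
#' @param p_threshold,delta_beta_cut EWAS thresholds (9.8e-8, 0.02).
#' @param estimate_cut,csdmp_p_cut csDMP thresholds (2, 9.8e-8).
#' @param dmr_max_gap,dmr_min_cpgs,dmr_alpha DMR parameters (1000 bp, 3,
#'   0.05).
#' @param metqtl_half_width,metqtl_alpha methQTL window and alpha (18000 bp,
#'   0.05; Bonferroni within window).
#' @param score_train_fraction Fraction of samples used to train score
#'   weights (default 0.5; the rest is the held-out evaluation split).
#' @param cit_permutations,cit_top_k CIT settings (500 permutations, 4
#'   candidate mediator CpGs).
#' @param tag_snp Risk-haplotype tag-SNP id (default `"rs_tag"`, the
#'   simulator's tag).
#' @param seed Integer master seed.
#' @param output_dir Output directory.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL,
                       p_threshold = 9.8e-8, delta_beta_cut = 0.02,
                       estimate_cut = 2, csdmp_p_cut = 9.8e-8,
                       dmr_max_gap = 1000, dmr_min_cpgs = 3,
                       dmr_alpha = 0.05,
                       metqtl_half_width = 18000, metqtl_alpha = 0.05,
                       score_train_fraction = 0.5,
                       cit_permutations = 500, cit_top_k = 4,
                       tag_snp = "rs_tag", seed = 1,
                       output_dir = tempfile("grcmeth_run_")) {
  if (is.null(sim) && is.null(inputs))
    stop("either a sim block or input paths must be supplied")
  if (!is.null(sim) && !inherits(sim, "sim_config")) {
    unknown <- setdiff(names(sim), names(formals(sim_config)))
    if (length(unknown))
      stop("unknown sim configuration keys: ",
           paste(unknown, collapse = ", "))
    sim <- do.call(sim_config, sim)
  }
  cfg <- list(sim = sim, inputs = inputs, p_threshold = p_threshold,
              delta_beta_cut = delta_beta_cut, estimate_cut = estimate_cut,
              csdmp_p_cut = csdmp_p_cut, dmr_max_gap = dmr_max_gap,
              dmr_min_cpgs = dmr_min_cpgs, dmr_alpha = dmr_alpha,
              metqtl_half_width = metqtl_half_width,
              metqtl_alpha = metqtl_alpha,
              score_train_fraction = score_train_fraction,
              cit_permutations = cit_permutations, cit_top_k = cit_top_k,
              tag_snp = tag_snp, seed = as.integer(seed),
              output_dir = output_dir)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), RUN_CONFIG_FIELDS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[grcmeth] stage %-12s %6.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis chain
#'
#' Executes every stage in dependency order, writing all outputs and a
#' manifest into `config$output_dir`. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list with every stage's in-memory result.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list(config = config)

  # -- data ------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    cohort <- run_stage("simulate", {
      co <- generate_cohort(sim_cfg)
      write_cohort(co, out_dir)
      co
    })
    beta <- cohort$beta
    meta <- cohort$meta
    genotypes <- cohort$genotypes
    annotation <- cohort$annotation
    sig_ids <- unlist(cohort$truth$signature_cpgs, use.names = FALSE)
    reference <- cohort$reference[sig_ids, , drop = FALSE]
    prs_weights <- setNames(cohort$truth$prs$weight,
                            cohort$truth$prs$snp_id)
    results$cohort <- cohort
  } else {
    inp <- config$inputs
    beta <- run_stage("load", read_beta_tsv(inp$beta))
    meta <- read_meta_tsv(inp$meta)
    genotypes <- read_dosage_tsv(inp$dosages)
    annotation <- read_annotation_tsv(inp$annotation)
    reference <- read_beta_tsv(inp$reference)
    pw <- read.delim(inp$prs_weights, stringsAsFactors = FALSE)
    prs_weights <- setNames(pw$weight, pw$snp_id)
  }

  # -- QC --------------------------------------------------------------
  qc <- run_stage("qc", {
    pq <- filter_probes(beta)
    sq <- filter_samples(pq$beta)
    gq <- genotype_qc(genotypes)
    write_tsv(rbind(
      if (nrow(pq$report)) data.frame(kind = "probe", id = pq$report$cpg_id,
                                      value = pq$report$fail_fraction),
      if (nrow(sq$report)) data.frame(kind = "sample",
                                      id = sq$report$sample_id,
                                      value = sq$report$fail_fraction),
      if (nrow(gq$report)) data.frame(kind = gq$report$stage,
                                      id = gq$report$id,
                                      value = gq$report$value),
      data.frame(kind = character(), id = character(), value = numeric())),
      file.path(out_dir, "qc_report.tsv"))
    list(beta = sq$beta, genotypes = gq$genotypes)
  })
  beta <- qc$beta
  genotypes <- qc$genotypes
  meta <- meta[meta$sample_id %in% colnames(beta), , drop = FALSE]
  results$qc <- qc

  # -- deconvolution ---------------------------------------------------
  fractions <- run_stage("deconvolve", {
    fr <- estimate_fractions(beta, reference)
    write_beta_tsv(t(fr), file.path(out_dir, "fractions.tsv"),
                   id_column = "cell_type")
    fr
  })
  frac_cmp <- compare_fractions(fractions, meta$phenotype)
  write_tsv(frac_cmp, file.path(out_dir, "fraction_comparison.tsv"))
  results$fractions <- fractions
  results$fraction_comparison <- frac_cmp

  # -- whole-blood EWAS + DMRs -----------------------------------------
  ewas <- run_stage("ewas", {
    e <- run_ewas(beta, meta, fractions, config$p_threshold,
                  config$delta_beta_cut)
    write_tsv(e, file.path(out_dir, "ewas.tsv"))
    e
  })
  dmrs <- run_stage("dmr", {
    d <- combine_dmr(ewas, annotation, config$dmr_max_gap,
                     config$dmr_min_cpgs, config$dmr_alpha)
    write_tsv(d, file.path(out_dir, "dmrs.tsv"))
    write_dmr_bed(d, file.path(out_dir, "dmrs.bed"))
    d
  })
  results$ewas <- ewas
  results$dmrs <- dmrs

  # -- genotype-risk-corrected EWAS ------------------------------------
  hla <- hla_score(genotypes, config$tag_snp)[meta$sample_id]
  prs <- prs_score(genotypes, prs_weights)[meta$sample_id]
  grc <- run_stage("grc-ewas", {
    g <- run_grc_ewas(beta, meta, fractions, hla, prs,
                      config$p_threshold, config$delta_beta_cut)
    write_tsv(g, file.path(out_dir, "grc_ewas.tsv"))
    g
  })
  results$grc_ewas <- grc

  # -- scores + ROC ----------------------------------------------------
  scores <- run_stage("scores", {
    ph <- as_case(meta$phenotype)
    set.seed(config$seed + 1L)
    idx_case <- which(ph); idx_ctrl <- which(!ph)
    tr <- c(sample(idx_case, round(length(idx_case) *
                                     config$score_train_fraction)),
            sample(idx_ctrl, round(length(idx_ctrl) *
                                     config$score_train_fraction)))
    train <- sort(tr)
    test <- setdiff(seq_along(ph), train)

    g_train <- run_grc_ewas(beta[, train, drop = FALSE],
                            meta[train, , drop = FALSE],
                            fractions[train, , drop = FALSE],
                            hla[train], prs[train],
                            config$p_threshold, config$delta_beta_cut)
    sel <- g_train$cpg_id[g_train$significant]
    fallback <- length(sel) == 0
    if (fallback)
      sel <- g_train$cpg_id[order(g_train$p)][
        seq_len(min(10, nrow(g_train)))]
    w <- setNames(g_train$delta_beta[match(sel, g_train$cpg_id)], sel)

    meth <- grc_meth_score(beta, w)
    genetic_model <- combine_scores(cbind(hla = hla[train],
                                          prs = prs[train]),
                                    meta$phenotype[train])
    gen_lin <- drop(cbind(1, hla, prs) %*% genetic_model$coefficients)
    comb_model <- combine_scores(cbind(meth = meth[train],
                                       hla = hla[train], prs = prs[train]),
                                 meta$phenotype[train])
    comb_lin <- drop(cbind(1, meth, hla, prs) %*% comb_model$coefficients)

    auc_rows <- do.call(rbind, lapply(
      list(c("grcMethScore", "train"), c("grcMethScore", "test"),
           c("genetic", "train"), c("genetic", "test"),
           c("combined", "train"), c("combined", "test")),
      function(spec) {
        s <- switch(spec[1], grcMethScore = meth, genetic = gen_lin,
                    combined = comb_lin)
        i <- if (spec[2] == "train") train else test
        r <- roc_auc(s[i], meta$phenotype[i])
        data.frame(score = spec[1], split = spec[2], auc = r$auc,
                   ci_low = r$ci_low, ci_high = r$ci_high,
                   stringsAsFactors = FALSE)
      }))
    sc <- data.frame(sample_id = meta$sample_id,
                     split = ifelse(seq_along(ph) %in% train, "train",
                                    "test"),
                     grc_meth_score = meth, hla = hla, prs = prs,
                     genetic = gen_lin, combined = comb_lin)
    write_tsv(sc, file.path(out_dir, "scores.tsv"))
    write_tsv(auc_rows, file.path(out_dir, "auc.tsv"))
    list(scores = sc, auc = auc_rows, weights = w,
         weight_fallback = fallback, train = train, test = test)
  })
  results$scores <- scores

  # -- cell-type-specific DMPs -----------------------------------------
  csdmp <- run_stage("csdmp", {
    m <- beta_to_m(beta)
    cs <- run_csdmp(m, fractions, meta, estimate_cut = config$estimate_cut,
                    p_cut = config$csdmp_p_cut)
    write_tsv(cs, file.path(out_dir, "csdmp.tsv"))
    write_tsv(summarize_csdmp(cs)$counts,
              file.path(out_dir, "csdmp_summary.tsv"))
    cs
  })
  results$csdmp <- csdmp

  # -- CIT -------------------------------------------------------------
  cit <- run_stage("cit", {
    cand <- if (nrow(dmrs) && any(dmrs$significant)) {
      vapply(which(dmrs$significant), function(i) {
        members <- strsplit(dmrs$cpg_ids[i], ",")[[1]]
        members[which.min(ewas$p[match(members, ewas$cpg_id)])]
      }, character(1))
    } else {
      sig <- ewas[ewas$significant & ewas$estimable, , drop = FALSE]
      pool <- if (nrow(sig)) sig else ewas[ewas$estimable, , drop = FALSE]
      pool$cpg_id[order(pool$p)][seq_len(min(config$cit_top_k,
                                             nrow(pool)))]
    }
    rows <- lapply(seq_along(cand), function(i) {
      r <- cit_test(hla, beta[cand[i], ], meta$phenotype,
                    n_permutations = config$cit_permutations,
                    seed = config$seed + 10L + i)
      data.frame(snp_id = config$tag_snp, cpg_id = cand[i],
                 p_assoc_LT = r$p_assoc_LT,
                 p_assoc_LG_given_T = r$p_assoc_LG_given_T,
                 p_assoc_GT_given_L = r$p_assoc_GT_given_L,
                 p_indep_LT_given_G = r$p_indep_LT_given_G,
                 omnibus_p = r$omnibus_p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    write_tsv(tab, file.path(out_dir, "cit.tsv"))
    tab
  })
  results$cit <- cit

  # -- methQTL ---------------------------------------------------------
  metqtl <- run_stage("metqtl", {
    dmp_set <- grc$cpg_id[grc$significant]
    fallback <- length(dmp_set) == 0
    if (fallback)
      dmp_set <- grc$cpg_id[order(grc$p)][seq_len(min(20, nrow(grc)))]
    mq <- run_metqtl(beta, annotation, genotypes, dmp_set,
                     config$metqtl_half_width, config$metqtl_alpha)
    write_tsv(mq, file.path(out_dir, "metqtl.tsv"))
    mod <- proportion_modulated(dmp_set, mq)
    write_tsv(data.frame(count = mod$count, total = mod$total,
                         fraction = mod$fraction,
                         dmp_set = if (fallback) "top20_fallback" else
                           "grc_significant"),
              file.path(out_dir, "metqtl_modulation.tsv"))
    list(results = mq, modulation = mod, fallback = fallback)
  })
  results$metqtl <- metqtl

  # -- report + manifest -----------------------------------------------
  run_stage("report", make_report(out_dir))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        basename(manifest_path)))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  header <- sprintf("# grcmeth %s seed=%d",
                    as.character(packageVersion("grcmeth")), config$seed)
  writeLines(c(header, paste(c("file", "md5"), collapse = "\t"),
               paste(manifest$file, manifest$md5, sep = "\t")),
             manifest_path)
  results$manifest <- manifest
  invisible(results)
}

read_if <- function(path) if (file.exists(path))
  read.delim(path, stringsAsFactors = FALSE) else NULL

#' Generate the human-readable run report
#'
#' Summarises the stage outputs found in a run directory into
#' `report.md`: cell-fraction comparison, DMP/DMR counts, AUC table, csDMP
#' counts, CIT table and the methQTL modulation fraction. Missing stages
#' are marked absent, never fabricated. Regeneration is idempotent.
#'
#' @param output_dir A [run_all()] output directory.
#' @return Invisibly, the report text.
#' @export
make_report <- function(output_dir) {
  lines <- c("# grcmeth run report", "")
  fmt_tab <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, function(r) paste(format(r, trim = TRUE),
                                     collapse = " | ")))
  }
  section <- function(title, df, digest = identity) {
    if (is.null(df)) c(paste0("## ", title), "", "_absent_", "")
    else c(paste0("## ", title), "", fmt_tab(digest(df)), "")
  }
  fc <- read_if(file.path(output_dir, "fraction_comparison.tsv"))
  lines <- c(lines, section("Cell fractions (case vs control)", fc))
  ew <- read_if(file.path(output_dir, "ewas.tsv"))
  if (!is.null(ew)) {
    lines <- c(lines, "## Whole-blood EWAS", "",
               sprintf("- CpGs tested: %d", nrow(ew)),
               sprintf("- significant DMPs: %d", sum(ew$significant)),
               sprintf("- significant with large effect: %d",
                       sum(ew$significant & ew$large_effect)), "")
  } else lines <- c(lines, "## Whole-blood EWAS", "", "_absent_", "")
  dm <- read_if(file.path(output_dir, "dmrs.tsv"))
  if (!is.null(dm)) {
    lines <- c(lines, "## DMRs", "",
               sprintf("- candidate regions: %d", nrow(dm)),
               sprintf("- significant: %d", sum(dm$significant)), "")
  } else lines <- c(lines, "## DMRs", "", "_absent_", "")
  gr <- read_if(file.path(output_dir, "grc_ewas.tsv"))
  if (!is.null(gr)) {
    lines <- c(lines, "## Genotype-risk-corrected EWAS", "",
               sprintf("- significant DMPs: %d", sum(gr$significant)), "")
  } else lines <- c(lines, "## Genotype-risk-corrected EWAS", "",
                    "_absent_", "")
  au <- read_if(file.path(output_dir, "auc.tsv"))
  lines <- c(lines, section("Score AUCs", au))
  cs <- read_if(file.path(output_dir, "csdmp_summary.tsv"))
  lines <- c(lines, section("csDMP counts per cell type", cs))
  ci <- read_if(file.path(output_dir, "cit.tsv"))
  lines <- c(lines, section("CIT mediation", ci))
  mo <- read_if(file.path(output_dir, "metqtl_modulation.tsv"))
  lines <- c(lines, section("DMPs modulated by cis genotype", mo))
  writeLines(lines, file.path(output_dir, "report.md"))
  invisible(paste(lines, collapse = "\n"))
}
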