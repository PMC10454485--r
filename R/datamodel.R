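# Core containers and quality filters shared by every stage.
#
# A beta matrix is a plain numeric matrix (CpG x sample) with unique row and
# column names; an M-value matrix is the same shape on the logit2 scale.
# Genotypes are held as a two-part object: a SNP info table and a dosage
# matrix (SNP x sample, values 0/1/2 or NA).

#' Construct and validate a beta-value matrix
#'
#' @param values Numeric matrix of methylation fractions, CpGs in rows,
#'   samples in columns.
#' @param cpg_ids,sample_ids Optional identifier vectors; defaults to the
#'   dimnames of `values`.
#' @return The validated matrix with dimnames set.
#' @export
beta_matrix <- function(values, cpg_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(cpg_ids) || is.null(sample_ids))
    stop("beta_matrix requires CpG and sample identifiers")
  if (length(cpg_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(cpg_ids)) stop("duplicated CpG identifiers")
  if (anyDuplicated(sample_ids)) stop("duplicated sample identifiers")
  dimnames(values) <- list(as.character(cpg_ids), as.character(sample_ids))
  bad <- which(!is.finite(values) & !is.na(values))
  if (length(bad))
    stop("non-finite beta value at ", .cell_name(values, bad[1]))
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]")
  values
}

.cell_name <- function(m, idx) {
  rc <- arrayInd(idx, dim(m))
  paste0("(", rownames(m)[rc[1]], ", ", colnames(m)[rc[2]], ")")
}

#' Convert beta values to M-values
#'
#' Betas are clipped to `[epsilon, 1 - epsilon]` before the logit2 transform
#' `M = log2(beta / (1 - beta))`, keeping M finite (|M| <= ~10 at the default
#' clip).
#'
#' @param beta Beta matrix (or numeric vector).
#' @param epsilon Clip bound, in (0, 0.5). Default 1e-3.
#' @return Matrix (or vector) of M-values.
#' @export
beta_to_m <- function(beta, epsilon = 1e-3) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must be a single value in (0, 0.5)")
  bad <- which(!is.finite(beta))
  if (length(bad)) {
    where <- if (is.matrix(beta)) .cell_name(beta, bad[1]) else
      paste0("position ", bad[1])
    stop("non-finite beta value at ", where)
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) dimnames(m) <- dimnames(beta)
  m
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()] away from the clip bounds:
#' `beta = 2^M / (1 + 2^M)`.
#'
#' @param m M-value matrix (or numeric vector).
#' @return Matrix (or vector) of beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m))) stop("non-finite M-value in input")
  plogis(m * log(2))
}

#' Remove low-performing probes
#'
#' A probe is removed when its fraction of samples failing detection exceeds
#' `max_fail_fraction`. When a detection p-value matrix is supplied, a sample
#' fails a probe if `detection_p > p_cut`; without one, missing (`NA`) beta
#' values count as failures.
#'
#' @param beta Beta matrix.
#' @param detection_p Optional matrix of per-(CpG, sample) detection p-values,
#'   aligned with `beta`.
#' @param p_cut Detection p-value threshold (default 0.01).
#' @param max_fail_fraction Maximum tolerated fraction of failing samples per
#'   probe (default 0.05).
#' @return List with `beta` (filtered matrix) and `report` (data frame of
#'   removed probes with failure fractions).
#' @export
filter_probes <- function(beta, detection_p = NULL, p_cut = 0.01,
                          max_fail_fraction = 0.05) {
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)))
      stop("detection_p is not aligned with the beta matrix")
    fails <- detection_p > p_cut
  } else {
    fails <- is.na(beta)
  }
  frac <- rowMeans(fails)
  drop <- frac > max_fail_fraction
  if (all(drop)) stop("all probes removed by detection filtering")
  report <- data.frame(
    cpg_id = rownames(beta)[drop],
    fail_fraction = unname(frac[drop]),
    reason = rep("detection_failure", sum(drop)),
    stringsAsFactors = FALSE
  )
  list(beta = beta[!drop, , drop = FALSE], report = report)
}

#' Remove low-performing samples
#'
#' Samples whose fraction of missing (failed) probes exceeds
#' `max_fail_fraction` are removed.
#'
#' @param beta Beta matrix (missing values mark failed probes).
#' @param max_fail_fraction Maximum tolerated fraction of failed probes per
#'   sample (default 0.1).
#' @return List with `beta` and `report` as in [filter_probes()].
#' @export
filter_samples <- function(beta, max_fail_fraction = 0.1) {
  frac <- colMeans(is.na(beta))
  drop <- frac > max_fail_fraction
  if (all(drop)) stop("all samples removed by missingness filtering")
  report <- data.frame(
    sample_id = colnames(beta)[drop],
    fail_fraction = unname(frac[drop]),
    reason = rep("probe_missingness", sum(drop)),
    stringsAsFactors = FALSE
  )
  list(beta = beta[, !drop, drop = FALSE], report = report)
}

#' Construct a genotype table
#'
#' @param info Data frame with columns `snp_id`, `chromosome`, `position`
#'   (1-based base pairs).
#' @param dosages Numeric matrix (SNP x sample) of effect-allele counts in
#'   \{0, 1, 2\} or `NA`; row names must match `info$snp_id`.
#' @return Object of class `genotype_table`.
#' @export
genotype_table <- function(info, dosages) {
  stopifnot(is.data.frame(info),
            all(c("snp_id", "chromosome", "position") %in% names(info)))
  dosages <- as.matrix(dosages)
  if (anyDuplicated(info$snp_id)) stop("duplicated SNP identifiers")
  if (nrow(dosages) != nrow(info)) stop("dosage rows do not match SNP info")
  if (any(info$position <= 0) || any(info$position != round(info$position)))
    stop("positions must be positive integers")
  rownames(dosages) <- info$snp_id
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  structure(list(info = info, dosages = dosages), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$dosages), "SNPs x", ncol(x$dosages),
      "samples\n")
  invisible(x)
}

# 1-df Hardy-Weinberg chi-square from genotype counts (n0, n1, n2 = copies of
# the effect allele). Returns NA for monomorphic SNPs.
hwe_chisq <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1) return(NA_real_)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  sum((c(n0, n1, n2) - e)^2 / e)
}

#' Genotype quality control
#'
#' Filters are applied in a fixed order: (1) SNP call rate, (2) sample call
#' rate, (3) Hardy-Weinberg equilibrium (1-df chi-square on genotype counts) at
#' `hwe_alpha`. Monomorphic SNPs cannot be tested for HWE; they are retained
#' and flagged.
#'
#' @param g A [genotype_table()].
#' @param min_snp_call Minimum per-SNP call rate (default 0.98).
#' @param min_sample_call Minimum per-sample call rate (default 0.95).
#' @param hwe_alpha HWE test significance threshold (default 1e-6).
#' @return List with `genotypes` (filtered table) and `report` (data frame of
#'   removals and flags with stage, id, metric and value).
#' @export
genotype_qc <- function(g, min_snp_call = 0.98, min_sample_call = 0.95,
                        hwe_alpha = 1e-6) {
  stopifnot(inherits(g, "genotype_table"))
  d <- g$dosages
  report <- list()

  snp_call <- rowMeans(!is.na(d))
  drop_snp <- snp_call < min_snp_call
  if (any(drop_snp))
    report$snp_call <- data.frame(
      stage = "snp_call_rate", id = rownames(d)[drop_snp],
      metric = "call_rate", value = unname(snp_call[drop_snp]),
      action = "removed", stringsAsFactors = FALSE)
  d <- d[!drop_snp, , drop = FALSE]

  sample_call <- colMeans(!is.na(d))
  drop_sample <- sample_call < min_sample_call
  if (any(drop_sample))
    report$sample_call <- data.frame(
      stage = "sample_call_rate", id = colnames(d)[drop_sample],
      metric = "call_rate", value = unname(sample_call[drop_sample]),
      action = "removed", stringsAsFactors = FALSE)
  d <- d[, !drop_sample, drop = FALSE]

  counts <- t(apply(d, 1, function(x)
    c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
      sum(x == 2, na.rm = TRUE))))
  chisq <- vapply(seq_len(nrow(d)), function(i)
    hwe_chisq(counts[i, 1], counts[i, 2], counts[i, 3]), numeric(1))
  hwe_p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  mono <- is.na(chisq)
  drop_hwe <- !mono & hwe_p < hwe_alpha
  if (any(drop_hwe))
    report$hwe <- data.frame(
      stage = "hwe", id = rownames(d)[drop_hwe], metric = "hwe_p",
      value = unname(hwe_p[drop_hwe]), action = "removed",
      stringsAsFactors = FALSE)
  if (any(mono))
    report$mono <- data.frame(
      stage = "hwe", id = rownames(d)[mono], metric = "hwe_p",
      value = NA_real_, action = "retained_monomorphic",
      stringsAsFactors = FALSE)
  d <- d[!drop_hwe, , drop = FALSE]

  info <- g$info[match(rownames(d), g$info$snp_id), , drop = FALSE]
  rownames(info) <- NULL
  report <- if (length(report)) do.call(rbind, unname(report)) else
    data.frame(stage = character(), id = character(), metric = character(),
               value = numeric(), action = character())
  list(genotypes = genotype_table(info, d), report = report)
}

# Normalise a phenotype vector to logical case indicator. Accepts logical,
# 0/1 numeric, or a two-level factor/character where "case" (if present) or
# the second sorted level marks cases.
as_case <- function(phenotype) {
  if (is.logical(phenotype)) {
    ph <- phenotype
  } else if (is.numeric(phenotype)) {
    if (!all(phenotype %in% c(0, 1))) stop("numeric phenotype must be 0/1")
    ph <- phenotype == 1
  } else {
    f <- as.factor(phenotype)
    if (nlevels(f) != 2) stop("phenotype must have exactly two levels")
    case_level <- if ("case" %in% levels(f)) "case" else levels(f)[2]
    ph <- f == case_level
  }
  if (any(is.na(ph))) stop("phenotype contains missing values")
  ph
}

#' Per-CpG case/control methylation difference
#'
#' `delta_beta_i = mean(case beta_i) - mean(control beta_i)`; positive values
#' indicate hypermethylation in cases.
#'
#' @param beta Beta matrix.
#' @param phenotype Case/control labels (logical, 0/1, or two-level factor;
#'   `"case"` or the second level marks cases).
#' @return Named numeric vector of per-CpG delta-beta values.
#' @export
delta_beta <- function(beta, phenotype) {
  ph <- as_case(phenotype)
  if (length(ph) != ncol(beta))
    stop("phenotype length does not match number of samples")
  if (!any(ph) || all(ph)) stop("both phenotype groups must be non-empty")
  rowMeans(beta[, ph, drop = FALSE]) - rowMeans(beta[, !ph, drop = FALSE])
}
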