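# TSV and VCF readers/writers. All TSV dialects are plain tab-separated text
# (gzip-transparent on read through R's connection handling): the beta/M and
# dosage matrices carry the row identifier in the first column with sample ids
# as the header; annotation and metadata are ordinary one-row-per-record
# tables.

#' Read a beta (or M-value) matrix from TSV
#'
#' First column CpG id, remaining columns one per sample.
#'
#' @param path File path (plain or gzipped TSV).
#' @return Numeric matrix with CpG row names and sample column names.
#' @export
read_beta_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a beta (or M-value) matrix to TSV
#'
#' @param beta Matrix with CpG row names and sample column names.
#' @param path Output path.
#' @param id_column Name for the identifier column (default `"cpg_id"`).
#' @export
write_beta_tsv <- function(beta, path, id_column = "cpg_id") {
  df <- data.frame(rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read probe annotation from TSV
#'
#' Expects columns `cpg_id`, `chromosome`, `position` (1-based) and
#' optionally `gene`.
#'
#' @param path File path.
#' @return Data frame of probe annotation.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cpg_id", "chromosome", "position")
  if (!all(need %in% names(df)))
    stop("annotation must contain columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$cpg_id)) stop("duplicated CpG ids in annotation")
  if (any(df$position <= 0)) stop("annotation positions must be positive")
  if (!"gene" %in% names(df)) df$gene <- ""
  df
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `phenotype`, `age`, `sex`, `region`, and
#' optionally `batch`. Phenotype must be binary with no missing values.
#'
#' @param path File path.
#' @return Data frame of sample metadata.
#' @export
read_meta_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "phenotype", "age", "sex", "region")
  if (!all(need %in% names(df)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  as_case(df$phenotype)  # validates binary, no missing
  df
}

#' Write a data frame to TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a SNP dosage table from TSV
#'
#' Expects columns `snp_id`, `chromosome`, `position`, followed by one column
#' per sample holding effect-allele dosages in \{0, 1, 2\} (blank/NA for
#' missing).
#'
#' @param path File path.
#' @return A [genotype_table()].
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  info_cols <- c("snp_id", "chromosome", "position")
  if (!all(info_cols %in% names(df)))
    stop("dosage table must contain columns: ",
         paste(info_cols, collapse = ", "))
  dos <- as.matrix(df[, setdiff(names(df), info_cols), drop = FALSE])
  storage.mode(dos) <- "double"
  genotype_table(df[info_cols], dos)
}

#' Write a genotype table to TSV
#'
#' @param g A [genotype_table()].
#' @param path Output path.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_table"))
  df <- cbind(g$info[c("snp_id", "chromosome", "position")],
              as.data.frame(g$dosages, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read genotypes from a VCF file as effect-allele dosages
#'
#' The GT field is converted to the per-sample count of the first ALT allele;
#' missing genotypes become `NA`. Multi-allelic records count any non-reference
#' allele.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_table()].
#' @export
read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    out <- rep(NA_real_, length(x))
    known <- !is.na(x) & !grepl("\\.", x)
    alleles <- strsplit(gsub("\\|", "/", x[known]), "/", fixed = FALSE)
    out[known] <- vapply(alleles, function(a) sum(a != "0"), numeric(1))
    out
  }
  dos <- t(apply(gt, 1, count_alt))
  colnames(dos) <- colnames(gt)
  fx <- vcfR::getFIX(v)
  ids <- fx[, "ID"]
  if (any(is.na(ids) | ids == "."))
    ids <- paste0(fx[, "CHROM"], ":", fx[, "POS"])
  info <- data.frame(snp_id = ids, chromosome = fx[, "CHROM"],
                     position = as.integer(fx[, "POS"]),
                     stringsAsFactors = FALSE)
  genotype_table(info, dos)
}
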