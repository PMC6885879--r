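#' Cohort and summary-statistic readers and writers
#'
#' Plain-text interchange for the cohort container: dosage matrix and
#' phenotype table as TSV, genotypes additionally as a minimal VCF
#' (GT-only, one record per SNP, samples as columns), and per-SNP outcome
#' statistics as a GWAS-summary TSV.
#'
#' @param cohort an `mr_cohort`.
#' @param path output file path.
#' @return the path, invisibly (writers); the parsed object (readers).
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_dosage_tsv <- function(cohort, path) {
  d <- data.frame(sample_id = rownames(cohort$dosages), cohort$dosages,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_dosage_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  m
}

#' @rdname cohort_io
#' @export
write_phenotype_tsv <- function(cohort, path) {
  write.table(cohort$phenotype, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_phenotype_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname cohort_io
#' @param instruments instrument table supplying alleles for the VCF REF
#'   (other allele) and ALT (effect allele) fields.
#' @export
write_cohort_vcf <- function(cohort, instruments, path) {
  inst <- instruments(instruments)
  ids <- rownames(cohort$dosages)
  absent <- setdiff(inst$snp_id, colnames(cohort$dosages))
  if (length(absent))
    abort("instrument(s) absent from dosage columns: ",
          paste(absent, collapse = ", "))
  gt_of <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=telomr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  for (j in seq_len(nrow(inst))) {
    dos <- cohort$dosages[, inst$snp_id[j]]
    gt <- ifelse(is.na(dos), "./.", gt_of[as.character(dos)])
    lines <- c(lines, paste(c("1", as.character(j), inst$snp_id[j],
                              inst$other_allele[j], inst$effect_allele[j],
                              ".", "PASS", ".", "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname cohort_io
#' @details `read_dosage_vcf()` parses a GT-only VCF back into an
#'   effect-allele (ALT) dosage matrix; it uses the `vcfR` package.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("read_dosage_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(g, "[/|]"), function(a)
             sum(a == "1"), integer(1)))
  }
  m <- apply(gt, 2, count_alt)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(rownames(gt), colnames(gt)))
  t(m)  # individuals x SNPs, SNP ids as colnames
}

#' @rdname cohort_io
#' @param assocs `mr_summary_assoc` table.
#' @export
write_summary_tsv <- function(assocs, instruments, path) {
  inst <- instruments(instruments)
  m <- match(assocs$snp_id, inst$snp_id)
  if (anyNA(m)) abort("association snp_id(s) missing from instrument table")
  out <- data.frame(snp_id = assocs$snp_id,
                    effect_allele = inst$effect_allele[m],
                    other_allele = inst$other_allele[m],
                    beta_y = assocs$beta_y, se_y = assocs$se_y,
                    pval_y = assocs$pval_y, n = assocs$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_summary_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "beta_y", "se_y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort("summary TSV lacks columns: ", paste(miss, collapse = ", "))
  if (!"pval_y" %in% names(d))
    d$pval_y <- 2 * pnorm(-abs(d$beta_y / d$se_y))
  if (!"n" %in% names(d)) d$n <- NA_integer_
  class(d) <- c("mr_summary_assoc", "data.frame")
  d
}

#' Bundled per-SNP lung cancer outcome statistics
#'
#' Published per-SNP lung cancer association estimates (odds ratio and 95%
#' CI per effect allele) for the nine telomere-length instruments in a
#' pooled East Asian case-control sample of 7127 cases and 6818 controls,
#' by histology stratum (`overall`, `adenocarcinoma`, `squamous`). Used by
#' the worked examples to reconstruct log-ORs and standard errors via
#' [assoc_from_or_ci()].
#'
#' @param stratum one of `"overall"`, `"adenocarcinoma"`, `"squamous"`.
#' @return An `mr_summary_assoc` data.frame.
#' @export
example_outcome_stats <- function(stratum = c("overall", "adenocarcinoma",
                                              "squamous")) {
  stratum <- match.arg(stratum)
  d <- read.delim(system.file("extdata", "lung_outcome_summary.tsv",
                              package = "telomr", mustWork = TRUE),
                  stringsAsFactors = FALSE)
  d <- d[d$stratum == stratum, , drop = FALSE]
  assoc_from_or_ci(d$snp_id, d$or_value, d$ci_low, d$ci_high, n = d$n)
}
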