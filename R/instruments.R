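#' Construct a telomere-length instrument table
#'
#' An instrument table holds one row per TL-associated SNP with its
#' exposure-side effect estimate. After harmonization the effect allele is
#' the long-TL allele, so `beta_x` (kb of TL per effect allele) is
#' non-negative, and `unit` is `"kb"` after [scale_to_kb()].
#'
#' @param x data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `maf`, `beta_x`, `se_x`, `pval_x`, `unit`, and
#'   optionally `source`.
#' @return An object of class `mr_instruments` (a validated data.frame).
#' @examples
#' instruments(data.frame(
#'   snp_id = "rs2736100", effect_allele = "C", other_allele = "A",
#'   maf = 0.4, beta_x = 0.078, se_x = 0.009, pval_x = 1e-19, unit = "kb"))
#' @export
instruments <- function(x) {
  required <- c("snp_id", "effect_allele", "other_allele", "maf",
                "beta_x", "se_x", "pval_x", "unit")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    abort("instrument table lacks columns: ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"source" %in% names(x)) x$source <- NA_character_
  x$snp_id <- as.character(x$snp_id)
  if (anyDuplicated(x$snp_id))
    abort("duplicated snp_id in instrument table: ",
          paste(unique(x$snp_id[duplicated(x$snp_id)]), collapse = ", "))
  if (any(!is.finite(x$maf)) || any(x$maf <= 0) || any(x$maf >= 0.5))
    abort("maf must lie strictly in (0, 0.5) (minor-allele frequency)")
  if (any(!is.finite(x$se_x)) || any(x$se_x <= 0))
    abort("se_x must be positive")
  if (any(!x$unit %in% c("kb", "bp")))
    abort("unsupported unit(s): ", paste(setdiff(unique(x$unit), c("kb", "bp")),
                                         collapse = ", "),
          " (supported: kb, bp)")
  rownames(x) <- NULL
  class(x) <- c("mr_instruments", "data.frame")
  x
}

#' Read / write an instrument table as TSV
#'
#' The TSV has header columns `snp_id, effect_allele, other_allele, maf,
#' beta_x, se_x, pval_x, unit, source`.
#'
#' @param path file path.
#' @return `read_instruments()` returns an `mr_instruments` table.
#' @export
read_instruments <- function(path) {
  instruments(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_instruments
#' @param inst instrument table.
#' @export
write_instruments <- function(inst, path) {
  write.table(as.data.frame(inst), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Bundled nine-SNP telomere-length instrument catalog
#'
#' Returns the package's example catalog of nine TL-associated loci (TERC,
#' TERT, NAF1, OBFC1, ZNF208, RTEL1, ACYP2, CTC1, ZNF676 regions) with
#' East-Asian-plausible minor-allele frequencies. The kb-per-allele weights
#' are approximate literature-typical values shipped for demonstration and
#' simulation (the file is labelled `synthetic`); for a real analysis supply
#' the exact weights of the TL GWAS you are instrumenting from via
#' [read_instruments()].
#'
#' @return An `mr_instruments` table with nine rows.
#' @export
default_instruments <- function() {
  read_instruments(system.file("extdata", "tl_instruments_synthetic.tsv",
                               package = "telomr", mustWork = TRUE))
}

#' Construct a pairwise LD matrix
#'
#' @param snp_ids character vector of SNP identifiers, in matrix order.
#' @param r2 square symmetric matrix of pairwise r-squared values in
#'   \[0, 1\] with unit diagonal.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, r2) {
  r2 <- as.matrix(r2)
  snp_ids <- as.character(snp_ids)
  if (nrow(r2) != length(snp_ids) || ncol(r2) != length(snp_ids))
    abort("r2 must be a square matrix matching length(snp_ids)")
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1))
    abort("r2 values must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-12) abort("r2 matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-12)) abort("r2 diagonal must be exactly 1")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Read an LD matrix from square TSV
#'
#' Expects a header row of SNP ids and a leading id column, as written by
#' `write.table(..., row.names = TRUE)`.
#'
#' @param path file path.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  ld_matrix(rownames(m), m)
}

#' Convert instrument effect sizes to kb
#'
#' TL GWAS report per-allele effects in kb or bp; the GRS and IVW arms
#' require a uniform kb scale. Divides `beta_x` and `se_x` by 1000 for rows
#' in bp; kb rows pass through unchanged. The z-score `beta_x / se_x` is
#' preserved exactly.
#'
#' @param inst instrument table.
#' @return The table with all rows in kb.
#' @export
scale_to_kb <- function(inst) {
  inst <- instruments(inst)
  bp <- inst$unit == "bp"
  inst$beta_x[bp] <- inst$beta_x[bp] / 1000
  inst$se_x[bp] <- inst$se_x[bp] / 1000
  inst$unit[bp] <- "kb"
  inst
}

#' Orient instruments to the long-telomere allele
#'
#' MR convention here takes the long-TL allele as effect allele, so every
#' exposure-side effect is non-negative. Rows reported for the short allele
#' (`beta_x < 0`) have their alleles swapped and the sign flipped. The `maf`
#' column is the minor-allele frequency and is unaffected by orientation.
#'
#' @param inst instrument table.
#' @return The table with `beta_x >= 0` on every row.
#' @export
harmonize_orientation <- function(inst) {
  inst <- instruments(inst)
  if (any(inst$beta_x == 0))
    abort("uninformative instrument(s) with beta_x = 0: ",
          paste(inst$snp_id[inst$beta_x == 0], collapse = ", "))
  flip <- inst$beta_x < 0
  if (any(flip)) {
    ea <- inst$effect_allele[flip]
    inst$effect_allele[flip] <- inst$other_allele[flip]
    inst$other_allele[flip] <- ea
    inst$beta_x[flip] <- -inst$beta_x[flip]
  }
  inst
}

#' Select instruments by significance, frequency and LD pruning
#'
#' Applies the three selection criteria used for TL instruments: discovery
#' p-value at most `p_threshold` (genome-wide significance by default),
#' minor-allele frequency strictly greater than `maf_min` in the reference
#' population, and pairwise LD `r2 < r2_max`. LD violations are resolved by
#' greedy pruning in ascending discovery p-value: the more significant SNP
#' of a violating pair is kept, as in standard clumping.
#'
#' @param candidates instrument table of candidate SNPs.
#' @param ld [ld_matrix()] covering every candidate.
#' @param p_threshold significance cutoff, default `5e-8`.
#' @param maf_min frequency cutoff (strict), default `0.05`.
#' @param r2_max pairwise LD cutoff (strict), default `0.5`.
#' @return The retained rows, in input order. Idempotent: reapplying to its
#'   own output is a no-op.
#' @export
select_instruments <- function(candidates, ld, p_threshold = 5e-8,
                               maf_min = 0.05, r2_max = 0.5) {
  stopifnot(p_threshold > 0, p_threshold < 1, maf_min > 0, maf_min < 1,
            r2_max > 0, r2_max < 1)
  if (NROW(candidates) == 0) return(instruments(empty_instrument_df()))
  candidates <- instruments(candidates)
  if (!inherits(ld, "ld_matrix")) abort("ld must be an ld_matrix")
  absent <- setdiff(candidates$snp_id, rownames(ld))
  if (length(absent))
    abort("candidate SNP(s) missing from LD matrix: ",
          paste(absent, collapse = ", "))
  keep <- candidates$pval_x <= p_threshold & candidates$maf > maf_min
  pool <- candidates[keep, , drop = FALSE]
  if (nrow(pool) == 0) return(pool)
  ord <- order(pool$pval_x)           # greedy by ascending discovery p
  kept <- character(0)
  for (id in pool$snp_id[ord]) {
    if (all(ld[id, kept] < r2_max)) kept <- c(kept, id)
  }
  pool[pool$snp_id %in% kept, , drop = FALSE]
}

empty_instrument_df <- function() {
  data.frame(snp_id = character(0), effect_allele = character(0),
             other_allele = character(0), maf = numeric(0),
             beta_x = numeric(0), se_x = numeric(0), pval_x = numeric(0),
             unit = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.mr_instruments <- function(x, ...) {
  cat(sprintf("<mr_instruments> %d SNP(s), units: %s\n", nrow(x),
              paste(unique(x$unit), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}
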