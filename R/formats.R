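# On-disk formats: genotype panels (traw / VCF), summary statistics,
# phenotype tables, score files.  Coordinates are 1-based inclusive
# throughout (PLINK/VCF convention).

#' Construct a genotype panel
#'
#' A genotype panel holds an additive dosage matrix (samples x variants,
#' entries 0/1/2 counting the `allele_counted` allele, `NA` for missing)
#' together with variant metadata.  Variants are kept sorted by
#' `(chrom, pos)`; if the input is not sorted the columns are reordered and
#' a message is emitted (the only reordering a panel ever undergoes —
#' sample order is preserved verbatim).
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `allele_counted`, `allele_other`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param dosage numeric matrix, `length(sample_ids)` rows and
#'   `nrow(variants)` columns, entries in `{0, 1, 2, NA}`.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(variants, sample_ids, dosage) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "allele_counted", "allele_other")
  miss <- setdiff(req, names(variants))
  if (length(miss)) fail("variant table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$variant_id))
    fail("duplicate variant_id in panel: %s",
         variants$variant_id[duplicated(variants$variant_id)][1])
  if (anyDuplicated(sample_ids))
    fail("duplicate sample ids in panel")
  if (any(variants$pos < 1)) fail("variant positions must be >= 1 (1-based)")
  if (any(variants$allele_counted == variants$allele_other))
    fail("allele_counted must differ from allele_other")
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(sample_ids) || ncol(dosage) != nrow(variants))
    fail("dosage is %d x %d but panel has %d samples and %d variants",
         nrow(dosage), ncol(dosage), length(sample_ids), nrow(variants))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && any(bad != 0 & bad != 1 & bad != 2))
    fail("dosage entries must be 0, 1, 2 or NA")
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord, strictly = FALSE) || any(ord != seq_along(ord))) {
    log_msg("genotype_panel: variants reordered by (chrom, pos)")
    variants <- variants[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  dimnames(dosage) <- list(as.character(sample_ids), variants$variant_id)
  structure(list(variants = variants,
                 sample_ids = as.character(sample_ids),
                 dosage = dosage),
            class = "genotype_panel")
}

# fast path for internally generated data: inputs already validated and
# variant-sorted, no full-matrix scan
panel_unchecked <- function(variants, sample_ids, dosage) {
  rownames(variants) <- NULL
  dimnames(dosage) <- list(as.character(sample_ids), variants$variant_id)
  structure(list(variants = variants,
                 sample_ids = as.character(sample_ids),
                 dosage = dosage),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants (%d chromosome(s))\n",
              length(x$sample_ids), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Allele frequency and MAF of each variant in a panel
#'
#' @param panel a `genotype_panel`.
#' @return data.frame with `variant_id`, `freq_counted` (frequency of the
#'   counted allele) and `maf` (folded minor-allele frequency).
#' @export
panel_freq <- function(panel) {
  f <- colMeans(panel$dosage, na.rm = TRUE) / 2
  data.frame(variant_id = panel$variants$variant_id,
             freq_counted = as.numeric(f),
             maf = pmin(f, 1 - f),
             stringsAsFactors = FALSE)
}

#' Read a genotype panel
#'
#' `traw` is the PLINK text dosage export: tab-separated, header
#' `CHR SNP CM POS COUNTED ALT` followed by one column per sample; one row
#' per variant; dosage counts the COUNTED allele; missing is `NA`.
#' The VCF dialect reads biallelic SNP records with a GT field and counts
#' the ALT allele; non-biallelic records are skipped with a logged count.
#'
#' @param path path to the file.
#' @param dialect one of `"traw"`, `"vcf"`.
#' @return a `genotype_panel`.
#' @export
read_genotypes <- function(path, dialect = c("traw", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) fail("file not found: %s", path)
  switch(dialect, traw = read_traw(path), vcf = read_vcf_panel(path))
}

read_traw <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  exp6 <- c("CHR", "SNP", "CM", "POS", "COUNTED", "ALT")
  if (length(hdr) < 6 || !identical(hdr[1:6], exp6))
    fail("malformed traw header at line 1 of %s: expected columns %s",
         path, paste(exp6, collapse = " "))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("CHR", "SNP", "COUNTED", "ALT")),
                          na.strings = "NA", data.table = FALSE)
  sample_ids <- names(dt)[-(1:6)]
  variants <- data.frame(variant_id = dt$SNP, chrom = dt$CHR,
                         pos = as.integer(dt$POS),
                         allele_counted = dt$COUNTED, allele_other = dt$ALT,
                         stringsAsFactors = FALSE)
  dos <- if (length(sample_ids))
    t(as.matrix(dt[, -(1:6), drop = FALSE])) else
    matrix(numeric(0), 0, nrow(dt))
  genotype_panel(variants, sample_ids, dos)
}

read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  if (any(!snp))
    log_msg("read_genotypes(vcf): skipped %d non-biallelic-SNP record(s)", sum(!snp))
  if (!sum(snp)) fail("no biallelic SNP records in %s", path)
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  # ALT-allele count from unphased or phased GT
  count_alt <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(z) {
      if (length(z) != 2L || any(z == ".")) return(NA_real_)
      sum(z == "1")
    }, numeric(1))
  }
  dos <- apply(gt, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = list(NULL, colnames(gt)))
  ids <- fix[snp, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[snp, "CHROM"], ":", fix[snp, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(variant_id = ids, chrom = fix[snp, "CHROM"],
                         pos = as.integer(fix[snp, "POS"]),
                         allele_counted = alt[snp], allele_other = ref[snp],
                         stringsAsFactors = FALSE)
  genotype_panel(variants, colnames(gt), t(dos))
}

#' Write a genotype panel in traw dialect
#'
#' @param panel a `genotype_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  out <- data.frame(CHR = v$chrom, SNP = v$variant_id,
                    CM = rep(0L, nrow(v)), POS = v$pos,
                    COUNTED = v$allele_counted, ALT = v$allele_other,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (length(panel$sample_ids)) {
    dos <- as.data.frame(t(panel$dosage))
    names(dos) <- panel$sample_ids
    out <- cbind(out, dos)
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read an association summary-statistics table
#'
#' Tab-separated with header; required columns `SNP`, `CHR`, `BP`, `A1`
#' (effect/counted allele), `A2`, `SE`, `P`, `N` and either `BETA` or `OR`
#' (in which case `beta = log(OR)`); optional `MAF`.  Rows with non-finite
#' beta or P are dropped with a logged count.
#'
#' @param path path to the TSV.
#' @return a `summary_stats` data.frame with columns `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `z`, `p`, `n`,
#'   `maf` (NA when absent).
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) fail("file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  req <- c("SNP", "CHR", "BP", "A1", "A2", "SE", "P", "N")
  miss <- setdiff(req, names(dt))
  if (length(miss)) fail("summary-statistics file lacks column(s): %s",
                         paste(miss, collapse = ", "))
  if ("BETA" %in% names(dt)) {
    beta <- as.numeric(dt$BETA)
  } else if ("OR" %in% names(dt)) {
    beta <- log(as.numeric(dt$OR))
  } else fail("summary-statistics file lacks column(s): BETA (or OR)")
  p <- as.numeric(dt$P)
  keep <- is.finite(beta) & is.finite(p)
  if (any(!keep)) log_msg("read_sumstats: dropped %d row(s) with non-finite beta or P",
                          sum(!keep))
  se <- as.numeric(dt$SE)
  out <- data.frame(variant_id = as.character(dt$SNP),
                    chrom = as.character(dt$CHR),
                    pos = as.integer(dt$BP),
                    effect_allele = as.character(dt$A1),
                    other_allele = as.character(dt$A2),
                    beta = beta, se = se,
                    z = beta / se,
                    p = p,
                    n = as.numeric(dt$N),
                    maf = if ("MAF" %in% names(dt)) as.numeric(dt$MAF) else NA_real_,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write a summary-statistics table
#'
#' Inverse of [read_sumstats()]: columns SNP CHR BP A1 A2 BETA SE P N MAF.
#'
#' @param stats a `summary_stats` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- data.frame(SNP = stats$variant_id, CHR = stats$chrom, BP = stats$pos,
                    A1 = stats$effect_allele, A2 = stats$other_allele,
                    BETA = stats$beta, SE = stats$se, P = stats$p,
                    N = stats$n, MAF = stats$maf, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write any tabular result as TSV
#'
#' Header always present; column order is the data.frame order
#' (deterministic).  An empty result yields a header-only file.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  data.table::fwrite(rows, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' TSV with a `sample_id` column plus named phenotype/covariate columns.
#'
#' @param path path to the TSV.
#' @return data.frame with `sample_id` first.
#' @export
read_phenotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample_id" %in% names(dt)) fail("phenotype file lacks column: sample_id")
  dt$sample_id <- as.character(dt$sample_id)
  dt
}

#' Write a PRS vector as a scores TSV
#'
#' Columns `sample_id`, `PRS`, `N_SNPS_USED`.
#'
#' @param prs a `prs_vector` (see [prs_score()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(prs, path) {
  write_table(data.frame(sample_id = prs$sample_ids, PRS = prs$score,
                         N_SNPS_USED = prs$n_snps_used,
                         stringsAsFactors = FALSE), path)
}
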