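# Clumping + thresholding PRS: MAF and P filtering, region exclusion,
# greedy LD clumping, top-k selection, allele-matched scoring.

# deterministic ordering used everywhere a "lowest P first" scan occurs
order_by_p <- function(df) order(df$p, df$chrom, df$pos, df$variant_id)

#' Filter summary statistics before clumping
#'
#' Removes variants with MAF below `maf_min` (default 1%), P above `p_max`
#' (default 0.5), or position inside any exclusion interval (1-based,
#' inclusive on both ends — the analog of excluding everything within 1 Mb
#' of the APOE region in an AD analysis).  Non-converged or monomorphic
#' rows from [run_gwas()] are removed as well.  Counts are logged per
#' filter.
#'
#' @param stats a `summary_stats` data.frame.
#' @param maf_min minimum minor-allele frequency.
#' @param p_max maximum association P-value.
#' @param exclude_regions data.frame with `chrom`, `start`, `end` (or NULL).
#' @param maf optional numeric vector overriding the `maf` column
#'   (e.g. frequencies from an LD panel), aligned to `stats` rows.
#' @return the filtered `summary_stats`.
#' @export
filter_sumstats <- function(stats, maf_min = 0.01, p_max = 0.5,
                            exclude_regions = NULL, maf = NULL) {
  m <- maf %||% stats$maf
  drop_flag <- if (!is.null(stats$converged)) !stats$converged else rep(FALSE, nrow(stats))
  if (!is.null(stats$monomorphic)) drop_flag <- drop_flag | stats$monomorphic
  drop_maf <- !is.na(m) & m < maf_min
  drop_p <- !is.na(stats$p) & stats$p > p_max
  drop_reg <- rep(FALSE, nrow(stats))
  if (!is.null(exclude_regions) && nrow(exclude_regions)) {
    if (any(exclude_regions$start > exclude_regions$end))
      fail("exclusion region with start > end")
    for (i in seq_len(nrow(exclude_regions)))
      drop_reg <- drop_reg |
        (stats$chrom == as.character(exclude_regions$chrom[i]) &
           stats$pos >= exclude_regions$start[i] &
           stats$pos <= exclude_regions$end[i])
  }
  log_msg("filter_sumstats: removed %d (flagged) + %d (MAF < %g) + %d (P > %g) + %d (excluded region) of %d",
          sum(drop_flag), sum(drop_maf & !drop_flag), maf_min,
          sum(drop_p & !drop_flag & !drop_maf), p_max,
          sum(drop_reg & !drop_flag & !drop_maf & !drop_p), nrow(stats))
  out <- stats[!(drop_flag | drop_maf | drop_p | drop_reg), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Greedy LD clumping
#'
#' Iterates variants by ascending P (ties broken by chrom, pos, id): the
#' current variant becomes an index SNP and every not-yet-kept variant on
#' the same chromosome within `window_bp` whose dosage r-squared with the
#' index in `ld_panel` is at least `r2_max` is pruned; repeat until
#' exhausted.  This is the PLINK-style clump with window +/- 1 Mb and
#' r2 < 0.1 by default.
#'
#' @param stats filtered `summary_stats`; variants absent from `ld_panel`
#'   are dropped with a log message.
#' @param ld_panel `genotype_panel` supplying the dosages for r-squared.
#' @param window_bp half-window in basepairs.
#' @param r2_max r-squared at or above which a neighbor is pruned.
#' @return a `snp_selection` data.frame of retained variants sorted by
#'   ascending P, with columns `variant_id, chrom, pos, p, beta,
#'   effect_allele, other_allele`; attribute `n_pruned` records how many
#'   variants each index removed.
#' @export
clump <- function(stats, ld_panel, window_bp = 1e6, r2_max = 0.1) {
  in_panel <- stats$variant_id %in% ld_panel$variants$variant_id
  if (any(!in_panel))
    log_msg("clump: dropped %d variant(s) absent from the LD panel", sum(!in_panel))
  st <- stats[in_panel, , drop = FALSE]
  if (!nrow(st)) {
    warning("clump: no variants to clump; returning empty selection")
    return(empty_selection())
  }
  st <- st[order_by_p(st), , drop = FALSE]
  G <- ld_panel$dosage[, st$variant_id, drop = FALSE]
  if (anyNA(G)) {  # pairwise-complete r2 would be ill-defined; mean-impute
    cmz <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- cmz[na_idx[, 2]]
  }
  ns <- nrow(G)
  cm <- colMeans(G)
  css <- sqrt(pmax(colSums(G * G) - ns * cm^2, 0))  # ||g - mean(g)||
  n <- nrow(st)
  alive <- rep(TRUE, n)
  kept <- logical(n)
  pruned_by <- integer(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    nb <- which(alive & st$chrom == st$chrom[i] &
                  abs(st$pos - st$pos[i]) <= window_bp)
    if (length(nb)) {
      num <- as.numeric(crossprod(G[, i], G[, nb, drop = FALSE])) -
        ns * cm[i] * cm[nb]
      r2 <- (num / (css[i] * css[nb]))^2
      r2[!is.finite(r2)] <- 0   # monomorphic neighbor or index
      kill <- nb[r2 >= r2_max]
      alive[kill] <- FALSE
      pruned_by[i] <- length(kill)
    }
  }
  sel <- st[kept, c("variant_id", "chrom", "pos", "p", "beta",
                    "effect_allele", "other_allele"), drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("snp_selection", "data.frame")
  attr(sel, "n_pruned") <- sum(pruned_by)
  sel
}

empty_selection <- function() {
  sel <- data.frame(variant_id = character(0), chrom = character(0),
                    pos = integer(0), p = numeric(0), beta = numeric(0),
                    effect_allele = character(0), other_allele = character(0),
                    stringsAsFactors = FALSE)
  class(sel) <- c("snp_selection", "data.frame")
  sel
}

#' Keep the top-k lowest-P SNPs of a selection
#'
#' @param selection a `snp_selection`.
#' @param k number of SNPs to keep (`k >= 0`); ties broken by (chrom, pos).
#' @return the truncated `snp_selection`.
#' @export
select_top <- function(selection, k) {
  stopifnot(k >= 0)
  sel <- selection[order_by_p(selection), , drop = FALSE]
  sel <- sel[seq_len(min(k, nrow(sel))), , drop = FALSE]
  rownames(sel) <- NULL
  class(sel) <- c("snp_selection", "data.frame")
  sel
}

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Score a genotype panel with a SNP selection
#'
#' Per sample, `score = sum_j beta_j * dosage_j(effect allele)`.  If the
#' panel counts the other allele the dosage is reflected (`2 - d`).
#' Strand-ambiguous SNPs (A/T, C/G) and SNPs absent from the panel or with
#' unmatchable alleles are dropped with a log message.  Missing dosages are
#' imputed as `2 x` the effect-allele frequency in the panel (PLINK
#' `--score` mean imputation); `n_snps_used` counts SNPs with an observed
#' dosage per sample.
#'
#' @param panel a `genotype_panel` of the cohort to score.
#' @param selection a `snp_selection` with `beta` and `effect_allele`.
#' @return an object of class `prs_vector`: `sample_ids`, `score`,
#'   `n_snps_used`, and the `snp_report` data.frame of per-SNP fates.
#' @export
prs_score <- function(panel, selection) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$sample_ids)
  fate <- rep("used", nrow(selection))
  idx <- match(selection$variant_id, panel$variants$variant_id)
  fate[is.na(idx)] <- "absent"
  amb <- is_ambiguous_pair(selection$effect_allele, selection$other_allele)
  fate[amb & fate == "used"] <- "ambiguous"
  flip <- rep(FALSE, nrow(selection))
  ok <- which(fate == "used")
  for (j in ok) {
    pa <- panel$variants$allele_counted[idx[j]]
    pb <- panel$variants$allele_other[idx[j]]
    if (selection$effect_allele[j] == pa && selection$other_allele[j] == pb) {
      # direct match
    } else if (selection$effect_allele[j] == pb && selection$other_allele[j] == pa) {
      flip[j] <- TRUE
    } else fate[j] <- "allele_mismatch"
  }
  used <- which(fate == "used")
  if (length(used) < nrow(selection))
    log_msg("prs_score: dropped %d SNP(s): %s", nrow(selection) - length(used),
            paste(sprintf("%s=%d", names(table(fate[fate != "used"])),
                          as.integer(table(fate[fate != "used"]))), collapse = ", "))
  if (!length(used)) fail("prs_score: zero usable SNPs after allele matching")
  D <- panel$dosage[, idx[used], drop = FALSE]
  if (any(flip[used])) {
    fcols <- which(flip[used])
    D[, fcols] <- 2 - D[, fcols, drop = FALSE]
  }
  n_obs <- rowSums(!is.na(D))
  if (anyNA(D)) {
    ef <- colMeans(D, na.rm = TRUE) / 2     # effect-allele frequency
    na_idx <- which(is.na(D), arr.ind = TRUE)
    D[na_idx] <- 2 * ef[na_idx[, 2]]
  }
  score <- as.numeric(D %*% selection$beta[used])
  structure(list(sample_ids = panel$sample_ids, score = score,
                 n_snps_used = n_obs,
                 snp_report = data.frame(variant_id = selection$variant_id,
                                         fate = fate, flipped = flip,
                                         stringsAsFactors = FALSE)),
            class = "prs_vector")
}

#' @export
print.prs_vector <- function(x, ...) {
  cat(sprintf("prs_vector: %d samples, %d SNPs scored (mean score %.4g)\n",
              length(x$sample_ids), sum(x$snp_report$fate == "used"),
              mean(x$score)))
  invisible(x)
}
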