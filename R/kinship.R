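# PLINK-style method-of-moments IBD estimation from IBS counts
# (Purcell et al. 2007 --genome scheme): expected IBS-state counts given
# IBD state under HWE with plug-in allele frequencies, solved for
# P(IBD=0/1/2), clamped to [0,1] and renormalized; PI_HAT = P2 + P1/2.

#' IBS state counts for one sample pair
#'
#' Per locus, IBS = `2 - |d1 - d2|` for dosages in `{0,1,2}`; loci missing
#' in either sample are excluded.
#'
#' @param g1,g2 dosage vectors of equal length.
#' @return named integer vector `c(ibs0, ibs1, ibs2)`.
#' @export
ibs_counts <- function(g1, g2) {
  if (length(g1) != length(g2)) fail("dosage vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  d <- abs(g1[ok] - g2[ok])
  c(ibs0 = sum(d == 2), ibs1 = sum(d == 1), ibs2 = sum(d == 0))
}

# per-locus IBS-state probabilities given IBD state under HWE at
# counted-allele frequency p (q = 1-p):
#   P(IBS0|IBD0) = 2 p^2 q^2
#   P(IBS1|IBD0) = 4 p^3 q + 4 p q^3
#   P(IBS1|IBD1) = 2 p^2 q + 2 p q^2
# complements give the IBS2 rows; IBD1 cannot show IBS0; IBD2 is always IBS2.
ibs_given_ibd <- function(p) {
  q <- 1 - p
  e0_0 <- 2 * p^2 * q^2
  e1_0 <- 4 * p^3 * q + 4 * p * q^3
  e2_0 <- 1 - e0_0 - e1_0
  e1_1 <- 2 * p^2 * q + 2 * p * q^2
  e2_1 <- 1 - e1_1
  list(e0_0 = e0_0, e1_0 = e1_0, e2_0 = e2_0, e1_1 = e1_1, e2_1 = e2_1)
}

# cross-panel IBS counts via indicator-matrix crossproducts (BLAS-bound):
# N_ab[i,j] = #loci with dosage a in A-sample i and b in B-sample j
cross_ibs <- function(A, B) {
  ind <- function(M, v) {
    X <- (M == v); X[is.na(X)] <- FALSE; storage.mode(X) <- "double"; X
  }
  A0 <- ind(A, 0); A1 <- ind(A, 1); A2 <- ind(A, 2)
  B0 <- ind(B, 0); B1 <- ind(B, 1); B2 <- ind(B, 2)
  ibs0 <- tcrossprod(A0, B2) + tcrossprod(A2, B0)
  ibs1 <- tcrossprod(A0, B1) + tcrossprod(A1, B0) +
    tcrossprod(A1, B2) + tcrossprod(A2, B1)
  ibs2 <- tcrossprod(A0, B0) + tcrossprod(A1, B1) + tcrossprod(A2, B2)
  list(ibs0 = ibs0, ibs1 = ibs1, ibs2 = ibs2)
}

#' Estimate pairwise IBD proportions (PI_HAT) across two panels
#'
#' For every cross-panel sample pair, observed IBS-state counts over the
#' shared MAF-filtered variants are compared with their HWE expectations
#' (allele frequencies pooled over both panels unless `freq_counted` is
#' supplied) to give moment estimates of P(IBD=0/1/2) and
#' `PI_HAT = P(IBD=2) + P(IBD=1)/2`.  Variants present in both panels with
#' swapped counted/other alleles are reflected; allele-incompatible
#' variants are dropped with a log message.  Pairs with fewer than 100
#' informative loci are flagged `unstable`.
#'
#' @param panel_a,panel_b `genotype_panel` objects (may be the same panel).
#' @param maf_min minimum pooled MAF for a locus to be used.
#' @param freq_counted optional named vector of external counted-allele
#'   frequencies (names = variant IDs) replacing the pooled estimate.
#' @param min_pi_hat only pairs with `pi_hat >= min_pi_hat` are returned
#'   (use `-Inf`, the default, for the full table).
#' @param max_loci if finite, at most this many shared loci are used,
#'   subsampled deterministically under `seed` (keeps all-pairs scans on
#'   large panels affordable; duplicates and first-degree relatives are
#'   separable from a few thousand loci).
#' @param seed seed for the locus subsample.
#' @return a `kinship_table` data.frame: `id1, id2, ibs0, ibs1, ibs2,
#'   p_ibd0, p_ibd1, p_ibd2, pi_hat, n_loci_used, unstable`.
#' @export
estimate_pi_hat <- function(panel_a, panel_b, maf_min = 0.01,
                            freq_counted = NULL, min_pi_hat = -Inf,
                            max_loci = Inf, seed = 1L) {
  shared <- intersect(panel_a$variants$variant_id, panel_b$variants$variant_id)
  if (!length(shared)) fail("no shared variants between panels")
  ia <- match(shared, panel_a$variants$variant_id)
  ib <- match(shared, panel_b$variants$variant_id)
  va <- panel_a$variants[ia, ]; vb <- panel_b$variants[ib, ]
  direct <- va$allele_counted == vb$allele_counted & va$allele_other == vb$allele_other
  swapped <- va$allele_counted == vb$allele_other & va$allele_other == vb$allele_counted
  usable <- direct | swapped
  if (any(!usable))
    log_msg("estimate_pi_hat: dropped %d allele-incompatible shared variant(s)",
            sum(!usable))
  shared <- shared[usable]; ia <- ia[usable]; ib <- ib[usable]
  swapped <- swapped[usable]
  A <- panel_a$dosage[, ia, drop = FALSE]
  B <- panel_b$dosage[, ib, drop = FALSE]
  if (any(swapped)) B[, swapped] <- 2 - B[, swapped, drop = FALSE]
  if (is.null(freq_counted)) {
    p <- (colSums(A, na.rm = TRUE) + colSums(B, na.rm = TRUE)) /
      (2 * (colSums(!is.na(A)) + colSums(!is.na(B))))
  } else {
    p <- unname(freq_counted[shared])
    if (anyNA(p)) fail("freq_counted lacks %d shared variant(s)", sum(is.na(p)))
  }
  keep <- pmin(p, 1 - p) >= maf_min
  if (!sum(keep)) fail("no shared variants pass the MAF filter")
  A <- A[, keep, drop = FALSE]; B <- B[, keep, drop = FALSE]; p <- p[keep]
  if (is.finite(max_loci) && ncol(A) > max_loci) {
    set.seed(seed)
    sub <- sort(sample.int(ncol(A), max_loci))
    A <- A[, sub, drop = FALSE]; B <- B[, sub, drop = FALSE]; p <- p[sub]
  }
  ex <- ibs_given_ibd(p)
  cc <- cross_ibs(A, B)
  complete <- !anyNA(A) && !anyNA(B)
  if (complete) {
    E0_0 <- sum(ex$e0_0); E1_0 <- sum(ex$e1_0); E2_0 <- sum(ex$e2_0)
    E1_1 <- sum(ex$e1_1); E2_1 <- sum(ex$e2_1)
    M <- matrix(ncol(A), nrow(A), nrow(B))
  } else {
    # per-pair expectations restricted to the loci observed in both samples
    Aok <- !is.na(A); storage.mode(Aok) <- "double"
    Bok <- !is.na(B); storage.mode(Bok) <- "double"
    wsum <- function(w) tcrossprod(Aok * rep(w, each = nrow(Aok)), Bok)
    E0_0 <- wsum(ex$e0_0); E1_0 <- wsum(ex$e1_0); E2_0 <- wsum(ex$e2_0)
    E1_1 <- wsum(ex$e1_1); E2_1 <- wsum(ex$e2_1)
    M <- tcrossprod(Aok, Bok)
  }
  P0 <- cc$ibs0 / E0_0
  P1 <- (cc$ibs1 - P0 * E1_0) / E1_1
  P2 <- (cc$ibs2 - P0 * E2_0 - P1 * E2_1) / M
  P0 <- pmin(pmax(P0, 0), 1); P1 <- pmin(pmax(P1, 0), 1); P2 <- pmin(pmax(P2, 0), 1)
  tot <- P0 + P1 + P2
  P0 <- P0 / tot; P1 <- P1 / tot; P2 <- P2 / tot
  pihat <- P2 + 0.5 * P1
  out <- data.frame(id1 = rep(panel_a$sample_ids, times = ncol(pihat)),
                    id2 = rep(panel_b$sample_ids, each = nrow(pihat)),
                    ibs0 = as.integer(cc$ibs0), ibs1 = as.integer(cc$ibs1),
                    ibs2 = as.integer(cc$ibs2),
                    p_ibd0 = as.numeric(P0), p_ibd1 = as.numeric(P1),
                    p_ibd2 = as.numeric(P2), pi_hat = as.numeric(pihat),
                    n_loci_used = as.integer(M),
                    stringsAsFactors = FALSE)
  out$unstable <- out$n_loci_used < 100L
  if (any(out$unstable))
    log_msg("estimate_pi_hat: %d pair(s) flagged unstable (< 100 informative loci)",
            sum(out$unstable))
  out <- out[out$pi_hat >= min_pi_hat, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kinship_table", "data.frame")
  out
}

#' Remove test subjects genetically close to the discovery cohort
#'
#' Every test subject whose maximum cross-cohort PI_HAT reaches
#' `pi_hat_cutoff` is removed (cutoff 1 catches only duplicates/MZ twins;
#' lower cutoffs additionally sweep out first-degree relatives).
#'
#' @param test,discovery `prs_cohort` objects sharing a variant set.
#' @param pi_hat_cutoff removal threshold in `(0, 1]`; values above 1
#'   trivially remove nothing.
#' @param maf_min,max_loci,seed passed to [estimate_pi_hat()].
#' @return list with `cohort` (the pruned test `prs_cohort`) and `removed`
#'   (data.frame `test_id, best_match_discovery_id, pi_hat`).
#' @export
prune_overlap <- function(test, discovery, pi_hat_cutoff, maf_min = 0.01,
                          max_loci = Inf, seed = 1L) {
  if (pi_hat_cutoff <= 0) fail("pi_hat_cutoff must be positive")
  kin <- estimate_pi_hat(test$panel, discovery$panel, maf_min = maf_min,
                         min_pi_hat = pi_hat_cutoff, max_loci = max_loci,
                         seed = seed)
  removed <- data.frame(test_id = character(0),
                        best_match_discovery_id = character(0),
                        pi_hat = numeric(0), stringsAsFactors = FALSE)
  if (nrow(kin)) {
    best <- do.call(rbind, lapply(split(kin, kin$id1), function(d)
      d[which.max(d$pi_hat), c("id1", "id2", "pi_hat")]))
    removed <- data.frame(test_id = best$id1,
                          best_match_discovery_id = best$id2,
                          pi_hat = best$pi_hat, stringsAsFactors = FALSE)
    removed <- removed[order(removed$test_id), , drop = FALSE]
    rownames(removed) <- NULL
  }
  keep <- setdiff(test$panel$sample_ids, removed$test_id)
  if (!length(keep))
    fail("pruning at PI_HAT >= %g removed every test subject; raise the cutoff",
         pi_hat_cutoff)
  list(cohort = cohort_subset(test, keep), removed = removed)
}
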