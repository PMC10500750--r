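# shared fixture builders and independent oracles

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# hand-written 3-sample x 4-variant panel exercising allele flips,
# ambiguity and missingness in scoring tests
tiny_panel <- function() {
  variants <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = c("1", "1", "1", "2"),
    pos = c(100L, 2000L, 500000L, 100L),
    allele_counted = c("A", "C", "A", "C"),
    allele_other = c("G", "T", "T", "G"),   # rs3 = A/T, rs4 = C/G: ambiguous
    stringsAsFactors = FALSE)
  dosage <- rbind(c(2, 1, 0, 1),
                  c(0, 2, 1, 0),
                  c(1, NA, 2, 2))
  genotype_panel(variants, c("s1", "s2", "s3"), dosage)
}

# minimal summary_stats construction for prs-module tests
make_stats <- function(variant_id, chrom, pos, p, beta = 0.1,
                       effect_allele = "A", other_allele = "G", maf = 0.3) {
  out <- data.frame(variant_id = variant_id, chrom = as.character(chrom),
                    pos = as.integer(pos),
                    effect_allele = effect_allele, other_allele = other_allele,
                    beta = beta, se = 0.05, z = beta / 0.05, p = p,
                    n = 1000, maf = maf, stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

# independent brute-force clumping oracle: after every index selection the
# whole remaining list is re-scanned (no shared code with clump())
oracle_clump <- function(stats, panel, window_bp = 1e6, r2_max = 0.1) {
  remaining <- stats[order(stats$p, stats$chrom, stats$pos, stats$variant_id), ]
  kept <- character(0)
  while (nrow(remaining)) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$variant_id)
    drop <- rep(FALSE, nrow(remaining))
    drop[1] <- TRUE
    near <- which(remaining$chrom == idx$chrom &
                    abs(remaining$pos - idx$pos) <= window_bp & !drop)
    for (i in near) {
      r <- cor(panel$dosage[, idx$variant_id],
               panel$dosage[, remaining$variant_id[i]])
      if (!is.na(r) && r^2 >= r2_max) drop[i] <- TRUE
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# small simulated cohort pair for pipeline-level tests
small_pair <- function(n_disc = 600, n_test = 300, m = 800, h2 = 0.4,
                       trait_type = "binary", seed = 5, rho = 0.6,
                       n_causal = 60) {
  cfg <- sim_config(n_samples = n_disc + n_test, n_variants = m,
                    block_size = 20, rho = rho,
                    n_causal = min(n_causal, max(3, m %/% 5)),
                    h2 = h2, prevalence = 0.314, trait_type = trait_type,
                    seed = seed)
  panel <- simulate_genotypes(cfg)
  eff <- assign_effects(panel, cfg)
  ph <- simulate_phenotype(eff, cfg)
  pair <- build_cohorts(panel, ph, n_disc, n_test, 0, seed = seed + 1)
  list(cfg = cfg, panel = panel, effects = eff, pheno = ph, pair = pair)
}
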