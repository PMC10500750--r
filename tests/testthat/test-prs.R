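test_that("summary-statistic filters apply the MAF, P and region rules", {
  st <- make_stats(paste0("rs", 1:5), chrom = "1",
                   pos = c(100, 500, 1000, 1500, 2000),
                   p = c(0.01, 0.6, 0.2, 0.3, 0.4),
                   maf = c(0.005, 0.3, 0.3, 0.3, 0.3))
  out <- quiet(filter_sumstats(st))
  expect_setequal(out$variant_id, c("rs3", "rs4", "rs5"))  # maf + p filters

  # exclusion interval inclusive on both ends (1-based)
  reg <- data.frame(chrom = "1", start = 1000, end = 1500)
  out2 <- quiet(filter_sumstats(st, exclude_regions = reg))
  expect_setequal(out2$variant_id, "rs5")     # rs3 at start, rs4 at end removed
  expect_error(filter_sumstats(st, exclude_regions = data.frame(
    chrom = "1", start = 10, end = 5)), "start > end")

  # flagged rows from the association scan are dropped
  st$converged <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_false("rs3" %in% quiet(filter_sumstats(st))$variant_id)
})

test_that("greedy clumping keeps the lowest-P SNP per LD neighborhood", {
  set.seed(31)
  n <- 300
  g1 <- rbinom(n, 2, 0.3)
  noise <- rbinom(n, 2, 0.3)
  v <- data.frame(variant_id = c("a", "b", "c"), chrom = c("1", "1", "2"),
                  pos = c(1000L, 2000L, 1000L),
                  allele_counted = "A", allele_other = "G")
  panel <- genotype_panel(v, sprintf("i%d", 1:n), cbind(g1, g1, noise))
  st <- make_stats(c("a", "b", "c"), c("1", "1", "2"), c(1000, 2000, 1000),
                   p = c(1e-8, 1e-4, 1e-5))
  sel <- clump(st, panel)
  expect_setequal(sel$variant_id, c("a", "c"))  # b pruned by a (r2 = 1)
  expect_equal(sel$variant_id[1], "a")          # sorted ascending p

  # single SNP passes through
  expect_equal(clump(st[1, ], panel)$variant_id, "a")
  # identical genotypes on another chromosome are not clumped together
  panel2 <- genotype_panel(v, sprintf("i%d", 1:n), cbind(g1, noise, g1))
  expect_setequal(clump(st, panel2)$variant_id, c("a", "b", "c"))
})

test_that("greedy clump matches the brute-force rescan oracle on random instances", {
  cfg <- sim_config(n_samples = 250, n_variants = 100, block_size = 10,
                    rho = 0.7, n_causal = 10, maf_range = c(0.05, 0.5), seed = 32)
  panel <- simulate_genotypes(cfg)
  for (r in 1:10) {
    set.seed(100 + r)
    st <- make_stats(panel$variants$variant_id, panel$variants$chrom,
                     panel$variants$pos, p = runif(100))
    sel <- clump(st, panel, window_bp = 100000, r2_max = 0.2)
    expect_identical(sel$variant_id,
                     oracle_clump(st, panel, window_bp = 100000, r2_max = 0.2))
    # post-hoc invariant: retained pairs within the window have r2 < r2_max
    if (nrow(sel) > 1) {
      for (i in seq_len(nrow(sel) - 1)) for (j in (i + 1):nrow(sel)) {
        if (sel$chrom[i] == sel$chrom[j] &&
            abs(sel$pos[i] - sel$pos[j]) <= 100000) {
          r2 <- cor(panel$dosage[, sel$variant_id[i]],
                    panel$dosage[, sel$variant_id[j]])^2
          expect_lt(r2, 0.2)
        }
      }
    }
  }
})

test_that("select_top truncates by ascending P with deterministic ties", {
  st <- make_stats(c("a", "b", "c"), c("2", "1", "1"), c(5, 9, 3),
                   p = c(0.01, 0.01, 0.5))
  sel <- st; class(sel) <- c("snp_selection", "data.frame")
  expect_equal(nrow(select_top(sel, 0)), 0)
  expect_equal(select_top(sel, 10)$variant_id, c("b", "a", "c"))  # tie: chrom/pos
  expect_equal(select_top(sel, 1)$variant_id, "b")
})

test_that("scoring matches alleles, reflects swaps, drops ambiguous SNPs", {
  panel <- tiny_panel()
  # rs1 direct match: beta 0.5, dosages 2/0/1
  sel <- make_stats("rs1", "1", 100, p = 0.01, beta = 0.5,
                    effect_allele = "A", other_allele = "G")
  class(sel) <- c("snp_selection", "data.frame")
  prs <- prs_score(panel, sel)
  expect_equal(prs$score, c(1.0, 0.0, 0.5))

  # swapped alleles: dosage reflected to 2 - d
  sel2 <- make_stats("rs1", "1", 100, p = 0.01, beta = 0.5,
                     effect_allele = "G", other_allele = "A")
  class(sel2) <- c("snp_selection", "data.frame")
  expect_equal(prs_score(panel, sel2)$score, 0.5 * (2 - c(2, 0, 1)))

  # ambiguous A/T SNP dropped; with nothing left scoring errors
  sel3 <- make_stats("rs3", "1", 500000, p = 0.01, beta = 1,
                     effect_allele = "A", other_allele = "T")
  class(sel3) <- c("snp_selection", "data.frame")
  expect_error(quiet(prs_score(panel, sel3)), "zero usable")

  # allele mismatch dropped with a log message
  sel4 <- rbind(sel, make_stats("rs2", "1", 2000, p = 0.1, beta = 1,
                                effect_allele = "A", other_allele = "C"))
  class(sel4) <- c("snp_selection", "data.frame")
  expect_message(p4 <- prs_score(panel, sel4), "allele_mismatch")
  expect_equal(p4$score, prs$score)
})

test_that("missing dosages are mean-imputed and n_snps_used reflects observation", {
  panel <- tiny_panel()
  sel <- make_stats("rs2", "1", 2000, p = 0.01, beta = 1,
                    effect_allele = "C", other_allele = "T")
  class(sel) <- c("snp_selection", "data.frame")
  prs <- prs_score(panel, sel)
  # s3 has NA at rs2; effect-allele frequency from observed (1+2)/4
  expect_equal(prs$score, c(1, 2, 2 * 0.75))
  expect_equal(prs$n_snps_used, c(1L, 1L, 0L), ignore_attr = TRUE)
})

test_that("scores are linear in the effect sizes", {
  s <- small_pair(n_disc = 200, n_test = 100, m = 50, seed = 33)
  panel <- s$pair$test$panel
  st <- make_stats(panel$variants$variant_id[1:20], panel$variants$chrom[1:20],
                   panel$variants$pos[1:20], p = runif(20),
                   beta = rnorm(20, 0, 0.1))
  class(st) <- c("snp_selection", "data.frame")
  p1 <- prs_score(panel, st)
  st2 <- st; st2$beta <- 2 * st$beta
  expect_equal(prs_score(panel, st2)$score, 2 * p1$score)
  st0 <- st; st0$beta <- 0
  expect_true(all(prs_score(panel, st0)$score == 0))
})
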