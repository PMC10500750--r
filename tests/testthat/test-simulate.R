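test_that("configuration rejects invalid parameter ranges", {
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(n_variants = 10, n_causal = 20), "n_causal")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(covariate_spec = list(bmi = 1)), "bmi")
})

test_that("genotype simulation is seed-deterministic and HWE-consistent", {
  cfg <- sim_config(n_samples = 300, n_variants = 60, n_causal = 5, seed = 2)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosage, p2$dosage)
  p3 <- simulate_genotypes(sim_config(n_samples = 300, n_variants = 60,
                                      n_causal = 5, seed = 3))
  expect_false(identical(p1$dosage, p3$dosage))
  expect_true(all(p1$dosage %in% 0:2))
  # realized counted-allele frequencies track the drawn MAFs
  expect_lt(max(abs(colMeans(p1$dosage) / 2 - attr(p1, "maf_true"))), 0.12)
})

test_that("LD copula: independent blocks at rho = 0, strong LD at rho = 0.9", {
  cfg0 <- sim_config(n_samples = 2000, n_variants = 50, block_size = 10,
                     rho = 0, n_causal = 5, seed = 4)
  cc <- cor(simulate_genotypes(cfg0)$dosage)
  expect_lt(mean(cc[upper.tri(cc)]^2), 0.01)

  cfg9 <- sim_config(n_samples = 5000, n_variants = 40, block_size = 20,
                     rho = 0.9, n_causal = 5, seed = 4)
  d <- simulate_genotypes(cfg9)$dosage
  within <- cor(d[, 1], d[, 2])
  expect_gt(within, 0.5)
  # cross-block LD decays to nothing
  expect_lt(mean(cor(d[, 1:20], d[, 21:40])^2), 0.01)
})

test_that("effect assignment respects h2 and the causal count", {
  cfg <- sim_config(n_samples = 500, n_variants = 100, n_causal = 10,
                    h2 = 0, seed = 6)
  eff <- assign_effects(simulate_genotypes(cfg), cfg)
  expect_true(all(eff$beta_true == 0))
  expect_true(all(eff$g == 0))

  cfg1 <- sim_config(n_samples = 500, n_variants = 100, n_causal = 1,
                     h2 = 0.5, seed = 6)
  eff1 <- assign_effects(simulate_genotypes(cfg1), cfg1)
  expect_equal(sum(eff1$beta_true != 0), 1)

  # realized liability R2 close to configured h2 at large n
  cfg2 <- sim_config(n_samples = 20000, n_variants = 400, n_causal = 100,
                     h2 = 0.5, seed = 7)
  eff2 <- assign_effects(simulate_genotypes(cfg2), cfg2)
  r2 <- summary(lm(eff2$liability ~ eff2$g))$r.squared
  expect_gt(r2, 0.45); expect_lt(r2, 0.55)
})

test_that("liability thresholding hits the configured prevalence", {
  cfg <- sim_config(n_samples = 20000, n_variants = 200, n_causal = 50,
                    h2 = 0.3, prevalence = 0.25, seed = 8)
  ph <- simulate_phenotype(assign_effects(simulate_genotypes(cfg), cfg), cfg)
  expect_gt(mean(ph$phenotype), 0.24)
  expect_lt(mean(ph$phenotype), 0.26)
  expect_true(attr(ph, "trait_type") == "binary")

  # degenerate prevalence at small n errors with advice
  cfg2 <- sim_config(n_samples = 50, n_variants = 50, n_causal = 5,
                     prevalence = 1e-4, seed = 8)
  expect_error(simulate_phenotype(assign_effects(simulate_genotypes(cfg2), cfg2), cfg2),
               "larger n")
})

test_that("covariates only influence the phenotype when given an effect", {
  base <- list(n_samples = 4000, n_variants = 50, n_causal = 5, h2 = 0.2,
               trait_type = "quantitative", seed = 9)
  cfg0 <- do.call(sim_config, c(base, list(covariate_spec = list(sex = 0))))
  ph0 <- simulate_phenotype(assign_effects(simulate_genotypes(cfg0), cfg0), cfg0)
  expect_gt(t.test(ph0$phenotype ~ ph0$sex)$p.value, 0.001)

  cfg1 <- do.call(sim_config, c(base, list(covariate_spec = list(sex = 1))))
  ph1 <- simulate_phenotype(assign_effects(simulate_genotypes(cfg1), cfg1), cfg1)
  expect_lt(t.test(ph1$phenotype ~ ph1$sex)$p.value, 1e-10)
})

test_that("cohort construction delivers the requested overlap exactly", {
  cfg <- sim_config(n_samples = 1200, n_variants = 40, n_causal = 5, seed = 10)
  panel <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(assign_effects(panel, cfg), cfg)

  cp0 <- build_cohorts(panel, ph, 500, 400, 0, seed = 1)
  expect_length(cp0$overlap_ids, 0)
  expect_length(intersect(cp0$discovery$panel$sample_ids,
                          cp0$test$panel$sample_ids), 0)

  cp1 <- build_cohorts(panel, ph, 500, 400, 1, seed = 1)
  expect_true(all(cp1$test$panel$sample_ids %in% cp1$discovery$panel$sample_ids))

  cp5 <- build_cohorts(panel, ph, 500, 692, 0.5, seed = 1)
  expect_length(cp5$overlap_ids, 346)
  # overlapping subjects are verbatim copies (same genotype and phenotype)
  sid <- cp5$overlap_ids[1]
  expect_identical(cp5$discovery$panel$dosage[sid, ], cp5$test$panel$dosage[sid, ])

  expect_error(build_cohorts(panel, ph, 1000, 400, 0, seed = 1), "pool")
})

test_that("inject_overlap preserves test size and replaces verbatim", {
  s <- small_pair(n_disc = 300, n_test = 150, m = 100, seed = 12)
  t0 <- inject_overlap(s$pair$test, s$pair$discovery, 0, seed = 1)
  expect_identical(t0, s$pair$test)
  for (f in c(0.25, 0.6, 1)) {
    tf <- inject_overlap(s$pair$test, s$pair$discovery, f, seed = 2)
    expect_length(tf$panel$sample_ids, 150)
    inc <- intersect(tf$panel$sample_ids, s$pair$discovery$panel$sample_ids)
    expect_length(inc, round(f * 150))
    expect_identical(tf$panel$dosage[inc, , drop = FALSE],
                     s$pair$discovery$panel$dosage[inc, , drop = FALSE])
  }
  expect_error(inject_overlap(s$pair$test, s$pair$discovery, 1.5), "fraction")
})

test_that("spawn_relative produces duplicates and Mendelian relatives", {
  set.seed(1)
  m <- 3000
  fr <- runif(m, 0.1, 0.5)
  g <- rbinom(m, 2, fr)
  expect_identical(spawn_relative(g, "duplicate", fr, 1), g)
  po <- spawn_relative(g, "parent_offspring", fr, 2)
  # offspring shares at least one allele with the parent at every locus
  expect_true(all(abs(po - g) < 2))
  expect_error(spawn_relative(g, "cousin", fr, 1))
  expect_error(spawn_relative(c(g, NA), "parent_offspring", c(fr, 0.2), 1),
               "complete")
})
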