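# Orchestration of the study designs over the simulator and the analysis
# stack: contamination sweep, discovery-scale effect, SNP-count sweep,
# test-size power curve, case:control-ratio sweep, and the
# contaminate-then-prune repair check.  Every grid cell gets its own seed
# derived from the master seed by a counter, recorded in the output, so any
# cell is re-runnable in isolation.

new_grid <- function(design, axis, cells, summary, params) {
  structure(list(design = design, axis = axis, cells = cells,
                 summary = summary, params = params),
            class = "prs_experiment_grid")
}

#' @export
print.prs_experiment_grid <- function(x, ...) {
  cat(sprintf("prs_experiment_grid '%s' over %s: %d cell(s), %d grid point(s)\n",
              x$design, x$axis, nrow(x$cells), nrow(x$summary)))
  print(x$summary, digits = 4)
  invisible(x)
}

# simulate a pool and split it into disjoint discovery/test cohorts
sim_cohort_pair <- function(config, n_discovery, n_test, seed) {
  cfg <- config
  cfg$n_samples <- as.integer(n_discovery + n_test)
  cfg$seed <- seed
  panel <- simulate_genotypes(cfg)
  eff <- assign_effects(panel, cfg)
  pheno <- simulate_phenotype(eff, cfg)
  pair <- build_cohorts(panel, pheno, n_discovery, n_test,
                        overlap_fraction = 0, seed = derive_seed(seed, 9L))
  list(pair = pair, effects = eff, panel = panel)
}

# discovery phase: GWAS -> MAF/P filter -> clump
train_selection <- function(discovery, trait_type,
                            gwas_covariates = character(),
                            maf_min = 0.01, p_max = 0.5,
                            window_bp = 1e6, r2_max = 0.1) {
  ss <- suppressMessages(run_gwas(discovery$panel, discovery$pheno,
                                  gwas_covariates, trait_type))
  fss <- suppressMessages(filter_sumstats(ss, maf_min = maf_min, p_max = p_max))
  suppressMessages(clump(fss, discovery$panel,
                         window_bp = window_bp, r2_max = r2_max))
}

zero_prs <- function(panel) {
  structure(list(sample_ids = panel$sample_ids,
                 score = numeric(length(panel$sample_ids)),
                 n_snps_used = integer(length(panel$sample_ids)),
                 snp_report = data.frame(variant_id = character(0),
                                         fate = character(0),
                                         flipped = logical(0))),
            class = "prs_vector")
}

score_or_zero <- function(panel, selection) {
  if (!nrow(selection)) return(zero_prs(panel))
  suppressMessages(prs_score(panel, selection))
}

# score + PCs + Model II/III evaluation of one test cohort
eval_cohort <- function(selection, test, trait_type,
                        covariate_names = c("age", "sex"), n_pcs = 20,
                        pcs = NULL) {
  prs <- score_or_zero(test$panel, selection)
  if (is.null(pcs)) pcs <- compute_pcs(test$panel, n_pcs)
  suppressWarnings(suppressMessages(
    evaluate(prs, test$pheno, pcs, trait_type,
             covariate_names = covariate_names, n_pcs = n_pcs)))
}

metrics_row <- function(dm) {
  data.frame(delta_auc = dm$delta_auc, delong_p = dm$delong_p,
             delta_r2 = dm$delta_r2, r2_p = dm$r2_p,
             neglog10_p = -log10(max(if (dm$trait_type == "binary")
               dm$delong_p else dm$r2_p, 1e-300)))
}

summarize_grid <- function(cells, by = "point") {
  agg <- function(col) {
    sp <- split(cells[[col]], cells[[by]])
    data.frame(point = as.numeric(names(sp)),
               mean = vapply(sp, mean, numeric(1), na.rm = TRUE),
               sd = vapply(sp, sd, numeric(1)),
               n = vapply(sp, function(z) sum(!is.na(z)), numeric(1)))
  }
  metric <- if (all(is.na(cells$delta_auc))) "delta_r2" else "delta_auc"
  a <- agg(metric)
  out <- data.frame(point = a$point,
                    mean_delta_auc = if (metric == "delta_auc") a$mean else NA_real_,
                    sd_delta_auc = if (metric == "delta_auc") a$sd else NA_real_,
                    mean_delta_r2 = agg("delta_r2")$mean,
                    sd_delta_r2 = agg("delta_r2")$sd,
                    mean_neglog10_p = agg("neglog10_p")$mean,
                    n_replicates = a$n)
  out[order(out$point), , drop = FALSE]
}

#' Contamination sweep: subject overlap from 0 to 100%
#'
#' Per replicate a pool is simulated and split into a discovery set and an
#' initially independent test set; the discovery GWAS + clumping + scoring
#' model is trained once, then for each overlap fraction the test set is
#' contaminated with discovery subjects by [inject_overlap()] and
#' re-evaluated.  A single-covariate reference model (the dosage of the
#' strongest causal variant, a stand-in for a known major risk locus such
#' as APOE e4) is evaluated alongside as a stability control: its gain
#' should not depend on the overlap.
#'
#' @param config a [sim_config()] (binary trait for the AUC metrics).
#' @param fractions overlap fractions, default `seq(0, 1, 0.1)`.
#' @param replicates number of replicates.
#' @param n_discovery,n_test cohort sizes.
#' @param covariate_names evaluation covariates.
#' @param gwas_covariates discovery-phase covariates.
#' @param n_pcs leading PCs in Models II/III.
#' @param seed master seed.
#' @return a `prs_experiment_grid`; cells carry `ref_delta_auc` for the
#'   reference model.
#' @export
contamination_experiment <- function(config, fractions = seq(0, 1, by = 0.1),
                                     replicates = 20, n_discovery = 3000,
                                     n_test = 800,
                                     covariate_names = c("age", "sex"),
                                     gwas_covariates = character(),
                                     n_pcs = 20, seed = 1L) {
  cells <- list()
  for (r in seq_len(replicates)) {
    seed_r <- derive_seed(seed, r)
    sim <- sim_cohort_pair(config, n_discovery, n_test, seed_r)
    sel <- train_selection(sim$pair$discovery, config$trait_type, gwas_covariates)
    ref_var <- sim$panel$variants$variant_id[which.max(abs(sim$effects$beta_true))]
    for (fi in seq_along(fractions)) {
      f <- fractions[fi]
      test_f <- inject_overlap(sim$pair$test, sim$pair$discovery, f,
                               seed = derive_seed(seed_r, 100L + fi))
      pcs <- compute_pcs(test_f$panel, n_pcs)
      dm <- eval_cohort(sel, test_f, config$trait_type, covariate_names,
                        n_pcs, pcs = pcs)
      ref <- structure(list(sample_ids = test_f$panel$sample_ids,
                            score = as.numeric(test_f$panel$dosage[, ref_var]),
                            n_snps_used = rep(1L, n_test),
                            snp_report = data.frame()), class = "prs_vector")
      dm_ref <- suppressWarnings(suppressMessages(
        evaluate(ref, test_f$pheno, pcs, config$trait_type,
                 covariate_names = covariate_names, n_pcs = n_pcs)))
      cells[[length(cells) + 1L]] <-
        cbind(data.frame(point = f, replicate = r,
                         seed = derive_seed(seed_r, 100L + fi)),
              metrics_row(dm),
              data.frame(ref_delta_auc = dm_ref$delta_auc,
                         ref_delta_r2 = dm_ref$delta_r2))
    }
  }
  cells <- do.call(rbind, cells)
  new_grid("contamination", "overlap_fraction", cells, summarize_grid(cells),
           list(config = config, fractions = fractions,
                replicates = replicates, n_discovery = n_discovery,
                n_test = n_test, n_pcs = n_pcs, seed = seed))
}

#' Scale effect of the discovery-set size
#'
#' The test set is simulated once per replicate and held fixed; the
#' discovery set is resampled at each size from a disjoint discovery pool.
#' The per-sample slope of the mean gain versus discovery size is fitted by
#' least squares on the grid means and reported per sample and per 3k
#' samples.
#'
#' @param config a [sim_config()] (`"quantitative"` gives the
#'   height-style Delta adjusted-R2; `"binary"` the hypertension-style
#'   Delta-AUC).
#' @param discovery_sizes ascending discovery sizes (desk-scale analog of
#'   the 9k / 60k / 300k cohorts).
#' @param n_test fixed test-set size.
#' @inheritParams contamination_experiment
#' @return a `prs_experiment_grid` with extra fields `slope_per_sample`,
#'   `slope_per_3k` (on the headline gain metric).
#' @export
scale_experiment <- function(config, discovery_sizes = c(1000, 3000, 9000),
                             n_test = 2000, replicates = 10,
                             covariate_names = c("age", "sex"),
                             gwas_covariates = character(),
                             n_pcs = 20, seed = 1L) {
  if (is.unsorted(discovery_sizes)) fail("discovery_sizes must be ascending")
  cells <- list()
  for (r in seq_len(replicates)) {
    seed_r <- derive_seed(seed, r)
    sim <- sim_cohort_pair(config, max(discovery_sizes), n_test, seed_r)
    pcs <- compute_pcs(sim$pair$test$panel, n_pcs)
    pool_ids <- sim$pair$discovery$panel$sample_ids
    for (si in seq_along(discovery_sizes)) {
      s <- discovery_sizes[si]
      set.seed(derive_seed(seed_r, 200L + si))
      disc <- cohort_subset(sim$pair$discovery, sample(pool_ids, s))
      sel <- train_selection(disc, config$trait_type, gwas_covariates)
      dm <- eval_cohort(sel, sim$pair$test, config$trait_type,
                        covariate_names, n_pcs, pcs = pcs)
      cells[[length(cells) + 1L]] <-
        cbind(data.frame(point = s, replicate = r,
                         seed = derive_seed(seed_r, 200L + si)),
              metrics_row(dm))
    }
  }
  cells <- do.call(rbind, cells)
  summ <- summarize_grid(cells)
  metric <- if (config$trait_type == "binary") "mean_delta_auc" else "mean_delta_r2"
  sl <- coef(lm(summ[[metric]] ~ summ$point))[2]
  grid <- new_grid("scale", "discovery_size", cells, summ,
                   list(config = config, discovery_sizes = discovery_sizes,
                        n_test = n_test, replicates = replicates,
                        n_pcs = n_pcs, seed = seed))
  grid$slope_per_sample <- as.numeric(sl)
  grid$slope_per_3k <- as.numeric(sl) * 3000
  grid
}

#' SNP-count sweep: gain versus number of top-P SNPs
#'
#' One GWAS + clump per replicate; the score is re-evaluated at each top-k
#' subset of the clumped selection (lowest P first).  `k` beyond the
#' available SNPs is capped with a log message; `k = 0` scores everyone 0
#' and the gain collapses to 0.
#'
#' @param ks ascending SNP counts.
#' @inheritParams contamination_experiment
#' @return a `prs_experiment_grid`.
#' @export
snp_count_sweep <- function(config, ks = c(10, 100, 1000), replicates = 10,
                            n_discovery = 3000, n_test = 800,
                            covariate_names = c("age", "sex"),
                            gwas_covariates = character(),
                            n_pcs = 20, seed = 1L) {
  if (is.unsorted(ks)) fail("ks must be ascending")
  cells <- list()
  for (r in seq_len(replicates)) {
    seed_r <- derive_seed(seed, r)
    sim <- sim_cohort_pair(config, n_discovery, n_test, seed_r)
    sel <- train_selection(sim$pair$discovery, config$trait_type, gwas_covariates)
    pcs <- compute_pcs(sim$pair$test$panel, n_pcs)
    for (ki in seq_along(ks)) {
      k <- ks[ki]
      if (k > nrow(sel))
        log_msg("snp_count_sweep: k = %d capped at %d available SNPs", k, nrow(sel))
      dm <- eval_cohort(select_top(sel, k), sim$pair$test, config$trait_type,
                        covariate_names, n_pcs, pcs = pcs)
      cells[[length(cells) + 1L]] <-
        cbind(data.frame(point = k, replicate = r, seed = seed_r),
              metrics_row(dm))
    }
  }
  cells <- do.call(rbind, cells)
  new_grid("snp_count", "n_snps", cells, summarize_grid(cells),
           list(config = config, ks = ks, replicates = replicates,
                n_discovery = n_discovery, n_test = n_test,
                n_pcs = n_pcs, seed = seed))
}

#' Power of the DeLong test versus test-set size
#'
#' Per test size, power is the fraction of replicates whose Model III vs
#' Model II DeLong p-value falls below `alpha`; the minimal adequate size
#' is the smallest grid point reaching `power_target` (NA when none does).
#'
#' @param test_sizes ascending test-set sizes.
#' @param alpha significance level (default 0.01).
#' @param power_target required power (default 0.8; the notion of
#'   "sufficient power" is operationalized as this fraction of significant
#'   replicates).
#' @inheritParams contamination_experiment
#' @return a `prs_experiment_grid` with `power` per size and
#'   `minimal_test_size`.
#' @export
power_curve <- function(config, n_discovery = 3000, test_sizes = c(200, 800),
                        alpha = 0.01, power_target = 0.8, replicates = 10,
                        covariate_names = c("age", "sex"),
                        gwas_covariates = character(),
                        n_pcs = 20, seed = 1L) {
  if (is.unsorted(test_sizes)) fail("test_sizes must be ascending")
  if (config$trait_type != "binary") fail("power_curve requires a binary trait")
  cells <- list()
  for (si in seq_along(test_sizes)) {
    nt <- test_sizes[si]
    for (r in seq_len(replicates)) {
      seed_c <- derive_seed(seed, si * 1000L + r)
      sim <- sim_cohort_pair(config, n_discovery, nt, seed_c)
      sel <- train_selection(sim$pair$discovery, "binary", gwas_covariates)
      dm <- eval_cohort(sel, sim$pair$test, "binary", covariate_names, n_pcs)
      cells[[length(cells) + 1L]] <-
        cbind(data.frame(point = nt, replicate = r, seed = seed_c),
              metrics_row(dm))
    }
  }
  cells <- do.call(rbind, cells)
  pw <- vapply(split(cells$delong_p, cells$point),
               function(p) mean(p < alpha, na.rm = TRUE), numeric(1))
  power_tab <- data.frame(point = as.numeric(names(pw)), power = as.numeric(pw))
  power_tab <- power_tab[order(power_tab$point), ]
  hit <- power_tab$point[power_tab$power >= power_target]
  grid <- new_grid("power", "test_size", cells, summarize_grid(cells),
                   list(config = config, n_discovery = n_discovery,
                        test_sizes = test_sizes, alpha = alpha,
                        power_target = power_target,
                        replicates = replicates, n_pcs = n_pcs, seed = seed))
  grid$power <- power_tab
  grid$minimal_test_size <- if (length(hit)) min(hit) else NA_real_
  grid
}

#' Case:control-ratio sweep at a fixed case count
#'
#' The number of discovery cases is held fixed while controls are set to
#' `ratio x cases`; an independent test set with the pool's natural case
#' rate is held fixed per replicate.
#'
#' @param n_cases_fixed discovery case count (desk-scale analog of holding
#'   17,008 cases fixed).
#' @param ratios control:case ratios.
#' @inheritParams contamination_experiment
#' @return a `prs_experiment_grid`; cells record `n_discovery_total =
#'   cases + round(ratio x cases)`.
#' @export
ratio_experiment <- function(config, n_cases_fixed = 1500,
                             ratios = c(0.33, 1, 3), n_test = 800,
                             replicates = 10,
                             covariate_names = c("age", "sex"),
                             gwas_covariates = character(),
                             n_pcs = 20, seed = 1L) {
  if (any(ratios <= 0)) fail("ratios must be positive")
  if (config$trait_type != "binary") fail("ratio_experiment requires a binary trait")
  K <- config$prevalence
  n_pool <- ceiling(1.25 * max(n_cases_fixed / K,
                               n_cases_fixed * max(ratios) / (1 - K))) + n_test
  cells <- list()
  for (r in seq_len(replicates)) {
    seed_r <- derive_seed(seed, r)
    cfg <- config; cfg$n_samples <- as.integer(n_pool); cfg$seed <- seed_r
    panel <- simulate_genotypes(cfg)
    eff <- assign_effects(panel, cfg)
    pheno <- simulate_phenotype(eff, cfg)
    set.seed(derive_seed(seed_r, 7L))
    test_ids <- sample(panel$sample_ids, n_test)
    rest <- setdiff(panel$sample_ids, test_ids)
    case_ids <- rest[pheno$phenotype[match(rest, pheno$sample_id)] == 1]
    ctrl_ids <- rest[pheno$phenotype[match(rest, pheno$sample_id)] == 0]
    pool <- make_cohort(panel, pheno)
    test <- cohort_subset(pool, test_ids)
    pcs <- compute_pcs(test$panel, n_pcs)
    for (qi in seq_along(ratios)) {
      q <- ratios[qi]
      n_ctrl <- round(q * n_cases_fixed)
      if (length(case_ids) < n_cases_fixed || length(ctrl_ids) < n_ctrl)
        fail("pool of %d yields %d cases / %d controls; need %d / %d",
             n_pool, length(case_ids), length(ctrl_ids), n_cases_fixed, n_ctrl)
      set.seed(derive_seed(seed_r, 300L + qi))
      disc <- cohort_subset(pool, sample(c(sample(case_ids, n_cases_fixed),
                                           sample(ctrl_ids, n_ctrl))))
      sel <- train_selection(disc, "binary", gwas_covariates)
      dm <- eval_cohort(sel, test, "binary", covariate_names, n_pcs, pcs = pcs)
      cells[[length(cells) + 1L]] <-
        cbind(data.frame(point = q, replicate = r,
                         seed = derive_seed(seed_r, 300L + qi),
                         n_discovery_total = n_cases_fixed + n_ctrl),
              metrics_row(dm))
    }
  }
  cells <- do.call(rbind, cells)
  new_grid("ratio", "case_control_ratio", cells, summarize_grid(cells),
           list(config = config, n_cases_fixed = n_cases_fixed,
                ratios = ratios, n_test = n_test, replicates = replicates,
                n_pcs = n_pcs, seed = seed))
}

#' Contaminate-then-prune repair check
#'
#' Per replicate three arms of the same replicate are evaluated: the clean
#' independent test set, the test set contaminated with discovery subjects
#' at `fraction`, and the contaminated set pruned against the discovery
#' cohort at `PI_HAT >= cutoff`.  Pruning should return the gain to the
#' clean arm's level.
#'
#' @param fraction contamination fraction (default 0.3).
#' @param cutoff PI_HAT removal threshold (default 0.9, duplicates only).
#' @param max_loci loci used for the all-pairs PI_HAT scan (subsampled; a
#'   few thousand loci separate duplicates from unrelated pairs cleanly).
#' @inheritParams contamination_experiment
#' @return a `prs_experiment_grid` whose cells carry `arm` in
#'   `clean | contaminated | pruned`; summary is per arm.
#' @export
prune_repair_experiment <- function(config, fraction = 0.3, cutoff = 0.9,
                                    replicates = 10, n_discovery = 3000,
                                    n_test = 800,
                                    covariate_names = c("age", "sex"),
                                    gwas_covariates = character(),
                                    n_pcs = 20, max_loci = 2000, seed = 1L) {
  cells <- list()
  for (r in seq_len(replicates)) {
    seed_r <- derive_seed(seed, r)
    sim <- sim_cohort_pair(config, n_discovery, n_test, seed_r)
    sel <- train_selection(sim$pair$discovery, config$trait_type, gwas_covariates)
    contaminated <- inject_overlap(sim$pair$test, sim$pair$discovery, fraction,
                                   seed = derive_seed(seed_r, 11L))
    pruned <- suppressMessages(
      prune_overlap(contaminated, sim$pair$discovery, cutoff,
                    max_loci = max_loci, seed = derive_seed(seed_r, 12L)))$cohort
    arms <- list(clean = sim$pair$test, contaminated = contaminated,
                 pruned = pruned)
    for (a in names(arms)) {
      dm <- eval_cohort(sel, arms[[a]], config$trait_type, covariate_names, n_pcs)
      cells[[length(cells) + 1L]] <-
        cbind(data.frame(arm = a, point = match(a, names(arms)),
                         replicate = r, seed = seed_r),
              metrics_row(dm))
    }
  }
  cells <- do.call(rbind, cells)
  summ <- summarize_grid(cells)
  summ$arm <- c("clean", "contaminated", "pruned")[summ$point]
  new_grid("prune_repair", "arm", cells, summ,
           list(config = config, fraction = fraction, cutoff = cutoff,
                replicates = replicates, n_discovery = n_discovery,
                n_test = n_test, n_pcs = n_pcs, max_loci = max_loci,
                seed = seed))
}
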