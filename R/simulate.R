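# Synthetic cohorts: genotype panels with blockwise LD, liability-threshold
# phenotypes, and discovery/test pairs with controlled subject overlap and
# relatedness.  All randomness flows from the single seed in the config via
# derive_seed(), so identical config => identical cohorts.

#' Simulation configuration
#'
#' @param n_samples number of samples in the panel.
#' @param n_variants number of biallelic variants.
#' @param block_size variants per LD block.
#' @param rho within-block latent correlation in `[0, 1)` (exchangeable
#'   Gaussian copula); blocks are independent.
#' @param maf_range range of per-variant counted-allele frequencies,
#'   drawn uniformly; must lie in `(0, 0.5]`.
#' @param n_causal number of causal variants.
#' @param h2 narrow-sense heritability of the liability in `[0, 1]`.
#'   Reference points used throughout the package: 0.497 (height-like
#'   quantitative trait) and 0.147 (hypertension-like binary trait).
#' @param prevalence population prevalence K in `(0, 1)` for binary traits.
#'   Default 0.314 mirrors the case fraction of a large AD discovery
#'   meta-analysis cohort.
#' @param trait_type `"binary"` (liability-threshold) or `"quantitative"`.
#' @param covariate_spec named list of liability coefficients for the
#'   emitted nuisance covariates (`age`, `sex`, `center`), applied to the
#'   standardized covariate.  Defaults to all zero, so covariates and
#'   principal components are pure nuisance (no population stratification).
#' @param seed master seed for the configuration.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2000, n_variants = 5000, block_size = 20,
                       rho = 0.6, maf_range = c(0.01, 0.5), n_causal = 200,
                       h2 = 0.147, prevalence = 0.314,
                       trait_type = c("binary", "quantitative"),
                       covariate_spec = list(age = 0, sex = 0, center = 0),
                       seed = 1L) {
  trait_type <- match.arg(trait_type)
  if (rho < 0 || rho >= 1) fail("rho must lie in [0, 1), got %g", rho)
  if (h2 < 0 || h2 > 1) fail("h2 must lie in [0, 1], got %g", h2)
  if (prevalence <= 0 || prevalence >= 1)
    fail("prevalence must lie in (0, 1), got %g", prevalence)
  if (n_causal > n_variants)
    fail("n_causal (%d) exceeds n_variants (%d)", n_causal, n_variants)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    fail("maf_range must be [low, high] within (0, 0.5]")
  bad <- setdiff(names(covariate_spec), c("age", "sex", "center"))
  if (length(bad)) fail("unknown covariate(s) in covariate_spec: %s",
                        paste(bad, collapse = ", "))
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 block_size = as.integer(block_size), rho = rho,
                 maf_range = maf_range, n_causal = as.integer(n_causal),
                 h2 = h2, prevalence = prevalence, trait_type = trait_type,
                 covariate_spec = covariate_spec, seed = as.integer(seed)),
            class = "sim_config")
}

# variants laid out on chromosomes of 1000 variants, 5 kb apart, so a
# +/- 1 Mb clumping window spans ~400 variants (20 LD blocks); the order
# returned is already the canonical (chrom, pos) character sort
variant_map <- function(m) {
  chrom <- sprintf("chr%02d", (seq_len(m) - 1L) %/% 1000L + 1L)
  pos <- ((seq_len(m) - 1L) %% 1000L) * 5000L + 10000L
  data.frame(variant_id = sprintf("snp%06d", seq_len(m)),
             chrom = chrom, pos = pos,
             allele_counted = "A", allele_other = "G",
             stringsAsFactors = FALSE)
}

#' Simulate a genotype panel with blockwise LD
#'
#' Dosages are drawn per variant under Hardy-Weinberg equilibrium at a
#' counted-allele frequency uniform in `maf_range`.  Within each block of
#' `block_size` consecutive variants a latent Gaussian with exchangeable
#' correlation `rho` is thresholded at the HWE genotype quantiles, inducing
#' LD; blocks are independent.
#'
#' @param config a [sim_config()].
#' @return a `genotype_panel` with `n_samples` samples and `n_variants`
#'   variants.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples; m <- config$n_variants
  set.seed(derive_seed(config$seed, 1L))
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  # HWE genotype thresholds on the latent normal (upper tail = carriers)
  q1 <- qnorm((1 - maf)^2)        # below: dosage 0
  q2 <- qnorm(1 - maf^2)          # above: dosage 2
  rho <- config$rho
  bs <- config$block_size
  dos <- matrix(0, n, m)
  start <- 1L
  while (start <= m) {
    end <- min(start + bs - 1L, m)
    w <- end - start + 1L
    z <- sqrt(1 - rho) * matrix(rnorm(n * w), n, w)
    if (rho > 0) z <- z + sqrt(rho) * rnorm(n)
    dos[, start:end] <- (z > rep(q1[start:end], each = n)) +
      (z > rep(q2[start:end], each = n))
    start <- end + 1L
  }
  panel <- panel_unchecked(variant_map(m), sprintf("S%06d", seq_len(n)), dos)
  attr(panel, "maf_true") <- maf
  panel
}

#' Assign additive causal effects and build liabilities
#'
#' `n_causal` variants are sampled uniformly; their effects on standardized
#' dosages are `Normal(0, h2 / n_causal)` so the genetic variance is `h2`
#' in expectation regardless of the MAF spectrum.  The liability is
#' `l = g + e` with `e ~ Normal(0, 1 - h2)`.
#'
#' @param panel a `genotype_panel`.
#' @param config the [sim_config()] used to build it.
#' @return an object of class `effect_vector` with per-variant `beta_true`,
#'   per-sample `g`, `e`, `liability`, and the liability threshold
#'   `qnorm(1 - prevalence)`.
#' @export
assign_effects <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  m <- nrow(panel$variants)
  if (config$n_causal > m) fail("n_causal exceeds panel variants")
  set.seed(derive_seed(config$seed, 2L))
  causal <- sort(sample.int(m, config$n_causal))
  beta <- numeric(m)
  if (config$h2 > 0 && config$n_causal > 0)
    beta[causal] <- rnorm(config$n_causal, 0, sqrt(config$h2 / config$n_causal))
  X <- panel$dosage[, causal, drop = FALSE]
  mu <- colMeans(X); s <- sqrt(col_var(X))
  s[s == 0] <- 1  # monomorphic causal variant contributes nothing
  g <- as.numeric(scale(X, center = mu, scale = s) %*% beta[causal])
  e <- rnorm(length(g), 0, sqrt(1 - config$h2))
  structure(list(beta_true = beta, causal_idx = causal, g = g, e = e,
                 liability = g + e,
                 threshold = qnorm(1 - config$prevalence),
                 h2 = config$h2),
            class = "effect_vector")
}

std_covariate <- function(x) {
  s <- sd(x)
  if (s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Simulate a phenotype table from liabilities
#'
#' Nuisance covariates `age`, `sex`, `center` are generated independently of
#' genotype and added to the liability with the standardized coefficients in
#' `covariate_spec`.  Binary traits are thresholded at the quantile matching
#' the configured prevalence of the total liability (threshold scaled by its
#' theoretical standard deviation so prevalence stays close to `K` even with
#' nonzero covariate effects); quantitative traits are the total liability
#' itself.
#'
#' @param effects an `effect_vector` from [assign_effects()] on the same
#'   panel.
#' @param config the [sim_config()].
#' @param sample_ids sample IDs to emit (defaults to `S...` matching
#'   [simulate_genotypes()]).
#' @return a phenotype data.frame with columns `sample_id`, `phenotype`,
#'   `age`, `sex`, `center` and attribute `trait_type`.
#' @export
simulate_phenotype <- function(effects, config,
                               sample_ids = sprintf("S%06d", seq_along(effects$liability))) {
  stopifnot(inherits(effects, "effect_vector"), inherits(config, "sim_config"))
  n <- length(effects$liability)
  set.seed(derive_seed(config$seed, 3L))
  age <- round(rnorm(n, 60, 8))
  sex <- rbinom(n, 1, 0.5)
  center <- sample(c("C1", "C2", "C3"), n, replace = TRUE)
  cs <- config$covariate_spec
  cov_eff <- (cs$age %||% 0) * std_covariate(age) +
    (cs$sex %||% 0) * std_covariate(sex) +
    (cs$center %||% 0) * std_covariate(match(center, c("C1", "C2", "C3")))
  lt <- effects$liability + cov_eff
  if (config$trait_type == "binary") {
    sd_tot <- sqrt(1 + (cs$age %||% 0)^2 + (cs$sex %||% 0)^2 + (cs$center %||% 0)^2)
    y <- as.integer(lt > qnorm(1 - config$prevalence) * sd_tot)
    if (sum(y) == 0L || sum(y) == n)
      fail("prevalence %g produced a single-class phenotype at n=%d; use a larger n",
           config$prevalence, n)
  } else {
    y <- lt
  }
  out <- data.frame(sample_id = sample_ids, phenotype = y, age = age,
                    sex = sex, center = center, stringsAsFactors = FALSE)
  attr(out, "trait_type") <- config$trait_type
  out
}

#' Subset a genotype panel by sample IDs
#'
#' @param panel a `genotype_panel`.
#' @param ids sample IDs to keep, in the requested order.
#' @return a `genotype_panel` restricted to `ids`.
#' @export
subset_panel <- function(panel, ids) {
  idx <- match(ids, panel$sample_ids)
  if (anyNA(idx)) fail("sample id(s) not in panel: %s",
                       paste(head(ids[is.na(idx)], 3), collapse = ", "))
  if (anyDuplicated(ids)) fail("duplicate sample ids requested")
  panel_unchecked(panel$variants, ids, panel$dosage[idx, , drop = FALSE])
}

subset_pheno <- function(pheno, ids) {
  idx <- match(ids, pheno$sample_id)
  if (anyNA(idx)) fail("sample id(s) not in phenotype table")
  out <- pheno[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_type") <- attr(pheno, "trait_type")
  out
}

#' Bundle a genotype panel and phenotype table as a cohort
#'
#' @param panel a `genotype_panel`.
#' @param pheno a phenotype data.frame aligned to the same samples.
#' @return an object of class `prs_cohort`.
#' @export
make_cohort <- function(panel, pheno) {
  if (!identical(panel$sample_ids, pheno$sample_id))
    fail("cohort panel and phenotype sample IDs disagree")
  structure(list(panel = panel, pheno = pheno), class = "prs_cohort")
}

#' @export
print.prs_cohort <- function(x, ...) {
  cat(sprintf("prs_cohort: %d samples x %d variants\n",
              length(x$panel$sample_ids), nrow(x$panel$variants)))
  invisible(x)
}

cohort_subset <- function(cohort, ids)
  make_cohort(subset_panel(cohort$panel, ids), subset_pheno(cohort$pheno, ids))

#' Split a sample pool into discovery and test cohorts with controlled overlap
#'
#' `round(overlap_fraction * n_test)` test subjects are copied verbatim from
#' the discovery set (identical ID, genotype and phenotype — the same
#' subject measured in both cohorts); the remainder are disjoint pool
#' members.  Assignment is uniformly random under `seed`.
#'
#' @param panel_pool,pheno_pool the sample pool (e.g. from
#'   [simulate_genotypes()] / [simulate_phenotype()]).
#' @param n_discovery,n_test cohort sizes.
#' @param overlap_fraction fraction of the test set shared with discovery,
#'   in `[0, 1]`.
#' @param seed integer seed.
#' @return an object of class `cohort_pair` with elements `discovery`,
#'   `test` (both `prs_cohort`), `overlap_ids`, `related_pairs`.
#' @export
build_cohorts <- function(panel_pool, pheno_pool, n_discovery, n_test,
                          overlap_fraction = 0, seed = 1L) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    fail("overlap_fraction must lie in [0, 1]")
  pool <- panel_pool$sample_ids
  k <- round(overlap_fraction * n_test)
  need <- n_discovery + n_test - k
  if (length(pool) < need)
    fail("pool of %d samples too small: need %d (n_discovery + n_test*(1-overlap))",
         length(pool), need)
  set.seed(seed)
  disc_ids <- sample(pool, n_discovery)
  rest <- setdiff(pool, disc_ids)
  shared <- if (k > 0) sample(disc_ids, k) else character(0)
  fresh <- if (n_test - k > 0) sample(rest, n_test - k) else character(0)
  test_ids <- sample(c(shared, fresh))  # shuffle so shared are not clustered
  structure(list(
    discovery = cohort_subset(make_cohort(panel_pool, pheno_pool), disc_ids),
    test = cohort_subset(make_cohort(panel_pool, pheno_pool), test_ids),
    overlap_ids = shared,
    related_pairs = data.frame(discovery_id = character(0),
                               test_id = character(0),
                               relationship = character(0),
                               stringsAsFactors = FALSE)),
    class = "cohort_pair")
}

#' Generate the genotype of a relative of a given subject
#'
#' `duplicate` returns the identical dosage vector.  `parent_offspring`
#' transmits one allele per variant from the source genotype and draws the
#' other from the population frequency.  `full_sib` reconstructs two
#' parents consistent with the source genotype (each carrying one source
#' allele plus a population allele) and draws a sibling by Mendelian
#' transmission, giving the standard 1/4 : 1/2 : 1/4 IBD-state distribution.
#'
#' @param genotype dosage vector in `{0,1,2}`, no missing values.
#' @param relationship one of `"duplicate"`, `"parent_offspring"`,
#'   `"full_sib"`.
#' @param freq_counted per-variant counted-allele frequencies (same length).
#' @param seed integer seed.
#' @return a dosage vector of the relative.
#' @export
spawn_relative <- function(genotype, relationship = c("duplicate", "parent_offspring", "full_sib"),
                           freq_counted, seed = 1L) {
  relationship <- match.arg(relationship)
  if (anyNA(genotype)) fail("spawn_relative requires complete dosages")
  m <- length(genotype)
  if (relationship == "duplicate") return(genotype)
  stopifnot(length(freq_counted) == m)
  set.seed(seed)
  if (relationship == "parent_offspring") {
    transmitted <- rbinom(m, 1, genotype / 2)
    return(transmitted + rbinom(m, 1, freq_counted))
  }
  # full_sib: split source into two alleles, one per reconstructed parent
  a1 <- ifelse(genotype == 2, 1L, ifelse(genotype == 0, 0L, rbinom(m, 1, 0.5)))
  a2 <- genotype - a1
  p1 <- cbind(a1, rbinom(m, 1, freq_counted))
  p2 <- cbind(a2, rbinom(m, 1, freq_counted))
  pick <- function(par) par[cbind(seq_len(m), rbinom(m, 1, 0.5) + 1L)]
  pick(p1) + pick(p2)
}

#' Replace a fraction of a test cohort with discovery subjects
#'
#' `round(fraction * n_test)` uniformly chosen test slots are overwritten
#' with uniformly sampled discovery members (IDs, genotypes and phenotypes
#' taken verbatim from the discovery cohort); the test-set size is
#' preserved.  Sampled discovery members are restricted to those not
#' already present in the retained part of the test set so sample IDs stay
#' unique.
#'
#' @param test,discovery `prs_cohort` objects over the same variants.
#' @param fraction fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return the contaminated test `prs_cohort`.
#' @export
inject_overlap <- function(test, discovery, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) fail("fraction must lie in [0, 1]")
  n_test <- length(test$panel$sample_ids)
  k <- round(fraction * n_test)
  if (k == 0) return(test)
  set.seed(seed)
  slots <- sample.int(n_test, k)
  kept <- test$panel$sample_ids[-slots]
  candidates <- setdiff(discovery$panel$sample_ids, kept)
  if (length(candidates) < k)
    fail("discovery cohort has only %d usable subjects; need %d", length(candidates), k)
  incoming <- sample(candidates, k)
  new_ids <- test$panel$sample_ids
  new_ids[slots] <- incoming
  pool_panel <- test$panel
  dos <- pool_panel$dosage
  dos[slots, ] <- discovery$panel$dosage[match(incoming, discovery$panel$sample_ids), , drop = FALSE]
  if (anyDuplicated(new_ids)) fail("inject_overlap produced duplicate sample ids")
  new_panel <- panel_unchecked(pool_panel$variants, new_ids, dos)
  new_pheno <- test$pheno
  new_pheno[slots, ] <- discovery$pheno[match(incoming, discovery$pheno$sample_id), , drop = FALSE]
  new_pheno$sample_id <- new_ids
  attr(new_pheno, "trait_type") <- attr(test$pheno, "trait_type")
  make_cohort(new_panel, new_pheno)
}
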