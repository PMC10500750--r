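mk_prs <- function(ids, score) {
  structure(list(sample_ids = ids, score = score,
                 n_snps_used = rep(1L, length(ids)),
                 snp_report = data.frame()), class = "prs_vector")
}

test_that("model fits recover exact relationships in degenerate designs", {
  ids <- sprintf("i%02d", 1:60)
  set.seed(51)
  y <- rnorm(60)
  ph <- data.frame(sample_id = ids, phenotype = y)
  # Model I with PRS identical to the phenotype: slope 1, intercept 0
  f1 <- fit_model(ph, mk_prs(ids, y), model = "I", trait_type = "quantitative")
  expect_equal(unname(f1$coefficients), c(0, 1), tolerance = 1e-8)

  # Model II on balanced binary labels with no informative covariate:
  # intercept is the logit of 0.5
  phb <- data.frame(sample_id = ids, phenotype = rep(c(0, 1), 30))
  f2 <- fit_model(phb, model = "II", trait_type = "binary")
  expect_equal(unname(f2$coefficients), 0, tolerance = 1e-8)
})

test_that("Model III logistic coefficients match a direct ML oracle", {
  set.seed(52)
  ids <- sprintf("i%02d", 1:50)
  x1 <- rnorm(50); prs <- rnorm(50)
  y <- rbinom(50, 1, plogis(-0.3 + 0.8 * x1 + 0.6 * prs))
  ph <- data.frame(sample_id = ids, phenotype = y, x1 = x1)
  f3 <- fit_model(ph, mk_prs(ids, prs), model = "III",
                  covariate_names = "x1", trait_type = "binary")
  # independent oracle: numeric maximization of the Bernoulli log-likelihood
  nll <- function(b) {
    eta <- b[1] + b[2] * x1 + b[3] * prs
    -sum(y * eta - log1p(exp(eta)))
  }
  ora <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(f3$coefficients), ora$par, tolerance = 1e-5)
  expect_equal(f3$loglik, -ora$value, tolerance = 1e-8)
})

test_that("rank AUC handles the degenerate cases and equals ROC integration", {
  y <- c(0, 0, 1, 1)
  expect_equal(auc(c(0, 0, 1, 1), y), 1)
  expect_equal(auc(rep(2, 4), y), 0.5)
  expect_equal(auc(c(1, 1, 0, 0), y), 0)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")

  # trapezoidal ROC oracle on a tied random fixture
  set.seed(53)
  sc <- sample(round(rnorm(200), 1))
  yy <- rbinom(200, 1, 0.4)
  th <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(sc[yy == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(sc[yy == 0] >= t), numeric(1))
  trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(auc(sc, yy), trap, tolerance = 1e-10)
})

test_that("DeLong paired test agrees with pROC and honors the degenerate rule", {
  set.seed(54)
  n <- 250
  y <- rbinom(n, 1, 0.5)
  s2 <- rnorm(n) + 0.4 * y
  s3 <- 0.6 * s2 + rnorm(n) + 0.5 * y
  dl <- delong_delta_auc(s2, s3, y)
  expect_equal(dl$auc_II, auc(s2, y))
  skip_if_not_installed("pROC")
  rt <- pROC::roc.test(pROC::roc(y, s2, quiet = TRUE),
                       pROC::roc(y, s3, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(dl$p, rt$p.value, tolerance = 1e-10)
  expect_equal(dl$delta_auc,
               as.numeric(pROC::auc(pROC::roc(y, s3, quiet = TRUE))) -
                 as.numeric(pROC::auc(pROC::roc(y, s2, quiet = TRUE))),
               tolerance = 1e-12)

  ident <- delong_delta_auc(s2, s2, y)
  expect_equal(ident$delta_auc, 0)
  expect_equal(ident$p, 1)
})

test_that("Nagelkerke R2 matches the likelihood formula and its bounds", {
  set.seed(55)
  ids <- sprintf("i%02d", 1:20)
  x <- rnorm(20)
  y <- rbinom(20, 1, plogis(1.2 * x))
  ph <- data.frame(sample_id = ids, phenotype = y, x = x)
  fit <- fit_model(ph, model = "II", covariate_names = "x", trait_type = "binary")
  null <- fit_model(ph, model = "II", trait_type = "binary")
  # direct likelihood oracle through stats::glm
  ll1 <- as.numeric(logLik(glm(y ~ x, family = binomial())))
  ll0 <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
  expected <- (1 - exp((2 / 20) * (ll0 - ll1))) / (1 - exp((2 / 20) * ll0))
  expect_equal(nagelkerke_r2(fit, null), expected, tolerance = 1e-8)
  expect_equal(nagelkerke_r2(null, null), 0)

  # perfect separation pushes the normalized R2 to (almost) 1
  ph2 <- data.frame(sample_id = ids, phenotype = rep(c(0, 1), each = 10),
                    z = rep(c(-1, 1), each = 10))
  f2 <- quiet(fit_model(ph2, model = "II", covariate_names = "z",
                        trait_type = "binary"))
  n2 <- fit_model(ph2, model = "II", trait_type = "binary")
  expect_gt(nagelkerke_r2(f2, n2), 0.9)
  expect_error(nagelkerke_r2(null, fit), "nesting")
})

test_that("extra-sum-of-squares F equals the squared t of a single regressor", {
  set.seed(56)
  ids <- sprintf("i%02d", 1:80)
  x <- rnorm(80); prs <- rnorm(80)
  y <- 0.5 * x + 0.3 * prs + rnorm(80)
  ph <- data.frame(sample_id = ids, phenotype = y, x = x)
  f2 <- fit_model(ph, model = "II", covariate_names = "x",
                  trait_type = "quantitative")
  f3 <- fit_model(ph, mk_prs(ids, prs), model = "III", covariate_names = "x",
                  trait_type = "quantitative")
  ess <- extra_ss_test(f2, f3)
  tstat <- coef(summary(lm(y ~ x + prs)))["prs", "t value"]
  expect_equal(ess$F, tstat^2, tolerance = 1e-8)
  expect_equal(ess$delta_r2_adj,
               summary(lm(y ~ x + prs))$adj.r.squared -
                 summary(lm(y ~ x))$adj.r.squared, tolerance = 1e-10)
  # identical models: F = 0, p = 1
  same <- extra_ss_test(f2, f2)
  expect_equal(same$F, 0); expect_equal(same$p, 1)
})

test_that("stratified folds are balanced, disjoint and reproducible", {
  set.seed(57)
  ph <- data.frame(sample_id = sprintf("i%04d", 1:1000),
                   phenotype = rep(c(0, 1), 500),
                   age = rnorm(1000, 60, 8))
  folds <- stratified_kfold(ph, "phenotype", k = 10, seed = 3)
  expect_length(folds, 10)
  test_ids <- lapply(folds, `[[`, "test_ids")
  expect_equal(sort(unlist(test_ids)), sort(ph$sample_id))   # cover, disjoint
  for (f in folds) {
    expect_length(f$test_ids, 100)
    n_case <- sum(ph$phenotype[ph$sample_id %in% f$test_ids])
    expect_gte(n_case, 49); expect_lte(n_case, 51)
    expect_length(intersect(f$test_ids, f$discovery_ids), 0)
  }
  expect_identical(folds, stratified_kfold(ph, "phenotype", k = 10, seed = 3))

  # continuous columns are quintile-binned; tiny strata merge with a warning
  f2 <- stratified_kfold(ph, c("phenotype", "age"), k = 5, seed = 3)
  expect_length(f2, 5)
  ph$rare <- c(rep("r", 3), rep("common", 997))
  expect_warning(stratified_kfold(ph, "rare", k = 10, seed = 3), "merged")
})

test_that("evaluate reports zero gain for a constant PRS and is affine-invariant", {
  s <- small_pair(n_disc = 300, n_test = 200, m = 60, seed = 58)
  test <- s$pair$test
  pcs <- compute_pcs(test$panel, 4)
  ids <- test$panel$sample_ids

  z <- quiet(evaluate(mk_prs(ids, rep(0, 200)), test$pheno, pcs, "binary"))
  expect_equal(z$delta_auc, 0)
  expect_equal(z$delta_r2, 0, tolerance = 1e-12)

  set.seed(58)
  sc <- rnorm(200)
  e1 <- evaluate(mk_prs(ids, sc), test$pheno, pcs, "binary")
  e2 <- evaluate(mk_prs(ids, 5 * sc - 3), test$pheno, pcs, "binary")
  expect_equal(e1$delta_auc, e2$delta_auc, tolerance = 1e-8)
  expect_equal(e1$delta_r2, e2$delta_r2, tolerance = 1e-8)
  expect_equal(e1$delong_p, e2$delong_p, tolerance = 1e-8)

  # quantitative: PRS identical to the phenotype drives R2 to ~1
  phq <- test$pheno
  phq$phenotype <- s$effects$liability[match(ids, s$pheno$sample_id)]
  attr(phq, "trait_type") <- "quantitative"
  eq <- evaluate(mk_prs(ids, phq$phenotype), phq, pcs, "quantitative")
  expect_gt(eq$r2_III, 0.999)
  expect_equal(eq$delta_r2, eq$r2_III - eq$r2_II, tolerance = 1e-12)
})
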