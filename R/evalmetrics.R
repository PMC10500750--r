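# Model II vs Model III evaluation: logistic/linear fits, rank AUC, DeLong
# paired-AUC test, Nagelkerke pseudo-R2, extra-sum-of-squares F test, and
# covariate-stratified k-fold splits.
#
# Model I   : y ~ PRS
# Model II  : y ~ covariates + PCs        (no PRS)
# Model III : y ~ covariates + PCs + PRS
# Delta-AUC / Delta-R2 = gain of Model III over Model II.

align_eval_inputs <- function(pheno, prs = NULL, pcs = NULL) {
  ids <- pheno$sample_id
  if (!is.null(prs)) ids <- intersect(ids, prs$sample_ids)
  if (!is.null(pcs) && !is.null(rownames(pcs))) ids <- intersect(ids, rownames(pcs))
  dropped <- nrow(pheno) - length(ids)
  if (dropped > 0) log_msg("evalmetrics: %d sample(s) dropped in input join", dropped)
  if (!length(ids)) fail("no samples shared across evaluation inputs")
  df <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  if (!is.null(prs)) df$PRS <- prs$score[match(ids, prs$sample_ids)]
  if (!is.null(pcs) && ncol(pcs))
    df <- cbind(df, as.data.frame(pcs[match(ids, rownames(pcs)), , drop = FALSE]))
  rownames(df) <- NULL
  df
}

#' Fit Model I, II or III
#'
#' Binary traits are fit by logistic regression (IRLS, convergence epsilon
#' 1e-10, at most 25 iterations); quantitative traits by ordinary least
#' squares.  The intercept is always included.  A constant (or collinear
#' with the design) PRS column in Model III is dropped with a warning so
#' the degenerate Model III = Model II case evaluates to zero gain rather
#' than erroring.
#'
#' @param pheno phenotype data.frame (`sample_id`, `phenotype`, covariates).
#' @param prs a `prs_vector` (required for Models I and III).
#' @param pcs PC score matrix with sample-ID rownames (or NULL).
#' @param model `"I"`, `"II"` or `"III"`.
#' @param covariate_names covariate columns entering Models II/III.
#' @param n_pcs number of leading PCs entering Models II/III (default all
#'   supplied columns; the package-wide convention is 20).
#' @param trait_type `"binary"` or `"quantitative"`.
#' @return an object of class `prs_fit`: coefficients, `loglik` (binary)
#'   or `rss` (quantitative), linear-predictor `scores`, `n`, `converged`,
#'   plus the underlying `stats::glm`/`stats::lm` object.
#' @export
fit_model <- function(pheno, prs = NULL, pcs = NULL,
                      model = c("III", "I", "II"),
                      covariate_names = character(),
                      n_pcs = if (is.null(pcs)) 0L else ncol(pcs),
                      trait_type = c("binary", "quantitative")) {
  model <- match.arg(model)
  trait_type <- match.arg(trait_type)
  if (model %in% c("I", "III") && is.null(prs)) fail("Model %s requires a PRS", model)
  df <- align_eval_inputs(pheno, prs = if (model == "II") NULL else prs, pcs = pcs)
  terms <- character(0)
  if (model %in% c("II", "III")) {
    terms <- covariate_names
    if (n_pcs > 0) {
      pc_names <- paste0("PC", seq_len(n_pcs))
      if (!all(pc_names %in% names(df))) fail("n_pcs = %d but PCs missing", n_pcs)
      terms <- c(terms, pc_names)
    }
  }
  if (model %in% c("I", "III")) {
    if (var(df$PRS) == 0 && model == "III") {
      warning("fit_model: constant PRS dropped from Model III")
    } else terms <- c(terms, "PRS")
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- as.formula(paste("phenotype ~", rhs))
  if (trait_type == "binary") {
    if (length(unique(df$phenotype)) < 2) fail("binary phenotype has one class")
    fit <- glm(f, data = df, family = binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 25))
    ll <- as.numeric(logLik(fit)); rss <- NA_real_
    converged <- fit$converged
  } else {
    fit <- lm(f, data = df)
    rss <- sum(residuals(fit)^2); ll <- NA_real_
    converged <- TRUE
  }
  if (any(is.na(coef(fit)))) {
    nac <- names(coef(fit))[is.na(coef(fit))]
    if (identical(nac, "PRS") && model == "III") {
      warning("fit_model: PRS collinear with Model II design; dropped")
      return(fit_model(pheno, prs = NULL, pcs = pcs, model = "II",
                       covariate_names = covariate_names, n_pcs = n_pcs,
                       trait_type = trait_type))
    }
    fail("collinear design column(s): %s", paste(nac, collapse = ", "))
  }
  structure(list(model = model, coefficients = coef(fit), loglik = ll,
                 rss = rss, scores = as.numeric(predict(fit)),
                 sample_ids = df$sample_id, y = df$phenotype,
                 n = nrow(df), n_params = length(coef(fit)),
                 converged = converged, trait_type = trait_type,
                 terms = terms, fit = fit),
            class = "prs_fit")
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return the AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    fail("auc requires 0/1 labels with both classes present")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components via midranks (Sun & Xu 2014 formulation):
# V10[i] for cases, V01[j] for controls
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rx) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - ry) / m
  a <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = a, v10 = v10, v01 = v01)
}

#' DeLong test for the paired difference of two AUCs
#'
#' Both score vectors must be computed on the same samples.  The variance
#' of `auc(scores_III) - auc(scores_II)` is estimated from the DeLong
#' structural components and a two-sided normal p-value is returned.  A
#' zero-variance difference (e.g. identical score vectors) returns
#' `delta_auc` as observed and `p = 1` by convention.
#'
#' @param scores_II,scores_III paired prediction scores.
#' @param labels 0/1 labels.
#' @return list `delta_auc`, `p`, `auc_II`, `auc_III`, `se`.
#' @export
delong_delta_auc <- function(scores_II, scores_III, labels) {
  stopifnot(length(scores_II) == length(labels),
            length(scores_III) == length(labels))
  c2 <- delong_components(scores_II, labels)
  c3 <- delong_components(scores_III, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  d10 <- c3$v10 - c2$v10
  d01 <- c3$v01 - c2$v01
  v <- var(d10) / m + var(d01) / n
  delta <- c3$auc - c2$auc
  if (!is.finite(v) || v < 1e-14)
    return(list(delta_auc = delta, p = 1, auc_II = c2$auc, auc_III = c3$auc,
                se = sqrt(max(v, 0))))
  z <- delta / sqrt(v)
  list(delta_auc = delta, p = 2 * pnorm(-abs(z)),
       auc_II = c2$auc, auc_III = c3$auc, se = sqrt(v))
}

#' Nagelkerke pseudo-R-squared
#'
#' `R2 = (1 - exp((2/n) (LL0 - LL1))) / (1 - exp((2/n) LL0))` with `LL0`
#' the log-likelihood of the intercept-only null fit.
#'
#' @param fit a binary `prs_fit`.
#' @param null_fit the intercept-only `prs_fit` on the same samples.
#' @return the pseudo-R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit, null_fit) {
  stopifnot(inherits(fit, "prs_fit"), inherits(null_fit, "prs_fit"))
  if (fit$trait_type != "binary") fail("nagelkerke_r2 applies to binary fits")
  if (fit$n != null_fit$n) fail("fits are on different samples")
  ll1 <- fit$loglik; ll0 <- null_fit$loglik
  if (ll1 < ll0 - 1e-6) fail("nesting violated: full-model log-likelihood below null")
  n <- fit$n
  cs <- 1 - exp((2 / n) * (ll0 - ll1))      # Cox-Snell
  max_cs <- 1 - exp((2 / n) * ll0)
  max(cs / max_cs, 0)
}

#' Extra-sum-of-squares F test between nested linear models
#'
#' `F = ((RSS_II - RSS_III) / ddf) / (RSS_III / (n - p_III))`; the change in
#' adjusted R-squared is reported alongside.  `RSS_II = RSS_III` (or no
#' added parameters) yields `F = 0, p = 1`.
#'
#' @param fit_II,fit_III nested quantitative `prs_fit` objects (II within
#'   III).
#' @return list `delta_r2_adj`, `F`, `p`, `df1`, `df2`, plus the adjusted
#'   and unadjusted R-squared of both models.
#' @export
extra_ss_test <- function(fit_II, fit_III) {
  stopifnot(inherits(fit_II, "prs_fit"), inherits(fit_III, "prs_fit"))
  if (fit_II$trait_type != "quantitative" || fit_III$trait_type != "quantitative")
    fail("extra_ss_test applies to quantitative fits")
  if (fit_II$n != fit_III$n) fail("fits are on different samples")
  if (!all(names(fit_II$coefficients) %in% names(fit_III$coefficients)))
    fail("models are not nested (Model II terms missing from Model III)")
  n <- fit_III$n
  df1 <- fit_III$n_params - fit_II$n_params
  df2 <- n - fit_III$n_params
  tss <- sum((fit_II$y - mean(fit_II$y))^2)
  r2 <- function(f) 1 - f$rss / tss
  adj <- function(f) 1 - (f$rss / (n - f$n_params)) / (tss / (n - 1))
  if (df1 <= 0 || fit_II$rss - fit_III$rss <= 0) {
    Fstat <- 0; p <- 1
  } else {
    Fstat <- ((fit_II$rss - fit_III$rss) / df1) / (fit_III$rss / df2)
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  list(delta_r2_adj = adj(fit_III) - adj(fit_II), F = Fstat, p = p,
       df1 = df1, df2 = df2,
       r2_adj_II = adj(fit_II), r2_adj_III = adj(fit_III),
       r2_II = r2(fit_II), r2_III = r2(fit_III))
}

#' Covariate-stratified k-fold splits
#'
#' Samples are partitioned into `k` folds so that every stratum defined by
#' the (discretized) stratification columns is represented proportionally
#' in each fold (within-stratum fold counts differ by at most one).
#' Continuous columns are binned into quintiles.  Strata smaller than `k`
#' are merged into a single pooled stratum with a warning.  Each fold is a
#' 9:1-style discovery/test split: discovery = complement of the test fold.
#'
#' @param pheno phenotype data.frame with `sample_id`.
#' @param strat_columns columns to stratify on (e.g. `"phenotype"`, `"sex"`).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return list of `k` elements, each `list(discovery_ids, test_ids)`.
#' @export
stratified_kfold <- function(pheno, strat_columns, k = 10, seed = 1L) {
  if (k < 2) fail("k must be >= 2")
  miss <- setdiff(strat_columns, names(pheno))
  if (length(miss)) fail("stratification column(s) missing: %s",
                         paste(miss, collapse = ", "))
  disc <- lapply(strat_columns, function(cn) {
    x <- pheno[[cn]]
    if (is.numeric(x) && length(unique(x)) > 10) {
      br <- unique(quantile(x, probs = seq(0, 1, 0.2)))
      as.character(cut(x, breaks = br, include.lowest = TRUE))
    } else as.character(x)
  })
  stratum <- if (length(disc)) do.call(paste, c(disc, sep = "|")) else
    rep("all", nrow(pheno))
  tab <- table(stratum)
  small <- names(tab)[tab < k]
  if (length(small)) {
    warning(sprintf("stratified_kfold: %d stratum(a) smaller than k merged into one pooled stratum",
                    length(small)))
    stratum[stratum %in% small] <- ".pooled"
  }
  set.seed(seed)
  fold <- integer(nrow(pheno))
  offset <- 0L
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
    offset <- (offset + length(idx)) %% k
  }
  lapply(seq_len(k), function(i)
    list(discovery_ids = pheno$sample_id[fold != i],
         test_ids = pheno$sample_id[fold == i]))
}

#' Evaluate the additive gain of a PRS over the covariate model
#'
#' Fits Model II (covariates + PCs) and Model III (covariates + PCs + PRS)
#' and reports the headline gain metrics: for binary traits, Delta-AUC
#' with the DeLong p-value and Delta Nagelkerke R2; for quantitative
#' traits, Delta adjusted R2 with the extra-sum-of-squares F p-value.
#'
#' @param prs a `prs_vector`.
#' @param pheno phenotype data.frame.
#' @param pcs PC score matrix (rownames = sample IDs) or NULL.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param covariate_names covariate columns for Models II/III.
#' @param n_pcs leading PCs to include (default: all columns of `pcs`,
#'   package convention 20).
#' @return an object of class `delta_metrics`: `auc_II, auc_III, delta_auc,
#'   delong_p, r2_II, r2_III, delta_r2, r2_p, trait_type, n`.
#' @export
evaluate <- function(prs, pheno, pcs = NULL,
                     trait_type = c("binary", "quantitative"),
                     covariate_names = c("age", "sex"),
                     n_pcs = if (is.null(pcs)) 0L else ncol(pcs)) {
  trait_type <- match.arg(trait_type)
  # align all fits on the common sample set so Models II and III are paired
  ids <- intersect(pheno$sample_id, prs$sample_ids)
  if (!is.null(pcs) && !is.null(rownames(pcs))) ids <- intersect(ids, rownames(pcs))
  if (length(ids) < nrow(pheno))
    log_msg("evaluate: %d sample(s) dropped in input join", nrow(pheno) - length(ids))
  ph <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  attr(ph, "trait_type") <- attr(pheno, "trait_type")
  f2 <- fit_model(ph, prs = NULL, pcs = pcs, model = "II",
                  covariate_names = covariate_names, n_pcs = n_pcs,
                  trait_type = trait_type)
  f3 <- fit_model(ph, prs = prs, pcs = pcs, model = "III",
                  covariate_names = covariate_names, n_pcs = n_pcs,
                  trait_type = trait_type)
  if (trait_type == "binary") {
    null_fit <- fit_model(ph, prs = NULL, pcs = NULL, model = "II",
                          covariate_names = character(), n_pcs = 0L,
                          trait_type = "binary")
    dl <- delong_delta_auc(f2$scores, f3$scores, f2$y)
    r2_2 <- nagelkerke_r2(f2, null_fit)
    r2_3 <- nagelkerke_r2(f3, null_fit)
    out <- list(auc_II = dl$auc_II, auc_III = dl$auc_III,
                delta_auc = dl$delta_auc, delong_p = dl$p,
                r2_II = r2_2, r2_III = r2_3, delta_r2 = r2_3 - r2_2,
                r2_p = NA_real_, trait_type = trait_type, n = f2$n)
  } else {
    ess <- extra_ss_test(f2, f3)
    out <- list(auc_II = NA_real_, auc_III = NA_real_,
                delta_auc = NA_real_, delong_p = NA_real_,
                r2_II = ess$r2_adj_II, r2_III = ess$r2_adj_III,
                delta_r2 = ess$delta_r2_adj, r2_p = ess$p,
                r2_unadj_II = ess$r2_II, r2_unadj_III = ess$r2_III,
                trait_type = trait_type, n = f2$n)
  }
  structure(out, class = "delta_metrics")
}

#' @export
print.delta_metrics <- function(x, ...) {
  if (x$trait_type == "binary")
    cat(sprintf("delta_metrics (binary, n=%d): dAUC = %.4f (DeLong p = %.3g), dR2 = %.4f\n",
                x$n, x$delta_auc, x$delong_p, x$delta_r2))
  else
    cat(sprintf("delta_metrics (quantitative, n=%d): dR2_adj = %.4f (extra-SS p = %.3g)\n",
                x$n, x$delta_r2, x$r2_p))
  invisible(x)
}
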