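# Discovery-phase association testing: per-variant logistic (binary) or
# linear (quantitative) regression with covariates, and principal-component
# nuisance covariates.

# build a full-rank covariate design matrix (intercept first); factors are
# expanded to treatment contrasts
covariate_design <- function(pheno, covariate_names) {
  miss <- setdiff(covariate_names, names(pheno))
  if (length(miss)) fail("covariate(s) not in phenotype table: %s",
                         paste(miss, collapse = ", "))
  if (!length(covariate_names))
    return(matrix(1, nrow(pheno), 1, dimnames = list(NULL, "(Intercept)")))
  f <- as.formula(paste("~", paste(covariate_names, collapse = " + ")))
  X <- stats::model.matrix(f, data = pheno)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    fail("collinear covariate column(s): %s", paste(drop, collapse = ", "))
  }
  X
}

#' Per-variant association scan (GWAS)
#'
#' Fits `phenotype ~ dosage + covariates` for every variant: logistic
#' regression (IRLS, coefficient-change tolerance 1e-8, at most 25
#' iterations) for binary traits, ordinary least squares for quantitative
#' traits.  Wald statistics are reported (`z = beta / se`, two-sided normal
#' p).  Monomorphic variants get `beta = 0, p = 1` and are flagged; fits
#' that fail to converge (e.g. separation) are flagged `converged = FALSE`
#' and excluded by [filter_sumstats()].  Missing dosages are mean-imputed
#' for the fit (count logged).
#'
#' @param panel a `genotype_panel`.
#' @param pheno phenotype data.frame with `sample_id`, `phenotype` and any
#'   covariates; joined to the panel by sample ID (mismatches logged).
#' @param covariate_names character vector of covariate columns (may be
#'   empty).
#' @param trait_type `"binary"` or `"quantitative"`.
#' @return a `summary_stats` data.frame (one row per variant) with columns
#'   `variant_id, chrom, pos, effect_allele, other_allele, beta, se, z, p,
#'   n, maf, monomorphic, converged`.  The effect allele is the panel's
#'   counted allele.
#' @export
run_gwas <- function(panel, pheno, covariate_names = character(),
                     trait_type = c("binary", "quantitative")) {
  trait_type <- match.arg(trait_type)
  stopifnot(inherits(panel, "genotype_panel"))
  common <- intersect(panel$sample_ids, pheno$sample_id)
  if (length(common) < length(panel$sample_ids) ||
      length(common) < nrow(pheno))
    log_msg("run_gwas: %d sample(s) dropped in panel/phenotype join",
            length(panel$sample_ids) + nrow(pheno) - 2L * length(common))
  if (!length(common)) fail("no samples shared between panel and phenotypes")
  idx_g <- match(common, panel$sample_ids)
  ph <- pheno[match(common, pheno$sample_id), , drop = FALSE]
  y <- ph$phenotype
  if (trait_type == "binary") {
    if (!all(y %in% c(0, 1))) fail("binary trait must be coded 0/1")
    if (length(unique(y)) < 2) fail("binary trait has a single class")
  }
  G <- panel$dosage[idx_g, , drop = FALSE]
  nmiss <- sum(is.na(G))
  if (nmiss) {
    log_msg("run_gwas: mean-imputed %d missing dosage cell(s)", nmiss)
    cm <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- cm[na_idx[, 2]]
  }
  X <- covariate_design(ph, covariate_names)
  n <- length(y)
  mono <- col_var(G) == 0
  beta <- se <- rep(NA_real_, ncol(G))
  conv <- rep(TRUE, ncol(G))
  poly <- which(!mono)
  if (length(poly)) {
    if (trait_type == "binary") {
      res <- cpp_logistic_gwas(X, G[, poly, drop = FALSE], as.numeric(y),
                               1e-8, 25L)
      beta[poly] <- res[, 1]; se[poly] <- res[, 2]
      conv[poly] <- res[, 3] == 1
    } else {
      # Frisch-Waugh: residualize y and g on covariates, then per-variant
      # OLS slope with the exact full-model residual variance
      Q <- qr.Q(qr(X))
      ry <- y - Q %*% crossprod(Q, y)
      Gp <- G[, poly, drop = FALSE]
      Rg <- Gp - Q %*% crossprod(Q, Gp)
      gtg <- colSums(Rg^2)
      gty <- as.numeric(crossprod(Rg, ry))
      b <- gty / gtg
      dfres <- n - ncol(X) - 1L
      rss <- as.numeric(crossprod(ry)) - b^2 * gtg
      s2 <- pmax(rss, 0) / dfres
      beta[poly] <- b
      se[poly] <- sqrt(s2 / gtg)
      conv[poly] <- is.finite(b) & is.finite(se[poly]) & se[poly] > 0
    }
  }
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
  beta[mono] <- 0; se[mono] <- NA_real_; z[mono] <- 0; p[mono] <- 1
  fr <- colMeans(G) / 2
  out <- data.frame(variant_id = panel$variants$variant_id,
                    chrom = panel$variants$chrom,
                    pos = panel$variants$pos,
                    effect_allele = panel$variants$allele_counted,
                    other_allele = panel$variants$allele_other,
                    beta = beta, se = se, z = z, p = p,
                    n = n, maf = pmin(fr, 1 - fr),
                    monomorphic = mono, converged = conv,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Principal components of a genotype panel
#'
#' PCs of the column-standardized dosage matrix.  Scores are orthonormal
#' (unit-norm left singular vectors) with a deterministic sign convention:
#' the largest-magnitude variant loading of each component is positive.
#' Duplicated samples therefore receive identical scores.
#'
#' @param panel a `genotype_panel`.
#' @param k number of components, `0 <= k <= min(n_samples, n_variants)`.
#' @return numeric matrix `n_samples x k`, rownames = sample IDs, colnames
#'   `PC1..PCk`.
#' @export
compute_pcs <- function(panel, k) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$sample_ids); m <- nrow(panel$variants)
  if (k > min(n, m)) fail("k = %d exceeds min(n_samples, n_variants) = %d",
                          k, min(n, m))
  if (k == 0)
    return(matrix(numeric(0), n, 0, dimnames = list(panel$sample_ids, NULL)))
  G <- panel$dosage
  if (anyNA(G)) {
    cm <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- cm[na_idx[, 2]]
  }
  mu <- colMeans(G); s <- sqrt(col_var(G)); s[s == 0] <- 1
  Xs <- scale(G, center = mu, scale = s)
  if (n <= m) {
    K <- tcrossprod(Xs)
    eig <- eigen(K, symmetric = TRUE)
    U <- eig$vectors[, seq_len(k), drop = FALSE]
  } else {
    U <- svd(Xs, nu = k, nv = 0)$u
  }
  # sign convention via the loadings
  V <- crossprod(Xs, U)
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) U[, j] <- -U[, j]
  }
  dimnames(U) <- list(panel$sample_ids, paste0("PC", seq_len(k)))
  U
}
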