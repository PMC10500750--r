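#' @useDynLib prsoverlap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.formula binomial coef cor glm lm logLik pchisq pf
#'   pnorm qnorm quantile rbinom rnorm runif sd setNames var prcomp
#'   ks.test cor.test residuals
#' @importFrom utils head
NULL

# internal logging: informative messages that callers can silence with
# suppressMessages(); never cat() so output is testable
log_msg <- function(...) message(sprintf(...))

#' Derive a child seed from a master seed
#'
#' Counter-based derivation so that every cell of an experiment grid is
#' re-runnable in isolation from `(master_seed, counter)` alone.  Values stay
#' below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer counter.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter), counter >= 0)
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) * 1009 + as.numeric(counter) * 735632791 + 12345
  as.integer(x %% (m - 2)) + 1L
}

# stop() with sprintf formatting
fail <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-pass column variance (no per-column apply); NA-free input assumed
col_var <- function(G) {
  n <- nrow(G)
  cm <- colMeans(G)
  pmax(colSums(G * G) - n * cm^2, 0) / (n - 1)
}
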