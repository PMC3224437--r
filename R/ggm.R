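#' Pearson correlation matrix
#'
#' Product-moment correlations between metabolite columns.  Zero-variance
#' columns are rejected with the offending column named, since a correlation
#' is undefined for them.
#'
#' @param X numeric matrix (samples x metabolites) or a
#'   [concentration_ensemble()].
#' @return symmetric m x m matrix with unit diagonal.
#' @export
pearson_matrix <- function(X) {
  X <- as_log_matrix(X)
  if (nrow(X) < 3) stop("at least 3 samples are required")
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  }
  stats::cor(X)
}

#' Partial correlation matrix from a correlation matrix
#'
#' Full-order partial correlations are read off the inverse of the Pearson
#' correlation matrix: with `omega = solve(P)`,
#' `zeta_ij = -omega_ij / sqrt(omega_ii * omega_jj)`.  The diagonal, which
#' the formula would set to -1, is fixed to 1 by convention and excluded
#' from downstream statistics.  The inverse is computed via a Cholesky
#' factorization with a condition-number guard: estimating a GGM needs more
#' samples than metabolites, otherwise the sample correlation matrix is
#' singular or ill-conditioned.
#'
#' @param P symmetric positive-definite correlation matrix.
#' @param max_condition condition-number threshold above which the matrix is
#'   treated as numerically singular.
#' @return symmetric matrix of partial correlations with unit diagonal.
#' @export
partial_matrix <- function(P, max_condition = 1e12) {
  P <- as.matrix(P)
  if (!isSymmetric(P, tol = 1e-8)) stop("P must be symmetric")
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(ch) || kappa(P, exact = FALSE) > max_condition) {
    stop("correlation matrix is singular or ill-conditioned; ",
         "a GGM requires more samples than metabolites (n > m)")
  }
  omega <- chol2inv(ch)
  d <- sqrt(diag(omega))
  Z <- -omega / tcrossprod(d)
  diag(Z) <- 1
  dimnames(Z) <- dimnames(P)
  (Z + t(Z)) / 2
}

#' Fisher-z p-value for a (partial) correlation
#'
#' Two-sided significance of a correlation of order `q` estimated from `n`
#' samples: `z = atanh(zeta)`, `p = 2 * (1 - pnorm(sqrt(n - q - 3) * |z|))`.
#' For the full-order GGM on m metabolites use `q = m - 2`; for Pearson
#' correlations `q = 0`; for low-order partial correlations `q` is the
#' conditioning-set size.
#'
#' @param zeta correlation value(s) in \[-1, 1\] (vectorized).
#' @param n sample count.
#' @param q conditioning order; `n - q - 3` must be positive.
#' @return p-value(s) in \[0, 1\].  Inputs with `|zeta| = 1` return an exact
#'   zero and set the `"exact_zero"` attribute.
#' @export
fisher_pvalue <- function(zeta, n, q) {
  if (any(abs(zeta) > 1)) stop("|zeta| must be <= 1")
  if (n - q - 3 <= 0) stop("n - q - 3 must be > 0 (too few samples)")
  z <- atanh(pmin(pmax(zeta, -1), 1))
  p <- 2 * (1 - stats::pnorm(sqrt(n - q - 3) * abs(z)))
  p <- pmin(pmax(p, 0), 1)
  if (any(abs(zeta) == 1)) attr(p, "exact_zero") <- which(abs(zeta) == 1)
  p
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha nominal level in (0, 1].
#' @param n_tests number of tests; for an m-metabolite panel this is
#'   `choose(m, 2)`.
#' @export
bonferroni_alpha <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

#' Correlation cutoff equivalent to a significance level
#'
#' Inverts the Fisher-z test: the absolute correlation at which the
#' two-sided p-value equals `alpha_adj`,
#' `tanh(qnorm(1 - alpha_adj/2) / sqrt(n - q - 3))`.  Monotone decreasing in
#' `n`.
#'
#' @inheritParams fisher_pvalue
#' @param alpha_adj adjusted significance level in (0, 1).
#' @export
significance_cutoff <- function(alpha_adj, n, q) {
  stopifnot(alpha_adj > 0, alpha_adj < 1)
  if (n - q - 3 <= 0) stop("n - q - 3 must be > 0")
  tanh(stats::qnorm(1 - alpha_adj / 2) / sqrt(n - q - 3))
}

#' Estimate the Gaussian graphical model of a metabolite panel
#'
#' Computes Pearson and full-order partial correlations of the (log-scale)
#' concentration matrix, Fisher-z p-values for both, the Bonferroni-adjusted
#' significance level for all `choose(m, 2)` pairwise tests and the
#' equivalent absolute-correlation cutoff.
#'
#' @param X numeric matrix (samples x metabolites) or
#'   [concentration_ensemble()]; values must already be on log scale.
#' @param alpha nominal significance level.
#' @param correction `"bonferroni"` or `"none"`.
#' @return object of class `correlation_result` with components `P`, `Z`,
#'   `p_pearson`, `p_partial`, `n`, `m`, `order_q`, `alpha`, `alpha_adj`,
#'   `cutoff`, `annotation`.
#' @examples
#' net <- make_network("chain_reversible")
#' ens <- simulate_ensemble(net, sigma = 0.2, n_samples = 200, seed = 1)
#' res <- ggm(ens)
#' res$Z
#' @export
ggm <- function(X, alpha = 0.01, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  annotation <- if (inherits(X, "concentration_ensemble")) X$annotation else NULL
  X <- as_log_matrix(X)
  n <- nrow(X); m <- ncol(X)
  P <- pearson_matrix(X)
  Z <- partial_matrix(P)
  q <- m - 2
  n_tests <- choose(m, 2)
  alpha_adj <- if (correction == "bonferroni") bonferroni_alpha(alpha, n_tests) else alpha
  p_pearson <- offdiag_apply(P, fisher_pvalue, n = n, q = 0)
  p_partial <- offdiag_apply(Z, fisher_pvalue, n = n, q = q)
  structure(
    list(P = P, Z = Z, p_pearson = p_pearson, p_partial = p_partial,
         n = n, m = m, order_q = q, alpha = alpha, alpha_adj = alpha_adj,
         cutoff = significance_cutoff(alpha_adj, n, q),
         annotation = annotation),
    class = "correlation_result"
  )
}

offdiag_apply <- function(M, f, ...) {
  out <- f(M, ...)
  out <- matrix(as.numeric(out), nrow(M), ncol(M), dimnames = dimnames(M))
  diag(out) <- 1  # self-correlation is never tested
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  sig <- sum(x$p_partial[upper.tri(x$p_partial)] <= x$alpha_adj)
  cat("<correlation_result> n =", x$n, ", m =", x$m, "\n")
  cat("  adjusted alpha:", format(x$alpha_adj, digits = 3),
      " |zeta| cutoff:", format(x$cutoff, digits = 4), "\n")
  cat("  significant partial correlations:", sig, "of", choose(x$m, 2), "\n")
  invisible(x)
}

#' Long-format edge table of a correlation result
#'
#' @param result a `correlation_result`.
#' @return data frame with one row per unordered metabolite pair: Pearson
#'   and partial correlations, both p-values and significance flags at the
#'   adjusted level.
#' @export
edge_table <- function(result) {
  stopifnot(inherits(result, "correlation_result"))
  ids <- colnames(result$Z)
  idx <- which(upper.tri(result$Z), arr.ind = TRUE)
  data.frame(
    met_a = ids[idx[, 1]],
    met_b = ids[idx[, 2]],
    pearson = result$P[idx],
    partial = result$Z[idx],
    p_pearson = result$p_pearson[idx],
    p_partial = result$p_partial[idx],
    sig_pearson = result$p_pearson[idx] <= result$alpha_adj,
    sig_partial = result$p_partial[idx] <= result$alpha_adj,
    stringsAsFactors = FALSE
  )
}
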