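#' Low-order partial correlations
#'
#' First-, second- and third-order partial correlations condition each
#' metabolite pair on every subset of `q` other metabolites rather than on
#' all of them, which needs far fewer samples than the full-order GGM.
#' Order-1 values follow
#' `zeta_ij|k = (rho_ij - rho_ik rho_jk) / sqrt((1 - rho_ik^2)(1 - rho_jk^2))`
#' and higher orders the standard recursion on the conditioning set.
#'
#' An edge survives only if the order-q partial correlation is significant
#' (Fisher-z at `alpha_adj` with conditioning order `q`) for *every*
#' conditioning subset; the reported value per pair is the minimum-magnitude
#' partial correlation over subsets, i.e. the most conservative one.
#'
#' @param X matrix or [concentration_ensemble()] of log concentrations.
#' @param q conditioning-set size (1, 2 or 3; must satisfy `q < m - 1`).
#' @param alpha_adj adjusted significance level for the edge rule.
#' @return list with `Z_min` (matrix of minimal-magnitude order-q partial
#'   correlations, unit diagonal), `keep` (logical edge mask), `q`, `n`.
#' @export
low_order_partial <- function(X, q, alpha_adj) {
  stopifnot(q %in% 1:3)
  X <- as_log_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (q >= m - 1) stop("q must be < m - 1; use the full-order GGM instead")
  if (n <= q + 2) stop("too few samples for order-", q, " partial correlations")
  P <- pearson_matrix(X)
  ids <- colnames(P)
  Z_min <- diag(1, m); dimnames(Z_min) <- dimnames(P)
  keep <- matrix(FALSE, m, m, dimnames = dimnames(P))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      others <- setdiff(seq_len(m), c(i, j))
      sets <- if (length(others) == 1L) matrix(others) else utils::combn(others, q)
      vals <- apply(sets, 2, function(K) pcor_recursive(P, i, j, K))
      pvals <- fisher_pvalue(vals, n, q)
      best <- which.min(abs(vals))
      Z_min[i, j] <- Z_min[j, i] <- vals[best]
      keep[i, j] <- keep[j, i] <- all(pvals <= alpha_adj)
    }
  }
  list(Z_min = Z_min, keep = keep, q = q, n = n)
}

# partial correlation of variables i, j given the (index vector) set K,
# by the recursion on the last conditioning variable
pcor_recursive <- function(P, i, j, K) {
  if (length(K) == 0) return(P[i, j])
  k <- K[length(K)]
  rest <- K[-length(K)]
  r_ij <- pcor_recursive(P, i, j, rest)
  r_ik <- pcor_recursive(P, i, k, rest)
  r_jk <- pcor_recursive(P, j, k, rest)
  (r_ij - r_ik * r_jk) / sqrt((1 - r_ik^2) * (1 - r_jk^2))
}
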