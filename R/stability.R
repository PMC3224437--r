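#' Bootstrap stability of the partial correlation matrix
#'
#' Resamples the rows of the data matrix with replacement `B` times,
#' re-estimates the partial correlation matrix and summarizes, over
#' resamples, the mean absolute off-diagonal difference from the
#' original matrix.  Resamples whose correlation matrix is singular or
#' ill-conditioned are skipped and counted.
#'
#' @param X matrix or [concentration_ensemble()] of log concentrations.
#' @param B number of bootstrap resamples (>= 2).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, `B`, `n_skipped`, `differences`.
#' @export
bootstrap_stability <- function(X, B = 100, seed = 1) {
  stopifnot(B >= 2)
  X <- as_log_matrix(X)
  set.seed(seed)
  Z0 <- partial_matrix(pearson_matrix(X))
  diffs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
    Zb <- tryCatch(partial_matrix(pearson_matrix(X[idx, , drop = FALSE])),
                   error = function(e) NULL)
    if (is.null(Zb)) next
    diffs[b] <- mean(abs(Zb - Z0)[upper.tri(Z0)])
  }
  ok <- diffs[!is.na(diffs)]
  list(mean = mean(ok), sd = stats::sd(ok), B = B,
       n_skipped = sum(is.na(diffs)), differences = diffs)
}

#' Subsampling stability for decreasing sample sizes
#'
#' Draws, without replacement, subsets of the requested sizes and compares
#' the re-estimated partial correlations to those of the full data set using
#' the same mean-absolute-difference statistic as [bootstrap_stability()].
#' Sizes at or below the number of metabolites leave the correlation matrix
#' ill-conditioned; such replicates are skipped and reported.
#'
#' @param X matrix or [concentration_ensemble()].
#' @param sizes integer vector of subsample sizes (each <= n).
#' @param reps replicates per size (>= 2).
#' @param seed integer seed.
#' @return data frame with one row per size: `size`, `mean`, `sd`,
#'   `n_skipped`.
#' @export
subsample_stability <- function(X, sizes, reps = 100, seed = 1) {
  stopifnot(reps >= 2)
  X <- as_log_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (any(sizes > n)) stop("subsample sizes must not exceed n = ", n)
  set.seed(seed)
  Z0 <- partial_matrix(pearson_matrix(X))
  rows <- lapply(sizes, function(s) {
    diffs <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      if (s <= m) next  # guaranteed singular: skip without attempting
      idx <- sample.int(n, s, replace = FALSE)
      Zs <- tryCatch(partial_matrix(pearson_matrix(X[idx, , drop = FALSE])),
                     error = function(e) NULL)
      if (is.null(Zs)) next
      diffs[r] <- mean(abs(Zs - Z0)[upper.tri(Z0)])
    }
    ok <- diffs[!is.na(diffs)]
    data.frame(size = s,
               mean = if (length(ok)) mean(ok) else NA_real_,
               sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
               n_skipped = sum(is.na(diffs)))
  })
  do.call(rbind, rows)
}
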