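# shared fixtures built in code

# two disconnected 4-cliques, classes along the cliques
two_cliques_graph <- function() {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  metabolite_graph(A, rep(c("a", "b"), each = 4))
}

# path on 4 nodes 1-2-3-4, split {1,2} | {3,4}
path4_graph <- function() {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  A[3, 4] <- A[4, 3] <- 1
  metabolite_graph(A, c("a", "a", "b", "b"))
}

# ensembles of library networks are reused across test files via a cache
.sim_cache <- new.env(parent = emptyenv())
cached_ensemble <- function(name, n = 1000, sigma = 0.2, seed = 7) {
  key <- paste(name, n, sigma, seed, sep = "|")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_ensemble(make_network(name), sigma = sigma,
                                           n_samples = n, seed = seed)
  }
  .sim_cache[[key]]
}

cached_ggm <- function(name, n = 1000, sigma = 0.2, seed = 7) {
  ggm(cached_ensemble(name, n, sigma, seed))
}

# adjacency of significantly positive partial correlations
positive_adjacency <- function(result) {
  unname(threshold_graph(result)$adjacency)
}

# expected binary adjacency from an edge list over node names
adjacency_from_edges <- function(nodes, edges) {
  A <- matrix(0, length(nodes), length(nodes))
  for (i in seq_len(nrow(edges))) {
    a <- match(edges[i, 1], nodes)
    b <- match(edges[i, 2], nodes)
    A[a, b] <- A[b, a] <- 1
  }
  A
}

# partial correlation of columns i, j by regressing both on the rest
# (independent construction used as the oracle for partial_matrix)
regression_partial <- function(X, i, j) {
  others <- setdiff(seq_len(ncol(X)), c(i, j))
  ri <- stats::lm.fit(cbind(1, X[, others]), X[, i])$residuals
  rj <- stats::lm.fit(cbind(1, X[, others]), X[, j])$residuals
  stats::cor(ri, rj)
}
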