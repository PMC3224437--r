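#' Relative out-degree between node classes
#'
#' For a partition (V_1, ..., V_K) of the nodes, `R[i, j]` is the proportion
#' of class i's edge endpoints that land in class j:
#' `R_ij = A(V_i, V_j) / A(V_i, V)` where `A(V', V'')` sums adjacency
#' entries over the two node sets (so each within-class edge contributes
#' twice to `A(V_i, V_i)`).  Rows of classes with at least one edge sum to
#' one; classes without any edge get a zero row and are flagged.
#'
#' @param graph a [metabolite_graph()].
#' @param partition class label per node (defaults to the graph's classes).
#' @return K x K matrix with a `zero_degree_classes` attribute.
#' @export
relative_outdegree <- function(graph, partition = graph$classes) {
  A <- graph$adjacency
  stopifnot(length(partition) == length(graph$nodes))
  cls <- sort(unique(as.character(partition)))
  K <- length(cls)
  Acc <- matrix(0, K, K, dimnames = list(cls, cls))
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      Acc[a, b] <- sum(A[partition == cls[a], partition == cls[b], drop = FALSE])
    }
  }
  deg <- rowSums(Acc)
  R <- Acc / ifelse(deg == 0, 1, deg)
  R[deg == 0, ] <- 0
  attr(R, "zero_degree_classes") <- cls[deg == 0]
  R
}

#' Class-based network modularity
#'
#' Compares within-class edges with the expectation from class degrees:
#' `Q = sum_i [ A(V_i, V_i)/A(V, V) - (A(V_i, V)/A(V, V))^2 ]`.  Applies to
#' binary and weighted adjacency alike.  `Q = 0` when all nodes share one
#' class; two equal disconnected cliques split along their classes give
#' `Q = 0.5`.
#'
#' @inheritParams relative_outdegree
#' @export
modularity_Q <- function(graph, partition = graph$classes) {
  A <- abs(graph$adjacency)
  if (sum(A) == 0) stop("modularity is undefined for an edgeless graph")
  stopifnot(length(partition) == length(graph$nodes))
  cls <- unique(as.character(partition))
  total <- sum(A)
  sum(vapply(cls, function(cl) {
    within <- sum(A[partition == cl, partition == cl, drop = FALSE])
    out <- sum(A[partition == cl, , drop = FALSE])
    within / total - (out / total)^2
  }, numeric(1)))
}

#' Degree-preserving edge rewiring
#'
#' Randomizes a graph by repeated double-edge swaps: two edges (a, b) and
#' (c, d) are replaced by (a, d) and (c, b).  Swaps that would create a
#' self-loop or a multi-edge are redrawn, so the degree sequence is
#' preserved exactly.  On weighted graphs each edge weight travels with the
#' stub of its first endpoint (a neighbor-preserving weighted variant).
#'
#' @param graph a [metabolite_graph()] with at least 2 edges.
#' @param n_swaps number of swaps; the default `5 * e` gives sufficient
#'   randomization.
#' @param seed optional integer seed.
#' @return a rewired `metabolite_graph` with identical degree sequence.
#' @export
rewire_graph <- function(graph, n_swaps = 5 * graph$e, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (graph$e < 2) stop("rewiring needs at least 2 edges")
  A <- graph$adjacency
  idx <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  edges <- cbind(idx, w = A[idx])
  n_edges <- nrow(edges)
  adj <- A != 0
  done <- 0
  attempts <- 0
  max_attempts <- 100 * n_swaps
  while (done < n_swaps && attempts < max_attempts) {
    attempts <- attempts + 1
    pick <- sample.int(n_edges, 2)
    a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
    c_ <- edges[pick[2], 1]; d <- edges[pick[2], 2]
    # randomly orient the second edge so both pairings are reachable
    if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    if (length(unique(c(a, b, c_, d))) < 4) next
    if (adj[a, d] || adj[c_, b]) next
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c_, d] <- adj[d, c_] <- FALSE
    adj[a, d] <- adj[d, a] <- TRUE
    adj[c_, b] <- adj[b, c_] <- TRUE
    w1 <- edges[pick[1], 3]; w2 <- edges[pick[2], 3]
    edges[pick[1], ] <- c(a, d, w1)
    edges[pick[2], ] <- c(c_, b, w2)
    done <- done + 1
  }
  if (done == 0) {
    warning("no valid double-edge swap exists; returning the input graph")
    return(graph)
  }
  A_new <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (r in seq_len(n_edges)) {
    A_new[edges[r, 1], edges[r, 2]] <- edges[r, 3]
    A_new[edges[r, 2], edges[r, 1]] <- edges[r, 3]
  }
  out <- metabolite_graph(A_new, graph$classes)
  stopifnot(identical(rowSums(out$adjacency != 0),
                      rowSums(graph$adjacency != 0)))
  out
}

#' Modularity z-score against a rewiring null model
#'
#' Compares the observed class modularity with the distribution obtained
#' from degree-preserving randomizations of the same graph:
#' `z = (Q_obs - mean(Q_null)) / sd(Q_null)`.
#'
#' @inheritParams relative_outdegree
#' @param n_random number of randomized graphs (>= 10).
#' @param seed integer seed.
#' @param drop_singletons exclude classes with a single member from the
#'   partition-based statistics (their modularity contribution is not
#'   meaningful); a note is emitted when any are dropped.
#' @return object of class `modularity_result`: list with `Q`, `R`,
#'   `null_mean`, `null_sd`, `z_score`, `n_random`, `Q_null`.
#' @export
modularity_zscore <- function(graph, partition = graph$classes,
                              n_random = 100, seed = 1,
                              drop_singletons = TRUE) {
  stopifnot(n_random >= 10)
  partition <- as.character(partition)
  if (drop_singletons) {
    sizes <- table(partition)
    single <- names(sizes)[sizes == 1]
    if (length(single)) {
      message("dropping singleton class(es): ", paste(single, collapse = ", "))
      keep <- !partition %in% single
      graph <- metabolite_graph(graph$adjacency[keep, keep, drop = FALSE],
                                graph$classes[keep])
      partition <- partition[keep]
    }
  }
  set.seed(seed)
  Q_obs <- modularity_Q(graph, partition)
  Q_null <- vapply(seq_len(n_random), function(i) {
    modularity_Q(rewire_graph(graph), partition)
  }, numeric(1))
  null_sd <- stats::sd(Q_null)
  structure(
    list(Q = Q_obs, R = relative_outdegree(graph, partition),
         null_mean = mean(Q_null), null_sd = null_sd,
         z_score = if (null_sd > 0) (Q_obs - mean(Q_null)) / null_sd
                   else if (isTRUE(all.equal(Q_obs, mean(Q_null)))) 0
                   else NA_real_,
         n_random = n_random, Q_null = Q_null),
    class = "modularity_result"
  )
}

#' @export
print.modularity_result <- function(x, ...) {
  cat("<modularity_result> Q =", format(x$Q, digits = 4),
      "; null =", format(x$null_mean, digits = 3), "+/-",
      format(x$null_sd, digits = 3),
      "; z =", format(x$z_score, digits = 4), "\n")
  invisible(x)
}

#' Partition optimization by simulated annealing
#'
#' Searches node-to-class assignments maximizing [modularity_Q()] with
#' single-node move proposals and geometric cooling.  The best partition
#' ever visited is returned, so the result is never worse than the initial
#' partition.
#'
#' @param graph a [metabolite_graph()] with at least one edge.
#' @param seed integer seed.
#' @param initial initial assignment (defaults to singleton classes).
#' @param t0 initial temperature.
#' @param cooling geometric cooling factor per sweep.
#' @param sweeps number of sweeps (each attempts one move per node).
#' @return list with `partition` (integer labels per node) and `Q`.
#' @export
anneal_partition <- function(graph, seed = 1, initial = NULL,
                             t0 = 0.05, cooling = 0.95, sweeps = 200) {
  set.seed(seed)
  n <- length(graph$nodes)
  part <- if (is.null(initial)) seq_len(n) else as.integer(factor(initial))
  Q <- modularity_Q(graph, part)
  best <- list(partition = part, Q = Q)
  temp <- t0
  for (s in seq_len(sweeps)) {
    for (step in seq_len(n)) {
      node <- sample.int(n, 1)
      new_label <- sample(c(unique(part), max(part) + 1L), 1)
      if (new_label == part[node]) next
      cand <- part
      cand[node] <- new_label
      Q_new <- modularity_Q(graph, cand)
      if (Q_new >= Q || stats::runif(1) < exp((Q_new - Q) / temp)) {
        part <- cand
        Q <- Q_new
        if (Q > best$Q) best <- list(partition = part, Q = Q)
      }
    }
    temp <- temp * cooling
  }
  best$partition <- as.integer(factor(best$partition))
  names(best$partition) <- graph$nodes
  best
}
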