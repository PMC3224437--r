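#' Metabolite graph container
#'
#' Undirected graph over metabolites, stored as a symmetric weight matrix
#' (binary for unweighted graphs) with a class label per node and no
#' self-loops.
#'
#' @param adjacency symmetric numeric matrix with zero diagonal; nonzero
#'   entries are edges (their values the weights).
#' @param classes character vector of node class labels (defaults to a
#'   single class).
#' @export
metabolite_graph <- function(adjacency, classes = NULL) {
  A <- as.matrix(adjacency)
  stopifnot(nrow(A) == ncol(A))
  if (is.null(colnames(A))) {
    colnames(A) <- rownames(A) <- paste0("V", seq_len(ncol(A)))
  }
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("self-loops are not allowed")
  if (is.null(classes)) classes <- rep("all", ncol(A))
  stopifnot(length(classes) == ncol(A))
  structure(
    list(adjacency = A, nodes = colnames(A),
         classes = stats::setNames(as.character(classes), colnames(A)),
         e = sum(A != 0) / 2),
    class = "metabolite_graph"
  )
}

#' @export
print.metabolite_graph <- function(x, ...) {
  cat("<metabolite_graph> ", length(x$nodes), " nodes, ", x$e, " edges\n",
      sep = "")
  invisible(x)
}

#' Threshold a correlation result into a graph
#'
#' Builds the unweighted (or partial-correlation-weighted) graph induced by
#' significant partial correlations: an edge joins metabolites whose partial
#' correlation has `p <= alpha_adj` and satisfies the requested sign
#' condition.
#'
#' @param result a `correlation_result`.
#' @param mode `"positive"` (significantly positive edges, the default),
#'   `"negative"`, or `"both"`.
#' @param alpha_adj significance level (defaults to the result's adjusted
#'   level).
#' @param weighted if `TRUE`, edges carry the partial correlation as
#'   weight.
#' @export
threshold_graph <- function(result, mode = c("positive", "negative", "both"),
                            alpha_adj = result$alpha_adj, weighted = FALSE) {
  stopifnot(inherits(result, "correlation_result"))
  mode <- match.arg(mode)
  # a level-0 test rejects nothing, even where p underflows to exactly zero
  sig <- result$p_partial <= alpha_adj & alpha_adj > 0
  keep <- switch(mode,
    positive = sig & result$Z > 0,
    negative = sig & result$Z < 0,
    both = sig & result$Z != 0
  )
  diag(keep) <- FALSE
  A <- ifelse(keep, if (weighted) result$Z else 1, 0)
  dimnames(A) <- dimnames(result$Z)
  classes <- if (!is.null(result$annotation)) result$annotation$class else NULL
  metabolite_graph(A, classes)
}

#' One-negative/two-positive correlation triads
#'
#' Finds all unordered metabolite triples whose three pairwise partial
#' correlations comprise exactly two significantly positive and one
#' significantly negative value.  The negatively correlated pair is the
#' predicted distance-2 pair: two metabolites that both react with a shared
#' neighbor but have no direct reaction tend to show a negative partial
#' correlation with each other.
#'
#' @param result a `correlation_result`.
#' @param alpha_adj significance level (defaults to the result's).
#' @return data frame with columns `hub`, `neg_a`, `neg_b`: `neg_a`/`neg_b`
#'   share the negative edge and both connect positively to `hub`.
#' @export
find_triads <- function(result, alpha_adj = result$alpha_adj) {
  stopifnot(inherits(result, "correlation_result"))
  sig <- result$p_partial <= alpha_adj
  diag(sig) <- FALSE
  pos <- sig & result$Z > 0
  neg <- sig & result$Z < 0
  ids <- colnames(result$Z)
  out <- list()
  neg_idx <- which(neg & upper.tri(neg), arr.ind = TRUE)
  for (row in seq_len(nrow(neg_idx))) {
    i <- neg_idx[row, 1]; j <- neg_idx[row, 2]
    hubs <- which(pos[i, ] & pos[j, ])
    for (k in hubs) {
      out[[length(out) + 1]] <- data.frame(
        hub = ids[k], neg_a = ids[i], neg_b = ids[j],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(hub = character(), neg_a = character(),
                      neg_b = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Convert to an igraph object
#'
#' @param graph a `metabolite_graph`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "metabolite_graph"))
  g <- igraph::graph_from_adjacency_matrix(abs(graph$adjacency),
                                           mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$class <- unname(graph$classes[igraph::V(g)$name])
  g
}

#' Export a graph
#'
#' `write_edge_list()` writes a delimited table (source, target, weight,
#' sign); `write_graphml()` writes GraphML with the class attribute on
#' nodes.
#'
#' @param graph a `metabolite_graph`.
#' @param file output path.
#' @export
write_edge_list <- function(graph, file) {
  idx <- which(graph$adjacency != 0 & upper.tri(graph$adjacency),
               arr.ind = TRUE)
  w <- graph$adjacency[idx]
  df <- data.frame(source = graph$nodes[idx[, 1]],
                   target = graph$nodes[idx[, 2]],
                   weight = w, sign = ifelse(w >= 0, "+", "-"))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(graph, file) {
  igraph::write_graph(as_igraph(graph), file, format = "graphml")
  invisible(file)
}
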