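#' Shortest reaction-step distance between two fatty acids
#'
#' Breadth-first shortest path length on the undirected reaction graph of
#' one projection domain.  Reaction reversibility is not modeled, so
#' distances are symmetric; unconnected fatty acids get `Inf`.
#'
#' @param fa1,fa2 fatty-acid ids (`"C18:2"`).
#' @param model a [pathway_model()].
#' @param domain `"biosynthesis"` (default) or `"beta_oxidation"`.
#' @export
fatty_acid_distance <- function(fa1, fa2, model = default_pathway_model(),
                                domain = "biosynthesis") {
  D <- domain_distance_matrix(model, domain)
  for (fa in c(fa1, fa2)) {
    if (!fa %in% rownames(D)) {
      stop("fatty acid '", fa, "' is not in the ", domain, " model")
    }
  }
  unname(D[fa1, fa2])
}

# cached all-pairs BFS distances of one domain
domain_distance_matrix <- function(model, domain) {
  cache <- attr(model, "distance_cache")
  if (!is.null(cache[[domain]])) return(cache[[domain]])
  igraph::distances(domain_graph(model, domain))
}

# precompute and attach distance caches (used by distance_matrix for speed)
with_distance_cache <- function(model) {
  attr(model, "distance_cache") <- list(
    biosynthesis = igraph::distances(domain_graph(model, "biosynthesis")),
    beta_oxidation = igraph::distances(domain_graph(model, "beta_oxidation"))
  )
  model
}

#' Side-chain decompositions of a brutto-composition lipid
#'
#' A measured lipid only reports the summed carbon and double-bond counts
#' of its fatty-acid residues.  For one-residue lipids the decomposition is
#' the fatty acid itself (when the model contains it); for two-residue
#' lipids all unordered pairs of model fatty acids whose carbons and double
#' bonds add up to the measured totals are returned.
#'
#' @param annotation a [parse_metabolite_name()] result (or an id string).
#' @param model a [pathway_model()].
#' @return list of character vectors, each of length `residues`; empty when
#'   no decomposition exists.
#' @examples
#' enumerate_sidechain_variants("PC aa C38:4")
#' @export
enumerate_sidechain_variants <- function(annotation,
                                         model = default_pathway_model()) {
  if (is.character(annotation)) annotation <- parse_metabolite_name(annotation)
  stopifnot(inherits(annotation, "lipid_annotation"))
  if (is.na(annotation$residues)) {
    stop("'", annotation$id, "' is not a fatty-acid based lipid")
  }
  nd <- model$nodes[model$nodes$domain == "biosynthesis", , drop = FALSE]
  if (annotation$residues == 1L) {
    fa <- sprintf("C%d:%d", annotation$carbons, annotation$double_bonds)
    return(if (fa %in% nd$fa) list(fa) else list())
  }
  out <- list()
  for (i in seq_len(nrow(nd))) {
    c2 <- annotation$carbons - nd$carbons[i]
    b2 <- annotation$double_bonds - nd$double_bonds[i]
    if (c2 < nd$carbons[i] || (c2 == nd$carbons[i] && b2 < nd$double_bonds[i])) {
      next  # enumerate unordered pairs once
    }
    partner <- nd$fa[nd$carbons == c2 & nd$double_bonds == b2]
    if (length(partner)) {
      out[[length(out) + 1]] <- c(nd$fa[i], partner[1])
    }
  }
  out
}

#' Pathway distance between two measured metabolites
#'
#' Minimal number of reaction steps between two metabolites, minimized over
#' all side-chain decompositions consistent with their brutto compositions.
#' For two-residue lipids the residues of both variants are matched so as to
#' minimize the summed per-residue distances.  Lipid classes are projected
#' onto the fatty-acid biosynthesis domain, acyl-carnitines onto the
#' beta-oxidation chain; pairs across domains, amino acids and hexose are
#' not applicable and return `NA`.
#'
#' @param met1,met2 metabolite ids.
#' @param model a [pathway_model()].
#' @return number of steps (0 for identical metabolites, `Inf` when no
#'   finite decomposition pair is connected, `NA` when not applicable).
#' @examples
#' metabolite_pathway_distance("PC aa C38:4", "PC aa C38:5")
#' @export
metabolite_pathway_distance <- function(met1, met2,
                                        model = default_pathway_model()) {
  a1 <- parse_metabolite_name(met1)
  a2 <- parse_metabolite_name(met2)
  d1 <- class_domain(a1$class)
  d2 <- class_domain(a2$class)
  if (is.na(d1) || is.na(d2) || d1 != d2) return(NA_real_)
  if (met1 == met2) return(0)
  if (d1 == "beta_oxidation") {
    fa1 <- sprintf("C%d:%d", a1$carbons, a1$double_bonds)
    fa2 <- sprintf("C%d:%d", a2$carbons, a2$double_bonds)
    D <- domain_distance_matrix(model, "beta_oxidation")
    if (!fa1 %in% rownames(D) || !fa2 %in% rownames(D)) return(Inf)
    return(unname(D[fa1, fa2]))
  }
  v1 <- enumerate_sidechain_variants(a1, model)
  v2 <- enumerate_sidechain_variants(a2, model)
  if (!length(v1) || !length(v2)) return(Inf)
  D <- domain_distance_matrix(model, "biosynthesis")
  best <- Inf
  for (u in v1) {
    for (w in v2) {
      if (length(u) == 2L && length(w) == 2L) {
        d <- min(D[u[1], w[1]] + D[u[2], w[2]],
                 D[u[1], w[2]] + D[u[2], w[1]])
      } else {
        # unequal residue counts (e.g. lyso-PC vs diacyl-PC): closest residue
        d <- min(D[u, w])
      }
      if (d < best) best <- d
    }
  }
  unname(best)
}

#' All pairwise pathway distances of a panel
#'
#' @param ids character vector of metabolite identifiers.
#' @param model a [pathway_model()].
#' @return symmetric matrix of minimal reaction-step counts with zero
#'   diagonal; `Inf` marks unconnected pairs within a projection domain and
#'   `NA` pairs to which the pathway model does not apply (amino acids,
#'   hexose, or metabolites from different domains).
#' @export
distance_matrix <- function(ids, model = default_pathway_model()) {
  model <- with_distance_cache(model)
  m <- length(ids)
  D <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  diag(D) <- 0
  if (m < 2) return(D)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      D[i, j] <- D[j, i] <- metabolite_pathway_distance(ids[i], ids[j], model)
    }
  }
  D
}
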