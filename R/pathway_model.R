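#' Fatty-acid pathway model
#'
#' Undirected graph over fatty acids `Cx:y` (x carbons, y double bonds) with
#' reaction edges of type elongation (+/- C2), desaturation (+/- one double
#' bond) or beta-oxidation (C2 removal).  Two disjoint projection domains
#' are maintained: `biosynthesis` (fatty-acid synthesis, onto which
#' phospholipid and sphingomyelin side chains are projected) and
#' `beta_oxidation` (a linear chain of C2 degradation steps, onto which
#' acyl-carnitines are projected).  Fatty acids with identical mass that a
#' brutto-composition measurement cannot distinguish (such as the omega-3
#' and omega-6 C20:4 species) are merged into a single node carrying both
#' pathway tags.
#'
#' @param nodes data frame with columns `fa` (id, `"C18:2"`), `carbons`,
#'   `double_bonds`, `domain`, `tags` (comma-separated pathway memberships).
#' @param edges data frame with columns `from`, `to`, `type`, `domain`.
#' @return object of class `pathway_model`.
#' @seealso [default_pathway_model()], [load_pathway_model()]
#' @export
pathway_model <- function(nodes, edges) {
  stopifnot(all(c("fa", "carbons", "double_bonds", "domain", "tags") %in%
                  names(nodes)),
            all(c("from", "to", "type", "domain") %in% names(edges)))
  key <- paste(nodes$fa, nodes$domain)
  if (anyDuplicated(key)) stop("duplicate fatty-acid nodes within a domain")
  if (any(nodes$carbons %% 2 != 0)) {
    stop("odd carbon counts are not allowed in the default chemistry: ",
         paste(unique(nodes$fa[nodes$carbons %% 2 != 0]), collapse = ", "))
  }
  if (nrow(edges)) {
    ek_from <- paste(edges$from, edges$domain)
    ek_to <- paste(edges$to, edges$domain)
    dangling <- setdiff(c(ek_from, ek_to), key)
    if (length(dangling)) {
      stop("edge references unknown node(s): ", paste(dangling, collapse = "; "))
    }
    if (any(edges$from == edges$to)) stop("self-loop reaction edges are not allowed")
  }
  structure(list(nodes = nodes, edges = edges), class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  for (d in unique(x$nodes$domain)) {
    cat("<pathway_model> domain ", d, ": ", sum(x$nodes$domain == d),
        " fatty acids, ", sum(x$edges$domain == d), " reactions\n", sep = "")
  }
  invisible(x)
}

# igraph of one projection domain
domain_graph <- function(model, domain) {
  nd <- model$nodes[model$nodes$domain == domain, , drop = FALSE]
  ed <- model$edges[model$edges$domain == domain, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(nd), name = nd$fa)
  if (nrow(ed)) {
    g <- igraph::add_edges(g, rbind(ed$from, ed$to), type = ed$type)
  }
  igraph::simplify(g)
}

#' Default literature-style fatty-acid pathway model
#'
#' Encodes three series of fatty-acid biosynthesis: de novo synthesis
#' (C2 elongation steps from C2:0 up to C26:0 with SCD-type desaturations
#' C16:0 to C16:1 and C18:0 to C18:1), and the omega-3 and omega-6
#' polyunsaturated pathways (alternating elongations and desaturations from
#' the essential fatty acids C18:3 and C18:2, including the final
#' peroxisomal beta-oxidation shortening steps C24:6 to C22:6 and C24:5 to
#' C22:5).  Species of identical mass arising in both omega pathways
#' (C18:3, C20:4, C22:5, C24:5) are merged.  Double-bond positions are
#' deliberately omitted, matching brutto-composition measurements.  The
#' degradation domain is a linear chain of C2 beta-oxidation steps over
#' acyl chain lengths C2 to C18 (carried out separately for 0, 1 and 2
#' double bonds).
#'
#' The model is also shipped as an editable plain-text file, see
#' [load_pathway_model()].
#'
#' @export
default_pathway_model <- function() {
  nodes <- list(); edges <- list()
  add_node <- function(fa, domain, tag) {
    cb <- fa_composition(fa)
    key <- paste(fa, domain)
    if (!is.null(nodes[[key]])) {
      # isobaric merge: same mass reached from another pathway
      old <- nodes[[key]]$tags
      if (!tag %in% strsplit(old, ",")[[1]]) {
        nodes[[key]]$tags <<- paste(old, tag, sep = ",")
      }
    } else {
      nodes[[key]] <<- data.frame(fa = fa, carbons = cb[1], double_bonds = cb[2],
                                  domain = domain, tags = tag,
                                  stringsAsFactors = FALSE)
    }
  }
  add_edge <- function(from, to, type, domain) {
    edges[[length(edges) + 1]] <<- data.frame(from = from, to = to, type = type,
                                              domain = domain,
                                              stringsAsFactors = FALSE)
  }
  add_series <- function(fas, types, domain, tag) {
    for (fa in fas) add_node(fa, domain, tag)
    for (i in seq_along(types)) add_edge(fas[i], fas[i + 1], types[i], domain)
  }

  # de novo synthesis: C2 elongations with SCD desaturations
  sat <- sprintf("C%d:0", seq(2, 26, by = 2))
  add_series(sat, rep("elongation", length(sat) - 1), "biosynthesis", "de_novo")
  add_node("C16:1", "biosynthesis", "de_novo")
  add_node("C18:1", "biosynthesis", "de_novo")
  add_edge("C16:0", "C16:1", "desaturation", "biosynthesis")
  add_edge("C18:0", "C18:1", "desaturation", "biosynthesis")

  # omega-6: 18:2 -> 18:3 -> 20:3 -> 20:4 -> 22:4 -> 24:4 -> 24:5 -> 22:5
  add_series(c("C18:2", "C18:3", "C20:3", "C20:4", "C22:4", "C24:4", "C24:5",
               "C22:5"),
             c("desaturation", "elongation", "desaturation", "elongation",
               "elongation", "desaturation", "beta_oxidation"),
             "biosynthesis", "omega6")
  # omega-3: 18:3 -> 18:4 -> 20:4 -> 20:5 -> 22:5 -> 24:5 -> 24:6 -> 22:6
  add_series(c("C18:3", "C18:4", "C20:4", "C20:5", "C22:5", "C24:5", "C24:6",
               "C22:6"),
             c("desaturation", "elongation", "desaturation", "elongation",
               "elongation", "desaturation", "beta_oxidation"),
             "biosynthesis", "omega3")

  # mitochondrial beta-oxidation chains for acyl-carnitines
  for (y in 0:2) {
    xs <- seq(2, 18, by = 2)
    xs <- xs[xs / 2 - 1 >= y | y == 0]  # enough carbons to carry the bonds
    fas <- sprintf("C%d:%d", xs, y)
    add_series(fas, rep("beta_oxidation", length(fas) - 1),
               "beta_oxidation", "degradation")
  }

  pathway_model(do.call(rbind, unname(nodes)), do.call(rbind, edges))
}

fa_composition <- function(fa) {
  m <- regmatches(fa, regexec("^C([0-9]+):([0-9]+)$", fa))[[1]]
  if (length(m) != 3) stop("malformed fatty acid id '", fa, "'")
  c(as.integer(m[2]), as.integer(m[3]))
}

#' Read / write a pathway model file
#'
#' Plain-text format, one record per line:
#' `node C18:2 domain=biosynthesis tags=omega6` and
#' `edge C18:2 C18:3 type=desaturation domain=biosynthesis`.
#' Blank lines and `#` comments are ignored; the file is validated on load
#' (dangling edges and odd carbon counts are rejected).
#'
#' @param file path to a model file.
#' @export
load_pathway_model <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nodes <- list(); edges <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    kv <- function(key, from) {
      hit <- grep(paste0("^", key, "="), from, value = TRUE)
      if (!length(hit)) stop("missing '", key, "=' in line: ", ln)
      sub(paste0("^", key, "="), "", hit[1])
    }
    if (tok[1] == "node") {
      cb <- fa_composition(tok[2])
      nodes[[length(nodes) + 1]] <- data.frame(
        fa = tok[2], carbons = cb[1], double_bonds = cb[2],
        domain = kv("domain", tok), tags = kv("tags", tok),
        stringsAsFactors = FALSE)
    } else if (tok[1] == "edge") {
      edges[[length(edges) + 1]] <- data.frame(
        from = tok[2], to = tok[3], type = kv("type", tok),
        domain = kv("domain", tok), stringsAsFactors = FALSE)
    } else {
      stop("unrecognized record '", tok[1], "' in ", file)
    }
  }
  if (!length(nodes)) stop("model file declares no fatty-acid nodes")
  pathway_model(do.call(rbind, nodes),
                if (length(edges)) do.call(rbind, edges) else
                  data.frame(from = character(), to = character(),
                             type = character(), domain = character()))
}

#' @rdname load_pathway_model
#' @param model a `pathway_model` to serialize.
#' @export
write_pathway_model <- function(model, file) {
  n <- model$nodes; e <- model$edges
  lines <- c(
    "# fatty-acid pathway model",
    sprintf("node %s domain=%s tags=%s", n$fa, n$domain, n$tags),
    if (nrow(e)) sprintf("edge %s %s type=%s domain=%s",
                         e$from, e$to, e$type, e$domain)
  )
  writeLines(lines, file)
  invisible(file)
}
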