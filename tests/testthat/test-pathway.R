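test_that("the default model encodes the canonical synthesis series", {
  model <- default_pathway_model()
  expect_equal(fatty_acid_distance("C16:0", "C18:0", model), 1)
  expect_equal(fatty_acid_distance("C18:0", "C18:1", model), 1)
  expect_equal(fatty_acid_distance("C20:4", "C20:5", model), 1)
  expect_equal(fatty_acid_distance("C2:0", "C26:0", model), 12)
  # essential fatty acids are unreachable from the de novo series
  expect_equal(fatty_acid_distance("C16:0", "C18:2", model), Inf)
  expect_equal(fatty_acid_distance("C18:1", "C18:2", model), Inf)
  # isobaric merge: C20:4 carries both omega tags
  tags <- model$nodes$tags[model$nodes$fa == "C20:4" &
                             model$nodes$domain == "biosynthesis"]
  expect_true(grepl("omega6", tags) && grepl("omega3", tags))
  expect_error(fatty_acid_distance("C99:0", "C16:0", model), "not in")
})

test_that("distances are symmetric with zero diagonal and obey the triangle inequality", {
  model <- default_pathway_model()
  D <- ggmetab:::domain_distance_matrix(model, "biosynthesis")
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, nrow(D)))
  fin <- rownames(D)
  for (rep in 1:200) {
    ijk <- sample(fin, 3)
    d_ij <- D[ijk[1], ijk[2]]; d_jk <- D[ijk[2], ijk[3]]
    d_ik <- D[ijk[1], ijk[3]]
    if (is.finite(d_ij) && is.finite(d_jk)) {
      expect_lte(d_ik, d_ij + d_jk)
    }
  }
})

test_that("model files round-trip and are validated on load", {
  model <- default_pathway_model()
  f <- withr::local_tempfile(fileext = ".txt")
  write_pathway_model(model, f)
  model2 <- load_pathway_model(f)
  expect_equal(model2$nodes[order(model2$nodes$fa, model2$nodes$domain), ],
               model$nodes[order(model$nodes$fa, model$nodes$domain), ],
               ignore_attr = TRUE)
  expect_equal(nrow(model2$edges), nrow(model$edges))
  expect_equal(fatty_acid_distance("C16:0", "C20:0", model2), 2)

  writeLines(c("node C16:0 domain=biosynthesis tags=de_novo",
               "edge C16:0 C18:0 type=elongation domain=biosynthesis"), f)
  expect_error(load_pathway_model(f), "unknown node")
  writeLines("node C15:0 domain=biosynthesis tags=odd", f)
  expect_error(load_pathway_model(f), "odd carbon")
})

test_that("a model without reactions yields only self-distances", {
  nodes <- data.frame(fa = c("C16:0", "C18:0"), carbons = c(16L, 18L),
                      double_bonds = 0L, domain = "biosynthesis",
                      tags = "de_novo")
  edges <- data.frame(from = character(), to = character(),
                      type = character(), domain = character())
  model <- pathway_model(nodes, edges)
  expect_equal(fatty_acid_distance("C16:0", "C16:0", model), 0)
  expect_equal(fatty_acid_distance("C16:0", "C18:0", model), Inf)
})

test_that("side-chain variants enumerate all consistent decompositions", {
  v4 <- enumerate_sidechain_variants("PC aa C38:4")
  keys <- vapply(v4, function(p) paste(sort(p), collapse = "+"), "")
  expect_true("C18:0+C20:4" %in% keys)
  expect_true("C16:0+C22:4" %in% keys)
  v5 <- enumerate_sidechain_variants("PC aa C38:5")
  keys5 <- vapply(v5, function(p) paste(sort(p), collapse = "+"), "")
  expect_true("C18:0+C20:5" %in% keys5)
  expect_true("C16:0+C22:5" %in% keys5)
  # every decomposition must add up to the brutto composition
  for (p in v4) {
    comp <- rowSums(sapply(p, ggmetab:::fa_composition))
    expect_equal(unname(comp), c(38, 4))
  }
  expect_equal(enumerate_sidechain_variants("lysoPC a C16:0"), list("C16:0"))
  expect_error(enumerate_sidechain_variants("Val"), "not a fatty-acid")
})

test_that("metabolite distances minimize over decompositions and matchings", {
  expect_equal(metabolite_pathway_distance("PC aa C38:4", "PC aa C38:5"), 1)
  expect_equal(metabolite_pathway_distance("PC aa C38:4", "PC aa C38:4"), 0)
  expect_equal(metabolite_pathway_distance("lysoPC a C16:0", "lysoPC a C18:0"), 1)
  expect_equal(metabolite_pathway_distance("C8:0-carn", "C10:0-carn"), 1)
  # saturated carnitine chain: one step per C2 unit
  expect_equal(metabolite_pathway_distance("C4:0-carn", "C16:0-carn"), 6)
  # carnitines never project onto the biosynthesis classes
  expect_true(is.na(metabolite_pathway_distance("C8:0-carn", "PC aa C38:4")))
  expect_true(is.na(metabolite_pathway_distance("Val", "PC aa C38:4")))
})

test_that("the distance matrix matches pairwise calls and a brute-force oracle", {
  panel <- c("PC aa C38:4", "PC aa C38:5", "PC aa C36:4", "lysoPC a C16:0",
             "lysoPC a C18:0", "lysoPC a C18:2", "SM C18:0", "SM C18:1",
             "C8:0-carn", "C10:0-carn", "Val")
  model <- default_pathway_model()
  D <- distance_matrix(panel, model)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, length(panel)))
  for (i in seq_along(panel)) {
    for (j in seq_along(panel)) {
      if (i == j) next
      expect_equal(D[i, j],
                   metabolite_pathway_distance(panel[i], panel[j], model))
    }
  }

  # brute-force oracle: scan all ordered node pairs per lipid and minimize
  # the matched per-residue BFS distances directly
  Dfa <- ggmetab:::domain_distance_matrix(model, "biosynthesis")
  nodes <- model$nodes[model$nodes$domain == "biosynthesis", ]
  brute <- function(id1, id2) {
    decomp <- function(id) {
      a <- parse_metabolite_name(id)
      out <- list()
      if (a$residues == 1) {
        fa <- sprintf("C%d:%d", a$carbons, a$double_bonds)
        if (fa %in% nodes$fa) out[[1]] <- c(fa, NA)
      } else {
        for (i in seq_len(nrow(nodes))) {
          for (j in seq_len(nrow(nodes))) {
            if (nodes$carbons[i] + nodes$carbons[j] == a$carbons &&
                nodes$double_bonds[i] + nodes$double_bonds[j] == a$double_bonds) {
              out[[length(out) + 1]] <- c(nodes$fa[i], nodes$fa[j])
            }
          }
        }
      }
      out
    }
    best <- Inf
    for (u in decomp(id1)) {
      for (w in decomp(id2)) {
        d <- if (is.na(u[2]) || is.na(w[2])) {
          min(Dfa[u[!is.na(u)], w[!is.na(w)]])
        } else {
          min(Dfa[u[1], w[1]] + Dfa[u[2], w[2]],
              Dfa[u[1], w[2]] + Dfa[u[2], w[1]])
        }
        best <- min(best, d)
      }
    }
    best
  }
  lipids <- panel[1:8]
  for (i in seq_along(lipids)) {
    for (j in seq_along(lipids)) {
      if (i >= j) next
      expect_equal(D[lipids[i], lipids[j]], brute(lipids[i], lipids[j]),
                   label = paste(lipids[i], "vs", lipids[j]))
    }
  }
})

test_that("adding a reaction never increases any distance", {
  model <- default_pathway_model()
  panel <- c("PC aa C34:2", "PC aa C36:2", "lysoPC a C16:0", "lysoPC a C18:2")
  D_before <- distance_matrix(panel, model)
  grown <- model
  grown$edges <- rbind(grown$edges,
                       data.frame(from = "C16:0", to = "C18:2",
                                  type = "desaturation",
                                  domain = "biosynthesis"))
  D_after <- distance_matrix(panel, grown)
  comparable <- is.finite(D_before) | is.finite(D_after)
  expect_true(all(D_after[comparable] <= D_before[comparable]))
})
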