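test_that("modularity matches hand-computed closed forms", {
  # all nodes in one class: 1 - 1^2 = 0
  g <- path4_graph()
  expect_equal(modularity_Q(g, rep("x", 4)), 0)
  # two disconnected equal cliques split along the classes: 2 (1/2 - 1/4)
  expect_equal(modularity_Q(two_cliques_graph()), 0.5)
  # 4-path split {1,2} | {3,4}: A(V,V) = 6, within = 2 + 2, out = 3 + 3
  expect_equal(modularity_Q(g), 1 / 6)
  expect_error(modularity_Q(metabolite_graph(matrix(0, 3, 3))), "edgeless")
})

test_that("relative out-degree rows are stochastic and flag empty classes", {
  R <- relative_outdegree(path4_graph())
  expect_equal(unname(R), rbind(c(2 / 3, 1 / 3), c(1 / 3, 2 / 3)),
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(R)), c(1, 1))

  # two disconnected same-class cliques still give R = [[1]]
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  expect_equal(unname(relative_outdegree(metabolite_graph(A))),
               matrix(1), ignore_attr = TRUE)

  # class of isolated nodes: zero row, flagged
  B <- matrix(0, 4, 4)
  B[1, 2] <- B[2, 1] <- 1
  gB <- metabolite_graph(B, c("a", "a", "iso", "iso"))
  RB <- relative_outdegree(gB)
  expect_equal(unname(RB["iso", ]), c(0, 0))
  expect_equal(attr(RB, "zero_degree_classes"), "iso")
})

test_that("modularity is invariant under relabeling and bounded by one", {
  set.seed(30)
  for (rep in 1:5) {
    gi <- igraph::sample_gnp(25, 0.2)
    A <- as.matrix(igraph::as_adjacency_matrix(gi))
    memb <- sample(1:4, 25, replace = TRUE)
    g <- metabolite_graph(A, as.character(memb))
    Q <- modularity_Q(g)
    # independent oracle: the same quantity in igraph
    expect_equal(Q, igraph::modularity(gi, memb), tolerance = 1e-12)
    expect_lte(Q, 1)
    # relabel classes
    relab <- c("1" = "w", "2" = "x", "3" = "y", "4" = "z")[as.character(memb)]
    expect_equal(modularity_Q(g, relab), Q)
    # node permutation
    perm <- sample(25)
    gp <- metabolite_graph(A[perm, perm], as.character(memb)[perm])
    expect_equal(modularity_Q(gp), Q)
  }
})

test_that("binary and weighted modularity agree for unit weights", {
  g <- two_cliques_graph()
  gw <- metabolite_graph(g$adjacency * 1.0, g$classes)
  expect_equal(modularity_Q(gw), modularity_Q(g))
})

test_that("rewiring preserves the degree sequence for every seed", {
  set.seed(31)
  gi <- igraph::sample_gnp(40, 0.15)
  A <- as.matrix(igraph::as_adjacency_matrix(gi))
  g <- metabolite_graph(A)
  for (seed in 1:10) {
    rw <- rewire_graph(g, seed = seed)
    expect_identical(rowSums(rw$adjacency != 0), rowSums(g$adjacency != 0))
    expect_equal(rw$e, g$e)
  }
})

test_that("5e swaps randomize away most of the original edge set", {
  set.seed(32)
  gi <- igraph::sample_gnp(100, 0.05)
  g <- metabolite_graph(as.matrix(igraph::as_adjacency_matrix(gi)))
  overlaps <- vapply(1:20, function(seed) {
    rw <- rewire_graph(g, seed = seed)
    both <- sum(rw$adjacency * g$adjacency != 0) / 2
    both / g$e  # Jaccard numerator over fixed edge count e
  }, numeric(1))
  expect_true(all(overlaps < 0.5))
})

test_that("weighted rewiring carries weights with the stubs", {
  set.seed(33)
  gi <- igraph::sample_gnp(30, 0.2)
  A <- as.matrix(igraph::as_adjacency_matrix(gi))
  W <- A * matrix(runif(900, 0.5, 2), 30)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  g <- metabolite_graph(W)
  rw <- rewire_graph(g, seed = 1)
  expect_identical(rowSums(rw$adjacency != 0), rowSums(g$adjacency != 0))
  # the multiset of edge weights is preserved exactly
  expect_equal(sort(rw$adjacency[upper.tri(rw$adjacency) & rw$adjacency != 0]),
               sort(g$adjacency[upper.tri(g$adjacency) & g$adjacency != 0]))
})

test_that("rewiring refuses graphs without a valid swap", {
  # a triangle admits no degree-preserving double-edge swap
  A <- matrix(1, 3, 3); diag(A) <- 0
  g <- metabolite_graph(A)
  expect_warning(rw <- rewire_graph(g, seed = 1), "no valid")
  expect_identical(rw$adjacency, g$adjacency)
})

test_that("modularity z-scores separate planted structure from noise", {
  # single class: observed and null modularity are identically zero
  g1 <- metabolite_graph(two_cliques_graph()$adjacency)
  m1 <- modularity_zscore(g1, n_random = 20, seed = 1)
  expect_equal(m1$Q, 0)
  expect_equal(m1$z_score, 0)

  # planted two-clique structure is far outside the rewiring null
  A <- matrix(0, 12, 12)
  A[1:6, 1:6] <- 1; A[7:12, 7:12] <- 1; diag(A) <- 0
  big <- metabolite_graph(A, rep(c("a", "b"), each = 6))
  m2 <- modularity_zscore(big, n_random = 1000, seed = 2)
  expect_equal(m2$Q, 0.5)
  expect_gt(m2$z_score, 5)

  # a random partition of a random graph stays within ~3 sigma
  set.seed(34)
  zs <- vapply(1:40, function(seed) {
    set.seed(seed)
    gi <- igraph::sample_gnp(30, 0.25)
    g <- metabolite_graph(as.matrix(igraph::as_adjacency_matrix(gi)),
                          sample(c("a", "b", "c"), 30, replace = TRUE))
    modularity_zscore(g, n_random = 100, seed = seed)$z_score
  }, numeric(1))
  expect_gte(mean(abs(zs) < 3), 0.95)
})

test_that("singleton classes are excluded from partition statistics", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- A[4, 5] <- A[5, 4] <- 1
  g <- metabolite_graph(A, c("a", "a", "b", "b", "only_one"))
  expect_message(m <- modularity_zscore(g, n_random = 10, seed = 1),
                 "singleton")
  expect_false("only_one" %in% rownames(m$R))
})

test_that("annealing recovers planted partitions and never regresses", {
  g <- two_cliques_graph()
  res <- anneal_partition(g, seed = 1, sweeps = 60)
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$partition[1:4])), 1)
  expect_equal(length(unique(res$partition[5:8])), 1)
  expect_false(res$partition[1] == res$partition[5])

  # elitism: the result is at least as good as the initial partition
  set.seed(35)
  init <- sample(1:3, 8, replace = TRUE)
  res2 <- anneal_partition(g, seed = 2, initial = init, sweeps = 30)
  expect_gte(res2$Q, modularity_Q(g, init))

  # determinism under a fixed seed and schedule
  res3 <- anneal_partition(g, seed = 2, initial = init, sweeps = 30)
  expect_identical(res2, res3)
})
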