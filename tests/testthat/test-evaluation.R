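# a correlation_result-like object assembled by hand for deterministic tests
fake_result <- function(Z, p, ids, classes = NULL) {
  dimnames(Z) <- dimnames(p) <- list(ids, ids)
  structure(list(P = Z, Z = Z, p_pearson = p, p_partial = p,
                 n = 1000, m = length(ids), order_q = length(ids) - 2,
                 alpha = 0.01, alpha_adj = 0.01,
                 cutoff = 0.1,
                 annotation = if (is.null(classes)) NULL else
                   data.frame(id = ids, class = classes)),
            class = "correlation_result")
}

test_that("stratification keeps exactly the applicable pairs", {
  ids <- c("A", "B", "C", "D")
  Z <- diag(4); Z[upper.tri(Z)] <- c(0.5, 0.3, 0.1, 0.2, 0.05, 0.4)
  Z[lower.tri(Z)] <- t(Z)[lower.tri(Z)]
  p <- matrix(0.001, 4, 4)
  D <- matrix(c(0, 1, 2, NA,
                1, 0, 1, NA,
                2, 1, 0, NA,
                NA, NA, NA, 0), 4, 4, dimnames = list(ids, ids))
  res <- fake_result(Z, p, ids)
  tab <- stratify_by_distance(res, D)
  expect_equal(nrow(tab), 3)  # D is excluded everywhere
  expect_setequal(paste(tab$met_a, tab$met_b), c("A B", "A C", "B C"))
  expect_equal(tab$distance[tab$met_a == "A" & tab$met_b == "C"], 2)
})

test_that("confusion counts implement the printed classification rule", {
  # 130 direct pairs, 86 of them significantly positive; 50 indirect pairs,
  # 10 significant
  n_direct <- 130; n_indirect <- 50
  tab <- data.frame(
    distance = c(rep(1, n_direct), rep(c(2, Inf), n_indirect / 2)),
    sig_partial = c(rep(c(TRUE, FALSE), c(86, 44)),
                    rep(c(TRUE, FALSE), c(10, 40))),
    partial = 0.3
  )
  tab$sig_positive <- tab$sig_partial & tab$partial > 0
  conf <- classify_edges(tab)
  expect_equal(conf$TP, 86)
  expect_equal(conf$FN, 44)
  expect_equal(conf$FP, 10)
  expect_equal(conf$TN, 40)
  # the four counts partition the applicable pairs
  expect_equal(conf$TP + conf$FP + conf$TN + conf$FN, nrow(tab))

  met <- sens_spec_f1(conf)
  expect_equal(met[["sens"]], 86 / 130, tolerance = 1e-12)
  expect_equal(met[["spec"]], 40 / 50)

  # permuting the rows changes nothing
  conf2 <- classify_edges(tab[sample(nrow(tab)), ])
  expect_identical(conf, conf2)

  # significant negatives count as negative predictions under the default
  tab$partial[1] <- -0.3
  tab$sig_positive <- tab$sig_partial & tab$partial > 0
  conf3 <- classify_edges(tab)
  expect_equal(conf3$TP, 85)
  conf4 <- classify_edges(tab, rule = "absolute")
  expect_equal(conf4$TP, 86)
})

test_that("rates with empty denominators are undefined, not zero", {
  expect_equal(unname(sens_spec_f1(list(TP = 5, FP = 0, TN = 3, FN = 0))),
               c(1, 1, 1))
  expect_equal(sens_spec_f1(list(TP = 3, FP = 0, TN = 2, FN = 2))[["f1"]],
               2 * 0.6 * 1 / 1.6)
  met <- sens_spec_f1(list(TP = 0, FP = 2, TN = 3, FN = 0))
  expect_true(is.na(met[["sens"]]))
  expect_true(is.na(met[["f1"]]))
})

test_that("the rank-sum comparison behaves like a rank statistic", {
  tab <- data.frame(distance = rep(c(1, 2), each = 50),
                    partial = c(rnorm(50, 0.5, 0.1), rnorm(50, 0, 0.1)))
  p <- ranksum_direct_vs_indirect(tab)
  expect_lt(p, 1e-6)
  # invariant under monotone transforms of the correlation scale
  tab2 <- tab; tab2$partial <- tanh(5 * tab$partial)
  expect_equal(ranksum_direct_vs_indirect(tab2), p, tolerance = 1e-9)
  # identical groups: no separation
  tab3 <- data.frame(distance = rep(c(1, 2), 20), partial = rep(1:20, each = 2))
  expect_gt(ranksum_direct_vs_indirect(tab3), 0.9)
  # one group empty: not applicable
  expect_true(is.na(ranksum_direct_vs_indirect(tab[tab$distance == 1, ])))
})

test_that("direct pairs out-correlate indirect pairs on a simulated pathway", {
  m <- 8
  ids <- paste0("X", 1:m)
  ens <- simulate_ensemble(chain_network(m, ids = ids), sigma = 0.2,
                           n_samples = 1000, seed = 3)
  res <- ggm(ens)
  D <- outer(1:m, 1:m, function(i, j) abs(i - j))
  dimnames(D) <- list(ids, ids)
  tab <- stratify_by_distance(res, D)
  expect_equal(nrow(tab), choose(m, 2))
  expect_gt(mean(tab$partial[tab$distance == 1]),
            mean(tab$partial[tab$distance == 2]))
  expect_lt(ranksum_direct_vs_indirect(tab), 1e-3)
})

test_that("Pearson correlations stay significant far beyond the model horizon", {
  # an incompletely annotated pathway: the model only records distances up
  # to 2 steps, everything farther is formally unconnected
  m <- 8
  ids <- paste0("X", 1:m)
  # a chain without exchange reactions: the whole pathway stays in mutual
  # equilibrium, so Pearson correlations reach across the entire chain
  net <- chain_network(m, reversible = TRUE, exchange = FALSE, ids = ids)
  ens <- simulate_ensemble(net, sigma = 0.2, n_samples = 1000, seed = 4)
  res <- ggm(ens)
  D <- outer(1:m, 1:m, function(i, j) abs(i - j))
  D[D > 2] <- Inf
  dimnames(D) <- list(ids, ids)
  tab <- stratify_by_distance(res, D)
  summ <- pearson_vs_partial_summary(tab)
  expect_true(all(summ$n_sig_pearson <= summ$n_pairs))
  expect_true(all(summ$frac_sig_partial >= 0 & summ$frac_sig_partial <= 1,
                  na.rm = TRUE))
  far <- summ[is.infinite(summ$distance), ]
  expect_gt(far$frac_sig_pearson, far$frac_sig_partial + 0.3)
})

test_that("the full evaluation report nails a clean first-order pathway", {
  m <- 8
  ids <- paste0("X", 1:m)
  ens <- simulate_ensemble(chain_network(m, ids = ids), sigma = 0.2,
                           n_samples = 1000, seed = 5)
  res <- ggm(ens)
  D <- outer(1:m, 1:m, function(i, j) abs(i - j))
  dimnames(D) <- list(ids, ids)
  rep <- evaluate_against_model(res, D)
  all_row <- rep$by_class[rep$by_class$class == "(all)", ]
  expect_gte(all_row$f1, 0.9)
  expect_equal(all_row$TP + all_row$FN, m - 1)

  dir <- withr::local_tempdir()
  write_evaluation_report(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("pairs.tsv", "metrics.tsv", "strata.tsv")))))
  back <- read.delim(file.path(dir, "metrics.tsv"))
  expect_equal(back$f1[back$class == "(all)"], all_row$f1, tolerance = 1e-6)
})
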