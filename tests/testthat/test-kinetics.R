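test_that("mass-action rates follow the educt stoichiometry products", {
  # x1 + x2 -> x3
  expect_equal(mass_action_rate(c(x1 = 2, x2 = 3, x3 = 1), k = 1,
                                educts = c(x1 = 1, x2 = 1)), 6)
  # 2 x1 + 3 x2 -> 2 x3 at x = (2, 1): c = x1^2 x2^3 = 4
  expect_equal(mass_action_rate(c(x1 = 2, x2 = 1), k = 1,
                                educts = c(x1 = 2, x2 = 3)), 4)
  # zeroth-order input reaction returns its constant
  expect_equal(mass_action_rate(c(x1 = 3), k = 5, educts = character()), 5)
  expect_error(mass_action_rate(c(x1 = -1), k = 1, educts = c(x1 = 1)),
               "negative")
  expect_error(mass_action_rate(c(x1 = 1), k = 0, educts = c(x1 = 1)), "> 0")
})

test_that("reversible Michaelis-Menten rate has the expected limits", {
  p <- c(vmax_fwd = 2, vmax_bwd = 1, km_s = 0.7, km_p = 1.3)
  expect_equal(reversible_mm_rate(0, 0, p), 0)
  # chemical balance: vmax_fwd * S / km_s == vmax_bwd * P / km_p
  s <- 0.9
  p_bal <- s * (p[["vmax_fwd"]] / p[["km_s"]]) * p[["km_p"]] / p[["vmax_bwd"]]
  expect_equal(reversible_mm_rate(s, p_bal, p), 0)
  # saturation: S -> Inf, P = 0 approaches vmax_fwd
  expect_equal(reversible_mm_rate(1e9, 0, p), p[["vmax_fwd"]],
               tolerance = 1e-6)
  expect_error(reversible_mm_rate(-0.1, 0, p), "negative")
})

test_that("mixed inhibition reduces to and halves the uninhibited rate", {
  p <- c(vmax_fwd = 2, vmax_bwd = 1, km_s = 1, km_p = 1, ki = 0.8, kii = 0.8)
  for (s in c(0.5, 2)) {
    for (pr in c(0.1, 1)) {
      expect_equal(mixed_inhibition_rate(s, pr, 0, p),
                   reversible_mm_rate(s, pr, p))
      # I = ki = kii doubles the whole denominator algebraically
      expect_equal(mixed_inhibition_rate(s, pr, 0.8, p),
                   reversible_mm_rate(s, pr, p) / 2)
    }
  }
  expect_lt(abs(mixed_inhibition_rate(1, 0.5, 1e12, p)), 1e-10)
  expect_error(mixed_inhibition_rate(1, 1, 1, p[1:4]), "ki")
  # constructor rejects missing inhibition constants
  expect_error(rxn_mm_inhibited("A", "B", "C", ki = -1), "positive")
})

test_that("log-normal parameter sampling is reproducible and calibrated", {
  net <- make_network("chain_reversible")
  nominal <- nominal_constants(net)

  d0 <- sample_parameters(net, sigma = 0, seed = 1)
  expect_equal(d0$values, nominal)

  d1 <- sample_parameters(net, sigma = 0.3, seed = 42)
  d2 <- sample_parameters(net, sigma = 0.3, seed = 42)
  expect_identical(d1$values, d2$values)
  expect_true(all(d1$values > 0))

  expect_error(sample_parameters(net, sigma = -0.1), ">= 0")

  # moment check: sd of log(k / nominal) estimates sigma
  set.seed(7)
  draws <- replicate(2e4, sample_parameters(net, 0.2)$values[1])
  se <- 0.2 / sqrt(2 * (2e4 - 1))
  expect_lt(abs(sd(log(draws / nominal[1])) - 0.2), 3 * se)

  # mean-one convention shifts the median below nominal
  set.seed(8)
  dm <- replicate(2e4, sample_parameters(net, 0.5, location = "mean")$values[1])
  expect_lt(abs(mean(dm / nominal[1]) - 1), 0.02)

  # a constant mask freezes everything else at nominal
  dmask <- sample_parameters(make_network("mm_chain"), 0.4, seed = 3,
                             mask = "vmax_fwd")
  frozen <- !grepl("vmax_fwd$", names(dmask$values))
  expect_equal(dmask$values[frozen],
               nominal_constants(make_network("mm_chain"))[frozen])
})

test_that("compiled rate evaluator agrees with the generic one", {
  for (nm in c("chain_reversible", "cofactor_glycolysis", "mm_chain",
               "end_product_inhibition_open")) {
    net <- make_network(nm)
    cmp <- ggmetab:::compile_network(net)
    k <- nominal_constants(net)
    set.seed(11)
    for (rep in 1:5) {
      x <- stats::setNames(exp(rnorm(length(net$metabolites), 0, 0.5)),
                           net$metabolites)
      expect_equal(cmp$rates(as.numeric(x), as.numeric(k)),
                   reaction_rates(net, x, k), tolerance = 1e-12)
    }
  }
})

test_that("analytic Jacobian matches finite differences", {
  for (nm in c("cofactor_glycolysis", "end_product_inhibition_open")) {
    net <- make_network(nm)
    cmp <- ggmetab:::compile_network(net)
    k <- as.numeric(nominal_constants(net))
    set.seed(2)
    x <- exp(rnorm(length(net$metabolites), 0, 0.4))
    J <- cmp$jac(x, k)
    Jfd <- sapply(seq_along(x), function(i) {
      h <- 1e-6
      xp <- x; xp[i] <- x[i] + h
      xm <- x; xm[i] <- x[i] - h
      (cmp$deriv(xp, k) - cmp$deriv(xm, k)) / (2 * h)
    })
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
})

test_that("network construction validates its inputs", {
  expect_error(reaction_network(c("A", "A"), list(rxn_ma("A", character()))),
               "duplicate")
  expect_error(reaction_network("A", list(rxn_ma("B", "A"))), "undeclared")
  expect_error(reaction_network("A", list()), "at least one")
  expect_error(rxn_ma("A", "B", k = -2), "positive")
  net <- make_network("chain_irreversible")
  expect_identical(net$S_e, pmin(net$S, 0L))
  expect_true(all(colSums(abs(net$S)) > 0))
})

test_that("network definition files round-trip", {
  for (nm in c("chain_reversible", "mm_chain", "end_product_inhibition_open")) {
    net <- make_network(nm)
    f <- withr::local_tempfile(fileext = ".json")
    write_reaction_network(net, f)
    net2 <- read_reaction_network(f)
    expect_identical(net2$metabolites, net$metabolites)
    expect_identical(net2$S, net$S)
    expect_equal(nominal_constants(net2), nominal_constants(net))
  }
  expect_error(make_network("no_such_network"), "unknown network")
})
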