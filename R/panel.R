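#' Metabolite panel specification
#'
#' Describes the composition of a targeted metabolomics panel: metabolite
#' classes with member counts and identifier templates matching the panel
#' nomenclature understood by [parse_metabolite_name()].  The default
#' mirrors a lipid-focused serum panel: 14 amino acids, one hexose pool,
#' 23 acyl-carnitines with 7 hydroxy-, 6 dicarboxy- and 2 methyl-dicarboxy
#' variants, 9 sphingomyelins and 5 hydroxy-sphingomyelins, 36 diacyl-, 38
#' acyl-alkyl- and 13 lyso-phosphatidylcholines (154 identifiers in total;
#' see the methods vignette on this count).
#'
#' @param counts named integer vector of members per class; names must be
#'   classes known to the id generators.
#' @return object of class `panel_spec` with the generated, unique,
#'   parseable identifiers per class.
#' @export
panel_spec <- function(counts = c(
  "amino acid" = 14, "hexose" = 1,
  "acyl-carnitine" = 23, "hydroxy-acylcarnitine" = 7,
  "dicarboxy-acylcarnitine" = 6, "methyl-dicarboxy-acylcarnitine" = 2,
  "sphingomyelin" = 9, "hydroxy-sphingomyelin" = 5,
  "diacyl-PC" = 36, "acyl-alkyl-PC" = 38, "lyso-PC" = 13
)) {
  ids <- unlist(lapply(names(counts), function(cl) {
    generate_panel_ids(cl, counts[[cl]])
  }))
  classes <- rep(names(counts), counts)
  if (anyDuplicated(ids)) stop("panel id generation produced duplicates")
  invisible(lapply(ids, parse_metabolite_name))  # every id must parse
  structure(list(ids = ids, classes = classes, counts = counts),
            class = "panel_spec")
}

# deterministic id templates per class, walking plausible (carbons, bonds)
# combinations of the measured chemistry
generate_panel_ids <- function(class, k) {
  combos <- function(xs, ys) {
    grid <- expand.grid(y = ys, x = xs)
    grid[grid$y <= pmax(0, grid$x / 2 - 1) | grid$y == 0, c("x", "y")]
  }
  take <- function(fmt, grid, k) {
    if (k > nrow(grid)) stop("class ", class, ": only ", nrow(grid),
                             " id combinations available, ", k, " requested")
    sprintf(fmt, grid$x[seq_len(k)], grid$y[seq_len(k)])
  }
  switch(class,
    "amino acid" = utils::head(amino_acid_ids(), k),
    "hexose" = rep("H1", k),
    "acyl-carnitine" = take("C%d:%d-carn", combos(seq(2, 18, 2), 0:2), k),
    "hydroxy-acylcarnitine" = take("C%d:%d-OH-carn", combos(seq(2, 18, 2), 0:1), k),
    "dicarboxy-acylcarnitine" = take("C%d:%d-DC-carn", combos(seq(2, 18, 2), 0:1), k),
    "methyl-dicarboxy-acylcarnitine" =
      take("C%d:%d-M-DC-carn", combos(seq(4, 18, 2), 0:1), k),
    "sphingomyelin" = take("SM C%d:%d", combos(seq(16, 26, 2), 0:2), k),
    "hydroxy-sphingomyelin" = take("SM (OH) C%d:%d", combos(seq(14, 24, 2), 1:2), k),
    "diacyl-PC" = take("PC aa C%d:%d", combos(seq(28, 42, 2), 0:6), k),
    "acyl-alkyl-PC" = take("PC ae C%d:%d", combos(seq(28, 44, 2), 0:6), k),
    "lyso-PC" = take("lysoPC a C%d:%d", combos(seq(14, 28, 2), 0:3), k),
    stop("unknown panel class '", class, "'")
  )
}

#' Generate a synthetic metabolite panel with known ground truth
#'
#' Emulates a cross-sectional metabolomics matrix without access to cohort
#' data.  In `block_cov` mode, log concentrations are drawn from a
#' multivariate normal whose precision matrix carries a within-class chain
#' structure: consecutive members of each class are conditionally dependent
#' with partial correlation `strength`, classes are mutually independent.
#' In `simulator` mode each class is an independently simulated first-order
#' reversible reaction chain with exchange reactions (see
#' [chain_network()]).  Both modes return the true edge set for evaluation.
#'
#' @param spec a [panel_spec()].
#' @param n number of samples.
#' @param structure `"block_cov"` or `"simulator"`.
#' @param strength target partial correlation of within-class chain edges
#'   (block_cov mode; absolute value below 0.5 keeps the precision matrix
#'   diagonally dominant and hence positive definite).
#' @param sigma enzymatic log-normal spread (simulator mode).
#' @param seed integer seed.
#' @param base_log_mean,base_log_sd location and spread of the random
#'   per-metabolite log-abundance offsets (block_cov mode).
#' @return list with `ensemble` (a [concentration_ensemble()]), `truth`
#'   (binary adjacency matrix of generating edges) and `spec`.
#' @export
generate_synthetic_panel <- function(spec = panel_spec(), n = 1000,
                                     structure = c("block_cov", "simulator"),
                                     strength = 0.3, sigma = 0.2, seed = 1,
                                     base_log_mean = 3, base_log_sd = 1) {
  structure_mode <- match.arg(structure)
  set.seed(seed)
  m <- length(spec$ids)
  truth <- matrix(0, m, m, dimnames = list(spec$ids, spec$ids))
  if (structure_mode == "block_cov") {
    if (abs(strength) >= 0.5) stop("strength must satisfy |strength| < 0.5")
    omega <- diag(m)
    for (cl in unique(spec$classes)) {
      idx <- which(spec$classes == cl)
      if (length(idx) < 2) next
      for (t in seq_len(length(idx) - 1)) {
        i <- idx[t]; j <- idx[t + 1]
        omega[i, j] <- omega[j, i] <- -strength
        truth[i, j] <- truth[j, i] <- 1
      }
    }
    ch <- tryCatch(chol(omega), error = function(e) {
      stop("requested precision matrix is not positive definite")
    })
    sigma_mat <- chol2inv(ch)
    X <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = sigma_mat)
    X <- sweep(X, 2, stats::rnorm(m, base_log_mean, base_log_sd), "+")
    colnames(X) <- spec$ids
    ens <- concentration_ensemble(X, spec$classes)
  } else {
    blocks <- lapply(unique(spec$classes), function(cl) {
      idx <- which(spec$classes == cl)
      if (length(idx) == 1) {
        # lone metabolite: independent log-normal abundance
        matrix(stats::rnorm(n, 0, sigma), ncol = 1,
               dimnames = list(NULL, spec$ids[idx]))
      } else {
        net <- chain_network(length(idx), reversible = TRUE, exchange = TRUE,
                             ids = spec$ids[idx])
        for (t in seq_len(length(idx) - 1)) {
          truth[idx[t], idx[t + 1]] <<- truth[idx[t + 1], idx[t]] <<- 1
        }
        simulate_ensemble(net, sigma = sigma, n_samples = n,
                          seed = sample.int(.Machine$integer.max / 2, 1))$X
      }
    })
    X <- do.call(cbind, blocks)[, spec$ids, drop = FALSE]
    ens <- concentration_ensemble(X, spec$classes)
  }
  list(ensemble = ens, truth = truth, spec = spec)
}
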