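#' Construct a reaction network
#'
#' A reaction network couples a stoichiometry matrix with per-reaction rate
#' laws and nominal kinetic constants.  Reactions are either elementary
#' mass-action steps (any order, including zeroth-order input reactions),
#' reversible Michaelis-Menten conversions of a single substrate into a
#' single product, or the same with a mixed-inhibition term.
#'
#' @param metabolites character vector of unique metabolite identifiers.
#' @param reactions list of reaction records, each created by [rxn_ma()],
#'   [rxn_mm()] or [rxn_mm_inhibited()].
#' @param name optional display name.
#'
#' @return An object of class `reaction_network` with components
#'   `metabolites`, `reactions`, `S` (m x r stoichiometry matrix, educts
#'   negative, products positive), `S_e` (educt part of `S`, entries <= 0)
#'   and `name`.
#'
#' @examples
#' net <- reaction_network(
#'   c("A", "B"),
#'   list(
#'     rxn_ma(character(), "A", k = 2),  # input
#'     rxn_ma("A", "B", k = 1),
#'     rxn_ma("B", character(), k = 1)   # output
#'   )
#' )
#' @export
reaction_network <- function(metabolites, reactions, name = "network") {
  stopifnot(is.character(metabolites), length(metabolites) >= 1)
  if (anyDuplicated(metabolites)) {
    stop("duplicate metabolite identifiers")
  }
  if (!length(reactions)) stop("at least one reaction is required")

  m <- length(metabolites)
  r <- length(reactions)
  S <- matrix(0L, m, r, dimnames = list(metabolites, NULL))
  for (j in seq_len(r)) {
    rx <- reactions[[j]]
    if (!inherits(rx, "ggmetab_reaction")) {
      stop("reaction ", j, " was not built by rxn_ma()/rxn_mm()")
    }
    species <- c(names(rx$educts), names(rx$products))
    unknown <- setdiff(species, metabolites)
    if (length(unknown)) {
      stop("reaction ", j, " references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    for (s in names(rx$educts))   S[s, j] <- S[s, j] - as.integer(rx$educts[[s]])
    for (s in names(rx$products)) S[s, j] <- S[s, j] + as.integer(rx$products[[s]])
    if (all(S[, j] == 0) && length(species)) {
      stop("reaction ", j, " has zero net stoichiometry")
    }
    if (!is.null(rx$inhibitor) && !(rx$inhibitor %in% metabolites)) {
      stop("reaction ", j, " names unknown inhibitor '", rx$inhibitor, "'")
    }
  }
  if (any(colSums(abs(S)) == 0)) stop("every reaction must move mass")

  net <- structure(
    list(metabolites = metabolites, reactions = reactions,
         S = S, S_e = pmin(S, 0L), name = name),
    class = "reaction_network"
  )
  # all nominal constants strictly positive by construction of rxn_*()
  invisible(nominal_constants(net))
  net
}

new_reaction <- function(educts, products, law, constants, inhibitor = NULL) {
  educts <- normalize_side(educts)
  products <- normalize_side(products)
  if (any(constants <= 0) || any(!is.finite(constants))) {
    stop("kinetic constants must be strictly positive and finite")
  }
  structure(
    list(educts = educts, products = products, law = law,
         constants = constants, inhibitor = inhibitor),
    class = "ggmetab_reaction"
  )
}

normalize_side <- function(x) {
  if (is.null(x) || length(x) == 0) return(stats::setNames(integer(0), character(0)))
  if (is.character(x)) x <- stats::setNames(rep(1L, length(x)), x)
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("stoichiometries must be named by metabolite")
  }
  storage.mode(x) <- "integer"
  if (any(x < 1)) stop("stoichiometric coefficients must be >= 1")
  x
}

#' Mass-action reaction
#'
#' @param educts,products named integer vectors of stoichiometric
#'   coefficients (or bare character vectors for unit coefficients); an empty
#'   educt set defines a zeroth-order input reaction, an empty product set an
#'   output reaction.
#' @param k elementary rate constant (> 0).
#' @export
rxn_ma <- function(educts, products, k = 1) {
  new_reaction(educts, products, "mass_action", c(k = k))
}

#' Reversible Michaelis-Menten reaction
#'
#' Single substrate, single product, rate
#' `(vmax_fwd/km_s * S - vmax_bwd/km_p * P) / (1 + S/km_s + P/km_p)`.
#'
#' @param substrate,product metabolite names.
#' @param vmax_fwd,vmax_bwd maximal forward/backward rates.
#' @param km_s,km_p Michaelis constants of substrate and product.
#' @export
rxn_mm <- function(substrate, product, vmax_fwd = 2, vmax_bwd = 1,
                   km_s = 1, km_p = 1) {
  stopifnot(length(substrate) == 1, length(product) == 1)
  new_reaction(substrate, product, "reversible_mm",
               c(vmax_fwd = vmax_fwd, vmax_bwd = vmax_bwd,
                 km_s = km_s, km_p = km_p))
}

#' Michaelis-Menten reaction with mixed inhibition
#'
#' Extends [rxn_mm()] with an allosteric inhibitor acting on both the free
#' enzyme (constant `ki`) and the substrate/product-enzyme complex (`kii`).
#' Equal `ki` and `kii` give the non-competitive special case.
#'
#' @inheritParams rxn_mm
#' @param inhibitor metabolite name of the inhibiting species.
#' @param ki,kii inhibition constants (> 0).
#' @export
rxn_mm_inhibited <- function(substrate, product, inhibitor,
                             vmax_fwd = 2, vmax_bwd = 1, km_s = 1, km_p = 1,
                             ki = 1, kii = ki) {
  stopifnot(length(substrate) == 1, length(product) == 1,
            length(inhibitor) == 1)
  if (missing(ki) && missing(kii)) {
    # defaults already set; nothing to do
  }
  new_reaction(substrate, product, "mixed_inhibition",
               c(vmax_fwd = vmax_fwd, vmax_bwd = vmax_bwd,
                 km_s = km_s, km_p = km_p, ki = ki, kii = kii),
               inhibitor = inhibitor)
}

#' Nominal kinetic constants of a network
#'
#' Flattens all per-reaction constants into a single named vector
#' (`r<j>.<constant>`), the object that log-normal parameter sampling
#' perturbs.
#'
#' @param network a `reaction_network`.
#' @return named numeric vector of strictly positive constants.
#' @export
nominal_constants <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  out <- unlist(lapply(seq_along(network$reactions), function(j) {
    k <- network$reactions[[j]]$constants
    stats::setNames(k, paste0("r", j, ".", names(k)))
  }))
  if (any(out <= 0)) stop("nominal constants must be strictly positive")
  out
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", x$name, "\n", sep = "")
  cat("  metabolites:", length(x$metabolites), paste0("(",
      paste(utils::head(x$metabolites, 8), collapse = ", "),
      if (length(x$metabolites) > 8) ", ..." else "", ")"), "\n")
  cat("  reactions:  ", length(x$reactions), "\n")
  laws <- table(vapply(x$reactions, `[[`, "", "law"))
  cat("  rate laws:  ", paste(names(laws), laws, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# TRUE when every reaction is zeroth- or first-order mass action, i.e. the
# steady state is the solution of a linear system.
is_linear_network <- function(network) {
  all(vapply(network$reactions, function(rx) {
    rx$law == "mass_action" && sum(rx$educts) <= 1L
  }, logical(1)))
}

#' Read / write a reaction network definition file
#'
#' Networks are stored as JSON: a list of metabolites and one record per
#' reaction (educts, products, law, constants, optional inhibitor).
#'
#' @param file path to a network definition file.
#' @export
read_reaction_network <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  reactions <- lapply(obj$reactions, function(rx) {
    k <- unlist(rx$constants)
    ed <- unlist(rx$educts); pr <- unlist(rx$products)
    switch(rx$law,
      mass_action = rxn_ma(ed, pr, k = k[["k"]]),
      reversible_mm = rxn_mm(names(ed), names(pr),
        vmax_fwd = k[["vmax_fwd"]], vmax_bwd = k[["vmax_bwd"]],
        km_s = k[["km_s"]], km_p = k[["km_p"]]),
      mixed_inhibition = rxn_mm_inhibited(names(ed), names(pr), rx$inhibitor,
        vmax_fwd = k[["vmax_fwd"]], vmax_bwd = k[["vmax_bwd"]],
        km_s = k[["km_s"]], km_p = k[["km_p"]],
        ki = k[["ki"]], kii = k[["kii"]]),
      stop("unknown rate law '", rx$law, "' in ", file)
    )
  })
  reaction_network(unlist(obj$metabolites), reactions,
                   name = obj$name %||% "network")
}

#' @rdname read_reaction_network
#' @param network a `reaction_network` to serialize.
#' @export
write_reaction_network <- function(network, file) {
  stopifnot(inherits(network, "reaction_network"))
  obj <- list(
    name = network$name,
    metabolites = network$metabolites,
    reactions = lapply(network$reactions, function(rx) {
      out <- list(educts = as.list(rx$educts), products = as.list(rx$products),
                  law = rx$law, constants = as.list(rx$constants))
      if (!is.null(rx$inhibitor)) out$inhibitor <- rx$inhibitor
      out
    })
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
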