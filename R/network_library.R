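#' Library of benchmark reaction networks
#'
#' Small reaction systems used to probe when partial-correlation networks can
#' and cannot recover the generating topology from steady-state ensembles:
#' reversible and irreversible three-metabolite chains (with and without
#' exchange reactions for every species), a branched first-order module, a
#' diamond motif, end-product inhibition in closed and open variants, a
#' cofactor-coupled module resembling the first reactions of glycolysis, a
#' reversible bimolecular split with isomerization, and a four-metabolite
#' chain of reversible Michaelis-Menten reactions whose forward maximal
#' rates are set twice as fast as the backward rates.
#'
#' All nominal constants default to 1 unless the motif requires otherwise
#' (see the methods vignette for the cofactor-supply and inhibition choices).
#'
#' @param name one of `"chain_reversible"`, `"chain_irreversible"`,
#'   `"chain_irreversible_exchange"`, `"branched"`, `"diamond"`,
#'   `"end_product_inhibition_closed"`, `"end_product_inhibition_open"`,
#'   `"cofactor_glycolysis"`, `"bimolecular_split"`, `"mm_chain"`.
#' @return a [reaction_network()].
#' @examples
#' make_network("chain_reversible")
#' @export
make_network <- function(name) {
  builders <- list(
    chain_reversible = function() {
      # interconversion 10x faster than the exchange fluxes: reversible
      # reactions keep the chain in mutual equilibrium, the regime in which
      # partial correlations separate direct from indirect neighbors (the
      # indirect A-C dependence through the shared input/output parameters
      # vanishes in the fast-interconversion limit)
      reaction_network(c("A", "B", "C"), c(
        list(rxn_ma(character(), "A", k = 1)),
        rev_pair("A", "B", 10, 10), rev_pair("B", "C", 10, 10),
        list(rxn_ma("C", character(), k = 1))
      ), name = "chain_reversible")
    },
    chain_irreversible = function() {
      reaction_network(c("A", "B", "C"), list(
        rxn_ma(character(), "A", k = 1),
        rxn_ma("A", "B", k = 1),
        rxn_ma("B", "C", k = 1),
        rxn_ma("C", character(), k = 1)
      ), name = "chain_irreversible")
    },
    chain_irreversible_exchange = function() {
      reaction_network(c("A", "B", "C"), list(
        rxn_ma(character(), "A", k = 1),
        rxn_ma("A", "B", k = 1),
        rxn_ma("B", "C", k = 1),
        rxn_ma("C", character(), k = 1),
        # exchange reactions for every species
        rxn_ma("A", character(), k = 1),
        rxn_ma(character(), "B", k = 1),
        rxn_ma("B", character(), k = 1),
        rxn_ma(character(), "C", k = 1)
      ), name = "chain_irreversible_exchange")
    },
    branched = function() {
      reaction_network(c("A", "B", "C", "D"), c(
        list(rxn_ma(character(), "A", k = 1)),
        rev_pair("A", "B", 10, 10), rev_pair("B", "C", 10, 10),
        rev_pair("B", "D", 10, 10),
        list(rxn_ma("C", character(), k = 1),
             rxn_ma("D", character(), k = 1))
      ), name = "branched")
    },
    diamond = function() {
      reaction_network(c("A", "B", "C", "D"), c(
        list(rxn_ma(character(), "A", k = 1)),
        rev_pair("A", "B", 10, 10), rev_pair("A", "C", 10, 10),
        rev_pair("B", "D", 10, 10), rev_pair("C", "D", 10, 10),
        list(rxn_ma("D", character(), k = 1))
      ), name = "diamond")
    },
    end_product_inhibition_closed = function() {
      # input flux 0.5 stays below the saturating capacity of the inhibited
      # first enzyme (~ vmax_fwd / (1 + D/ki)); a unit input would have no
      # positive steady state
      reaction_network(c("A", "B", "C", "D"), list(
        rxn_ma(character(), "A", k = 0.5),
        rxn_mm_inhibited("A", "B", inhibitor = "D",
                         vmax_fwd = 2, vmax_bwd = 1, ki = 1),
        rxn_mm("B", "C", vmax_fwd = 2, vmax_bwd = 1),
        rxn_mm("C", "D", vmax_fwd = 2, vmax_bwd = 1),
        rxn_ma("D", character(), k = 1)
      ), name = "end_product_inhibition_closed")
    },
    end_product_inhibition_open = function() {
      reaction_network(c("A", "B", "C", "D"), list(
        rxn_ma(character(), "A", k = 0.5),
        rxn_mm_inhibited("A", "B", inhibitor = "D",
                         vmax_fwd = 2, vmax_bwd = 1, ki = 1),
        rxn_mm("B", "C", vmax_fwd = 2, vmax_bwd = 1),
        rxn_mm("C", "D", vmax_fwd = 2, vmax_bwd = 1),
        rxn_ma("D", character(), k = 1),
        # exchange for the intermediates
        rxn_ma(character(), "B", k = 0.5),
        rxn_ma("B", character(), k = 0.5),
        rxn_ma(character(), "C", k = 0.5),
        rxn_ma("C", character(), k = 0.5)
      ), name = "end_product_inhibition_open")
    },
    cofactor_glycolysis = function() {
      # M1 -> M2 -> M3 -> M4 backbone with two ATP-coupled phosphorylations,
      # modeled (like all interconversions here) as reversible mass-action
      # pairs fast relative to the exchange fluxes; cofactors carry exchange
      # reactions, and the ATP supply exceeds its net consumption by the two
      # backbone reactions so the steady state stays positive under
      # parameter fluctuations.
      reaction_network(c("M1", "M2", "M3", "M4", "ATP", "ADP"), c(
        list(rxn_ma(character(), "M1", k = 1),
             rxn_ma(c(M1 = 1L, ATP = 1L), c(M2 = 1L, ADP = 1L), k = 10),
             rxn_ma(c(M2 = 1L, ADP = 1L), c(M1 = 1L, ATP = 1L), k = 10)),
        rev_pair("M2", "M3", 10, 10),
        list(rxn_ma(c(M3 = 1L, ATP = 1L), c(M4 = 1L, ADP = 1L), k = 10),
             rxn_ma(c(M4 = 1L, ADP = 1L), c(M3 = 1L, ATP = 1L), k = 10),
             rxn_ma("M4", character(), k = 1),
             rxn_ma(character(), "ATP", k = 8),
             rxn_ma("ATP", character(), k = 1),
             rxn_ma(character(), "ADP", k = 1),
             rxn_ma("ADP", character(), k = 1))
      ), name = "cofactor_glycolysis")
    },
    bimolecular_split = function() {
      reaction_network(c("A", "B", "C"), list(
        rxn_ma(character(), "A", k = 1),
        rxn_ma("A", c(B = 1L, C = 1L), k = 1),
        rxn_ma(c(B = 1L, C = 1L), "A", k = 1),
        rxn_ma("B", "C", k = 1),
        rxn_ma("C", "B", k = 1),
        rxn_ma("B", character(), k = 1),
        rxn_ma("C", character(), k = 1)
      ), name = "bimolecular_split")
    },
    mm_chain = function() {
      # input flux 0.5 leaves headroom below the saturating capacity of the
      # enzymatic steps for every plausible parameter draw
      reaction_network(c("A", "B", "C", "D"), list(
        rxn_ma(character(), "A", k = 0.5),
        rxn_mm("A", "B", vmax_fwd = 2, vmax_bwd = 1),
        rxn_mm("B", "C", vmax_fwd = 2, vmax_bwd = 1),
        rxn_mm("C", "D", vmax_fwd = 2, vmax_bwd = 1),
        rxn_ma("D", character(), k = 1)
      ), name = "mm_chain")
    }
  )
  if (!name %in% names(builders)) {
    stop("unknown network '", name, "'; available: ",
         paste(names(builders), collapse = ", "))
  }
  builders[[name]]()
}

#' Names of the bundled benchmark networks
#' @export
network_library <- function() {
  c("chain_reversible", "chain_irreversible", "chain_irreversible_exchange",
    "branched", "diamond", "end_product_inhibition_closed",
    "end_product_inhibition_open", "cofactor_glycolysis",
    "bimolecular_split", "mm_chain")
}

rev_pair <- function(a, b, k_fwd = 1, k_bwd = 1) {
  list(rxn_ma(a, b, k = k_fwd), rxn_ma(b, a, k = k_bwd))
}

#' First-order chain pathway of arbitrary length
#'
#' Generic linear pathway generator: `n_met` metabolites connected by
#' consecutive (optionally reversible) first-order reactions, an input
#' reaction to the first metabolite, an output from the last, and optional
#' exchange (input + output) reactions for every intermediate.  Used both as
#' a simulation fixture and by the synthetic-panel generator.
#'
#' @param n_met number of metabolites (>= 2).
#' @param reversible include backward reactions along the chain.
#' @param exchange include input/output reactions for every metabolite.
#' @param ids metabolite names (default `X1 ... Xn`).
#' @param k_exchange rate constant of the exchange reactions.
#' @export
chain_network <- function(n_met, reversible = TRUE, exchange = TRUE,
                          ids = paste0("X", seq_len(n_met)), k_exchange = 1) {
  stopifnot(n_met >= 2, length(ids) == n_met)
  rxns <- list(rxn_ma(character(), ids[1], k = 1))
  for (i in seq_len(n_met - 1)) {
    rxns <- c(rxns, list(rxn_ma(ids[i], ids[i + 1], k = 1)))
    if (reversible) rxns <- c(rxns, list(rxn_ma(ids[i + 1], ids[i], k = 1)))
  }
  rxns <- c(rxns, list(rxn_ma(ids[n_met], character(), k = 1)))
  if (exchange) {
    for (i in seq_len(n_met)) {
      rxns <- c(rxns, list(
        rxn_ma(character(), ids[i], k = k_exchange),
        rxn_ma(ids[i], character(), k = k_exchange)
      ))
    }
  }
  reaction_network(ids, rxns, name = sprintf("chain%d", n_met))
}
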