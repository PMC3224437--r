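#' Mass-action reaction rate
#'
#' For a reaction with educt stoichiometries s_i the rate is
#' `k * prod(x_i ^ s_i)`; zeroth-order (input) reactions return `k`.
#'
#' @param x named (or positionally ordered) non-negative concentration
#'   vector.
#' @param k rate constant (> 0).
#' @param educts named integer vector of educt stoichiometries (may be
#'   empty).
#' @export
mass_action_rate <- function(x, k, educts) {
  if (any(x < 0)) stop("negative concentration in mass_action_rate()")
  if (k <= 0) stop("rate constant must be > 0")
  educts <- normalize_side(educts)
  if (!length(educts)) return(k)
  xs <- if (!is.null(names(x))) x[names(educts)] else x[seq_along(educts)]
  k * prod(xs ^ as.numeric(educts))
}

#' Reversible Michaelis-Menten rate
#'
#' `(vmax_fwd/km_s * S - vmax_bwd/km_p * P) / (1 + S/km_s + P/km_p)`.
#'
#' @param s_conc,p_conc substrate and product concentrations (>= 0).
#' @param params named vector/list with `vmax_fwd`, `vmax_bwd`, `km_s`,
#'   `km_p`.
#' @export
reversible_mm_rate <- function(s_conc, p_conc, params) {
  if (s_conc < 0 || p_conc < 0) stop("negative concentration in reversible_mm_rate()")
  p <- as.list(params)
  num <- p$vmax_fwd / p$km_s * s_conc - p$vmax_bwd / p$km_p * p_conc
  num / (1 + s_conc / p$km_s + p_conc / p$km_p)
}

#' Mixed-inhibition Michaelis-Menten rate
#'
#' Extends [reversible_mm_rate()] with an inhibitor binding both the free
#' enzyme (`ki`) and the enzyme-substrate/product complex (`kii`); the
#' denominator becomes `1 + I/ki + (S/km_s + P/km_p) * (1 + I/kii)`.  With
#' `ki == kii` this is classical non-competitive inhibition.
#'
#' @inheritParams reversible_mm_rate
#' @param i_conc inhibitor concentration (>= 0).
#' @export
mixed_inhibition_rate <- function(s_conc, p_conc, i_conc, params) {
  if (s_conc < 0 || p_conc < 0 || i_conc < 0) {
    stop("negative concentration in mixed_inhibition_rate()")
  }
  p <- as.list(params)
  if (is.null(p$ki) || is.null(p$kii)) {
    stop("mixed inhibition requires 'ki' and 'kii' constants")
  }
  num <- p$vmax_fwd / p$km_s * s_conc - p$vmax_bwd / p$km_p * p_conc
  den <- 1 + i_conc / p$ki +
    (s_conc / p$km_s + p_conc / p$km_p) * (1 + i_conc / p$kii)
  num / den
}

#' Evaluate all reaction rates of a network
#'
#' @param network a `reaction_network`.
#' @param x concentration vector in the order of `network$metabolites`.
#' @param constants named constant vector as produced by
#'   [nominal_constants()] or [sample_parameters()].
#' @return numeric vector of length `r` (one rate per reaction).
#' @export
reaction_rates <- function(network, x, constants = nominal_constants(network)) {
  x <- stats::setNames(as.numeric(x), network$metabolites)
  vapply(seq_along(network$reactions), function(j) {
    rx <- network$reactions[[j]]
    k <- constants[paste0("r", j, ".", names(rx$constants))]
    names(k) <- names(rx$constants)
    switch(rx$law,
      mass_action = mass_action_rate(x, k[["k"]], rx$educts),
      reversible_mm = reversible_mm_rate(
        x[[names(rx$educts)]], x[[names(rx$products)]], k),
      mixed_inhibition = mixed_inhibition_rate(
        x[[names(rx$educts)]], x[[names(rx$products)]], x[[rx$inhibitor]], k)
    )
  }, numeric(1))
}

# time derivative dx/dt = S v(x, k)
network_derivative <- function(network, x, constants) {
  as.numeric(network$S %*% reaction_rates(network, x, constants))
}

# Precompile a fast derivative evaluator: resolves metabolite and constant
# positions once so that repeated calls inside the ODE solver avoid any
# name lookups.  Takes the flat constant vector in nominal_constants()
# order.
compile_network <- function(network) {
  S <- network$S
  storage.mode(S) <- "double"
  r <- length(network$reactions)
  kpos <- 0L
  info <- vector("list", r)
  for (j in seq_len(r)) {
    rx <- network$reactions[[j]]
    nk <- length(rx$constants)
    entry <- list(law = rx$law, k = kpos + seq_len(nk))
    kpos <- kpos + nk
    if (rx$law == "mass_action") {
      entry$eidx <- match(names(rx$educts), network$metabolites)
      entry$est <- as.numeric(rx$educts)
    } else {
      entry$s <- match(names(rx$educts), network$metabolites)
      entry$p <- match(names(rx$products), network$metabolites)
      if (!is.null(rx$inhibitor)) {
        entry$i <- match(rx$inhibitor, network$metabolites)
      }
    }
    info[[j]] <- entry
  }
  rates <- function(x, k) {
    v <- numeric(r)
    for (j in seq_len(r)) {
      e <- info[[j]]
      kk <- k[e$k]
      if (e$law == "mass_action") {
        v[j] <- if (length(e$eidx)) kk * prod(x[e$eidx]^e$est) else kk
      } else {
        # kk = (vmax_fwd, vmax_bwd, km_s, km_p[, ki, kii])
        s <- x[e$s]; p <- x[e$p]
        num <- kk[1] / kk[3] * s - kk[2] / kk[4] * p
        den <- if (e$law == "mixed_inhibition") {
          i <- x[e$i]
          1 + i / kk[5] + (s / kk[3] + p / kk[4]) * (1 + i / kk[6])
        } else {
          1 + s / kk[3] + p / kk[4]
        }
        v[j] <- num / den
      }
    }
    v
  }
  m <- nrow(S)
  # analytic Jacobian d(S v)/dx, so the stiff solver never has to
  # finite-difference the derivative
  jac <- function(x, k) {
    dv <- matrix(0, r, m)
    for (j in seq_len(r)) {
      e <- info[[j]]
      kk <- k[e$k]
      if (e$law == "mass_action") {
        if (length(e$eidx)) {
          for (t in seq_along(e$eidx)) {
            i <- e$eidx[t]
            others <- setdiff(seq_along(e$eidx), t)
            dv[j, i] <- kk * e$est[t] * x[i]^(e$est[t] - 1) *
              (if (length(others)) prod(x[e$eidx[others]]^e$est[others]) else 1)
          }
        }
      } else {
        s <- x[e$s]; p <- x[e$p]
        a <- kk[1] / kk[3]; b <- kk[2] / kk[4]
        num <- a * s - b * p
        if (e$law == "mixed_inhibition") {
          i <- x[e$i]
          f <- 1 + i / kk[6]
          den <- 1 + i / kk[5] + (s / kk[3] + p / kk[4]) * f
          dv[j, e$s] <- (a * den - num * f / kk[3]) / den^2
          dv[j, e$p] <- (-b * den - num * f / kk[4]) / den^2
          dv[j, e$i] <- dv[j, e$i] -
            num * (1 / kk[5] + (s / kk[3] + p / kk[4]) / kk[6]) / den^2
        } else {
          den <- 1 + s / kk[3] + p / kk[4]
          dv[j, e$s] <- (a * den - num / kk[3]) / den^2
          dv[j, e$p] <- (-b * den - num / kk[4]) / den^2
        }
      }
    }
    S %*% dv
  }
  list(rates = rates,
       deriv = function(x, k) as.numeric(S %*% rates(x, k)),
       jac = jac)
}

#' Sample kinetic constants under log-normal variation
#'
#' Each constant is drawn as `nominal * exp(e)` with
#' `e ~ Normal(mu, sigma^2)`, independently across constants.  By default
#' `mu = 0`, i.e. the nominal value is the median of the sampled
#' distribution; `location = "mean"` uses `mu = -sigma^2/2` so that the
#' nominal value is the mean instead.  For first-order systems the two
#' conventions differ only by a per-metabolite shift of the log steady
#' states and leave correlation structure unchanged.
#'
#' @param network a `reaction_network`.
#' @param sigma standard deviation of the underlying normal (>= 0); either a
#'   scalar applied to all constants or a scalar default combined with
#'   `sigma_map`.
#' @param seed optional integer seed (draws are reproducible given the
#'   seed).
#' @param sigma_map optional named vector of per-reaction overrides
#'   (`r3 = 0.5` scales all constants of reaction 3).
#' @param mask optional character vector restricting which constant names
#'   (suffixes, e.g. `"vmax_fwd"`) fluctuate; others stay nominal.
#' @param location `"median"` (default) or `"mean"`, see Details.
#' @return object of class `parameter_draw`: list with `values` (named
#'   vector), `sigma`, `seed`.
#' @export
sample_parameters <- function(network, sigma, seed = NULL, sigma_map = NULL,
                              mask = NULL, location = c("median", "mean")) {
  location <- match.arg(location)
  if (any(sigma < 0)) stop("sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  nominal <- nominal_constants(network)
  sig <- rep(sigma[[1]], length(nominal))
  names(sig) <- names(nominal)
  if (!is.null(sigma_map)) {
    rxn_of <- sub("\\..*$", "", names(nominal))
    for (r in names(sigma_map)) sig[rxn_of == r] <- sigma_map[[r]]
  }
  if (!is.null(mask)) {
    const_of <- sub("^r[0-9]+\\.", "", names(nominal))
    sig[!const_of %in% mask] <- 0
  }
  mu <- if (location == "mean") -sig^2 / 2 else 0
  eps <- stats::rnorm(length(nominal), mean = mu, sd = sig)
  structure(
    list(values = nominal * exp(eps), sigma = sigma, seed = seed),
    class = "parameter_draw"
  )
}
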