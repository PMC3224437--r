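#' Analytic steady state of a zeroth/first-order network
#'
#' For networks containing only zeroth-order (input) and first-order
#' mass-action reactions the rate vector is affine in the concentrations, so
#' the steady-state condition `S v(x, k) = 0` reduces to the linear system
#' `A x = -b` with `A` collecting first-order columns of `S k` and `b` the
#' zeroth-order fluxes.
#'
#' @param network a `reaction_network` with only zeroth/first-order
#'   mass-action reactions.
#' @param constants named constant vector (a `parameter_draw` is also
#'   accepted).
#' @return named concentration vector, strictly positive.
#' @export
linear_steady_state <- function(network, constants = nominal_constants(network)) {
  if (inherits(constants, "parameter_draw")) constants <- constants$values
  if (!is_linear_network(network)) {
    stop("linear_steady_state() requires a zeroth/first-order mass-action network")
  }
  m <- length(network$metabolites)
  A <- matrix(0, m, m, dimnames = list(network$metabolites, network$metabolites))
  b <- stats::setNames(numeric(m), network$metabolites)
  for (j in seq_along(network$reactions)) {
    rx <- network$reactions[[j]]
    k <- constants[[paste0("r", j, ".k")]]
    if (length(rx$educts) == 0) {
      b <- b + k * network$S[, j]
    } else {
      A[, names(rx$educts)] <- A[, names(rx$educts)] + k * network$S[, j]
    }
  }
  if (rcond_sym(A) < 1e-12) {
    stop("steady-state system is singular: no unique steady state ",
         "(does every metabolite have a route out of the system?)")
  }
  x <- solve(A, -b)
  if (any(x <= 0)) {
    stop("steady state has non-positive concentrations; the network has no ",
         "admissible equilibrium for these constants")
  }
  stats::setNames(as.numeric(x), network$metabolites)
}

rcond_sym <- function(A) {
  s <- svd(A, nu = 0, nv = 0)$d
  if (max(s) == 0) return(0)
  min(s) / max(s)
}

#' Numerical steady state by stiff ODE integration
#'
#' Integrates `dx/dt = S v(x, k)` (lsoda, switching between stiff and
#' non-stiff methods) over successively doubled time horizons until the
#' derivative norm satisfies `||dx/dt|| < tol * (1 + ||x||)`.
#'
#' @param network a `reaction_network`.
#' @param constants named constant vector or `parameter_draw`.
#' @param x0 strictly positive initial state (defaults to 1 for every
#'   metabolite).
#' @param tol relative-derivative convergence tolerance.
#' @param t_chunk initial integration horizon; doubled until convergence.
#' @param max_time hard cap on the simulated time horizon.
#' @return named steady-state concentration vector.
#' @export
numerical_steady_state <- function(network, constants = nominal_constants(network),
                                   x0 = NULL, tol = 1e-9,
                                   t_chunk = 50, max_time = 1e6,
                                   compiled = NULL) {
  if (inherits(constants, "parameter_draw")) constants <- constants$values
  constants <- as.numeric(constants)
  m <- length(network$metabolites)
  if (is.null(x0)) x0 <- rep(1, m)
  if (length(x0) != m || any(x0 <= 0)) {
    stop("x0 must be a strictly positive vector of length ", m)
  }
  if (is.null(compiled)) compiled <- compile_network(network)
  deriv <- function(t, y, parms) {
    list(compiled$deriv(pmax(y, 0), constants))
  }
  jac <- function(t, y, parms) {
    compiled$jac(pmax(y, 0), constants)
  }
  x <- as.numeric(x0)
  t_total <- 0
  horizon <- t_chunk
  repeat {
    sol <- deSolve::ode(y = x, times = c(0, horizon), func = deriv,
                        parms = NULL, method = "lsoda",
                        jacfunc = jac, jactype = "fullusr",
                        rtol = 1e-8, atol = 1e-10)
    x <- sol[nrow(sol), -1]
    if (any(x < -1e-6)) {
      stop("integration left the positive orthant")
    }
    x <- pmax(x, 0)
    t_total <- t_total + horizon
    d <- compiled$deriv(x, constants)
    if (sqrt(sum(d^2)) < tol * (1 + sqrt(sum(x^2)))) break
    if (t_total >= max_time) {
      stop("no steady state within time horizon ", max_time,
           " (residual derivative norm ", signif(sqrt(sum(d^2)), 3), ")")
    }
    horizon <- min(2 * horizon, max_time - t_total)
  }
  stats::setNames(as.numeric(x), network$metabolites)
}

# dispatch to the analytic solver when possible
steady_state <- function(network, constants, ...) {
  if (is_linear_network(network)) {
    linear_steady_state(network, constants)
  } else {
    numerical_steady_state(network, constants, ...)
  }
}

#' Empirical monostability check
#'
#' Samples kinetic parameters and, for each draw, steady states from
#' several random initial conditions; the network is reported monostable
#' when all initial conditions reach the same equilibrium within `tol`
#' (relative, per metabolite).  Solver failures are collected, not raised.
#'
#' @param network a `reaction_network`.
#' @param n_param_draws,n_init_draws numbers of parameter and initial-value
#'   samples (>= 1).
#' @param sigma log-normal parameter spread.
#' @param seed integer seed.
#' @param tol agreement tolerance between steady states.
#' @param init_spread sd of the log-uniform spread of initial states around
#'   1.
#' @return list with `pass`, `worst_divergence`, `n_failures`, `failures`
#'   (messages) and the per-draw divergence table.
#' @export
verify_monostability <- function(network, n_param_draws = 10, n_init_draws = 5,
                                 sigma = 0.2, seed = 1, tol = 1e-4,
                                 init_spread = 1) {
  stopifnot(n_param_draws >= 1, n_init_draws >= 1)
  set.seed(seed)
  m <- length(network$metabolites)
  divergence <- rep(NA_real_, n_param_draws)
  failures <- character(0)
  for (d in seq_len(n_param_draws)) {
    draw <- sample_parameters(network, sigma)
    states <- vector("list", n_init_draws)
    ok <- TRUE
    for (i in seq_len(n_init_draws)) {
      x0 <- exp(stats::rnorm(m, 0, init_spread))
      res <- tryCatch(
        numerical_steady_state(network, draw$values, x0 = x0, tol = 1e-9),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures <- c(failures,
                      sprintf("draw %d, init %d: %s", d, i, conditionMessage(res)))
        ok <- FALSE
        break
      }
      states[[i]] <- res
    }
    if (!ok) next
    ref <- states[[1]]
    divergence[d] <- max(vapply(states, function(s) {
      max(abs(s - ref) / (1 + abs(ref)))
    }, numeric(1)))
  }
  finite <- divergence[!is.na(divergence)]
  list(
    pass = length(failures) == 0 && length(finite) > 0 && max(finite) < tol,
    worst_divergence = if (length(finite)) max(finite) else NA_real_,
    n_failures = length(failures),
    failures = failures,
    divergence = divergence
  )
}
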