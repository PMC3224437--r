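#' Concentration ensemble container
#'
#' Holds an n x m matrix of natural-log metabolite concentrations together
#' with metabolite annotations (id and, optionally, class).
#'
#' @param X numeric matrix of log concentrations, one row per sample, with
#'   column names.
#' @param classes optional character vector of metabolite classes (recycled
#'   to `"unknown"`).
#' @export
concentration_ensemble <- function(X, classes = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have metabolite column names")
  if (anyNA(X)) stop("ensemble contains missing values")
  if (is.null(classes)) classes <- rep("unknown", ncol(X))
  stopifnot(length(classes) == ncol(X))
  structure(
    list(X = X, n = nrow(X), m = ncol(X),
         annotation = data.frame(id = colnames(X), class = classes,
                                 stringsAsFactors = FALSE)),
    class = "concentration_ensemble"
  )
}

#' @export
print.concentration_ensemble <- function(x, ...) {
  cat("<concentration_ensemble> ", x$n, " samples x ", x$m,
      " metabolites (log scale)\n", sep = "")
  cls <- table(x$annotation$class)
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# coerce matrix-or-ensemble arguments
as_log_matrix <- function(X) {
  if (inherits(X, "concentration_ensemble")) X$X else as.matrix(X)
}

#' Simulate a steady-state concentration ensemble
#'
#' Draws `n_samples` independent log-normal parameter sets, computes the
#' corresponding steady-state concentrations (analytically for purely
#' zeroth/first-order mass-action networks, by stiff ODE integration
#' otherwise) and returns the natural-log concentrations.  This emulates
#' enzymatic variability across individuals of a cross-sectional cohort:
#' every row is one "individual" with its own kinetic constants.
#'
#' @param network a `reaction_network`.
#' @param sigma log-normal parameter spread (the underlying normal sd).
#' @param n_samples number of parameter draws (>= 2).
#' @param seed integer seed.
#' @param sigma_map,mask,location passed to [sample_parameters()].
#' @param ... further arguments for [numerical_steady_state()].
#' @return a [concentration_ensemble()].  When `sigma = 0` all columns are
#'   constant; these are flagged in the `constant_columns` attribute and a
#'   warning is emitted.
#' @export
simulate_ensemble <- function(network, sigma = 0.2, n_samples = 1000,
                              seed = 1, sigma_map = NULL, mask = NULL,
                              location = "median", ...) {
  stopifnot(n_samples >= 2)
  set.seed(seed)
  linear <- is_linear_network(network)
  m <- length(network$metabolites)
  X <- matrix(NA_real_, n_samples, m,
              dimnames = list(NULL, network$metabolites))
  compiled <- if (linear) NULL else compile_network(network)
  # nominal equilibrium as warm start for the numerical solver
  x_start <- if (linear) NULL else
    numerical_steady_state(network, tol = 1e-9, compiled = compiled, ...)
  for (i in seq_len(n_samples)) {
    draw <- sample_parameters(network, sigma, sigma_map = sigma_map,
                              mask = mask, location = location)
    x <- tryCatch(
      if (linear) linear_steady_state(network, draw$values)
      else numerical_steady_state(network, draw$values, x0 = x_start,
                                  compiled = compiled, ...),
      error = function(e) {
        stop("steady-state solution failed at draw ", i, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    X[i, ] <- log(x)
  }
  ens <- concentration_ensemble(X)
  constant <- apply(X, 2, function(col) stats::var(col) == 0)
  if (any(constant)) {
    attr(ens, "constant_columns") <- colnames(X)[constant]
    warning("zero-variance metabolite column(s): ",
            paste(colnames(X)[constant], collapse = ", "))
  }
  ens
}
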