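# Parameter vectorization: a spectral_model <-> named numeric vector, under a
# binary adjacency ("space entry") that switches off-diagonal couplings on or
# off. Switched-off couplings are excluded from the vector and restored as
# exact zeros. Order (column-major over the free off-diagonals):
#   A_<i>_<j> ..., self_1..n, amp_1..n, exp_1..n, noise_amp, noise_exp,
#   transit_1..n, decay_1..n, epsilon

#' Names of the free parameters of a model specification
#'
#' @param n_nodes number of nodes.
#' @param adjacency n x n binary matrix; entry \code{[i, j] = 1} means the
#'   influence of node j on node i is a free parameter. The diagonal
#'   (self-connections) is always treated as present. Default: full.
#' @return character vector of parameter names.
#' @export
param_names <- function(n_nodes, adjacency = NULL) {
  n <- n_nodes
  if (is.null(adjacency)) adjacency <- matrix(1, n, n)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  a_names <- character(0)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i != j && adjacency[i, j] != 0) a_names <- c(a_names, sprintf("A_%d_%d", i, j))
    }
  }
  c(a_names,
    sprintf("self_%d", seq_len(n)),
    sprintf("amp_%d", seq_len(n)),
    sprintf("exp_%d", seq_len(n)),
    "noise_amp", "noise_exp",
    sprintf("transit_%d", seq_len(n)),
    sprintf("decay_%d", seq_len(n)),
    "epsilon")
}

#' Pack a spectral model into a named parameter vector
#'
#' @param model a [spectral_model()].
#' @param adjacency binary switch matrix (see [param_names()]); couplings
#'   switched off are dropped from the vector.
#' @return named numeric vector.
#' @export
pack_parameters <- function(model, adjacency = NULL) {
  stopifnot(inherits(model, "spectral_model"))
  n <- model$coupling$n_nodes
  if (is.null(adjacency)) adjacency <- matrix(1, n, n)
  nm <- param_names(n, adjacency)
  off <- model$coupling$offdiag
  a_vals <- numeric(0)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i != j && adjacency[i, j] != 0) a_vals <- c(a_vals, off[i, j])
    }
  }
  theta <- c(a_vals,
             model$coupling$selfparams,
             model$fluct$neural_amplitude,
             model$fluct$neural_exponent,
             model$fluct$noise_amplitude,
             model$fluct$noise_exponent,
             model$hemo$transit,
             model$hemo$decay,
             model$hemo$epsilon)
  stats::setNames(theta, nm)
}

#' Unpack a parameter vector into a spectral model
#'
#' @param theta numeric vector in [param_names()] order for the adjacency.
#' @param n_nodes number of nodes.
#' @param adjacency binary switch matrix; switched-off couplings are
#'   restored as exact zeros.
#' @param constants a [balloon_constants()].
#' @return a [spectral_model()].
#' @export
unpack_parameters <- function(theta, n_nodes, adjacency = NULL,
                              constants = balloon_constants()) {
  n <- n_nodes
  if (is.null(adjacency)) adjacency <- matrix(1, n, n)
  nm <- param_names(n, adjacency)
  stopifnot(length(theta) == length(nm))
  theta <- stats::setNames(as.numeric(theta), nm)
  off <- matrix(0, n, n)
  k <- 1
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i != j && adjacency[i, j] != 0) {
        off[i, j] <- theta[k]
        k <- k + 1
      }
    }
  }
  take <- function(pat, m) {
    out <- theta[k:(k + m - 1)]
    k <<- k + m
    unname(out)
  }
  selfp <- take("self", n)
  amp <- take("amp", n)
  expo <- take("exp", n)
  namp <- take("noise_amp", 1)
  nexp <- take("noise_exp", 1)
  transit <- take("transit", n)
  decay <- take("decay", n)
  eps <- take("epsilon", 1)
  spectral_model(
    neural_coupling(off, selfp),
    fluctuation_params(amp, expo, namp, nexp),
    hemodynamic_params(transit, decay, eps),
    constants
  )
}

#' Prior specification over a parameter vector
#'
#' Independent Gaussian priors, stored as mean and variance per free
#' parameter. Defaults: off-diagonal couplings N(0, 1/64); self log-scalings
#' N(0, 1/256); fluctuation and observation-noise log-parameters N(0, 1/64);
#' hemodynamic log-scalings N(0, 1/256). A coupling switched off by the
#' adjacency simply does not appear (equivalently: zero mean, zero
#' variance).
#'
#' @param n_nodes number of nodes.
#' @param adjacency binary switch matrix (see [param_names()]).
#' @param overrides optional named list \code{name = c(mean, var)} applied on
#'   top of the defaults.
#' @return object of class \code{prior_spec}: list with \code{mean},
#'   \code{var} (named vectors), \code{adjacency}, \code{n_nodes}.
#' @export
default_priors <- function(n_nodes, adjacency = NULL, overrides = NULL) {
  n <- n_nodes
  if (is.null(adjacency)) adjacency <- matrix(1, n, n)
  nm <- param_names(n, adjacency)
  v <- numeric(length(nm))
  v[grepl("^A_", nm)] <- 1 / 64
  v[grepl("^self_", nm)] <- 1 / 256
  v[grepl("^(amp|exp)_", nm)] <- 1 / 64
  v[nm %in% c("noise_amp", "noise_exp")] <- 1 / 64
  v[grepl("^(transit|decay)_", nm)] <- 1 / 256
  v[nm == "epsilon"] <- 1 / 256
  mu <- stats::setNames(numeric(length(nm)), nm)
  v <- stats::setNames(v, nm)
  if (!is.null(overrides)) {
    for (name in names(overrides)) {
      if (!name %in% nm) stop("unknown parameter in prior override: ", name)
      mu[name] <- overrides[[name]][1]
      v[name] <- overrides[[name]][2]
    }
  }
  if (any(v < 0)) stop("prior variances must be >= 0")
  structure(list(mean = mu, var = v, adjacency = adjacency, n_nodes = n),
            class = "prior_spec")
}
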