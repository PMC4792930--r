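# Variational-Laplace inversion of the spectral model from an observed
# cross-spectrum: Gauss-Newton ascent on the free energy with
# Levenberg-Marquardt damping and step rejection, a single log-precision
# hyperparameter for the observation error, and a Laplace posterior.

# 0-based (row, col) indices of free off-diagonal couplings, column-major,
# matching the param_names() ordering.
offdiag_index <- function(adjacency) {
  n <- nrow(adjacency)
  idx <- NULL
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i != j && adjacency[i, j] != 0) idx <- rbind(idx, c(i - 1L, j - 1L))
    }
  }
  if (is.null(idx)) idx <- matrix(0L, 0, 2)
  storage.mode(idx) <- "integer"
  idx
}

constants_vector <- function(constants) {
  with(constants, c(gamma, grubb, E0, V0, kappa0, tau0, eps0, k1, k2, k3,
                    noise_ref))
}

# Stacked forward prediction g(theta); compiled path by default, with the
# plain-R forward model available as reference.
forward_vector <- function(theta, n_nodes, adjacency, freqs, constants,
                           use_compiled = TRUE) {
  if (use_compiled) {
    return(as.numeric(csd_forward_cpp(as.numeric(theta), n_nodes,
                                      offdiag_index(adjacency), freqs,
                                      constants_vector(constants))))
  }
  model <- unpack_parameters(theta, n_nodes, adjacency, constants)
  csd_to_vector(predicted_csd(model, freqs))
}

forward_jacobian <- function(theta, n_nodes, adjacency, freqs, constants,
                             h = 1e-4, use_compiled = TRUE) {
  if (use_compiled) {
    out <- csd_jacobian_cpp(as.numeric(theta), n_nodes,
                            offdiag_index(adjacency), freqs,
                            constants_vector(constants), h)
    return(list(g = as.numeric(out$g), J = out$J))
  }
  g0 <- forward_vector(theta, n_nodes, adjacency, freqs, constants, FALSE)
  p <- length(theta)
  J <- matrix(0, length(g0), p)
  for (k in seq_len(p)) {
    tp <- theta; tp[k] <- theta[k] + h
    tm <- theta; tm[k] <- theta[k] - h
    J[, k] <- (forward_vector(tp, n_nodes, adjacency, freqs, constants, FALSE) -
                 forward_vector(tm, n_nodes, adjacency, freqs, constants, FALSE)) / (2 * h)
  }
  list(g = g0, J = J)
}

# Gaussian KL divergence KL(q || prior) for diagonal prior precision p0.
gaussian_kl <- function(dmu, Sigma, p0) {
  p <- length(dmu)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus + sum(log(p0))
  0.5 * (sum(p0 * diag(Sigma)) + sum(p0 * dmu^2) - p - as.numeric(ld))
}

#' Free energy of a Gaussian posterior under the spectral model
#'
#' Computes the variational free energy
#' \deqn{F = \langle \log p(y \mid \theta) \rangle_q - KL(q \,\|\, prior)}
#' for a Gaussian error model on the stacked real and imaginary parts of the
#' observed cross-spectrum, with a single estimated error log-precision on
#' top of fixed whitening weights: each entry's residual is scaled by
#' 1/sqrt(S_ii S_jj), the leading term of the sampling variance of spectral
#' estimates, computed once from the observed spectrum and shared by every
#' candidate model. The expected log-likelihood is evaluated to second
#' order (Gauss-Newton curvature) about the posterior mean. With \code{posterior_cov} equal to the prior
#' covariance and \code{theta} at the prior mean the complexity term is
#' exactly zero.
#'
#' @param theta posterior mean vector (free parameters, [param_names()]
#'   order for the prior's adjacency).
#' @param prior a [default_priors()] object.
#' @param observed a [cross_spectrum()].
#' @param freqs frequencies (Hz); default the observed grid.
#' @param posterior_cov posterior covariance (default: prior covariance).
#' @param log_precision error log-precision; if NULL, set to its MAP value
#'   under a scale-aware Gaussian hyperprior (centered on the precision at
#'   which the residual is ~13% of the centered data power), which keeps the
#'   precision bounded as the fit approaches the data.
#' @param constants a [balloon_constants()].
#' @param use_compiled use the compiled forward model (default TRUE).
#' @return list with \code{F} (nats), \code{accuracy}, \code{complexity},
#'   \code{log_precision}, \code{sse}.
#' @export
free_energy <- function(theta, prior, observed, freqs = NULL,
                        posterior_cov = NULL, log_precision = NULL,
                        constants = balloon_constants(),
                        use_compiled = TRUE) {
  stopifnot(inherits(prior, "prior_spec"), inherits(observed, "cross_spectrum"))
  if (!all(is.finite(theta))) stop("non-finite parameter vector")
  if (is.null(freqs)) freqs <- observed$freqs
  y <- csd_to_vector(observed)
  check_observed_psd(observed)
  n <- prior$n_nodes
  fj <- forward_jacobian(theta, n, prior$adjacency, freqs, constants,
                         use_compiled = use_compiled)
  sw <- sqrt(csd_whitening(observed))
  e <- (y - fj$g) * sw
  Jw <- fj$J * sw
  if (is.null(posterior_cov)) posterior_cov <- diag(prior$var, length(theta))
  Ebar <- sum(e^2) + sum(diag(Jw %*% posterior_cov %*% t(Jw)))
  n_e <- length(y)
  hyper <- lambda_hyperprior(y * sw, observed$noise_level)
  if (is.null(log_precision)) {
    log_precision <- hyper$mean
    for (it in 1:20) {
      g1 <- -0.5 * Ebar * exp(log_precision) + 0.5 * n_e -
        (log_precision - hyper$mean) / hyper$var
      g2 <- -0.5 * Ebar * exp(log_precision) - 1 / hyper$var
      step <- g1 / g2
      log_precision <- log_precision - max(min(step, 4), -4)
      if (abs(step) < 1e-8) break
    }
  }
  pi_e <- exp(log_precision)
  accuracy <- -0.5 * pi_e * Ebar + 0.5 * n_e * log_precision -
    0.5 * n_e * log(2 * pi)
  hyper_pen <- -0.5 * (log_precision - hyper$mean)^2 / hyper$var
  complexity <- gaussian_kl(theta - prior$mean, posterior_cov, 1 / prior$var)
  list(F = accuracy + hyper_pen - complexity, accuracy = accuracy,
       complexity = complexity, log_precision = log_precision, sse = sum(e^2))
}

check_observed_psd <- function(observed, tol = 1e-8) {
  for (M in observed$matrices) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * max(sum(abs(ev)), 1)) {
      stop("observed cross-spectrum is not positive semidefinite")
    }
  }
  invisible(TRUE)
}

# Fixed precision weights for the stacked cross-spectral data vector.
# The sampling variance of a spectral estimate S_ij scales with S_ii * S_jj
# (complex-Wishart first-order term), so residuals are whitened by the
# data-derived entry scale sqrt(S_ii S_jj); the weights are computed once
# from the observed spectrum and shared by every model fitted to it, with a
# single estimated log-precision on top.
csd_whitening <- function(observed) {
  n <- observed$n_nodes
  iu <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  is <- which(upper.tri(diag(n), diag = FALSE), arr.ind = TRUE)
  s <- unlist(lapply(observed$matrices, function(M) {
    d <- pmax(Re(diag(M)), 0)
    c(sqrt(d[iu[, 1]] * d[iu[, 2]]), sqrt(d[is[, 1]] * d[is[, 2]]))
  }))
  floor_s <- 1e-12 * max(s)
  1 / pmax(s, floor_s)^2
}

# Hyperprior on the error log-precision of the whitened residuals:
# lambda ~ N(lambda0, lambda_var). When the observed spectrum carries a
# split-half estimate of its own sampling-noise level, lambda0 is centered
# on that measured precision; otherwise it falls back to a scale-aware
# default (residual ~13% of the centered whitened data power). Without a
# hyperprior the precision is unbounded as the fit approaches the data and
# free-energy differences between models degenerate.
lambda_hyperprior <- function(yw, noise_level = NULL, lambda_var = 1 / 128) {
  if (!is.null(noise_level) && is.finite(noise_level) && noise_level > 0) {
    return(list(mean = -log(noise_level), var = lambda_var))
  }
  ssy <- sum((yw - mean(yw))^2)
  list(mean = log(length(yw) / ssy) + 2, var = lambda_var)
}

# F for a candidate mean: sets Sigma and the MAP lambda self-consistently,
# returns everything needed by the optimizer. `sw` is the square-root
# whitening weight vector from csd_whitening(); residuals and Jacobian are
# whitened before entering the Gaussian error model.
vl_evaluate <- function(theta, y, prior, freqs, constants, h, use_compiled,
                        sw, lambda_init = NULL,
                        hyper = lambda_hyperprior(y * sw)) {
  n <- prior$n_nodes
  fj <- forward_jacobian(theta, n, prior$adjacency, freqs, constants, h,
                         use_compiled)
  e <- (y - fj$g) * sw
  if (any(!is.finite(e))) return(NULL)
  J <- fj$J * sw
  JtJ <- crossprod(J)
  P0 <- 1 / prior$var
  n_e <- length(y)
  lambda <- if (is.null(lambda_init)) hyper$mean else lambda_init
  Sigma <- NULL
  Ebar <- sum(e^2)
  for (it in 1:8) {
    Prec <- exp(lambda) * JtJ + diag(P0, length(theta))
    Sigma <- tryCatch(chol2inv(chol(Prec)), error = function(err) NULL)
    if (is.null(Sigma)) return(NULL)
    Ebar <- sum(e^2) + sum(JtJ * Sigma)   # tr(J' J Sigma)
    # Newton step on the lambda-MAP condition
    g1 <- -0.5 * Ebar * exp(lambda) + 0.5 * n_e - (lambda - hyper$mean) / hyper$var
    g2 <- -0.5 * Ebar * exp(lambda) - 1 / hyper$var
    step <- g1 / g2
    lambda <- lambda - max(min(step, 4), -4)
    if (abs(step) < 1e-6) break
  }
  accuracy <- -0.5 * exp(lambda) * Ebar + 0.5 * n_e * lambda -
    0.5 * n_e * log(2 * pi)
  hyper_pen <- -0.5 * (lambda - hyper$mean)^2 / hyper$var
  complexity <- gaussian_kl(theta - prior$mean, Sigma, P0)
  list(theta = theta, g = fj$g, J = J, JtJ = JtJ, e = e, Sigma = Sigma,
       lambda = lambda, F = accuracy + hyper_pen - complexity)
}

#' Invert a spectral model from an observed cross-spectrum
#'
#' Gauss-Newton ascent on the free energy with Levenberg-Marquardt damping:
#' a candidate step is kept only if it increases F, otherwise the damping is
#' increased and the step recomputed. Returns the Laplace posterior (mean
#' and covariance over the free parameters), the final free energy, and fit
#' diagnostics.
#'
#' @param observed a [cross_spectrum()].
#' @param prior a [default_priors()] object (its adjacency defines which
#'   couplings are free; switched-off couplings are exact zeros in the
#'   model).
#' @param options list: \code{max_iter} (default 128), \code{tol} (|dF|
#'   threshold, 0.01 nats on 4 consecutive accepted steps), \code{h}
#'   (Jacobian step, 1e-4), \code{use_compiled} (TRUE), \code{constants}
#'   ([balloon_constants()]), \code{verbose}.
#' @return object of class \code{dcm_fit}: \code{mean} (named posterior
#'   mean), \code{cov}, \code{free_energy}, \code{variance_explained},
#'   \code{iterations}, \code{converged}, \code{log_precision},
#'   \code{F_trace} (accepted-step free energies), \code{adjacency},
#'   \code{n_nodes}, \code{freqs}, \code{predicted} (stacked vector).
#' @export
invert <- function(observed, prior, options = list()) {
  stopifnot(inherits(observed, "cross_spectrum"), inherits(prior, "prior_spec"))
  o <- utils::modifyList(list(max_iter = 128L, tol = 0.01, h = 1e-4,
                              use_compiled = TRUE,
                              constants = balloon_constants(),
                              verbose = FALSE), options)
  check_observed_psd(observed)
  freqs <- observed$freqs
  y <- csd_to_vector(observed)
  sw <- sqrt(csd_whitening(observed))
  hyper <- lambda_hyperprior(y * sw, observed$noise_level)
  theta <- prior$mean
  cur <- vl_evaluate(theta, y, prior, freqs, o$constants, o$h, o$use_compiled,
                     sw = sw, hyper = hyper)
  if (is.null(cur) || !is.finite(cur$F)) stop("non-finite free energy at the prior mean")
  F_trace <- cur$F
  damping <- 1 / 64
  small_steps <- 0L
  iters <- 0L
  converged <- FALSE
  P0 <- 1 / prior$var
  for (iter in seq_len(o$max_iter)) {
    iters <- iter
    grad <- exp(cur$lambda) * crossprod(cur$J, cur$e) -
      P0 * (cur$theta - prior$mean)
    accepted <- FALSE
    for (try in 1:12) {
      Prec <- exp(cur$lambda) * cur$JtJ + diag(P0, length(theta))
      H <- Prec + damping * diag(diag(Prec), length(theta))
      step <- tryCatch(solve(H, grad), error = function(err) NULL)
      if (!is.null(step)) {
        cand <- vl_evaluate(cur$theta + as.numeric(step), y, prior, freqs,
                            o$constants, o$h, o$use_compiled, sw = sw,
                            lambda_init = cur$lambda, hyper = hyper)
        if (!is.null(cand) && is.finite(cand$F) && cand$F > cur$F) {
          dF <- cand$F - cur$F
          cur <- cand
          F_trace <- c(F_trace, cur$F)
          damping <- max(damping / 2, 1e-8)
          accepted <- TRUE
          small_steps <- if (dF < o$tol) small_steps + 1L else 0L
          break
        }
      }
      damping <- damping * 8
    }
    if (o$verbose) message(sprintf("iter %3d  F = %.4f  damping = %.2g", iter, cur$F, damping))
    if (!accepted) break                      # no uphill step found
    if (small_steps >= 4L) { converged <- TRUE; break }
  }
  ve <- variance_explained_vec(y, cur$g)
  nm <- param_names(prior$n_nodes, prior$adjacency)
  structure(list(
    mean = stats::setNames(as.numeric(cur$theta), nm),
    cov = cur$Sigma,
    free_energy = cur$F,
    variance_explained = ve,
    iterations = iters,
    converged = converged || (!converged && length(F_trace) > 1 &&
                                all(abs(diff(utils::tail(F_trace, 5))) < o$tol)),
    log_precision = cur$lambda,
    F_trace = F_trace,
    adjacency = prior$adjacency,
    n_nodes = prior$n_nodes,
    freqs = freqs,
    predicted = cur$g
  ), class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> %d free parameters, F = %.2f nats, VE = %.1f%%, %d iterations%s\n",
              length(x$mean), x$free_energy, 100 * x$variance_explained,
              x$iterations, if (x$converged) " (converged)" else ""))
  invisible(x)
}

variance_explained_vec <- function(y, g) {
  ve <- 1 - sum((y - g)^2) / sum((y - mean(y))^2)
  if (ve < 0) {
    warning("negative variance explained clipped to 0")
    ve <- 0
  }
  min(ve, 1)
}

#' Proportion of observed cross-spectral variance explained by a fit
#'
#' \code{1 - sum |observed - predicted|^2 / sum |observed - mean|^2} over the
#' stacked real and imaginary parts of the band, clipped to [0, 1].
#'
#' @param fit a [invert()] result (or any list with \code{predicted}).
#' @param observed the [cross_spectrum()] the fit was estimated from (same
#'   frequency grid).
#' @return proportion in [0, 1].
#' @export
variance_explained <- function(fit, observed) {
  stopifnot(inherits(observed, "cross_spectrum"))
  if (!isTRUE(all.equal(fit$freqs, observed$freqs))) {
    stop("fit and observed spectrum are on different frequency grids")
  }
  variance_explained_vec(csd_to_vector(observed), fit$predicted)
}

#' Expand a fit's posterior to the full parameter naming
#'
#' Couplings switched off by the fit's adjacency are restored with posterior
#' mean exactly 0 and posterior variance exactly 0, so fits of different
#' models can be averaged on a common support.
#'
#' @param fit a [invert()] result.
#' @return list with named \code{mean} and \code{var} over
#'   \code{param_names(n, full adjacency)}.
#' @export
expand_fit <- function(fit) {
  full <- param_names(fit$n_nodes)
  mu <- stats::setNames(numeric(length(full)), full)
  v <- stats::setNames(numeric(length(full)), full)
  mu[names(fit$mean)] <- fit$mean
  v[names(fit$mean)] <- diag(fit$cov)
  list(mean = mu, var = v)
}
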