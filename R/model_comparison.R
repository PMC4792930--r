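# Bayesian model selection over a model space from per-subject free
# energies, and Bayesian model averaging of parameter posteriors.

#' Evidence table of per-subject, per-model free energies
#'
#' @param free_energies numeric subjects x models matrix (nats), finite.
#' @param subject_ids,model_ids optional identifiers.
#' @return object of class \code{evidence_table}.
#' @export
evidence_table <- function(free_energies, subject_ids = NULL, model_ids = NULL) {
  F <- as.matrix(free_energies)
  if (any(!is.finite(F))) stop("free energies must be finite")
  if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_len(nrow(F)))
  if (is.null(model_ids)) model_ids <- paste0("m", seq_len(ncol(F)))
  dimnames(F) <- list(subject_ids, model_ids)
  structure(list(free_energies = F, subject_ids = subject_ids,
                 model_ids = model_ids), class = "evidence_table")
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Fixed-effects Bayesian model selection
#'
#' Treats every subject as sharing one model: the group posterior is the
#' softmax of free energies summed over subjects. Exceedance probability
#' degenerates to an indicator of the maximum-evidence model.
#'
#' @param table an [evidence_table()].
#' @return object of class \code{bms_result} with \code{expected_probs},
#'   \code{exceedance_probs}, \code{method = "fixed"}.
#' @export
fixed_effects_bms <- function(table) {
  stopifnot(inherits(table, "evidence_table"))
  F <- table$free_energies
  if (nrow(F) < 1) stop("need at least one subject")
  p <- softmax(colSums(F))
  xp <- as.numeric(seq_along(p) == which.max(p))
  structure(list(expected_probs = stats::setNames(p, table$model_ids),
                 exceedance_probs = stats::setNames(xp, table$model_ids),
                 dirichlet_alpha = NULL, method = "fixed"),
            class = "bms_result")
}

#' Random-effects Bayesian model selection
#'
#' Variational estimation of a Dirichlet distribution over model frequencies
#' in the population: iterate
#' \deqn{u_{nk} \propto \exp(F_{nk} + \psi(\alpha_k) - \psi(\sum_j \alpha_j)),
#'   \quad \alpha_k = \alpha_0 + \sum_n u_{nk}}
#' to convergence, then estimate exceedance probabilities (the probability
#' that model k is more frequent than every other) by Monte-Carlo sampling
#' from the fitted Dirichlet.
#'
#' @param table an [evidence_table()].
#' @param alpha0 Dirichlet prior count per model (default 1, uniform).
#' @param n_samples Monte-Carlo draws for exceedance (default 1e6).
#' @param tol convergence threshold on the change in alpha.
#' @param max_iter iteration cap (error if exceeded).
#' @return object of class \code{bms_result} with \code{expected_probs},
#'   \code{exceedance_probs}, \code{dirichlet_alpha},
#'   \code{method = "random"}.
#' @export
random_effects_bms <- function(table, alpha0 = 1, n_samples = 1e6,
                               tol = 1e-8, max_iter = 1e4) {
  stopifnot(inherits(table, "evidence_table"))
  F <- table$free_energies
  K <- ncol(F)
  if (nrow(F) < 2) warning("random-effects BMS with fewer than 2 subjects")
  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lg <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    g <- t(apply(lg, 1, softmax))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
    if (it == max_iter) stop("random-effects BMS did not converge")
  }
  xp <- dirichlet_exceedance(alpha, n_samples)
  structure(list(expected_probs = stats::setNames(alpha / sum(alpha), table$model_ids),
                 exceedance_probs = stats::setNames(xp, table$model_ids),
                 dirichlet_alpha = stats::setNames(alpha, table$model_ids),
                 method = "random"),
            class = "bms_result")
}

# Monte-Carlo exceedance probabilities of a Dirichlet(alpha), sampled in
# blocks via independent Gamma draws. Uses the current RNG state.
dirichlet_exceedance <- function(alpha, n_samples = 1e6, block = 1e5) {
  K <- length(alpha)
  if (K == 1) return(1)
  wins <- numeric(K)
  left <- n_samples
  while (left > 0) {
    b <- min(block, left)
    G <- matrix(stats::rgamma(b * K, shape = rep(alpha, each = b)), nrow = b)
    idx <- max.col(G, ties.method = "first")
    wins <- wins + tabulate(idx, nbins = K)
    left <- left - b
  }
  wins / n_samples
}

#' @export
print.bms_result <- function(x, ...) {
  best <- which.max(x$exceedance_probs)
  cat(sprintf("<bms_result> %s effects, %d models; top model %s (xp = %.3f)\n",
              x$method, length(x$expected_probs), names(x$exceedance_probs)[best],
              x$exceedance_probs[best]))
  invisible(x)
}

#' Bayesian model averaging of per-subject fits
#'
#' Moment-matched mixture of the per-model Gaussian posteriors: for each
#' subject, averaged mean \eqn{\sum_m w_m \mu_m} and averaged variance
#' \eqn{\sum_m w_m (\sigma^2_m + \mu_m^2) - (\sum_m w_m \mu_m)^2} per
#' parameter. Fits are first expanded to the full parameter naming, so a
#' coupling absent from a model contributes exact zeros with that model's
#' weight. Models below the Occam window relative to the subject's best
#' model are dropped and the weights renormalized.
#'
#' @param fits list over subjects of lists over models of [invert()] fits.
#' @param probs subjects x models matrix of model weights, rows summing to 1
#'   (e.g. softmax of each row of an evidence table, or a group BMS
#'   posterior replicated across subjects).
#' @param occam_window log-weight window; models with
#'   \code{log(w) < log(max w) - occam_window} are dropped (default Inf:
#'   all models included).
#' @return object of class \code{bma_result}: \code{mean} and \code{var}
#'   (subjects x full parameter set), \code{weights} used.
#' @export
bma <- function(fits, probs, occam_window = Inf) {
  ns <- length(fits)
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == ns, ncol(probs) == length(fits[[1]]))
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("model weights must sum to 1 per subject")
  full <- param_names(fits[[1]][[1]]$n_nodes)
  mean_out <- matrix(0, ns, length(full), dimnames = list(NULL, full))
  var_out <- matrix(0, ns, length(full), dimnames = list(NULL, full))
  W <- matrix(0, ns, ncol(probs))
  for (s in seq_len(ns)) {
    w <- probs[s, ]
    keep <- log(w) >= log(max(w)) - occam_window
    w <- ifelse(keep, w, 0)
    w <- w / sum(w)
    W[s, ] <- w
    m1 <- numeric(length(full))
    m2 <- numeric(length(full))
    for (m in seq_along(w)) {
      if (w[m] == 0) next
      ex <- expand_fit(fits[[s]][[m]])
      m1 <- m1 + w[m] * ex$mean
      m2 <- m2 + w[m] * (ex$var + ex$mean^2)
    }
    mean_out[s, ] <- m1
    var_out[s, ] <- pmax(m2 - m1^2, 0)
  }
  structure(list(mean = mean_out, var = var_out, weights = W),
            class = "bma_result")
}

#' Per-subject model posterior probabilities from an evidence table
#'
#' Softmax of each subject's free energies; invariant to adding a constant
#' per subject.
#'
#' @param table an [evidence_table()].
#' @return subjects x models matrix of probabilities.
#' @export
subject_model_probs <- function(table) {
  stopifnot(inherits(table, "evidence_table"))
  t(apply(table$free_energies, 1, softmax))
}

#' Write an evidence table or BMS result as delimited text
#'
#' @param x an \code{evidence_table} or \code{bms_result}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_comparison <- function(x, path) {
  if (inherits(x, "evidence_table")) {
    utils::write.table(x$free_energies, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else if (inherits(x, "bms_result")) {
    df <- data.frame(model = names(x$expected_probs),
                     expected_prob = as.numeric(x$expected_probs),
                     exceedance_prob = as.numeric(x$exceedance_probs))
    if (!is.null(x$dirichlet_alpha)) df$alpha <- as.numeric(x$dirichlet_alpha)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
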