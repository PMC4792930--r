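# Group-level statistics relating connectivity parameters to age and
# cognition: multiple regression, canonical correlation analysis with
# structure correlations and permutation inference, moderation analysis,
# and false-discovery-rate control. The same machinery is applied to
# effective-connectivity (model-averaged) parameters and to the Fisher-z
# functional-connectivity baseline.

zstd <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) stop("constant column cannot be standardized")
  scale(x)[, , drop = FALSE]
}

drop_incomplete <- function(...) {
  pieces <- list(...)
  M <- do.call(cbind, lapply(pieces, as.matrix))
  ok <- stats::complete.cases(M)
  if (!all(ok)) message(sprintf("dropping %d incomplete case(s)", sum(!ok)))
  ok
}

#' Multiple regression of age on a parameter set
#'
#' Ordinary least squares of standardized age on standardized parameters
#' plus (standardized) covariates. Reports the multiple correlation R of the
#' full model, per-parameter standardized coefficients with analytic 95%
#' confidence intervals, and a flag for coefficients whose interval
#' excludes zero.
#'
#' @param params numeric matrix, subjects x parameters (named columns).
#' @param age numeric vector of ages.
#' @param covariates optional matrix/data.frame of nuisance covariates.
#' @return object of class \code{age_regression}: \code{R},
#'   \code{r_squared}, \code{p_value} (overall F test), and
#'   \code{coefficients} (data.frame: term, estimate, se, ci_lo, ci_hi,
#'   p, significant).
#' @export
age_regression <- function(params, age, covariates = NULL) {
  params <- as.matrix(params)
  if (is.null(colnames(params))) colnames(params) <- paste0("p", seq_len(ncol(params)))
  ok <- if (is.null(covariates)) drop_incomplete(params, age) else
    drop_incomplete(params, age, covariates)
  params <- params[ok, , drop = FALSE]
  age <- age[ok]
  X <- zstd(params)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
    X <- cbind(X, zstd(covariates))
  }
  n <- length(age)
  if (n <= ncol(X) + 2) stop("too few subjects for the number of predictors")
  y <- as.numeric(zstd(matrix(age)))
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  terms <- colnames(X)
  rows <- match(paste0("X", terms), rownames(ci))
  coefs <- data.frame(
    term = terms,
    estimate = stats::coef(fit)[rows],
    se = sm$coefficients[rows, "Std. Error"],
    ci_lo = ci[rows, 1], ci_hi = ci[rows, 2],
    p = sm$coefficients[rows, "Pr(>|t|)"],
    row.names = NULL
  )
  coefs$significant <- coefs$ci_lo > 0 | coefs$ci_hi < 0
  fstat <- sm$fstatistic
  p_overall <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(R = sqrt(sm$r.squared), r_squared = sm$r.squared,
                 p_value = as.numeric(p_overall), coefficients = coefs,
                 n = n), class = "age_regression")
}

# Symmetric inverse square root with ridge regularization for
# rank-deficient covariances.
inv_sqrt <- function(S, ridge_tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < ridge_tol * max(e$values)) {
    warning("rank-deficient covariance; applying ridge regularization")
    S <- S + diag(1e-8 * sum(diag(S)) / nrow(S), nrow(S))
    e <- eigen(S, symmetric = TRUE)
  }
  e$vectors %*% (1 / sqrt(e$values) * t(e$vectors))
}

#' Canonical correlation analysis
#'
#' Canonical weights via the singular value decomposition of the whitened
#' cross-covariance of the (internally standardized) sets. Variates have
#' unit variance. Sign convention: each weight vector's largest-magnitude
#' element is positive. Correlations are reported in [0, 1],
#' non-increasing.
#'
#' @param X,Y numeric matrices (subjects x variables).
#' @return object of class \code{cca_result}: \code{correlations},
#'   \code{x_weights}, \code{y_weights}, \code{x_variates},
#'   \code{y_variates} (V; first columns are the "connectivity profile" V1
#'   and "cognitive profile" W1 in the pipeline's usage).
#' @export
cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  if (n <= ncol(X) + ncol(Y) + 2) stop("too few subjects for CCA")
  Xs <- zstd(X); Ys <- zstd(Y)
  Sxx <- stats::cov(Xs); Syy <- stats::cov(Ys)
  Sxy <- stats::cov(Xs, Ys)
  Wx <- inv_sqrt(Sxx); Wy <- inv_sqrt(Syy)
  sv <- svd(Wx %*% Sxy %*% Wy)
  d <- min(ncol(X), ncol(Y))
  A <- Wx %*% sv$u[, seq_len(d), drop = FALSE]
  B <- Wy %*% sv$v[, seq_len(d), drop = FALSE]
  # unit-variance variates; deterministic orientation: X weights get their
  # largest-magnitude element positive, Y weights then take the sign that
  # keeps the realized canonical correlation non-negative
  for (k in seq_len(d)) {
    A[, k] <- A[, k] / stats::sd(Xs %*% A[, k])
    B[, k] <- B[, k] / stats::sd(Ys %*% B[, k])
    if (A[which.max(abs(A[, k])), k] < 0) A[, k] <- -A[, k]
    if (stats::cor(Xs %*% A[, k], Ys %*% B[, k]) < 0) B[, k] <- -B[, k]
  }
  rho <- pmin(pmax(sv$d[seq_len(d)], 0), 1)
  structure(list(correlations = rho, x_weights = A, y_weights = B,
                 x_variates = Xs %*% A, y_variates = Ys %*% B, n = n),
            class = "cca_result")
}

#' Structure correlations (loadings) of the first canonical pair
#'
#' Pearson correlation of every original variable with its own set's first
#' canonical variate. Loadings with |r| < 0.3 are flagged as
#' low-contribution.
#'
#' @param result a [cca()] result.
#' @param X,Y the original variable sets the CCA was fitted on.
#' @param threshold low-contribution threshold (default 0.3).
#' @return data.frame: set ("X"/"Y"), variable, loading, low_contribution.
#' @export
structure_correlations <- function(result, X, Y, threshold = 0.3) {
  stopifnot(inherits(result, "cca_result"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  lx <- as.numeric(stats::cor(X, result$x_variates[, 1]))
  ly <- as.numeric(stats::cor(Y, result$y_variates[, 1]))
  nx <- colnames(X); if (is.null(nx)) nx <- paste0("x", seq_len(ncol(X)))
  ny <- colnames(Y); if (is.null(ny)) ny <- paste0("y", seq_len(ncol(Y)))
  out <- data.frame(
    set = c(rep("X", length(lx)), rep("Y", length(ly))),
    variable = c(nx, ny),
    loading = c(lx, ly)
  )
  out$low_contribution <- abs(out$loading) < threshold
  out
}

#' Permutation significance of the first canonical correlation
#'
#' Rows of Y are permuted, the CCA refitted, and
#' \code{p = (1 + #(perm r >= observed r)) / (1 + n_perm)}. Bartlett's
#' chi-square approximation for the hypothesis that all canonical
#' correlations vanish is reported alongside.
#'
#' @param X,Y variable sets.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @return list: \code{observed_r}, \code{p_perm}, \code{p_bartlett},
#'   \code{n_perm}. Uses the current RNG state.
#' @export
cca_significance <- function(X, Y, n_perm = 1000) {
  stopifnot(n_perm >= 100)
  X <- as.matrix(X); Y <- as.matrix(Y)
  obs <- cca(X, Y)
  r1 <- obs$correlations[1]
  n <- nrow(Y)
  count <- 0L
  for (b in seq_len(n_perm)) {
    rp <- cca(X, Y[sample.int(n), , drop = FALSE])$correlations[1]
    if (rp >= r1) count <- count + 1L
  }
  p_perm <- (1 + count) / (1 + n_perm)
  rho <- obs$correlations
  lam <- -(n - 1 - (ncol(X) + ncol(Y) + 1) / 2) * sum(log(pmax(1 - rho^2, 1e-300)))
  p_bart <- stats::pchisq(lam, df = ncol(X) * ncol(Y), lower.tail = FALSE)
  list(observed_r = r1, p_perm = p_perm, p_bartlett = p_bart, n_perm = n_perm)
}

#' Moderation analysis: does age change the connectivity-cognition slope?
#'
#' OLS of the cognitive profile W1 on age, the connectivity profile V1,
#' their product, and nuisance covariates; age and V1 are standardized
#' before forming the interaction, and W1 is standardized, so coefficients
#' are on a standardized scale. Also returns simple slopes of W1 on V1
#' within age tertiles for plotting.
#'
#' @param W1 cognitive profile (vector).
#' @param V1 connectivity profile (vector).
#' @param age ages (vector).
#' @param covariates optional covariate matrix/data.frame.
#' @return object of class \code{moderation_result}: \code{coefficients}
#'   (data.frame with term, estimate, se, p), \code{R}, \code{p_value}
#'   (overall), \code{tertile_slopes} (data.frame: tertile, slope, se, n).
#' @export
moderation <- function(W1, V1, age, covariates = NULL) {
  stopifnot(length(W1) == length(V1), length(V1) == length(age))
  ok <- if (is.null(covariates)) drop_incomplete(W1, V1, age) else
    drop_incomplete(W1, V1, age, covariates)
  W1 <- W1[ok]; V1 <- V1[ok]; age <- age[ok]
  za <- as.numeric(zstd(matrix(age)))
  zv <- as.numeric(zstd(matrix(V1)))
  zw <- as.numeric(zstd(matrix(W1)))
  df <- data.frame(w = zw, age = za, profile = zv, interaction = za * zv)
  fm <- w ~ age + profile + interaction
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)[ok, , drop = FALSE]
    cz <- zstd(covariates)
    colnames(cz) <- paste0("cov_", seq_len(ncol(cz)))
    df <- cbind(df, cz)
    fm <- stats::as.formula(paste("w ~ age + profile + interaction +",
                                  paste(colnames(cz), collapse = " + ")))
  }
  qrX <- qr(stats::model.matrix(fm, df))
  if (qrX$rank < ncol(qrX$qr)) stop("moderation design matrix is rank deficient")
  fit <- stats::lm(fm, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  coefs <- data.frame(term = rownames(co)[-1], estimate = co[-1, "Estimate"],
                      se = co[-1, "Std. Error"], p = co[-1, "Pr(>|t|)"],
                      row.names = NULL)
  tert <- cut(age, stats::quantile(age, probs = c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = c("young", "middle", "older"))
  slopes <- do.call(rbind, lapply(levels(tert), function(g) {
    sel <- tert == g
    f <- stats::lm(zw[sel] ~ zv[sel])
    s <- summary(f)$coefficients
    data.frame(tertile = g, slope = s[2, 1], se = s[2, 2], n = sum(sel))
  }))
  fstat <- sm$fstatistic
  structure(list(coefficients = coefs, R = sqrt(sm$r.squared),
                 p_value = as.numeric(stats::pf(fstat[1], fstat[2], fstat[3],
                                                lower.tail = FALSE)),
                 tertile_slopes = slopes, n = length(zw)),
            class = "moderation_result")
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up FDR control across a family of p-values; a thin, named wrapper
#' over \code{stats::p.adjust(method = "BH")} returning both q-values and
#' the rejection set at the requested level.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param q_level rejection level (default 0.05).
#' @return list: \code{q_values}, \code{rejected} (logical), \code{q_level}.
#' @export
fdr_correct <- function(pvals, q_level = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  q <- stats::p.adjust(pvals, method = "BH")
  list(q_values = q, rejected = q <= q_level, q_level = q_level)
}

#' Run the full group-statistics battery on one parameter set
#'
#' Age regression, CCA of parameters against cognition with structure
#' correlations and permutation significance, and the moderation analysis
#' on the first canonical pair. This is the code path shared by the
#' effective-connectivity analysis and the functional-connectivity
#' reanalysis.
#'
#' @param params subjects x parameters matrix (named columns).
#' @param cognition subjects x scores matrix.
#' @param age ages.
#' @param covariates nuisance covariates (entered in the age regression and
#'   the moderation model, not the CCA).
#' @param n_perm permutations for CCA significance.
#' @param label tag attached to the output ("EC" or "FC").
#' @return object of class \code{group_stats}: \code{age_regression},
#'   \code{cca}, \code{cca_significance}, \code{structure_correlations},
#'   \code{moderation}, \code{label}.
#' @export
run_group_stats <- function(params, cognition, age, covariates = NULL,
                            n_perm = 1000, label = "EC") {
  params <- as.matrix(params)
  cognition <- as.matrix(cognition)
  ar <- age_regression(params, age, covariates)
  cc <- cca(params, cognition)
  sig <- cca_significance(params, cognition, n_perm = n_perm)
  sc <- structure_correlations(cc, params, cognition)
  mod <- moderation(cc$y_variates[, 1], cc$x_variates[, 1], age, covariates)
  structure(list(age_regression = ar, cca = cc, cca_significance = sig,
                 structure_correlations = sc, moderation = mod,
                 label = label), class = "group_stats")
}

#' Functional-connectivity reanalysis
#'
#' Applies the identical statistical machinery to Fisher-z functional
#' connectivity values instead of model parameters; outputs are labeled
#' "FC".
#'
#' @param fc_values subjects x edge matrix of Fisher-z correlations (e.g.
#'   rows of [fc_to_vector()]).
#' @inheritParams run_group_stats
#' @return a \code{group_stats} object with \code{label = "FC"}.
#' @export
fc_reanalysis <- function(fc_values, cognition, age, covariates = NULL,
                          n_perm = 1000) {
  run_group_stats(fc_values, cognition, age, covariates, n_perm, label = "FC")
}

#' Tidy coefficient tables from a group_stats object
#'
#' @param x a \code{group_stats} object.
#' @param dir output directory.
#' @return \code{dir}, invisibly. Writes age-regression coefficients,
#'   structure correlations, and moderation coefficients as TSV plus a JSON
#'   summary.
#' @export
write_group_stats <- function(x, dir) {
  stopifnot(inherits(x, "group_stats"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(dir, tolower(x$label))
  utils::write.table(x$age_regression$coefficients,
                     paste0(pre, "_age_regression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$structure_correlations,
                     paste0(pre, "_structure_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$moderation$coefficients,
                     paste0(pre, "_moderation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    label = x$label,
    age_R = x$age_regression$R,
    age_p = x$age_regression$p_value,
    cca_r1 = x$cca$correlations[1],
    cca_p_perm = x$cca_significance$p_perm,
    moderation_interaction = x$moderation$coefficients$estimate[
      x$moderation$coefficients$term == "interaction"],
    moderation_interaction_p = x$moderation$coefficients$p[
      x$moderation$coefficients$term == "interaction"]
  ), paste0(pre, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
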