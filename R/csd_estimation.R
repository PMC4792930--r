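#' Multichannel BOLD time series
#'
#' @param data numeric matrix, volumes x channels, no missing values.
#' @param tr repetition time in seconds.
#' @param labels optional channel names (defaults to column names or node1..n).
#' @return An object of class \code{time_series}.
#' @export
time_series <- function(data, tr, labels = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("time series contains missing values")
  stopifnot(is.numeric(data), tr > 0)
  if (nrow(data) < 17) stop("need at least 17 volumes")
  if (is.null(labels)) labels <- colnames(data)
  if (is.null(labels)) labels <- paste0("node", seq_len(ncol(data)))
  colnames(data) <- labels
  structure(list(data = data, tr = tr, labels = labels), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d volumes x %d channels, TR = %g s\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Representative time course of a region by SVD
#'
#' Returns the first left singular vector of the (column-demeaned) voxel
#' matrix, scaled by its singular value — the first principal component time
#' course of the region. Its sign is fixed so that the correlation with the
#' voxel-mean series is non-negative.
#'
#' @param voxel_matrix numeric matrix, volumes x voxels (>= 3 volumes,
#'   >= 2 voxels).
#' @param center subtract voxel means first (default TRUE).
#' @return numeric vector of length \code{nrow(voxel_matrix)}.
#' @export
svd_timeseries <- function(voxel_matrix, center = TRUE) {
  X <- as.matrix(voxel_matrix)
  stopifnot(nrow(X) >= 3, ncol(X) >= 2)
  if (all(X == 0)) stop("all-zero voxel matrix")
  if (center) X <- sweep(X, 2, colMeans(X))
  if (all(abs(X) < .Machine$double.eps)) stop("voxel matrix constant after centering")
  sv <- svd(X, nu = 1, nv = 0)
  u <- sv$u[, 1] * sv$d[1]
  m <- rowMeans(X)
  if (sum(u * m) < 0) u <- -u
  u
}

# Least-squares fit of a vector autoregressive model of given order.
# Returns coefficient array A[p] (n x n, lag p) and innovation covariance.
fit_mar <- function(data, order) {
  n_t <- nrow(data)
  n <- ncol(data)
  if (n_t <= order + 1) stop("too few volumes for the requested MAR order")
  Y <- data[(order + 1):n_t, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(order), function(p) {
    data[(order + 1 - p):(n_t - p), , drop = FALSE]
  }))
  XtX <- crossprod(X)
  cn <- kappa(XtX, exact = FALSE)
  if (!is.finite(cn) || cn > 1e12) {
    stop(sprintf("ill-conditioned MAR regression (condition number %.3g)", cn))
  }
  B <- solve(XtX, crossprod(X, Y))      # (order*n) x n
  E <- Y - X %*% B
  Sigma <- crossprod(E) / (nrow(Y) - order * n)
  A <- lapply(seq_len(order), function(p) {
    t(B[((p - 1) * n + 1):(p * n), , drop = FALSE])
  })
  list(A = A, Sigma = Sigma, order = order)
}

#' Empirical cross-spectral density by multivariate autoregression
#'
#' Fits a vector autoregressive (MAR) model of the given order by least
#' squares and evaluates its implied spectral matrix on the requested
#' frequency grid:
#' \deqn{S(f) = \Delta \, H(f) \Sigma H(f)^H, \quad
#'   H(f) = (I - \sum_p A_p e^{-2\pi i f p \Delta})^{-1}}
#' with \eqn{\Delta} the repetition time, so the output is a two-sided
#' spectral density per Hz on the same scale as [predicted_csd()].
#'
#' @param ts a [time_series()].
#' @param order MAR order (default 8).
#' @param freqs frequencies (Hz); default [default_freqs()] for the recording.
#' @param detrend remove a linear trend per channel first (default TRUE).
#' @param standardize divide each channel by its standard deviation after
#'   detrending (default FALSE, preserving absolute spectral scale).
#' @param error_estimate also estimate the estimator's own sampling-noise
#'   level by a split-half contrast (two MAR fits on the two halves of the
#'   recording); stored as \code{noise_level}, the average variance of a
#'   whitened cross-spectral entry, and used downstream to calibrate the
#'   inversion's error precision. Default TRUE.
#' @return a [cross_spectrum()] (with a \code{noise_level} element when
#'   \code{error_estimate} is TRUE).
#' @export
estimate_csd <- function(ts, order = 8, freqs = NULL, detrend = TRUE,
                         standardize = FALSE, error_estimate = TRUE) {
  stopifnot(inherits(ts, "time_series"))
  X <- ts$data
  n_t <- nrow(X)
  n <- ncol(X)
  if (is.null(freqs)) freqs <- default_freqs(n_t, ts$tr)
  if (n_t <= order * n) {
    warning(sprintf("only %d volumes for MAR order %d with %d channels", n_t, order, n))
  }
  if (detrend) {
    tt <- seq_len(n_t)
    X <- apply(X, 2, function(col) stats::lsfit(tt, col)$residuals)
  } else {
    X <- sweep(X, 2, colMeans(X))
  }
  if (standardize) X <- sweep(X, 2, apply(X, 2, stats::sd), "/")
  fit <- fit_mar(X, order)
  out <- cross_spectrum(freqs, mar_spectrum(fit, freqs, ts$tr),
                        labels = ts$labels)
  if (error_estimate) {
    half <- nrow(X) %/% 2
    v0 <- tryCatch({
      f1 <- fit_mar(X[seq_len(half), , drop = FALSE], order)
      f2 <- fit_mar(X[(half + 1):nrow(X), , drop = FALSE], order)
      s1 <- cross_spectrum(freqs, mar_spectrum(f1, freqs, ts$tr))
      s2 <- cross_spectrum(freqs, mar_spectrum(f2, freqs, ts$tr))
      sw <- sqrt(csd_whitening(out))
      d <- (csd_to_vector(s1) - csd_to_vector(s2)) * sw
      # halves each carry ~2x the variance of the full estimate
      mean(d^2) / 4
    }, error = function(err) NA_real_)
    out$noise_level <- v0
  }
  out
}

# Spectral matrix implied by a MAR fit on a frequency grid (per-Hz,
# two-sided): S(f) = tr * H(f) Sigma H(f)^H, H = (I - sum_p A_p z^-p)^-1.
mar_spectrum <- function(fit, freqs, tr) {
  n <- nrow(fit$Sigma)
  I <- diag(n)
  lapply(freqs, function(f) {
    Af <- I
    for (p in seq_len(fit$order)) {
      Af <- Af - fit$A[[p]] * exp(-2i * pi * f * p * tr)
    }
    H <- solve(Af)
    S <- tr * H %*% fit$Sigma %*% Conj(t(H))
    (S + Conj(t(S))) / 2
  })
}

#' Functional connectivity as Fisher-z correlations
#'
#' @param ts a [time_series()] with at least 3 volumes and no constant
#'   channel.
#' @return An object of class \code{fc_matrix}: list with \code{labels} and
#'   \code{z_values}, a symmetric matrix of \code{atanh(r)} with \code{NA}
#'   on the diagonal.
#' @export
fisher_fc <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  X <- ts$data
  if (nrow(X) < 3) stop("need at least 3 volumes")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant channel: ", paste(ts$labels[sds == 0], collapse = ", "))
  r <- stats::cor(X)
  off <- abs(r[upper.tri(r)])
  if (any(off >= 1 - 1e-12)) stop("perfectly correlated channel pair; Fisher z undefined")
  z <- atanh(r)
  diag(z) <- NA_real_
  structure(list(labels = ts$labels, z_values = z), class = "fc_matrix")
}

#' Flatten the upper triangle of an FC matrix to a named vector
#'
#' @param fc an \code{fc_matrix} from [fisher_fc()].
#' @return named numeric vector \code{zFC_<i>_<j>} over unordered pairs.
#' @export
fc_to_vector <- function(fc) {
  n <- length(fc$labels)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  v <- fc$z_values[upper.tri(fc$z_values)]
  names(v) <- paste0("zFC_", fc$labels[idx[, 1]], "_", fc$labels[idx[, 2]])
  v
}

#' Read / write time series as delimited text
#'
#' The first line is a comment header \code{# tr=<seconds>}; the second is
#' tab-separated channel labels; the rest is the volumes x channels matrix.
#'
#' @param ts a [time_series()].
#' @param path file path.
#' @return \code{write_time_series} returns \code{path} invisibly;
#'   \code{read_time_series} returns a [time_series()].
#' @export
write_time_series <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr=%.10g", ts$tr), con)
  utils::write.table(ts$data, con, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_time_series
#' @export
read_time_series <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# tr=", hdr)) stop("missing '# tr=' header in ", path)
  tr <- as.numeric(sub("^# tr=", "", hdr))
  dat <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                           check.names = FALSE)
  time_series(as.matrix(dat), tr = tr, labels = colnames(dat))
}
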