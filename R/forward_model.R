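#' Neural coupling matrix with parameterized self-inhibition
#'
#' Builds the directed coupling object used throughout the generative model.
#' Off-diagonal entries are coupling rates in Hz (entry \code{[i, j]} is the
#' influence of node j on node i). Diagonal entries are not free rates:
#' each node's self-connection is \code{-0.5 * exp(a_ii)} Hz, a log-scaling
#' of a -0.5 Hz reference decay, so the diagonal is negative for every real
#' \code{a_ii} and "stronger self-inhibition" is simply a larger \code{a_ii}.
#'
#' @param offdiag numeric n x n matrix of off-diagonal coupling rates (Hz);
#'   its diagonal is ignored and forced to zero.
#' @param selfparams numeric vector of length n of unitless log-scalings
#'   \code{a_ii}.
#' @return An object of class \code{neural_coupling} with elements
#'   \code{n_nodes}, \code{offdiag}, \code{selfparams}.
#' @seealso [coupling_matrix()], [stability_check()]
#' @export
neural_coupling <- function(offdiag, selfparams) {
  offdiag <- as.matrix(offdiag)
  n <- nrow(offdiag)
  stopifnot(ncol(offdiag) == n, length(selfparams) == n)
  diag(offdiag) <- 0
  structure(
    list(n_nodes = n, offdiag = offdiag, selfparams = as.numeric(selfparams)),
    class = "neural_coupling"
  )
}

#' Full coupling matrix A (Hz)
#'
#' @param coupling a [neural_coupling()] object.
#' @return The n x n matrix \code{A = offdiag + diag(-0.5 * exp(a_ii))}.
#' @export
coupling_matrix <- function(coupling) {
  stopifnot(inherits(coupling, "neural_coupling"))
  A <- coupling$offdiag
  diag(A) <- -0.5 * exp(coupling$selfparams)
  A
}

#' Stability of a coupling matrix
#'
#' A linear network \code{dx/dt = A x + input} is stable iff every eigenvalue
#' of A has strictly negative real part.
#'
#' @param coupling a [neural_coupling()] object or a plain square matrix A.
#' @return \code{TRUE} iff the maximum real part of the eigenvalues is < 0.
#' @export
stability_check <- function(coupling) {
  A <- if (inherits(coupling, "neural_coupling")) coupling_matrix(coupling) else as.matrix(coupling)
  stopifnot(nrow(A) == ncol(A))
  max(Re(eigen(A, only.values = TRUE)$values)) < 0
}

#' Endogenous fluctuation and observation-noise spectral parameters
#'
#' Neural fluctuations driving each node are modelled with a two-parameter
#' power law, \code{g(omega) = exp(alpha) * omega^(-beta)} (omega in rad/s),
#' i.e. a log-amplitude and a spectral exponent per node. Observation
#' (channel) noise has a single global amplitude/exponent pair shared by all
#' channels.
#'
#' @param neural_amplitude per-node log-amplitudes alpha_v.
#' @param neural_exponent per-node exponents beta_v (unitless; 0 = white).
#' @param noise_amplitude global observation-noise log-amplitude alpha_e.
#' @param noise_exponent global observation-noise exponent beta_e.
#' @return An object of class \code{fluctuation_params}.
#' @export
fluctuation_params <- function(neural_amplitude, neural_exponent,
                               noise_amplitude = -4, noise_exponent = 0) {
  stopifnot(length(neural_amplitude) == length(neural_exponent),
            length(noise_amplitude) == 1, length(noise_exponent) == 1)
  structure(
    list(neural_amplitude = as.numeric(neural_amplitude),
         neural_exponent = as.numeric(neural_exponent),
         noise_amplitude = as.numeric(noise_amplitude),
         noise_exponent = as.numeric(noise_exponent)),
    class = "fluctuation_params"
  )
}

#' Hemodynamic parameters (log-scalings of balloon-model rates)
#'
#' Per-node transit time tau = tau0 * exp(transit) and vasodilatory signal
#' decay kappa = kappa0 * exp(decay); a global epsilon = eps0 * exp(epsilon)
#' sets the intravascular/extravascular mixing of the BOLD read-out. The
#' exponential map keeps every physical rate positive for unconstrained
#' parameters.
#'
#' @param transit per-node log-scalings of the transit time (tau0 = 2 s).
#' @param decay per-node log-scalings of signal decay (kappa0 = 0.64 s^-1).
#' @param epsilon scalar log-scaling of the mixing ratio (eps0 = 1).
#' @return An object of class \code{hemodynamic_params}.
#' @export
hemodynamic_params <- function(transit, decay, epsilon = 0) {
  stopifnot(length(transit) == length(decay), length(epsilon) == 1)
  structure(
    list(transit = as.numeric(transit), decay = as.numeric(decay),
         epsilon = as.numeric(epsilon)),
    class = "hemodynamic_params"
  )
}

#' Fixed balloon-model constants
#'
#' Constants of the balloon observation model that are not estimated per
#' subject: vasodilatory autoregulation rate gamma, Grubb's flow-volume
#' exponent, resting oxygen extraction E0, resting venous volume fraction V0,
#' the reference rates kappa0 (signal decay) and tau0 (transit), the
#' reference mixing ratio eps0, and the BOLD read-out coefficients k1, k2,
#' k3. Defaults are the standard published balloon-model values; all can be
#' overridden.
#'
#' @param gamma autoregulation rate (s^-1).
#' @param grubb Grubb's exponent (unitless).
#' @param E0 resting oxygen extraction fraction.
#' @param V0 resting venous volume expressed in percent of tissue volume
#'   (the read-out is in percent signal change).
#' @param kappa0 reference signal-decay rate (s^-1).
#' @param tau0 reference transit time (s).
#' @param eps0 reference intravascular/extravascular mixing ratio.
#' @param k1,k2,k3 BOLD read-out coefficients; in the read-out the k2 term is
#'   scaled by epsilon (see [hemodynamic_kernel()]).
#' @param noise_ref reference level of the observation-noise spectrum
#'   (percent^2 per Hz); the free noise log-amplitude scales this reference,
#'   which is set so that in-band signal-to-noise is realistic (~10) when
#'   all log-parameters are zero.
#' @return An object of class \code{balloon_constants}.
#' @export
balloon_constants <- function(gamma = 0.32, grubb = 0.32, E0 = 0.4, V0 = 4,
                              kappa0 = 0.64, tau0 = 2, eps0 = 1,
                              k1 = 2.77, k2 = 0.4, k3 = 0.1,
                              noise_ref = 100) {
  vals <- c(gamma, grubb, E0, V0, kappa0, tau0, eps0, k1, k2, k3, noise_ref)
  if (any(vals <= 0)) stop("all balloon constants must be positive")
  structure(
    list(gamma = gamma, grubb = grubb, E0 = E0, V0 = V0, kappa0 = kappa0,
         tau0 = tau0, eps0 = eps0, k1 = k1, k2 = k2, k3 = k3,
         noise_ref = noise_ref),
    class = "balloon_constants"
  )
}

#' Full generative model for one subject
#'
#' @param coupling [neural_coupling()].
#' @param fluct [fluctuation_params()] with one amplitude/exponent per node.
#' @param hemo [hemodynamic_params()] with one transit/decay per node.
#' @param constants [balloon_constants()].
#' @return An object of class \code{spectral_model}.
#' @export
spectral_model <- function(coupling, fluct, hemo, constants = balloon_constants()) {
  stopifnot(inherits(coupling, "neural_coupling"),
            inherits(fluct, "fluctuation_params"),
            inherits(hemo, "hemodynamic_params"),
            inherits(constants, "balloon_constants"))
  n <- coupling$n_nodes
  stopifnot(length(fluct$neural_amplitude) == n, length(hemo$transit) == n)
  structure(
    list(coupling = coupling, fluct = fluct, hemo = hemo, constants = constants),
    class = "spectral_model"
  )
}

#' Default frequency grid for a recording
#'
#' 32 linearly spaced frequencies from 1/(n_volumes * tr) up to the top of
#' the resting-state band (0.1 Hz by default), matching the usual band-pass
#' analysis window for slow BOLD fluctuations.
#'
#' @param n_volumes number of volumes in the recording.
#' @param tr repetition time (s).
#' @param n_freq number of grid points.
#' @param f_max upper band edge (Hz).
#' @return strictly increasing vector of frequencies in Hz.
#' @export
default_freqs <- function(n_volumes, tr, n_freq = 32, f_max = 0.1) {
  stopifnot(n_volumes > 0, tr > 0)
  f_min <- 1 / (n_volumes * tr)
  if (f_min >= f_max) stop("recording too short for the requested band")
  seq(f_min, f_max, length.out = n_freq)
}

#' Neural transfer functions (i omega I - A)^-1
#'
#' @param coupling [neural_coupling()] (must be stable).
#' @param freqs frequencies in Hz.
#' @return list of complex n x n matrices, one per frequency.
#' @export
neural_transfer <- function(coupling, freqs) {
  A <- if (inherits(coupling, "neural_coupling")) coupling_matrix(coupling) else as.matrix(coupling)
  if (!stability_check(A)) stop("coupling matrix is unstable (eigenvalue with non-negative real part)")
  n <- nrow(A)
  I <- diag(n)
  lapply(freqs, function(f) {
    w <- 2 * pi * f
    solve((0+1i) * w * I - A)
  })
}

# Jacobian of the linearized balloon system for one node, plus the input and
# output maps. States: vasodilatory signal s, flow df, volume dv, dHb dq
# (deviations about the fixed point s=0, f=v=q=1):
#   ds  = u - kappa s - gamma df
#   ddf = s
#   tau ddv = df - (1/grubb) dv
#   tau ddq = cf df - (1/grubb - 1) dv - dq,  cf = 1 + (1-E0) log(1-E0) / E0
# BOLD read-out y = V0 [ k1 (1-q) + eps k2 (1 - q/v) + k3 (1-v) ] linearizes
# to dy = V0 [ (eps k2 - k3) dv - (k1 + eps k2) dq ].
balloon_linear_system <- function(kappa, tau, eps, constants) {
  cf <- 1 + (1 - constants$E0) * log(1 - constants$E0) / constants$E0
  ia <- 1 / constants$grubb
  J <- matrix(c(
    -kappa, -constants$gamma, 0,             0,
    1,      0,                0,             0,
    0,      1 / tau,          -ia / tau,     0,
    0,      cf / tau,         -(ia - 1) / tau, -1 / tau
  ), nrow = 4, byrow = TRUE)
  B <- c(1, 0, 0, 0)
  C <- constants$V0 * c(0, 0, eps * constants$k2 - constants$k3,
                        -(constants$k1 + eps * constants$k2))
  list(J = J, B = B, C = C)
}

#' Hemodynamic frequency response per node
#'
#' Linearizes the balloon model (vasodilatory signal with decay kappa and
#' autoregulation gamma; inflow; venous volume with transit tau and Grubb
#' exponent; deoxyhemoglobin; BOLD read-out) about its resting fixed point
#' and returns the first-order transfer function from neural activity to
#' BOLD, \code{K(omega) = C (i omega I - J)^-1 B}, for each node at each
#' frequency.
#'
#' @param hemo [hemodynamic_params()].
#' @param constants [balloon_constants()].
#' @param freqs frequencies in Hz.
#' @return complex matrix, \code{length(freqs)} x n_nodes.
#' @export
hemodynamic_kernel <- function(hemo, constants, freqs) {
  stopifnot(inherits(hemo, "hemodynamic_params"), inherits(constants, "balloon_constants"))
  n <- length(hemo$transit)
  kappa <- constants$kappa0 * exp(hemo$decay)
  tau <- constants$tau0 * exp(hemo$transit)
  eps <- constants$eps0 * exp(hemo$epsilon)
  if (any(kappa <= 0) || any(tau <= 0) || eps <= 0) stop("non-positive hemodynamic rate")
  out <- matrix(0+0i, nrow = length(freqs), ncol = n)
  I4 <- diag(4)
  for (j in seq_len(n)) {
    sys <- balloon_linear_system(kappa[j], tau[j], eps, constants)
    for (k in seq_along(freqs)) {
      w <- 2 * pi * freqs[k]
      out[k, j] <- sum(sys$C * solve((0+1i) * w * I4 - sys$J, sys$B))
    }
  }
  out
}

# Power-law spectra g(omega) = exp(alpha) omega^(-beta) evaluated on a Hz grid.
powerlaw_spectrum <- function(alpha, beta, freqs) {
  w <- 2 * pi * freqs
  outer_vals <- sapply(seq_along(alpha), function(j) exp(alpha[j]) * w^(-beta[j]))
  matrix(outer_vals, nrow = length(freqs))
}

#' Predicted cross-spectral density of a spectral model
#'
#' Implements the generative observation equation
#' \deqn{G_y(\omega) = K(\omega) (i\omega I - A)^{-1} G_v(\omega)
#'   (i\omega I - A)^{-H} K(\omega)^H + G_e(\omega)}
#' with diagonal hemodynamic kernels K, diagonal power-law neural spectra
#' G_v, and a diagonal observation-noise spectrum
#' \code{G_e = noise_ref * exp(alpha_e) * omega^(-beta_e)} shared across
#' channels (\code{noise_ref} from [balloon_constants()]).
#'
#' @param model [spectral_model()] (must be stable).
#' @param freqs frequencies in Hz.
#' @param identity_kernel if TRUE, replace the hemodynamic kernel by 1 for
#'   every node (direct observation of neural states); used for analytic
#'   checks and degenerate configurations.
#' @return a [cross_spectrum()] object.
#' @export
predicted_csd <- function(model, freqs, identity_kernel = FALSE) {
  stopifnot(inherits(model, "spectral_model"))
  n <- model$coupling$n_nodes
  S <- neural_transfer(model$coupling, freqs)
  Gv <- powerlaw_spectrum(model$fluct$neural_amplitude, model$fluct$neural_exponent, freqs)
  Ge <- model$constants$noise_ref *
    powerlaw_spectrum(rep(model$fluct$noise_amplitude, n),
                      rep(model$fluct$noise_exponent, n), freqs)
  K <- if (identity_kernel) matrix(1+0i, length(freqs), n) else
    hemodynamic_kernel(model$hemo, model$constants, freqs)
  mats <- vector("list", length(freqs))
  for (k in seq_along(freqs)) {
    KS <- K[k, ] * S[[k]]              # diag(K) %*% S
    G <- KS %*% (Gv[k, ] * Conj(t(KS)))  # KS %*% diag(Gv) %*% KS^H
    G <- (G + Conj(t(G))) / 2
    diag(G) <- Re(diag(G)) + Ge[k, ]
    mats[[k]] <- G
  }
  cross_spectrum(freqs, mats)
}

#' Cross-spectral density container
#'
#' @param freqs strictly increasing positive frequencies (Hz).
#' @param matrices list of complex Hermitian n x n matrices, one per
#'   frequency (symmetrized on construction; an error if far from Hermitian).
#' @param labels optional channel names.
#' @return An object of class \code{cross_spectrum}.
#' @export
cross_spectrum <- function(freqs, matrices, labels = NULL) {
  freqs <- as.numeric(freqs)
  stopifnot(length(freqs) == length(matrices), all(diff(freqs) > 0), all(freqs > 0))
  n <- nrow(matrices[[1]])
  mats <- lapply(matrices, function(M) {
    M <- as.matrix(M)
    stopifnot(nrow(M) == n, ncol(M) == n)
    H <- (M + Conj(t(M))) / 2
    if (max(Mod(M - H)) > 1e-6 * (1 + max(Mod(M)))) stop("matrix is not Hermitian")
    H
  })
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  structure(list(freqs = freqs, matrices = mats, labels = labels, n_nodes = n),
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d channels, %d frequencies in [%.4g, %.4g] Hz\n",
              x$n_nodes, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

# Stack a cross_spectrum into a real vector: per frequency, upper-triangular
# real parts (including the diagonal) then strict-upper imaginary parts.
# This is the data representation the inverter's Gaussian error model sees.
csd_to_vector <- function(csd) {
  n <- csd$n_nodes
  iu <- which(upper.tri(diag(n), diag = TRUE))
  is <- which(upper.tri(diag(n), diag = FALSE))
  unlist(lapply(csd$matrices, function(M) c(Re(M[iu]), Im(M[is]))))
}

#' Serialize / deserialize a cross-spectrum as JSON + delimited text
#'
#' The JSON header carries frequencies and labels; the matrix file holds one
#' row per frequency with interleaved real and imaginary parts, column-major.
#'
#' @param csd a [cross_spectrum()].
#' @param path base path; writes \code{<path>.json} and \code{<path>.tsv}.
#' @return \code{write_csd} returns \code{path} invisibly; \code{read_csd}
#'   returns the reconstructed [cross_spectrum()].
#' @export
write_csd <- function(csd, path) {
  jsonlite::write_json(list(freqs = csd$freqs, labels = csd$labels,
                            n_nodes = csd$n_nodes),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  flat <- t(vapply(csd$matrices, function(M) {
    as.numeric(rbind(Re(as.vector(M)), Im(as.vector(M))))
  }, numeric(2 * csd$n_nodes^2)))
  utils::write.table(flat, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_csd
#' @export
read_csd <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  n <- hdr$n_nodes
  mats <- lapply(seq_len(nrow(flat)), function(k) {
    row <- flat[k, ]
    re <- row[seq(1, length(row), by = 2)]
    im <- row[seq(2, length(row), by = 2)]
    matrix(complex(real = re, imaginary = im), n, n)
  })
  cross_spectrum(hdr$freqs, mats, labels = hdr$labels)
}
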