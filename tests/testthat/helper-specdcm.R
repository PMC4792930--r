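# Shared fixtures: small models and cohorts built in code.

toy_model <- function(n = 3, beta = 0.5) {
  baseline_model(n)
}

# a single-node model observing the neural state directly (identity kernel
# used via predicted_csd argument); white unit-amplitude input
single_node_white <- function(noise_amplitude = -30) {
  spectral_model(
    neural_coupling(matrix(0, 1, 1), 0),
    fluctuation_params(0, 0, noise_amplitude = noise_amplitude,
                       noise_exponent = 0),
    hemodynamic_params(0, 0, 0)
  )
}

study_freqs <- function(n_freq = 32) default_freqs(255, 1.97, n_freq = n_freq)

quiet_invert <- function(...) suppressWarnings(invert(...))

# band-average relative error between two cross_spectrum objects
csd_rel_error <- function(est, ref) {
  mean(vapply(seq_along(ref$freqs), function(k) {
    mean(Mod(est$matrices[[k]] - ref$matrices[[k]])) /
      mean(Mod(ref$matrices[[k]]))
  }, numeric(1)))
}

# Independent Welch oracle: Hann-windowed, overlapped, Daniell-smoothed
# periodogram averaging, interpolated onto a frequency grid; per-Hz
# two-sided convention matching predicted_csd().
welch_csd <- function(x, tr, seg = 256, hop = 64, freqs, smooth = 5) {
  n <- nrow(x); ch <- ncol(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))
  U <- sum(w^2)
  starts <- seq(1, n - seg + 1, by = hop)
  acc <- array(0 + 0i, c(seg, ch, ch))
  for (s in starts) {
    X <- mvfft(x[s:(s + seg - 1), , drop = FALSE] * w)
    for (i in 1:ch) for (j in 1:ch) {
      acc[, i, j] <- acc[, i, j] + X[, i] * Conj(X[, j])
    }
  }
  acc <- acc * tr / (U * length(starts))
  half <- smooth %/% 2
  sm <- acc
  for (k in (half + 1):(seg / 2)) {
    sm[k, , ] <- apply(acc[(k - half):(k + half), , , drop = FALSE], c(2, 3), mean)
  }
  lapply(freqs, function(f) {
    k <- f * seg * tr + 1
    k0 <- floor(k); a <- k - k0
    (1 - a) * sm[k0, , ] + a * sm[k0 + 1, , ]
  })
}
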