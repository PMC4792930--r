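test_that("coupling matrix and stability follow the self-inhibition parameterization", {
  nc <- neural_coupling(matrix(c(0, 0.2, 0, 0), 2, 2), c(0, 0))
  A <- coupling_matrix(nc)
  expect_equal(diag(A), c(-0.5, -0.5))
  expect_equal(A[2, 1], 0.2)
  expect_true(stability_check(nc))
  expect_true(stability_check(-0.5 * diag(3)))
  expect_false(stability_check(0.5 * diag(3)))
})

test_that("stability_check agrees with long-horizon SDE state boundedness", {
  # Euler-Maruyama oracle: integrate dx = A x dt + sigma dW over a long
  # horizon; stable systems stay bounded, unstable ones blow up
  set.seed(42)
  sde_bounded <- function(A, t_max = 150, dt = 0.01) {
    n <- nrow(A)
    x <- rep(0, n)
    peak <- 0
    for (i in seq_len(t_max / dt)) {
      x <- x + (A %*% x) * dt + sqrt(dt) * rnorm(n, 0, 0.1)
      peak <- max(peak, max(abs(x)))
      if (peak > 1e6) return(FALSE)
    }
    peak < 1e3
  }
  agree <- replicate(100, {
    A <- matrix(rnorm(16, 0, 0.35), 4, 4)
    diag(A) <- diag(A) - 0.4
    # skip marginal systems where the finite horizon cannot separate decay
    # from growth
    ev <- max(Re(eigen(A, only.values = TRUE)$values))
    if (abs(ev) < 0.1) return(NA)
    stability_check(A) == sde_bounded(A)
  })
  expect_true(all(agree, na.rm = TRUE))
})

test_that("neural transfer matches scalar and dense-solve oracles", {
  # single node, a_11 = 0 -> A = -0.5; at omega = 0 the transfer is -1/A = 2
  nc1 <- neural_coupling(matrix(0, 1, 1), 0)
  expect_equal(neural_transfer(nc1, 0)[[1]][1, 1], 2 + 0i)
  # diagonal coupling -> diagonal transfer at every frequency
  ncd <- neural_coupling(matrix(0, 3, 3), c(0.1, -0.2, 0))
  Td <- neural_transfer(ncd, c(0.01, 0.05, 0.1))
  for (M in Td) expect_equal(M[upper.tri(M) | lower.tri(M)], rep(0 + 0i, 6))
  # 2-node triangular coupling vs an independent dense inverse
  A <- matrix(c(-0.5, 0, 0.2, -0.5), 2, 2)
  nc <- neural_coupling(matrix(c(0, 0, 0.2, 0), 2, 2), c(0, 0))
  w <- 2 * pi * 0.05
  direct <- solve(1i * w * diag(2) - A)
  expect_equal(neural_transfer(nc, 0.05)[[1]], direct, tolerance = 1e-12)
  expect_error(neural_transfer(0.5 * diag(2), 0.05), "unstable")
})

test_that("hemodynamic kernel is symmetric across identical nodes and low-pass", {
  hemo <- hemodynamic_params(c(0.1, 0.1, 0.1), c(-0.2, -0.2, -0.2), 0.05)
  K <- hemodynamic_kernel(hemo, balloon_constants(), c(0.01, 0.05, 1))
  expect_equal(K[, 1], K[, 2])
  expect_equal(K[, 1], K[, 3])
  expect_lt(Mod(K[3, 1]), 0.05 * Mod(K[1, 1]))   # 1 Hz vs 0.01 Hz
  expect_error(hemodynamic_params(0, 0, c(0, 0)))
})

test_that("hemodynamic kernel matches RK4 integration of the linearized balloon ODEs", {
  hemo <- hemodynamic_params(0.15, -0.1, 0.1)
  const <- balloon_constants()
  sys <- specdcm:::balloon_linear_system(const$kappa0 * exp(hemo$decay[1]),
                                         const$tau0 * exp(hemo$transit[1]),
                                         const$eps0 * exp(hemo$epsilon), const)
  # time-domain impulse response by RK4 on dx/dt = J x, x(0) = B
  dt <- 0.01
  t_max <- 64
  nt <- t_max / dt
  x <- sys$B
  h_rk4 <- numeric(nt)
  f <- function(x) sys$J %*% x
  for (i in seq_len(nt)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    h_rk4[i] <- sum(sys$C * x)
  }
  # frequency response on the matching DFT grid, inverse transformed
  n_fft <- nt
  fgrid <- (1:(n_fft / 2 - 1)) / (n_fft * dt)
  K <- hemodynamic_kernel(hemo, const, fgrid)[, 1]
  spec <- complex(real = rep(0, n_fft))
  spec[2:(n_fft / 2)] <- K
  spec[n_fft:(n_fft / 2 + 2)] <- Conj(K)
  K0 <- sum(sys$C * solve(-sys$J, sys$B))        # zero-frequency gain
  spec[1] <- K0
  h_fft <- Re(fft(spec, inverse = TRUE)) / (n_fft * dt)
  # compare on the open interval (impulse response sampled mid-steps)
  idx <- 2:(30 / dt)
  err <- sqrt(sum((h_fft[idx] - h_rk4[idx - 1])^2) / sum(h_rk4[idx - 1]^2))
  expect_lt(err, 0.02)
})

test_that("predicted cross-spectrum obeys its degenerate and PSD contracts", {
  freqs <- study_freqs()
  # zero neural amplitude -> exactly the observation-noise spectrum
  m0 <- spectral_model(
    neural_coupling(matrix(0, 2, 2), c(0, 0)),
    fluctuation_params(c(-Inf, -Inf), c(0, 0), noise_amplitude = -1,
                       noise_exponent = 0.3),
    hemodynamic_params(c(0, 0), c(0, 0), 0)
  )
  G0 <- predicted_csd(m0, freqs)
  ge <- balloon_constants()$noise_ref * exp(-1) * (2 * pi * freqs)^(-0.3)
  for (k in seq_along(freqs)) {
    expect_equal(G0$matrices[[k]], diag(ge[k], 2) + 0i, tolerance = 1e-12)
  }
  # diagonal coupling and fluctuations -> zero off-diagonals
  md <- spectral_model(
    neural_coupling(matrix(0, 3, 3), c(0, 0.1, -0.1)),
    fluctuation_params(c(0, 0, 0), c(0.3, 0.3, 0.3)),
    hemodynamic_params(rep(0, 3), rep(0, 3), 0)
  )
  Gd <- predicted_csd(md, freqs)
  for (M in Gd$matrices) expect_lt(max(Mod(M[upper.tri(M)])), 1e-12)
  # generic 3-node model: Hermitian and PSD at every frequency
  G <- predicted_csd(baseline_model(3), freqs)
  for (M in G$matrices) {
    expect_equal(M, Conj(t(M)))
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("single-node white-input spectrum matches the analytic Lorentzian", {
  freqs <- study_freqs()
  G <- predicted_csd(single_node_white(), freqs, identity_kernel = TRUE)
  w <- 2 * pi * freqs
  got <- vapply(G$matrices, function(M) Re(M[1, 1]), numeric(1))
  want <- 1 / (w^2 + 0.25) + balloon_constants()$noise_ref * exp(-30)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("neural amplitude scales the signal part of the spectrum linearly", {
  freqs <- study_freqs()
  m <- baseline_model(3)
  base_noise <- balloon_constants()$noise_ref *
    exp(m$fluct$noise_amplitude) * (2 * pi * freqs)^(-m$fluct$noise_exponent)
  g1 <- predicted_csd(m, freqs)
  m2 <- m
  m2$fluct$neural_amplitude <- m$fluct$neural_amplitude + log(3)
  g2 <- predicted_csd(m2, freqs)
  for (k in seq_along(freqs)) {
    s1 <- g1$matrices[[k]] - diag(base_noise[k], 3)
    s2 <- g2$matrices[[k]] - diag(base_noise[k], 3)
    expect_equal(s2, 3 * s1, tolerance = 1e-10)
  }
})

test_that("compiled forward model agrees with the plain-R reference", {
  freqs <- study_freqs()
  set.seed(3)
  for (i in 1:5) {
    theta <- rnorm(24, 0, 0.2)
    gR <- specdcm:::forward_vector(theta, 3, matrix(1, 3, 3), freqs,
                                   balloon_constants(), use_compiled = FALSE)
    gC <- specdcm:::forward_vector(theta, 3, matrix(1, 3, 3), freqs,
                                   balloon_constants(), use_compiled = TRUE)
    expect_equal(gC, gR, tolerance = 1e-12)
  }
  # and under a sparse adjacency
  adj <- matrix(c(1, 0, 1, 1, 1, 0, 0, 1, 1), 3, 3)
  theta <- rnorm(length(param_names(3, adj)), 0, 0.2)
  gR <- specdcm:::forward_vector(theta, 3, adj, freqs, balloon_constants(), FALSE)
  gC <- specdcm:::forward_vector(theta, 3, adj, freqs, balloon_constants(), TRUE)
  expect_equal(gC, gR, tolerance = 1e-12)
})

test_that("cross-spectrum serialization round-trips", {
  g <- predicted_csd(baseline_model(3), study_freqs(8))
  path <- file.path(tempdir(), "csd_test")
  write_csd(g, path)
  back <- read_csd(path)
  expect_equal(back$freqs, g$freqs)
  expect_equal(back$matrices, g$matrices, tolerance = 1e-12)
})
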