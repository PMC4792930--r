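test_that("degenerate configs reproduce the baseline and exact linear age effects", {
  zero_sd <- setNames(numeric(24), param_names(3))
  cfg0 <- cohort_config(age_effects = numeric(0), subject_sd = zero_sd)
  set.seed(1)
  m1 <- draw_subject_parameters(cfg0, 25)
  m2 <- draw_subject_parameters(cfg0, 80)
  expect_equal(pack_parameters(m1), pack_parameters(cfg0$baseline))
  expect_equal(pack_parameters(m1), pack_parameters(m2))
  # one slope, no noise: difference is exactly s * (a1 - a2)
  cfgs <- cohort_config(age_effects = c(self_1 = 0.004), subject_sd = zero_sd)
  d <- pack_parameters(draw_subject_parameters(cfgs, 70))["self_1"] -
    pack_parameters(draw_subject_parameters(cfgs, 30))["self_1"]
  expect_equal(unname(d), 0.004 * 40, tolerance = 1e-12)
})

test_that("regression on the generator's own output recovers the age slopes", {
  cfg <- cohort_config(n_subjects = 200, seed = 7)
  coh <- simulate_cohort(cfg, simulate_series = FALSE)
  for (pn in c("self_1", "decay_2", "exp_1", "A_2_1")) {
    fit <- summary(lm(coh$true_theta[, pn] ~ coh$subjects$age))
    est <- fit$coefficients[2, 1]
    se <- fit$coefficients[2, 2]
    expect_lt(abs(est - cfg$age_effects[pn]) / se, 3)
  }
})

test_that("an impossible stability requirement names the offending slope", {
  cfg <- cohort_config(age_effects = c(A_2_1 = 1, self_1 = 0.001),
                       subject_sd = setNames(numeric(24), param_names(3)))
  expect_error(draw_subject_parameters(cfg, 88), "A_2_1")
})

test_that("simulated series are deterministic, stationary, and uncorrelated when decoupled", {
  m <- baseline_model(3)
  set.seed(11); a <- simulate_bold(m, 128, 1.97)
  set.seed(11); b <- simulate_bold(m, 128, 1.97)
  expect_identical(a$data, b$data)
  # independent channels: diagonal coupling, identical white nodes
  md <- spectral_model(
    neural_coupling(matrix(0, 3, 3), c(0, 0, 0)),
    fluctuation_params(rep(0, 3), rep(0, 3)),
    hemodynamic_params(rep(0, 3), rep(0, 3), 0)
  )
  set.seed(12)
  tsd <- simulate_bold(md, 65536, 1.97)
  r <- cor(tsd$data)
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)
  # stationarity: first-half vs second-half mean difference below 5 SE,
  # with the SE of each half-mean taken from non-overlapping block means
  # (the series are strongly autocorrelated, so per-sample SEs understate
  # the half-mean variability)
  cfg <- cohort_config(n_subjects = 40, seed = 3)
  coh <- simulate_cohort(cfg)
  block_se <- function(x, nblocks = 8) {
    bm <- tapply(x, rep(seq_len(nblocks), each = ceiling(length(x) / nblocks))[seq_along(x)], mean)
    sd(bm) / sqrt(nblocks)
  }
  ok <- vapply(coh$series, function(ts) {
    half <- nrow(ts$data) %/% 2
    all(vapply(seq_len(ncol(ts$data)), function(j) {
      x1 <- ts$data[1:half, j]
      x2 <- ts$data[(half + 1):nrow(ts$data), j]
      se <- sqrt(block_se(x1)^2 + block_se(x2)^2)
      abs(mean(x1) - mean(x2)) < 5 * se
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("long-run Welch spectrum converges to the model prediction", {
  set.seed(21)
  m <- baseline_model(3)
  ts <- simulate_bold(m, 16384, 1.97)
  freqs <- study_freqs()
  W <- welch_csd(ts$data, 1.97, freqs = freqs)
  gt <- predicted_csd(m, freqs)
  keep <- which(freqs >= 3 / (256 * 1.97))   # resolvable at this window
  err <- mean(vapply(keep, function(k) {
    mean(Mod(W[[k]] - gt$matrices[[k]])) / mean(Mod(gt$matrices[[k]]))
  }, numeric(1)))
  expect_lt(err, 0.10)
})

test_that("cognition generation implements the age-moderated profile slope", {
  n <- 3000
  set.seed(5)
  age <- runif(n, 18, 88)
  profile <- rnorm(n)
  # lambda = 0, no noise: identical slope in every age tertile
  cfg0 <- cohort_config(n_subjects = n, moderation_strength = 0, noise_sd = 1e-12)
  set.seed(6)
  y0 <- generate_cognition(profile, age, cfg0)
  tert <- cut(age, quantile(age, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)
  za <- specdcm:::age_zscore(age, cfg0)
  slopes <- vapply(levels(tert), function(g) {
    sel <- tert == g
    coef(lm(y0[sel, 1] ~ profile[sel] + za[sel]))[2]
  }, numeric(1))
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-6)
  # lambda > 0: OLS interaction recovers lambda * w_k within 3 SE
  cfg1 <- cohort_config(n_subjects = n, moderation_strength = 0.3)
  set.seed(7)
  y1 <- generate_cognition(profile, age, cfg1)
  for (k in c(1, 3)) {
    fit <- summary(lm(y1[, k] ~ profile * za))
    est <- fit$coefficients["profile:za", 1]
    se <- fit$coefficients["profile:za", 2]
    expect_lt(abs(est - 0.3 * cfg1$cognitive_weights[k]) / se, 3)
    expect_gt(est, 0)
  }
  # zero weights: cognition independent of the profile
  cfgz <- cohort_config(n_subjects = n, cognitive_weights = rep(0, 6))
  set.seed(8)
  yz <- generate_cognition(profile, age, cfgz)
  expect_gt(min(vapply(1:6, function(k) {
    summary(lm(yz[, k] ~ profile))$coefficients[2, 4]
  }, numeric(1))), 1e-4)
})

test_that("a cohort is reproducible bit-for-bit from its seed and round-trips to disk", {
  cfg <- cohort_config(n_subjects = 4, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$true_theta, b$true_theta)
  expect_identical(lapply(a$series, `[[`, "data"), lapply(b$series, `[[`, "data"))
  dir <- file.path(tempdir(), "cohort_test")
  write_cohort(a, dir)
  tab <- read_cohort_table(dir)
  expect_equal(tab$age, a$subjects$age, tolerance = 1e-12)
  ts1 <- read_time_series(file.path(dir, "sub0001_bold.tsv"))
  expect_equal(ts1$tr, 1.97)
  expect_equal(unname(ts1$data), unname(a$series[[1]]$data), tolerance = 1e-6)
})
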