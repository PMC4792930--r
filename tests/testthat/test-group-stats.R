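test_that("age regression detects a perfect linear predictor and nothing else", {
  set.seed(1)
  n <- 120
  P <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("p", 1:4)))
  age <- 50 + 10 * P[, 2]
  ar <- age_regression(P, age)
  expect_equal(ar$R, 1, tolerance = 1e-8)
  expect_true(ar$coefficients$significant[ar$coefficients$term == "p2"])
  expect_false(any(ar$coefficients$significant[ar$coefficients$term != "p2"]))
})

test_that("age regression p-values are uniform under label permutation", {
  set.seed(2)
  n <- 80
  P <- matrix(rnorm(n * 3), n, 3)
  age <- runif(n, 18, 88)
  ps <- replicate(100, age_regression(P, sample(age))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("age regression recovers the generator's standardized slopes", {
  cfg <- cohort_config(n_subjects = 300, seed = 9)
  coh <- simulate_cohort(cfg, simulate_series = FALSE)
  params <- coh$true_theta[, c("self_1", "self_2", "self_3", "A_2_1")]
  ar <- age_regression(params, coh$subjects$age)
  # construction: age ranges +-35 years around the midpoint with slope
  # 0.004/yr on self terms against subject scatter 0.08
  for (term in c("self_1", "self_2", "self_3")) {
    row <- ar$coefficients[ar$coefficients$term == term, ]
    expect_gt(row$estimate, 0)
    expect_true(row$significant)
  }
  expect_gt(ar$R, 0.5)
})

test_that("cca handles identity, independence, and affine invariance", {
  set.seed(3)
  x <- rnorm(200)
  r1 <- cca(matrix(x), matrix(x))
  expect_equal(r1$correlations[1], 1, tolerance = 1e-10)
  # independent sets: permutation p above 0.05 in most seeded runs
  hits <- replicate(20, {
    X <- matrix(rnorm(500 * 5), 500)
    Y <- matrix(rnorm(500 * 5), 500)
    cca_significance(X, Y, n_perm = 199)$p_perm > 0.05
  })
  expect_gte(mean(hits), 0.9)
  # invertible affine transform of X leaves correlations unchanged
  X <- matrix(rnorm(300 * 4), 300)
  Y <- matrix(rnorm(300 * 3), 300)
  A <- matrix(rnorm(16), 4)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
  base <- cca(X, Y)$correlations
  trans <- cca(sweep(X %*% A, 2, c(1, -2, 3, 0), "+"), Y)$correlations
  expect_equal(trans, base, tolerance = 1e-10)
  expect_true(all(diff(base) <= 1e-10))
  expect_true(all(base >= 0 & base <= 1))
})

test_that("first canonical correlation dominates every single-pair correlation", {
  set.seed(4)
  X <- matrix(rnorm(150 * 3), 150)
  Y <- matrix(rnorm(150 * 4), 150)
  Y[, 1] <- Y[, 1] + 0.5 * X[, 2]
  r1 <- cca(X, Y)$correlations[1]
  expect_gte(r1 + 1e-10, max(abs(cor(X, Y))))
})

test_that("cca matches the base-R cancor cross-check", {
  set.seed(5)
  X <- matrix(rnorm(200 * 3), 200)
  Y <- matrix(rnorm(200 * 3), 200)
  Y[, 2] <- Y[, 2] + X[, 1]
  expect_equal(cca(X, Y)$correlations, unname(cancor(scale(X), scale(Y))$cor),
               tolerance = 1e-8)
})

test_that("structure correlations flag signal variables and respect symmetry", {
  set.seed(6)
  x <- rnorm(200)
  X <- cbind(a = x, b = x, c = rnorm(200))
  Y <- matrix(x + rnorm(200, 0, 0.5), dimnames = list(NULL, "y"))
  cc <- cca(X, Y)
  sc <- structure_correlations(cc, X, Y)
  expect_equal(sc$loading[sc$variable == "a"], sc$loading[sc$variable == "b"],
               tolerance = 1e-6)
  expect_equal(abs(sc$loading[sc$variable == "y"]), 1, tolerance = 1e-6)
  # single-column X: loading +-1
  cc1 <- cca(matrix(x), Y)
  sc1 <- structure_correlations(cc1, matrix(x), Y)
  expect_equal(abs(sc1$loading[sc1$set == "X"]), 1, tolerance = 1e-10)
  # identification: the signal-carrying columns have the largest loadings
  hit <- replicate(20, {
    n <- 300
    latent <- rnorm(n)
    P <- matrix(rnorm(n * 9), n, 9)
    P[, 2] <- latent + rnorm(n, 0, 0.7)
    P[, 7] <- latent + rnorm(n, 0, 0.7)
    Yl <- matrix(latent + rnorm(n, 0, 0.8))
    sc2 <- structure_correlations(cca(P, Yl), P, Yl)
    lx <- abs(sc2$loading[sc2$set == "X"])
    all(rank(-lx)[c(2, 7)] <= 2)
  })
  expect_gte(sum(hit), 18)
})

test_that("permutation p attains its minimum under perfect dependence and Bartlett agrees", {
  set.seed(7)
  x <- rnorm(300)
  s <- cca_significance(matrix(x), matrix(x), n_perm = 199)
  expect_equal(s$p_perm, 1 / 200)
  X <- matrix(rnorm(500 * 4), 500)
  Y <- matrix(rnorm(500 * 4), 500)
  s2 <- cca_significance(X, Y, n_perm = 499)
  expect_lt(abs(s2$p_perm - s2$p_bartlett), 0.05)
  expect_error(cca_significance(X, Y, n_perm = 10), "n_perm")
})

test_that("cca permutation p-values are uniform under the null", {
  set.seed(8)
  ps <- replicate(100, {
    X <- matrix(rnorm(60 * 3), 60)
    Y <- matrix(rnorm(60 * 2), 60)
    cca_significance(X, Y, n_perm = 199)$p_perm
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("moderation is calibrated at lambda = 0 and monotone in age when lambda > 0", {
  n <- 2000
  set.seed(9)
  age <- runif(n, 18, 88)
  profile <- rnorm(n)
  cfg0 <- cohort_config(n_subjects = n, moderation_strength = 0)
  y0 <- generate_cognition(profile, age, cfg0)
  W0 <- as.numeric(y0 %*% cfg0$cognitive_weights)
  m0 <- moderation(W0, profile, age)
  row <- m0$coefficients[m0$coefficients$term == "interaction", ]
  expect_lt(abs(row$estimate) / row$se, 3)
  # lambda > 0, no noise: tertile simple slopes strictly increase with age
  cfg1 <- cohort_config(n_subjects = n, moderation_strength = 0.4,
                        noise_sd = 1e-12)
  y1 <- generate_cognition(profile, age, cfg1)
  W1 <- as.numeric(y1 %*% cfg1$cognitive_weights)
  m1 <- moderation(W1, profile, age)
  expect_true(all(diff(m1$tertile_slopes$slope) > 0))
  expect_gt(m1$coefficients$estimate[m1$coefficients$term == "interaction"], 0)
})

test_that("moderation rejects a rank-deficient design", {
  set.seed(10)
  age <- runif(50, 18, 88)
  v <- rnorm(50)
  expect_error(moderation(rnorm(50), v, age, covariates = cbind(v, v)),
               "rank deficient")
})

test_that("Benjamini-Hochberg correction matches the hand-evaluated rule", {
  r <- fdr_correct(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(r$rejected))
  expect_true(all(r$q_values <= 0.05))
  expect_identical(fdr_correct(rep(1, 5))$rejected, rep(FALSE, 5))
  expect_true(fdr_correct(0.04)$rejected)
  set.seed(11)
  p <- runif(30)
  r2 <- fdr_correct(p)
  expect_true(all(r2$q_values >= p))
  expect_true(all(diff(r2$q_values[order(p)]) >= -1e-12))
  expect_error(fdr_correct(c(0.5, 1.2)))
})

test_that("the FC reanalysis runs the identical machinery under an FC label", {
  set.seed(12)
  n <- 150
  fcv <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("z12", "z13", "z23")))
  cog <- matrix(rnorm(n * 6), n, 6)
  age <- runif(n, 18, 88)
  out <- fc_reanalysis(fcv, cog, age, n_perm = 199)
  expect_s3_class(out, "group_stats")
  expect_identical(out$label, "FC")
  ec <- run_group_stats(fcv, cog, age, n_perm = 199, label = "EC")
  expect_identical(ec$cca$correlations, out$cca$correlations)
  dir <- file.path(tempdir(), "gs_out")
  write_group_stats(out, dir)
  expect_true(file.exists(file.path(dir, "fc_summary.json")))
})
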