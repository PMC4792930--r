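test_that("fixed-effects BMS follows the softmax of summed evidence", {
  et <- evidence_table(matrix(c(-10, -10, -10, -10), 2, 2))
  r <- fixed_effects_bms(et)
  expect_equal(unname(r$expected_probs), c(0.5, 0.5))
  # one model larger by 1000 nats saturates
  et2 <- evidence_table(cbind(rep(-10, 3), rep(-10, 3) + 1000 / 3))
  r2 <- fixed_effects_bms(et2)
  expect_gte(unname(r2$expected_probs[2]), 1 - 1e-6)
  expect_equal(unname(r2$exceedance_probs), c(0, 1))
  # single subject, dF = log 3 -> (0.75, 0.25)
  et3 <- evidence_table(matrix(c(log(3), 0), 1, 2))
  expect_equal(unname(fixed_effects_bms(et3)$expected_probs), c(0.75, 0.25),
               tolerance = 1e-12)
})

test_that("probabilities are invariant to per-subject constants", {
  set.seed(1)
  F0 <- matrix(rnorm(15, -100, 3), 5, 3)
  shifted <- F0 + rnorm(5, 0, 50)
  expect_equal(fixed_effects_bms(evidence_table(F0))$expected_probs,
               fixed_effects_bms(evidence_table(shifted))$expected_probs,
               tolerance = 1e-9)
  expect_equal(subject_model_probs(evidence_table(F0)),
               subject_model_probs(evidence_table(shifted)), tolerance = 1e-9)
  set.seed(2)
  a <- random_effects_bms(evidence_table(F0), n_samples = 1e5)
  set.seed(2)
  b <- random_effects_bms(evidence_table(shifted), n_samples = 1e5)
  expect_equal(a$dirichlet_alpha, b$dirichlet_alpha, tolerance = 1e-6)
})

test_that("random-effects BMS respects symmetry, count conservation, and saturation", {
  K <- 4; n <- 12
  et <- evidence_table(matrix(-50, n, K))
  set.seed(3)
  r <- random_effects_bms(et, n_samples = 2e5)
  expect_equal(sum(r$dirichlet_alpha), 1 * K + n, tolerance = 1e-6)
  mc_se <- sqrt(0.25 / K / 2e5) * K   # generous bound on the MC error
  expect_true(all(abs(r$exceedance_probs - 1 / K) < 3 * sqrt(1 / K * (1 - 1 / K) / 2e5) + 0.01))
  expect_equal(sum(r$exceedance_probs), 1, tolerance = 1e-6)
  # one overwhelming model
  F2 <- matrix(-100, 10, 3)
  F2[, 2] <- -50
  set.seed(4)
  r2 <- random_effects_bms(evidence_table(F2), n_samples = 1e5)
  expect_gte(unname(r2$exceedance_probs[2]), 0.99)
})

test_that("K = 2 exceedance matches the Beta-tail quadrature", {
  set.seed(5)
  F0 <- matrix(rnorm(20, -80, 1.5), 10, 2)
  r <- random_effects_bms(evidence_table(F0), n_samples = 1e6)
  a <- unname(r$dirichlet_alpha)
  # P(p1 > p2) for (p1, p2) ~ Dirichlet(a1, a2): Beta tail above 1/2
  oracle <- pbeta(0.5, a[1], a[2], lower.tail = FALSE)
  expect_lt(abs(unname(r$exceedance_probs[1]) - oracle), 0.01)
})

test_that("model averaging reproduces mixture moments", {
  mkfit <- function(mu, v, adj = matrix(1, 2, 2)) {
    nm <- param_names(2, adj)
    structure(list(mean = setNames(rep(mu, length(nm)), nm),
                   cov = diag(v, length(nm)), n_nodes = 2,
                   adjacency = adj), class = "dcm_fit")
  }
  # single model: identity
  b1 <- bma(list(list(mkfit(0.3, 0.1))), matrix(1, 1, 1))
  expect_equal(unname(b1$mean[1, "A_2_1"]), 0.3)
  expect_equal(unname(b1$var[1, "A_2_1"]), 0.1)
  # two identical models, weights 0.3 / 0.7: unchanged moments
  b2 <- bma(list(list(mkfit(0.3, 0.1), mkfit(0.3, 0.1))),
            matrix(c(0.3, 0.7), 1, 2))
  expect_equal(unname(b2$mean[1, "A_2_1"]), 0.3)
  expect_equal(unname(b2$var[1, "A_2_1"]), 0.1, tolerance = 1e-12)
  # means 0 and 1, zero variances, equal weights -> mean .5, var .25
  b3 <- bma(list(list(mkfit(0, 0), mkfit(1, 0))), matrix(0.5, 1, 2))
  expect_equal(unname(b3$mean[1, "A_2_1"]), 0.5)
  expect_equal(unname(b3$var[1, "A_2_1"]), 0.25)
  # a parameter absent from one model contributes zeros with weight
  adj_red <- matrix(1, 2, 2); adj_red[1, 2] <- 0
  b4 <- bma(list(list(mkfit(1, 0), mkfit(1, 0, adj_red))), matrix(0.5, 1, 2))
  expect_equal(unname(b4$mean[1, "A_1_2"]), 0.5)
  expect_equal(unname(b4$var[1, "A_1_2"]), 0.25)
  expect_error(bma(list(list(mkfit(0, 0), mkfit(1, 0))), matrix(c(0.5, 0.4), 1, 2)),
               "sum to 1")
  # Occam window drops negligible models and renormalizes
  b5 <- bma(list(list(mkfit(0, 0), mkfit(1, 0))), matrix(c(1e-12, 1 - 1e-12), 1, 2),
            occam_window = 10)
  expect_equal(unname(b5$mean[1, "A_2_1"]), 1)
})

test_that("evidence tables reject non-finite entries and serialize", {
  expect_error(evidence_table(matrix(c(1, NA), 1, 2)), "finite")
  et <- evidence_table(matrix(c(-1, -2, -3, -4), 2, 2))
  p1 <- file.path(tempdir(), "ev.tsv")
  write_comparison(et, p1)
  expect_true(file.exists(p1))
  set.seed(6)
  p2 <- file.path(tempdir(), "bms.tsv")
  write_comparison(random_effects_bms(et, n_samples = 1e4), p2)
  got <- read.delim(p2)
  expect_equal(nrow(got), 2)
  expect_equal(sum(got$exceedance_prob), 1, tolerance = 1e-6)
})
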