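test_that("full enumeration counts follow 2^(n^2)", {
  expect_length(enumerate_full(1)$models, 2)
  expect_length(enumerate_full(2)$models, 16)
  expect_length(enumerate_full(3)$models, 512)
})

test_that("self-connection and connectedness rules yield the plausible sets", {
  rules <- plausibility_rules()
  expect_length(apply_rules(enumerate_full(3), rules)$models, 54)
  expect_length(apply_rules(enumerate_full(2), rules)$models, 3)
})

test_that("filtered counts match independent combinatorial oracles", {
  # brute force over the 4 off-diagonal patterns for n = 2, written out
  # directly: self-connections fixed to 1; only the empty off-diagonal
  # pattern leaves a node isolated
  n2 <- 0
  for (a12 in 0:1) for (a21 in 0:1) {
    if (a12 + a21 > 0) n2 <- n2 + 1
  }
  expect_equal(length(apply_rules(enumerate_full(2), plausibility_rules())$models), n2)
  # inclusion-exclusion for n = 3 over the 2^6 off-diagonal patterns:
  # subtract patterns isolating node 1, 2 or 3 (each fixes 4 of 6 edges off:
  # 2^2 each), add back pairwise isolations (2^0 each... all three pairs
  # force 6 edges off except the edge pair between the remaining nodes),
  # subtract the fully empty pattern counted three times
  iso_one <- 3 * 2^2
  iso_two <- 3 * 1       # both nodes of a pair isolated: remaining node free edges = 0 -> 1 pattern each
  iso_all <- 1
  n3 <- 2^6 - (iso_one - iso_two + iso_all)
  expect_equal(n3, 54)
  expect_equal(length(apply_rules(enumerate_full(3), plausibility_rules())$models), n3)
})

test_that("filtering is idempotent and deterministic in order", {
  rules <- plausibility_rules()
  once <- apply_rules(enumerate_full(3), rules)
  twice <- apply_rules(once, rules)
  expect_identical(once$models, twice$models)
  flat <- vapply(once$models, function(m) paste(as.vector(m), collapse = ""), "")
  expect_identical(flat, sort(flat))
})

test_that("laterality rules prune asymmetric and unilateral models", {
  labels <- c("dACC", "lAI", "rAI")
  space <- enumerate_full(3, labels)
  sym <- apply_rules(space, plausibility_rules(sagittal_symmetry = TRUE))
  # closure under left<->right relabeling
  perm <- specdcm:::laterality_map(labels)
  expect_equal(perm, c(1, 3, 2))
  for (m in sym$models) {
    expect_true(any(vapply(sym$models, identical, logical(1), m[perm, perm])))
  }
  # bilateral homotopic pair must be bidirectional or absent
  homo <- apply_rules(space, plausibility_rules(
    bilateral_homotopic_only = list(c("lAI", "rAI"))))
  for (m in homo$models) expect_equal(m[2, 3], m[3, 2])
  # forbidden link removes all direct edges of the pair
  forb <- apply_rules(space, plausibility_rules(
    forbidden_links = list(c("dACC", "rAI"))))
  for (m in forb$models) expect_equal(m[1, 3] + m[3, 1], 0)
  # required link keeps at least one direction
  req <- apply_rules(space, plausibility_rules(
    required_links = list(c("dACC", "lAI"))))
  for (m in req$models) expect_gt(m[1, 2] + m[2, 1], 0)
  expect_error(apply_rules(space, plausibility_rules(
    required_links = list(c("dACC", "nope")))), "unknown node label")
})

test_that("an unsatisfiable rule set warns and returns an empty space", {
  space <- enumerate_full(2, c("lX", "rX"))
  expect_warning(
    out <- apply_rules(space, plausibility_rules(
      require_connected = TRUE, forbidden_links = list(c("lX", "rX")))),
    "no model")
  expect_length(out$models, 0)
})

test_that("model specifications translate into switched priors", {
  full <- matrix(1, 3, 3)
  pr_full <- to_prior(full)
  expect_length(pr_full$mean, 24)
  empty <- diag(3)
  pr_empty <- to_prior(empty)
  expect_length(pr_empty$mean, 18)       # no off-diagonal couplings
  expect_false(any(grepl("^A_", names(pr_empty$mean))))
  expect_equal(sum(grepl("^self_", names(pr_empty$mean))), 3)
  one <- diag(3); one[2, 1] <- 1
  pr_one <- to_prior(one)
  expect_equal(sum(grepl("^A_", names(pr_one$mean))), 1)
  expect_true("A_2_1" %in% names(pr_one$mean))
  # defaults propagate
  base <- default_priors(3, overrides = list(A_2_1 = c(0.2, 0.1)))
  pr_inherit <- to_prior(one, defaults = base)
  expect_equal(unname(pr_inherit$mean["A_2_1"]), 0.2)
})

test_that("reduced_space keeps requested members and order", {
  space <- apply_rules(enumerate_full(3), plausibility_rules())
  red <- reduced_space(space, 8, include = 20)
  expect_length(red$models, 8)
  expect_true(any(vapply(red$models, identical, logical(1), space$models[[20]])))
})

test_that("model spaces round-trip through JSON", {
  space <- reduced_space(apply_rules(enumerate_full(3), plausibility_rules()), 8)
  space$labels <- c("SN", "DAN", "DMN")
  path <- file.path(tempdir(), "space.json")
  write_model_space(space, path)
  back <- read_model_space(path)
  expect_identical(back$labels, space$labels)
  expect_identical(back$models, space$models)
})
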