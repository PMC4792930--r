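# Synthetic lifespan cohort: per-subject generative parameters with linear
# age trends, BOLD series synthesized from the model's own cross-spectrum,
# demographics, and cognition with an age-moderated connectivity slope.

#' Cohort configuration
#'
#' Defines the study conditions emulated by the generator: a large adult
#' lifespan cohort (ages approximately uniform between 18 and 88), short
#' resting-state recordings (255 volumes at TR = 1.97 s), a 3-node network,
#' linear age effects on coupling, fluctuation, and hemodynamic parameters,
#' and six cognitive scores driven by a connectivity profile whose slope
#' grows with age (moderation strength lambda).
#'
#' @param n_subjects number of subjects (default 200 for routine runs; the
#'   emulated study has 602).
#' @param age_range c(low, high) in years.
#' @param n_nodes number of network nodes.
#' @param n_volumes retained volumes per recording.
#' @param tr repetition time (s).
#' @param baseline a [spectral_model()] giving every parameter's value at the
#'   age midpoint; default [baseline_model()].
#' @param age_effects named numeric vector of linear slopes per year, keyed
#'   by [param_names()] names; default [default_age_effects()].
#' @param subject_sd named numeric vector of between-subject SDs around the
#'   age trend (recycled over families via [default_subject_sd()]).
#' @param moderation_strength unitless interaction coefficient lambda: the
#'   profile-to-cognition slope is scaled by (1 + lambda * z(age)).
#' @param cognitive_weights length-6 loadings of the connectivity profile on
#'   each cognitive score.
#' @param age_cognition_slopes length-6 direct (standardized) age slopes of
#'   each score.
#' @param noise_sd residual SD per cognitive score (length 1 or 6).
#' @param seed integer root seed.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 200,
                          age_range = c(18, 88),
                          n_nodes = 3,
                          n_volumes = 255,
                          tr = 1.97,
                          baseline = baseline_model(n_nodes),
                          age_effects = default_age_effects(n_nodes),
                          subject_sd = default_subject_sd(n_nodes),
                          moderation_strength = 0.3,
                          cognitive_weights = c(0.5, 0.4, 0.35, 0.3, 0.25, 0.2),
                          age_cognition_slopes = c(-0.45, -0.3, -0.4, -0.25, -0.3, -0.2),
                          noise_sd = 1,
                          seed = 1L) {
  stopifnot(n_subjects >= 2, tr > 0, n_volumes > 16,
            length(age_range) == 2, age_range[1] < age_range[2],
            length(cognitive_weights) == 6, length(age_cognition_slopes) == 6,
            length(noise_sd) %in% c(1L, 6L),
            inherits(baseline, "spectral_model"),
            baseline$coupling$n_nodes == n_nodes)
  nm <- param_names(n_nodes)
  slopes <- stats::setNames(numeric(length(nm)), nm)
  if (length(age_effects)) {
    bad <- setdiff(names(age_effects), nm)
    if (length(bad)) stop("unknown parameter in age_effects: ", paste(bad, collapse = ", "))
    slopes[names(age_effects)] <- age_effects
  }
  sds <- stats::setNames(numeric(length(nm)), nm)
  if (length(subject_sd)) {
    bad <- setdiff(names(subject_sd), nm)
    if (length(bad)) stop("unknown parameter in subject_sd: ", paste(bad, collapse = ", "))
    sds[names(subject_sd)] <- subject_sd
  }
  structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    n_nodes = as.integer(n_nodes), n_volumes = as.integer(n_volumes), tr = tr,
    baseline = baseline, age_effects = slopes, subject_sd = sds,
    moderation_strength = moderation_strength,
    cognitive_weights = cognitive_weights,
    age_cognition_slopes = age_cognition_slopes,
    noise_sd = rep(noise_sd, length.out = 6), seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Baseline generative model at the age midpoint
#'
#' A weakly coupled, comfortably stable network: a few positive and negative
#' off-diagonal couplings well inside the stability margin set by the
#' -0.5 Hz self-decay, near-pink neural fluctuations of unit log-amplitude 0,
#' and hemodynamics at the reference balloon values.
#'
#' @param n_nodes number of nodes (coupling pattern defined for any n; the
#'   default study uses 3).
#' @param constants a [balloon_constants()].
#' @return a [spectral_model()].
#' @export
baseline_model <- function(n_nodes = 3, constants = balloon_constants()) {
  off <- matrix(0, n_nodes, n_nodes)
  # ring of forward excitation with one feedback, scaled to stay stable
  for (i in seq_len(n_nodes - 1)) off[i + 1, i] <- 0.20
  if (n_nodes > 1) off[1, n_nodes] <- -0.15
  spectral_model(
    neural_coupling(off, rep(0, n_nodes)),
    fluctuation_params(rep(0, n_nodes), rep(0.5, n_nodes),
                       noise_amplitude = 0, noise_exponent = 0.5),
    hemodynamic_params(rep(0, n_nodes), rep(0, n_nodes), 0),
    constants
  )
}

#' Default linear age effects (per year)
#'
#' Directions mirror the aging narrative the generator emulates: stronger
#' inhibitory self-connections and slower hemodynamic signal decay with age
#' in every node, an increased fluctuation exponent in node 1, reduced
#' fluctuation amplitude in node 2, and small opposing drifts on two
#' couplings.
#'
#' @param n_nodes number of nodes.
#' @return named numeric vector of slopes, keyed by [param_names()] names.
#' @export
default_age_effects <- function(n_nodes = 3) {
  eff <- c(stats::setNames(rep(0.004, n_nodes), sprintf("self_%d", seq_len(n_nodes))),
           stats::setNames(rep(0.003, n_nodes), sprintf("decay_%d", seq_len(n_nodes))),
           exp_1 = 0.003)
  if (n_nodes >= 2) {
    eff <- c(eff, amp_2 = -0.003, A_2_1 = -0.002)
    eff <- c(eff, stats::setNames(0.002, sprintf("A_1_%d", n_nodes)))
  }
  eff
}

#' Default between-subject SDs around the age trend
#'
#' @param n_nodes number of nodes.
#' @return named numeric vector keyed by [param_names()] names.
#' @export
default_subject_sd <- function(n_nodes = 3) {
  nm <- param_names(n_nodes)
  sd <- stats::setNames(numeric(length(nm)), nm)
  sd[grepl("^A_", nm)] <- 0.08
  sd[grepl("^self_", nm)] <- 0.08
  sd[grepl("^amp_", nm)] <- 0.10
  sd[grepl("^exp_", nm)] <- 0.10
  sd[nm %in% c("noise_amp", "noise_exp")] <- 0.05
  sd[grepl("^(transit|decay)_", nm)] <- 0.08
  sd[nm == "epsilon"] <- 0.05
  sd
}

# z-score of age against the configured uniform age distribution (not the
# realized sample), so the construction is deterministic given the config.
age_zscore <- function(age, config) {
  lo <- config$age_range[1]; hi <- config$age_range[2]
  (age - (lo + hi) / 2) / ((hi - lo) / sqrt(12))
}

#' Draw one subject's generative parameters
#'
#' Every packed parameter has expectation
#' \code{baseline + slope * (age - midpoint)} and between-subject Gaussian
#' scatter. Draws whose coupling eigenvalues come within \code{margin} of
#' instability are rejected and redrawn, up to 100 attempts: resting-state
#' network dynamics decay on the time scale of the self-connections, and
#' near-critical systems (spectral power diverging at the lowest
#' frequencies) are not physiologically representative.
#'
#' @param config a [cohort_config()].
#' @param age subject age in years (within the configured range).
#' @param margin required stability margin: all coupling eigenvalues must
#'   have real part below \code{-margin} (Hz; default 0.125).
#' @return a [spectral_model()] (stable with margin).
#' @export
draw_subject_parameters <- function(config, age, margin = 0.125) {
  stopifnot(inherits(config, "cohort_config"),
            age >= config$age_range[1], age <= config$age_range[2])
  mid <- mean(config$age_range)
  base <- pack_parameters(config$baseline)
  mu <- base + config$age_effects * (age - mid)
  for (attempt in seq_len(100)) {
    theta <- mu + stats::rnorm(length(mu), 0, config$subject_sd)
    model <- unpack_parameters(theta, config$n_nodes,
                               constants = config$baseline$constants)
    ev <- max(Re(eigen(coupling_matrix(model$coupling), only.values = TRUE)$values))
    if (ev < -margin) return(model)
  }
  shift <- abs(config$age_effects * (age - mid))
  worst <- names(shift)[which.max(shift)]
  stop(sprintf(
    "no stable parameter draw in 100 attempts at age %.1f; largest age-driven shift is on '%s'",
    age, worst))
}

#' Simulate a BOLD series from a spectral model
#'
#' Frequency-domain synthesis: independent complex Gaussian Fourier
#' coefficients at each DFT frequency are scaled by a Hermitian matrix
#' square root of the model's predicted cross-spectral density and inverse
#' transformed, so the population cross-spectrum of the output equals
#' [predicted_csd()] exactly (no transient, no discretization error). The
#' zero-frequency and Nyquist coefficients are set to zero (the series is
#' mean-free).
#'
#' @param model a stable [spectral_model()].
#' @param n_volumes number of volumes.
#' @param tr repetition time (s).
#' @param identity_kernel passed to [predicted_csd()].
#' @return a [time_series()].
#' @export
simulate_bold <- function(model, n_volumes, tr, identity_kernel = FALSE) {
  stopifnot(inherits(model, "spectral_model"), n_volumes > 16, tr > 0)
  if (!stability_check(model$coupling)) stop("unstable model")
  n <- model$coupling$n_nodes
  N <- as.integer(n_volumes)
  m <- (N - 1) %/% 2                     # strictly positive, non-Nyquist bins
  f <- (seq_len(m)) / (N * tr)
  csd <- predicted_csd(model, f, identity_kernel = identity_kernel)
  Xf <- matrix(0+0i, nrow = N, ncol = n)
  for (k in seq_len(m)) {
    S <- csd$matrices[[k]]
    ed <- eigen(S, symmetric = TRUE)
    lam <- pmax(ed$values, 0)
    L <- ed$vectors %*% (sqrt(lam) * Conj(t(ed$vectors)))
    z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
    Xf[k + 1, ] <- sqrt(N / tr) * (L %*% z)
  }
  Xf[N + 1 - seq_len(m), ] <- Conj(Xf[seq_len(m) + 1, ])
  x <- Re(stats::mvfft(Xf, inverse = TRUE)) / N
  time_series(x, tr = tr)
}

#' Generate cognitive scores from a connectivity profile
#'
#' Each score k is
#' \deqn{y_k = w_k \, p \, (1 + \lambda z(a)) + \beta_k z(a) + e_k}
#' where p is the subject's connectivity profile, z(a) the standardized age,
#' lambda the moderation strength, and e_k Gaussian noise — so the
#' profile-to-cognition slope strengthens linearly with age when lambda > 0.
#'
#' @param connectivity_profile numeric vector, one value per subject.
#' @param age ages in years, same length.
#' @param config a [cohort_config()] (supplies lambda, weights, age slopes,
#'   noise SDs, and the age standardization).
#' @return numeric matrix, subjects x 6 scores, columns \code{cog1..cog6}.
#' @export
generate_cognition <- function(connectivity_profile, age, config) {
  stopifnot(length(connectivity_profile) == length(age))
  za <- age_zscore(age, config)
  lam <- config$moderation_strength
  w <- config$cognitive_weights
  b <- config$age_cognition_slopes
  s <- config$noise_sd
  Y <- sapply(1:6, function(k) {
    w[k] * connectivity_profile * (1 + lam * za) + b[k] * za +
      stats::rnorm(length(age), 0, s[k])
  })
  Y <- matrix(Y, ncol = 6)
  colnames(Y) <- paste0("cog", 1:6)
  Y
}

# Connectivity profile carried into cognition: mean self-inhibition
# log-scaling, standardized across the cohort and negated (stronger
# self-inhibition -> lower profile -> lower scores for positive weights).
cohort_profile <- function(true_thetas, n_nodes) {
  selfs <- true_thetas[, sprintf("self_%d", seq_len(n_nodes)), drop = FALSE]
  p <- -rowMeans(selfs)
  as.numeric(scale(p))
}

#' Simulate a full synthetic cohort
#'
#' Draws ages (uniform over the configured range), demographics, per-subject
#' generative parameters with age trends, BOLD time series, and cognition.
#' Fully determined by \code{config$seed} unless \code{seed} is given.
#'
#' @param config a [cohort_config()].
#' @param seed optional integer overriding \code{config$seed}.
#' @param simulate_series if FALSE, skip BOLD synthesis (parameters and
#'   cognition only; much faster for statistical calibration work).
#' @return object of class \code{synthetic_cohort}: list with
#'   \code{config}, \code{subjects} (data.frame of id, age, covariates and
#'   cog1..cog6), \code{true_params} (list of [spectral_model()]),
#'   \code{true_theta} (subjects x parameters matrix), \code{profile}, and
#'   \code{series} (list of [time_series()] or NULL).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL,
                            simulate_series = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(as.integer(seed))
  ns <- config$n_subjects
  age <- stats::runif(ns, config$age_range[1], config$age_range[2])
  gender <- stats::rbinom(ns, 1, 0.5)
  handedness <- pmax(-100, pmin(100, stats::rnorm(ns, 70, 40)))
  education <- sample.int(5, ns, replace = TRUE)
  # head motion gets a small positive age slope; everything else independent
  head_motion <- 0.08 + 0.0012 * (age - config$age_range[1]) +
    abs(stats::rnorm(ns, 0, 0.03))
  models <- vector("list", ns)
  for (s in seq_len(ns)) models[[s]] <- draw_subject_parameters(config, age[s])
  theta <- t(vapply(models, pack_parameters, pack_parameters(config$baseline)))
  profile <- cohort_profile(theta, config$n_nodes)
  cog <- generate_cognition(profile, age, config)
  series <- NULL
  if (simulate_series) {
    series <- lapply(models, simulate_bold, n_volumes = config$n_volumes,
                     tr = config$tr)
  }
  subjects <- data.frame(
    id = sprintf("sub%04d", seq_len(ns)), age = age, gender = gender,
    handedness = handedness, education = education, head_motion = head_motion,
    stringsAsFactors = FALSE
  )
  subjects <- cbind(subjects, as.data.frame(cog))
  structure(list(config = config, subjects = subjects, true_params = models,
                 true_theta = theta, profile = profile, series = series),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d nodes, %d volumes at TR %g s, ages %.0f-%.0f\n",
              x$config$n_subjects, x$config$n_nodes, x$config$n_volumes,
              x$config$tr, min(x$subjects$age), max(x$subjects$age)))
  invisible(x)
}

#' Write / read a synthetic cohort as plain text
#'
#' One tab-delimited time-series file per subject, a covariate/cognition
#' table, a JSON file of true packed parameters, and a YAML snapshot of the
#' scalar configuration.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return \code{write_cohort} returns \code{dir} invisibly;
#'   \code{read_cohort_table} reads back the covariate table.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  th <- cohort$true_theta
  jsonlite::write_json(
    stats::setNames(lapply(seq_len(nrow(th)), function(i) as.list(th[i, ])),
                    cohort$subjects$id),
    file.path(dir, "true_parameters.json"), auto_unbox = TRUE, digits = NA)
  cfg <- cohort$config
  yaml::write_yaml(list(
    n_subjects = cfg$n_subjects, age_range = cfg$age_range,
    n_nodes = cfg$n_nodes, n_volumes = cfg$n_volumes, tr = cfg$tr,
    moderation_strength = cfg$moderation_strength, seed = cfg$seed
  ), file.path(dir, "config.yaml"))
  if (!is.null(cohort$series)) {
    for (s in seq_along(cohort$series)) {
      write_time_series(cohort$series[[s]],
                        file.path(dir, paste0(cohort$subjects$id[s], "_bold.tsv")))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort_table <- function(dir) {
  utils::read.table(file.path(dir, "subjects.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Draw a subject whose couplings respect a binary model specification
#'
#' Like [draw_subject_parameters()], but the off-diagonal couplings are
#' generated from a binary adjacency: present edges get
#' \code{edge_strength} plus the configured between-subject scatter, absent
#' edges are exact zeros. Used by model-recovery simulations, where data
#' must be generated from a specific member of a model space.
#'
#' @param config a [cohort_config()].
#' @param age subject age (years).
#' @param adjacency binary n x n matrix (diagonal ignored; self-connections
#'   always present).
#' @param edge_strength mean coupling (Hz) on present edges.
#' @param margin stability margin as in [draw_subject_parameters()].
#' @return a [spectral_model()] whose absent couplings are exactly zero.
#' @export
draw_subject_from_model <- function(config, age, adjacency,
                                    edge_strength = 0.2, margin = 0.125) {
  n <- config$n_nodes
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  sdA <- config$subject_sd[grep("^A_", names(config$subject_sd))[1]]
  if (is.na(sdA)) sdA <- 0
  for (attempt in seq_len(100)) {
    m <- draw_subject_parameters(config, age, margin = margin)
    off <- matrix(0, n, n)
    present <- adjacency == 1 & row(off) != col(off)
    off[present] <- edge_strength + stats::rnorm(sum(present), 0, sdA)
    m$coupling$offdiag <- off
    ev <- max(Re(eigen(coupling_matrix(m$coupling), only.values = TRUE)$values))
    if (ev < -margin) return(m)
  }
  stop("no stable draw for the requested model specification in 100 attempts")
}
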