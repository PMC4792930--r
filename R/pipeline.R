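# Orchestration helpers: a validated run configuration, named seed
# substreams, and the stage drivers used by the analysis scripts. Each
# stage is an ordinary function of (config, upstream outputs); the numbered
# scripts under analysis/ are thin narrative wrappers around these.

#' Derive a named substream seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; each stage
#' draws from its own substream so stages stay reproducible independently
#' of execution order. The derived seed is a deterministic 31-bit hash of
#' the root seed and the stage name.
#'
#' @param root_seed integer root seed.
#' @param name stage name (character).
#' @return integer seed in [1, 2^31 - 2].
#' @export
substream_seed <- function(root_seed, name) {
  h <- as.double(root_seed) %% 2147483647
  for (ch in utf8ToInt(name)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h + 1)
}

#' Run configuration for the pipeline
#'
#' Bundles the cohort configuration with the analysis settings (frequency
#' band, MAR order, prior overrides, BMS method, permutation count, output
#' directory) and validates them up front.
#'
#' @param cohort a [cohort_config()].
#' @param mar_order MAR order for spectral estimation.
#' @param f_max upper band edge (Hz).
#' @param n_freq frequency-grid size.
#' @param prior_overrides named list passed to [default_priors()].
#' @param bms_method "random" (default) or "fixed".
#' @param n_perm CCA permutation count.
#' @param out_dir output directory for stage artifacts.
#' @param seed root seed (defaults to the cohort's).
#' @return object of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_config(), mar_order = 8, f_max = 0.1,
                       n_freq = 32, prior_overrides = NULL,
                       bms_method = c("random", "fixed"), n_perm = 1000,
                       out_dir = "results", seed = NULL) {
  bms_method <- match.arg(bms_method)
  stopifnot(inherits(cohort, "cohort_config"), mar_order >= 1, f_max > 0,
            n_freq >= 4, n_perm >= 100)
  if (is.null(seed)) seed <- cohort$seed
  if (1 / (cohort$n_volumes * cohort$tr) >= f_max) {
    stop("recording too short for the requested frequency band")
  }
  structure(list(cohort = cohort, mar_order = mar_order, f_max = f_max,
                 n_freq = n_freq, prior_overrides = prior_overrides,
                 bms_method = bms_method, n_perm = n_perm,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return \code{write_run_config} returns \code{path} invisibly;
#'   \code{read_run_config} a [run_config()] (non-scalar cohort fields such
#'   as the baseline model are rebuilt from package defaults).
#' @export
write_run_config <- function(config, path) {
  ch <- config$cohort
  yaml::write_yaml(list(
    cohort = list(n_subjects = ch$n_subjects, age_range = ch$age_range,
                  n_nodes = ch$n_nodes, n_volumes = ch$n_volumes, tr = ch$tr,
                  moderation_strength = ch$moderation_strength,
                  noise_sd = ch$noise_sd, seed = ch$seed),
    mar_order = config$mar_order, f_max = config$f_max,
    n_freq = config$n_freq, bms_method = config$bms_method,
    n_perm = config$n_perm, out_dir = config$out_dir, seed = config$seed
  ), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ch <- do.call(cohort_config, y$cohort)
  run_config(cohort = ch, mar_order = y$mar_order, f_max = y$f_max,
             n_freq = y$n_freq, bms_method = y$bms_method, n_perm = y$n_perm,
             out_dir = y$out_dir, seed = y$seed)
}

#' Frequency grid implied by a run configuration
#' @param config a [run_config()].
#' @return frequencies in Hz.
#' @export
config_freqs <- function(config) {
  default_freqs(config$cohort$n_volumes, config$cohort$tr,
                n_freq = config$n_freq, f_max = config$f_max)
}

#' Fit every model of a space to every subject
#'
#' Estimates each subject's empirical cross-spectrum (MAR), inverts every
#' model of the space against it, and collects fits, free energies, and
#' diagnostics. Subjects whose fit explains less than \code{ve_floor} of
#' the spectral variance are flagged for exclusion from group statistics
#' (they are retained in the output).
#'
#' @param series list of [time_series()] (one per subject).
#' @param space a \code{model_space} (or a list of adjacency matrices).
#' @param config a [run_config()].
#' @param ve_floor variance-explained exclusion floor (default 0.1).
#' @param progress print a line per subject.
#' @return list: \code{fits} (subjects x models nested list),
#'   \code{evidence} ([evidence_table()]), \code{variance_explained}
#'   (subjects x models), \code{keep} (logical per subject),
#'   \code{csd} (list of observed spectra).
#' @export
fit_cohort <- function(series, space, config, ve_floor = 0.1,
                       progress = FALSE) {
  models <- if (inherits(space, "model_space")) space$models else space
  freqs <- config_freqs(config)
  ns <- length(series)
  nm <- length(models)
  fits <- vector("list", ns)
  Fe <- matrix(NA_real_, ns, nm)
  VE <- matrix(NA_real_, ns, nm)
  csds <- vector("list", ns)
  for (s in seq_len(ns)) {
    csd <- estimate_csd(series[[s]], order = config$mar_order, freqs = freqs)
    csds[[s]] <- csd
    fits[[s]] <- vector("list", nm)
    for (m in seq_len(nm)) {
      pr <- to_prior(models[[m]], overrides = config$prior_overrides)
      fit <- invert(csd, pr)
      fits[[s]][[m]] <- fit
      Fe[s, m] <- fit$free_energy
      VE[s, m] <- fit$variance_explained
    }
    if (progress) message(sprintf("subject %d/%d: best F %.1f, best VE %.2f",
                                  s, ns, max(Fe[s, ]), max(VE[s, ])))
  }
  keep <- apply(VE, 1, max) >= ve_floor
  if (!all(keep)) message(sprintf("%d subject(s) below the variance-explained floor", sum(!keep)))
  list(fits = fits, evidence = evidence_table(Fe), variance_explained = VE,
       keep = keep, csd = csds)
}

#' One-line stage log entry
#'
#' @param path log file.
#' @param stage stage name.
#' @param seconds elapsed time.
#' @param ... named scalars echoed into the entry.
#' @return invisibly, the written line.
#' @export
log_stage <- function(path, stage, seconds, ...) {
  extras <- list(...)
  kv <- if (length(extras)) {
    paste(sprintf("%s=%s", names(extras), vapply(extras, format, "")),
          collapse = " ")
  } else ""
  line <- sprintf("[%s] stage=%s elapsed=%.1fs %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, seconds, kv)
  cat(line, "\n", file = path, append = TRUE)
  invisible(line)
}

#' Parameter-recovery simulation
#'
#' Draws subjects from the generator, simulates recordings, estimates
#' cross-spectra, inverts the full model, and correlates true with
#' estimated off-diagonal couplings per replicate.
#'
#' @param config a [cohort_config()].
#' @param n_replicates number of subjects/replicates.
#' @param n_volumes recording length (default: the config's).
#' @param seed integer seed.
#' @param n_freq frequency-grid size for estimation and inversion.
#' @return data.frame: replicate, correlation (true vs posterior-mean
#'   off-diagonal couplings), mae (their mean absolute error),
#'   variance_explained, monotone (accepted-step free energy
#'   non-decreasing).
#' @export
parameter_recovery <- function(config = cohort_config(), n_replicates = 20,
                               n_volumes = NULL, seed = 1, n_freq = 32) {
  if (is.null(n_volumes)) n_volumes <- config$n_volumes
  set.seed(as.integer(seed))
  freqs <- default_freqs(config$n_volumes, config$tr, n_freq = n_freq)
  pr <- default_priors(config$n_nodes)
  out <- lapply(seq_len(n_replicates), function(r) {
    m <- draw_subject_parameters(config, stats::runif(1, config$age_range[1],
                                                      config$age_range[2]))
    ts <- simulate_bold(m, n_volumes, config$tr)
    fit <- invert(estimate_csd(ts, freqs = freqs), pr)
    true <- pack_parameters(m)
    offn <- grep("^A_", names(true))
    data.frame(replicate = r,
               correlation = stats::cor(true[offn], fit$mean[offn]),
               mae = mean(abs(true[offn] - fit$mean[offn])),
               variance_explained = fit$variance_explained,
               monotone = all(diff(fit$F_trace) >= 0))
  })
  do.call(rbind, out)
}

#' Model-recovery simulation (confusion design)
#'
#' Each replicate draws a generating model from the space, simulates a
#' group of subjects from it, fits every model of the space to every
#' subject, runs random-effects BMS, and records whether the generating
#' model attains the top exceedance probability.
#'
#' @param space a \code{model_space} (typically a [reduced_space()] of the
#'   plausibility-filtered set).
#' @param config a [cohort_config()].
#' @param n_subjects subjects per replicate.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @param edge_strength mean coupling on present edges.
#' @param n_samples Monte-Carlo draws for exceedance probabilities.
#' @param n_freq frequency-grid size.
#' @return data.frame: replicate, generator, winner, winner_xp,
#'   generator_xp, recovered.
#' @export
model_recovery <- function(space, config = cohort_config(), n_subjects = 20,
                           n_replicates = 10, seed = 1, edge_strength = 0.2,
                           n_samples = 1e5, n_freq = 32) {
  models <- space$models
  K <- length(models)
  freqs <- default_freqs(config$n_volumes, config$tr, n_freq = n_freq)
  out <- lapply(seq_len(n_replicates), function(r) {
    set.seed(as.integer(seed) + r)
    gi <- sample.int(K, 1)
    Fe <- matrix(NA_real_, n_subjects, K)
    for (s in seq_len(n_subjects)) {
      m <- draw_subject_from_model(config,
                                   stats::runif(1, config$age_range[1],
                                                config$age_range[2]),
                                   models[[gi]], edge_strength)
      ts <- simulate_bold(m, config$n_volumes, config$tr)
      csd <- estimate_csd(ts, freqs = freqs)
      for (k in seq_len(K)) {
        Fe[s, k] <- invert(csd, to_prior(models[[k]]))$free_energy
      }
    }
    bms <- random_effects_bms(evidence_table(Fe), n_samples = n_samples)
    w <- which.max(bms$exceedance_probs)
    data.frame(replicate = r, generator = gi, winner = w,
               winner_xp = max(bms$exceedance_probs),
               generator_xp = bms$exceedance_probs[gi],
               recovered = w == gi)
  })
  do.call(rbind, out)
}
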