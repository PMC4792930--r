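#!/usr/bin/env Rscript
# Stage 5 — relate model-averaged connectivity parameters to age and
# cognition: multiple regression of age on the coupling parameters, CCA of
# parameters against the six cognitive scores with structure correlations
# and permutation inference, and the moderation analysis testing whether
# the connectivity-cognition relationship strengthens with age. FDR
# correction is applied across the multivariate analyses of this stage and
# the FC baseline (stage 6 reads the p-value ledger and completes it).

library(specdcm)

root_seed <- 2026L
tab <- read_cohort_table("results/cohort")
bma_tab <- utils::read.table("results/cohort_with_bma.tsv", sep = "\t",
                             header = TRUE, check.names = FALSE)

params <- as.matrix(bma_tab[, grep("^(A_|self_)", colnames(bma_tab))])
cog <- as.matrix(tab[, paste0("cog", 1:6)])
covars <- tab[, c("gender", "handedness", "education", "head_motion")]

t0 <- Sys.time()
set.seed(substream_seed(root_seed, "stats"))
gs <- run_group_stats(params, cog, tab$age, covars, n_perm = 1000, label = "EC")
write_group_stats(gs, "results")

cat(sprintf("EC age regression: R = %.3f (p = %.2g)\n",
            gs$age_regression$R, gs$age_regression$p_value))
sig_terms <- gs$age_regression$coefficients$term[gs$age_regression$coefficients$significant]
cat(sprintf("  significant age predictors: %s\n",
            if (length(sig_terms)) paste(sig_terms, collapse = ", ") else "none"))
cat(sprintf("EC-cognition CCA: r = %.3f (permutation p = %.4g; Bartlett p = %.4g)\n",
            gs$cca$correlations[1], gs$cca_significance$p_perm,
            gs$cca_significance$p_bartlett))
mo <- gs$moderation$coefficients
cat(sprintf("moderation (age x connectivity profile): beta = %.3f, p = %.3g\n",
            mo$estimate[mo$term == "interaction"], mo$p[mo$term == "interaction"]))

# p-value ledger for the FDR correction across multivariate analyses
pv <- data.frame(
  analysis = c("EC_age_regression", "EC_cca", "EC_moderation_interaction"),
  p = c(gs$age_regression$p_value, gs$cca_significance$p_perm,
        mo$p[mo$term == "interaction"])
)
utils::write.table(pv, "results/multivariate_pvalues.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
log_stage("results/pipeline.log", "stats",
          as.numeric(difftime(Sys.time(), t0, units = "secs")),
          age_R = round(gs$age_regression$R, 3),
          cca_r = round(gs$cca$correlations[1], 3))
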