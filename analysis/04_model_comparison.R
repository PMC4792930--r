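#!/usr/bin/env Rscript
# Stage 4 — Bayesian model selection and parameter averaging.
#
# Random-effects BMS over the evidence table (variational Dirichlet over
# model frequencies; exceedance probabilities by Monte-Carlo), then
# Bayesian model averaging of each subject's posteriors weighted by the
# subject's model probabilities. Averaged parameters join the cohort table
# for the group statistics.

library(specdcm)

root_seed <- 2026L
fits <- readRDS("scratch/fits.rds")
subjects <- read_cohort_table("results/cohort")

t0 <- Sys.time()
set.seed(substream_seed(root_seed, "bms"))
bms <- random_effects_bms(fits$evidence)
print(bms)
write_comparison(bms, "results/bms_random_effects.tsv")
ffx <- fixed_effects_bms(fits$evidence)
write_comparison(ffx, "results/bms_fixed_effects.tsv")

probs <- subject_model_probs(fits$evidence)
avg <- bma(fits$fits, probs)
out <- cbind(subjects, as.data.frame(avg$mean))
utils::write.table(out, "results/cohort_with_bma.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

log_stage("results/pipeline.log", "bms",
          as.numeric(difftime(Sys.time(), t0, units = "secs")),
          method = bms$method,
          top_model = names(which.max(bms$exceedance_probs)),
          top_xp = round(max(bms$exceedance_probs), 3))
cat(sprintf("top model by exceedance probability: %s (xp = %.3f)\n",
            names(which.max(bms$exceedance_probs)), max(bms$exceedance_probs)))
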