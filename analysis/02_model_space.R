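#!/usr/bin/env Rscript
# Stage 2 — enumerate the candidate model spaces.
#
# Between-network space: all 2^(3x3) = 512 binary coupling patterns over
# {SN, DAN, DMN}, pruned to the biologically plausible connected set by
# requiring every node's self-connection and no isolated node — 54 models.
# A laterality-aware within-network example (dACC, lAI, rAI) shows the
# sagittal-symmetry and homotopic rules; its count is logged, not asserted.

library(specdcm)

dir.create("results", showWarnings = FALSE)
t0 <- Sys.time()

between <- enumerate_full(3, labels = c("SN", "DAN", "DMN"))
plausible <- apply_rules(between, plausibility_rules())
cat(sprintf("between-network: %d full models -> %d plausible connected\n",
            length(between$models), length(plausible$models)))
write_model_space(plausible, "results/model_space_between.json")

sn <- enumerate_full(3, labels = c("dACC", "lAI", "rAI"))
sn_rules <- plausibility_rules(sagittal_symmetry = TRUE,
                               bilateral_homotopic_only = list(c("lAI", "rAI")))
sn_space <- apply_rules(sn, sn_rules)
cat(sprintf("within-SN with laterality rules: %d models (logged, not asserted)\n",
            length(sn_space$models)))

# a deterministic 8-model subset of the plausible set for the fast pipeline
red <- reduced_space(plausible, 8)
write_model_space(red, "results/model_space_reduced.json")
cat(sprintf("reduced pipeline space: %d models\n", length(red$models)))

log_stage("results/pipeline.log", "enumerate",
          as.numeric(difftime(Sys.time(), t0, units = "secs")),
          full = length(between$models), plausible = length(plausible$models),
          reduced = length(red$models))
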