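#!/usr/bin/env Rscript
# Generate the two synthetic scenario bundles the downstream analyses use:
# a "coupled" world in which rearrangement/indel intensity tracks the branch
# substitution-rate multipliers (coupling = 1), and a "decoupled" null world
# (coupling = 0). Everything is written under results/synthetic/.

suppressPackageStartupMessages(library(plastorate))

seed <- 2024L
for (coupling in c(1, 0)) {
  cfg <- simulation_config(seed = seed + coupling, coupling = coupling)
  dir <- file.path("results", "synthetic",
                   ifelse(coupling == 1, "coupled", "null"))
  b <- make_scenario(cfg, out_dir = dir)
  message(sprintf(
    "scenario coupling=%g: %d taxa, %d-codon alignment, reversals per taxon %d-%d, indels %d-%d -> %s",
    coupling, length(b$tree$tip.label), alignment_length(b$aln) / 3,
    min(b$truth$n_reversals), max(b$truth$n_reversals),
    min(b$truth$n_indels), max(b$truth$n_indels), dir))
}
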