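#!/usr/bin/env Rscript
# Gene-order analyses on the published 40-plastome signed LCB table: group
# taxa with identical order and compute the exact pairwise inversion-distance
# matrix. Outputs under results/rearrangement/.

suppressPackageStartupMessages(library(plastorate))

perms <- parse_lcb_table(system.file("extdata", "lcb_diatom40.tsv",
                                     package = "plastorate"))
dir.create("results/rearrangement", recursive = TRUE, showWarnings = FALSE)

g <- identical_order_groups(perms)
shared <- Filter(function(x) length(x) >= 2, g$groups)
message(sprintf("%d taxa share their gene order with at least one other taxon (%d groups):",
                g$n_shared, length(shared)))
for (grp in shared) message("  - ", paste(grp, collapse = ", "))

D <- pairwise_iv_matrix(perms)
write_iv_matrix(D, "results/rearrangement/iv_matrix.tsv")
up <- D[upper.tri(D)]
message(sprintf("inversion distances: range %d-%d, median %.0f; %d identical pairs",
                min(up), max(up), median(up), sum(up == 0)))
imax <- which(D == max(D), arr.ind = TRUE)[1, ]
message(sprintf("most rearranged pair: %s vs %s (d = %d)",
                rownames(D)[imax[1]], colnames(D)[imax[2]], max(D)))
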