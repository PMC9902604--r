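#!/usr/bin/env Rscript
# Stage 1: generate the two-species synthetic study system.
#
# Species B is derived from species A by one 20 kb deletion and one 30 kb
# insertion per chromosome (described exactly by the emitted chain files).
# CTCF motifs are planted at every loop anchor and TAD border; 30% of
# anchor sites sit inside a TE with full-motif overlap, 50% of loops and
# TAD boundaries are shared between the species, 40% of loops carry
# enhancer-promoter chromatin and one lineage-specific TE-derived loop is
# engineered to satisfy every CRISPR candidate filter.

suppressPackageStartupMessages(library(teloop))

seed <- 1
out <- "results/synthetic"
ds <- generate_synthetic_dataset(sim_config(seed = seed))
write_synthetic_dataset(ds, out)

cat("wrote", length(list.files(out, recursive = TRUE)), "files to", out, "\n")
cat(sprintf("species A: %d loops, %d TADs, %d TEs\n",
            nrow(ds$loops$A), nrow(ds$tads$A), nrow(ds$repeats$A)))
cat(sprintf("planted: %.0f%% RE-derived anchors, %.0f%% conserved loops, %.0f%% E-P loops\n",
            100 * mean(ds$sites$A$origin_truth[ds$sites$A$role == "loop_anchor"] == "RE_derived"),
            100 * mean(ds$truth$loops$A$orthology_truth == "conserved"),
            100 * mean(ds$truth$loops$A$function_truth == "enhancer_promoter")))
cat("engineered candidate loop:", ds$candidate_loop_id, "\n")
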