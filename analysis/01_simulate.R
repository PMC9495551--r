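#!/usr/bin/env Rscript
# Stage 1: generate the synthetic paired tumor/normal study.
#
# Emulates the structure of a paired-design RNA-Seq/miRNA-Seq cohort:
# 100 tumor/normal pairs; negative-binomial counts for 600 mRNAs,
# 150 lncRNAs and 80 miRNAs; 100/60/30 planted DE features per class at
# |log2FC| = 2; 10 planted ceRNA modules (one miRNA, one lncRNA, five
# mRNAs each -> 50 triplets) coupled at Pearson strength 0.7; a planted
# interaction clique per module plus background edges; validated-target
# tables with decoy pairs. Everything downstream reads these files.

library(cernaMod)

seed <- 42L
out <- "results/data"

cfg <- sim_config(seed = seed)
ds <- generate_dataset(cfg)
write_dataset(ds, out)

cat("wrote", out, "\n")
cat("samples:", nrow(ds$metadata), " (", cfg$n_pairs, "pairs )\n")
cat("features:", paste(names(ds$counts),
                       vapply(ds$counts, nrow, 1L), collapse = ", "), "\n")
cat("planted DE:", nrow(ds$truth$de_features),
    "| planted triplets:", nrow(ds$truth$triplets),
    "| planted modules:", length(ds$truth$modules), "\n")
cat("interaction edges:", nrow(ds$edges),
    "(", nrow(ds$truth$graph_edges), "planted )\n")
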