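#!/usr/bin/env Rscript
# Stage 5: ceRNA triplet screen, ceRNA classifier, and regulatory modules.
#
# Triplets (mRNA, miRNA, lncRNA) are kept when both pairs appear in the
# validated-target tables and the correlations show the ceRNA pattern
# (miRNA negative with both partners, partners positive, all p < 0.05).
# A second classifier (hidden 400/100/40, no normalization layers) is
# trained on the ceRNA-network nodes; RNAs with contribution > 1e-4 are
# the potential ceRNAs, and each miRNA's same-direction targets form a
# regulatory module. Recovery is scored against the planted truth.

library(cernaMod)

seed <- 42L
ds <- read_dataset("results/data")
de <- utils::read.delim("results/de_table.tsv")
candidates <- utils::read.delim("results/candidates.tsv")$feature_id
expr <- do.call(rbind, lapply(c("mrna", "lncrna", "mirna"), function(cls) {
  read_expression(sprintf("results/logcpm_%s.tsv", cls))
}))

triplets <- screen_triplets(expr, de, ds$targets_mrna, ds$targets_lncrna,
                            candidates, p_threshold = 0.05)
write_tsv(triplets, "results/triplets.tsv")
rec <- triplet_recovery(triplets, ds$truth)
cat(sprintf("triplets: %d screened, recall %.2f, precision %.2f\n",
            nrow(triplets), rec$recall, rec$precision))

graph <- list(edges = utils::read.delim("results/interaction_edges.tsv"),
              nodes = unique(unlist(
                utils::read.delim("results/interaction_edges.tsv")[1:2])))
class(graph) <- "interaction_graph"
network <- build_cerna_network(triplets, graph, de)
cat("ceRNA network:", nrow(network$nodes), "nodes,",
    nrow(network$edges), "edges\n")

X <- t(expr[network$nodes$id, , drop = FALSE])
y <- as.numeric(ds$metadata$condition[
  match(rownames(X), ds$metadata$sample_id)] == "tumor")
spec <- model_spec(ncol(X), c(400L, 100L, 40L), use_regularization = FALSE)
cfg <- train_config(epochs = 200L, seed = seed, n_repeats = 50L)
fit <- train_repeats(spec, X, y, cfg)
cat(sprintf("ceRNA model: val acc %.3f (mean over 50 splits %.3f)\n",
            fit$repeats$val_acc[1], mean(fit$repeats$val_acc)))
write_tsv(fit$history, "results/training_curves_cerna.tsv")

bg <- X[head(fit$split$train, 100), , drop = FALSE]
contrib <- compute_attributions(fit$model, X, background = bg)
write_tsv(contrib$table, "results/contributions_cerna.tsv")

subnet <- select_potential_cernas(contrib, network, threshold = 1e-4)
write_tsv(subnet$nodes, "results/potential_cernas.tsv")
cls_count <- table(subnet$nodes$class)
cat("potential ceRNAs:", paste(names(cls_count), cls_count, collapse = ", "),
    "\n")

modules <- extract_modules(subnet, de)
cernaMod:::modules_to_json(modules, "results/modules.json")
mrec <- module_recovery(modules, ds$truth)
cat(sprintf(
  "modules: %d extracted; planted miRNAs recovered: %s; mean Jaccard %.2f\n",
  length(modules), mrec$all_mirnas_found, mrec$mean_jaccard))
for (m in head(modules, 3)) {
  cat(sprintf("  %s (%s): %d mRNAs, %d lncRNAs\n", m$mirna_id, m$direction,
              length(m$mrna_ids), length(m$lncrna_ids)))
}
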