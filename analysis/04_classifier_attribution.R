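#!/usr/bin/env Rscript
# Stage 4: the mRNA classifier and its feature attributions.
#
# A fully connected net (hidden layers 400 and 100, batch-normalization
# after each, sigmoid output) is trained to separate tumor from normal on
# the network mRNAs' log-CPM, with Adam (lr 1e-4), binary cross-entropy,
# batch size 16, stratified 70/30 splits repeated 50 times. Contribution
# scores are the mean |attribution| per feature; zero-contribution mRNAs
# are pruned and the model relearned. Candidate mRNAs are those with
# MCC > 8 and contribution > 1e-4.

library(cernaMod)

seed <- 42L
ds <- read_dataset("results/data")
logcpm <- read_expression("results/logcpm_mrna.tsv")
cent_tab <- utils::read.delim("results/centrality.tsv")
centrality <- stats::setNames(cent_tab$mcc, cent_tab$node)

X <- t(logcpm[cent_tab$node, , drop = FALSE])
y <- as.numeric(ds$metadata$condition[
  match(rownames(X), ds$metadata$sample_id)] == "tumor")

spec <- model_spec(ncol(X), c(400L, 100L), use_regularization = TRUE)
cfg <- train_config(epochs = 200L, seed = seed, n_repeats = 50L)
fit <- train_repeats(spec, X, y, cfg)
cat(sprintf("designated model: train acc %.3f, val acc %.3f\n",
            fit$repeats$train_acc[1], fit$repeats$val_acc[1]))
cat(sprintf("across 50 splits: mean val acc %.3f (sd %.3f)\n",
            mean(fit$repeats$val_acc), sd(fit$repeats$val_acc)))
write_tsv(fit$history, "results/training_curves_mrna.tsv")

bg <- X[head(fit$split$train, 100), , drop = FALSE]
contrib <- compute_attributions(fit$model, X, background = bg)
pruned <- prune_and_retrain(spec, X, y, contrib, cfg)
cat("zero-contribution mRNAs pruned:", pruned$n_pruned, "\n")
write_tsv(pruned$contributions$table, "results/contributions_mrna.tsv")

candidates <- select_candidate_mrnas(pruned$contributions, centrality,
                                     shap_threshold = 1e-4,
                                     mcc_threshold = 8)
write_tsv(data.frame(feature_id = candidates), "results/candidates.tsv")
cat("candidate mRNAs (MCC > 8 and contribution > 1e-4):",
    length(candidates), "\n")
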