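#!/usr/bin/env Rscript
# Stage 6: ROC/AUC comparison of the neural model against six conventional
# classifiers (KNN, SVM, decision tree, naive Bayes, logistic regression,
# random forest) on the module members' expression, same split protocol.

library(cernaMod)

seed <- 42L
ds <- read_dataset("results/data")
modules <- jsonlite::read_json("results/modules.json",
                               simplifyVector = FALSE)
expr <- do.call(rbind, lapply(c("mrna", "lncrna", "mirna"), function(cls) {
  read_expression(sprintf("results/logcpm_%s.tsv", cls))
}))

feats <- unique(unlist(lapply(modules, function(m) {
  c(m$mirna_id, unlist(m$mrna_ids), unlist(m$lncrna_ids))
})))
X <- t(expr[feats, , drop = FALSE])
y <- as.numeric(ds$metadata$condition[
  match(rownames(X), ds$metadata$sample_id)] == "tumor")
cat("features from modules:", length(feats), "\n")

base <- baseline_classifiers(X, y, seed = seed)

spec <- model_spec(ncol(X), c(400L, 100L, 40L), use_regularization = FALSE)
cfg <- train_config(epochs = 200L, seed = seed, n_repeats = 1L)
fit <- train_repeats(spec, X, y, cfg)
dnn_auc <- evaluate_roc(fit$model, X[fit$split$val, , drop = FALSE],
                        y[fit$split$val])$auc

tab <- rbind(data.frame(method = "dnn", auc = dnn_auc), base)
write_tsv(tab, "results/classifier_auc.tsv")
print(tab)
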