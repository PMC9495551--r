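# ROC/AUC evaluation and the panel of conventional classifiers the neural
# model is compared against (KNN, SVM, decision tree, naive Bayes, logistic
# regression, random forest), all at default hyperparameters under the same
# split protocol.

#' ROC curve and AUC from scores
#'
#' Sweeps every distinct score as a cut-off, collecting (false positive
#' rate, true positive rate) points, and integrates by the trapezoid rule —
#' equivalent to the normalized Mann-Whitney U statistic with ties counted
#' half.
#'
#' @param scores Numeric classifier scores (larger = more class-1).
#' @param labels 0/1 labels, both classes present.
#' @return List: `roc` (data.frame fpr, tpr ordered along the sweep),
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    stop("ROC is undefined with a single class")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # one point per distinct threshold
  last <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  tpr <- c(0, tp / sum(labels))
  fpr <- c(0, fp / sum(1 - labels))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a trained model by ROC/AUC
#'
#' @param model `mlp_model` (or any function mapping `X` to scores).
#' @param X Sample x feature matrix.
#' @param y 0/1 labels.
#' @return As [roc_auc()].
#' @export
evaluate_roc <- function(model, X, y) {
  scores <- if (is.function(model)) model(X) else predict_prob(model, X)
  roc_auc(scores, y)
}

#' AUCs of six conventional classifiers
#'
#' Trains KNN (k = 5), SVM (RBF, probability output), a decision tree,
#' naive Bayes, logistic regression and a random forest at default
#' hyperparameters on a stratified split, and scores each on the
#' validation part by AUC.
#'
#' @param X Sample x feature matrix.
#' @param y 0/1 labels.
#' @param seed Seed controlling the split and the stochastic learners.
#' @param split_fraction Training fraction (default 0.7).
#' @return data.frame `method`, `auc` with exactly six rows.
#' @export
baseline_classifiers <- function(X, y, seed = 1L, split_fraction = 0.7) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  sp <- stratified_split(y, split_fraction, seed)
  Xtr <- X[sp$train, , drop = FALSE]
  Xva <- X[sp$val, , drop = FALSE]
  ytr <- y[sp$train]
  yva <- y[sp$val]
  ftr <- factor(ytr, levels = c(0, 1))
  dtr <- data.frame(y = ftr, Xtr, check.names = TRUE)
  dva <- data.frame(Xva, check.names = TRUE)
  names(dva) <- names(dtr)[-1]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  scores <- list()
  kn <- class::knn(Xtr, Xva, ftr, k = 5, prob = TRUE)
  pwin <- attr(kn, "prob")
  scores$knn <- ifelse(kn == "1", pwin, 1 - pwin)
  sv <- e1071::svm(Xtr, ftr, probability = TRUE)
  scores$svm <- attr(predict(sv, Xva, probability = TRUE),
                     "probabilities")[, "1"]
  tr <- rpart::rpart(y ~ ., data = dtr, method = "class")
  scores$decision_tree <- predict(tr, dva, type = "prob")[, "1"]
  nb <- e1071::naiveBayes(Xtr, ftr)
  scores$naive_bayes <- predict(nb, Xva, type = "raw")[, "1"]
  lo <- suppressWarnings(glm(y ~ ., data = dtr, family = binomial()))
  scores$logistic <- suppressWarnings(predict(lo, dva, type = "response"))
  rf <- randomForest::randomForest(Xtr, ftr)
  scores$random_forest <- predict(rf, Xva, type = "prob")[, "1"]

  data.frame(method = names(scores),
             auc = vapply(scores, function(s) roc_auc(s, yva)$auc, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
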