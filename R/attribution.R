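# Per-feature contribution scores for trained classifiers: additive
# attributions computed by backpropagating difference-from-reference
# multipliers (the rescale rule) through the network, averaged over a
# background reference set, then summarized per feature as the arithmetic
# mean of absolute per-sample attributions. The rescale rule makes the
# local-accuracy identity sum_i phi_i = f(x) - mean_ref f(ref) exact for
# this architecture (linear layers, affine inference-mode normalization,
# ReLU, sigmoid output).

# fold inference-mode batch norm into the linear layers, giving a plain
# (W, b) stack with ReLU between and sigmoid on top
fold_affine <- function(model) {
  L <- length(model$W)
  W <- model$W
  b <- model$b
  if (!is.null(model$bn)) {
    for (l in seq_len(L - 1L)) {
      p <- model$bn[[l]]
      s <- p$gamma / sqrt(p$var + .bn_eps)
      W[[l]] <- sweep(W[[l]], 2, s, "*")
      b[[l]] <- (b[[l]] - p$mean) * s + p$beta
    }
  }
  list(W = W, b = b)
}

# attributions of all rows of X against a single reference row
rescale_attributions_one <- function(net, X, ref) {
  L <- length(net$W)
  n <- nrow(X)
  # forward both, keeping pre-activations
  Zx <- Zr <- vector("list", L)
  Ax <- X
  Ar <- matrix(ref, 1)
  for (l in seq_len(L)) {
    Zx[[l]] <- sweep(Ax %*% net$W[[l]], 2, net$b[[l]], "+")
    Zr[[l]] <- sweep(Ar %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) {
      Ax <- pmax(Zx[[l]], 0)
      Ar <- pmax(Zr[[l]], 0)
    }
  }
  sig <- function(z) 1 / (1 + exp(-z))
  # output sigmoid multiplier delta(out)/delta(z), derivative in the limit
  dz <- Zx[[L]] - matrix(Zr[[L]], n, 1, byrow = TRUE)
  dout <- sig(Zx[[L]]) - matrix(sig(Zr[[L]]), n, 1, byrow = TRUE)
  px <- sig(Zx[[L]])
  G <- ifelse(abs(dz) < 1e-7, px * (1 - px), dout / dz)   # n x 1
  for (l in rev(seq_len(L))) {
    G <- G %*% t(net$W[[l]])                              # onto activations
    if (l > 1) {
      dzp <- Zx[[l - 1]] - matrix(Zr[[l - 1]], n, ncol(Zx[[l - 1]]),
                                  byrow = TRUE)
      dap <- pmax(Zx[[l - 1]], 0) - matrix(pmax(Zr[[l - 1]], 0), n,
                                           ncol(Zx[[l - 1]]), byrow = TRUE)
      m <- ifelse(abs(dzp) < 1e-7, (Zx[[l - 1]] > 0) * 1, dap / dzp)
      G <- G * m                                          # through ReLU
    }
  }
  sweep(X, 2, ref) * G
}

#' Per-feature contribution scores
#'
#' Computes additive per-sample attributions of the model's probability
#' output against each background reference, averages over the background,
#' and summarizes each feature as the arithmetic mean over samples of the
#' absolute attribution (the feature's contribution score).
#'
#' @param model Trained `mlp_model`.
#' @param X Sample x feature matrix to explain (feature columns named).
#' @param background Reference matrix; if NULL, up to `n_background` rows of
#'   `X` are drawn under `seed`.
#' @param n_background Background size cap (default 100).
#' @param seed Seed for the background draw.
#' @return `contribution_table` list: `table` (data.frame feature,
#'   shap_value, sorted by score descending), `attributions` (sample x
#'   feature matrix), `fx` (model output per sample), `base` (mean output
#'   over the background).
#' @export
compute_attributions <- function(model, X, background = NULL,
                                 n_background = 100L, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) != model$spec$n_features) {
    stop("X has ", ncol(X), " features; model expects ",
         model$spec$n_features)
  }
  if (is.null(background)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    background <- X[sample.int(nrow(X), min(n_background, nrow(X))), ,
                    drop = FALSE]
  }
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("background must be non-empty")
  net <- fold_affine(model)
  phi <- matrix(0, nrow(X), ncol(X))
  for (r in seq_len(nrow(background))) {
    phi <- phi + rescale_attributions_one(net, X, background[r, ])
  }
  phi <- phi / nrow(background)
  colnames(phi) <- colnames(X)
  rownames(phi) <- rownames(X)
  shap <- colMeans(abs(phi))
  tab <- data.frame(feature = colnames(X), shap_value = unname(shap),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$shap_value), ]
  rownames(tab) <- NULL
  out <- list(table = tab, attributions = phi,
              fx = predict_prob(model, X),
              base = mean(predict_prob(model, background)))
  class(out) <- "contribution_table"
  out
}

#' Exact Shapley values by coalition enumeration (test oracle)
#'
#' Enumerates all 2^n feature coalitions; absent features are imputed by
#' background means. Only feasible for n <= 12 features; used to validate
#' [compute_attributions()].
#'
#' @param model Trained `mlp_model`.
#' @param x Single sample (numeric vector).
#' @param background Background matrix whose column means impute absent
#'   features.
#' @return Numeric attribution vector, one value per feature.
#' @export
exact_shapley <- function(model, x, background) {
  n <- length(x)
  if (n > 12) stop("exact_shapley enumerates 2^n coalitions; n must be <= 12")
  mu <- colMeans(as.matrix(background))
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ximp <- matrix(mu, nrow(masks), n, byrow = TRUE)
  Ximp[masks] <- matrix(x, nrow(masks), n, byrow = TRUE)[masks]
  v <- predict_prob(model, Ximp)
  key <- masks %*% 2^(seq_len(n) - 1)
  val <- numeric(2^n)
  val[key + 1] <- v
  sizes <- rowSums(masks)
  phi <- numeric(n)
  fact <- factorial(0:n)
  for (i in seq_len(n)) {
    without_i <- which(!masks[, i])
    s <- sizes[without_i]
    w <- fact[s + 1] * fact[n - s] / fact[n + 1]
    k0 <- key[without_i]
    phi[i] <- sum(w * (val[k0 + 2^(i - 1) + 1] - val[k0 + 1]))
  }
  names(phi) <- names(x)
  phi
}

#' Remove zero-contribution features and retrain
#'
#' Drops features whose contribution score is exactly zero (after rounding
#' at 1e-12), rebuilds the input layer for the surviving features, retrains
#' under the repeated-split protocol, and recomputes contributions. If no
#' feature has zero score the model is returned unchanged and no retraining
#' happens.
#'
#' @param spec [model_spec()] of the current model.
#' @param X,y Full sample matrix and labels.
#' @param contributions `contribution_table` for the current model on `X`.
#' @param config [train_config()].
#' @return List: `features` (kept feature names), `n_pruned`, `fit`
#'   (new [train_repeats()] result or NULL if skipped), `contributions`
#'   (new table or the input one if skipped).
#' @export
prune_and_retrain <- function(spec, X, y, contributions, config) {
  X <- as.matrix(X)
  tab <- contributions$table
  zero <- tab$feature[round(tab$shap_value / 1e-12) == 0]
  keep <- setdiff(colnames(X), zero)
  if (length(keep) == 0) stop("pruning would remove every feature")
  if (length(zero) == 0) {
    return(list(features = keep, n_pruned = 0L, fit = NULL,
                contributions = contributions))
  }
  message("pruning ", length(zero), " zero-contribution feature(s)")
  spec2 <- model_spec(length(keep), spec$hidden_sizes,
                      spec$use_regularization, spec$activation)
  X2 <- X[, keep, drop = FALSE]
  fit <- train_repeats(spec2, X2, y, config)
  ctab <- compute_attributions(fit$model, X2, seed = config$seed)
  list(features = keep, n_pruned = length(zero), fit = fit,
       contributions = ctab)
}
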