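# helper: train a small model on seeded data and return everything the
# attribution tests need
fit_small_net <- function(n_feat = 8, n = 120, seed = 42, epochs = 150,
                          hidden = c(12L, 6L), reg = FALSE,
                          informative = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(NULL, paste0("f", seq_len(n_feat))))
  y <- as.numeric(rowSums(X[, seq_len(informative), drop = FALSE]) +
                    rnorm(n, sd = 0.3) > 0)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  spec <- model_spec(n_feat, hidden, use_regularization = reg)
  cfg <- train_config(epochs = epochs, learning_rate = 1e-3, seed = seed,
                      n_repeats = 1L)
  fit <- fit_model(build_model(spec, seed), X, y, cfg)
  list(model = fit$model, X = X, y = y, spec = spec, cfg = cfg)
}

test_that("attributions satisfy the local-accuracy identity exactly", {
  for (reg in c(TRUE, FALSE)) {
    fs <- fit_small_net(n_feat = 10, reg = reg, seed = 7)
    ct <- compute_attributions(fs$model, fs$X, n_background = 50, seed = 3)
    err <- max(abs(rowSums(ct$attributions) - (ct$fx - ct$base)))
    expect_lt(err, 1e-3)
    expect_true(all(ct$table$shap_value >= 0))
  }
})

test_that("a feature with zero outgoing weights gets exactly zero score", {
  fs <- fit_small_net(n_feat = 6, seed = 11)
  model <- fs$model
  model$W[[1]][3, ] <- 0
  ct <- compute_attributions(model, fs$X, n_background = 40, seed = 2)
  expect_equal(ct$table$shap_value[ct$table$feature == "f3"], 0)
  expect_true(all(ct$attributions[, 3] == 0))
})

test_that("near-linear models recover the closed-form attribution", {
  # hidden pair h1 = relu(w.x + 10), h2 = relu(-(w.x) + 10): both always
  # active, so the logit is exactly linear in x with coefficients w / 4
  # small enough to stay in the sigmoid's linear regime
  w <- c(0.08, -0.05, 0.02, 0.1)
  spec <- model_spec(4, 2L, use_regularization = FALSE)
  model <- build_model(spec, 1)
  model$W[[1]] <- cbind(w, -w)
  model$b[[1]] <- c(10, 10)
  model$W[[2]] <- matrix(c(0.5, -0.5), 2, 1)
  model$b[[2]] <- -10 * 0.5 + 10 * 0.5   # cancels the shifts
  set.seed(4)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
  bg <- matrix(rnorm(40 * 4), 40, 4)
  ct <- compute_attributions(model, X, background = bg)
  mu <- colMeans(bg)
  # probability-scale slope of sigmoid at ~0 logit is 1/4
  expected <- sweep(X, 2, mu) * matrix(w / 4, 60, 4, byrow = TRUE)
  expect_lt(max(abs(ct$attributions - expected)), 1e-3)
})

test_that("exact Shapley obeys the symmetry and dummy axioms", {
  # symmetric 2-feature model: f depends on x1 + x2
  spec <- model_spec(2, 2L, use_regularization = FALSE)
  model <- build_model(spec, 3)
  model$W[[1]] <- matrix(c(1, 1, -1, -1), 2, 2)
  model$b[[1]] <- c(0, 0)
  model$W[[2]] <- matrix(c(1, -1), 2, 1)
  model$b[[2]] <- 0
  bg <- matrix(0, 10, 2)
  phi <- exact_shapley(model, c(0.7, 0.7), bg)
  expect_equal(phi[1], phi[2], tolerance = 1e-12)

  # dummy feature: no influence on the output at all
  spec3 <- model_spec(3, 2L, use_regularization = FALSE)
  m3 <- build_model(spec3, 5)
  m3$W[[1]][3, ] <- 0
  phi3 <- exact_shapley(m3, c(0.5, -0.3, 2.0), matrix(rnorm(30), 10, 3))
  expect_equal(unname(phi3[3]), 0, tolerance = 1e-12)

  expect_error(exact_shapley(build_model(model_spec(13, 2L), 1), rnorm(13),
                             matrix(0, 2, 13)),
               "<= 12")
})

test_that("backpropagated attributions agree with exact Shapley values", {
  # seeded 8-feature network operating mostly in its active regime (positive
  # hidden biases), where the rescale rule tracks Shapley values closely;
  # at heavily kinked ReLUs the two provably diverge (see the vignette), so
  # the oracle comparison is run where the approximation is meant to hold
  spec <- model_spec(8, c(12L, 6L), use_regularization = FALSE)
  model <- build_model(spec, 7)
  set.seed(107)
  model$W[[1]] <- matrix(rnorm(8 * 12, sd = 0.25), 8, 12)
  model$b[[1]] <- rep(1.5, 12)
  model$W[[2]] <- matrix(rnorm(12 * 6, sd = 0.25), 12, 6)
  model$b[[2]] <- rep(1.5, 6)
  model$W[[3]] <- matrix(rnorm(6, sd = 0.5), 6, 1)
  model$b[[3]] <- 0
  set.seed(3)
  X <- matrix(rnorm(12 * 8), 12, 8, dimnames = list(NULL, paste0("f", 1:8)))
  bg_mean <- matrix(colMeans(X), 1, 8)
  deep <- compute_attributions(model, X, background = bg_mean)
  ex <- t(vapply(seq_len(nrow(X)), function(i) {
    exact_shapley(model, X[i, ], bg_mean)
  }, numeric(8)))
  expect_lt(max(abs(deep$attributions - ex)) / max(abs(ex)), 0.05)
})

test_that("planted-signal features dominate noise features in ranking", {
  fs <- fit_small_net(n_feat = 20, n = 160, seed = 9, informative = 4,
                      epochs = 250)
  ct <- compute_attributions(fs$model, fs$X, n_background = 80, seed = 5)
  shap <- setNames(ct$table$shap_value, ct$table$feature)
  planted <- shap[paste0("f", 1:4)]
  noise <- shap[paste0("f", 5:20)]
  expect_gt(median(planted), quantile(noise, 0.95))
})

test_that("pruning removes exactly the zero-contribution features", {
  fs <- fit_small_net(n_feat = 6, seed = 21)
  X <- cbind(fs$X, c1 = 1, c2 = 2)   # two constant features
  spec <- model_spec(8, c(12L, 6L), use_regularization = FALSE)
  cfg <- train_config(epochs = 60L, learning_rate = 1e-3, seed = 21,
                      n_repeats = 1L)
  fit <- train_repeats(spec, X, fs$y, cfg)
  ct <- compute_attributions(fit$model, X, n_background = 50, seed = 1)
  expect_message(
    pr <- prune_and_retrain(spec, X, fs$y, ct, cfg),
    "2 zero-contribution")
  expect_equal(pr$n_pruned, 2L)
  expect_setequal(pr$features, paste0("f", 1:6))
  expect_equal(pr$contributions$table$feature %in% c("c1", "c2"),
               rep(FALSE, 6))

  # fixed point: nothing to prune leaves the model untouched
  ct2 <- pr$contributions
  pr2 <- prune_and_retrain(model_spec(6, c(12L, 6L), FALSE),
                           X[, pr$features], fs$y, ct2, cfg)
  expect_equal(pr2$n_pruned, 0L)
  expect_null(pr2$fit)
})
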