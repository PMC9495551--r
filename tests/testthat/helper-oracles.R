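# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

# Benjamini-Hochberg step-up from the definition: adj_(i) running minimum of
# p_(i) * m / i from the largest rank down.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# TMM factors from the published trimmed-mean formula, written from scratch:
# reference = sample whose 75th percentile of count fractions is closest to
# the mean; per sample, M = log2((k/N)/(kr/Nr)) over doubly-positive
# features, 30% two-sided M-trim and 5% two-sided A-trim, inverse-variance
# (delta-method binomial) weights; factors rescaled to geometric mean 1.
tmm_oracle <- function(counts) {
  counts <- as.matrix(counts)
  N <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x[x > 0] / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    k <- counts[, j]; kr <- counts[, ref]
    keep <- k > 0 & kr > 0
    k <- k[keep]; kr <- kr[keep]
    M <- log2((k / N[j]) / (kr / N[ref]))
    A <- 0.5 * log2((k / N[j]) * (kr / N[ref]))
    w <- (N[j] - k) / (N[j] * k) + (N[ref] - kr) / (N[ref] * kr)
    loM <- quantile(M, 0.3, type = 7); hiM <- quantile(M, 0.7, type = 7)
    loA <- quantile(A, 0.05, type = 7); hiA <- quantile(A, 0.95, type = 7)
    keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, 0)
  f / exp(mean(log(f)))
}

# maximal cliques by exhaustive subset enumeration (n <= 12); returns a
# sorted list of sorted vertex-name vectors
cliques_oracle <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 12)
  nodes <- rownames(adj)
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(FALSE)
    all(adj[s, s][upper.tri(diag(length(s)))] == 1)
  }, TRUE)
  cl <- subsets[is_clique]
  # keep cliques not strictly contained in another clique
  maximal <- vapply(seq_along(cl), function(i) {
    !any(vapply(cl, function(other) {
      length(other) > length(cl[[i]]) && all(cl[[i]] %in% other)
    }, TRUE))
  }, TRUE)
  out <- lapply(cl[maximal], function(s) sort(nodes[s]))
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

mcc_oracle <- function(adj) {
  mcc <- setNames(rep(0, nrow(adj)), rownames(adj))
  for (cl in cliques_oracle(adj)) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  }
  mcc
}

# AUC as the normalized count of concordant (positive, negative) score
# pairs, ties counted half
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n, dimnames = list(letters[1:n], letters[1:n]))
  idx <- which(upper.tri(adj), arr.ind = TRUE)
  on <- runif(nrow(idx)) < p
  adj[idx[on, , drop = FALSE]] <- 1L
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

adj_to_graph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# small paired count dataset with optional planted fold change on the first
# n_de features; plain rnbinom, independent of the package generator
tiny_counts <- function(n_feat = 50, n_pairs = 10, log2fc = 0, n_de = 0,
                        seed = 1) {
  set.seed(seed)
  n <- 2 * n_pairs
  base <- exp(runif(n_feat, log(50), log(500)))
  cond <- rep(c("tumor", "normal"), n_pairs)
  shift <- matrix(1, n_feat, n)
  if (n_de > 0) {
    shift[seq_len(n_de), cond == "tumor"] <- 2^log2fc
  }
  mu <- base * shift
  cnt <- matrix(rnbinom(n_feat * n, mu = mu, size = 10), n_feat, n)
  rownames(cnt) <- sprintf("F%03d", seq_len(n_feat))
  colnames(cnt) <- paste0(rep(sprintf("P%02d", seq_len(n_pairs)), each = 2),
                          "_", cond)
  meta <- data.frame(sample_id = colnames(cnt), condition = cond,
                     pair_id = rep(sprintf("P%02d", seq_len(n_pairs)),
                                   each = 2),
                     stringsAsFactors = FALSE)
  list(counts = cnt, metadata = meta)
}
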