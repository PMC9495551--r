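# Interaction network under confidence + co-expression filters, and
# Maximal Clique Centrality.

#' Pearson correlation test
#'
#' Sample Pearson r with a p-value from the t-distribution on n - 2 degrees
#' of freedom. A zero-variance vector makes r undefined; such pairs are
#' flagged non-significant (r = NA, p = 1) rather than erroring, so screens
#' over many pairs keep running.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`; the
#'   one-sided variants serve sign-constrained screens.
#' @return List with elements `r` and `p`.
#' @export
pearson_test <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, p = 1))
  ct <- cor.test(x, y, method = "pearson", alternative = alternative)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Build the mRNA interaction network
#'
#' Keeps edges with `confidence > conf_threshold` (STRING-style 0-1000
#' score, strict inequality) whose endpoints are significantly co-expressed
#' (two-sided Pearson p < `p_threshold` on the normalized abundance matrix,
#' all samples pooled). Duplicate rows and self-loops collapse; edges with
#' an endpoint missing from `expr` are dropped with a message; isolated
#' nodes are not part of the result.
#'
#' @param edge_list data.frame `node_a`, `node_b`, `confidence`.
#' @param expr Normalized abundance matrix (features x samples) supplying
#'   the co-expression profiles.
#' @param conf_threshold Confidence cut (default 700).
#' @param p_threshold Co-expression significance cut (default 0.05).
#' @return List of class `interaction_graph`: `edges` (node_a, node_b,
#'   confidence, r, p) and `nodes`.
#' @export
build_interaction_graph <- function(edge_list, expr, conf_threshold = 700,
                                    p_threshold = 0.05) {
  req <- c("node_a", "node_b", "confidence")
  if (!all(req %in% names(edge_list))) {
    stop("edge_list must have columns ", paste(req, collapse = ", "))
  }
  el <- edge_list[req]
  el <- el[el$node_a != el$node_b, , drop = FALSE]
  a <- pmin(el$node_a, el$node_b)
  b <- pmax(el$node_a, el$node_b)
  el$node_a <- a
  el$node_b <- b
  el <- el[!duplicated(paste(a, b)), , drop = FALSE]
  known <- el$node_a %in% rownames(expr) & el$node_b %in% rownames(expr)
  if (any(!known)) {
    message("dropping ", sum(!known),
            " edge(s) with endpoints absent from the expression matrix")
    el <- el[known, , drop = FALSE]
  }
  el <- el[el$confidence > conf_threshold, , drop = FALSE]
  if (nrow(el) > 0) {
    rp <- vapply(seq_len(nrow(el)), function(i) {
      pt <- pearson_test(expr[el$node_a[i], ], expr[el$node_b[i], ])
      c(if (is.na(pt$r)) NA_real_ else pt$r, pt$p)
    }, numeric(2))
    el$r <- rp[1, ]
    el$p <- rp[2, ]
    el <- el[el$p < p_threshold, , drop = FALSE]
  } else {
    el$r <- numeric(0)
    el$p <- numeric(0)
  }
  rownames(el) <- NULL
  out <- list(edges = el, nodes = sort(unique(c(el$node_a, el$node_b))))
  class(out) <- "interaction_graph"
  out
}

as_igraph <- function(graph) {
  if (inherits(graph, "igraph")) return(graph)
  if (inherits(graph, "interaction_graph")) {
    return(igraph::graph_from_data_frame(graph$edges[, c("node_a", "node_b")],
                                         directed = FALSE,
                                         vertices = graph$nodes))
  }
  if (is.data.frame(graph)) {
    return(igraph::graph_from_data_frame(graph[, 1:2], directed = FALSE))
  }
  stop("unsupported graph representation: ", paste(class(graph), collapse = "/"))
}

#' Enumerate maximal cliques
#'
#' All maximal cliques of size >= 2 (Bron-Kerbosch with pivoting, via
#' igraph). A node-count guard protects against accidental worst-case
#' inputs.
#'
#' @param graph An `interaction_graph`, igraph object, or two-column edge
#'   data.frame.
#' @param max_nodes Guard on the node count (default 5000).
#' @return List of character vectors, each a maximal clique (sorted); the
#'   list is sorted lexicographically for determinism.
#' @export
enumerate_maximal_cliques <- function(graph, max_nodes = 5000L) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (n > max_nodes) {
    stop("graph has ", n, " nodes, above the guard of ", max_nodes,
         "; raise 'max_nodes' to override")
  }
  cl <- igraph::max_cliques(g, min = 2)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  cl[order(vapply(cl, paste, "", collapse = "\r"))]
}

#' Maximal Clique Centrality
#'
#' `MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!`
#' (cliques of size >= 2). An isolated node scores 0; a node whose maximal
#' cliques are all single edges scores its degree.
#'
#' @inheritParams enumerate_maximal_cliques
#' @return Named numeric vector, node id -> MCC.
#' @export
mcc_centrality <- function(graph, max_nodes = 5000L) {
  g <- as_igraph(graph)
  nodes <- igraph::V(g)$name
  mcc <- setNames(rep(0, length(nodes)), nodes)
  for (cl in enumerate_maximal_cliques(g, max_nodes)) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  }
  mcc
}
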