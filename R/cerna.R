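# Joint contribution x centrality candidate selection, sign-constrained
# ceRNA triplet screening, ceRNA network assembly, potential-ceRNA
# selection, and direction-consistent regulatory-module extraction.

contribution_vector <- function(contributions) {
  if (inherits(contributions, "contribution_table")) {
    setNames(contributions$table$shap_value, contributions$table$feature)
  } else if (is.numeric(contributions) && !is.null(names(contributions))) {
    contributions
  } else {
    stop("contributions must be a contribution_table or a named numeric vector")
  }
}

#' Select candidate mRNAs by contribution and centrality
#'
#' Candidates are the mRNAs with `MCC > mcc_threshold` and contribution
#' score `> shap_threshold` (both strict, matching the published cuts
#' MCC > 8 and score > 1e-4). Nodes absent from the centrality table count
#' as MCC 0.
#'
#' @param contributions `contribution_table` (or named score vector) from
#'   the mRNA classifier.
#' @param centrality Named MCC vector from [mcc_centrality()].
#' @param shap_threshold Contribution cut (default 1e-4).
#' @param mcc_threshold Centrality cut (default 8).
#' @return Sorted character vector of candidate mRNA ids.
#' @export
select_candidate_mrnas <- function(contributions, centrality,
                                   shap_threshold = 1e-4, mcc_threshold = 8) {
  shap <- contribution_vector(contributions)
  mcc <- centrality[names(shap)]
  mcc[is.na(mcc)] <- 0
  out <- sort(names(shap)[shap > shap_threshold & mcc > mcc_threshold])
  if (length(out) == 0) warning("no mRNA passes both candidate cuts")
  out
}

#' Screen sign-constrained ceRNA triplets
#'
#' Enumerates (mRNA, miRNA, lncRNA) triplets whose miRNA-mRNA and
#' miRNA-lncRNA pairs both appear in the validated-target tables, with the
#' miRNA and lncRNA restricted to stable significant DE features and the
#' mRNA to the candidate set, and keeps triplets satisfying the ceRNA
#' correlation pattern: miRNA negatively correlated with mRNA and lncRNA,
#' mRNA positively correlated with lncRNA, all three two-sided Pearson
#' p-values below `p_threshold`.
#'
#' @param expr Normalized abundance matrix whose rows cover all three RNA
#'   classes (all samples pooled).
#' @param de_table Combined `de_table` over the classes (from [run_de()]).
#' @param targets_mrna,targets_lncrna Validated miRNA target tables
#'   (`mirna_id`, `target_id`).
#' @param candidate_mrnas Candidate mRNA ids (e.g. from
#'   [select_candidate_mrnas()]).
#' @param p_threshold Correlation significance cut (default 0.05).
#' @return data.frame of retained triplets: `mrna_id`, `mirna_id`,
#'   `lncrna_id`, `r_mm`, `p_mm`, `r_ml`, `p_ml`, `r_gl`, `p_gl`, sorted by
#'   (mirna, mrna, lncrna); row-order invariant in its inputs.
#' @export
screen_triplets <- function(expr, de_table, targets_mrna, targets_lncrna,
                            candidate_mrnas, p_threshold = 0.05) {
  if (nrow(targets_mrna) == 0 || nrow(targets_lncrna) == 0) {
    warning("empty target table; no triplets to screen")
    return(empty_triplets())
  }
  sig <- de_table[de_table$stable & de_table$direction != "none", ]
  mirnas <- sig$feature_id[sig$class == "mirna"]
  lncrnas <- sig$feature_id[sig$class == "lncrna"]
  tm <- targets_mrna[targets_mrna$mirna_id %in% mirnas &
                       targets_mrna$target_id %in% candidate_mrnas &
                       targets_mrna$target_id %in% rownames(expr), ]
  tl <- targets_lncrna[targets_lncrna$mirna_id %in% mirnas &
                         targets_lncrna$target_id %in% lncrnas &
                         targets_lncrna$target_id %in% rownames(expr), ]
  shared <- sort(intersect(tm$mirna_id, tl$mirna_id))
  shared <- shared[shared %in% rownames(expr)]
  rows <- list()
  corr_cache <- new.env(parent = emptyenv())
  corr <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    hit <- corr_cache[[key]]
    if (is.null(hit)) {
      hit <- pearson_test(expr[a, ], expr[b, ])
      corr_cache[[key]] <- hit
    }
    hit
  }
  for (mi in shared) {
    gs <- sort(unique(tm$target_id[tm$mirna_id == mi]))
    ls <- sort(unique(tl$target_id[tl$mirna_id == mi]))
    for (g in gs) {
      mm <- corr(mi, g)
      if (is.na(mm$r) || mm$r >= 0 || mm$p >= p_threshold) next
      for (l in ls) {
        ml <- corr(mi, l)
        if (is.na(ml$r) || ml$r >= 0 || ml$p >= p_threshold) next
        gl <- corr(g, l)
        if (is.na(gl$r) || gl$r <= 0 || gl$p >= p_threshold) next
        rows[[length(rows) + 1L]] <- data.frame(
          mrna_id = g, mirna_id = mi, lncrna_id = l,
          r_mm = mm$r, p_mm = mm$p, r_ml = ml$r, p_ml = ml$p,
          r_gl = gl$r, p_gl = gl$p, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_triplets())
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$mrna_id, out$lncrna_id), ]
  rownames(out) <- NULL
  out
}

empty_triplets <- function() {
  data.frame(mrna_id = character(), mirna_id = character(),
             lncrna_id = character(), r_mm = numeric(), p_mm = numeric(),
             r_ml = numeric(), p_ml = numeric(), r_gl = numeric(),
             p_gl = numeric(), stringsAsFactors = FALSE)
}

#' Assemble the ceRNA network
#'
#' Nodes are the union of triplet members; edges are the triplet pairings
#' (miRNA-mRNA, miRNA-lncRNA, mRNA-lncRNA) plus interaction-graph edges
#' between included mRNAs. Nodes carry RNA class and DE direction.
#'
#' @param triplets Output of [screen_triplets()].
#' @param interaction_graph `interaction_graph` (may be NULL).
#' @param de_table Combined `de_table` supplying class and direction.
#' @return `cerna_network` list: `nodes` (id, class, direction), `edges`
#'   (from, to, type with type in ceRNA/interaction).
#' @export
build_cerna_network <- function(triplets, interaction_graph = NULL,
                                de_table = NULL) {
  if (nrow(triplets) == 0) {
    out <- list(nodes = data.frame(id = character(), class = character(),
                                   direction = character(),
                                   stringsAsFactors = FALSE),
                edges = data.frame(from = character(), to = character(),
                                   type = character(), stringsAsFactors = FALSE))
    class(out) <- "cerna_network"
    return(out)
  }
  edges <- unique(rbind(
    data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
               type = "ceRNA", stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna_id, to = triplets$lncrna_id,
               type = "ceRNA", stringsAsFactors = FALSE),
    data.frame(from = triplets$mrna_id, to = triplets$lncrna_id,
               type = "ceRNA", stringsAsFactors = FALSE)))
  ids <- data.frame(
    id = c(triplets$mrna_id, triplets$mirna_id, triplets$lncrna_id),
    class = rep(c("mrna", "mirna", "lncrna"), each = nrow(triplets)),
    stringsAsFactors = FALSE)
  nodes <- unique(ids)
  if (!is.null(interaction_graph) && nrow(interaction_graph$edges) > 0) {
    mr <- nodes$id[nodes$class == "mrna"]
    ie <- interaction_graph$edges
    ie <- ie[ie$node_a %in% mr & ie$node_b %in% mr, , drop = FALSE]
    if (nrow(ie) > 0) {
      edges <- unique(rbind(edges, data.frame(from = ie$node_a, to = ie$node_b,
                                              type = "interaction",
                                              stringsAsFactors = FALSE)))
    }
  }
  nodes$direction <- if (!is.null(de_table)) {
    de_table$direction[match(nodes$id, de_table$feature_id)]
  } else NA_character_
  nodes <- nodes[order(nodes$class, nodes$id), c("id", "class", "direction")]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$type, edges$from, edges$to), ]
  rownames(edges) <- NULL
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "cerna_network"
  out
}

#' Select potential ceRNAs and induce their subnetwork
#'
#' Keeps network nodes whose contribution score in the ceRNA classifier
#' exceeds `threshold` (published cut: 1e-4), retains edges with both
#' endpoints surviving, and drops nodes left isolated.
#'
#' @param contributions `contribution_table` (or named vector) from the
#'   ceRNA classifier.
#' @param network `cerna_network` from [build_cerna_network()].
#' @param threshold Contribution cut (default 1e-4, strict).
#' @return `cerna_network` restricted to the potential ceRNAs; node table
#'   gains a `shap_value` column.
#' @export
select_potential_cernas <- function(contributions, network,
                                    threshold = 1e-4) {
  shap <- contribution_vector(contributions)
  keep <- names(shap)[shap > threshold]
  nodes <- network$nodes[network$nodes$id %in% keep, , drop = FALSE]
  edges <- network$edges[network$edges$from %in% nodes$id &
                           network$edges$to %in% nodes$id, , drop = FALSE]
  connected <- unique(c(edges$from, edges$to))
  nodes <- nodes[nodes$id %in% connected, , drop = FALSE]
  if (nrow(nodes) == 0) warning("potential ceRNA subnetwork is empty")
  nodes$shap_value <- unname(shap[nodes$id])
  rownames(nodes) <- rownames(edges) <- NULL
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "cerna_network"
  out
}

#' Extract direction-consistent regulatory modules
#'
#' For each miRNA in the subnetwork, its validated targets (neighbors via
#' ceRNA edges) are partitioned by DE direction; each group with at least
#' one mRNA becomes a module "one miRNA plus its regulated mRNAs/lncRNAs
#' sharing one up/down direction". When a miRNA yields both an up and a
#' down group, the larger is marked primary. Modules are ordered by the
#' miRNA's contribution score (descending) when available.
#'
#' @param subnetwork `cerna_network`, typically from
#'   [select_potential_cernas()].
#' @param de_table Combined `de_table` supplying member directions.
#' @return List of modules; each is a list with `mirna_id`, `direction`,
#'   `mrna_ids`, `lncrna_ids`, `primary` (logical), `has_lncrna` (logical;
#'   modules without a lncRNA are kept but flagged).
#' @export
extract_modules <- function(subnetwork, de_table) {
  nodes <- subnetwork$nodes
  edges <- subnetwork$edges[subnetwork$edges$type == "ceRNA", , drop = FALSE]
  dir_of <- setNames(de_table$direction, de_table$feature_id)
  cls_of <- setNames(nodes$class, nodes$id)
  modules <- list()
  mirnas <- sort(nodes$id[nodes$class == "mirna"])
  for (mi in mirnas) {
    nb <- unique(c(edges$to[edges$from == mi], edges$from[edges$to == mi]))
    nb <- nb[cls_of[nb] %in% c("mrna", "lncrna")]
    if (length(nb) == 0) next
    groups <- split(nb, dir_of[nb])
    groups <- groups[names(groups) %in% c("up", "down")]
    groups <- Filter(function(g) any(cls_of[g] == "mrna"), groups)
    if (length(groups) == 0) next
    primary_dir <- names(groups)[which.max(lengths(groups))]
    for (d in names(groups)) {
      g <- groups[[d]]
      lnc <- sort(g[cls_of[g] == "lncrna"])
      modules[[length(modules) + 1L]] <- list(
        mirna_id = mi, direction = d,
        mrna_ids = sort(g[cls_of[g] == "mrna"]),
        lncrna_ids = lnc,
        primary = d == primary_dir,
        has_lncrna = length(lnc) > 0)
    }
  }
  if ("shap_value" %in% names(nodes)) {
    sv <- setNames(nodes$shap_value, nodes$id)
    ord <- order(-vapply(modules, function(m) sv[[m$mirna_id]], 0),
                 vapply(modules, function(m) m$mirna_id, ""))
    modules <- modules[ord]
  }
  modules
}
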