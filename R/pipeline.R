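# End-to-end orchestration: differential expression -> interaction network
# -> mRNA classifier + attribution -> candidate selection -> triplet screen
# -> ceRNA classifier + attribution -> potential-ceRNA subnetwork ->
# regulatory modules, with every intermediate written to disk and a JSON
# manifest recording seeds and thresholds.

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full regulatory-module discovery pipeline
#'
#' Executes every stage on a dataset (by default a synthetic dataset
#' generated under `config$seed`): per-class TMM + stability-selected DE,
#' interaction-network construction over stable DE mRNAs, MCC centrality,
#' the mRNA classifier with attribution and zero-contribution pruning,
#' joint contribution x centrality candidate selection, the sign-constrained
#' triplet screen, the ceRNA classifier with attribution, potential-ceRNA
#' subnetwork reconstruction, module extraction, and the AUC comparison
#' against six conventional classifiers on the module members.
#'
#' Module membership is asserted against the stable DE set and the
#' potential subnetwork on every run. With a fixed config the run is
#' deterministic (single-threaded), and rerunning writes byte-identical
#' outputs.
#'
#' @param config [pipeline_config()].
#' @param dataset Dataset in [generate_dataset()] layout; NULL generates a
#'   synthetic one from `sim`.
#' @param sim [sim_config()] for the synthetic dataset (used only when
#'   `dataset` is NULL); defaults to the standard study conditions with the
#'   pipeline seed.
#' @param outdir Output directory; NULL skips writing.
#' @return Invisible list bundle: `de`, `graph`, `centrality`, `fit_mrna`,
#'   `contrib_mrna`, `pruned`, `candidates`, `triplets`, `network`,
#'   `fit_cerna`, `contrib_cerna`, `subnetwork`, `modules`, `auc_table`,
#'   `dataset`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         sim = NULL, outdir = NULL) {
  t0 <- Sys.time()
  if (is.null(dataset)) {
    if (is.null(sim)) sim <- sim_config(seed = config$seed)
    dataset <- stage_run("simulate", generate_dataset(sim))
  }
  meta <- dataset$metadata

  de <- stage_run("diffexpr", {
    do.call(rbind, lapply(c("mrna", "lncrna", "mirna"), function(cls) {
      run_de(dataset$counts[[cls]], meta, class = cls,
             rounds = config$stability_rounds,
             fraction = config$stability_fraction,
             seed = config$seed, lfc_threshold = config$de_log2fc,
             fdr_threshold = config$de_fdr)
    }))
  })
  stable_de <- de[de$stable & de$direction != "none", ]

  norm <- stage_run("normalize", {
    lapply(dataset$counts, function(cnt) {
      cnt[is.na(cnt)] <- 0
      normalize_logcpm(cnt, compute_tmm_factors(cnt))
    })
  })
  samples <- Reduce(intersect, lapply(norm, colnames))
  expr_all <- do.call(rbind, lapply(norm, function(m) m[, samples]))
  y <- as.numeric(meta$condition[match(samples, meta$sample_id)] == "tumor")

  graph <- stage_run("network", {
    de_mrna <- stable_de$feature_id[stable_de$class == "mrna"]
    el <- dataset$edges
    el <- el[el$node_a %in% de_mrna & el$node_b %in% de_mrna, , drop = FALSE]
    build_interaction_graph(el, norm$mrna, config$confidence, config$corr_p)
  })
  centrality <- stage_run("centrality", mcc_centrality(graph))

  fit_mrna <- stage_run("train_mrna", {
    if (length(graph$nodes) == 0) stop("interaction network is empty")
    X <- t(norm$mrna[graph$nodes, samples, drop = FALSE])
    spec <- model_spec(ncol(X), config$hidden_mrna, use_regularization = TRUE)
    cfg <- train_config(config$epochs, config$batch_size,
                        config$learning_rate, config$split_fraction,
                        config$n_repeats, config$seed)
    fit <- train_repeats(spec, X, y, cfg)
    c(fit, list(X = X, spec = spec, cfg = cfg))
  })

  contrib_mrna <- stage_run("attribute_mrna", {
    bg <- fit_mrna$X[head(fit_mrna$split$train, 100), , drop = FALSE]
    compute_attributions(fit_mrna$model, fit_mrna$X, background = bg)
  })
  pruned <- stage_run("prune", {
    prune_and_retrain(fit_mrna$spec, fit_mrna$X, y, contrib_mrna,
                      fit_mrna$cfg)
  })
  contrib_final <- pruned$contributions

  candidates <- stage_run("candidates", {
    select_candidate_mrnas(contrib_final, centrality,
                           config$shap_threshold, config$mcc_threshold)
  })

  triplets <- stage_run("triplets", {
    screen_triplets(expr_all, de, dataset$targets_mrna,
                    dataset$targets_lncrna, candidates, config$corr_p)
  })
  network <- stage_run("cerna_network",
                       build_cerna_network(triplets, graph, de))

  fit_cerna <- stage_run("train_cerna", {
    if (nrow(network$nodes) == 0) stop("ceRNA network is empty")
    X <- t(expr_all[network$nodes$id, , drop = FALSE])
    spec <- model_spec(ncol(X), config$hidden_cerna,
                       use_regularization = FALSE)
    cfg <- train_config(config$epochs, config$batch_size,
                        config$learning_rate, config$split_fraction,
                        config$n_repeats, config$seed)
    fit <- train_repeats(spec, X, y, cfg)
    c(fit, list(X = X, spec = spec, cfg = cfg))
  })
  contrib_cerna <- stage_run("attribute_cerna", {
    bg <- fit_cerna$X[head(fit_cerna$split$train, 100), , drop = FALSE]
    compute_attributions(fit_cerna$model, fit_cerna$X, background = bg)
  })

  subnetwork <- stage_run("subnetwork", {
    select_potential_cernas(contrib_cerna, network, config$shap_threshold)
  })
  modules <- stage_run("modules", extract_modules(subnetwork, de))

  # invariant: every module member is a potential ceRNA and stable DE
  stage_run("module_invariants", {
    members <- unlist(lapply(modules, function(m)
      c(m$mirna_id, m$mrna_ids, m$lncrna_ids)))
    stopifnot(all(members %in% subnetwork$nodes$id),
              all(members %in% stable_de$feature_id))
  })

  auc_table <- stage_run("evaluate", {
    feats <- unique(unlist(lapply(modules, function(m)
      c(m$mirna_id, m$mrna_ids, m$lncrna_ids))))
    if (length(feats) < 2) feats <- network$nodes$id
    Xm <- t(expr_all[feats, , drop = FALSE])
    base <- baseline_classifiers(Xm, y, seed = config$seed,
                                 split_fraction = config$split_fraction)
    sp <- fit_cerna$split
    dnn_auc <- evaluate_roc(fit_cerna$model,
                            fit_cerna$X[sp$val, , drop = FALSE],
                            y[sp$val])$auc
    rbind(data.frame(method = "dnn", auc = dnn_auc,
                     stringsAsFactors = FALSE), base)
  })

  manifest <- list(
    package = "cernaMod",
    version = as.character(utils::packageVersion("cernaMod")),
    config = unclass(config),
    n_samples = length(samples),
    n_stable_de = nrow(stable_de),
    n_network_nodes = length(graph$nodes),
    n_network_edges = nrow(graph$edges),
    n_pruned = pruned$n_pruned,
    n_candidates = length(candidates),
    n_triplets = nrow(triplets),
    n_potential_cernas = nrow(subnetwork$nodes),
    n_modules = length(modules),
    val_accuracy = fit_cerna$repeats$val_acc[1],
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- list(de = de, graph = graph, centrality = centrality,
                 fit_mrna = fit_mrna[c("history", "repeats")],
                 contrib_mrna = contrib_mrna, pruned_features = pruned$features,
                 n_pruned = pruned$n_pruned, candidates = candidates,
                 triplets = triplets, network = network,
                 fit_cerna = fit_cerna[c("model", "history", "repeats",
                                         "split")],
                 contrib_cerna = contrib_cerna, subnetwork = subnetwork,
                 modules = modules, auc_table = auc_table,
                 dataset = dataset, manifest = manifest)

  if (!is.null(outdir)) stage_run("write", write_bundle(bundle, outdir))
  invisible(bundle)
}

modules_to_json <- function(modules, path) {
  jsonlite::write_json(lapply(modules, function(m) {
    list(mirna_id = m$mirna_id, direction = m$direction,
         mrna_ids = as.list(m$mrna_ids), lncrna_ids = as.list(m$lncrna_ids),
         primary = m$primary, has_lncrna = m$has_lncrna)
  }), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_tsv(bundle$de, p("de_table.tsv"))
  write_tsv(bundle$graph$edges, p("interaction_edges.tsv"))
  write_tsv(data.frame(node = names(bundle$centrality),
                       mcc = unname(bundle$centrality)), p("centrality.tsv"))
  write_tsv(bundle$contrib_mrna$table, p("contributions_mrna.tsv"))
  write_tsv(bundle$contrib_cerna$table, p("contributions_cerna.tsv"))
  write_tsv(data.frame(feature_id = bundle$candidates), p("candidates.tsv"))
  write_tsv(bundle$triplets, p("triplets.tsv"))
  write_tsv(bundle$network$edges, p("cerna_edges.tsv"))
  write_tsv(bundle$subnetwork$nodes, p("potential_cernas.tsv"))
  write_tsv(bundle$fit_cerna$history, p("training_curves_cerna.tsv"))
  write_tsv(bundle$fit_mrna$history, p("training_curves_mrna.tsv"))
  write_tsv(bundle$auc_table, p("classifier_auc.tsv"))
  modules_to_json(bundle$modules, p("modules.json"))
  write_manifest(bundle$manifest, p("manifest.json"))
  invisible(outdir)
}
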