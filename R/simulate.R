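# Synthetic paired tumor/normal expression data with planted structure:
# negative-binomial counts, planted fold changes, a planted mRNA interaction
# graph, and ceRNA modules in which one miRNA is negatively coupled to its
# mRNA/lncRNA targets through a shared latent factor.

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a paired
#' tumor/normal design with negative-binomial counts, planted differential
#' expression at |log2FC| >= 1, and planted ceRNA modules. A module is one
#' miRNA, one lncRNA and `mrnas_per_module` mRNAs sharing a standard-normal
#' latent factor that enters mRNA/lncRNA log-means with sign +1 and the
#' miRNA log-mean with sign -1, producing the ceRNA correlation pattern
#' (miRNA negatively correlated with both partners, partners positively
#' correlated). Planted triplets are all (mRNA, miRNA, lncRNA) combinations
#' within a module; with one lncRNA per module there are exactly
#' `n_triplets` of them.
#'
#' @param n_pairs Number of tumor/normal sample pairs.
#' @param n_mrna,n_lncrna,n_mirna Feature counts per RNA class.
#' @param n_de_mrna,n_de_lncrna,n_de_mirna Planted differentially expressed
#'   features per class (module members are drawn from these).
#' @param planted_log2fc Magnitude of the planted effect; must be >= 1 (when
#'   positive) so planted features pass the |log2FC| > 1 gate in expectation.
#'   0 is allowed for null (calibration) datasets.
#' @param n_triplets Number of planted ceRNA triplets.
#' @param mrnas_per_module mRNAs per planted module; the number of planted
#'   modules is `ceiling(n_triplets / mrnas_per_module)`.
#' @param triplet_strength Target absolute Pearson correlation among module
#'   members, in (0, 1).
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2).
#' @param baseline_mean_range Range of per-feature baseline mean counts;
#'   baselines are drawn log-uniformly within it.
#' @param edge_prob Background interaction-graph edge probability among
#'   mRNAs.
#' @param n_decoy_targets Decoy rows added to each miRNA target table. Decoy
#'   pairs link random miRNAs to features without planted disease signal, so
#'   they exercise the target gate without being confounded by the shared
#'   tumor/normal shift.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pairs = 100L,
                       n_mrna = 600L, n_lncrna = 150L, n_mirna = 80L,
                       n_de_mrna = 100L, n_de_lncrna = 60L, n_de_mirna = 30L,
                       planted_log2fc = 2,
                       n_triplets = 50L,
                       mrnas_per_module = 5L,
                       triplet_strength = 0.7,
                       dispersion = 0.1,
                       baseline_mean_range = c(50, 500),
                       edge_prob = 0.01,
                       n_decoy_targets = 200L,
                       seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs),
              n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              n_de_mrna = as.integer(n_de_mrna),
              n_de_lncrna = as.integer(n_de_lncrna),
              n_de_mirna = as.integer(n_de_mirna),
              planted_log2fc = planted_log2fc,
              n_triplets = as.integer(n_triplets),
              mrnas_per_module = as.integer(mrnas_per_module),
              triplet_strength = triplet_strength,
              dispersion = dispersion,
              baseline_mean_range = baseline_mean_range,
              edge_prob = edge_prob,
              n_decoy_targets = as.integer(n_decoy_targets),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_pos <- function(field) {
    if (length(cfg[[field]]) != 1 || is.na(cfg[[field]]) || cfg[[field]] <= 0)
      stop("invalid simulation config: '", field, "' must be a positive scalar")
  }
  for (f in c("n_pairs", "n_mrna", "n_lncrna", "n_mirna", "mrnas_per_module",
              "dispersion", "edge_prob")) chk_pos(f)
  for (f in c("n_de_mrna", "n_de_lncrna", "n_de_mirna", "n_triplets",
              "n_decoy_targets")) {
    if (cfg[[f]] < 0) stop("invalid simulation config: '", f, "' must be >= 0")
  }
  if (cfg$planted_log2fc != 0 && abs(cfg$planted_log2fc) < 1) {
    stop("invalid simulation config: 'planted_log2fc' must be 0 or >= 1 in ",
         "magnitude so planted features clear the |log2FC| > 1 gate")
  }
  if (cfg$triplet_strength <= 0 || cfg$triplet_strength >= 1) {
    stop("invalid simulation config: 'triplet_strength' must be in (0, 1)")
  }
  if (cfg$n_de_mrna > cfg$n_mrna || cfg$n_de_lncrna > cfg$n_lncrna ||
      cfg$n_de_mirna > cfg$n_mirna) {
    stop("invalid simulation config: planted DE count exceeds class size ",
         "(check 'n_de_mrna'/'n_de_lncrna'/'n_de_mirna')")
  }
  if (cfg$n_triplets > min(cfg$n_de_mrna, cfg$n_de_lncrna)) {
    stop("invalid simulation config: 'n_triplets' exceeds ",
         "min(n_de_mrna, n_de_lncrna); triplet members must be planted DE")
  }
  n_modules <- ceiling(cfg$n_triplets / cfg$mrnas_per_module)
  if (n_modules > min(cfg$n_de_mirna, cfg$n_de_lncrna)) {
    stop("invalid simulation config: ", n_modules, " modules need at least ",
         "as many planted DE miRNAs and lncRNAs ('n_de_mirna'/'n_de_lncrna')")
  }
  if (length(cfg$baseline_mean_range) != 2 ||
      cfg$baseline_mean_range[1] <= 0 ||
      diff(cfg$baseline_mean_range) < 0) {
    stop("invalid simulation config: 'baseline_mean_range' must be an ",
         "increasing positive pair")
  }
  invisible(cfg)
}

#' Generate a synthetic paired dataset with planted ground truth
#'
#' Counts are negative binomial around per-sample latent abundances:
#' log-uniform per-feature baselines, lognormal library sizes (about +/-30%),
#' a mild lognormal per-patient effect shared by the two samples of a pair,
#' a 2^(+/- planted_log2fc) tumor shift for planted DE features, and a
#' per-module shared latent factor scaled so module-member correlations sit
#' near `triplet_strength`.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (named list of feature x sample count
#'   matrices per class: `mrna`, `lncrna`, `mirna`), `metadata` (sample_id,
#'   condition, pair_id), `edges` (interaction edge list with confidence),
#'   `targets_mrna`/`targets_lncrna` (miRNA target tables), and `truth`
#'   (planted DE features with direction, triplets, modules, planted graph
#'   edges).
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  n <- 2L * config$n_pairs
  pair_id <- rep(sprintf("P%03d", seq_len(config$n_pairs)), each = 2L)
  condition <- rep(c("tumor", "normal"), times = config$n_pairs)
  sample_id <- paste0(pair_id, "_", condition)
  metadata <- data.frame(sample_id = sample_id, condition = condition,
                         pair_id = pair_id, stringsAsFactors = FALSE)

  lib <- exp(rnorm(n, 0, 0.15))                 # library-size factors
  patient <- exp(rnorm(config$n_pairs, 0, 0.1)) # per-pair effect
  patient <- patient[match(pair_id, unique(pair_id))]

  ids <- list(mrna = sprintf("MR%04d", seq_len(config$n_mrna)),
              lncrna = sprintf("LNC%04d", seq_len(config$n_lncrna)),
              mirna = sprintf("MIR%04d", seq_len(config$n_mirna)))
  n_de <- c(mrna = config$n_de_mrna, lncrna = config$n_de_lncrna,
            mirna = config$n_de_mirna)

  # planted module layout: module i = 1 miRNA + 1 lncRNA + k mRNAs, drawn
  # from the head of each class's planted-DE block
  n_modules <- if (config$n_triplets > 0)
    as.integer(ceiling(config$n_triplets / config$mrnas_per_module)) else 0L
  mod_mirna <- if (n_modules > 0) ids$mirna[seq_len(n_modules)] else character()
  mod_lncrna <- if (n_modules > 0) ids$lncrna[seq_len(n_modules)] else character()
  mod_of_mrna <- if (config$n_triplets > 0)
    rep(seq_len(n_modules), each = config$mrnas_per_module)[seq_len(config$n_triplets)]
  else integer()
  mod_mrna <- ids$mrna[seq_along(mod_of_mrna)]
  mod_dir <- if (n_modules > 0) rep(c("up", "down"), length.out = n_modules)
  else character()

  # planted DE directions; module members take the module direction, the
  # module miRNA the opposite (negative regulation), the rest random
  direction <- list()
  for (cls in names(ids)) {
    d <- rep("none", length(ids[[cls]]))
    if (n_de[[cls]] > 0) {
      d[seq_len(n_de[[cls]])] <- sample(c("up", "down"), n_de[[cls]],
                                        replace = TRUE)
    }
    direction[[cls]] <- d
  }
  if (n_modules > 0) {
    direction$mrna[seq_along(mod_of_mrna)] <- mod_dir[mod_of_mrna]
    direction$lncrna[seq_len(n_modules)] <- mod_dir
    direction$mirna[seq_len(n_modules)] <- ifelse(mod_dir == "up", "down", "up")
  }

  # per-module latent factor, one value per sample
  z <- if (n_modules > 0) matrix(rnorm(n_modules * n), n_modules, n)
  else matrix(0, 0, n)
  rho <- config$triplet_strength
  lat_scale <- sqrt(rho / (1 - rho))

  tumor <- as.numeric(condition == "tumor")
  counts <- list()
  for (cls in names(ids)) {
    p <- length(ids[[cls]])
    base <- exp(runif(p, log(config$baseline_mean_range[1]),
                      log(config$baseline_mean_range[2])))
    dirnum <- (direction[[cls]] == "up") - (direction[[cls]] == "down")
    # module membership and latent sign for this class
    mod_idx <- rep(0L, p)
    sign_lat <- rep(0, p)
    if (n_modules > 0) {
      if (cls == "mrna" && length(mod_of_mrna) > 0) {
        mod_idx[seq_along(mod_of_mrna)] <- mod_of_mrna
        sign_lat[seq_along(mod_of_mrna)] <- 1
      } else if (cls == "lncrna") {
        mod_idx[seq_len(n_modules)] <- seq_len(n_modules)
        sign_lat[seq_len(n_modules)] <- 1
      } else if (cls == "mirna") {
        mod_idx[seq_len(n_modules)] <- seq_len(n_modules)
        sign_lat[seq_len(n_modules)] <- -1
      }
    }
    # latent coefficient reproducing triplet_strength after counting noise:
    # natural-log noise variance of NB is approx 1/mu + dispersion
    sd_noise <- sqrt(1 / base + config$dispersion)
    a <- sign_lat * lat_scale * sd_noise

    logmu <- matrix(log(base), p, n) +
      matrix(log(2) * config$planted_log2fc * dirnum, p, n) *
        matrix(tumor, p, n, byrow = TRUE) +
      matrix(log(lib * patient), p, n, byrow = TRUE)
    if (n_modules > 0) {
      has_mod <- mod_idx > 0
      if (any(has_mod)) {
        logmu[has_mod, ] <- logmu[has_mod, ] +
          a[has_mod] * z[mod_idx[has_mod], , drop = FALSE]
      }
    }
    cnt <- matrix(rnbinom(p * n, size = 1 / config$dispersion,
                          mu = exp(logmu)), p, n)
    dimnames(cnt) <- list(ids[[cls]], sample_id)
    counts[[cls]] <- cnt
  }

  # interaction graph: a clique among each module's mRNAs (confidence > 700)
  # plus Erdos-Renyi background edges with mixed confidences
  planted_edges <- NULL
  if (config$n_triplets > 0) {
    planted_edges <- do.call(rbind, lapply(seq_len(n_modules), function(m) {
      mem <- mod_mrna[mod_of_mrna == m]
      if (length(mem) < 2) return(NULL)
      pr <- t(combn(mem, 2))
      data.frame(node_a = pr[, 1], node_b = pr[, 2],
                 confidence = sample(750:999, nrow(pr), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }
  bg <- which(upper.tri(matrix(0, config$n_mrna, config$n_mrna)), arr.ind = TRUE)
  keep <- runif(nrow(bg)) < config$edge_prob
  bg <- bg[keep, , drop = FALSE]
  bg_edges <- data.frame(node_a = ids$mrna[bg[, 1]], node_b = ids$mrna[bg[, 2]],
                         confidence = sample(150:1000, nrow(bg), replace = TRUE),
                         stringsAsFactors = FALSE)
  edges <- rbind(planted_edges, bg_edges)
  if (!is.null(edges)) {
    key <- paste(pmin(edges$node_a, edges$node_b),
                 pmax(edges$node_a, edges$node_b))
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(), node_b = character(),
                        confidence = integer(), stringsAsFactors = FALSE)
  }

  # validated-target tables: planted module pairs + decoys among features
  # with no planted signal
  triplets <- if (config$n_triplets > 0) {
    data.frame(mrna_id = mod_mrna, mirna_id = mod_mirna[mod_of_mrna],
               lncrna_id = mod_lncrna[mod_of_mrna], stringsAsFactors = FALSE)
  } else {
    data.frame(mrna_id = character(), mirna_id = character(),
               lncrna_id = character(), stringsAsFactors = FALSE)
  }
  decoy_pairs <- function(targets_pool) {
    if (config$n_decoy_targets == 0 || length(targets_pool) == 0)
      return(data.frame(mirna_id = character(), target_id = character(),
                        stringsAsFactors = FALSE))
    data.frame(mirna_id = sample(ids$mirna, config$n_decoy_targets,
                                 replace = TRUE),
               target_id = sample(targets_pool, config$n_decoy_targets,
                                  replace = TRUE),
               stringsAsFactors = FALSE)
  }
  null_mrna <- ids$mrna[direction$mrna == "none"]
  null_lncrna <- ids$lncrna[direction$lncrna == "none"]
  targets_mrna <- unique(rbind(
    data.frame(mirna_id = triplets$mirna_id, target_id = triplets$mrna_id,
               stringsAsFactors = FALSE),
    decoy_pairs(null_mrna)))
  targets_lncrna <- unique(rbind(
    data.frame(mirna_id = triplets$mirna_id, target_id = triplets$lncrna_id,
               stringsAsFactors = FALSE),
    decoy_pairs(null_lncrna)))
  rownames(targets_mrna) <- rownames(targets_lncrna) <- NULL

  de_features <- do.call(rbind, lapply(names(ids), function(cls) {
    sel <- direction[[cls]] != "none"
    if (!any(sel)) return(NULL)
    data.frame(feature_id = ids[[cls]][sel], class = cls,
               direction = direction[[cls]][sel], stringsAsFactors = FALSE)
  }))
  if (is.null(de_features)) {
    de_features <- data.frame(feature_id = character(), class = character(),
                              direction = character(), stringsAsFactors = FALSE)
  }
  modules <- lapply(seq_len(n_modules), function(m) {
    list(mirna_id = mod_mirna[m], direction = mod_dir[m],
         mrna_ids = mod_mrna[mod_of_mrna == m], lncrna_ids = mod_lncrna[m])
  })

  truth <- list(de_features = de_features, triplets = triplets,
                modules = modules,
                graph_edges = if (is.null(planted_edges))
                  data.frame(node_a = character(), node_b = character(),
                             confidence = integer(), stringsAsFactors = FALSE)
                else planted_edges)

  list(counts = counts, metadata = metadata, edges = edges,
       targets_mrna = targets_mrna, targets_lncrna = targets_lncrna,
       truth = truth, config = config)
}

#' Write a synthetic dataset to a directory
#'
#' Emits per-class count TSVs, sample metadata, the interaction edge list,
#' the two miRNA target tables, and the planted ground truth as JSON.
#' [read_dataset()] round-trips the files exactly.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mrna = file.path(dir, "counts_mrna.tsv"),
    lncrna = file.path(dir, "counts_lncrna.tsv"),
    mirna = file.path(dir, "counts_mirna.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    edges = file.path(dir, "edges.tsv"),
    targets_mrna = file.path(dir, "targets_mrna.tsv"),
    targets_lncrna = file.path(dir, "targets_lncrna.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  for (cls in c("mrna", "lncrna", "mirna")) {
    write_expression(dataset$counts[[cls]], paths[[cls]])
  }
  write_tsv(dataset$metadata, paths[["metadata"]])
  write_tsv(dataset$edges, paths[["edges"]])
  write_tsv(dataset$targets_mrna, paths[["targets_mrna"]])
  write_tsv(dataset$targets_lncrna, paths[["targets_lncrna"]])
  truth <- dataset$truth
  jsonlite::write_json(
    list(de_features = truth$de_features,
         triplets = truth$triplets,
         modules = truth$modules,
         graph_edges = truth$graph_edges),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Directory holding the files.
#' @return The same structure [generate_dataset()] returns (minus `config`).
#' @export
read_dataset <- function(dir) {
  counts <- list(
    mrna = read_expression(file.path(dir, "counts_mrna.tsv")),
    lncrna = read_expression(file.path(dir, "counts_lncrna.tsv")),
    mirna = read_expression(file.path(dir, "counts_mirna.tsv")))
  tj <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE, simplifyDataFrame = TRUE)
  modules <- tj$modules
  if (is.data.frame(modules)) {
    modules <- lapply(seq_len(nrow(modules)), function(i) {
      list(mirna_id = modules$mirna_id[i], direction = modules$direction[i],
           mrna_ids = unlist(modules$mrna_ids[i]),
           lncrna_ids = unlist(modules$lncrna_ids[i]))
    })
  } else if (is.null(modules)) modules <- list()
  as_df <- function(x, cols) {
    if (is.null(x) || length(x) == 0) {
      setNames(as.data.frame(replicate(length(cols), character(),
                                       simplify = FALSE)), cols)
    } else as.data.frame(x, stringsAsFactors = FALSE)
  }
  truth <- list(de_features = as_df(tj$de_features,
                                    c("feature_id", "class", "direction")),
                triplets = as_df(tj$triplets,
                                 c("mrna_id", "mirna_id", "lncrna_id")),
                modules = modules,
                graph_edges = as_df(tj$graph_edges,
                                    c("node_a", "node_b", "confidence")))
  list(counts = counts,
       metadata = read_metadata(file.path(dir, "metadata.tsv")),
       edges = read_edge_list(file.path(dir, "edges.tsv")),
       targets_mrna = read_targets(file.path(dir, "targets_mrna.tsv")),
       targets_lncrna = read_targets(file.path(dir, "targets_lncrna.tsv")),
       truth = truth)
}
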