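#' @importFrom stats cor.test p.adjust rnorm rbinom rnbinom runif predict
#'   pnorm qlogis quantile median sd glm binomial setNames complete.cases
#' @importFrom utils read.delim write.table head combn
NULL

# All on-disk tables are TSV, UTF-8, no quoting; gene identifiers are opaque
# strings. Readers validate and fail with row/column context.

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers. Values may be counts (integers) or normalized abundances.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, features in rows, samples in columns.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("expression file has no columns: ", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicated feature id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) > 0 && ncol(m) > 0 && !is.numeric(m)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 2, is.numeric))
    stop("non-numeric expression column(s) in ", path, ": ",
         paste(names(bad), collapse = ", "))
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: first column `feature_id`, then one column
#' per sample.
#'
#' @param mat Numeric matrix with feature row names and sample column names.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Columns: `sample_id`, `condition` (`tumor`/`normal`), `pair_id`.
#'
#' @param path Path to a tab-separated metadata file.
#' @return data.frame with the three required columns.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "pair_id")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("metadata ", path, " missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in ", path)
  bad <- setdiff(unique(df$condition), c("tumor", "normal"))
  if (length(bad) > 0) {
    stop("metadata condition must be tumor/normal, found: ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Read a miRNA target table
#'
#' Two tab-separated columns, `mirna_id` and `target_id`, one validated
#' miRNA-target pair per row. Duplicate rows are collapsed.
#'
#' @param path Path to the table.
#' @return data.frame with columns `mirna_id`, `target_id` (de-duplicated).
#' @export
read_targets <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) != 2) {
    stop("target table ", path, " must have exactly 2 columns, has ", ncol(df))
  }
  names(df) <- c("mirna_id", "target_id")
  bad <- which(is.na(df$mirna_id) | is.na(df$target_id) |
                 df$mirna_id == "" | df$target_id == "")
  if (length(bad) > 0) {
    stop("malformed target row at line ", bad[1] + 1L, " of ", path)
  }
  out <- unique(df)
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("target table ", path, " is empty")
  out
}

#' Read a weighted interaction edge list
#'
#' Tab-separated columns `node_a`, `node_b`, `confidence` with confidence on
#' the STRING 0-1000 integer scale.
#'
#' @param path Path to the edge list.
#' @return data.frame with columns `node_a`, `node_b`, `confidence`.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("node_a", "node_b", "confidence")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("edge list ", path, " missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) df$confidence <- as.numeric(df$confidence)
  if (!is.numeric(df$confidence)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$confidence))))
    stop("non-numeric confidence at line ", bad[1] + 1L, " of ", path)
  }
  df[req]
}

#' Write a generic data.frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All filtering thresholds default to the published protocol: fold-change
#' gate |log2FC| > 1 with BH FDR < 0.05; 50 rounds of 4/5 pair subsampling for
#' mRNA/lncRNA stability selection; interaction confidence > 700 with
#' co-expression p < 0.05; candidate hubs at MCC > 8 and attribution
#' score > 1e-4; potential ceRNAs at attribution score > 1e-4.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    de_log2fc = 1,
    de_fdr = 0.05,
    stability_rounds = 50L,
    stability_fraction = 0.8,
    confidence = 700,
    corr_p = 0.05,
    shap_threshold = 1e-4,
    mcc_threshold = 8,
    hidden_mrna = c(400L, 100L),
    hidden_cerna = c(400L, 100L, 40L),
    batch_size = 16L,
    epochs = 200L,
    learning_rate = 1e-4,
    split_fraction = 0.7,
    n_repeats = 50L,
    seed = 42L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] fields.
#' @return `pipeline_config` list.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Write a run manifest
#'
#' Records package version, seeds, thresholds and output files of a pipeline
#' run as JSON so a run can be audited and reproduced.
#'
#' @param manifest Named list.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
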