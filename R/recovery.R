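# Recovery metrics against the planted ground truth of a synthetic
# dataset: how much of the planted structure the pipeline got back.

triplet_key <- function(df) {
  paste(df$mrna_id, df$mirna_id, df$lncrna_id, sep = "|")
}

#' Triplet recovery against planted ground truth
#'
#' @param screened data.frame from [screen_triplets()].
#' @param truth Ground-truth list from [generate_dataset()] (uses
#'   `truth$triplets`).
#' @return List: `recall`, `precision`, `n_true`, `n_screened`, `n_hit`.
#' @export
triplet_recovery <- function(screened, truth) {
  true_keys <- triplet_key(truth$triplets)
  got_keys <- triplet_key(screened)
  hit <- intersect(true_keys, got_keys)
  list(recall = if (length(true_keys) > 0) length(hit) / length(true_keys)
       else NA_real_,
       precision = if (length(got_keys) > 0) length(hit) / length(got_keys)
       else NA_real_,
       n_true = length(true_keys), n_screened = length(got_keys),
       n_hit = length(hit))
}

#' Module recovery against planted ground truth
#'
#' Matches each planted module to the extracted module with the same miRNA
#' and direction, and scores the member overlap (mRNAs + lncRNAs) by
#' Jaccard index. Also reports whether every planted miRNA produced a
#' module and the pooled member recall.
#'
#' @param modules Extracted modules from [extract_modules()].
#' @param truth Ground-truth list from [generate_dataset()] (uses
#'   `truth$modules`).
#' @return List: `per_module` (data.frame mirna_id, jaccard, found),
#'   `all_mirnas_found`, `pooled_recall`, `mean_jaccard`.
#' @export
module_recovery <- function(modules, truth) {
  tm <- truth$modules
  if (length(tm) == 0) {
    return(list(per_module = data.frame(), all_mirnas_found = NA,
                pooled_recall = NA_real_, mean_jaccard = NA_real_))
  }
  got_by_mirna <- split(modules,
                        vapply(modules, function(m) m$mirna_id, ""))
  n_hit <- 0L
  n_planted <- 0L
  rows <- lapply(tm, function(t) {
    planted <- c(t$mrna_ids, t$lncrna_ids)
    n_planted <<- n_planted + length(planted)
    cand <- got_by_mirna[[t$mirna_id]]
    if (is.null(cand)) {
      return(data.frame(mirna_id = t$mirna_id, jaccard = 0, found = FALSE,
                        stringsAsFactors = FALSE))
    }
    # planted module direction is the targets' shared direction
    dir_match <- Filter(function(m) m$direction == t$direction, cand)
    if (length(dir_match) == 0) dir_match <- cand
    jac <- vapply(dir_match, function(m) {
      got <- c(m$mrna_ids, m$lncrna_ids)
      length(intersect(got, planted)) / length(union(got, planted))
    }, 0)
    best <- dir_match[[which.max(jac)]]
    n_hit <<- n_hit + length(intersect(c(best$mrna_ids, best$lncrna_ids),
                                       planted))
    data.frame(mirna_id = t$mirna_id, jaccard = max(jac), found = TRUE,
               stringsAsFactors = FALSE)
  })
  per_module <- do.call(rbind, rows)
  list(per_module = per_module,
       all_mirnas_found = all(per_module$found),
       pooled_recall = n_hit / n_planted,
       mean_jaccard = mean(per_module$jaccard))
}
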