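# TMM normalization and stability-selected differential expression.
# Thresholds follow the published protocol: |log2FC| > 1 and BH FDR < 0.05,
# with 50 rounds of 4/5 pair subsampling and intersection for mRNA/lncRNA
# and a single pass for miRNA.

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample TMM factors (reference sample chosen by upper-quartile
#' proximity, 30% two-sided M-trim, 5% A-trim, precision weights), rescaled
#' to geometric mean 1. Computation is delegated to edgeR's TMM
#' implementation; the test suite checks it against an independent
#' from-scratch trimmed-mean oracle.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @param weighted Use the delta-method precision weights (the default).
#'   The unweighted trimmed mean is exactly invariant to rescaling a single
#'   library; the weighted one is invariant only to global rescaling.
#' @return Numeric vector of factors, one per sample (names = sample names).
#' @export
compute_tmm_factors <- function(counts, weighted = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  libs <- colSums(counts, na.rm = TRUE)
  if (any(libs == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[libs == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              doWeighting = weighted)
  names(f) <- colnames(counts)
  f
}

#' Normalized log2 counts-per-million
#'
#' `log2(CPM + 0.5)` with `CPM = count / (library_size * factor) * 1e6`.
#' The pseudocount sits on the CPM scale so the result is exactly invariant
#' to rescaling any library (counts and library size scale together); zero
#' counts map to the finite floor `log2(0.5)`.
#'
#' @param counts Count matrix, features x samples.
#' @param factors Per-sample factors from [compute_tmm_factors()].
#' @return Matrix of log2-CPM values with the dimensions of `counts`.
#' @export
normalize_logcpm <- function(counts, factors) {
  counts <- as.matrix(counts)
  if (length(factors) != ncol(counts)) {
    stop("length(factors) [", length(factors), "] != ncol(counts) [",
         ncol(counts), "]")
  }
  eff <- colSums(counts, na.rm = TRUE) * factors
  cpm <- sweep(counts, 2, eff, "/") * 1e6
  log2(cpm + 0.5)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, clipped at 1.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(pvalues, method = "BH")
}

#' Paired Wilcoxon signed-rank test across features
#'
#' Row-wise signed-rank test on per-pair differences using the normal
#' approximation with tie correction and continuity correction (the same
#' approximation `wilcox.test(exact = FALSE)` uses). Features whose
#' differences are all zero get p = 1.
#'
#' @param d Matrix of per-pair differences, features x pairs.
#' @return Two-sided p-value per feature.
#' @export
paired_wilcoxon_p <- function(d) {
  d <- as.matrix(d)
  apply(d, 1L, function(x) {
    x <- x[!is.na(x) & x != 0]
    n <- length(x)
    if (n == 0) return(1)
    r <- rank(abs(x))
    v <- sum(r[x > 0])
    z <- v - n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) return(1)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  })
}

#' Drop features with too many missing values
#'
#' Mirrors the published quality-control rule: RNA-Seq features with more
#' than 1/3 missing samples, or miRNA features with more than 2 missing
#' samples, are removed. "Missing" means NA, not zero.
#'
#' @param counts Count matrix (may contain NA).
#' @param class RNA class; `"mirna"` uses the absolute-2 rule, anything else
#'   the 1/3 rule.
#' @return The filtered matrix.
#' @export
filter_missing <- function(counts, class = c("mrna", "lncrna", "mirna")) {
  class <- match.arg(class)
  n_missing <- rowSums(is.na(counts))
  keep <- if (class == "mirna") n_missing <= 2 else n_missing <= ncol(counts) / 3
  counts[keep, , drop = FALSE]
}

# pairs metadata into an ordered (tumor column, normal column) index table
pair_index <- function(counts, design) {
  miss <- setdiff(design$sample_id, colnames(counts))
  if (length(miss) > 0) {
    stop("sample(s) in design absent from counts: ",
         paste(miss, collapse = ", "))
  }
  pairs <- unique(design$pair_id)
  idx <- lapply(pairs, function(p) {
    rows <- design[design$pair_id == p, ]
    tu <- rows$sample_id[rows$condition == "tumor"]
    no <- rows$sample_id[rows$condition == "normal"]
    if (length(tu) != 1 || length(no) != 1) {
      stop("pair ", p, " must have exactly one tumor and one normal sample")
    }
    c(match(tu, colnames(counts)), match(no, colnames(counts)))
  })
  m <- do.call(rbind, idx)
  dimnames(m) <- list(pairs, c("tumor", "normal"))
  m
}

#' Paired differential-expression test
#'
#' TMM-normalizes, computes per-feature log2 fold change as the mean
#' tumor-minus-normal log-CPM difference, tests it with a pluggable paired
#' statistic (default: [paired_wilcoxon_p()]), BH-adjusts, and assigns an
#' up/down/none direction under the thresholds |log2FC| > `lfc_threshold`
#' and FDR < `fdr_threshold`.
#'
#' @param counts Count matrix, features x samples (NA allowed before
#'   filtering; this function assumes filtering already happened).
#' @param design data.frame with `sample_id`, `condition`, `pair_id`.
#' @param lfc_threshold Fold-change gate on |log2FC| (default 1).
#' @param fdr_threshold FDR gate (default 0.05).
#' @param engine Function of the per-pair log-CPM difference matrix
#'   returning a p-value per feature.
#' @return data.frame (`de_table`): `feature_id`, `log2fc`, `pvalue`, `fdr`,
#'   `direction`.
#' @export
test_differential <- function(counts, design, lfc_threshold = 1,
                              fdr_threshold = 0.05,
                              engine = paired_wilcoxon_p) {
  idx <- pair_index(counts, design)
  if (nrow(idx) < 3) stop("need at least 3 pairs, got ", nrow(idx))
  f <- compute_tmm_factors(counts)
  lc <- normalize_logcpm(counts, f)
  d <- lc[, idx[, "tumor"], drop = FALSE] - lc[, idx[, "normal"], drop = FALSE]
  log2fc <- rowMeans(d)
  pvalue <- engine(d)
  fdr <- bh_adjust(pvalue)
  sig <- abs(log2fc) > lfc_threshold & fdr < fdr_threshold
  direction <- ifelse(sig & log2fc > 0, "up",
                      ifelse(sig & log2fc < 0, "down", "none"))
  data.frame(feature_id = rownames(counts), log2fc = log2fc, pvalue = pvalue,
             fdr = fdr, direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Stability selection by repeated pair subsampling
#'
#' Runs [test_differential()] on `rounds` random subsamples of
#' `ceiling(fraction * n_pairs)` pairs (both members of a pair always kept
#' together) and intersects the significant feature sets over all rounds.
#' With `rounds = 1, fraction = 1` this reduces to a single-pass analysis.
#'
#' @inheritParams test_differential
#' @param rounds Number of subsampling rounds (protocol default 50).
#' @param fraction Fraction of pairs kept per round (protocol default 4/5).
#' @param seed Master seed; each round gets a derived child seed.
#' @return List: `stable` (feature ids significant in every round),
#'   `per_round` (list of per-round significant sets), `seeds` (child seeds).
#' @export
stability_select <- function(counts, design, rounds = 50L, fraction = 0.8,
                             seed = 1L, lfc_threshold = 1,
                             fdr_threshold = 0.05,
                             engine = paired_wilcoxon_p) {
  if (rounds < 1) stop("rounds must be >= 1")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  pairs <- unique(design$pair_id)
  k <- ceiling(fraction * length(pairs))
  if (k < 3) stop("subsample of ", k, " pairs is below the 3-pair minimum")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  child_seeds <- sample.int(2147483647L, rounds)
  per_round <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    set.seed(child_seeds[r])
    sub_pairs <- sample(pairs, k)
    sub_design <- design[design$pair_id %in% sub_pairs, , drop = FALSE]
    sub_counts <- counts[, sub_design$sample_id, drop = FALSE]
    tab <- test_differential(sub_counts, sub_design, lfc_threshold,
                             fdr_threshold, engine)
    per_round[[r]] <- tab$feature_id[tab$direction != "none"]
  }
  stable <- Reduce(intersect, per_round)
  list(stable = stable, per_round = per_round, seeds = child_seeds)
}

#' Full differential-expression stage for one RNA class
#'
#' Single-pass [test_differential()] on all pairs plus, for mRNA/lncRNA,
#' stability selection; the returned table carries a `stable` flag (for
#' miRNA, single-pass significance per the protocol).
#'
#' @inheritParams stability_select
#' @param class RNA class label added to the table; `"mirna"` switches off
#'   subsampling (single-pass analysis).
#' @param stability Whether to run the subsampling intersection; defaults to
#'   TRUE except for miRNA.
#' @return `de_table` data.frame with columns `feature_id`, `class`,
#'   `log2fc`, `pvalue`, `fdr`, `direction`, `stable`.
#' @export
run_de <- function(counts, design, class = "mrna", rounds = 50L,
                   fraction = 0.8, seed = 1L, lfc_threshold = 1,
                   fdr_threshold = 0.05, stability = class != "mirna",
                   engine = paired_wilcoxon_p) {
  counts <- filter_missing(counts, if (class == "mirna") "mirna" else "mrna")
  counts[is.na(counts)] <- 0
  tab <- test_differential(counts, design, lfc_threshold, fdr_threshold,
                           engine)
  if (stability) {
    sel <- stability_select(counts, design, rounds, fraction, seed,
                            lfc_threshold, fdr_threshold, engine)
    stable <- tab$feature_id %in% sel$stable
  } else {
    stable <- tab$direction != "none"
  }
  cbind(tab[, "feature_id", drop = FALSE],
        class = class,
        tab[, c("log2fc", "pvalue", "fdr", "direction")],
        stable = stable,
        stringsAsFactors = FALSE)
}
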