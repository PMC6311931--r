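# ChIP-seq-based evaluation: a gold standard per (TF, cell line) truncated
# at the median size M of three gene sets, ROC/AUC against it, overlap
# scores, relative changes, and exact binomial summaries.

#' Build a ChIP-seq gold standard for one TF in one cell line
#'
#' Peaks are mapped into promoter windows; each gene hit becomes a
#' candidate with score = max over its overlapping peaks. M is the median
#' of three set sizes: the candidates, the refined network's targets and
#' the preliminary network's targets. Positives are the top-M candidates by
#' score (descending), ties at the boundary broken by gene id (ascending).
#'
#' @param peaks Peak table (`chrom`, `start`, `end`, `score`).
#' @param genes Gene-model table.
#' @param mrf_targets,prelim_targets Character vectors of target genes of
#'   the TF in the refined / preliminary network for this cell line.
#' @param halfwidth Promoter half-width (default 2000).
#' @param tf_id,cell_line Optional identifiers carried along.
#' @return Object of class `gold_standard`: `M`, `positives`,
#'   `candidate_scores` (named numeric vector), `tf_id`, `cell_line`.
#' @export
build_gold_standard <- function(peaks, genes, mrf_targets, prelim_targets,
                                halfwidth = 2000L, tf_id = NULL,
                                cell_line = NULL) {
  windows <- promoter_windows(genes, halfwidth)
  if (nrow(peaks) == 0) stop("no candidate target genes (no peaks)")
  hits <- GenomicRanges::findOverlaps(
    .granges(peaks$chrom, peaks$start, peaks$end),
    .granges(windows$chrom, windows$start, windows$end),
    minoverlap = 1L)
  if (length(hits) == 0) stop("no candidate target genes (no peak in a promoter)")
  df <- data.frame(gene = windows$gene_id[S4Vectors::subjectHits(hits)],
                   score = peaks$score[S4Vectors::queryHits(hits)])
  sc <- tapply(df$score, df$gene, max)
  candidates <- stats::setNames(as.numeric(sc), names(sc))
  M <- as.integer(stats::median(c(length(candidates), length(unique(mrf_targets)),
                                  length(unique(prelim_targets)))))
  ord <- order(-candidates, names(candidates))
  positives <- names(candidates)[ord][seq_len(min(M, length(candidates)))]
  structure(list(tf_id = tf_id, cell_line = cell_line, M = M,
                 positives = positives, candidate_scores = candidates),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> ", x$tf_id %||% "?", " / ", x$cell_line %||% "?",
      ": M = ", x$M, ", ", length(x$positives), " positives of ",
      length(x$candidate_scores), " candidates\n", sep = "")
  invisible(x)
}

#' ROC AUC with midrank tie handling
#'
#' Positives are the gold-standard genes, negatives all remaining universe
#' genes; genes without a score get 0. The AUC is the Wilcoxon midrank
#' statistic, so tied scores earn half credit.
#'
#' @param scores Named numeric vector of regulatory probabilities.
#' @param positives Character vector of positive genes (subset of universe).
#' @param universe Character vector of all evaluable genes.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, positives, universe) {
  positives <- intersect(positives, universe)
  negatives <- setdiff(universe, positives)
  if (length(positives) == 0 || length(negatives) == 0)
    stop("need at least one positive and one negative")
  s <- stats::setNames(rep(0, length(universe)), universe)
  common <- intersect(names(scores), universe)
  s[common] <- scores[common]
  r <- rank(s)                             # midranks
  np <- length(positives); nn <- length(negatives)
  (sum(r[positives]) - np * (np + 1) / 2) / (np * nn)
}

#' Overlap between a network's top-M targets and the gold standard
#'
#' @param network_targets_topM Character vector: the network's targets for
#'   the TF truncated to the top M by refined probability.
#' @param gold [build_gold_standard()] object.
#' @return Integer overlap count.
#' @export
overlap_score <- function(network_targets_topM, gold) {
  length(intersect(unique(network_targets_topM), gold$positives))
}

#' Relative change (new - old) / old
#'
#' @param new,old Numeric scalars (vectorised). `old = 0` yields `NA` with
#'   a warning; such records are excluded from improvement counts.
#' @return Relative change.
#' @export
relative_change <- function(new, old) {
  out <- ifelse(old == 0, NA_real_, (new - old) / old)
  if (anyNA(out)) warning("relative change undefined where old = 0; NA returned")
  out
}

#' One-sided exact binomial tail P(X >= k)
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability (default 0.5).
#' @return Upper-tail p-value.
#' @export
binomial_test_one_sided <- function(k, n, p0 = 0.5) {
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Truncate a network's targets for a TF to the top M by probability
#'
#' Ties at the boundary are broken by gene id (ascending) after score.
#'
#' @param edges Edge table with `gene_id` and `probability` (one TF, one
#'   cell line).
#' @param M Truncation rank.
#' @return Character vector of at most M gene ids.
#' @export
top_m_targets <- function(edges, M) {
  if (nrow(edges) == 0) return(character())
  ord <- order(-edges$probability, edges$gene_id)
  edges$gene_id[ord][seq_len(min(M, nrow(edges)))]
}

#' Aggregate evaluation records to TF level
#'
#' Arithmetic mean of each relative-change criterion over the cell lines of
#' each TF.
#'
#' @param records Data frame with `tf_id` and one or more `rel_change_*`
#'   columns.
#' @return Data frame, one row per TF, with the per-TF means.
#' @export
aggregate_tf_level <- function(records) {
  cols <- grep("^rel_change", names(records), value = TRUE)
  if (length(cols) == 0) stop("no rel_change_* columns")
  out <- stats::aggregate(records[cols], by = list(tf_id = records$tf_id),
                          FUN = function(v) mean(v, na.rm = TRUE))
  out[order(out$tf_id), , drop = FALSE]
}

#' Improvement summary with exact binomial support
#'
#' Counts evaluations whose relative change is strictly positive and tests
#' the count against a fair coin with the one-sided exact binomial tail.
#'
#' @param rel_changes Numeric vector of relative changes (`NA`s excluded).
#' @return List with `k_improved`, `n_total`, `percent` (100 k / n) and
#'   `p_value`.
#' @export
improvement_summary <- function(rel_changes) {
  rel_changes <- rel_changes[!is.na(rel_changes)]
  n <- length(rel_changes)
  if (n == 0) stop("no evaluable records")
  k <- sum(rel_changes > 0)
  list(k_improved = k, n_total = n, percent = 100 * k / n,
       p_value = binomial_test_one_sided(k, n, 0.5))
}
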