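# Downstream analyses: tissue-level merging, network comparison,
# differential regulation, Fisher/GSEA-style enrichment, and hierarchical
# clustering of networks or expression-based similarities.

#' Merge cell-line networks into a tissue network
#'
#' Edge union of the called edges of the member networks, with a support
#' count (number of member networks containing each edge).
#'
#' @param networks List of [cell_line_network()] objects.
#' @param tissue_id Optional tissue label.
#' @return Object of class `tissue_network`: `tissue_id`, `cell_lines`,
#'   `edges` (data frame `tf_id`, `gene_id`, `support`).
#' @export
merge_tissue <- function(networks, tissue_id = NULL) {
  if (length(networks) == 0) stop("need >= 1 network")
  all_edges <- do.call(rbind, lapply(networks, function(nw)
    unique(nw$edges[, c("tf_id", "gene_id"), drop = FALSE])))
  if (is.null(all_edges) || nrow(all_edges) == 0) {
    edges <- data.frame(tf_id = character(), gene_id = character(),
                        support = integer())
  } else {
    key <- paste(all_edges$tf_id, all_edges$gene_id, sep = "\r")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    edges <- data.frame(tf_id = parts[, 1], gene_id = parts[, 2],
                        support = as.integer(tab), stringsAsFactors = FALSE)
    edges <- edges[order(edges$tf_id, edges$gene_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(tissue_id = tissue_id,
                 cell_lines = vapply(networks, `[[`, "", "cell_line"),
                 edges = edges),
            class = "tissue_network")
}

#' @export
print.tissue_network <- function(x, ...) {
  cat("<tissue_network> ", x$tissue_id %||% "?", ": ",
      length(x$cell_lines), " cell lines, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Node, edge and degree summary of a network
#'
#' Mean in-degree = edges / distinct target genes; mean out-degree =
#' edges / distinct TFs; nodes = TFs union targets.
#'
#' @param net A `tissue_network` or [cell_line_network()].
#' @return List with `n_nodes`, `n_edges`, `mean_in_degree`,
#'   `mean_out_degree`.
#' @export
degree_summary <- function(net) {
  e <- net$edges
  if (nrow(e) == 0) stop("empty network")
  n_edges <- nrow(unique(e[, c("tf_id", "gene_id")]))
  tfs <- unique(e$tf_id); tg <- unique(e$gene_id)
  list(n_nodes = length(union(tfs, tg)), n_edges = n_edges,
       mean_in_degree = n_edges / length(tg),
       mean_out_degree = n_edges / length(tfs))
}

.edge_keys <- function(x) {
  if (is.data.frame(x)) paste(x$tf_id, x$gene_id, sep = "\r") else x
}

#' Jaccard similarity of two edge sets
#'
#' @param e1,e2 Edge sets: either character keys or data frames with
#'   `tf_id`/`gene_id`.
#' @return `|E1 n E2| / |E1 u E2|`; 0 (with a warning) if both are empty.
#' @export
network_jaccard <- function(e1, e2) {
  k1 <- unique(.edge_keys(e1)); k2 <- unique(.edge_keys(e2))
  u <- length(union(k1, k2))
  if (u == 0) { warning("both edge sets empty"); return(0) }
  length(intersect(k1, k2)) / u
}

#' Per-TF Jaccard distance between two conditions
#'
#' `1 - |T_A n T_B| / |T_A u T_B|` for the TF's target sets in conditions A
#' and B, plus the differential edge count `|T_A symmetric-difference T_B|`.
#'
#' @param targets_a,targets_b Character vectors of target genes.
#' @return List with `distance` and `n_differential`; `NULL` if both sets
#'   are empty (undefined).
#' @export
tf_target_jaccard_distance <- function(targets_a, targets_b) {
  a <- unique(targets_a); b <- unique(targets_b)
  u <- length(union(a, b))
  if (u == 0) return(NULL)
  inter <- length(intersect(a, b))
  list(distance = 1 - inter / u, n_differential = u - inter)
}

#' Differential network between two conditions
#'
#' Symmetric difference of the called edge sets, annotated with the
#' condition each edge came from.
#'
#' @param edges_a,edges_b Edge data frames (`tf_id`, `gene_id`).
#' @param conditions Length-2 labels.
#' @return Object of class `differential_network` with `edges` (data frame
#'   `tf_id`, `gene_id`, `condition`).
#' @export
differential_network <- function(edges_a, edges_b,
                                 conditions = c("A", "B")) {
  ka <- unique(.edge_keys(edges_a)); kb <- unique(.edge_keys(edges_b))
  only_a <- setdiff(ka, kb); only_b <- setdiff(kb, ka)
  keys <- c(only_a, only_b)
  parts <- if (length(keys))
    do.call(rbind, strsplit(keys, "\r", fixed = TRUE)) else
    matrix(character(), 0, 2)
  edges <- data.frame(tf_id = parts[, 1], gene_id = parts[, 2],
                      condition = rep(conditions, c(length(only_a),
                                                    length(only_b))),
                      stringsAsFactors = FALSE)
  structure(list(conditions = conditions, edges = edges),
            class = "differential_network")
}

#' Rank genes by number of differential incoming edges
#'
#' @param diff [differential_network()].
#' @return Data frame `gene_id`, `n_differential_edges`, sorted
#'   descending, ties broken by gene id.
#' @export
rank_differential_targets <- function(diff) {
  if (nrow(diff$edges) == 0)
    return(data.frame(gene_id = character(), n_differential_edges = integer()))
  tab <- table(diff$edges$gene_id)
  out <- data.frame(gene_id = names(tab),
                    n_differential_edges = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_differential_edges, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher's exact enrichment test of targets in a gene set
#'
#' One-sided (enrichment) exact test of the 2x2 table
#' (in targets & in term, in targets only, in term only, neither) over the
#' gene universe.
#'
#' @param targets,term_genes Character vectors, subsets of `universe`.
#' @param universe Character vector of all genes.
#' @return List with `table` (2x2 matrix), `odds_ratio` (conditional MLE),
#'   `p`.
#' @export
fisher_go_enrichment <- function(targets, term_genes, universe) {
  if (length(universe) == 0) stop("empty universe")
  targets <- intersect(unique(targets), universe)
  term_genes <- intersect(unique(term_genes), universe)
  a <- length(intersect(targets, term_genes))
  b <- length(targets) - a
  cc <- length(term_genes) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(target = c("yes", "no"),
                                term = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Proportion of BH-significant enrichment tests
#'
#' Benjamini-Hochberg across the test collection; the score is the
#' fraction of tests with adjusted p <= `fdr`. With `mode = "positive"`
#' tests are first restricted to terms annotated to each test's TF.
#'
#' @param tests Data frame with a `p` column (and `tf_id`, `term_id` for
#'   positive mode).
#' @param mode `"total"` (all tests) or `"positive"`.
#' @param fdr FDR level (default 0.2).
#' @param tf_annotation For positive mode: named list, TF id -> character
#'   vector of its annotated term ids.
#' @return Proportion in \[0, 1\].
#' @export
enrichment_score <- function(tests, mode = c("total", "positive"),
                             fdr = 0.2, tf_annotation = NULL) {
  mode <- match.arg(mode)
  if (mode == "positive") {
    if (is.null(tf_annotation)) stop("positive mode needs tf_annotation")
    keep <- mapply(function(tf, term)
      term %in% (tf_annotation[[tf]] %||% character()),
      tests$tf_id, tests$term_id)
    tests <- tests[keep, , drop = FALSE]
  }
  if (nrow(tests) == 0) stop("zero tests")
  adj <- stats::p.adjust(tests$p, method = "BH")
  mean(adj <= fdr)
}

#' GSEA-style rank-set enrichment with permutation p-value
#'
#' Weighted Kolmogorov-Smirnov running sum over genes sorted by score
#' (descending): members advance by `|score| / sum(|score| of members)`,
#' non-members retreat by `1 / (N - Nh)`. Tied scores are processed as one
#' block so the statistic does not depend on the order within ties (all
#' scores equal gives ES = 0). The enrichment score is the maximum of the
#' running sum; the p-value is the add-one fraction of seeded random member
#' sets with ES >= observed.
#'
#' @param gene_scores Named numeric vector (e.g. association scores).
#' @param target_set Character vector, subset of the scored genes.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutations.
#' @return List with `es` and `p`.
#' @export
rank_set_enrichment <- function(gene_scores, target_set, n_perm = 1000L,
                                seed = 1L) {
  target_set <- unique(target_set)
  if (length(target_set) == 0) stop("empty target set")
  if (!all(target_set %in% names(gene_scores)))
    stop("target set contains unscored genes")
  if (n_perm < 100) stop("n_perm must be >= 100")
  nh <- length(target_set)
  n <- length(gene_scores)
  if (nh >= n) stop("target set must be a proper subset of scored genes")
  ord <- order(-gene_scores, names(gene_scores))
  sc <- gene_scores[ord]
  is_block_end <- c(sc[-n] != sc[-1], TRUE)
  es_of <- function(member) {
    hit <- abs(sc) * member
    denom_h <- sum(hit)
    step <- if (denom_h > 0) hit / denom_h else rep(0, n)
    step <- step - (1 - member) / (n - nh)
    run <- cumsum(step)
    max(c(0, run[is_block_end]))
  }
  member_obs <- as.numeric(names(sc) %in% target_set)
  es <- es_of(member_obs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    member <- numeric(n)
    member[sample.int(n, nh)] <- 1
    if (es_of(member) >= es) hits <- hits + 1L
  }
  list(es = es, p = (1 + hits) / (n_perm + 1))
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return An `hclust` object.
#' @export
hclust_average <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have zero diagonal")
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Serialise a dendrogram as a Newick string
#'
#' @param hc `hclust` object (e.g. from [hclust_average()]).
#' @return Newick string with branch lengths.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
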