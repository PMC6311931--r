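# Independent oracles used across the suite; deliberately naive
# implementations, kept separate from the package's code paths.

# upper binomial tail P(X >= k) by direct summation in log space
oracle_binom_tail <- function(k, n, p0 = 0.5) {
  if (k <= 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log(1 - p0)))
}

# one-sided (enrichment) Fisher p for table (a, b; c, d) by summing the
# hypergeometric tail: overlap >= a given margins
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b          # targets
  k <- a + c          # term size
  n <- a + b + c + d  # universe
  hi <- min(m, k)
  x <- a:hi
  sum(choose(k, x) * choose(n - k, m - x)) / choose(n, m)
}

# AUC by counting concordant pairs, ties get half credit
oracle_auc_pairs <- function(pos_scores, neg_scores) {
  total <- 0
  for (p in pos_scores) for (q in neg_scores)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos_scores) * length(neg_scores))
}

# tiny gene-model table generator: genes spaced far apart on chr1
toy_genes <- function(n = 5, spacing = 10000L, strand = "+") {
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr1",
             strand = rep(strand, length.out = n),
             tss = spacing * seq_len(n), stringsAsFactors = FALSE)
}

toy_sites <- function(tf, cell_line, gene_tss, probs, chrom = "chr1") {
  data.frame(tf_id = tf, cell_line = cell_line, chrom = chrom,
             start = as.integer(gene_tss), end = as.integer(gene_tss + 10L),
             strand = "+", probability = probs, stringsAsFactors = FALSE)
}

# network built directly from an edge list (tf, gene, prob)
toy_network <- function(cell_line, tf, genes, probs = 0.9) {
  cell_line_network(cell_line, data.frame(
    tf_id = rep(tf, length(genes)), gene_id = genes,
    probability = rep(probs, length.out = length(genes)),
    stringsAsFactors = FALSE))
}
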