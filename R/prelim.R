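# Preliminary per-cell-line networks: binding sites mapped into promoter
# windows (TSS +/- halfwidth). A site supports an edge when it overlaps any
# promoter window of the gene by >= 1 bp; multiple sites per (tf, gene,
# cell line) keep the maximum probability.

#' Promoter windows around transcription start sites
#'
#' One window per transcript TSS per gene, `[tss - halfwidth, tss +
#' halfwidth)` in 0-based half-open coordinates, clipped at 0. Windows of
#' the same gene may overlap; a gene's promoter territory is their union.
#'
#' @param genes Gene-model table from [read_gene_models()] (a
#'   `transcript_tss` list-column is used when present, otherwise `tss`).
#' @param halfwidth Window half-width in bp (default 2000, i.e. TSS +/- 2 kb).
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `source_tss`.
#' @export
promoter_windows <- function(genes, halfwidth = 2000L) {
  stopifnot(halfwidth > 0)
  tss_list <- if ("transcript_tss" %in% names(genes))
    genes$transcript_tss else as.list(genes$tss)
  n_per <- lengths(tss_list)
  tss <- unlist(tss_list, use.names = FALSE)
  out <- data.frame(
    gene_id = rep(genes$gene_id, n_per),
    chrom = rep(genes$chrom, n_per),
    start = pmax(0L, as.integer(tss - halfwidth)),
    end = as.integer(tss + halfwidth),
    source_tss = as.integer(tss),
    stringsAsFactors = FALSE)
  out
}

.granges <- function(chrom, start, end) {
  # internal 0-based half-open -> GRanges 1-based inclusive
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

#' Assign binding sites to promoters and form regulatory edges
#'
#' A site is assigned to a gene if its interval overlaps any of that gene's
#' promoter windows by at least 1 bp; per (tf, gene, cell line) the edge
#' probability is the maximum over assigned sites.
#'
#' @param sites Binding-site table ([read_binding_sites()]).
#' @param windows Promoter windows ([promoter_windows()]).
#' @return `data.frame` of edges: `tf_id`, `gene_id`, `cell_line`,
#'   `probability`, sorted by (tf, gene, cell line).
#' @export
assign_sites_to_promoters <- function(sites, windows) {
  empty <- data.frame(tf_id = character(), gene_id = character(),
                      cell_line = character(), probability = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0 || nrow(windows) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(
    .granges(sites$chrom, sites$start, sites$end),
    .granges(windows$chrom, windows$start, windows$end),
    minoverlap = 1L)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  df <- data.frame(tf_id = sites$tf_id[qi],
                   gene_id = windows$gene_id[si],
                   cell_line = sites$cell_line[qi],
                   probability = sites$probability[qi],
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(probability ~ tf_id + gene_id + cell_line,
                          data = df, FUN = max)
  agg <- agg[order(agg$tf_id, agg$gene_id, agg$cell_line), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("tf_id", "gene_id", "cell_line", "probability")]
}

#' Per-cell-line network container
#'
#' @param cell_line Cell-line id.
#' @param edges Edge table with `tf_id`, `gene_id`, `probability`.
#' @return An object of class `cell_line_network`: list with `cell_line`,
#'   `edges`, and a `tf_targets` index (tf id -> character vector of genes).
#' @export
cell_line_network <- function(cell_line, edges) {
  edges <- edges[, c("tf_id", "gene_id", "probability"), drop = FALSE]
  structure(list(
    cell_line = cell_line,
    edges = edges,
    tf_targets = lapply(split(edges$gene_id, edges$tf_id), unique)),
    class = "cell_line_network")
}

#' @export
print.cell_line_network <- function(x, ...) {
  cat("<cell_line_network> ", x$cell_line, ": ", nrow(x$edges), " edges, ",
      length(x$tf_targets), " TFs\n", sep = "")
  invisible(x)
}

#' Build preliminary networks for all cell lines
#'
#' @param sites Binding-site table covering one or more cell lines.
#' @param genes Gene-model table.
#' @param halfwidth Promoter half-width in bp.
#' @param cell_lines Optional full set of cell lines (cell lines without any
#'   site get an empty network with a warning).
#' @return Named list of [cell_line_network()] objects.
#' @export
build_preliminary_networks <- function(sites, genes, halfwidth = 2000L,
                                       cell_lines = NULL) {
  if (is.null(cell_lines)) cell_lines <- sort(unique(sites$cell_line))
  if (length(cell_lines) == 0) stop("no cell lines")
  windows <- promoter_windows(genes, halfwidth)
  edges <- assign_sites_to_promoters(sites, windows)
  out <- lapply(cell_lines, function(cl) {
    e <- edges[edges$cell_line == cl, c("tf_id", "gene_id", "probability"),
               drop = FALSE]
    if (nrow(e) == 0)
      warning("cell line '", cl, "' has no edges (no sites in promoters)")
    rownames(e) <- NULL
    cell_line_network(cl, e)
  })
  stats::setNames(out, cell_lines)
}
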