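# All genomic intervals are held 0-based half-open internally; formats that
# are 1-based inclusive (GTF) are converted on read. No missing-value
# imputation anywhere: malformed or missing cells are errors.

.read_tabular <- function(path, n_min_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  has_content <- length(grep("^[^#[:space:]]", readLines(path, warn = FALSE))) > 0
  if (!has_content) return(data.frame())
  df <- utils::read.table(path, header = FALSE, sep = "", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", fill = FALSE,
                          blank.lines.skip = TRUE)
  if (nrow(df) > 0 && ncol(df) < n_min_cols)
    stop("expected >= ", n_min_cols, " columns in ", path, ", found ", ncol(df))
  df
}

.as_num <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop("non-numeric ", what, " at line ", bad[1], " of ", path, ": '", x[bad[1]], "'")
  v
}

#' Read predicted TF binding sites with binding probabilities
#'
#' Reads a BED-like file of probability-scored predicted binding sites, one
#' row per site. The default dialect is BED6 with the probability in the
#' score column: `chrom start end tf_id probability strand`.
#'
#' @param path Path to the site file (whitespace- or tab-separated).
#' @param cell_line Cell-line identifier attached to every record; defaults
#'   to the file name without extension.
#' @param dialect Column layout. `"bed6prob"` (default) reads the
#'   probability from column 5; `"bed6+prob"` reads BED6 plus a 7th
#'   probability column.
#' @param one_based Set `TRUE` if the start coordinates are 1-based
#'   inclusive; they are converted to 0-based half-open.
#' @return A `data.frame` with columns `tf_id`, `cell_line`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `probability`.
#' @export
read_binding_sites <- function(path, cell_line = NULL,
                               dialect = c("bed6prob", "bed6+prob"),
                               one_based = FALSE) {
  dialect <- match.arg(dialect)
  if (is.null(cell_line))
    cell_line <- sub("\\.[^.]*$", "", basename(path))
  df <- .read_tabular(path, if (dialect == "bed6prob") 6L else 7L)
  if (nrow(df) == 0) {
    return(data.frame(tf_id = character(), cell_line = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), probability = numeric()))
  }
  prob_col <- if (dialect == "bed6prob") 5L else 7L
  start <- .as_num(df[[2]], "start", path)
  end <- .as_num(df[[3]], "end", path)
  if (one_based) start <- start - 1
  prob <- .as_num(df[[prob_col]], "probability", path)
  bad <- which(prob < 0 | prob > 1)
  if (length(bad))
    stop("probability outside [0,1] at line ", bad[1], " of ", path,
         ": ", prob[bad[1]])
  bad <- which(start >= end)
  if (length(bad))
    stop("start >= end at line ", bad[1], " of ", path)
  strand <- df[[6]]
  if (!all(strand %in% c("+", "-", ".")))
    stop("invalid strand value in ", path)
  data.frame(tf_id = df[[4]], cell_line = cell_line, chrom = df[[1]],
             start = as.integer(start), end = as.integer(end),
             strand = strand, probability = prob,
             stringsAsFactors = FALSE)
}

#' Read gene models with transcription start sites
#'
#' For BED input (0-based half-open, one row per gene/transcript) the TSS is
#' the `start` for `+`-strand features and `end - 1` for `-`-strand
#' features. GTF input (1-based inclusive) is converted on read; all
#' transcript TSSs of a gene are retained and the gene-level `tss` is the
#' 5'-most of them.
#'
#' @param path Path to a BED(6/12) or GTF file.
#' @param format `"bed"` or `"gtf"`.
#' @return A `data.frame` with one row per gene: `gene_id`, `chrom`,
#'   `strand`, `tss` (0-based) and a list-column `transcript_tss`.
#' @export
read_gene_models <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- .read_tabular(path, 6L)
    if (nrow(df) == 0)
      return(data.frame(gene_id = character(), chrom = character(),
                        strand = character(), tss = integer()))
    strand <- df[[6]]
    if (!all(strand %in% c("+", "-")))
      stop("gene without strand in ", path)
    start <- as.integer(.as_num(df[[2]], "start", path))
    end <- as.integer(.as_num(df[[3]], "end", path))
    tss <- ifelse(strand == "+", start, end - 1L)
    tab <- data.frame(gene_id = df[[4]], chrom = df[[1]], strand = strand,
                      tss = tss, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to read GTF")
    gr <- rtracklayer::import(path, format = "gtf")
    keep <- if ("type" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$type) %in% c("transcript", "mRNA") else rep(TRUE, length(gr))
    if (!any(keep)) keep <- rep(TRUE, length(gr))
    gr <- gr[keep]
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*")) stop("gene without strand in ", path)
    # GRanges are 1-based inclusive: 0-based TSS is start-1 (+) or end-1 (-)
    tss <- ifelse(strand == "+", BiocGenerics::start(gr) - 1L,
                  BiocGenerics::end(gr) - 1L)
    tab <- data.frame(gene_id = as.character(gr$gene_id),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = strand, tss = as.integer(tss),
                      stringsAsFactors = FALSE)
  }
  split_tss <- split(tab$tss, tab$gene_id)
  first <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  first <- first[order(first$gene_id), , drop = FALSE]
  tss_list <- split_tss[first$gene_id]
  # gene-level TSS: 5'-most transcript start
  first$tss <- mapply(function(s, v) if (s == "+") min(v) else max(v),
                      first$strand, tss_list)
  first$transcript_tss <- I(lapply(tss_list, function(v) sort(unique(v))))
  rownames(first) <- NULL
  first
}

#' Read a genes x cell-lines expression table
#'
#' TSV with a header of cell-line names; first column holds gene ids.
#' Duplicated gene ids and non-numeric or missing cells are errors (no
#' imputation).
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix, rownames = gene ids, colnames = cell lines.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("expression table needs a gene column and >= 1 cell line")
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1])
  m <- as.matrix(df[, -1, drop = FALSE])
  v <- suppressWarnings(as.numeric(m))
  if (anyNA(v)) {
    idx <- which(is.na(v))[1]
    stop("non-numeric or missing expression value at row ",
         (idx - 1) %% nrow(m) + 1, ", column ", (idx - 1) %/% nrow(m) + 1)
  }
  out <- matrix(v, nrow = nrow(m), dimnames = list(ids, colnames(df)[-1]))
  out
}

#' Read gene sets from a GMT file
#'
#' Each line: term id, description, then member genes. Duplicated genes
#' within a line are deduplicated; terms with zero genes are skipped with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (term id -> gene ids).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(f) < 3 || length(genes) == 0) {
      warning("gene set '", f[1], "' has no genes; skipped")
      next
    }
    sets[[f[1]]] <- genes
  }
  sets
}

#' Write / read a network edge table
#'
#' TSV with fixed column order `tf_id`, `gene_id`, `cell_line`,
#' `probability`. `read_network(write_network(x))` reproduces `x` exactly.
#'
#' @param net Data frame with the four columns above.
#' @param path Output path.
#' @return `write_network` returns `path` invisibly; `read_network` the table.
#' @export
write_network <- function(net, path) {
  cols <- c("tf_id", "gene_id", "cell_line", "probability")
  if (!all(cols %in% names(net))) stop("network table must have columns: ",
                                       paste(cols, collapse = ", "))
  net <- net[, cols, drop = FALSE]
  if (any(net$probability < 0 | net$probability > 1))
    stop("probability outside [0,1]")
  key <- paste(net$tf_id, net$gene_id, net$cell_line)
  if (anyDuplicated(key)) stop("duplicate (tf, gene, cell_line) row")
  utils::write.table(net, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  cols <- c("tf_id", "gene_id", "cell_line", "probability")
  if (!identical(names(df), cols))
    stop("unexpected columns in ", path, ": ", paste(names(df), collapse = ", "))
  if (nrow(df)) {
    df$probability <- as.numeric(df$probability)
    if (anyNA(df$probability) || any(df$probability < 0 | df$probability > 1))
      stop("invalid probability in ", path)
  }
  df
}

#' Read ChIP-seq peaks (BED / narrowPeak)
#'
#' @param path Path to a BED-like peak file (0-based half-open).
#' @param score_col Column holding the peak score (default 5, the BED score;
#'   use 7 for narrowPeak signalValue).
#' @return `data.frame` with `chrom`, `start`, `end`, `score`.
#' @export
read_peaks <- function(path, score_col = 5L) {
  df <- .read_tabular(path, max(3L, score_col))
  if (nrow(df) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), score = numeric()))
  start <- as.integer(.as_num(df[[2]], "start", path))
  end <- as.integer(.as_num(df[[3]], "end", path))
  if (any(start >= end)) stop("start >= end in ", path)
  data.frame(chrom = df[[1]], start = start, end = end,
             score = .as_num(df[[score_col]], "score", path),
             stringsAsFactors = FALSE)
}
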