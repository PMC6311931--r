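# Cell-line similarity: CSI from the SVD of a z-scored differential-
# expression matrix, TNI from per-TF target-set overlap, and the thresholded
# coupling graph whose edge weights drive the MRF.

#' Z-score each gene across cell lines
#'
#' Each gene row is normalised to mean 0 and standard deviation 1 using the
#' population standard deviation (divisor n). Constant rows carry no
#' between-cell-line information and are dropped with a warning.
#'
#' @param expr Numeric matrix, genes x cell lines.
#' @return Matrix of the same shape minus dropped constant rows.
#' @export
zscore_genes <- function(expr) {
  if (ncol(expr) < 2) stop("need >= 2 cell lines to z-score")
  mu <- rowMeans(expr)
  centred <- expr - mu
  sd_pop <- sqrt(rowMeans(centred^2))
  keep <- sd_pop > 0
  if (!all(keep))
    warning(sum(!keep), " constant gene row(s) dropped")
  centred[keep, , drop = FALSE] / sd_pop[keep]
}

# Fix the sign of each right singular vector so that its largest-magnitude
# component is positive; removes the arbitrary sign of the SVD and makes
# the CSI reproducible across gene orderings and rotations.
.canonical_v <- function(v) {
  for (k in seq_len(ncol(v))) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) v[, k] <- -v[, k]
  }
  v
}

#' Cell-line Similarity Index (CSI)
#'
#' The z-scored differential-expression matrix (genes x cell lines) is
#' decomposed as \eqn{U S V^T}; cell line j is represented by its
#' coordinates \eqn{(s_1 v_{1j}, \dots, s_k v_{kj})} in the leading k
#' singular dimensions and CSI(i, j) is the Pearson correlation of the two
#' coordinate vectors.
#'
#' @param expr Expression matrix, genes x cell lines.
#' @param n_dims Number of leading singular dimensions k (default 16);
#'   must not exceed the matrix rank.
#' @param de_genes Optional character vector of differentially expressed
#'   gene ids; rows are restricted to it. Without it the
#'   `n_fallback_genes` most variable genes are used.
#' @param n_fallback_genes Size of the variance-ranked fallback gene list
#'   (default 592); capped at the number of genes available.
#' @param scale_dims If `TRUE` (default) coordinates are scaled by the
#'   singular values, weighting dimensions by explained variance.
#' @return Symmetric cell-line x cell-line matrix of class `csi_matrix`,
#'   unit diagonal, values in \[-1, 1\].
#' @export
compute_csi <- function(expr, n_dims = 16L, de_genes = NULL,
                        n_fallback_genes = 592L, scale_dims = TRUE) {
  if (!is.null(de_genes)) {
    missing <- setdiff(de_genes, rownames(expr))
    if (length(missing))
      warning(length(missing), " DE gene(s) absent from the expression table")
    expr <- expr[intersect(rownames(expr), de_genes), , drop = FALSE]
    if (nrow(expr) == 0) stop("no DE genes present in the expression table")
  } else {
    v <- apply(expr, 1, stats::var)
    n_take <- min(n_fallback_genes, nrow(expr))
    expr <- expr[order(v, decreasing = TRUE)[seq_len(n_take)], , drop = FALSE]
  }
  z <- zscore_genes(expr)
  dec <- svd(z)
  rank <- sum(dec$d > max(dim(z)) * .Machine$double.eps * dec$d[1])
  if (n_dims < 1 || n_dims > rank)
    stop("n_dims (", n_dims, ") exceeds matrix rank (", rank, ")")
  if (n_dims < 2) stop("n_dims must be >= 2 for a correlation")
  v <- .canonical_v(dec$v[, seq_len(n_dims), drop = FALSE])
  coords <- if (scale_dims) v %*% diag(dec$d[seq_len(n_dims)], n_dims) else v
  csi <- stats::cor(t(coords))
  csi[csi > 1] <- 1; csi[csi < -1] <- -1
  diag(csi) <- 1
  csi <- (csi + t(csi)) / 2
  dimnames(csi) <- list(colnames(expr), colnames(expr))
  structure(csi, class = c("csi_matrix", "matrix"))
}

#' TF non-specificity index (TNI)
#'
#' Proportion of common targets of a TF between two cell lines'
#' preliminary networks, read as the Jaccard index
#' \eqn{|T_i \cap T_j| / |T_i \cup T_j|} (a min-denominator variant is
#' available). Two empty target sets give 0.
#'
#' @param networks Named list of [cell_line_network()] objects.
#' @param tf_id TF identifier (must regulate >= 1 gene in some network).
#' @param denominator `"union"` (Jaccard, default) or `"min"`.
#' @return Symmetric cell-line x cell-line matrix in \[0, 1\] of class
#'   `tni_matrix` with attribute `tf_id`.
#' @export
compute_tni <- function(networks, tf_id, denominator = c("union", "min")) {
  denominator <- match.arg(denominator)
  targets <- lapply(networks, function(nw) {
    t <- nw$tf_targets[[tf_id]]
    if (is.null(t)) character() else t
  })
  if (all(lengths(targets) == 0))
    stop("unknown TF (no targets in any cell line): ", tf_id)
  n <- length(networks)
  tni <- matrix(0, n, n, dimnames = list(names(networks), names(networks)))
  for (i in seq_len(n)) {
    for (j in i:n) {
      inter <- length(intersect(targets[[i]], targets[[j]]))
      denom <- if (denominator == "union")
        length(union(targets[[i]], targets[[j]]))
      else min(length(targets[[i]]), length(targets[[j]]))
      tni[i, j] <- tni[j, i] <- if (denom == 0) 0 else inter / denom
    }
  }
  structure(tni, class = c("tni_matrix", "matrix"), tf_id = tf_id)
}

#' Cell-line coupling graph for one TF
#'
#' Edge weight \eqn{w_{ij} = (CSI_{ij} + TNI_{ij}) / 2}; cell lines i and j
#' are connected iff \eqn{w_{ij} > c}.
#'
#' @param csi CSI matrix ([compute_csi()]).
#' @param tni TNI matrix for the TF ([compute_tni()]).
#' @param c Coupling threshold (default 0.5). Non-negative values keep all
#'   edge energies submodular.
#' @return Object of class `coupling_graph`: list with `tf_id`,
#'   `cell_lines`, `weights` (full matrix), `threshold`, and `edges`
#'   (2-column index matrix, i < j, one row per retained edge) with `w`.
#' @export
coupling_graph <- function(csi, tni, c = 0.5) {
  if (!identical(rownames(csi), rownames(tni)))
    stop("CSI and TNI cell-line sets differ")
  w <- (unclass(csi) + unclass(tni)) / 2
  n <- nrow(w)
  idx <- which(upper.tri(w) & w > c, arr.ind = TRUE)
  structure(list(
    tf_id = attr(tni, "tf_id"),
    cell_lines = rownames(w),
    weights = w,
    threshold = c,
    edges = unname(idx),
    w = w[idx]),
    class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat("<coupling_graph> TF ", x$tf_id %||% "?", ": ", length(x$cell_lines),
      " cell lines, ", nrow(x$edges), " couplings (w > ", x$threshold,
      ")\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
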