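# MRF refinement of the preliminary networks. For every TF-gene pair seen
# in at least one preliminary network an MRF instance is built over ALL
# cell lines (pairs unobserved in a cell line enter with p1 = eps:
# "not observed", not "impossible") and inference yields a refined
# regulatory probability per cell line.

#' Refine preliminary networks with the Markov random field
#'
#' For each TF a coupling graph is built from the global CSI and the TF's
#' TNI; every TF-gene pair present in >= 1 preliminary network becomes a
#' binary field over all cell lines. With `method = "lbp"` the refined
#' probability is the belief Pr(x_i = 1); with `"mincut"` or `"icm"` it is
#' the 0/1 MAP label. A final edge is called in cell line i when the
#' refined probability exceeds `call_threshold` (MAP labels: when x_i = 1).
#'
#' @param prelim Named list of [cell_line_network()] objects.
#' @param csi CSI matrix covering at least these cell lines.
#' @param c Coupling threshold (default 0.5).
#' @param call_threshold Probability cut-off for final edge calls.
#' @param method `"lbp"` (default), `"mincut"` or `"icm"`.
#' @param eps Probability clamp / placeholder for unobserved pairs.
#' @param tni_denominator Passed to [compute_tni()].
#' @param observed_only If `TRUE`, each pair's field is restricted to the
#'   cell lines where the pair was observed (default `FALSE`: all cell
#'   lines participate).
#' @param damping,tol,max_iter LBP controls (see [lbp_marginals()]).
#' @return List with `networks` (refined [cell_line_network()]s holding the
#'   called edges with refined probabilities) and `table` (full
#'   tf/gene/cell-line/probability grid over each TF's pair universe).
#' @export
refine_networks <- function(prelim, csi, c = 0.5, call_threshold = 0.5,
                            method = c("lbp", "mincut", "icm"), eps = 1e-6,
                            tni_denominator = "union",
                            observed_only = FALSE,
                            damping = 0.5, tol = 1e-6, max_iter = 200L) {
  method <- match.arg(method)
  cls <- names(prelim)
  if (length(cls) == 0) stop("no preliminary networks")
  if (!all(cls %in% rownames(csi)))
    stop("CSI matrix does not cover all cell lines")
  csi_sub <- csi[cls, cls, drop = FALSE]
  class(csi_sub) <- class(csi)
  tfs <- sort(unique(unlist(lapply(prelim, function(nw) names(nw$tf_targets)))))
  if (length(tfs) == 0) stop("empty preliminary edge universe")
  n <- length(cls)
  tabs <- vector("list", length(tfs))
  for (ti in seq_along(tfs)) {
    tf <- tfs[ti]
    tni <- compute_tni(prelim, tf, denominator = tni_denominator)
    cg <- coupling_graph(csi_sub, tni, c = c)
    genes <- sort(unique(unlist(lapply(prelim, function(nw)
      nw$tf_targets[[tf]]))))
    p1m <- matrix(eps, length(genes), n,
                  dimnames = list(genes, cls))
    for (cl in cls) {
      e <- prelim[[cl]]$edges
      e <- e[e$tf_id == tf, , drop = FALSE]
      if (nrow(e)) p1m[e$gene_id, cl] <- pmin(pmax(e$probability, eps), 1 - eps)
    }
    if (method == "lbp" && !observed_only) {
      res <- .lbp_engine(p1m, cg$edges, cg$w, damping = damping, tol = tol,
                         max_iter = max_iter)
      prob <- res$pr1
    } else {
      prob <- matrix(NA_real_, nrow(p1m), n)
      for (gi in seq_len(nrow(p1m))) {
        keep <- if (observed_only) which(p1m[gi, ] > eps) else seq_len(n)
        if (length(keep) == 0) keep <- seq_len(n)
        sub_edges <- cg$edges[cg$edges[, 1] %in% keep &
                              cg$edges[, 2] %in% keep, , drop = FALSE]
        remap <- match(sub_edges, keep)
        inst <- mrf_instance(p1m[gi, keep], eps = eps)
        inst$edges <- matrix(as.integer(remap), ncol = 2)
        inst$w <- cg$w[cg$edges[, 1] %in% keep & cg$edges[, 2] %in% keep]
        val <- switch(method,
          lbp = lbp_marginals(inst, damping = damping, tol = tol,
                              max_iter = max_iter)$pr1,
          mincut = as.numeric(map_by_mincut(inst)),
          icm = as.numeric(icm_refine(inst)))
        prob[gi, ] <- eps
        prob[gi, keep] <- val
      }
    }
    tabs[[ti]] <- data.frame(
      tf_id = tf,
      gene_id = rep(genes, times = n),
      cell_line = rep(cls, each = length(genes)),
      probability = as.numeric(prob),
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, tabs)
  called <- if (method == "lbp") table$probability > call_threshold
    else table$probability >= 1
  nets <- lapply(cls, function(cl) {
    e <- table[called & table$cell_line == cl,
               c("tf_id", "gene_id", "probability"), drop = FALSE]
    rownames(e) <- NULL
    cell_line_network(cl, e)
  })
  list(networks = stats::setNames(nets, cls), table = table)
}
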