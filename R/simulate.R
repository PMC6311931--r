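# Seeded generators for every pipeline input with known ground truth:
# cell lines clustered into tissues, block-structured expression, true
# networks = shared core + tissue-specific + private edges, beta-noised
# binding probabilities over true and false candidate edges, and ChIP-like
# peaks placed in promoters of true targets.

#' Generator configuration
#'
#' @param n_cell_lines,n_tissues,n_tfs,n_genes Problem sizes.
#' @param core_edge_fraction Fraction of genes each TF regulates in every
#'   cell line (the shared core).
#' @param tissue_edge_fraction Fraction of genes added per tissue to the
#'   TF's targets in that tissue's cell lines.
#' @param private_edge_fraction Fraction of genes forming per-cell-line
#'   private edges.
#' @param false_candidate_rate False candidate edges per (TF, cell line),
#'   as a fraction of that cell line's true edge count.
#' @param noise_sd Gaussian expression noise sd around the tissue program
#'   (programs are N(0, 1) per gene).
#' @param binding_beta_concentration Beta concentration a: true edges get
#'   probability ~ Beta(0.8 a, 0.2 a), false candidates ~ Beta(0.2 a, 0.8 a).
#' @param seed Mandatory integer seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_cell_lines = 10L, n_tissues = 2L, n_tfs = 5L,
                             n_genes = 300L, core_edge_fraction = 0.10,
                             tissue_edge_fraction = 0.10,
                             private_edge_fraction = 0.02,
                             false_candidate_rate = 0.5,
                             noise_sd = 0.3,
                             binding_beta_concentration = 2,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_cell_lines = as.integer(n_cell_lines),
              n_tissues = as.integer(n_tissues), n_tfs = as.integer(n_tfs),
              n_genes = as.integer(n_genes),
              core_edge_fraction = core_edge_fraction,
              tissue_edge_fraction = tissue_edge_fraction,
              private_edge_fraction = private_edge_fraction,
              false_candidate_rate = false_candidate_rate,
              noise_sd = noise_sd,
              binding_beta_concentration = binding_beta_concentration,
              seed = as.integer(seed))
  fr <- c(cfg$core_edge_fraction, cfg$tissue_edge_fraction,
          cfg$private_edge_fraction, cfg$false_candidate_rate)
  if (any(fr < 0) || any(fr[1:3] > 1)) stop("fractions must lie in [0,1]")
  if (cfg$n_tissues > cfg$n_cell_lines) stop("more tissues than cell lines")
  need <- ceiling(cfg$n_genes * (cfg$core_edge_fraction +
                                 cfg$tissue_edge_fraction +
                                 cfg$private_edge_fraction))
  if (need > cfg$n_genes) stop("edge fractions exceed the gene universe")
  structure(cfg, class = "generator_config")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate ground truth
#'
#' Cell lines are split contiguously into tissues. Each TF's true target
#' set in a cell line is core targets (all cell lines) + tissue targets
#' (the cell line's tissue) + a private sample. Expression is a per-tissue
#' gene program (N(0,1)) plus N(0, noise_sd) noise, so within-tissue CSI
#' exceeds between-tissue CSI in expectation.
#'
#' @param cfg [generator_config()].
#' @return Object of class `synthetic_truth`: `cfg`, `cell_lines`,
#'   `tissues` (assignment), `genes` (gene-model table), `tfs`,
#'   `true_targets` (tf -> cell line -> character vector), `expression`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  .with_seed(cfg$seed, {
    cls <- sprintf("cl%02d", seq_len(cfg$n_cell_lines))
    tissues <- stats::setNames(
      sprintf("tissue%d", sort(rep(seq_len(cfg$n_tissues),
                                   length.out = cfg$n_cell_lines))), cls)
    gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
    genes <- data.frame(gene_id = gene_ids, chrom = "chr1",
                        strand = rep(c("+", "-"), length.out = cfg$n_genes),
                        tss = 10000L * seq_len(cfg$n_genes),
                        stringsAsFactors = FALSE)
    tfs <- sprintf("tf%02d", seq_len(cfg$n_tfs))
    n_core <- round(cfg$n_genes * cfg$core_edge_fraction)
    n_tis <- round(cfg$n_genes * cfg$tissue_edge_fraction)
    n_priv <- round(cfg$n_genes * cfg$private_edge_fraction)
    true_targets <- list()
    for (tf in tfs) {
      pool <- gene_ids
      core <- sample(pool, n_core)
      pool <- setdiff(pool, core)
      tis_targets <- list()
      for (ti in unique(tissues)) {
        tis_targets[[ti]] <- sample(pool, n_tis)
        pool <- setdiff(pool, tis_targets[[ti]])
      }
      per_cl <- list()
      for (cl in cls) {
        priv <- if (n_priv > 0) sample(pool, n_priv) else character()
        per_cl[[cl]] <- sort(unique(c(core, tis_targets[[tissues[cl]]], priv)))
      }
      true_targets[[tf]] <- per_cl
    }
    program <- matrix(stats::rnorm(cfg$n_genes * cfg$n_tissues),
                      cfg$n_genes, cfg$n_tissues,
                      dimnames = list(gene_ids, unique(tissues)))
    expression <- program[, tissues, drop = FALSE] +
      matrix(stats::rnorm(cfg$n_genes * cfg$n_cell_lines, sd = cfg$noise_sd),
             cfg$n_genes, cfg$n_cell_lines)
    colnames(expression) <- cls
    structure(list(cfg = cfg, cell_lines = cls, tissues = tissues,
                   genes = genes, tfs = tfs, true_targets = true_targets,
                   expression = expression),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", length(x$cell_lines), " cell lines / ",
      x$cfg$n_tissues, " tissues, ", length(x$tfs), " TFs, ",
      x$cfg$n_genes, " genes (seed ", x$cfg$seed, ")\n", sep = "")
  invisible(x)
}

#' Emit observable data from a simulated truth
#'
#' True edges receive a binding site in the target's promoter with
#' probability drawn from Beta(0.8 a, 0.2 a); false candidate edges
#' (sampled per TF and cell line) from Beta(0.2 a, 0.8 a), with
#' a = `binding_beta_concentration`. ChIP-like peaks are placed in the
#' promoters of true targets with scores increasing in the edge's drawn
#' strength. With `null_binding = TRUE` the binding observations carry no
#' information about the truth: sites are placed on a uniformly random
#' candidate set of the same size and their probabilities are drawn from a
#' single Beta(0.5 a, 0.5 a); the peaks (and hence the gold standard) still
#' reflect the true edges.
#'
#' @param truth [simulate_truth()] output.
#' @param dir Optional directory: writes per-cell-line site BED files, the
#'   expression TSV, per-(TF, cell line) peak BEDs and a gene BED that all
#'   parse back through the readers unchanged.
#' @param null_binding Draw truth-independent binding probabilities.
#' @return List with `sites` (binding-site table), `expression`, `genes`,
#'   `peaks` (nested list tf -> cell line -> peak table), `truth`, and
#'   `paths` when `dir` was given.
#' @export
emit_observations <- function(truth, dir = NULL, null_binding = FALSE) {
  cfg <- truth$cfg
  .with_seed(cfg$seed + 1L, {
    a <- cfg$binding_beta_concentration
    genes <- truth$genes
    tss <- stats::setNames(genes$tss, genes$gene_id)
    strand <- stats::setNames(genes$strand, genes$gene_id)
    site_rows <- list()
    peaks <- list()
    for (tf in truth$tfs) {
      peaks[[tf]] <- list()
      for (cl in truth$cell_lines) {
        true_t <- truth$true_targets[[tf]][[cl]]
        n_false <- round(length(true_t) * cfg$false_candidate_rate)
        if (null_binding) {
          # truth-independent observations: random candidates, one Beta
          cand <- sample(genes$gene_id, length(true_t) + n_false)
          prob <- stats::rbeta(length(cand), 0.5 * a, 0.5 * a)
        } else {
          false_t <- sample(setdiff(genes$gene_id, true_t), n_false)
          cand <- c(true_t, false_t)
          is_true <- rep(c(TRUE, FALSE), c(length(true_t), length(false_t)))
          prob <- ifelse(is_true,
                         stats::rbeta(length(cand), 0.8 * a, 0.2 * a),
                         stats::rbeta(length(cand), 0.2 * a, 0.8 * a))
        }
        prob <- pmin(pmax(prob, 1e-6), 1 - 1e-6)
        pos <- tss[cand]                     # site at the TSS, inside the window
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          tf_id = tf, cell_line = cl, chrom = "chr1",
          start = as.integer(pos), end = as.integer(pos + 10L),
          strand = strand[cand], probability = prob,
          stringsAsFactors = FALSE)
        strength <- stats::rbeta(length(true_t), 0.8 * a, 0.2 * a)
        peaks[[tf]][[cl]] <- data.frame(
          chrom = "chr1", start = as.integer(tss[true_t]),
          end = as.integer(tss[true_t] + 50L),
          score = round(1000 * strength, 3), stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, site_rows)
    rownames(sites) <- NULL
    out <- list(sites = sites, expression = truth$expression,
                genes = genes, peaks = peaks, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(sites = character(), peaks = character())
      for (cl in truth$cell_lines) {
        p <- file.path(dir, paste0(cl, ".sites.bed"))
        s <- sites[sites$cell_line == cl, , drop = FALSE]
        utils::write.table(
          data.frame(s$chrom, s$start, s$end, s$tf_id,
                     format(s$probability, digits = 17), s$strand),
          p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
        paths$sites[cl] <- p
      }
      pe <- file.path(dir, "expression.tsv")
      utils::write.table(
        data.frame(gene_id = rownames(truth$expression), truth$expression,
                   check.names = FALSE),
        pe, sep = "\t", quote = FALSE, row.names = FALSE)
      paths$expression <- pe
      pg <- file.path(dir, "genes.bed")
      # encode the TSS per BED convention: start for + genes, end-1 for -
      bed_start <- ifelse(genes$strand == "+", genes$tss, genes$tss - 999L)
      bed_end <- ifelse(genes$strand == "+", genes$tss + 1000L,
                        genes$tss + 1L)
      utils::write.table(
        data.frame(genes$chrom, bed_start, bed_end, genes$gene_id,
                   ".", genes$strand),
        pg, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      paths$genes <- pg
      for (tf in truth$tfs) for (cl in truth$cell_lines) {
        pp <- file.path(dir, paste0(tf, ".", cl, ".peaks.bed"))
        pk <- peaks[[tf]][[cl]]
        utils::write.table(
          data.frame(pk$chrom, pk$start, pk$end, paste0(tf, "_peak"),
                     pk$score),
          pp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
        paths$peaks[paste(tf, cl)] <- pp
      }
      out$paths <- paths
    }
    out
  })
}

#' End-to-end recovery experiment on synthetic data
#'
#' Runs the full pipeline (preliminary networks -> CSI -> MRF refinement)
#' on generated data and evaluates both networks per (TF, cell line)
#' against a ChIP-style gold standard derived from the true edges:
#' candidates from the emitted peaks, truncation at the median size M,
#' AUC and top-M overlap with relative changes.
#'
#' @param cfg [generator_config()].
#' @param n_replicates Number of independent replicates (seeds
#'   `cfg$seed + 1000 * (0:(r-1))`).
#' @param null_binding Passed to [emit_observations()].
#' @param method Inference method for refinement.
#' @param c Coupling threshold.
#' @param n_dims CSI dimensions; capped at the z-scored matrix rank
#'   (`n_cell_lines - 1`).
#' @return List with `records` (one row per TF, cell line, replicate:
#'   AUCs, overlaps, relative changes), `fraction_improved_auc`,
#'   `fraction_improved_overlap`.
#' @export
recovery_experiment <- function(cfg, n_replicates = 1L, null_binding = FALSE,
                                method = "lbp", c = 0.5, n_dims = 16L) {
  recs <- list()
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 1000L * (r - 1L)
    truth <- simulate_truth(cfg_r)
    obs <- emit_observations(truth, null_binding = null_binding)
    prelim <- build_preliminary_networks(obs$sites, obs$genes,
                                         cell_lines = truth$cell_lines)
    k <- min(n_dims, length(truth$cell_lines) - 1L)
    csi <- compute_csi(obs$expression, n_dims = k,
                       n_fallback_genes = min(592L, nrow(obs$expression)))
    refined <- refine_networks(prelim, csi, c = c, method = method)
    universe <- obs$genes$gene_id
    for (tf in truth$tfs) {
      for (cl in truth$cell_lines) {
        prelim_e <- prelim[[cl]]$edges
        prelim_e <- prelim_e[prelim_e$tf_id == tf, , drop = FALSE]
        ref_tab <- refined$table
        ref_e <- ref_tab[ref_tab$tf_id == tf & ref_tab$cell_line == cl, ,
                         drop = FALSE]
        mrf_called <- refined$networks[[cl]]$tf_targets[[tf]]
        if (is.null(mrf_called)) mrf_called <- character()
        gold <- build_gold_standard(obs$peaks[[tf]][[cl]], obs$genes,
                                    mrf_targets = mrf_called,
                                    prelim_targets = prelim_e$gene_id,
                                    tf_id = tf, cell_line = cl)
        sc_pre <- stats::setNames(prelim_e$probability, prelim_e$gene_id)
        sc_mrf <- stats::setNames(ref_e$probability, ref_e$gene_id)
        auc_pre <- roc_auc(sc_pre, gold$positives, universe)
        auc_mrf <- roc_auc(sc_mrf, gold$positives, universe)
        ov_pre <- overlap_score(top_m_targets(prelim_e, gold$M), gold)
        ov_mrf <- overlap_score(top_m_targets(
          ref_e[, c("gene_id", "probability")], gold$M), gold)
        recs[[length(recs) + 1L]] <- data.frame(
          replicate = r, tf_id = tf, cell_line = cl, M = gold$M,
          auc_prelim = auc_pre, auc_mrf = auc_mrf,
          overlap_prelim = ov_pre, overlap_mrf = ov_mrf,
          rel_change_auc = suppressWarnings(relative_change(auc_mrf, auc_pre)),
          rel_change_overlap = suppressWarnings(
            relative_change(ov_mrf, ov_pre)),
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, recs)
  list(records = records,
       fraction_improved_auc = mean(records$rel_change_auc > 0, na.rm = TRUE),
       fraction_improved_overlap =
         mean(records$rel_change_overlap > 0, na.rm = TRUE))
}
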