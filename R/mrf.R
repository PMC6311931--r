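# Pairwise binary Markov random field over cell lines for one TF-gene
# relationship. Node potentials come from binding probabilities, edge
# potentials from the thresholded (CSI + TNI)/2 coupling weights. The
# pseudo-energy E(X) = -gamma - sum_i ln phi_i(x_i) - sum_(i,j) ln psi(x_i, x_j)
# is minimised exactly by s-t min-cut (the pairwise log-potentials are
# submodular whenever the coupling threshold c >= 0), locally by iterated
# conditional modes, and marginals are approximated by loopy belief
# propagation. gamma only shifts the energy and is fixed at 0.

#' MRF instance for one TF-gene relationship across cell lines
#'
#' @param p1 Numeric vector of binding probabilities P(1,i), one per cell
#'   line; clamped to `[eps, 1 - eps]` so that the potential ratio is
#'   finite. P(0,i) is defined as 1 - P(1,i).
#' @param coupling [coupling_graph()] over the same cell lines (in the same
#'   order), or `NULL` for a field with no couplings.
#' @param cell_lines Optional cell-line ids (defaults to those of the
#'   coupling graph or names of `p1`).
#' @param tf_id,gene_id Optional identifiers carried along.
#' @param gamma Constant energy offset (default 0; it cannot change the
#'   argmin or the marginals).
#' @param eps Clamping constant (default 1e-6).
#' @return Object of class `mrf_instance`: `p1`, `p0`, `edges` (index
#'   pairs, i < j), `w` (edge weights), `cell_lines`, `gamma`.
#' @export
mrf_instance <- function(p1, coupling = NULL, cell_lines = NULL,
                         tf_id = NULL, gene_id = NULL, gamma = 0,
                         eps = 1e-6) {
  n <- length(p1)
  if (is.null(cell_lines))
    cell_lines <- if (!is.null(coupling)) coupling$cell_lines
      else if (!is.null(names(p1))) names(p1) else as.character(seq_len(n))
  if (length(cell_lines) != n) stop("p1 and cell_lines lengths differ")
  if (any(p1 < 0 | p1 > 1)) stop("p1 outside [0,1]")
  p1 <- pmin(pmax(p1, eps), 1 - eps)
  if (!is.null(coupling)) {
    if (length(coupling$cell_lines) != n)
      stop("coupling graph built over a different cell-line set")
    edges <- coupling$edges
    w <- coupling$w
  } else {
    edges <- matrix(integer(), 0, 2)
    w <- numeric()
  }
  structure(list(tf_id = tf_id, gene_id = gene_id, cell_lines = cell_lines,
                 p1 = unname(p1), p0 = unname(1 - p1),
                 edges = edges, w = w, gamma = gamma),
            class = "mrf_instance")
}

#' @export
print.mrf_instance <- function(x, ...) {
  cat("<mrf_instance> ", length(x$p1), " cell lines, ", nrow(x$edges),
      " couplings\n", sep = "")
  invisible(x)
}

#' Node potential phi_i
#'
#' `p1/p0` when the label agrees with a dominant binding probability
#' (`p1 > p0`, `x = 1`), `p0/p1` when it agrees with a dominant
#' non-binding probability, and 1 otherwise (including the tie `p1 = p0`).
#'
#' @param p1,p0 Binding / non-binding probabilities, `p1 + p0 = 1`.
#' @param x Label in \{0, 1\}.
#' @return Potential value >= 1 on the agreeing branch, 1 otherwise.
#' @export
node_potential <- function(p1, p0, x) {
  ifelse(p1 > p0 & x == 1, p1 / p0,
         ifelse(p0 > p1 & x == 0, p0 / p1, 1))
}

#' Edge potential psi_(i,j)
#'
#' `exp(w_ij)` when the two labels agree, 1 otherwise;
#' `w_ij = (CSI_ij + TNI_ij)/2`.
#'
#' @param w Edge weight.
#' @param xi,xj Labels in \{0, 1\}.
#' @return Potential value.
#' @export
edge_potential <- function(w, xi, xj) ifelse(xi == xj, exp(w), 1)

# log phi_i(x) for x = 0 and x = 1, vectorised over nodes
.alpha01 <- function(p1, p0) {
  a1 <- ifelse(p1 > p0, log(p1 / p0), 0)
  a0 <- ifelse(p0 > p1, log(p0 / p1), 0)
  cbind(a0, a1)
}

#' Pseudo-energy of a labeling
#'
#' \eqn{E(X) = -\gamma - \sum_i \ln\phi_i(x_i) - \sum_{(i,j)} \ln\psi_{ij}(x_i,x_j)}.
#' Minimising E is equivalent to maximising the joint distribution.
#'
#' @param inst [mrf_instance()].
#' @param x Binary labeling vector.
#' @return Scalar energy.
#' @export
pseudo_energy <- function(inst, x) {
  stopifnot(length(x) == length(inst$p1), all(x %in% c(0, 1)))
  a <- .alpha01(inst$p1, inst$p0)
  e_node <- sum(ifelse(x == 1, a[, 2], a[, 1]))
  e_edge <- if (nrow(inst$edges))
    sum(inst$w * (x[inst$edges[, 1]] == x[inst$edges[, 2]])) else 0
  -inst$gamma - e_node - e_edge
}

#' Exhaustive-enumeration MAP and exact marginals
#'
#' Enumerates all `2^n` labelings; intended as an oracle for small fields.
#' Ties in the MAP energy are broken toward the lexicographically smallest
#' labeling (as a 0/1 vector read left to right).
#'
#' @param inst [mrf_instance()] with at most 20 nodes.
#' @return List with `map` (labeling), `energy`, and `pr1` (exact
#'   marginals Pr(x_i = 1)).
#' @export
brute_force_infer <- function(inst) {
  n <- length(inst$p1)
  if (n > 20) stop("brute force limited to n <= 20")
  labs <- as.matrix(expand.grid(rev(replicate(n, 0:1, simplify = FALSE)),
                                KEEP.OUT.ATTRS = FALSE))[, n:1, drop = FALSE]
  # rows are in lexicographic order of (x_1, ..., x_n)
  a <- .alpha01(inst$p1, inst$p0)
  e <- -inst$gamma - labs %*% a[, 2] - (1 - labs) %*% a[, 1]
  if (nrow(inst$edges)) {
    for (k in seq_len(nrow(inst$edges))) {
      same <- labs[, inst$edges[k, 1]] == labs[, inst$edges[k, 2]]
      e <- e - inst$w[k] * same
    }
  }
  e <- as.numeric(e)
  best <- which.min(e)                     # first hit = lexicographically smallest
  wts <- exp(-(e - min(e)))
  pr1 <- as.numeric(crossprod(labs, wts) / sum(wts))
  list(map = unname(labs[best, ]), energy = e[best], pr1 = pr1)
}

#' Exact MAP labeling by s-t min-cut
#'
#' The pairwise term \eqn{-w_{ij}[x_i = x_j]} equals, up to a constant, the
#' Ising cut cost \eqn{w_{ij}[x_i \neq x_j]}; with submodular log-potentials
#' (guaranteed for coupling threshold c >= 0, since
#' \eqn{\beta(1,1)+\beta(0,0) = 2 w_{ij} \ge 0 = \beta(1,0)+\beta(0,1)})
#' the global pseudo-energy minimiser is the minimum s-t cut of a graph
#' with terminal capacities from the node log-potentials and pairwise
#' capacities \eqn{w_{ij}}.
#'
#' @param inst [mrf_instance()].
#' @return Binary labeling vector attaining the global energy minimum.
#' @export
map_by_mincut <- function(inst) {
  n <- length(inst$p1)
  if (nrow(inst$edges) && any(2 * inst$w < 0))
    stop("non-submodular edge (negative coupling weight); min-cut inapplicable")
  a <- .alpha01(inst$p1, inst$p0)
  theta0 <- -a[, 1]                        # cost of x_i = 0
  theta1 <- -a[, 2]
  m <- pmin(theta0, theta1)
  s <- n + 1L; t <- n + 2L
  # s -> i cut when i lands on the sink (x = 1) side; i -> t when x = 0
  from <- c(rep(s, n), seq_len(n))
  to <- c(seq_len(n), rep(t, n))
  cap <- c(theta1 - m, theta0 - m)
  if (nrow(inst$edges)) {
    from <- c(from, inst$edges[, 1], inst$edges[, 2])
    to <- c(to, inst$edges[, 2], inst$edges[, 1])
    cap <- c(cap, inst$w, inst$w)
  }
  keep <- cap > 0
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]))
  # ensure s and t exist even if all their arcs have zero capacity
  if (igraph::vcount(g) < t) g <- igraph::add_vertices(g, t - igraph::vcount(g))
  fl <- igraph::max_flow(g, source = s, target = t, capacity = cap[keep])
  x <- integer(n)
  sink_side <- setdiff(as.integer(fl$partition2), c(s, t))
  x[sink_side] <- 1L
  x
}

#' Iterated conditional modes
#'
#' Greedy coordinate descent on the pseudo-energy: sweep the nodes in
#' order, flipping any label whose flip strictly lowers the energy, until a
#' full sweep makes no change. The energy is non-increasing across sweeps.
#'
#' @param inst [mrf_instance()].
#' @param init Initial labeling (default: node-wise argmax of phi, ties to 0).
#' @param max_sweeps Safety cap on sweeps.
#' @return Locally optimal labeling.
#' @export
icm_refine <- function(inst, init = NULL, max_sweeps = 100L) {
  n <- length(inst$p1)
  x <- if (is.null(init)) as.integer(inst$p1 > inst$p0) else as.integer(init)
  stopifnot(length(x) == n)
  a <- .alpha01(inst$p1, inst$p0)
  nbr <- vector("list", n)
  if (nrow(inst$edges)) {
    for (k in seq_len(nrow(inst$edges))) {
      i <- inst$edges[k, 1]; j <- inst$edges[k, 2]
      nbr[[i]] <- rbind(nbr[[i]], c(j, inst$w[k]))
      nbr[[j]] <- rbind(nbr[[j]], c(i, inst$w[k]))
    }
  }
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      # local energy contribution of x_i = 0 / 1
      e0 <- -a[i, 1]; e1 <- -a[i, 2]
      if (!is.null(nbr[[i]])) {
        same1 <- x[nbr[[i]][, 1]] == 1
        e1 <- e1 - sum(nbr[[i]][same1, 2])
        e0 <- e0 - sum(nbr[[i]][!same1, 2])
      }
      xi <- if (e1 < e0) 1L else if (e0 < e1) 0L else x[i]
      if (xi != x[i]) { x[i] <- xi; changed <- TRUE }
    }
    if (!changed) break
  }
  x
}

# Vectorised sum-product LBP over m instances sharing one coupling graph.
# p1m: m x n matrix of clamped probabilities. Returns list(pr1 = m x n,
# converged, iterations).
.lbp_engine <- function(p1m, edges, w, damping = 0.5, tol = 1e-6,
                        max_iter = 200L) {
  m <- nrow(p1m); n <- ncol(p1m)
  p0m <- 1 - p1m
  phi1 <- ifelse(p1m > p0m, p1m / p0m, 1)
  phi0 <- ifelse(p0m > p1m, p0m / p1m, 1)
  ne <- nrow(edges)
  if (ne == 0) {
    b1 <- phi1 / (phi0 + phi1)
    return(list(pr1 = b1, converged = TRUE, iterations = 0L))
  }
  # directed edges: k -> (i to j), reverse index rev[k]
  de_from <- c(edges[, 1], edges[, 2])
  de_to <- c(edges[, 2], edges[, 1])
  de_w <- c(w, w)
  rev_idx <- c(seq_len(ne) + ne, seq_len(ne))
  nde <- 2L * ne
  M0 <- matrix(0.5, m, nde)
  M1 <- matrix(0.5, m, nde)
  in_by_node <- split(seq_len(nde), factor(de_to, levels = seq_len(n)))
  ew <- exp(de_w)
  converged <- FALSE
  iter <- 0L
  floor_ <- 1e-300
  for (iter in seq_len(max_iter)) {
    T0 <- phi0; T1 <- phi1
    for (i in seq_len(n)) {
      for (e in in_by_node[[i]]) {
        T0[, i] <- T0[, i] * M0[, e]
        T1[, i] <- T1[, i] * M1[, e]
      }
    }
    S0 <- T0[, de_from, drop = FALSE] / pmax(M0[, rev_idx, drop = FALSE], floor_)
    S1 <- T1[, de_from, drop = FALSE] / pmax(M1[, rev_idx, drop = FALSE], floor_)
    N0 <- sweep(S0, 2, ew, `*`) + S1
    N1 <- S0 + sweep(S1, 2, ew, `*`)
    z <- N0 + N1
    N0 <- N0 / z; N1 <- N1 / z
    U0 <- damping * M0 + (1 - damping) * N0
    U1 <- damping * M1 + (1 - damping) * N1
    delta <- max(abs(U0 - M0), abs(U1 - M1))
    M0 <- U0; M1 <- U1
    if (delta < tol) { converged <- TRUE; break }
  }
  T0 <- phi0; T1 <- phi1
  for (i in seq_len(n)) {
    for (e in in_by_node[[i]]) {
      T0[, i] <- T0[, i] * M0[, e]
      T1[, i] <- T1[, i] * M1[, e]
    }
  }
  list(pr1 = T1 / (T0 + T1), converged = converged, iterations = iter)
}

#' Loopy belief propagation marginals
#'
#' Synchronous (flooding) sum-product message passing with linear damping;
#' messages are normalised at every update so the partition function is
#' never formed. Exact on tree-structured fields; beliefs for isolated
#' nodes equal `p1` in closed form.
#'
#' @param inst [mrf_instance()].
#' @param damping Weight on the previous message (default 0.5).
#' @param tol Convergence threshold on the largest message change.
#' @param max_iter Iteration cap; non-convergence returns the last beliefs
#'   with `converged = FALSE`.
#' @return List with `pr1` (beliefs Pr(x_i = 1)), `converged`, `iterations`.
#' @export
lbp_marginals <- function(inst, damping = 0.5, tol = 1e-6, max_iter = 200L) {
  res <- .lbp_engine(matrix(inst$p1, nrow = 1), inst$edges, inst$w,
                     damping = damping, tol = tol, max_iter = max_iter)
  list(pr1 = as.numeric(res$pr1), converged = res$converged,
       iterations = res$iterations)
}

#' Random MRF instance generator
#'
#' Draws `p1 ~ U(eps, 1 - eps)` and a random topology (chain, tree, loop or
#' Erdos-Renyi-sparse) with edge weights `w ~ U(w_range[1], w_range[2])`.
#' Used for seeded property checks of the inference routines.
#'
#' @param n Number of nodes.
#' @param topology One of `"chain"`, `"tree"`, `"loop"`, `"random"`,
#'   `"mixed"` (picks one of the others at random).
#' @param w_range Range of edge weights (default `c(0.5, 1)`, matching the
#'   coupling threshold's admissible weights).
#' @param seed Optional integer seed (local to this call).
#' @param eps Probability clamp.
#' @return [mrf_instance()].
#' @export
random_mrf_instance <- function(n, topology = "mixed", w_range = c(0.5, 1),
                                seed = NULL, eps = 1e-6) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (topology == "mixed")
    topology <- sample(c("chain", "tree", "loop", "random"), 1)
  edges <- switch(topology,
    chain = if (n > 1) cbind(1:(n - 1), 2:n) else matrix(integer(), 0, 2),
    tree = if (n > 1) {
      parent <- vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1))
      cbind(parent, 2:n)
    } else matrix(integer(), 0, 2),
    loop = if (n > 2) cbind(1:n, c(2:n, 1L)) else if (n == 2)
      cbind(1L, 2L) else matrix(integer(), 0, 2),
    random = {
      all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(all_pairs)) < min(1, 2 / max(1, n - 1))
      all_pairs[keep, , drop = FALSE]
    },
    stop("unknown topology: ", topology))
  edges <- matrix(as.integer(edges), ncol = 2)
  p1 <- stats::runif(n, eps, 1 - eps)
  w <- stats::runif(nrow(edges), w_range[1], w_range[2])
  inst <- mrf_instance(p1, eps = eps)
  inst$edges <- edges
  inst$w <- w
  inst
}

#' Check submodularity of all edge log-potentials
#'
#' Verifies \eqn{\beta(1,1) + \beta(0,0) \ge \beta(1,0) + \beta(0,1)} for
#' every coupling edge (equivalently `2 w >= 0`).
#'
#' @param inst [mrf_instance()].
#' @return `TRUE` if every edge is submodular.
#' @export
is_submodular <- function(inst) {
  if (nrow(inst$edges) == 0) return(TRUE)
  all(2 * inst$w >= 0)
}
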