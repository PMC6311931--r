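# helper: small instance with explicit edges/weights
manual_instance <- function(p1, edges = matrix(integer(), 0, 2), w = numeric(),
                            eps = 1e-6) {
  inst <- mrf_instance(p1, eps = eps)
  inst$edges <- matrix(as.integer(edges), ncol = 2)
  inst$w <- w
  inst
}

test_that("node and edge potentials follow the three-branch definitions", {
  expect_equal(node_potential(0.8, 0.2, 1), 4.0)
  expect_equal(node_potential(0.8, 0.2, 0), 1.0)   # "otherwise" branch
  expect_equal(node_potential(0.2, 0.8, 0), 4.0)
  expect_equal(node_potential(0.5, 0.5, 1), 1.0)   # tie branch

  expect_equal(edge_potential(0.5, 1, 1), exp(0.5))
  expect_equal(edge_potential(0.9, 0, 1), 1.0)
  expect_equal(edge_potential(1, 0, 0), exp(1))
})

test_that("pseudo-energy matches direct evaluation and flip identities", {
  # all phi = 1, no edges -> E = 0
  inst <- manual_instance(c(0.5, 0.5, 0.5))
  expect_equal(pseudo_energy(inst, c(0, 1, 0)), 0)

  # n = 2, p1 = (0.9, 0.45), coupled with w = 0.9
  inst <- manual_instance(c(0.9, 0.45), edges = cbind(1L, 2L), w = 0.9)
  expect_equal(pseudo_energy(inst, c(1, 1)), -(log(9) + 0 + 0.9),
               tolerance = 1e-12)
  # cross-check against exhaustive enumeration
  bf <- brute_force_infer(inst)
  e_all <- vapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
                  function(x) pseudo_energy(inst, x), numeric(1))
  expect_equal(bf$energy, min(e_all))
  expect_equal(bf$map, c(1, 1))

  # flipping a label that only breaks one satisfied edge raises E by w
  inst3 <- manual_instance(c(0.5, 0.5), edges = cbind(1L, 2L), w = 0.7)
  expect_equal(pseudo_energy(inst3, c(1, 0)) - pseudo_energy(inst3, c(1, 1)),
               0.7, tolerance = 1e-12)
})

test_that("brute force gives closed-form marginals for isolated nodes", {
  expect_equal(brute_force_infer(mrf_instance(0.9))$pr1, 0.9, tolerance = 1e-12)
  expect_equal(brute_force_infer(mrf_instance(0.3))$pr1, 0.3, tolerance = 1e-12)
  expect_error(brute_force_infer(mrf_instance(runif(21))), "n <= 20")
})

test_that("min-cut MAP equals exhaustive enumeration on random instances", {
  for (s in 1:60) {
    inst <- random_mrf_instance(n = 2 + (s %% 11), topology = "mixed", seed = s)
    bf <- brute_force_infer(inst)
    x <- map_by_mincut(inst)
    expect_equal(pseudo_energy(inst, x), bf$energy, tolerance = 1e-9)
  }
  # no edges: nodewise argmax
  inst <- manual_instance(c(0.9, 0.2, 0.5))
  expect_equal(map_by_mincut(inst)[1:2], c(1L, 0L))
})

test_that("ICM descends and is stationary at the global MAP", {
  for (s in 1:20) {
    inst <- random_mrf_instance(n = 8, seed = 100 + s)
    init <- as.integer(runif(8) > 0.5)
    out <- icm_refine(inst, init)
    expect_lte(pseudo_energy(inst, out), pseudo_energy(inst, init))
    map <- map_by_mincut(inst)
    expect_equal(icm_refine(inst, map), map)   # local minimum stays put
  }
  # isolated nodes from any init -> nodewise argmax
  inst <- manual_instance(c(0.9, 0.2))
  expect_equal(icm_refine(inst, c(0L, 1L)), c(1L, 0L))
})

test_that("LBP is exact on trees and for isolated nodes", {
  lb <- lbp_marginals(mrf_instance(0.8))
  expect_equal(lb$pr1, 0.8, tolerance = 1e-12)
  expect_true(lb$converged)

  for (s in 1:40) {
    inst <- random_mrf_instance(n = 3 + (s %% 10), topology = "tree",
                                seed = 200 + s)
    bf <- brute_force_infer(inst)
    lb <- lbp_marginals(inst, tol = 1e-12, max_iter = 500)
    expect_equal(lb$pr1, bf$pr1, tolerance = 1e-6)
    expect_true(all(lb$pr1 >= 0 & lb$pr1 <= 1))
  }

  # positive coupling pulls the weak node up relative to isolation
  inst <- manual_instance(c(0.9, 0.45), edges = cbind(1L, 2L), w = 0.9)
  lb <- lbp_marginals(inst)
  expect_gt(lb$pr1[2], 0.3)   # isolated belief would be p1-driven: 0.3-ish
  expect_equal(lb$pr1, brute_force_infer(inst)$pr1, tolerance = 1e-5)
})

test_that("beliefs stay in [0,1] even on loopy graphs without convergence", {
  inst <- random_mrf_instance(n = 10, topology = "loop", seed = 5)
  lb <- lbp_marginals(inst, max_iter = 3)
  expect_true(all(lb$pr1 >= 0 & lb$pr1 <= 1))
  expect_false(lb$converged)
})

test_that("all instances built from c >= 0 couplings are submodular", {
  for (s in 1:25) {
    inst <- random_mrf_instance(n = 10, seed = 300 + s)
    expect_true(is_submodular(inst))
    # beta(1,1) + beta(0,0) >= beta(1,0) + beta(0,1), edge by edge
    if (nrow(inst$edges)) {
      b11 <- log(edge_potential(inst$w, 1, 1))
      b00 <- log(edge_potential(inst$w, 0, 0))
      b10 <- log(edge_potential(inst$w, 1, 0))
      b01 <- log(edge_potential(inst$w, 0, 1))
      expect_true(all(b11 + b00 >= b10 + b01))
    }
  }
  bad <- manual_instance(c(0.5, 0.5), edges = cbind(1L, 2L), w = -0.2)
  expect_false(is_submodular(bad))
  expect_error(map_by_mincut(bad), "submodular")
})

test_that("inference is equivariant under cell-line permutation", {
  set.seed(77)
  inst <- random_mrf_instance(n = 9, topology = "random", seed = 42)
  perm <- sample(9)
  inst_p <- inst
  inst_p$p1 <- inst$p1[perm]
  inst_p$p0 <- inst$p0[perm]
  inv <- order(perm)
  inst_p$edges <- matrix(as.integer(inv[inst$edges]), ncol = 2)
  bf <- brute_force_infer(inst)
  bf_p <- brute_force_infer(inst_p)
  expect_equal(bf_p$pr1, bf$pr1[perm], tolerance = 1e-12)
  expect_equal(pseudo_energy(inst_p, bf$map[perm]), bf$energy,
               tolerance = 1e-12)
  lb <- lbp_marginals(inst, tol = 1e-10, max_iter = 500)
  lb_p <- lbp_marginals(inst_p, tol = 1e-10, max_iter = 500)
  expect_equal(lb_p$pr1, lb$pr1[perm], tolerance = 1e-8)
})
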