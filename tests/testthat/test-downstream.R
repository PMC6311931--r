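test_that("tissue merging unions edges with support counts", {
  n1 <- toy_network("A", "tfA", c("g1", "g2"))
  n2 <- toy_network("B", "tfA", c("g2", "g3"))
  tn <- merge_tissue(list(n1, n2), "tissueX")
  expect_equal(nrow(tn$edges), 3L)
  expect_equal(tn$edges$support[tn$edges$gene_id == "g2"], 2L)

  single <- merge_tissue(list(n1))
  expect_equal(sort(single$edges$gene_id), c("g1", "g2"))

  disjoint <- merge_tissue(list(n1, toy_network("C", "tfB", c("g8", "g9"))))
  expect_equal(nrow(disjoint$edges), 4L)
})

test_that("degree summary uses distinct TFs and targets as denominators", {
  bip <- merge_tissue(list(
    toy_network("A", "tf1", sprintf("g%d", 1:10)),
    toy_network("A", "tf2", sprintf("g%d", 1:10))))
  d <- degree_summary(bip)
  expect_equal(d$mean_in_degree, 2)
  expect_equal(d$mean_out_degree, 10)
  expect_equal(d$n_nodes, 12L)
  expect_equal(d$n_edges, 20L)

  one <- merge_tissue(list(toy_network("A", "tf1", "g1")))
  d1 <- degree_summary(one)
  expect_equal(c(d1$mean_in_degree, d1$mean_out_degree), c(1, 1))

  star <- merge_tissue(list(toy_network("A", "tf1", sprintf("g%d", 1:7))))
  ds <- degree_summary(star)
  expect_equal(ds$mean_out_degree, 7)
  expect_equal(ds$mean_in_degree, 1)
  expect_error(degree_summary(merge_tissue(list(toy_network("A", "t", character())))),
               "empty")
})

test_that("network Jaccard and per-TF Jaccard distance", {
  expect_equal(network_jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(network_jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(network_jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_warning(z <- network_jaccard(character(), character()), "empty")
  expect_equal(z, 0)

  expect_equal(tf_target_jaccard_distance(c("g1"), c("g1"))$distance, 0)
  expect_equal(tf_target_jaccard_distance("g1", "g2")$distance, 1)
  d <- tf_target_jaccard_distance(c("g1", "g2"), c("g2", "g3"))
  expect_equal(d$distance, 2 / 3)
  expect_equal(d$n_differential, 2L)
  expect_null(tf_target_jaccard_distance(character(), character()))

  # triangle inequality spot-check on random triples
  set.seed(4)
  jd <- function(a, b) tf_target_jaccard_distance(a, b)$distance
  for (i in 1:30) {
    u <- sprintf("g%d", 1:12)
    a <- sample(u, 5); b <- sample(u, 5); cc <- sample(u, 5)
    expect_lte(jd(a, cc), jd(a, b) + jd(b, cc) + 1e-12)
  }
})

test_that("differential network is the symmetric difference, ranked by in-edges", {
  ea <- data.frame(tf_id = c("t1", "t1", "t2", "t3"),
                   gene_id = c("g1", "g2", "g2", "g3"))
  eb <- data.frame(tf_id = c("t1", "t2"), gene_id = c("g1", "g9"))
  dn <- differential_network(ea, eb)
  expect_equal(nrow(dn$edges), 4L)          # (t1,g2),(t2,g2),(t3,g3),(t2,g9)
  expect_false(any(paste(dn$edges$tf_id, dn$edges$gene_id) %in% "t1 g1"))
  rk <- rank_differential_targets(dn)
  expect_equal(rk$gene_id[1], "g2")
  expect_equal(rk$n_differential_edges[1], 2L)
  expect_equal(rk$gene_id[-1], c("g3", "g9"))  # tie broken by id

  empty <- differential_network(ea, ea)
  expect_equal(nrow(rank_differential_targets(empty)), 0L)
})

test_that("Fisher enrichment matches the hypergeometric-summation oracle", {
  u <- sprintf("g%03d", 1:100)
  targets <- u[1:10]
  term <- u[6:15]          # overlap 5, table (5, 5, 5, 85)
  ft <- fisher_go_enrichment(targets, term, u)
  expect_equal(ft$table[1, 1], 5L)
  expect_equal(ft$p, oracle_fisher_greater(5, 5, 5, 85), tolerance = 1e-10)

  # disjoint small table can reach p = 1
  ft2 <- fisher_go_enrichment(u[1:2], u[3:4], u[1:10])
  expect_equal(ft2$p, oracle_fisher_greater(0, 2, 2, 6), tolerance = 1e-10)
  expect_equal(ft2$p, 1, tolerance = 1e-10)

  # randomised tables up to n = 200
  set.seed(8)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    uu <- sprintf("x%03d", 1:n)
    tg <- sample(uu, sample(3:(n / 2), 1))
    tm <- sample(uu, sample(3:(n / 2), 1))
    got <- fisher_go_enrichment(tg, tm, uu)
    a <- got$table[1, 1]; b <- got$table[1, 2]
    cc <- got$table[2, 1]; d <- got$table[2, 2]
    expect_equal(got$p, oracle_fisher_greater(a, b, cc, d), tolerance = 1e-10)
  }
  expect_error(fisher_go_enrichment("g1", "g2", character()), "empty universe")
})

test_that("enrichment score applies BH step-up at the stated FDR", {
  tests <- data.frame(p = c(0.01, 0.02, 0.04, 0.9))
  expect_equal(enrichment_score(tests, fdr = 0.2), 0.75)
  # hand-computed step-up: sorted p, adjusted = p * n / rank, cummin from top
  padj <- c(0.01 * 4 / 1, 0.02 * 4 / 2, 0.04 * 4 / 3, 0.9 * 4 / 4)
  padj <- rev(cummin(rev(padj)))
  expect_equal(sum(padj <= 0.2) / 4, 0.75)

  expect_equal(enrichment_score(data.frame(p = rep(1e-10, 5))), 1.0)
  expect_equal(enrichment_score(data.frame(p = rep(1, 5))), 0.0)
  # order invariance
  expect_equal(enrichment_score(tests[c(3, 1, 4, 2), , drop = FALSE]), 0.75)

  # positive mode keeps only terms annotated to the TF
  tests2 <- data.frame(tf_id = c("t1", "t1", "t2"),
                       term_id = c("GO1", "GO2", "GO1"),
                       p = c(1e-9, 0.9, 1e-9))
  sc <- enrichment_score(tests2, mode = "positive", fdr = 0.2,
                         tf_annotation = list(t1 = "GO1", t2 = character()))
  expect_equal(sc, 1.0)   # only (t1, GO1) retained
  expect_error(enrichment_score(tests2[0, ], fdr = 0.2), "zero tests")
})

test_that("rank-set enrichment: extreme, null and degenerate tie cases", {
  sc <- setNames(seq(1, 0.01, length.out = 50), sprintf("g%02d", 1:50))
  top <- names(sc)[1:8]
  res <- rank_set_enrichment(sc, top, n_perm = 200, seed = 1)
  expect_gt(res$es, 0.9)
  expect_lte(res$p, 1 / 201 + 1e-12)

  # all scores equal -> ES exactly 0 under block tie-handling
  eq <- setNames(rep(0.5, 30), sprintf("h%02d", 1:30))
  res_eq <- rank_set_enrichment(eq, names(eq)[1:5], n_perm = 100, seed = 1)
  expect_equal(res_eq$es, 0)

  # random target sets: p roughly uniform (mean near 0.5)
  set.seed(21)
  ps <- replicate(200, {
    tgt <- sample(names(sc), 8)
    rank_set_enrichment(sc, tgt, n_perm = 100, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  expect_error(rank_set_enrichment(sc, character(), 200), "empty target")
  expect_error(rank_set_enrichment(sc, "nope", 200), "unscored")
})

test_that("UPGMA clustering separates blocks and serialises to Newick", {
  # two well-separated blocks
  labs <- c("a1", "a2", "a3", "b1", "b2")
  d <- matrix(0.9, 5, 5, dimnames = list(labs, labs))
  d[1:3, 1:3] <- 0.1; d[4:5, 4:5] <- 0.1
  diag(d) <- 0
  hc <- hclust_average(d)
  top <- cutree(hc, k = 2)
  expect_equal(length(unique(top[1:3])), 1L)
  expect_equal(length(unique(top[4:5])), 1L)
  expect_true(top[1] != top[4])
  # final join height = mean of between-block distances (all 0.9)
  expect_equal(max(hc$height), 0.9)

  # two items join at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  hc2 <- hclust_average(d2)
  expect_equal(hc2$height, 0.4)

  # identical items join at height 0
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(max(hclust_average(d3)$height), 0)

  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "a1")

  d_bad <- d; d_bad[1, 2] <- 0.5
  expect_error(hclust_average(d_bad), "symmetric")
})
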