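test_that("identical groups yield no DEGs and zero fold change", {
  expr <- r_expr(8, 6, seed = 41)
  res <- deg_test(expr, colnames(expr)[1:3], colnames(expr)[1:3])
  expect_true(all(res$log2_fold_change == 0))
  expect_false(any(res$is_deg))
})

test_that("a strongly shifted gene is called and unshifted genes are not", {
  hits <- 0; false_hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    expr <- matrix(rnorm(20 * 6, 100, 5), nrow = 20,
                   dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6)))
    expr["g01", 4:6] <- expr["g01", 4:6] + 8 * 5 * 3  # ~8 SDs on log2 scale too
    res <- deg_test(expr, colnames(expr)[1:3], colnames(expr)[4:6])
    hits <- hits + ("g01" %in% res$gene[res$is_deg])
    false_hits <- false_hits + sum(res$is_deg & res$gene != "g01")
  }
  expect_gte(hits, 8)
  expect_lte(false_hits, 2)
})

test_that("BH adjustment matches the hand computation", {
  # p = {0.01, 0.02, 0.03, 0.04} -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # deg_test output respects fdr >= p
  expr <- r_expr(10, 6, seed = 51)
  res <- deg_test(expr, colnames(expr)[1:3], colnames(expr)[4:6])
  expect_true(all(res$fdr >= res$p - 1e-15))
})

test_that("TP-DEGs handle boundary tipping points and planted shifts", {
  set.seed(8)
  expr <- matrix(rnorm(10 * 9, 50, 2), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:9)))
  annot <- data.frame(
    sample_id = colnames(expr),
    group = c(rep("reference", 3), rep("case", 6)),
    time_label = c(rep("C", 3), rep(c("T1", "T2", "T3"), each = 2)),
    time_order = c(rep(0, 3), rep(1:3, each = 2)),
    replicate = c(1:3, rep(1:2, 3)))
  # shift g01 hugely between tipping (T2) and posterior (T3)
  t3 <- annot$sample_id[annot$time_label == "T3"]
  expr["g01", t3] <- expr["g01", t3] + 200
  cfg <- ldnb_config(deg_fdr = 0.05, deg_min_abs_log2fc = 0.5)
  res <- tp_degs(expr, annot, "T2", cfg)
  expect_true("g01" %in% res)

  # first time point as tipping: prior comparison skipped, still works
  expect_message(res1 <- tp_degs(expr, annot, "T1", cfg), "no prior")
  expect_true(is.character(res1))

  # no change anywhere -> empty
  set.seed(9)
  flat <- matrix(rnorm(10 * 9, 50, 2), nrow = 10,
                 dimnames = dimnames(expr))
  expect_length(tp_degs(flat, annot, "T2", cfg), 0)
})

test_that("fused SSNs follow the support rule and are monotone in support", {
  ssn1 <- graph_from_pairs(c("A", "B"), c("B", "C"))
  ssn2 <- graph_from_pairs(c("B", "C"), c("C", "D"))
  fused <- fuse_ssns(list(ssn1, ssn2), min_support = 2)
  expect_equal(igraph::ecount(fused), 1L)
  expect_setequal(as.vector(igraph::ends(fused, 1)), c("B", "C"))
  expect_equal(igraph::E(fused)$weight, 2L)

  union_net <- fuse_ssns(list(ssn1, ssn2), min_support = 1)
  expect_equal(igraph::ecount(union_net), 3L)

  ssn3 <- graph_from_pairs(c("A", "B"))
  f2of3 <- fuse_ssns(list(ssn1, ssn2, ssn3), min_support = 2)
  keys <- apply(igraph::as_edgelist(f2of3), 1, function(e)
    paste(sort(e), collapse = "-"))
  expect_setequal(keys, c("A-B", "B-C"))

  # monotone: support-2 edges are a subset of support-1 edges
  k1of3 <- apply(igraph::as_edgelist(fuse_ssns(list(ssn1, ssn2, ssn3), 1)), 1,
                 function(e) paste(sort(e), collapse = "-"))
  expect_true(all(keys %in% k1of3))
  expect_warning(fuse_ssns(list(ssn1), min_support = 2), "min_support")
})

test_that("differential networks are exact set differences and antisymmetric", {
  before <- graph_from_pairs(c("A", "B"), c("B", "C"))
  at <- graph_from_pairs(c("B", "C"), c("C", "D"))
  dn <- differential_network(before, at)
  expect_equal(igraph::ecount(dn$appeared), 1L)
  expect_equal(igraph::ecount(dn$disappeared), 1L)
  expect_setequal(as.vector(igraph::ends(dn$appeared, 1)),
                  c("C", "D"))
  expect_setequal(as.vector(igraph::ends(dn$disappeared, 1)),
                  c("A", "B"))

  same <- differential_network(before, before)
  expect_equal(igraph::ecount(same$appeared), 0L)
  expect_equal(igraph::ecount(same$disappeared), 0L)

  swapped <- differential_network(at, before)
  expect_equal(sort(ldnb:::edge_keys(swapped$appeared)),
               sort(ldnb:::edge_keys(dn$disappeared)))
  expect_equal(sort(ldnb:::edge_keys(swapped$disappeared)),
               sort(ldnb:::edge_keys(dn$appeared)))

  # node degrees recomputable from the union of changed edges
  set.seed(17)
  g1 <- igraph::sample_gnp(10, 0.3); igraph::V(g1)$name <- letters[1:10]
  g2 <- igraph::sample_gnp(10, 0.3); igraph::V(g2)$name <- letters[1:10]
  d12 <- differential_network(g1, g2)
  manual <- table(unlist(strsplit(c(ldnb:::edge_keys(d12$appeared),
                                    ldnb:::edge_keys(d12$disappeared)), "\t")))
  want <- setNames(as.integer(manual), names(manual))
  expect_equal(d12$node_degrees[sort(names(want))], want[sort(names(want))])
})

test_that("TP-DNG hubs are strictly-above-average-degree nodes", {
  star <- differential_network(igraph::make_empty_graph(0, directed = FALSE),
                               graph_from_pairs(c("h", "a"), c("h", "b"),
                                                c("h", "c"), c("h", "d")))
  expect_identical(tp_dngs(star), "h")

  ring <- differential_network(igraph::make_empty_graph(0, directed = FALSE),
                               graph_from_pairs(c("a", "b"), c("b", "c"),
                                                c("c", "a")))
  expect_length(tp_dngs(ring), 0)  # regular graph: strict inequality

  expect_warning(
    empty <- tp_dngs(differential_network(
      igraph::make_empty_graph(0, directed = FALSE),
      igraph::make_empty_graph(0, directed = FALSE))),
    "empty")
  expect_length(empty, 0)
})
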