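test_that("local modules match hand-countable topologies", {
  path <- graph_from_pairs(c("A", "B"), c("B", "C"), c("C", "D"))
  m <- extract_module(path, "B")
  expect_setequal(m$first_neighbors, c("A", "C"))
  expect_setequal(m$second_neighbors, "D")
  expect_equal(m$k_cross, 1L)  # edge C-D
  expect_false(m$eligible)     # only 2 first neighbors

  star <- graph_from_pairs(c("h", "l1"), c("h", "l2"), c("h", "l3"), c("h", "l4"))
  ms <- extract_module(star, "h")
  expect_equal(ms$n_first, 4L)
  expect_length(ms$second_neighbors, 0)
  expect_false(ms$eligible)

  absent <- extract_module(path, "Z")
  expect_false(absent$in_network)
  expect_false(absent$eligible)
})

test_that("local modules agree with an edge-scan BFS oracle on random graphs", {
  set.seed(77)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(15, 0.2)
    igraph::V(g)$name <- sprintf("g%02d", 1:15)
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) next
    for (gene in sample(igraph::V(g)$name, 5)) {
      m <- extract_module(g, gene)
      o <- o_neighbors(el, gene)
      expect_setequal(m$first_neighbors, o$first)
      expect_setequal(m$second_neighbors, o$second)
    }
  }
})

test_that("deviation statistics follow their defining arithmetic", {
  expr <- rbind(gx = c(1, 2, 3), gy = c(4, 4, 4), gz = c(0, 2, 4),
                gw = c(5, 5, 5))
  colnames(expr) <- paste0("r", 1:3)
  d <- c(gx = 2, gy = 7.5, gz = 2, gw = 5)
  expect_equal(sed("gx", d, expr), 0)
  expect_equal(sed("gy", d, expr), 3.5)

  mod <- structure(list(center = "gy", first_neighbors = c("gx", "gz", "gw"),
                        n_first = 3L), class = "ldnb_module")
  # center sED = 3.5, neighbors all 0 -> (3.5 + 0) / 4
  expect_equal(sed_in(mod, d, expr), 3.5 / 4)
})

test_that("module correlation terms follow the absolute-value convention", {
  g <- graph_from_pairs(c("x", "a"), c("x", "b"), c("x", "c"),
                        c("a", "m"), c("b", "m"))
  igraph::E(g)$spcc <- c(0.6, -0.6, 0.6, -0.2, 0.4)
  m <- extract_module(g, "x")
  expect_setequal(m$first_neighbors, c("a", "b", "c"))
  expect_setequal(m$second_neighbors, "m")
  expect_equal(m$k_cross, 2L)
  expect_equal(spcc_in(m, g), 0.6)
  expect_equal(spcc_in(m, g, convention = "signed"), 0.2)
  expect_equal(spcc_out(m, g), 0.3)  # mean(|-0.2|, |0.4|)

  # floor rule when no cross edges exist
  star <- graph_from_pairs(c("x", "a"), c("x", "b"), c("x", "c"))
  igraph::E(star)$spcc <- c(0.5, 0.5, 0.5)
  mstar <- extract_module(star, "x")
  expect_equal(spcc_out(mstar, star, epsilon_out = 1e-6), 1e-6)
})

test_that("the local score composes the three statistics", {
  expect_equal(local_score(2, 0.5, 0.25), 4)
  expect_equal(local_score(0, 0.7, 0.2), 0)
})

test_that("vectorized per-sample scores equal the naive raw-data oracle", {
  cfg <- ldnb_config(alpha_edge = 0.3)
  for (seed in c(2, 13)) {
    expr <- r_expr(15, 8, seed = seed)
    set.seed(seed + 100)
    d <- rnorm(15, 5, 2.5)
    names(d) <- rownames(expr)
    ssn <- suppressWarnings(build_ssn(expr, d, config = cfg))
    if (igraph::ecount(ssn) == 0) next
    tab <- dnb_scores(ssn, expr, d, cfg)
    el <- igraph::as_edgelist(ssn)
    for (i in seq_len(nrow(tab))) {
      o <- o_local_score(el, expr, d, tab$gene[i])
      if (is.na(o)) expect_false(tab$eligible[i])
      else expect_equal(tab$local_score[i], o, tolerance = 1e-10)
    }
  }
})

test_that("scores are invariant to gene and sample ordering", {
  cfg <- ldnb_config(alpha_edge = 0.3)
  expr <- r_expr(12, 8, seed = 31)
  set.seed(131)
  d <- rnorm(12, 5, 2); names(d) <- rownames(expr)
  ssn <- suppressWarnings(build_ssn(expr, d, config = cfg))
  tab1 <- dnb_scores(ssn, expr, d, cfg)
  perm_g <- sample(nrow(expr)); perm_s <- sample(ncol(expr))
  ssn2 <- suppressWarnings(build_ssn(expr[perm_g, perm_s], d[perm_g], config = cfg))
  tab2 <- dnb_scores(ssn2, expr[perm_g, perm_s], d[perm_g], cfg)
  m <- merge(tab1, tab2, by = "gene")
  expect_equal(m$local_score.x, m$local_score.y, tolerance = 1e-12)
})

test_that("sample scores use a tie-expanded top-k mean", {
  tab <- data.frame(sample_id = "s", gene = letters[1:4],
                    local_score = c(4, 3, 2, 1), eligible = TRUE)
  expect_equal(sample_score(tab, "s", 2), 3.5)
  expect_equal(sample_score(tab, "s", 10), 2.5)  # saturation: mean of all
  ties <- data.frame(sample_id = "s", gene = letters[1:4],
                     local_score = c(4, 3, 3, 1), eligible = TRUE)
  expect_equal(sample_score(ties, "s", 2), mean(c(4, 3, 3)))
  none <- data.frame(sample_id = "s", gene = "a", local_score = 2,
                     eligible = FALSE)
  expect_message(out <- sample_score(none, "s", 2), "no eligible")
  expect_true(is.na(out))
})

test_that("tipping call is the argmax with earliest-time tie-breaking", {
  annot <- data.frame(
    sample_id = c("r1", "r2", "r3", "c1", "c2", "c3"),
    group = c("reference", "reference", "reference", "case", "case", "case"),
    time_label = c("T1", "T1", "T1", "D1", "D6", "D8"),
    time_order = c(1, 1, 1, 1, 2, 3), replicate = c(1, 2, 3, 1, 1, 1))
  tab <- data.frame(sample_id = rep(c("c1", "c2", "c3"), each = 2),
                    gene = rep(c("a", "b"), 3),
                    local_score = c(2, 2, 5, 5, 1, 1), eligible = TRUE)
  tp <- detect_tipping_point(tab, annot, ldnb_config(top_k = 2))
  expect_equal(tp$tipping_time, "D6")
  expect_false(tp$tied)

  tab$local_score <- 3
  tp2 <- detect_tipping_point(tab, annot, ldnb_config(top_k = 2))
  expect_equal(tp2$tipping_time, "D1")
  expect_true(tp2$tied)
})

test_that("DNB genes require top-k membership in enough tipping samples", {
  annot <- data.frame(
    sample_id = c("r1", "r2", "r3", "c1", "c2", "c3", "d1"),
    group = c(rep("reference", 3), rep("case", 4)),
    time_label = c(rep("T0", 3), "D6", "D6", "D6", "D8"),
    time_order = c(0, 0, 0, 1, 1, 1, 2), replicate = c(1:3, 1:3, 1))
  tab <- rbind(
    data.frame(sample_id = "c1", gene = c("a", "b", "z"),
               local_score = c(9, 8, 1), eligible = TRUE),
    data.frame(sample_id = "c2", gene = c("a", "b", "z"),
               local_score = c(9, 1, 8), eligible = TRUE),
    data.frame(sample_id = "c3", gene = c("a", "b", "z"),
               local_score = c(9, 8, 1), eligible = TRUE))
  sel <- select_dnb_genes(tab, annot, "D6", ldnb_config(top_k = 2))
  expect_true("a" %in% sel$gene)        # top-2 in 3 of 3
  expect_true("b" %in% sel$gene)        # top-2 in 2 of 3
  expect_false("z" %in% sel$gene)       # top-2 in 1 of 3
  expect_equal(sel$support[sel$gene == "a"], 3L)

  # single-sample tipping time degrades with a warning
  expect_warning(
    sel1 <- select_dnb_genes(tab[tab$sample_id == "c1", ],
                             annot[annot$sample_id %in% c("r1", "r2", "r3", "c1"), ],
                             "D6", ldnb_config(top_k = 2)),
    "support threshold")
  expect_setequal(sel1$gene, c("a", "b"))
})
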