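test_that("reference correlations match hand values and the summation oracle", {
  expr <- rbind(gx = c(1, 2, 3), gy = c(2, 4, 6), gz = c(3, 2, 1))
  colnames(expr) <- paste0("r", 1:3)
  rc <- reference_pcc(expr)
  expect_equal(rc$pcc["gx", "gy"], 1)
  expect_equal(rc$pcc["gx", "gz"], -1)
  expect_equal(rc$n, 3L)

  expr2 <- r_expr(10, 6, seed = 11)
  rc2 <- reference_pcc(expr2)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(rc2$pcc[i, j], o_pcc(expr2[i, ], expr2[j, ]),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance genes are flagged undefined, small n is rejected", {
  expr <- rbind(gx = c(1, 1, 1), gy = c(1, 2, 3))
  colnames(expr) <- paste0("r", 1:3)
  rc <- reference_pcc(expr)
  expect_identical(rc$constant, "gx")
  expect_true(is.na(rc$pcc["gx", "gy"]))
  expect_error(reference_pcc(expr[, 1:2]), "3 reference samples")
})

test_that("sPCC matches closed forms: collinear extension and a worked pair", {
  expr <- rbind(gx = c(1, 2, 3), gy = c(1, 2, 3))
  colnames(expr) <- paste0("r", 1:3)
  expect_equal(spcc(expr, c(gx = 4, gy = 4), "gx", "gy"), 0)
  # PCC_4 = 0.5 / sqrt(5 * 2.75), PCC_3 = 1
  expect_equal(spcc(expr, c(gx = 4, gy = 1), "gx", "gy"),
               0.5 / sqrt(5 * 2.75) - 1, tolerance = 1e-12)
  expect_equal(spcc(expr, c(gx = 4, gy = 1), "gx", "gy"), -0.8652,
               tolerance = 1e-4)
  const <- rbind(gx = c(2, 2, 2), gy = c(1, 2, 3))
  colnames(const) <- paste0("r", 1:3)
  expect_true(is.na(spcc(const, c(gx = 2, gy = 5), "gx", "gy")))
})

test_that("sPCC matrix agrees with the raw-vector oracle on random data", {
  expr <- r_expr(8, 7, seed = 3)
  d <- rnorm(8, 5, 2)
  names(d) <- rownames(expr)
  sp <- ldnb:::spcc_matrix(expr, d)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(sp[i, j],
                 o_spcc(expr[i, ], expr[j, ], d[i], d[j]),
                 tolerance = 1e-12)
  }
})

test_that("edge significance follows the volcano z form", {
  expect_equal(edge_significance(0, 0.3, 10)$z, 0)
  expect_equal(edge_significance(0, 0.3, 10)$p, 1)
  res <- edge_significance(0.2, 0, 11)
  expect_equal(res$z, 2.0)
  expect_equal(res$p, 2 * pnorm(-2), tolerance = 1e-12)
  expect_equal(res$p, 0.0455, tolerance = 1e-3)
  degen <- edge_significance(0.1, 1, 11)
  expect_false(degen$testable)
  expect_true(is.na(degen$p))
})

test_that("SSN retains an analytically perturbed pair and drops null pairs", {
  # 6 genes, independent reference; sample d is extreme on g01 and g02 only,
  # producing |z| far above the alpha = 0.05 cut for that pair alone.
  expr <- r_expr(6, 10, seed = 21)
  d <- rowMeans(expr)
  d["g01"] <- d["g01"] + 6
  d["g02"] <- d["g02"] + 6
  g <- build_ssn(expr, d, config = ldnb_config(alpha_edge = 0.05))
  el <- igraph::as_edgelist(g)
  keys <- apply(el, 1, function(e) paste(sort(e), collapse = "-"))
  expect_true("g01-g02" %in% keys)
  # every retained edge involves a perturbed gene; null-null pairs dropped
  expect_true(all(el[, 1] %in% c("g01", "g02") | el[, 2] %in% c("g01", "g02")))
})

test_that("SSN edge set is simple, monotone in alpha, and deterministic", {
  expr <- r_expr(12, 8, seed = 5)
  d <- rnorm(12, 5, 2)
  names(d) <- rownames(expr)
  cfg_lo <- ldnb_config(alpha_edge = 0.01)
  cfg_hi <- ldnb_config(alpha_edge = 0.2)
  g_lo <- suppressWarnings(build_ssn(expr, d, config = cfg_lo))
  g_hi <- suppressWarnings(build_ssn(expr, d, config = cfg_hi))
  expect_true(igraph::ecount(g_lo) <= igraph::ecount(g_hi))
  expect_true(igraph::is_simple(g_hi))
  g_again <- suppressWarnings(build_ssn(expr, d, config = cfg_hi))
  expect_identical(igraph::as_edgelist(g_hi), igraph::as_edgelist(g_again))
  # alpha -> 0 limit: a near-reference sample has bounded |z|, so a tiny
  # alpha retains nothing
  d_near <- rowMeans(expr) + 0.3
  g0 <- suppressWarnings(
    build_ssn(expr, d_near, config = ldnb_config(alpha_edge = 1e-12)))
  expect_equal(igraph::ecount(g0), 0L)
})

test_that("a background network restricts the candidate pair space", {
  expr <- r_expr(6, 10, seed = 21)
  d <- rowMeans(expr)
  d["g01"] <- d["g01"] + 6
  d["g02"] <- d["g02"] + 6
  bg <- graph_from_pairs(c("g03", "g04"))  # perturbed pair not a candidate
  g <- suppressWarnings(
    build_ssn(expr, d, background = bg, config = ldnb_config()))
  if (igraph::ecount(g) > 0) {
    keys <- apply(igraph::as_edgelist(g), 1, function(e)
      paste(sort(e), collapse = "-"))
    expect_false("g01-g02" %in% keys)
  } else succeed()
})

test_that("a reference-mean sample yields near-null SSNs at moderate alpha", {
  expr <- r_expr(10, 12, seed = 9)
  d <- rowMeans(expr)
  g <- suppressWarnings(build_ssn(expr, d, config = ldnb_config(alpha_edge = 0.01)))
  # the mean vector is maximally consistent with the reference: few edges
  expect_true(igraph::ecount(g) <= 3)
})

test_that("the empirical-null (rank) edge test is a usable alternative", {
  expr <- r_expr(6, 10, seed = 21)
  d <- rowMeans(expr)
  d["g01"] <- d["g01"] + 6
  d["g02"] <- d["g02"] + 6
  cfg <- ldnb_config(edge_test = "u", alpha_edge = 0.15)
  g <- suppressWarnings(build_ssn(expr, d, config = cfg))
  keys <- apply(igraph::as_edgelist(g), 1, function(e)
    paste(sort(e), collapse = "-"))
  expect_true("g01-g02" %in% keys)
})
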