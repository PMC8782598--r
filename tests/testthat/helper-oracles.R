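# Straight-line, loop-based reimplementations used as independent oracles.
# These deliberately avoid the package's vectorized code paths.

# Pearson correlation by elementwise summation
o_pcc <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n
  yb <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx2 <- dx2 + (x[i] - xb)^2
    dy2 <- dy2 + (y[i] - yb)^2
  }
  as.numeric(num / sqrt(dx2 * dy2))
}

# classical log-rank in its expected-events (Peto) form, with risk sets
# shrinking as events occur; no censoring before the end of follow-up
o_logrank_peto <- function(event_time_by_sample, group_a, group_b, times) {
  n_at_risk <- function(group, t) {
    n <- 0
    for (s in group) {
      et <- event_time_by_sample[[s]]
      if (is.na(et) || et >= t) n <- n + 1
    }
    n
  }
  E_A <- 0; E_B <- 0; O_A <- 0; O_B <- 0
  for (t in times) {
    O_Ai <- sum(vapply(group_a, function(s) {
      et <- event_time_by_sample[[s]]; !is.na(et) && et == t
    }, logical(1)))
    O_Bi <- sum(vapply(group_b, function(s) {
      et <- event_time_by_sample[[s]]; !is.na(et) && et == t
    }, logical(1)))
    N_Ai <- n_at_risk(group_a, t); N_Bi <- n_at_risk(group_b, t)
    O_i <- O_Ai + O_Bi
    if (N_Ai + N_Bi > 0) {
      E_A <- E_A + O_i * N_Ai / (N_Ai + N_Bi)
      E_B <- E_B + O_i * N_Bi / (N_Ai + N_Bi)
    }
    O_A <- O_A + O_Ai; O_B <- O_B + O_Bi
  }
  if (O_A + O_B == 0) return(NA_real_)
  (O_A - E_A)^2 / E_A + (O_B - E_B)^2 / E_B
}

# single-sample correlation perturbation from raw vectors
o_spcc <- function(ref_x, ref_y, dx, dy) {
  o_pcc(c(ref_x, dx), c(ref_y, dy)) - o_pcc(ref_x, ref_y)
}

# first/second neighbors by explicit edge scans (no igraph)
o_neighbors <- function(edges, gene) {
  first <- character()
  for (i in seq_len(nrow(edges))) {
    if (edges[i, 1] == gene) first <- c(first, edges[i, 2])
    if (edges[i, 2] == gene) first <- c(first, edges[i, 1])
  }
  first <- unique(first)
  second <- character()
  for (f in first) {
    for (i in seq_len(nrow(edges))) {
      if (edges[i, 1] == f) second <- c(second, edges[i, 2])
      if (edges[i, 2] == f) second <- c(second, edges[i, 1])
    }
  }
  second <- setdiff(unique(second), c(gene, first))
  list(first = first, second = second)
}

# local DNB score recomputed from raw expression + the SSN edge list
o_local_score <- function(edges, expr_ref, sample_d, gene,
                          min_first = 3, min_second = 1, eps = 1e-6) {
  nb <- o_neighbors(edges, gene)
  if (length(nb$first) < min_first || length(nb$second) < min_second)
    return(NA_real_)
  sed1 <- function(g) abs(sample_d[[g]] - mean(expr_ref[g, ]))
  sp <- function(a, b) o_spcc(expr_ref[a, ], expr_ref[b, ],
                              sample_d[[a]], sample_d[[b]])
  sed_in <- (sed1(gene) + sum(vapply(nb$first, sed1, numeric(1)))) /
    (1 + length(nb$first))
  spcc_in <- mean(vapply(nb$first, function(y) abs(sp(gene, y)), numeric(1)))
  cross <- c()
  for (y in nb$first) for (z in nb$second) {
    hit <- any((edges[, 1] == y & edges[, 2] == z) |
               (edges[, 1] == z & edges[, 2] == y))
    if (hit) cross <- c(cross, abs(sp(y, z)))
  }
  spcc_out <- if (length(cross) == 0) eps else max(mean(cross), eps)
  sed_in * spcc_in / spcc_out
}

# fixed-group-size risk statistic, equation by equation
o_risk <- function(event_time_by_sample, group_a, group_b, times) {
  N_A <- length(group_a); N_B <- length(group_b); N <- N_A + N_B
  E_A <- 0; E_B <- 0; O_A <- 0; O_B <- 0
  for (t in times) {
    O_Ai <- 0; O_Bi <- 0
    for (s in group_a)
      if (!is.na(event_time_by_sample[[s]]) && event_time_by_sample[[s]] == t)
        O_Ai <- O_Ai + 1
    for (s in group_b)
      if (!is.na(event_time_by_sample[[s]]) && event_time_by_sample[[s]] == t)
        O_Bi <- O_Bi + 1
    O_i <- O_Ai + O_Bi
    E_A <- E_A + O_i * N_A / N
    E_B <- E_B + O_i * N_B / N
    O_A <- O_A + O_Ai
    O_B <- O_B + O_Bi
  }
  if (O_A + O_B == 0) return(NA_real_)
  (O_A - E_A)^2 / E_A + (O_B - E_B)^2 / E_B
}

# one-sided hypergeometric tail by explicit enumeration
o_hyper_tail <- function(n_universe, n1, n2, k) {
  tot <- 0
  for (j in k:min(n1, n2)) {
    tot <- tot + choose(n1, j) * choose(n_universe - n1, n2 - j) /
      choose(n_universe, n2)
  }
  tot
}

# small random expression fixture
r_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 5, 1), nrow = n_genes,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

graph_from_pairs <- function(...) {
  el <- do.call(rbind, list(...))
  igraph::graph_from_edgelist(el, directed = FALSE)
}
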