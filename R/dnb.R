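#' Extract a gene's local module from an SSN
#'
#' The local module of a target gene is the gene itself plus its first-order
#' neighbors; second-order neighbors (distance exactly 2) define the module
#' boundary for the outside-correlation term. `k_cross` counts SSN edges with
#' one endpoint among the first and one among the second neighbors. A module
#' is eligible for scoring when it has at least `min_first` first-order and
#' `min_second` second-order neighbors.
#'
#' @param ssn igraph SSN.
#' @param gene gene identifier.
#' @param min_first,min_second eligibility thresholds (defaults 3 and 1).
#' @return list of class `ldnb_module` with `center`, `first_neighbors`,
#'   `second_neighbors`, `n_first`, `k_cross`, `eligible`, `in_network`.
#' @export
extract_module <- function(ssn, gene, min_first = 3L, min_second = 1L) {
  vn <- igraph::V(ssn)$name
  if (!(gene %in% vn)) {
    return(structure(list(center = gene, first_neighbors = character(),
                          second_neighbors = character(), n_first = 0L,
                          k_cross = 0L, eligible = FALSE, in_network = FALSE),
                     class = "ldnb_module"))
  }
  first <- igraph::V(ssn)$name[igraph::neighbors(ssn, gene)]
  ego2 <- igraph::V(ssn)$name[igraph::ego(ssn, order = 2, nodes = gene)[[1L]]]
  second <- setdiff(ego2, c(gene, first))
  k_cross <- 0L
  if (length(first) && length(second)) {
    sub <- igraph::induced_subgraph(ssn, c(first, second))
    el <- igraph::as_edgelist(sub)
    if (nrow(el)) {
      k_cross <- sum((el[, 1L] %in% first & el[, 2L] %in% second) |
                     (el[, 2L] %in% first & el[, 1L] %in% second))
    }
  }
  structure(list(center = gene, first_neighbors = first,
                 second_neighbors = second, n_first = length(first),
                 k_cross = as.integer(k_cross),
                 eligible = length(first) >= min_first && length(second) >= min_second,
                 in_network = TRUE),
            class = "ldnb_module")
}

#' Single-sample expression deviation of one gene
#'
#' `sED = |x_d - mean(x_ref)|`: the absolute deviation of the case sample's
#' expression from the reference mean.
#'
#' @param gene gene identifier.
#' @param sample_d named numeric vector for the case sample.
#' @param expr_ref reference expression matrix.
#' @return non-negative deviation value.
#' @export
sed <- function(gene, sample_d, expr_ref) {
  abs(sample_d[[gene]] - mean(expr_ref[gene, ]))
}

#' Mean expression deviation inside a local module
#'
#' Averages the single-sample deviation over the `1 + n_first` module genes
#' (center plus first-order neighbors).
#'
#' @param module an [extract_module()] result.
#' @inheritParams sed
#' @return non-negative mean deviation.
#' @export
sed_in <- function(module, sample_d, expr_ref) {
  genes <- c(module$center, module$first_neighbors)
  vals <- vapply(genes, sed, numeric(1), sample_d = sample_d, expr_ref = expr_ref)
  sum(vals) / (1 + module$n_first)
}

# |sPCC| (or signed sPCC) of a set of SSN edges given as a 2-col matrix.
ssn_edge_spcc <- function(ssn, pairs, convention = "absolute") {
  eids <- igraph::get_edge_ids(ssn, t(pairs))
  v <- igraph::E(ssn)$spcc[eids]
  if (identical(convention, "absolute")) abs(v) else v
}

#' Mean correlation perturbation inside a local module
#'
#' Mean of the sPCC values on the center-to-first-neighbor SSN edges. Under
#' the default absolute-value convention the mean is taken over `|sPCC|`,
#' mirroring the "average absolute correlation" framing of the biomarker
#' conditions; the signed variant is available via `convention = "signed"`.
#'
#' @param module an [extract_module()] result with `n_first >= 1`.
#' @param ssn igraph SSN carrying edge attribute `spcc`.
#' @param convention `"absolute"` (default) or `"signed"`.
#' @return mean perturbation over the center's incident module edges.
#' @export
spcc_in <- function(module, ssn, convention = "absolute") {
  if (module$n_first < 1L) return(NA_real_)
  pairs <- cbind(module$center, module$first_neighbors)
  mean(ssn_edge_spcc(ssn, pairs, convention))
}

#' Mean correlation perturbation across the module boundary
#'
#' Mean sPCC over the `k_cross` SSN edges joining first-order to second-order
#' neighbors. If there are no cross edges, or the mean falls below
#' `epsilon_out`, the floor `epsilon_out` is returned so that the local score
#' stays finite (second-order neighbors guarantee at least one cross edge for
#' eligible modules, so the floor is rarely active).
#'
#' @inheritParams spcc_in
#' @param epsilon_out small positive floor.
#' @return positive value (absolute convention) or floored signed mean.
#' @export
spcc_out <- function(module, ssn, convention = "absolute", epsilon_out = 1e-6) {
  if (module$k_cross < 1L) return(epsilon_out)
  first <- module$first_neighbors
  second <- module$second_neighbors
  sub <- igraph::induced_subgraph(ssn, c(first, second))
  el <- igraph::as_edgelist(sub)
  keep <- (el[, 1L] %in% first & el[, 2L] %in% second) |
    (el[, 2L] %in% first & el[, 1L] %in% second)
  el <- el[keep, , drop = FALSE]
  v <- mean(ssn_edge_spcc(ssn, el, convention))
  max(v, epsilon_out)
}

#' Local DNB score
#'
#' `I_s(x) = sED_in * sPCC_in / sPCC_out`: deviation and intra-module
#' perturbation in the numerator, boundary perturbation in the denominator,
#' so genes whose neighborhood deviates strongly and coherently while
#' decoupling from the rest of the network score highest.
#'
#' @param sed_in,spcc_in,spcc_out the three module statistics.
#' @return non-negative score (under the absolute convention).
#' @export
local_score <- function(sed_in, spcc_in, spcc_out) {
  sed_in * spcc_in / spcc_out
}

#' Score every gene of one sample's SSN
#'
#' Vectorized computation of the local DNB score for all genes in an SSN.
#' Genes absent from the SSN get no row; ineligible genes (fewer than
#' `min_first_neighbors` first-order or `min_second_neighbors` second-order
#' neighbors) are reported with `eligible = FALSE` and an `NA` score.
#'
#' Implementation note: first/second neighborhoods, cross-edge counts and
#' sPCC sums are obtained from dense adjacency products, which is exact and
#' fast for SSNs up to a few thousand genes; the per-gene functions
#' ([extract_module()] etc.) define the reference semantics.
#'
#' @param ssn igraph SSN for one sample.
#' @param expr_ref reference expression matrix.
#' @param sample_d named numeric vector for the sample.
#' @param config an [ldnb_config()].
#' @return data.frame: gene, n_first, n_second, k_cross, sed_in, spcc_in,
#'   spcc_out, local_score, eligible.
#' @export
dnb_scores <- function(ssn, expr_ref, sample_d, config = ldnb_config()) {
  genes <- igraph::V(ssn)$name
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), n_first = integer(),
                      n_second = integer(), k_cross = integer(),
                      sed_in = numeric(), spcc_in = numeric(),
                      spcc_out = numeric(), local_score = numeric(),
                      eligible = logical()))
  }
  B <- as.matrix(igraph::as_adjacency_matrix(ssn, sparse = TRUE))
  W <- as.matrix(igraph::as_adjacency_matrix(ssn, attr = "spcc", sparse = TRUE))
  if (identical(config$spcc_convention, "absolute")) W <- abs(W)
  n_first <- rowSums(B)
  reach2 <- (B %*% B) > 0
  S <- reach2 & !(B > 0)
  diag(S) <- FALSE
  mode(S) <- "numeric"
  n_second <- rowSums(S)

  sed_vec <- abs(sample_d[genes] - rowMeans(expr_ref[genes, , drop = FALSE]))
  sed_in_v <- (sed_vec + as.vector(B %*% sed_vec)) / (1 + n_first)
  spcc_in_v <- ifelse(n_first > 0, rowSums(W) / n_first, NA_real_)

  k_cross <- as.vector(rowSums((B %*% B) * S))
  cross_sum <- as.vector(rowSums((B %*% W) * S))
  spcc_out_v <- ifelse(k_cross > 0, cross_sum / k_cross, config$epsilon_out)
  spcc_out_v <- pmax(spcc_out_v, config$epsilon_out)

  eligible <- n_first >= config$min_first_neighbors &
    n_second >= config$min_second_neighbors
  score <- ifelse(eligible, sed_in_v * spcc_in_v / spcc_out_v, NA_real_)
  data.frame(gene = genes, n_first = as.integer(n_first),
             n_second = as.integer(n_second), k_cross = as.integer(k_cross),
             sed_in = sed_in_v, spcc_in = spcc_in_v, spcc_out = spcc_out_v,
             local_score = score, eligible = eligible,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score table over all case samples
#'
#' @param ssns named list of SSNs from [build_all_ssns()].
#' @param expr expression matrix (genes x samples).
#' @param annot sample annotation.
#' @param config an [ldnb_config()].
#' @return data.frame with a `sample_id` column prepended to the
#'   [dnb_scores()] columns.
#' @export
dnb_score_table <- function(ssns, expr, annot, config = ldnb_config()) {
  ref_ids <- annot$sample_id[annot$group == "reference"]
  expr_ref <- expr[, ref_ids, drop = FALSE]
  out <- lapply(names(ssns), function(sid) {
    df <- dnb_scores(ssns[[sid]], expr_ref, expr[, sid], config)
    if (nrow(df)) cbind(sample_id = sid, df, stringsAsFactors = FALSE)
    else cbind(sample_id = character(0), df)
  })
  do.call(rbind, out)
}

# Tie-expanded top-k values: all values tied with the k-th largest are
# included, then averaged; deterministic under permutation of input order.
top_k_mean <- function(values, k) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) return(NA_real_)
  if (length(values) <= k) return(mean(values))
  sorted <- sort(values, decreasing = TRUE)
  thresh <- sorted[k]
  mean(values[values >= thresh])
}

#' DNB score of one sample
#'
#' Mean of the sample's `top_k` largest eligible local scores; if fewer than
#' `top_k` eligible genes exist, the mean of all of them. Values tied with
#' the k-th largest are all included (deterministic tie rule).
#'
#' @param score_table output of [dnb_score_table()].
#' @param sample sample identifier.
#' @param top_k count of top genes to average.
#' @return the sample score, or `NA` (with a message) if the sample has no
#'   eligible gene.
#' @export
sample_score <- function(score_table, sample, top_k) {
  rows <- score_table[score_table$sample_id == sample & score_table$eligible, ]
  if (nrow(rows) == 0L) {
    message("sample ", sample, " has no eligible genes; score undefined")
    return(NA_real_)
  }
  top_k_mean(rows$local_score, top_k)
}

#' Detect the tipping point from per-sample scores
#'
#' Each case time point's score is the mean over its samples' scores; the
#' tipping point is the time with the maximal score (ties resolved to the
#' earliest time and flagged).
#'
#' @param score_table output of [dnb_score_table()].
#' @param annot sample annotation.
#' @param config an [ldnb_config()].
#' @return list of class `ldnb_tipping`: `sample_scores` (data.frame),
#'   `time_scores` (data.frame time_label, time_order, score, n_samples),
#'   `tipping_time`, `tied` flag.
#' @export
detect_tipping_point <- function(score_table, annot, config = ldnb_config()) {
  ca <- annot[annot$group == "case", , drop = FALSE]
  if (length(unique(ca$time_label)) < 2L)
    stop("tipping-point detection needs at least two case time points", call. = FALSE)
  samp <- vapply(ca$sample_id, function(s)
    sample_score(score_table, s, config$top_k), numeric(1))
  sample_scores <- data.frame(sample_id = ca$sample_id,
                              time_label = ca$time_label,
                              time_order = ca$time_order,
                              score = unname(samp), stringsAsFactors = FALSE)
  lv <- unique(sample_scores[order(sample_scores$time_order),
                             c("time_label", "time_order")])
  per_time <- vapply(lv$time_label, function(lab) {
    v <- sample_scores$score[sample_scores$time_label == lab]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  agg <- data.frame(time_label = lv$time_label, time_order = lv$time_order,
                    score = unname(per_time),
                    n_samples = vapply(lv$time_label, function(lab)
                      sum(sample_scores$time_label == lab), integer(1)),
                    stringsAsFactors = FALSE)
  if (all(is.na(agg$score)))
    stop("no sample has a defined DNB score; cannot call a tipping point",
         call. = FALSE)
  best <- max(agg$score, na.rm = TRUE)
  hits <- which(!is.na(agg$score) & agg$score == best)
  structure(list(sample_scores = sample_scores,
                 time_scores = agg[, c("time_label", "time_order", "score", "n_samples")],
                 tipping_time = agg$time_label[hits[1L]],
                 tied = length(hits) > 1L),
            class = "ldnb_tipping")
}

#' @export
print.ldnb_tipping <- function(x, ...) {
  cat("l-DNB tipping-point call\n")
  print(x$time_scores, row.names = FALSE)
  cat("tipping point:", x$tipping_time, if (x$tied) "(tied; earliest kept)" else "", "\n")
  invisible(x)
}

# Per-sample top-k gene membership set (tie-expanded, eligible genes only).
top_k_genes <- function(score_table, sample, top_k) {
  rows <- score_table[score_table$sample_id == sample & score_table$eligible, ]
  rows <- rows[is.finite(rows$local_score), ]
  if (nrow(rows) == 0L) return(character())
  if (nrow(rows) <= top_k) return(rows$gene)
  thresh <- sort(rows$local_score, decreasing = TRUE)[top_k]
  rows$gene[rows$local_score >= thresh]
}

#' Select DNB genes at the tipping point
#'
#' A gene is a DNB gene if its local score ranks in the per-sample top
#' `top_k` in at least `dnb_gene_min_samples` of the tipping-time samples.
#' With a single sample at the tipping time the rule degrades to that
#' sample's top `top_k` (with a warning).
#'
#' @param score_table output of [dnb_score_table()].
#' @param annot sample annotation.
#' @param tipping_time the tipping time label.
#' @param config an [ldnb_config()].
#' @return data.frame `gene`, `support` (samples in whose top-k it appears),
#'   restricted to genes meeting the support threshold, ordered by
#'   decreasing support.
#' @export
select_dnb_genes <- function(score_table, annot, tipping_time,
                             config = ldnb_config()) {
  sids <- annot$sample_id[annot$group == "case" & annot$time_label == tipping_time]
  if (length(sids) == 0L)
    stop("no case samples at tipping time ", tipping_time, call. = FALSE)
  min_support <- config$dnb_gene_min_samples
  if (length(sids) < min_support) {
    warning("only ", length(sids), " sample(s) at the tipping time; ",
            "support threshold lowered to ", length(sids))
    min_support <- length(sids)
  }
  sets <- lapply(sids, function(s) top_k_genes(score_table, s, config$top_k))
  tab <- table(unlist(sets))
  sel <- tab[tab >= min_support]
  out <- data.frame(gene = names(sel), support = as.integer(sel),
                    stringsAsFactors = FALSE)
  out[order(-out$support, out$gene), , drop = FALSE]
}
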