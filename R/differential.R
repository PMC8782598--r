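#' Two-group differential expression test
#'
#' Per-gene two-sample test between two groups of samples, on
#' `log2(x + 1)`-transformed values by default. The default is Welch's
#' t-test; a Mann-Whitney option is available for heavy-tailed data. P-values
#' are BH-adjusted; a gene is flagged `is_deg` when `fdr < deg_fdr` and
#' `|log2FC| >= deg_min_abs_log2fc`. The fold change is group B minus group A
#' on the log2 scale.
#'
#' @param expr expression matrix (genes x samples).
#' @param samples_a,samples_b sample identifier vectors (>= 2 each).
#' @param config an [ldnb_config()].
#' @return data.frame: gene, log2_fold_change, p, fdr, direction, is_deg.
#' @export
deg_test <- function(expr, samples_a, samples_b, config = ldnb_config()) {
  if (length(samples_a) < 2L || length(samples_b) < 2L)
    stop("deg_test needs at least 2 samples per group", call. = FALSE)
  a <- expr[, samples_a, drop = FALSE]
  b <- expr[, samples_b, drop = FALSE]
  if (config$deg_log2) {
    a <- log2(a + 1)
    b <- log2(b + 1)
  }
  nst <- nrow(expr)
  p <- numeric(nst)
  lfc <- rowMeans(b) - rowMeans(a)
  for (i in seq_len(nst)) {
    ai <- a[i, ]
    bi <- b[i, ]
    if (stats::sd(ai) == 0 && stats::sd(bi) == 0) {
      p[i] <- if (mean(ai) == mean(bi)) 1 else 0
      next
    }
    p[i] <- tryCatch({
      if (identical(config$deg_method, "wilcoxon"))
        suppressWarnings(stats::wilcox.test(ai, bi)$p.value)
      else
        stats::t.test(ai, bi)$p.value
    }, error = function(e) NA_real_)
  }
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(expr),
             log2_fold_change = unname(lfc),
             p = p, fdr = fdr,
             direction = ifelse(lfc >= 0, "up", "down"),
             is_deg = !is.na(fdr) & fdr < config$deg_fdr &
               abs(lfc) >= config$deg_min_abs_log2fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differentially expressed genes around the tipping point (TP-DEGs)
#'
#' Compares the tipping time point against its adjacent case time points
#' (prior and posterior by the annotation's `time_order`) and returns the
#' union of the two DEG sets. A missing neighbor, or one with fewer than two
#' samples, restricts the comparison to the remaining side (logged).
#'
#' @param expr expression matrix.
#' @param annot sample annotation.
#' @param tipping_time tipping time label.
#' @param config an [ldnb_config()].
#' @return character vector of TP-DEG genes; per-comparison tables in the
#'   `"comparisons"` attribute.
#' @export
tp_degs <- function(expr, annot, tipping_time, config = ldnb_config()) {
  lv <- case_time_levels(annot)
  i <- match(tipping_time, lv)
  if (is.na(i)) stop("tipping_time not a case time label", call. = FALSE)
  ids_at <- function(lab) annot$sample_id[annot$group == "case" &
                                            annot$time_label == lab]
  tip_ids <- ids_at(tipping_time)
  comps <- list()
  for (side in c("prior", "posterior")) {
    j <- if (side == "prior") i - 1L else i + 1L
    if (j < 1L || j > length(lv)) {
      message("no ", side, " neighbor time point; comparison skipped")
      next
    }
    nb_ids <- ids_at(lv[j])
    if (length(nb_ids) < 2L || length(tip_ids) < 2L) {
      message(side, " comparison skipped: fewer than 2 samples per group")
      next
    }
    comps[[side]] <- deg_test(expr, nb_ids, tip_ids, config)
  }
  if (length(comps) == 0L) {
    warning("no neighbor time point with enough samples; TP-DEG set is empty")
    return(structure(character(), comparisons = comps))
  }
  genes <- unique(unlist(lapply(comps, function(d) d$gene[d$is_deg])))
  structure(sort(genes), comparisons = comps)
}

# canonical undirected edge keys for a graph
edge_keys <- function(g) {
  if (igraph::ecount(g) == 0L) return(character())
  el <- igraph::as_edgelist(g)
  paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\t")
}

keys_to_graph <- function(keys, weights = NULL) {
  if (length(keys) == 0L) return(igraph::make_empty_graph(0, directed = FALSE))
  el <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}

#' Fuse the SSNs of one time point
#'
#' Retains edges supported by at least `min_support` of the time point's
#' SSNs; the edge weight records the support count. With two replicates and
#' the default support of 2 this is the intersection; `min_support = 1` gives
#' the union.
#'
#' @param ssns list of igraph SSNs from the same time point.
#' @param min_support minimum number of SSNs an edge must appear in.
#' @return igraph with edge attribute `weight` = support count.
#' @export
fuse_ssns <- function(ssns, min_support = 2L) {
  if (length(ssns) == 0L) stop("fuse_ssns needs at least one SSN", call. = FALSE)
  if (length(ssns) < min_support)
    warning("fewer SSNs (", length(ssns), ") than min_support (", min_support,
            "); fused network is empty")
  keys <- unlist(lapply(ssns, edge_keys))
  tab <- table(keys)
  keep <- tab[tab >= min_support]
  keys_to_graph(names(keep), as.integer(keep))
}

#' Differential (rewiring) network between two fused SSNs
#'
#' Appeared edges are present at the later network but not the earlier one;
#' disappeared edges the converse. Node degrees are taken in the union of the
#' two edge sets.
#'
#' @param fused_before,fused_at igraph networks (e.g. fused SSNs of the time
#'   point before the tipping point and at it).
#' @return list of class `ldnb_diffnet`: `appeared` and `disappeared`
#'   (igraphs) and `node_degrees` (named integer vector over nodes incident
#'   to changed edges).
#' @export
differential_network <- function(fused_before, fused_at) {
  kb <- edge_keys(fused_before)
  ka <- edge_keys(fused_at)
  appeared <- keys_to_graph(setdiff(ka, kb))
  disappeared <- keys_to_graph(setdiff(kb, ka))
  union_g <- keys_to_graph(union(setdiff(ka, kb), setdiff(kb, ka)))
  deg <- if (igraph::vcount(union_g)) igraph::degree(union_g) else
    stats::setNames(integer(), character())
  structure(list(appeared = appeared, disappeared = disappeared,
                 node_degrees = deg),
            class = "ldnb_diffnet")
}

#' Differential-network hub genes (TP-DNGs)
#'
#' In each differential network, genes whose degree strictly exceeds the mean
#' degree over that network's nodes are hubs; the TP-DNG set is the union of
#' hubs over the prior and posterior differential networks. In a regular
#' (all-degrees-equal) network no gene qualifies.
#'
#' @param prior_diff,posterior_diff [differential_network()] results (either
#'   may be `NULL`).
#' @return character vector of TP-DNG genes.
#' @export
tp_dngs <- function(prior_diff, posterior_diff = NULL) {
  hubs <- function(dn) {
    if (is.null(dn) || length(dn$node_degrees) == 0L) return(character())
    names(dn$node_degrees)[dn$node_degrees > mean(dn$node_degrees)]
  }
  out <- union(hubs(prior_diff), hubs(posterior_diff))
  if (length(out) == 0L &&
      (is.null(prior_diff) || length(prior_diff$node_degrees) == 0L) &&
      (is.null(posterior_diff) || length(posterior_diff$node_degrees) == 0L))
    warning("both differential networks are empty; TP-DNG set is empty")
  sort(out)
}
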