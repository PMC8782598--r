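#' Reference Pearson correlation over the reference cohort
#'
#' Computes the Pearson correlation matrix of all genes over the `n` reference
#' samples, the backbone against which single-sample perturbations are
#' measured. Pairs involving a zero-variance gene are undefined and flagged,
#' never silently set to zero.
#'
#' @param expr_ref numeric matrix, genes x reference samples, `n >= 3`.
#' @return an object of class `ldnb_refcor`: list with `pcc` (gene x gene
#'   correlation matrix, `NA` where undefined), `n` (reference sample count)
#'   and `constant` (names of zero-variance genes).
#' @export
reference_pcc <- function(expr_ref) {
  n <- ncol(expr_ref)
  if (n < 3L)
    stop("at least 3 reference samples are required for the correlation test",
         call. = FALSE)
  sds <- apply(expr_ref, 1L, stats::sd)
  constant <- rownames(expr_ref)[sds == 0]
  pcc <- suppressWarnings(stats::cor(t(expr_ref)))
  if (length(constant)) {
    pcc[constant, ] <- NA_real_
    pcc[, constant] <- NA_real_
  }
  structure(list(pcc = pcc, n = n, constant = constant), class = "ldnb_refcor")
}

#' Single-sample Pearson correlation perturbation (sPCC)
#'
#' The sPCC of a gene pair for a new sample `d` is the change in Pearson
#' correlation caused by pooling `d` with the `n` reference samples:
#' `sPCC = PCC_{n+1} - PCC_n`. It lies in `[-2, 2]` and is near zero when `d`
#' is consistent with the reference joint distribution.
#'
#' @param expr_ref numeric matrix, genes x reference samples.
#' @param sample_d named numeric vector of the new sample's expression
#'   (must cover both genes).
#' @param gene_x,gene_y gene identifiers (rownames of `expr_ref`).
#' @return the sPCC value; `NA` if either correlation is undefined (constant
#'   vector among the reference or pooled samples).
#' @export
spcc <- function(expr_ref, sample_d, gene_x, gene_y) {
  x <- expr_ref[gene_x, ]
  y <- expr_ref[gene_y, ]
  xp <- c(x, sample_d[[gene_x]])
  yp <- c(y, sample_d[[gene_y]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0 ||
      stats::sd(xp) == 0 || stats::sd(yp) == 0)
    return(NA_real_)
  stats::cor(xp, yp) - stats::cor(x, y)
}

# Full sPCC matrix for one sample: PCC_{n+1} - PCC_n over all genes.
# refcor is a precomputed ldnb_refcor for expr_ref.
spcc_matrix <- function(expr_ref, sample_d, refcor = NULL) {
  if (is.null(refcor)) refcor <- reference_pcc(expr_ref)
  d <- sample_d[rownames(expr_ref)]
  pooled <- cbind(expr_ref, d)
  sds <- apply(pooled, 1L, stats::sd)
  pcc1 <- suppressWarnings(stats::cor(t(pooled)))
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    pcc1[bad, ] <- NA_real_
    pcc1[, bad] <- NA_real_
  }
  pcc1 - refcor$pcc
}

#' Significance of a single-sample correlation perturbation
#'
#' Under the null that the new sample follows the reference distribution, the
#' sPCC statistic follows the "volcano" distribution, approximately normal
#' for moderate `n` after standardization:
#' `z = sPCC * (n - 1) / (1 - PCC_n^2)`, with a two-sided normal p-value.
#' Pairs with `|PCC_n| = 1` are degenerate (the denominator vanishes) and are
#' flagged untestable.
#'
#' @param spcc sPCC value(s) (vectorized).
#' @param pcc_n reference correlation(s).
#' @param n reference sample count.
#' @return data.frame with columns `z`, `p`, `testable`.
#' @export
edge_significance <- function(spcc, pcc_n, n) {
  testable <- is.finite(spcc) & is.finite(pcc_n) & abs(pcc_n) < 1
  z <- ifelse(testable, spcc * (n - 1) / (1 - pcc_n^2), NA_real_)
  p <- ifelse(testable, 2 * stats::pnorm(-abs(z)), NA_real_)
  data.frame(z = z, p = p, testable = testable)
}

# Rank-based empirical-null alternative ("U-test" option): each reference
# sample j, held out and treated as a pseudo new sample against the other
# n-1, yields one null sPCC draw per pair; the p-value is the rank of |obs|
# among the null draws with the add-one correction.
spcc_empirical_p <- function(expr_ref, spcc_obs, refcor = NULL) {
  n <- ncol(expr_ref)
  if (n < 4L)
    stop("empirical-null edge test needs >= 4 reference samples", call. = FALSE)
  null_abs <- array(NA_real_, dim = c(nrow(expr_ref), nrow(expr_ref), n))
  for (j in seq_len(n)) {
    loo <- expr_ref[, -j, drop = FALSE]
    rc <- reference_pcc(loo)
    null_abs[, , j] <- abs(spcc_matrix(loo, expr_ref[, j], rc))
  }
  obs <- abs(spcc_obs)
  ge <- array(0L, dim = dim(obs))
  for (j in seq_len(n)) ge <- ge + (null_abs[, , j] >= obs)
  p <- (1 + ge) / (n + 1)
  p[!is.finite(obs)] <- NA_real_
  p
}

#' Build the single-sample network (SSN) for one case sample
#'
#' Candidate gene pairs (all pairs by default, or the edges of a supplied
#' background network restricted to measured genes) are scored by sPCC and
#' its significance test; pairs with `p < alpha_edge` (and
#' `|sPCC| >= min_abs_spcc`, if set) form the SSN. Undefined or untestable
#' pairs are dropped. The vertex set is the genes incident to retained edges.
#'
#' @param expr_ref numeric matrix of reference samples (genes x samples).
#' @param sample_d named numeric vector for the case sample.
#' @param background optional igraph background network defining the candidate
#'   pair space; `NULL` means all gene pairs.
#' @param config an [ldnb_config()].
#' @param refcor optional precomputed [reference_pcc()] result (avoids
#'   recomputation across samples).
#' @return igraph object with edge attributes `spcc`, `pcc_n`, `z`, `p`.
#' @export
build_ssn <- function(expr_ref, sample_d, background = NULL,
                      config = ldnb_config(), refcor = NULL) {
  if (is.null(refcor)) refcor <- reference_pcc(expr_ref)
  genes <- rownames(expr_ref)
  n <- refcor$n
  sp <- spcc_matrix(expr_ref, sample_d, refcor)

  cand <- upper.tri(sp)
  if (!is.null(background)) {
    bg <- igraph::induced_subgraph(
      background, intersect(igraph::V(background)$name, genes))
    mask <- matrix(FALSE, length(genes), length(genes),
                   dimnames = list(genes, genes))
    if (igraph::ecount(bg) > 0L) {
      el <- igraph::as_edgelist(bg)
      mask[el] <- TRUE
      mask[el[, c(2, 1), drop = FALSE]] <- TRUE
    }
    cand <- cand & mask
  }

  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("empty candidate pair set; returning empty SSN")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  spv <- sp[idx]
  pccv <- refcor$pcc[idx]
  if (identical(config$edge_test, "u")) {
    pmat <- spcc_empirical_p(expr_ref, sp, refcor)
    sig <- data.frame(z = rep(NA_real_, nrow(idx)), p = pmat[idx],
                      testable = is.finite(pmat[idx]))
  } else {
    sig <- edge_significance(spv, pccv, n)
  }
  keep <- sig$testable & !is.na(sig$p) & sig$p < config$alpha_edge &
    abs(spv) >= config$min_abs_spcc
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) {
    warning("no significant edges; returning empty SSN")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  el <- cbind(genes[idx[keep, 1L]], genes[idx[keep, 2L]])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$spcc <- spv[keep]
  igraph::E(g)$pcc_n <- pccv[keep]
  igraph::E(g)$z <- sig$z[keep]
  igraph::E(g)$p <- sig$p[keep]
  g
}

#' Build SSNs for every case sample
#'
#' @param expr numeric matrix, genes x samples (reference and case).
#' @param annot sample annotation data.frame (see [validate_annotation()]).
#' @param background optional igraph background network.
#' @param config an [ldnb_config()].
#' @return named list of igraph SSNs, one per case sample.
#' @export
build_all_ssns <- function(expr, annot, background = NULL,
                           config = ldnb_config()) {
  validate_annotation(annot)
  if (!all(annot$sample_id %in% colnames(expr)))
    stop("annotation sample_ids missing from expression matrix: ",
         paste(setdiff(annot$sample_id, colnames(expr)), collapse = ", "),
         call. = FALSE)
  ref_ids <- annot$sample_id[annot$group == "reference"]
  case_ids <- annot$sample_id[annot$group == "case"]
  expr_ref <- expr[, ref_ids, drop = FALSE]
  refcor <- reference_pcc(expr_ref)
  ssns <- lapply(case_ids, function(sid) {
    build_ssn(expr_ref, expr[, sid], background = background,
              config = config, refcor = refcor)
  })
  names(ssns) <- case_ids
  ssns
}
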