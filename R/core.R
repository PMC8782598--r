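#' Expand anchor signatures over a background PPI
#'
#' Skin-related (or, generally, phenotype-related) genes are the anchor
#' signatures plus their first-order neighbors in the protein-protein
#' interaction background, restricted to measured genes when a universe is
#' supplied.
#'
#' @param signatures character vector of anchor genes (nonempty).
#' @param ppi igraph background interaction network.
#' @param measured optional character vector restricting the result.
#' @return character vector: signatures plus their PPI neighbors.
#' @export
expand_signatures <- function(signatures, ppi, measured = NULL) {
  if (length(signatures) == 0L) stop("signatures must be nonempty", call. = FALSE)
  present <- intersect(signatures, igraph::V(ppi)$name)
  if (length(present) == 0L) {
    warning("no signature gene present in the PPI; returning signatures alone")
    out <- signatures
  } else {
    nb <- unique(unlist(lapply(present, function(g)
      igraph::V(ppi)$name[igraph::neighbors(ppi, g)])))
    out <- union(signatures, nb)
  }
  if (!is.null(measured)) out <- intersect(out, union(measured, signatures))
  sort(unique(out))
}

#' One-sided Fisher exact test for gene-set overlap
#'
#' Tests enrichment of the overlap of two gene sets within a finite universe:
#' the p-value is the upper hypergeometric tail
#' `P(X >= |set1 & set2|)` with `X ~ Hypergeom(|set1|, |universe| - |set1|,
#' |set2|)`, identical to `fisher.test(..., alternative = "greater")` on the
#' 2x2 membership table.
#'
#' @param set1,set2 character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes (nonempty).
#' @return one-sided p-value in `[0, 1]`.
#' @export
overlap_fisher <- function(set1, set2, universe) {
  if (length(universe) == 0L) stop("universe must be nonempty", call. = FALSE)
  set1 <- intersect(unique(set1), universe)
  set2 <- intersect(unique(set2), universe)
  k <- length(intersect(set1, set2))
  stats::phyper(k - 1, length(set1), length(universe) - length(set1),
                length(set2), lower.tail = FALSE)
}

#' Three-step core biomarker gene selection
#'
#' (i) expand the anchor signatures over the PPI to the phenotype-related
#' set; (ii) test the DNB-gene overlap with that set by one-sided Fisher
#' exact test; (iii) core genes are DNB genes that are signature genes and
#' also differentially expressed (TP-DEG) or differential-network hubs
#' (TP-DNG) at the tipping point. Candidate genes are DNB genes adjacent to a
#' core gene in the tipping-point fused SSN that are themselves TP-DEGs or
#' TP-DNGs but not core.
#'
#' @param dnb_genes character vector of DNB genes.
#' @param signatures anchor signature genes.
#' @param tp_deg_genes,tp_dng_genes tipping-point DEG and hub gene sets.
#' @param universe all measured genes (the Fisher universe).
#' @param ppi optional igraph PPI for signature expansion; `NULL` uses the
#'   signatures alone as the phenotype-related set.
#' @param fused_tip optional tipping-point fused SSN (igraph) used for the
#'   candidate-gene neighborhood; `NULL` yields no candidates.
#' @return list of class `ldnb_core`: `skin_related`, `overlap` (counts),
#'   `overlap_p`, `core_genes`, `candidate_genes`.
#' @export
select_core <- function(dnb_genes, signatures, tp_deg_genes, tp_dng_genes,
                        universe, ppi = NULL, fused_tip = NULL) {
  skin_related <- if (is.null(ppi)) intersect(signatures, universe)
  else expand_signatures(signatures, ppi, measured = universe)
  dnb_u <- intersect(dnb_genes, universe)
  overlap_p <- overlap_fisher(dnb_u, skin_related, universe)
  active <- union(tp_deg_genes, tp_dng_genes)
  core <- sort(intersect(intersect(dnb_u, signatures), active))
  candidates <- character()
  if (!is.null(fused_tip) && length(core)) {
    present <- intersect(core, igraph::V(fused_tip)$name)
    nb <- unique(unlist(lapply(present, function(g)
      igraph::V(fused_tip)$name[igraph::neighbors(fused_tip, g)])))
    candidates <- sort(setdiff(intersect(intersect(nb, dnb_u), active), core))
  }
  structure(list(
    skin_related = skin_related,
    overlap = c(dnb = length(dnb_u), skin_related = length(skin_related),
                overlap = length(intersect(dnb_u, skin_related)),
                universe = length(universe)),
    overlap_p = overlap_p,
    core_genes = core,
    candidate_genes = candidates), class = "ldnb_core")
}

#' @export
print.ldnb_core <- function(x, ...) {
  cat("Core DNB gene selection\n")
  cat("  phenotype-related genes:", length(x$skin_related), "\n")
  cat(sprintf("  DNB overlap: %d of %d DNB genes (Fisher p = %.3g)\n",
              x$overlap[["overlap"]], x$overlap[["dnb"]], x$overlap_p))
  cat("  core genes:", if (length(x$core_genes))
    paste(x$core_genes, collapse = ", ") else "(none)", "\n")
  cat("  candidate genes:", if (length(x$candidate_genes))
    paste(x$candidate_genes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
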