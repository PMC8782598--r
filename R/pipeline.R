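stage_log <- function(stage, ...) {
  message(sprintf("[ldnb] %s %s", stage, paste0(..., collapse = "")))
}

#' Run the full l-DNB analysis in memory
#'
#' Orchestrates SSN construction, local scoring, tipping-point detection,
#' DNB-gene selection, fused and differential networks, TP-DEG/TP-DNG
#' extraction, optional core-gene selection against a signature list, and
#' the optional phenotype risk screen.
#'
#' @param expr expression matrix (genes x samples).
#' @param annot sample annotation data.frame.
#' @param config an [ldnb_config()].
#' @param background optional igraph restricting the SSN candidate pair
#'   space; `NULL` means all gene pairs.
#' @param signatures optional anchor-signature gene vector; if `NULL` the
#'   core-gene stage is skipped with a warning.
#' @param ppi optional igraph PPI used for signature expansion (may equal
#'   `background`).
#' @param phenotype optional long phenotype data.frame enabling the risk
#'   stage (tested genes: core genes if any, else DNB genes).
#' @return list of class `ldnb_result` with elements `ssns`, `score_table`,
#'   `tipping`, `dnb_genes`, `fused`, `prior_diff`, `posterior_diff`,
#'   `tp_deg_genes`, `tp_dng_genes`, `core`, `risk`, `config`.
#' @export
ldnb_analyze <- function(expr, annot, config = ldnb_config(),
                         background = NULL, signatures = NULL, ppi = NULL,
                         phenotype = NULL) {
  validate_annotation(annot)
  missing_ids <- setdiff(annot$sample_id, colnames(expr))
  if (length(missing_ids))
    stop("sample ids in annotation but not expression: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)

  stage_log("ssn", sprintf("building SSNs (alpha_edge=%g, background=%s, test=%s)",
                           config$alpha_edge,
                           if (is.null(background)) "all-pairs" else "supplied",
                           config$edge_test))
  ssns <- build_all_ssns(expr, annot, background = background, config = config)

  stage_log("dnb", sprintf("scoring local modules (top_k=%d, eligibility >=%d/%d neighbors)",
                           config$top_k, config$min_first_neighbors,
                           config$min_second_neighbors))
  score_table <- dnb_score_table(ssns, expr, annot, config)
  tipping <- detect_tipping_point(score_table, annot, config)
  dnb_genes <- select_dnb_genes(score_table, annot, tipping$tipping_time, config)
  stage_log("dnb", sprintf("tipping point = %s; %d DNB genes",
                           tipping$tipping_time, nrow(dnb_genes)))

  stage_log("diffnet", sprintf("fusing SSNs (min_support=%d) and differencing around the tipping point",
                               config$fuse_min_support))
  lv <- case_time_levels(annot)
  fused <- lapply(lv, function(lab) {
    sids <- annot$sample_id[annot$group == "case" & annot$time_label == lab]
    suppressWarnings(fuse_ssns(ssns[sids], config$fuse_min_support))
  })
  names(fused) <- lv
  ti <- match(tipping$tipping_time, lv)
  prior_diff <- if (ti > 1L)
    differential_network(fused[[ti - 1L]], fused[[ti]]) else NULL
  posterior_diff <- if (ti < length(lv))
    differential_network(fused[[ti]], fused[[ti + 1L]]) else NULL
  tp_dng_genes <- suppressWarnings(tp_dngs(prior_diff, posterior_diff))
  tp_deg_genes <- tp_degs(expr, annot, tipping$tipping_time, config)
  stage_log("diffnet", sprintf("%d TP-DEGs, %d TP-DNGs",
                               length(tp_deg_genes), length(tp_dng_genes)))

  core <- NULL
  if (is.null(signatures)) {
    warning("no signature list supplied; core-gene stage skipped")
  } else {
    stage_log("core", sprintf("selecting core genes against %d signatures",
                              length(signatures)))
    core <- select_core(dnb_genes$gene, signatures, tp_deg_genes, tp_dng_genes,
                        universe = rownames(expr), ppi = ppi,
                        fused_tip = fused[[ti]])
  }

  risk <- NULL
  if (!is.null(phenotype)) {
    test_genes <- if (!is.null(core) && length(core$core_genes))
      core$core_genes else dnb_genes$gene
    stage_log("risk", sprintf("risk screen on %d genes (threshold=%g, direction=%s)",
                              length(test_genes), config$event_threshold,
                              config$event_direction))
    case_ids <- annot$sample_id[annot$group == "case"]
    risk <- risk_screen(expr[, case_ids, drop = FALSE],
                        phenotype[phenotype$sample_id %in% case_ids, ],
                        genes = test_genes, config = config)
  }

  structure(list(ssns = ssns, score_table = score_table, tipping = tipping,
                 dnb_genes = dnb_genes, fused = fused,
                 prior_diff = prior_diff, posterior_diff = posterior_diff,
                 tp_deg_genes = as.character(tp_deg_genes),
                 tp_dng_genes = tp_dng_genes,
                 core = core, risk = risk, config = config),
            class = "ldnb_result")
}

#' @export
print.ldnb_result <- function(x, ...) {
  cat("l-DNB analysis result\n")
  cat("  case samples:", length(x$ssns), "| tipping point:",
      x$tipping$tipping_time, "\n")
  cat("  DNB genes:", nrow(x$dnb_genes), "| TP-DEGs:", length(x$tp_deg_genes),
      "| TP-DNGs:", length(x$tp_dng_genes), "\n")
  if (!is.null(x$core))
    cat("  core genes:", length(x$core$core_genes),
        sprintf("(overlap p = %.3g)", x$core$overlap_p), "\n")
  if (!is.null(x$risk))
    cat("  risk screen:", nrow(x$risk), "genes tested; min p =",
        format(suppressWarnings(min(x$risk$p, na.rm = TRUE)), digits = 3), "\n")
  invisible(x)
}

diffnet_table <- function(dn) {
  tab <- function(g, lab) {
    if (igraph::ecount(g) == 0L)
      return(data.frame(gene1 = character(), gene2 = character(),
                        set = character()))
    el <- igraph::as_edgelist(g)
    data.frame(gene1 = el[, 1L], gene2 = el[, 2L], set = lab,
               stringsAsFactors = FALSE)
  }
  rbind(tab(dn$appeared, "appeared"), tab(dn$disappeared, "disappeared"))
}

#' Write an `ldnb_result` bundle to disk
#'
#' Writes per-sample SSN edge lists, the score table, the tipping-point
#' report (JSON), fused and differential network edge lists, the core-gene
#' report (JSON) and the risk table.
#'
#' @param res an [ldnb_analyze()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_ldnb_results <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ssn_dir <- file.path(dir, "ssn")
  if (!dir.exists(ssn_dir)) dir.create(ssn_dir)
  for (sid in names(res$ssns))
    write_network(res$ssns[[sid]], file.path(ssn_dir, paste0(sid, ".tsv")))
  utils::write.table(res$score_table, file.path(dir, "dnb_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(time_scores = res$tipping$time_scores,
         tipping_time = res$tipping$tipping_time,
         tied = res$tipping$tied,
         dnb_genes = res$dnb_genes),
    file.path(dir, "tipping_point.json"), auto_unbox = TRUE, pretty = TRUE,
    dataframe = "columns", digits = NA)
  for (lab in names(res$fused))
    write_network(res$fused[[lab]], file.path(dir, paste0("fused_", lab, ".tsv")))
  for (side in c("prior", "posterior")) {
    dn <- res[[paste0(side, "_diff")]]
    if (!is.null(dn))
      utils::write.table(diffnet_table(dn),
                         file.path(dir, paste0("diffnet_", side, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(res$tp_deg_genes, file.path(dir, "tp_degs.txt"))
  writeLines(res$tp_dng_genes, file.path(dir, "tp_dngs.txt"))
  if (!is.null(res$core))
    jsonlite::write_json(
      list(skin_related_size = length(res$core$skin_related),
           overlap = as.list(res$core$overlap),
           overlap_p = res$core$overlap_p,
           core_genes = res$core$core_genes,
           candidate_genes = res$core$candidate_genes),
      file.path(dir, "core_dnb.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  if (!is.null(res$risk))
    utils::write.table(res$risk, file.path(dir, "risk_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_config(res$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' File-based pipeline entry point
#'
#' Reads every input from disk, validates their mutual consistency, runs
#' [ldnb_analyze()] and writes all outputs to `output_dir`. Each stage and
#' its parameters are logged.
#'
#' @param expression path to the expression TSV/CSV.
#' @param metadata path to the sample annotation TSV.
#' @param output_dir directory for all outputs.
#' @param background optional path to an SSN background edge list.
#' @param signatures optional path to the anchor-signature list.
#' @param ppi optional path to a PPI edge list for signature expansion
#'   (defaults to `background` if that is given).
#' @param phenotype optional path to the phenotype TSV.
#' @param config an [ldnb_config()] or path to a YAML config.
#' @return the [ldnb_analyze()] result, invisibly.
#' @export
run_pipeline <- function(expression, metadata, output_dir,
                         background = NULL, signatures = NULL, ppi = NULL,
                         phenotype = NULL, config = ldnb_config()) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  expr <- read_expression(expression)
  annot <- read_metadata(metadata)
  bad <- setdiff(annot$sample_id, colnames(expr))
  if (length(bad))
    stop("inconsistent inputs: annotation samples absent from expression: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bg <- if (!is.null(background)) read_network(background) else NULL
  pg <- if (!is.null(ppi)) read_network(ppi) else bg
  sig <- if (!is.null(signatures)) read_signatures(signatures) else NULL
  phe <- if (!is.null(phenotype)) read_phenotype(phenotype) else NULL
  res <- ldnb_analyze(expr, annot, config = config, background = bg,
                      signatures = sig, ppi = pg, phenotype = phe)
  write_ldnb_results(res, output_dir)
  stage_log("done", "outputs written to ", output_dir)
  invisible(res)
}
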