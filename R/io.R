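#' Read a gene-by-sample expression matrix
#'
#' Expects a TSV (or CSV, by file extension) with gene identifiers in the
#' first column and sample identifiers in the header. Duplicated gene
#' identifiers and missing or non-numeric cells are rejected rather than
#' silently coerced: every downstream correlation statistic assumes a complete
#' numeric matrix.
#'
#' @param path path to a TSV/CSV file.
#' @return numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L)
    stop("expression file must have a gene-id column plus >=1 sample column: ", path,
         call. = FALSE)
  genes <- df[[1L]]
  if (anyDuplicated(genes))
    stop("duplicated gene identifiers in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric value at gene '%s', sample '%s' (line %d) in %s",
                 genes[bad[1L]], colnames(vals)[bad[2L]], bad[1L] + 1L, path),
         call. = FALSE)
  }
  rownames(vals) <- genes
  vals
}

#' Write an expression matrix as TSV
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample annotation table
#'
#' Requires columns `sample_id`, `group` (values `reference`/`case`),
#' `time_label`, `time_order` (numeric ordering of the time labels; labels such
#' as `D1-4h` do not sort lexically, so the order is explicit), and
#' `replicate`.
#'
#' @param path path to a TSV file.
#' @return data.frame with the five required columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_annotation(df)
}

#' Validate a sample annotation data.frame
#'
#' @param annot data.frame with columns `sample_id`, `group`, `time_label`,
#'   `time_order`, `replicate`.
#' @return the validated data.frame, invisibly usable.
#' @export
validate_annotation <- function(annot) {
  need <- c("sample_id", "group", "time_label", "time_order", "replicate")
  miss <- setdiff(need, names(annot))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(annot$sample_id))
    stop("duplicated sample_id in annotation", call. = FALSE)
  if (!all(annot$group %in% c("reference", "case")))
    stop("group must be 'reference' or 'case'", call. = FALSE)
  if (!any(annot$group == "reference"))
    stop("annotation has no reference samples", call. = FALSE)
  if (!any(annot$group == "case"))
    stop("annotation has no case samples", call. = FALSE)
  if (!is.numeric(annot$time_order))
    stop("time_order must be numeric", call. = FALSE)
  ord <- tapply(annot$time_order, annot$time_label, function(v) length(unique(v)))
  if (any(ord != 1L))
    stop("each time_label must map to a single time_order", call. = FALSE)
  annot
}

# Case time labels in temporal order.
case_time_levels <- function(annot) {
  ca <- annot[annot$group == "case", , drop = FALSE]
  lv <- unique(ca[order(ca$time_order), "time_label"])
  lv
}

#' Read an edge list as an undirected weighted network
#'
#' Accepts two columns (endpoints) or three (endpoints plus numeric weight).
#' Self-loops are dropped and duplicate edges collapsed (first weight kept),
#' so the result is always a simple undirected graph.
#'
#' @param path path to a whitespace/TSV edge-list file.
#' @return an [igraph::graph] object; edges carry a `weight` attribute when a
#'   third column is present.
#' @export
read_network <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(V1 = character(), V2 = character()))
      stop("cannot parse network file ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  if (nrow(df) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  # tolerate a header row of the package's own writer
  if (identical(tolower(as.character(df[1L, 1L])), "gene1")) {
    df <- df[-1L, , drop = FALSE]
    if (nrow(df) == 0L) return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (ncol(df) < 2L)
    stop("network file must have at least two columns: ", path, call. = FALSE)
  el <- cbind(as.character(df[[1L]]), as.character(df[[2L]]))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (ncol(df) >= 3L)
    igraph::E(g)$weight <- as.numeric(df[[3L]])
  igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE,
                   edge.attr.comb = "first")
}

#' Write a network as a TSV edge list
#'
#' All edge attributes are written as additional columns after the two
#' endpoint columns, so [read_network()] of the result recovers the graph
#' (with the first attribute as `weight`).
#'
#' @param g an igraph object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g)
  out <- data.frame(gene1 = el[, 1L], gene2 = el[, 2L], stringsAsFactors = FALSE)
  for (a in igraph::edge_attr_names(g)) out[[a]] <- igraph::edge_attr(g, a)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature (anchor) gene list
#'
#' One gene symbol per line; blank lines and duplicates dropped.
#' @param path path to the list file.
#' @return character vector of gene identifiers.
#' @export
read_signatures <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Read a long-format phenotype table
#'
#' Columns `sample_id`, `time` (numeric), `value`. Each sample is expected to
#' be observed on the same time grid; the risk module enforces this.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns sample_id, time, value.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$time <- as.numeric(df$time)
  df$value <- as.numeric(df$value)
  if (anyNA(df$value) || anyNA(df$time))
    stop("phenotype table contains missing values", call. = FALSE)
  df
}
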