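#' Run configuration for an l-DNB analysis
#'
#' Collects every tunable parameter of the pipeline in one validated object.
#' Defaults follow the published method where it states a value (`top_k = 600`,
#' eligibility thresholds of three first-order and one second-order neighbor,
#' fused-network support of two SSNs, biomarker-gene support of two samples)
#' and field-standard conventions elsewhere.
#'
#' @param alpha_edge significance level for retaining an SSN edge (two-sided).
#' @param top_k number of top-scoring genes averaged into a sample's DNB score,
#'   and the rank cutoff used when selecting DNB genes.
#' @param min_first_neighbors minimum first-order neighbors for a gene's local
#'   module to be scored.
#' @param min_second_neighbors minimum second-order neighbors for eligibility.
#' @param fuse_min_support minimum number of same-time-point SSNs an edge must
#'   appear in to enter the fused network.
#' @param dnb_gene_min_samples minimum number of tipping-point samples in whose
#'   top-`top_k` a gene must rank to be called a DNB gene.
#' @param deg_fdr BH-adjusted p-value cutoff for differential expression.
#' @param deg_min_abs_log2fc minimum absolute log2 fold change for a DEG call.
#' @param event_threshold phenotype change that defines a risk event.
#' @param event_direction `"decrease"` (default), `"increase"` or `"absolute"`:
#'   which direction of change from baseline counts toward the event threshold.
#' @param rng_seed integer seed echoed into pipeline runs for reproducibility.
#' @param epsilon_out small positive floor applied to the module-outside
#'   correlation so local scores stay finite.
#' @param spcc_convention `"absolute"` (default) averages `|sPCC|` in the
#'   intra- and outside-module terms; `"signed"` averages raw values.
#' @param edge_test `"z"` (default) uses the volcano-distribution Z statistic;
#'   `"u"` uses a rank-based empirical null built from leave-one-out reference
#'   perturbations.
#' @param min_abs_spcc optional additional floor on `|sPCC|` for SSN edges.
#' @param deg_method `"welch"` (default) or `"wilcoxon"` two-sample test.
#' @param deg_log2 if `TRUE` (default), DEG testing operates on `log2(x + 1)`.
#'
#' @return An object of class `ldnb_config` (a validated named list).
#' @examples
#' cfg <- ldnb_config(alpha_edge = 0.01, top_k = 100)
#' cfg$top_k
#' @export
ldnb_config <- function(alpha_edge = 0.05,
                        top_k = 600L,
                        min_first_neighbors = 3L,
                        min_second_neighbors = 1L,
                        fuse_min_support = 2L,
                        dnb_gene_min_samples = 2L,
                        deg_fdr = 0.05,
                        deg_min_abs_log2fc = 1.0,
                        event_threshold = 1.0,
                        event_direction = c("decrease", "increase", "absolute"),
                        rng_seed = 1L,
                        epsilon_out = 1e-6,
                        spcc_convention = c("absolute", "signed"),
                        edge_test = c("z", "u"),
                        min_abs_spcc = 0,
                        deg_method = c("welch", "wilcoxon"),
                        deg_log2 = TRUE) {
  cfg <- list(
    alpha_edge = as.numeric(alpha_edge),
    top_k = as.integer(top_k),
    min_first_neighbors = as.integer(min_first_neighbors),
    min_second_neighbors = as.integer(min_second_neighbors),
    fuse_min_support = as.integer(fuse_min_support),
    dnb_gene_min_samples = as.integer(dnb_gene_min_samples),
    deg_fdr = as.numeric(deg_fdr),
    deg_min_abs_log2fc = as.numeric(deg_min_abs_log2fc),
    event_threshold = as.numeric(event_threshold),
    event_direction = match.arg(event_direction),
    rng_seed = as.integer(rng_seed),
    epsilon_out = as.numeric(epsilon_out),
    spcc_convention = match.arg(spcc_convention),
    edge_test = match.arg(edge_test),
    min_abs_spcc = as.numeric(min_abs_spcc),
    deg_method = match.arg(deg_method),
    deg_log2 = isTRUE(deg_log2)
  )
  class(cfg) <- "ldnb_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "ldnb_config"))
  if (!(cfg$alpha_edge > 0 && cfg$alpha_edge < 1))
    stop("alpha_edge must lie strictly between 0 and 1", call. = FALSE)
  if (cfg$top_k < 1L) stop("top_k must be >= 1", call. = FALSE)
  if (cfg$min_first_neighbors < 1L)
    stop("min_first_neighbors must be >= 1", call. = FALSE)
  if (cfg$min_second_neighbors < 0L)
    stop("min_second_neighbors must be >= 0", call. = FALSE)
  if (cfg$epsilon_out <= 0) stop("epsilon_out must be > 0", call. = FALSE)
  if (cfg$fuse_min_support < 1L) stop("fuse_min_support must be >= 1", call. = FALSE)
  if (cfg$dnb_gene_min_samples < 1L)
    stop("dnb_gene_min_samples must be >= 1", call. = FALSE)
  if (!(cfg$deg_fdr > 0 && cfg$deg_fdr <= 1)) stop("deg_fdr must be in (0, 1]", call. = FALSE)
  if (cfg$min_abs_spcc < 0) stop("min_abs_spcc must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.ldnb_config <- function(x, ...) {
  cat("l-DNB run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, path))` returns
#' an object identical to `cfg`.
#'
#' @param cfg an [ldnb_config()] object.
#' @param path file path for the YAML configuration.
#' @return `write_config` returns `path` invisibly; `read_config` returns an
#'   `ldnb_config` object.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(ldnb_config, raw)
}
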