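#' Configuration of the synthetic time-series generator
#'
#' The generator emulates the study design the l-DNB analysis expects: a
#' reference (untreated) cohort, a treated time series with replicates, and a
#' planted biomarker module whose genes, at one designated tipping time,
#' deviate strongly and coherently while decoupling from the rest of the
#' transcriptome — the generative inverse of the three biomarker conditions
#' (rising deviation, rising intra-module correlation, falling
#' module-outside correlation).
#'
#' The signal enters through a single shared latent factor added to module
#' genes at the tipping time, so all three conditions move together, as the
#' theory assumes. The module loadings are parameterized so that the
#' no-signal limit (`deviation_gain = 1`, `rho_in_tip = rho_base`,
#' `rho_out_tip = rho_base`) reproduces the background distribution exactly,
#' making all time points exchangeable under the null.
#'
#' @param n_genes total gene count.
#' @param n_module planted module size (>= 4 so eligibility can hold).
#' @param n_ref reference sample count.
#' @param time_labels ordered character vector of case time labels.
#' @param replicates_per_time case replicates at each time.
#' @param tipping_index position (in `time_labels`) of the planted transition.
#' @param base_sd baseline expression standard deviation.
#' @param deviation_gain multiplier (> 1 for signal) on module-gene SD at the
#'   tipping time.
#' @param rho_in_tip intra-module correlation at the tipping time.
#' @param rho_out_tip module-outside correlation at the tipping time.
#' @param rho_base background pairwise correlation (one global latent factor).
#' @param displacement fixed mean displacement of module genes at the tipping
#'   time, in units of `base_sd`, with a random but fixed sign per module
#'   gene. The predisorder state is modeled as a displaced, strongly
#'   fluctuating attractor: without a displacement the whole module signal
#'   rides on one per-sample factor draw and is absent from a replicate
#'   whenever that draw is small, which no method could detect reliably from
#'   two replicates. Defaults to `deviation_gain - 1`, so it vanishes in the
#'   no-signal limit and the null generator stays exchangeable across times.
#' @param drift_sd SD of the per-time, per-gene mean drift given to case
#'   samples (shared across replicates), so non-tipping SSNs are non-empty;
#'   identically distributed across times to keep the null exchangeable.
#' @param phenotype_drop per-time phenotype decline after the tipping time.
#' @param phenotype_noise_sd SD of phenotype measurement noise.
#' @param phenotype_baseline phenotype baseline level (lightness-like scale).
#' @param seed integer seed; the whole module is deterministic given it.
#' @return validated list of class `ldnb_sim_config`.
#' @export
sim_config <- function(n_genes = 300L,
                       n_module = 10L,
                       n_ref = 12L,
                       time_labels = paste0("T", 1:8),
                       replicates_per_time = 2L,
                       tipping_index = 5L,
                       base_sd = 1,
                       deviation_gain = 3,
                       rho_in_tip = 0.9,
                       rho_out_tip = 0.05,
                       rho_base = 0.25,
                       displacement = deviation_gain - 1,
                       drift_sd = 0.3,
                       phenotype_drop = 1,
                       phenotype_noise_sd = 0.2,
                       phenotype_baseline = 60,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_module = as.integer(n_module),
              n_ref = as.integer(n_ref), time_labels = as.character(time_labels),
              replicates_per_time = as.integer(replicates_per_time),
              tipping_index = as.integer(tipping_index),
              base_sd = base_sd, deviation_gain = deviation_gain,
              rho_in_tip = rho_in_tip, rho_out_tip = rho_out_tip,
              rho_base = rho_base, displacement = displacement,
              drift_sd = drift_sd,
              phenotype_drop = phenotype_drop,
              phenotype_noise_sd = phenotype_noise_sd,
              phenotype_baseline = phenotype_baseline,
              seed = as.integer(seed))
  class(cfg) <- "ldnb_sim_config"
  if (cfg$n_module >= cfg$n_genes) stop("n_module must be < n_genes", call. = FALSE)
  if (cfg$n_module < 4L) stop("n_module must be >= 4", call. = FALSE)
  if (cfg$n_ref < 3L) stop("n_ref must be >= 3", call. = FALSE)
  if (cfg$tipping_index < 1L || cfg$tipping_index > length(cfg$time_labels))
    stop("tipping_index out of range", call. = FALSE)
  if (!(cfg$deviation_gain >= 1)) stop("deviation_gain must be >= 1", call. = FALSE)
  if (!(cfg$rho_base > 0 && cfg$rho_base < 1)) stop("rho_base must be in (0,1)", call. = FALSE)
  if (!(cfg$rho_in_tip > 0 && cfg$rho_in_tip <= 1)) stop("rho_in_tip must be in (0,1]", call. = FALSE)
  if (cfg$rho_out_tip < 0) stop("rho_out_tip must be >= 0", call. = FALSE)
  if (cfg$displacement < 0) stop("displacement must be >= 0", call. = FALSE)
  if (cfg$rho_in_tip < cfg$rho_out_tip^2 / cfg$rho_base)
    stop("infeasible correlation targets: need rho_in_tip >= rho_out_tip^2 / rho_base",
         call. = FALSE)
  cfg
}

#' Simulate a reference + treated expression time series
#'
#' Background: every gene loads `sqrt(rho_base)` on a global per-sample
#' latent factor, giving homogeneous background correlation `rho_base` and
#' unit-variance (times `base_sd`) noise. Case samples receive a per-time
#' mean drift (`drift_sd`). At the tipping time, module genes are displaced
#' by `displacement * base_sd` with a fixed per-gene sign and instead load
#' `alpha` on the global factor, `beta` on a module-shared factor and carry
#' idiosyncratic SD `gamma`, with
#' `alpha = deviation_gain * rho_out_tip / sqrt(rho_base)`,
#' `beta = sqrt(deviation_gain^2 * rho_in_tip - alpha^2)`,
#' `gamma = deviation_gain * sqrt(1 - rho_in_tip)`,
#' which yields total SD `deviation_gain * base_sd`, intra-module
#' correlation `rho_in_tip` and module-outside correlation `rho_out_tip`.
#'
#' @param cfg a [sim_config()].
#' @return list: `expr` (genes x samples matrix), `annotation` (data.frame),
#'   `module_genes`, `tipping_time` (label).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "ldnb_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(G))
  module <- sort(sample(genes, cfg$n_module))
  mod_sign <- sample(c(-1, 1), cfg$n_module, replace = TRUE)
  mu <- stats::rnorm(G, mean = 8, sd = 1.5)
  names(mu) <- genes
  nt <- length(cfg$time_labels)
  rep_t <- cfg$replicates_per_time

  ref_ids <- sprintf("REF_%02d", seq_len(cfg$n_ref))
  case_ids <- as.vector(t(outer(cfg$time_labels, seq_len(rep_t),
                                function(t, r) paste0("UV_", t, "_r", r))))
  annot <- rbind(
    data.frame(sample_id = ref_ids, group = "reference",
               time_label = rep(cfg$time_labels[round(seq(1, nt, length.out = 4))],
                                length.out = cfg$n_ref),
               time_order = rep(round(seq(1, nt, length.out = 4)),
                                length.out = cfg$n_ref),
               replicate = seq_len(cfg$n_ref), stringsAsFactors = FALSE),
    data.frame(sample_id = case_ids, group = "case",
               time_label = rep(cfg$time_labels, each = rep_t),
               time_order = rep(seq_len(nt), each = rep_t),
               replicate = rep(seq_len(rep_t), times = nt),
               stringsAsFactors = FALSE))

  # per-time per-gene drift for case samples, iid across times (null-exchangeable)
  drift <- matrix(stats::rnorm(nt * G, 0, cfg$drift_sd), nrow = G,
                  dimnames = list(genes, cfg$time_labels))

  is_mod <- genes %in% module
  l_bg <- sqrt(cfg$rho_base)
  alpha <- cfg$deviation_gain * cfg$rho_out_tip / sqrt(cfg$rho_base)
  beta <- sqrt(cfg$deviation_gain^2 * cfg$rho_in_tip - alpha^2)
  gam <- cfg$deviation_gain * sqrt(1 - cfg$rho_in_tip)

  draw_sample <- function(time_idx, tipping) {
    f <- stats::rnorm(1)
    eps <- stats::rnorm(G)
    v <- mu + cfg$base_sd * (l_bg * f + sqrt(1 - cfg$rho_base) * eps)
    if (!is.na(time_idx)) v <- v + drift[, time_idx]
    if (tipping) {
      h <- stats::rnorm(1)
      epsm <- stats::rnorm(sum(is_mod))
      v[is_mod] <- mu[is_mod] + drift[is_mod, time_idx] +
        cfg$base_sd * (cfg$displacement * mod_sign +
                         alpha * f + beta * h + gam * epsm)
    }
    v
  }

  expr <- matrix(NA_real_, nrow = G, ncol = nrow(annot),
                 dimnames = list(genes, annot$sample_id))
  for (i in seq_len(nrow(annot))) {
    if (annot$group[i] == "reference") {
      expr[, i] <- draw_sample(NA, FALSE)
    } else {
      ti <- annot$time_order[i]
      expr[, i] <- draw_sample(ti, ti == cfg$tipping_index)
    }
  }
  list(expr = expr, annotation = annot, module_genes = module,
       tipping_time = cfg$time_labels[cfg$tipping_index])
}

#' Simulate phenotype trajectories for the time-series design
#'
#' Every sample (treated as an individual observed longitudinally) gets a
#' full phenotype trajectory over the time grid: reference samples stay flat
#' at `phenotype_baseline`; case samples stay flat up to and including the
#' tipping time and then decline by `phenotype_drop` per time step, with
#' additive Gaussian measurement noise.
#'
#' @param cfg a [sim_config()].
#' @param annotation the annotation from [simulate_expression()].
#' @return long data.frame `sample_id`, `time`, `value`.
#' @export
simulate_phenotype <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "ldnb_sim_config"))
  set.seed(cfg$seed + 10000L)
  nt <- length(cfg$time_labels)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    caseness <- annotation$group[i] == "case"
    drop <- if (caseness)
      cfg$phenotype_drop * pmax(0, seq_len(nt) - cfg$tipping_index) else
        rep(0, nt)
    data.frame(sample_id = annotation$sample_id[i],
               time = seq_len(nt),
               value = cfg$phenotype_baseline - drop +
                 stats::rnorm(nt, 0, cfg$phenotype_noise_sd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a validation cohort for the risk test
#'
#' Emulates a two-arm validation design: baseline expression of a small gene
#' panel plus a phenotype (lightness-like) series per sample. One designated
#' prognostic gene modulates the probability that a sample is susceptible to
#' phenotype decline: `P(susceptible) = plogis(qlogis(base_event_prob) +
#' effect_gene_strength * z)` with `z` the standardized prognostic
#' expression, so higher expression means more (for positive strength)
#' decline events. Susceptible samples start an abrupt decline at a uniform
#' random onset time; others stay flat. All samples are observed at all
#' times (no censoring), matching the constant-group-size assumption of the
#' risk statistic.
#'
#' The base event probability is deliberately sparse (default 0.13): the
#' fixed-group-size chi-square has no risk-set shrinkage, and its null
#' distribution is closest to chi-square(1) when events involve a small
#' fraction of the cohort.
#'
#' @param n_per_group samples per arm (total `2 * n_per_group`).
#' @param effect_gene_strength log-odds shift in susceptibility per SD of
#'   prognostic-gene expression (0 = null).
#' @param seed integer seed.
#' @param n_genes panel size (first gene is prognostic).
#' @param n_times post-baseline observation times.
#' @param base_event_prob susceptibility probability at average expression.
#' @param decline_per_step phenotype drop per step once declining.
#' @param noise_sd phenotype measurement noise SD.
#' @return list: `expr` (genes x samples), `phenotype` (long data.frame),
#'   `prognostic_gene`, `event_threshold` (suggested: half the per-step
#'   decline, far above noise), `susceptible` (logical, for diagnostics).
#' @export
simulate_cohort <- function(n_per_group = 19L, effect_gene_strength = 2,
                            seed = 1L, n_genes = 6L, n_times = 4L,
                            base_event_prob = 0.13, decline_per_step = 2,
                            noise_sd = 0.3) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  set.seed(seed)
  N <- 2L * n_per_group
  ids <- sprintf("S%03d", seq_len(N))
  genes <- sprintf("G%04d", seq_len(n_genes))
  expr <- matrix(stats::rnorm(n_genes * N, 8, 1), nrow = n_genes,
                 dimnames = list(genes, ids))
  z <- as.vector(scale(expr[1L, ]))
  p_susc <- stats::plogis(stats::qlogis(base_event_prob) + effect_gene_strength * z)
  susceptible <- stats::runif(N) < p_susc
  onset <- sample(seq_len(n_times), N, replace = TRUE)
  times <- 0:n_times
  rows <- lapply(seq_len(N), function(i) {
    drop <- if (susceptible[i]) decline_per_step * pmax(0, times - onset[i] + 1)
    else rep(0, length(times))
    data.frame(sample_id = ids[i], time = times,
               value = 60 - drop + stats::rnorm(length(times), 0, noise_sd),
               stringsAsFactors = FALSE)
  })
  list(expr = expr, phenotype = do.call(rbind, rows),
       prognostic_gene = genes[1L],
       event_threshold = decline_per_step / 2,
       susceptible = susceptible)
}

#' Synthetic background interaction network
#'
#' A stand-in for a curated protein-protein interaction background: a sparse
#' Erdos-Renyi graph over the measured genes (default mean degree about 6,
#' typical of curated interactomes) augmented with the planted module's
#' clique, so the module's topology exists in the candidate edge space the
#' way a real biomarker module lives on the PPI.
#'
#' @param genes character vector of all gene identifiers.
#' @param module_genes planted module gene identifiers (clique added).
#' @param p background edge probability.
#' @param seed integer seed.
#' @return igraph object over `genes`.
#' @export
simulate_ppi <- function(genes, module_genes, p = 0.02, seed = 1L) {
  set.seed(seed)
  bg <- igraph::sample_gnp(length(genes), p = p)
  igraph::V(bg)$name <- genes
  cl <- igraph::make_full_graph(length(module_genes))
  igraph::V(cl)$name <- module_genes
  igraph::simplify(igraph::union(bg, cl))
}

#' Write a complete synthetic input bundle to a directory
#'
#' Produces every file the pipeline reads: expression and metadata TSVs, the
#' phenotype table, a synthetic anchor-signature list (half of the planted
#' module plus a few background genes, so core-gene selection is
#' exercisable), and a synthetic background PPI (an Erdos-Renyi graph over
#' the gene set augmented with the planted-module clique and
#' signature-neighborhood edges).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the list of written paths.
#' @export
simulate_bundle <- function(cfg = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_expression(cfg)
  pheno <- simulate_phenotype(cfg, sim$annotation)
  set.seed(cfg$seed + 20000L)
  genes <- rownames(sim$expr)
  sigs <- c(sim$module_genes[seq_len(ceiling(length(sim$module_genes) / 2))],
            sample(setdiff(genes, sim$module_genes), 5))
  ppi <- simulate_ppi(genes, sim$module_genes, p = 0.02,
                      seed = cfg$seed + 30000L)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    signatures = file.path(dir, "signatures.txt"),
    ppi = file.path(dir, "ppi.tsv"),
    truth = file.path(dir, "truth.json"))
  write_expression(sim$expr, paths$expression)
  utils::write.table(sim$annotation, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pheno, paths$phenotype, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sigs, paths$signatures)
  write_network(ppi, paths$ppi)
  jsonlite::write_json(list(module_genes = sim$module_genes,
                            tipping_time = sim$tipping_time,
                            signatures = sigs),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
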