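#' Define phenotype-change events
#'
#' For each sample, the baseline is the phenotype at its earliest observed
#' time; an event occurs at the first later time at which the change from
#' baseline exceeds `threshold` in the configured direction (`"decrease"`:
#' baseline minus value; `"increase"`: value minus baseline; `"absolute"`:
#' either). All samples must be observed on the same time grid with no
#' missing values: the fixed-group-size statistic assumes constant group
#' sizes over time.
#'
#' @param phenotype long data.frame with columns `sample_id`, `time`, `value`.
#' @param threshold positive change magnitude defining an event.
#' @param direction `"decrease"` (default), `"increase"` or `"absolute"`.
#' @return data.frame `sample_id`, `event_time` (`NA` if no event); event
#'   times (the post-baseline grid) in the `"times"` attribute.
#' @export
define_events <- function(phenotype, threshold,
                          direction = c("decrease", "increase", "absolute")) {
  direction <- match.arg(direction)
  if (anyNA(phenotype$value))
    stop("phenotype values must be complete (constant group sizes assumed)",
         call. = FALSE)
  grids <- tapply(phenotype$time, phenotype$sample_id,
                  function(v) paste(sort(v), collapse = ","))
  if (length(unique(grids)) != 1L)
    stop("all samples must be observed at the same time points", call. = FALSE)
  times <- sort(unique(phenotype$time))
  if (length(times) < 2L)
    stop("phenotype needs a baseline plus at least one later time", call. = FALSE)
  ids <- unique(phenotype$sample_id)
  ev <- vapply(ids, function(s) {
    rows <- phenotype[phenotype$sample_id == s, ]
    rows <- rows[order(rows$time), ]
    change <- rows$value - rows$value[1L]
    signal <- switch(direction,
                     decrease = -change,
                     increase = change,
                     absolute = abs(change))
    hit <- which(signal[-1L] > threshold)
    if (length(hit)) rows$time[-1L][hit[1L]] else NA_real_
  }, numeric(1))
  structure(data.frame(sample_id = ids, event_time = unname(ev),
                       stringsAsFactors = FALSE),
            times = times[-1L])
}

#' Split samples by one gene's expression
#'
#' Median split: samples strictly above the median form the high-expression
#' group A; samples at or below it the low group B (ties at the median are
#' deterministic and go low).
#'
#' @param values named numeric vector of one gene's expression across samples.
#' @return list with character vectors `A` (high) and `B` (low).
#' @export
split_by_expression <- function(values) {
  if (length(unique(values)) < 2L)
    stop("constant expression: no high/low split possible", call. = FALSE)
  med <- stats::median(values)
  A <- names(values)[values > med]
  B <- names(values)[values <= med]
  if (length(A) == 0L || length(B) == 0L)
    stop("degenerate split: one group is empty", call. = FALSE)
  list(A = A, B = B)
}

#' Fixed-group-size chi-square risk statistic
#'
#' At each event time `T_i` the observed events per group, `O_Ai` and `O_Bi`,
#' are compared with expected events under a common event rate,
#' `E_Ai = O_i * N_A / N` (with group sizes held constant over time, i.e. no
#' risk-set shrinkage after events — this is what distinguishes the statistic
#' from the classical log-rank test; the two coincide only when no event
#' precedes the final time point). The statistic is
#' `X2 = (O_A - E_A)^2 / E_A + (O_B - E_B)^2 / E_B`, referred to a
#' chi-square distribution with one degree of freedom.
#'
#' @param events a [define_events()] result.
#' @param groups a [split_by_expression()] result (list with `A` and `B`).
#' @return list of class `ldnb_risk`: `N_A`, `N_B`, `O_A`, `O_B`, `E_A`,
#'   `E_B`, `x2`, `p`, and a per-time table `by_time`. With zero total events
#'   the statistic is undefined (`x2 = NA`).
#' @export
risk_chi_square <- function(events, groups) {
  N_A <- length(groups$A)
  N_B <- length(groups$B)
  N <- N_A + N_B
  times <- attr(events, "times")
  if (is.null(times)) times <- sort(unique(events$event_time[!is.na(events$event_time)]))
  in_a <- events$sample_id %in% groups$A
  in_b <- events$sample_id %in% groups$B
  O_Ai <- vapply(times, function(t)
    sum(in_a & !is.na(events$event_time) & events$event_time == t), numeric(1))
  O_Bi <- vapply(times, function(t)
    sum(in_b & !is.na(events$event_time) & events$event_time == t), numeric(1))
  O_i <- O_Ai + O_Bi
  E_Ai <- O_i * N_A / N
  E_Bi <- O_i * N_B / N
  O_A <- sum(O_Ai); O_B <- sum(O_Bi)
  E_A <- sum(E_Ai); E_B <- sum(E_Bi)
  if (O_A + O_B == 0) {
    message("no events observed; risk statistic undefined")
    x2 <- NA_real_; p <- NA_real_
  } else {
    x2 <- (O_A - E_A)^2 / E_A + (O_B - E_B)^2 / E_B
    p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  }
  structure(list(N_A = N_A, N_B = N_B, O_A = O_A, O_B = O_B,
                 E_A = E_A, E_B = E_B, x2 = x2, p = p,
                 by_time = data.frame(time = times, O_Ai = O_Ai, O_Bi = O_Bi,
                                      O_i = O_i, E_Ai = E_Ai, E_Bi = E_Bi)),
            class = "ldnb_risk")
}

#' @export
print.ldnb_risk <- function(x, ...) {
  cat(sprintf("risk test: N_A=%d N_B=%d  O_A=%g E_A=%.3g  O_B=%g E_B=%.3g  X2=%.4g p=%.4g\n",
              x$N_A, x$N_B, x$O_A, x$E_A, x$O_B, x$E_B, x$x2, x$p))
  invisible(x)
}

#' Screen genes for phenotype-risk association
#'
#' For each gene, samples are median-split by expression and the
#' fixed-group-size chi-square statistic is computed from the phenotype
#' events. No multiple-testing correction is applied (per-gene p-values are
#' reported); results are ordered by p-value. Genes absent from the
#' expression matrix, or with constant expression, are skipped with a log
#' entry.
#'
#' @param expr expression matrix (genes x samples; one value per sample).
#' @param phenotype long phenotype data.frame (see [define_events()]).
#' @param genes gene identifiers to test; `NULL` tests all rows of `expr`.
#' @param config an [ldnb_config()] (supplies `event_threshold` and
#'   `event_direction`).
#' @return data.frame: gene, N_A, N_B, O_A, E_A, O_B, E_B, x2, p.
#' @export
risk_screen <- function(expr, phenotype, genes = NULL, config = ldnb_config()) {
  if (is.null(genes)) genes <- rownames(expr)
  shared <- intersect(colnames(expr), unique(phenotype$sample_id))
  if (length(shared) < 4L)
    stop("too few samples shared between expression and phenotype", call. = FALSE)
  events <- define_events(phenotype[phenotype$sample_id %in% shared, ],
                          threshold = config$event_threshold,
                          direction = config$event_direction)
  rows <- list()
  for (g in genes) {
    if (!(g %in% rownames(expr))) {
      message("gene ", g, " absent from cohort expression; skipped")
      next
    }
    vals <- expr[g, shared]
    groups <- tryCatch(split_by_expression(vals), error = function(e) {
      message("gene ", g, ": ", conditionMessage(e), "; skipped")
      NULL
    })
    if (is.null(groups)) next
    r <- risk_chi_square(events, groups)
    rows[[g]] <- data.frame(gene = g, N_A = r$N_A, N_B = r$N_B,
                            O_A = r$O_A, E_A = r$E_A, O_B = r$O_B, E_B = r$E_B,
                            x2 = r$x2, p = r$p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(), N_A = integer(), N_B = integer(),
                      O_A = numeric(), E_A = numeric(), O_B = numeric(),
                      E_B = numeric(), x2 = numeric(), p = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}
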