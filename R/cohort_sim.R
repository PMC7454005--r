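# Synthetic cohort generator: exposure tables with the compositional
# structure the enrichment analysis assumes and known planted truth.

#' Specification for a synthetic signature cohort
#'
#' Exposures are Dirichlet proportions (one concentration parameter per
#' signature) scaled by a log-normal per-sample mutation burden. Enrichment
#' is planted multiplicatively on the concentration of chosen signatures in
#' chosen strata only.
#'
#' @param n_samples cohort size (default 400).
#' @param signatures signature labels; default 65 SBS + 17 ID analogue
#'   labels (82 signatures).
#' @param concentration Dirichlet concentration per signature (recycled;
#'   default 1).
#' @param enriched named list: signature label -> list(stratum, fold);
#'   default plants a 2-fold SBS3 analogue in `WT_High`.
#' @param gene stratifying gene label (default `"POLQ"`).
#' @param prevalence mutant prevalence of `gene` (default 0.25).
#' @param expression_meanlog,expression_sdlog log-normal expression model.
#' @param burden_meanlog,burden_sdlog log-normal mutation burden model.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_samples = 400L,
                            signatures = c(paste0("SBS", 1:65),
                                           paste0("ID", 1:17)),
                            concentration = 1,
                            enriched = list(SBS3 = list(stratum = "WT_High",
                                                        fold = 2)),
                            gene = "POLQ",
                            prevalence = 0.25,
                            expression_meanlog = log(10),
                            expression_sdlog = 1,
                            burden_meanlog = log(3000),
                            burden_sdlog = 0.5) {
  stopifnot(n_samples >= 3L, prevalence >= 0, prevalence <= 1)
  concentration <- rep_len(concentration, length(signatures))
  if (any(concentration <= 0)) stop("concentrations must be positive")
  for (e in enriched) {
    if (is.null(e$fold) || e$fold <= 0) stop("fold-changes must be positive")
  }
  if (length(enriched) && !all(names(enriched) %in% signatures))
    stop("enriched signatures must be among the signature labels")
  structure(list(n_samples = as.integer(n_samples), signatures = signatures,
                 concentration = concentration, enriched = enriched,
                 gene = gene, prevalence = prevalence,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 burden_meanlog = burden_meanlog,
                 burden_sdlog = burden_sdlog),
            class = "cohort_sim_spec")
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a cohort with planted signature enrichment
#'
#' @param spec `cohort_sim_spec`.
#' @param seed integer seed; simulation is reproducible under a fixed seed.
#' @return list with `profiles` ([sample_profiles()]) and `truth` (list:
#'   `strata` per sample before exposure draws, `enriched` spec).
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(seed)
  n <- spec$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  status <- ifelse(stats::runif(n) < spec$prevalence, "mutant", "wildtype")
  expr <- stats::rlnorm(n, spec$expression_meanlog, spec$expression_sdlog)
  names(expr) <- ids
  tert <- stratify_expression(expr)
  strata <- paste0(ifelse(status == "mutant", "MT", "WT"), "_", tert)
  burden <- stats::rlnorm(n, spec$burden_meanlog, spec$burden_sdlog)
  k <- length(spec$signatures)
  ex <- matrix(0, n, k, dimnames = list(ids, spec$signatures))
  for (i in seq_len(n)) {
    alpha <- spec$concentration
    for (sg in names(spec$enriched)) {
      e <- spec$enriched[[sg]]
      if (strata[i] == e$stratum)
        alpha[match(sg, spec$signatures)] <-
          alpha[match(sg, spec$signatures)] * e$fold
    }
    ex[i, ] <- rdirichlet_one(alpha) * burden[i]
  }
  gs <- data.frame(sample = ids, gene = spec$gene, status = status)
  em <- matrix(expr, ncol = 1, dimnames = list(ids, spec$gene))
  profiles <- sample_profiles(ex, gs, em)
  list(profiles = profiles,
       truth = list(strata = stats::setNames(strata, ids),
                    enriched = spec$enriched))
}

#' Detection/false-flag rates over a grid of fold-changes and cohort sizes
#'
#' For each grid cell, simulates `n_reps` cohorts, runs
#' [enrichment_report()] on the planted contrast and records how often the
#' enriched signature is flagged (`p_adjusted < alpha`) and how often any
#' null signature is flagged.
#'
#' @param folds fold-changes to plant (1 = null cohort).
#' @param ns cohort sizes.
#' @param n_reps replicates per cell.
#' @param alpha significance threshold on adjusted p-values.
#' @param seed base seed; replicate r of cell (i,j) uses a deterministic
#'   offset.
#' @param spec_base template spec whose other fields are reused.
#' @return data.frame with one row per cell: detection and false-flag rate.
#' @export
recovery_suite <- function(folds = c(1, 2, 3), ns = c(200L, 400L),
                           n_reps = 20L, alpha = 0.05, seed = 1L,
                           spec_base = cohort_sim_spec()) {
  if (length(folds) == 0L || length(ns) == 0L) stop("empty grid")
  grid <- expand.grid(fold = folds, n = ns)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    fold <- grid$fold[g]
    n <- grid$n[g]
    det <- 0L
    fp <- 0L
    for (r in seq_len(n_reps)) {
      sp <- cohort_sim_spec(
        n_samples = n, signatures = spec_base$signatures,
        concentration = spec_base$concentration,
        enriched = list(SBS3 = list(stratum = "WT_High", fold = fold)),
        gene = spec_base$gene, prevalence = spec_base$prevalence,
        expression_meanlog = spec_base$expression_meanlog,
        expression_sdlog = spec_base$expression_sdlog,
        burden_meanlog = spec_base$burden_meanlog,
        burden_sdlog = spec_base$burden_sdlog)
      sim <- simulate_cohort(sp, seed = (seed + 7919L * g + r) %% .Machine$integer.max)
      rep_ <- enrichment_report(sim$profiles, sp$gene,
                                contrasts = list(c("WT_High", "WT_Low")))
      hits <- rep_$tests$signature[rep_$tests$p_adjusted < alpha]
      if (fold > 1 && "SBS3" %in% hits) det <- det + 1L
      if (any(setdiff(hits, if (fold > 1) "SBS3" else character(0)) != ""))
        fp <- fp + 1L
    }
    data.frame(fold = fold, n = n, n_reps = n_reps,
               detection_rate = if (fold > 1) det / n_reps else NA_real_,
               false_flag_rate = fp / n_reps)
  })
  do.call(rbind, rows)
}
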