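# Cohort arm: gene status calls from variant consequences, expression
# tertile stratification, rank-based signature association tests with
# Bonferroni correction, and the stratified enrichment report.

SOMATIC_CLASSES <- c("frameshift_deletion", "frameshift_insertion", "nonsense")

#' Call a gene mutant or wild type from its variant consequences
#'
#' A sample is mutant for a gene when it carries at least one variant of the
#' qualifying somatic classes (frameshift deletion, frameshift insertion,
#' nonsense); anything else - including no variant at all - is wild type.
#'
#' @param consequences character vector of consequence classes for the
#'   gene's variants in one sample (may be empty).
#' @return `"mutant"` or `"wildtype"`.
#' @export
call_gene_status <- function(consequences) {
  if (length(consequences) == 0L) return("wildtype")
  if (any(consequences %in% SOMATIC_CLASSES)) "mutant" else "wildtype"
}

#' Stratify samples into expression tertiles
#'
#' The bottom third of values is `Low`, the top third `High`, the middle
#' `Excluded` (the binary mode splits at the lower tertile boundary
#' instead, with nothing excluded). Boundaries use the empirical quantile
#' with linear interpolation (R type 7) at probabilities 1/3 and 2/3; a
#' value equal to the lower boundary is Low, equal to the upper boundary is
#' High. Degenerate input (all values identical) yields all `Excluded`.
#'
#' @param values named numeric vector of per-sample expression levels.
#' @param mode `"tertile"` (default) or `"binary"`.
#' @return character vector (`High`/`Low`/`Excluded`) aligned with `values`.
#' @export
stratify_expression <- function(values, mode = c("tertile", "binary")) {
  mode <- match.arg(mode)
  if (sum(!is.na(values)) < 3L) stop("need at least 3 numeric values")
  q <- stats::quantile(values, probs = c(1 / 3, 2 / 3), na.rm = TRUE,
                       names = FALSE, type = 7)
  out <- rep("Excluded", length(values))
  if (q[1] == q[2]) {
    names(out) <- names(values)
    return(out)  # degenerate: no spread to stratify on
  }
  if (mode == "binary") {
    out <- ifelse(values <= q[1], "Low", "High")
  } else {
    out[values <= q[1]] <- "Low"
    out[values >= q[2]] <- "High"
  }
  out[is.na(values)] <- "Excluded"
  names(out) <- names(values)
  out
}

#' Rank-based test for a signature exposure difference between two strata
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test by default; exact null
#' distribution for small tie-free samples, normal approximation with
#' continuity and tie correction otherwise. `paired = TRUE` gives the
#' signed-rank test for genuinely paired designs.
#'
#' @param exposures_a,exposures_b exposure values of the two strata.
#' @param paired use the signed-rank test (requires equal lengths).
#' @return list with `statistic`, `p_value`, `medians`, `n`.
#' @export
test_signature_association <- function(exposures_a, exposures_b,
                                       paired = FALSE) {
  if (length(exposures_a) == 0L || length(exposures_b) == 0L)
    stop("both strata must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(exposures_a, exposures_b,
                                            paired = paired,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       medians = c(a = stats::median(exposures_a),
                   b = stats::median(exposures_b)),
       n = c(a = length(exposures_a), b = length(exposures_b)))
}

#' Bonferroni adjustment
#'
#' @param p_values raw p-values.
#' @param m number of tests (defaults to `length(p_values)`; must be at
#'   least that).
#' @return adjusted p-values, `min(1, p * m)`.
#' @export
adjust_bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop("m must be >= the number of tests")
  pmin(1, p_values * m)
}

#' Pearson correlation between two signature exposures
#'
#' @param x,y paired exposure vectors (n >= 3).
#' @return list with `r` and `p_value` (two-sided).
#' @export
correlate_exposures <- function(x, y) {
  if (length(x) != length(y)) stop("exposure vectors must be paired")
  if (length(x) < 3L) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in an exposure vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Assemble per-sample profiles
#'
#' @param exposures samples x signatures numeric matrix (rownames = sample
#'   ids).
#' @param gene_status data.frame with columns `sample`, `gene`, `status`
#'   (`mutant`/`wildtype`).
#' @param expression samples x genes numeric matrix.
#' @return object of class `sample_profiles`.
#' @export
sample_profiles <- function(exposures, gene_status, expression) {
  stopifnot(is.matrix(exposures), !is.null(rownames(exposures)))
  if (any(exposures < 0)) stop("exposures must be non-negative")
  stopifnot(all(c("sample", "gene", "status") %in% names(gene_status)))
  stopifnot(is.matrix(expression), !is.null(rownames(expression)))
  structure(list(exposures = exposures, gene_status = gene_status,
                 expression = expression),
            class = "sample_profiles")
}

#' @export
print.sample_profiles <- function(x, ...) {
  cat("sample_profiles:", nrow(x$exposures), "samples x",
      ncol(x$exposures), "signatures;",
      length(unique(x$gene_status$gene)), "genes\n")
  invisible(x)
}

#' Stratum labels for one gene
#'
#' Combines the mutation status call with the expression tertile into the
#' four analysis strata `WT_High`, `WT_Low`, `MT_High`, `MT_Low` (samples
#' with mid-tertile expression are `*_Excluded`).
#'
#' @param profiles `sample_profiles`.
#' @param gene gene symbol.
#' @param mode tertile mode, see [stratify_expression()].
#' @return named character vector of stratum labels per sample.
#' @export
stratum_labels <- function(profiles, gene, mode = "tertile") {
  samples <- rownames(profiles$exposures)
  gs <- profiles$gene_status
  gs <- gs[gs$gene == gene, ]
  status <- stats::setNames(rep("wildtype", length(samples)), samples)
  status[gs$sample[gs$status == "mutant"]] <- "mutant"
  if (!(gene %in% colnames(profiles$expression)))
    stop("no expression values for gene ", gene)
  expr <- profiles$expression[samples, gene]
  tert <- stratify_expression(expr, mode = mode)
  paste0(ifelse(status == "mutant", "MT", "WT"), "_", tert)
}

#' Stratified signature enrichment report
#'
#' Stratifies the cohort by `gene` mutation status and expression tertile,
#' reports mean exposure proportions per stratum, and tests every requested
#' signature between strata pairs with the rank-sum test, Bonferroni
#' corrected over all tests of a contrast.
#'
#' @param profiles `sample_profiles`.
#' @param gene stratifying gene.
#' @param signatures signature labels to test (default: all columns).
#' @param contrasts list of stratum pairs; the default tests WT_High vs
#'   each other stratum (the contrasts a POLQ-style analysis reads off the
#'   proportion panels).
#' @param normalize divide each sample's exposures by their sum (treats
#'   input as counts; set FALSE if already proportions).
#' @param m Bonferroni denominator (default: number of signatures tested).
#' @param mode tertile mode.
#' @return list with `proportions` (stratum x signature means), `tests`
#'   (per contrast and signature: statistic, p_raw, p_adjusted, medians,
#'   group sizes), `strata` (per-sample labels), `skipped` contrasts.
#' @export
enrichment_report <- function(profiles, gene,
                              signatures = colnames(profiles$exposures),
                              contrasts = list(c("WT_High", "WT_Low"),
                                               c("WT_High", "MT_High"),
                                               c("WT_High", "MT_Low")),
                              normalize = TRUE,
                              m = length(signatures),
                              mode = "tertile") {
  stopifnot(inherits(profiles, "sample_profiles"))
  missing_sig <- setdiff(signatures, colnames(profiles$exposures))
  if (length(missing_sig))
    stop("profiles lack exposures for: ", paste(missing_sig, collapse = ", "))
  ex <- profiles$exposures[, signatures, drop = FALSE]
  if (normalize) {
    tot <- rowSums(profiles$exposures)
    tot[tot == 0] <- 1
    ex <- ex / tot
  }
  strata <- stratum_labels(profiles, gene, mode = mode)
  keep_levels <- c("WT_High", "WT_Low", "MT_High", "MT_Low")
  props <- matrix(NA_real_, length(keep_levels), ncol(ex),
                  dimnames = list(keep_levels, signatures))
  for (s in keep_levels) {
    idx <- strata == s
    if (any(idx)) props[s, ] <- colMeans(ex[idx, , drop = FALSE])
  }

  tests <- list()
  skipped <- character(0)
  for (ct in contrasts) {
    ia <- strata == ct[1]
    ib <- strata == ct[2]
    if (!any(ia) || !any(ib)) {
      skipped <- c(skipped, paste(ct, collapse = " vs "))
      next
    }
    rows <- lapply(signatures, function(sg) {
      tr <- test_signature_association(ex[ia, sg], ex[ib, sg])
      data.frame(contrast = paste(ct, collapse = "_vs_"), signature = sg,
                 statistic = tr$statistic, p_raw = tr$p_value,
                 median_a = tr$medians[["a"]], median_b = tr$medians[["b"]],
                 n_a = tr$n[["a"]], n_b = tr$n[["b"]])
    })
    df <- do.call(rbind, rows)
    df$p_adjusted <- adjust_bonferroni(df$p_raw, m = max(m, nrow(df)))
    tests[[length(tests) + 1L]] <- df
  }
  tests <- if (length(tests)) do.call(rbind, tests)
           else data.frame(contrast = character(0), signature = character(0),
                           statistic = numeric(0), p_raw = numeric(0),
                           median_a = numeric(0), median_b = numeric(0),
                           n_a = integer(0), n_b = integer(0),
                           p_adjusted = numeric(0))
  rownames(tests) <- NULL
  list(proportions = props, tests = tests, strata = strata,
       skipped = skipped)
}
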