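test_that("gene status calls follow the somatic class filter", {
  expect_identical(call_gene_status("nonsense"), "mutant")
  expect_identical(call_gene_status(c("missense", "synonymous")), "wildtype")
  expect_identical(call_gene_status(character(0)), "wildtype")
  expect_identical(call_gene_status(c("missense", "frameshift_deletion")),
                   "mutant")
})

test_that("expression tertiles split bottom/top thirds and handle edge cases", {
  x <- stats::setNames(1:9, paste0("s", 1:9))
  cls <- stratify_expression(x)
  expect_identical(unname(cls[1:3]), rep("Low", 3))
  expect_identical(unname(cls[7:9]), rep("High", 3))
  expect_identical(unname(cls[4:6]), rep("Excluded", 3))

  set.seed(11)
  u <- stats::runif(100)
  cls <- stratify_expression(u)
  # type-7 quantiles at 1/3 and 2/3 put 33-34 samples in each tail
  expect_true(sum(cls == "Low") %in% 33:34)
  expect_true(sum(cls == "High") %in% 33:34)

  expect_identical(unique(stratify_expression(rep(5, 10))), "Excluded")
  expect_error(stratify_expression(c(1, 2)), "at least 3")

  bin <- stratify_expression(x, mode = "binary")
  expect_false(any(bin == "Excluded"))
  expect_equal(sum(bin == "Low"), 3)
})

test_that("rank-sum test matches the exhaustive enumeration oracle", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 6)
  res <- test_signature_association(a, b)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_ranksum_p(a, b))
  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:50, 4)
    b <- sample(51:100, 5)  # disjoint -> tie-free
    expect_equal(test_signature_association(a, b)$p_value,
                 oracle_ranksum_p(a, b), tolerance = 1e-12)
  }
  expect_equal(test_signature_association(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(test_signature_association(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum test detects a 2-SD shift at n=50/50", {
  set.seed(99)
  hits <- vapply(1:40, function(i) {
    a <- stats::rnorm(50)
    b <- stats::rnorm(50, mean = 2)
    test_signature_association(a, b)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("rank test is invariant to adding a constant to both groups", {
  set.seed(3)
  a <- stats::rnorm(20)
  b <- stats::rnorm(25, 0.5)
  expect_equal(test_signature_association(a, b)$p_value,
               test_signature_association(a + 7, b + 7)$p_value)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(adjust_bonferroni(0.0005, 82), 0.041)
  expect_equal(adjust_bonferroni(0.5, 82), 1)
  expect_equal(adjust_bonferroni(0, 82), 0)
  p <- stats::runif(20)
  adj <- adjust_bonferroni(p, 50)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_error(adjust_bonferroni(p, 5), "m must be")
})

test_that("Pearson correlation behaves on exact and planted data", {
  x <- 1:10
  expect_equal(correlate_exposures(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_exposures(x, -x)$r, -1)
  expect_error(correlate_exposures(x, rep(1, 10)), "zero variance")
  expect_error(correlate_exposures(1:4, 1:5), "paired")
  # bivariate normal with rho = 0.66: r-hat within the n=500 sampling band
  set.seed(12)
  rho <- 0.66
  u <- stats::rnorm(500)
  v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(500)
  expect_equal(correlate_exposures(u, v)$r, rho, tolerance = 0.06 / rho)
})

test_that("enrichment report recovers a planted doubling and partitions samples", {
  spec <- cohort_sim_spec(n_samples = 400)
  sim <- simulate_cohort(spec, seed = 2024)
  rep_ <- enrichment_report(sim$profiles, "POLQ",
                            contrasts = list(c("WT_High", "WT_Low")))
  # stratification partition: one label per sample
  expect_length(rep_$strata, 400)
  expect_true(all(rep_$strata %in% c("WT_High", "WT_Low", "WT_Excluded",
                                     "MT_High", "MT_Low", "MT_Excluded")))
  flagged <- rep_$tests$signature[rep_$tests$p_adjusted < 0.05]
  expect_true("SBS3" %in% flagged)
  expect_length(setdiff(flagged, "SBS3"), 0)
  # p_adjusted dominates p_raw
  expect_true(all(rep_$tests$p_adjusted >= rep_$tests$p_raw))
})

test_that("single-signature proportions sum to 1 and empty strata are skipped", {
  ex <- matrix(stats::rlnorm(30), 30, 1,
               dimnames = list(sprintf("s%02d", 1:30), "SBS3"))
  gs <- data.frame(sample = rownames(ex), gene = "POLQ", status = "wildtype")
  em <- matrix(stats::rlnorm(30), 30, 1,
               dimnames = list(rownames(ex), "POLQ"))
  prof <- sample_profiles(ex, gs, em)
  rep_ <- enrichment_report(prof, "POLQ")
  expect_true(all(abs(rowSums(rep_$proportions[c("WT_High", "WT_Low"), ,
                                               drop = FALSE]) - 1) < 1e-12))
  # no mutant samples: MT contrasts are skipped, not errors
  expect_gte(length(rep_$skipped), 2)
})
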