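test_that("deletion MH matches the worked examples", {
  expect_equal(deletion_microhomology("GGATCAATCGG", 4, 7), 3)
  expect_equal(oracle_mh("GGATCAATCGG", 4, 7), 3)  # 4 placements - 1
  expect_equal(deletion_microhomology("AACCGGTT", 3, 6), 0)
  expect_equal(deletion_microhomology("AAAAAA", 3, 4), 4)
  expect_error(deletion_microhomology("ACGT", 0, 2), "out of range")
  expect_error(deletion_microhomology("ACGT", 3, 5), "out of range")
})

test_that("deletion MH equals the placement-enumeration oracle", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(10:60, 1)
    ref <- rand_seq(n)
    s <- sample(seq_len(n - 1), 1)
    e <- sample(s:min(n, s + 8), 1)
    expect_equal(deletion_microhomology(ref, s, e), oracle_mh(ref, s, e))
  }
})

test_that("TMEJ window flags 3-6 bp MH by default, configurable for distal", {
  expect_true(call_tmej(4))
  expect_false(call_tmej(2))
  expect_false(call_tmej(7))
  expect_true(call_tmej(3) && call_tmej(6))
  expect_true(call_tmej(2, window = c(0, 4)))
})

test_that("background lambda estimation uses the median-trimmed mean", {
  expect_equal(estimate_background(rep(1, 5)), 1)
  expect_equal(estimate_background(c(1, 1, 1, 1, 1000)), 1)
  expect_equal(estimate_background(c(2, 4, 6, 8, 1000), strategy = "mean"),
               204)
  expect_error(estimate_background(numeric(0)), "no event groups")
})

test_that("Poisson cutoffs match tail tables and are monotone", {
  expect_equal(poisson_cutoff(0, 0.9), 1)
  expect_equal(poisson_cutoff(1, 0.99), 5)
  expect_equal(poisson_cutoff(3, 0.95), 7)
  for (lam in c(0.2, 1, 2.5, 7)) for (lev in c(0.9, 0.95, 0.99)) {
    expect_equal(poisson_cutoff(lam, lev), oracle_poisson_cutoff(lam, lev))
  }
  # monotone in level and lambda
  lams <- c(0, 0.5, 1, 2, 4, 8)
  for (lev in c(0.9, 0.95, 0.99))
    expect_true(all(diff(vapply(lams, poisson_cutoff, 1L, level = lev)) >= 0))
  for (lam in lams)
    expect_true(all(diff(vapply(c(0.9, 0.95, 0.99), function(l)
      poisson_cutoff(lam, l), 1L)) >= 0))
  expect_error(poisson_cutoff(-1, 0.9), "non-negative")
})

test_that("insertion origin classes cover the definitional cases", {
  set.seed(51)
  ref <- rand_seq(400)
  refs <- c(amp = ref)
  j <- 200L
  # duplication of the 6 bases immediately left of the junction
  dup <- substr(ref, j - 5, j)
  oc <- classify_insertion_origin(dup, j, refs, length_bounds = c(5, 15))
  expect_identical(oc$class, "direct_repeat")
  # a 12-mer absent from the reference
  repeat {
    rnd <- rand_seq(12)
    if (nrow(find_motif(ref, rnd)) == 0) break
  }
  expect_identical(classify_insertion_origin(rnd, j, refs)$class, "random")
  # planted reverse-complement copy of an upstream 8-mer
  up <- substr(ref, 120, 127)
  sb <- classify_insertion_origin(rc_oracle(up), j, refs)
  expect_identical(sb$class, "snapback")
  expect_equal(sb$origin$start, 120)
  # sense copies by distance
  near <- substr(ref, 150, 157)
  ocn <- classify_insertion_origin(near, j, refs)
  expect_true(ocn$class %in% c("nearby", "excluded"))
  far <- substr(ref, 20, 31)
  ocf <- classify_insertion_origin(far, j, refs)
  expect_true(ocf$class %in% c("distant", "excluded"))
  expect_error(classify_insertion_origin("ACG", j, refs), "length outside")
})

test_that("multi-class origins are excluded or resolved by precedence", {
  # build a reference where the insertion matches both flank-dup and a
  # distant sense copy
  core <- "GATTACAGG"
  ref <- paste0(rand_seq(150), core, rand_seq(150), core, rand_seq(60))
  j <- 150L + nchar(core)  # junction right after the first copy
  oc <- classify_insertion_origin(core, j, c(amp = ref))
  expect_identical(oc$class, "excluded")
  oc2 <- classify_insertion_origin(core, j, c(amp = ref),
                                   ambiguity = "precedence")
  expect_identical(oc2$class, "direct_repeat")
})

test_that("short insertions use the three-class flanking scheme", {
  set.seed(61)
  ref <- rand_seq(300)
  j <- 150L
  expect_identical(classify_short_insertion("T", j, ref), "undetermined")
  tmpl <- substr(ref, 160, 167)
  expect_identical(classify_short_insertion(tmpl, j, ref), "template")
  # reverse-complement of a flank 8-mer; make sure no sense copy exists
  sb <- rc_oracle(substr(ref, 130, 137))
  if (!grepl(sb, substr(ref, 51, 250), fixed = TRUE))
    expect_identical(classify_short_insertion(sb, j, ref), "snapback")
  repeat {
    nn <- rand_seq(4)
    if (!grepl(nn, ref, fixed = TRUE) && !grepl(rc_oracle(nn), ref, fixed = TRUE))
      break
  }
  expect_identical(classify_short_insertion(nn, j, ref), "undetermined")
})

test_that("MH flags measure initiation and termination homology", {
  # engineered reference: left flank ends with GCA; origin copy at 220 is
  # preceded by GCA (3 bp initiation MH); insertion ends with the two bases
  # right of the junction (2 bp termination MH)
  set.seed(71)
  left <- paste0(rand_seq(97), "GCA")          # positions 1..100
  right <- paste0("TG", rand_seq(98))          # positions 101..200
  core <- "ACCGTCTG"                            # insertion template,ends TG
  mid <- paste0(rand_seq(19), "GCA", core, rand_seq(70))
  ref <- paste0(left, right, mid)
  j <- 100L
  o1 <- 200 + 19 + 3 + 1
  origin <- data.frame(ref = "amp", strand = "+", start = o1,
                       end = o1 + 7, dist = 100, class = "distant")
  fl <- insertion_mh_flags(core, j, origin, list(amp = ref))
  expect_equal(fl[["mh_init"]], 3)
  expect_equal(fl[["mh_end"]], 2)

  # no flanking identity: both flags zero (below the 2 bp minimum)
  origin2 <- data.frame(ref = "amp", strand = "+", start = 150,
                        end = 157, dist = 50, class = "nearby")
  ins2 <- substr(ref, 150, 157)
  fl2 <- insertion_mh_flags(ins2, j, origin2, list(amp = ref))
  expect_true(all(fl2 %in% 0:6))
  expect_error(insertion_mh_flags("ACGTACGT", j, NULL, list(amp = ref)),
               "origin must be resolved")
})

test_that("noise filter retains strong groups and annotates the table", {
  set.seed(81)
  groups <- data.frame(
    key = paste0("del:", 1:40, ":", 1:40 + 3),
    kind = "del", start = 1:40, end = 1:40 + 3, length = 4,
    sequence = "AAAA",
    n_reads = c(rep(1, 30), rep(2, 5), 40, 45, 50, 60, 80))
  fb <- filter_background(groups, level = 0.95)
  expect_true(all(groups$n_reads[fb$groups$retained] >= fb$cutoff))
  expect_true(all(fb$groups$n_reads[!fb$groups$retained] < fb$cutoff))
  expect_lte(fb$lambda, 2)  # median-trimmed mean ignores the true events
})

test_that("summarize_assay percentages are conserved and precise-only works", {
  hp <- hprt_fixture()
  reads <- stats::setNames(rep(hp$sequence, 5), paste0("r", 1:5))
  res <- analyze_junctions(reads, hp, assay = "proximal", lambda = 0)
  expect_equal(res$summary$overview$pct_no_mutation, 100)
  sim <- simulate_reads(junction_sim_spec(hp, cut = 266L, depth = 500L),
                        seed = 91)
  res2 <- analyze_junctions(sim$reads, hp, assay = "proximal", lambda = 0)
  ov <- res2$summary$overview
  expect_equal(ov$pct_no_mutation + ov$pct_deletion_reads +
                 ov$pct_insertion_reads + ov$pct_complex_reads, 100,
               tolerance = 1e-9)
  # origin-class composition sums to 100 over classified insertions
  oc <- res2$summary$origin_classes
  if (sum(oc$n_reads) > 0)
    expect_equal(sum(oc$pct_of_classified), 100, tolerance = 1e-9)
})
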