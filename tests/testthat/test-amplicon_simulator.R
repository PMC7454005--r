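test_that("plant_deletion self-verifies its MH and reports impossibilities", {
  set.seed(201)
  ref <- rand_seq(300)
  pd <- plant_deletion(ref, 10, 0, cut = 150L)
  if (!is.null(pd))
    expect_equal(deletion_microhomology(ref, pd$start, pd$end), 0)
  # engineered 3 bp repeat flanking the deleted block
  eng <- paste0(rand_seq(50), "CTG", rand_seq(7), "CTG", rand_seq(50))
  pd3 <- plant_deletion(eng, 10, 3, cut = 55L)
  expect_false(is.null(pd3))
  expect_equal(deletion_microhomology(eng, pd3$start, pd3$end), 3)
  expect_equal(oracle_mh(eng, pd3$start, pd3$end), 3)
  # unobtainable MH on a short repeat-free sequence
  expect_null(plant_deletion("ACGTACGTACGTACGTACGT", 4, 10, cut = 10L,
                             max_dist = 20L))
  expect_error(plant_deletion("ACGT", 10, 0))
})

test_that("plant_insertion round-trips through the classifier", {
  hp <- hprt_fixture()
  cases <- list(
    list(class = "snapback", len = 8, mh_init = 3, mh_end = 0),
    list(class = "direct_repeat", len = 6, mh_init = 0, mh_end = 0),
    list(class = "distant", len = 12, mh_init = 0, mh_end = 0),
    list(class = "nearby", len = 8, mh_init = 2, mh_end = 0),
    list(class = "snapback", len = 8, mh_init = 0, mh_end = 2),
    list(class = "random", len = 10, mh_init = 0, mh_end = 0))
  for (cs in cases) {
    set.seed(77)
    ev <- plant_insertion(hp, cs$class, cs$len, mh_init = cs$mh_init,
                          mh_end = cs$mh_end, cut = 266L)
    expect_identical(ev$origin_class, cs$class)
    oc <- classify_insertion_origin(ev$seq, ev$pos,
                                    c(hprt_synthetic = hp$sequence))
    expect_identical(oc$class, cs$class)
    if (cs$class %in% c("distant", "nearby", "snapback")) {
      fl <- insertion_mh_flags(ev$seq, ev$pos, oc$origin,
                               list(hprt_synthetic = hp$sequence))
      expect_equal(unname(fl), c(cs$mh_init, cs$mh_end))
    }
    if (cs$class == "distant") {
      d <- min(abs(ev$origin_start - ev$pos), abs(ev$origin_end - ev$pos))
      expect_gte(d, 100)
    }
  }
  expect_error(plant_insertion(hp, "nearby", 8, mh_init = 6, mh_end = 6,
                               cut = 266L), "not realizable")
  expect_error(plant_insertion(hp, "random", 8, mh_init = 2, cut = 266L),
               "cannot carry MH flags")
})

test_that("simulate_reads is deterministic and mixture-faithful", {
  hp <- hprt_fixture()
  spec <- junction_sim_spec(hp, cut = 266L, depth = 400L)
  a <- simulate_reads(spec, seed = 42)
  b <- simulate_reads(spec, seed = 42)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
  # FASTQ bytes identical too
  fa <- tempfile(fileext = ".fastq")
  fb <- tempfile(fileext = ".fastq")
  write_reads_fastq(a$reads, fa)
  write_reads_fastq(b$reads, fb)
  expect_identical(readLines(fa), readLines(fb))
  c_ <- simulate_reads(spec, seed = 43)
  expect_false(identical(a$reads, c_$reads))

  # precise fraction within the binomial band (p = 0.9, n = 1000)
  spec2 <- junction_sim_spec(hp, cut = 266L, depth = 1000L)
  sim <- simulate_reads(spec2, seed = 5)
  phat <- mean(sim$truth$type == "precise")
  expect_lt(abs(phat - 0.9), 4 * sqrt(0.9 * 0.1 / 1000))
})

test_that("invalid mixtures and specs are rejected", {
  hp <- hprt_fixture()
  bad <- default_outcomes()
  bad$prop[1] <- 0.5
  expect_error(junction_sim_spec(hp, 266L, outcomes = bad), "sum to 1")
})

test_that("noise-free simulation is recovered perfectly end to end", {
  hp <- hprt_fixture()
  spec <- junction_sim_spec(hp, cut = 266L, depth = 400L, error_rate = 0,
                            lambda = 0)
  sim <- simulate_reads(spec, seed = 11)
  calls <- call_junctions(sim$reads, hp)
  ev <- evaluate_calls(calls$per_read, sim$truth)
  expect_equal(ev$accuracy, 1)
  expect_true(all(diag(ev$confusion) == rowSums(ev$confusion)))
  # deletion coordinates match the planted canonical truth exactly
  m <- merge(calls$events, sim$truth, by = "read_id",
             suffixes = c(".call", ".true"))
  dels <- m[m$kind.true %in% "del", ]
  expect_true(all(dels$start.call == dels$start.true &
                    dels$end.call == dels$end.true))
  ins <- m[m$kind.true %in% "ins", ]
  expect_true(all(ins$sequence.call == ins$sequence.true))
})

test_that("background injection produces Poisson-count spurious groups", {
  hp <- hprt_fixture()
  spec <- junction_sim_spec(hp, cut = 266L, depth = 300L, lambda = 2,
                            n_background = 25L)
  sim <- simulate_reads(spec, seed = 19)
  bg <- sim$truth[sim$truth$background, ]
  expect_gt(nrow(bg), 0)
  cnt <- table(bg$outcome)
  expect_lt(abs(mean(cnt) - 2) , 1)  # crude sanity: counts near lambda
})

test_that("evaluate_calls validates inputs and scores mislabels", {
  hp <- hprt_fixture()
  sim <- simulate_reads(junction_sim_spec(hp, cut = 266L, depth = 50L),
                        seed = 3)
  calls <- call_junctions(sim$reads, hp)
  expect_error(evaluate_calls(calls$per_read[-1, ], sim$truth),
               "do not match")
  expect_error(evaluate_calls(calls$per_read, sim$truth[0, ]), "empty truth")
  pr <- calls$per_read
  flip <- which(pr$class == "precise")[1]
  pr$class[flip] <- "deletion_only"
  ev <- evaluate_calls(pr, sim$truth)
  n_prec <- sum(ev$confusion["precise", ])
  expect_equal(ev$per_class$recall[ev$per_class$class == "precise"],
               (n_prec - 1) / n_prec)
})
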