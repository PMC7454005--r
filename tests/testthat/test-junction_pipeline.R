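test_that("merge_pairs merges exact overlaps and applies the quality rule", {
  set.seed(31)
  left <- rand_seq(80)
  right <- rand_seq(80)
  ov <- rand_seq(50)
  r1 <- paste0(left, ov)
  r2 <- rc_oracle(paste0(ov, right))
  m <- merge_pairs(r1, r2, min_overlap = 20)
  expect_true(m$merged)
  expect_equal(nchar(m$sequence), nchar(r1) + nchar(r2) - 50)
  expect_identical(m$sequence, paste0(left, ov, right))

  # zero overlap
  expect_false(merge_pairs(rand_seq(40), rand_seq(40),
                           min_overlap = 15)$merged)

  # one disagreement resolved by quality
  ov2 <- paste0("A", substr(ov, 2, 50))
  r2b <- rc_oracle(paste0(ov2, right))
  q1 <- rep(20, nchar(r1))
  q2 <- rep(40, nchar(r2b))
  m2 <- merge_pairs(r1, r2b, q1, q2, min_overlap = 20)
  expect_true(m2$merged)
  # the disagreement sits at the overlap start (position 81)
  expect_identical(substr(m2$sequence, 81, 81), "A")  # higher-quality base
  m3 <- merge_pairs(r1, r2b, q2[seq_len(nchar(r1))], q1, min_overlap = 20)
  expect_identical(substr(m3$sequence, 81, 81), substr(ov, 1, 1))
})

test_that("align_read of a reference-identical read yields zero events", {
  hp <- hprt_fixture()
  aln <- align_read(c(r1 = hp$sequence), hp)[[1]]
  ex <- extract_events(aln)
  expect_identical(ex$class, "precise")
  expect_equal(nrow(ex$events), 0)
})

test_that("deletions are reported at their leftmost equivalent placement", {
  ref <- "GGATCAATCGG"
  aln <- align_read(c(r = "GGATCGG"), ref)[[1]]
  ex <- extract_events(aln)
  expect_equal(nrow(ex$events), 1)
  expect_identical(ex$events$kind, "del")
  expect_equal(ex$events$start, 3)
  expect_equal(ex$events$end, 6)
  expect_equal(unname(oracle_leftmost_del(ref, 4, 7)), c(3, 6))
})

test_that("planted indels are recovered with oracle-verified placement", {
  set.seed(17)
  for (i in 1:30) {
    ref <- rand_seq(60)
    if (i %% 2 == 0) {
      L <- sample(2:12, 1)
      s <- sample(10:(50 - L), 1)
      read <- mutate_ref(ref, "del", s, s + L - 1)
      expected <- oracle_leftmost_del(ref, s, s + L - 1)
      ex <- extract_events(align_read(c(r = read), ref)[[1]])
      expect_equal(nrow(ex$events), 1)
      expect_identical(ex$class, "deletion_only")
      expect_equal(c(ex$events$start, ex$events$end), unname(expected))
    } else {
      L <- sample(2:8, 1)
      j <- sample(10:50, 1)
      ins <- rand_seq(L)
      read <- mutate_ref(ref, "ins", j, ins = ins)
      expected <- oracle_leftmost_ins(ref, j, ins)
      ex <- extract_events(align_read(c(r = read), ref)[[1]])
      expect_equal(nrow(ex$events), 1)
      expect_identical(ex$class, "insertion_only")
      expect_equal(ex$events$start, expected$pos)
      expect_identical(ex$events$sequence, expected$seq)
    }
  }
})

test_that("a read with 2 deletions and 2 insertions yields four records", {
  set.seed(23)
  ref <- rand_seq(200)
  read <- ref
  # apply right-to-left so earlier coordinates stay valid
  read <- mutate_ref(read, "ins", 160, ins = "CATTGACA")
  read <- mutate_ref(read, "del", 120, 127)
  read <- mutate_ref(read, "ins", 80, ins = "TTGCAC")
  read <- mutate_ref(read, "del", 30, 35)
  ex <- extract_events(align_read(c(r = read), ref)[[1]])
  expect_identical(ex$class, "deletion_and_insertion")
  expect_equal(nrow(ex$events), 4)
  expect_equal(sum(ex$events$kind == "del"), 2)
  expect_equal(sum(ex$events$kind == "ins"), 2)
})

test_that("realign_softclip recovers large deletions and is idempotent", {
  set.seed(37)
  ref <- rand_seq(900)
  read <- mutate_ref(ref, "del", 301, 600)    # 300 bp deletion
  aln <- realign_softclip(read, ref)
  expect_false(is.null(aln))
  ex <- extract_events(aln)
  expect_identical(ex$class, "soft_clipped")
  dels <- ex$events[ex$events$kind == "del", ]
  expect_equal(nrow(dels), 1)
  expect_equal(dels$length, 300)
  expect_equal(unname(oracle_leftmost_del(ref, 301, 600)),
               c(dels$start, dels$end))

  # no clipping needed: realignment reproduces the plain alignment events
  clean <- realign_softclip(ref, ref)
  expect_equal(nrow(extract_events(clean)$events), 0)

  # irrecoverable read
  expect_null(realign_softclip(rand_seq(60), ref))
})

test_that("a distal simple-join read realigns to the full inter-site deletion", {
  ej5 <- load_ej5_construct()
  dj <- distal_joined_reference()
  read <- dj$nested$sequence
  aln <- realign_softclip(read, ej5)
  ex <- extract_events(aln)
  dels <- ex$events[ex$events$kind == "del", ]
  expect_equal(nrow(dels), 1)
  expect_equal(dels$length, dj$deletion_length)
})

test_that("group_events groups by the canonical keys and conserves counts", {
  ev <- data.frame(
    read_id = sprintf("r%d", 1:8),
    kind = c(rep("del", 5), "ins", "ins", "ins"),
    start = c(rep(10, 5), 50, 50, 50),
    end = c(rep(14, 5), 50, 50, 50),
    length = c(rep(5, 5), 3, 4, 3),
    sequence = c(rep("AAAAA", 5), "CAT", "CATT", "CAT"))
  g <- group_events(ev)
  expect_equal(sum(g$n_reads), nrow(ev))
  expect_equal(g$n_reads[g$kind == "del"], 5)
  # same position, different insertion length -> distinct groups
  expect_equal(sum(g$kind == "ins"), 2)
  # order invariance
  g2 <- group_events(ev[sample(nrow(ev)), ])
  expect_identical(g, g2)
  expect_equal(nrow(group_events(ev[0, ])), 0)
})

test_that("equivalent indel placements map to one group key", {
  set.seed(41)
  for (i in 1:15) {
    ref <- paste0(rand_seq(20), strrep(rand_seq(3), 4), rand_seq(20))
    # delete one repeat unit at two equivalent placements
    s1 <- 21; e1 <- 23
    s2 <- 24; e2 <- 26
    r1 <- mutate_ref(ref, "del", s1, e1)
    r2 <- mutate_ref(ref, "del", s2, e2)
    expect_identical(r1, r2)
    ex1 <- extract_events(align_read(c(a = r1), ref)[[1]])$events
    ex2 <- extract_events(align_read(c(b = r2), ref)[[1]])$events
    ex1$read_id <- ex2$read_id <- "x"
    expect_identical(group_events(ex1)$key, group_events(ex2)$key)
  }
})

test_that("reads and FASTQ round-trip through the text formats", {
  tmp <- tempfile(fileext = ".fastq")
  reads <- c(a = "ACGTACGTAC", b = "TTGCA")
  write_reads_fastq(reads, tmp)
  back <- read_reads(tmp)
  expect_identical(back, reads)
})
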