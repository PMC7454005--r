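# Independent oracles used across the suite. These deliberately use brute
# force / exhaustive enumeration and never call the implementation paths
# they check.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc_oracle <- function(x) {
  m <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(m[strsplit(x, "")[[1]]]), collapse = "")
}

# microhomology oracle: number of distinct placements of an equal-length
# deletion producing the identical repaired sequence, minus one
oracle_mh <- function(ref, s, e) {
  L <- e - s + 1
  n <- nchar(ref)
  target <- paste0(substr(ref, 1, s - 1), substr(ref, e + 1, n))
  hits <- 0L
  for (s2 in seq_len(n - L + 1)) {
    alt <- paste0(substr(ref, 1, s2 - 1), substr(ref, s2 + L, n))
    if (alt == target) hits <- hits + 1L
  }
  hits - 1L
}

# leftmost equivalent placement of a deletion (placement enumeration)
oracle_leftmost_del <- function(ref, s, e) {
  L <- e - s + 1
  n <- nchar(ref)
  target <- paste0(substr(ref, 1, s - 1), substr(ref, e + 1, n))
  for (s2 in seq_len(n - L + 1)) {
    alt <- paste0(substr(ref, 1, s2 - 1), substr(ref, s2 + L, n))
    if (alt == target) return(c(s2, s2 + L - 1))
  }
  stop("unreachable")
}

# leftmost equivalent placement of an insertion: smallest junction j2 and
# its sequence giving the same mutated string
oracle_leftmost_ins <- function(ref, j, ins) {
  n <- nchar(ref)
  L <- nchar(ins)
  target <- paste0(substr(ref, 1, j), ins, substr(ref, j + 1, n))
  for (j2 in 0:n) {
    cand_ins <- substr(target, j2 + 1, j2 + L)
    cand <- paste0(substr(ref, 1, j2), cand_ins, substr(ref, j2 + 1, n))
    if (cand == target) return(list(pos = j2, seq = cand_ins))
  }
  stop("unreachable")
}

# exhaustive 192 -> 96 folding table for SBS classification: every triplet
# with a purine centre maps through the reverse complement
oracle_sbs_label <- function(triplet, alt) {
  centre <- substr(triplet, 2, 2)
  if (centre %in% c("A", "G")) {
    m <- c(A = "T", C = "G", G = "C", T = "A")
    triplet <- rc_oracle(triplet)
    alt <- unname(m[alt])
    centre <- substr(triplet, 2, 2)
  }
  paste0(substr(triplet, 1, 1), "[", centre, ">", alt, "]",
         substr(triplet, 3, 3))
}

# exact two-sided rank-sum p-value by enumerating all assignments of the
# pooled ranks to group A (tie-free data only)
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  sums <- colSums(matrix(r[combs], nrow = na))
  mu <- na * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu))
}

# naive O(n*m) motif scan on both strands
oracle_motif_scan <- function(seqc, motif) {
  n <- nchar(seqc)
  m <- nchar(motif)
  out <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") motif else rc_oracle(motif)
    for (i in seq_len(n - m + 1)) {
      if (substr(seqc, i, i + m - 1) == pat)
        out <- rbind(out, data.frame(start = i, end = i + m - 1,
                                     strand = strand))
    }
  }
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               strand = character(0))
  else out[order(out$start, out$strand), , drop = FALSE]
}

# Poisson tail by direct summation (no qpois): smallest c with
# P(X >= c) <= 1 - level
oracle_poisson_cutoff <- function(lambda, level) {
  c_ <- 1L
  repeat {
    tail <- 1 - sum(stats::dpois(0:(c_ - 1L), lambda))
    if (tail <= 1 - level) return(c_)
    c_ <- c_ + 1L
  }
}

# apply an event to a reference (string surgery, independent of the
# simulator's helper)
mutate_ref <- function(ref, kind, start, end = NULL, ins = NULL) {
  n <- nchar(ref)
  if (kind == "del") paste0(substr(ref, 1, start - 1), substr(ref, end + 1, n))
  else paste0(substr(ref, 1, start), ins, substr(ref, start + 1, n))
}

hprt_fixture <- function() load_hprt_amplicon()
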