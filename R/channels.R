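# SBS96 / ID83 channel catalogs and per-variant classification.
#
# The 96 substitution channels are the six pyrimidine-centred substitutions
# (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the four 5' and four 3'
# flanking bases. The 83 indel channels follow the PCAWG layout:
# 12 one-bp deletion + 12 one-bp insertion channels binned by homopolymer
# length, 24 + 24 longer indel channels binned by flanking repeat count,
# and 11 deletion-at-microhomology channels (deletion length 2..5+, MH
# length 1..5+ with MH strictly shorter than the deletion).

SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Enumerate the fixed mutation channel catalogs
#'
#' Returns the ordered channel labels of the SBS96 or ID83 catalog. The
#' ordering is stable: SBS channels are grouped by substitution
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base, then 3' base, each in
#' A,C,G,T order. ID channels are ordered 1 bp deletions (C then T,
#' homopolymer-length bins), 1 bp insertions, >=2 bp deletions at repeats
#' (length 2,3,4,5+; repeat-count bins), >=2 bp insertions at repeats, and
#' finally the 11 microhomology deletion channels.
#'
#' Labels follow the COSMIC conventions: `"A[C>T]G"` for substitutions and
#' `"<len>:Del|Ins:C|T|R|M:<bin>"` for indels. For 1 bp deletions bin `k`
#' means a reference homopolymer run of `k + 1` (capped at 6+); for 1 bp
#' insertions bin `k` means a run of `k` (capped at 5+); for repeat channels
#' bin `k` means `k` additional copies of the indel unit in the reference;
#' for MH channels the bin is the microhomology length.
#'
#' @param kind `"sbs"` or `"id"`.
#' @return character vector of 96 or 83 channel labels.
#' @examples
#' length(enumerate_channels("sbs"))
#' length(enumerate_channels("id"))
#' @export
enumerate_channels <- function(kind = c("sbs", "id")) {
  kind <- match.arg(kind)
  if (kind == "sbs") {
    out <- character(0)
    for (sub in SBS_SUBS) {
      r <- substr(sub, 1, 1)
      for (f in BASES) for (t in BASES) {
        out <- c(out, paste0(f, "[", sub, "]", t))
      }
    }
    return(out)
  }
  del1 <- paste0("1:Del:", rep(c("C", "T"), each = 6), ":", 0:5)
  ins1 <- paste0("1:Ins:", rep(c("C", "T"), each = 6), ":", 0:5)
  delr <- paste0(rep(2:5, each = 6), ":Del:R:", 0:5)
  insr <- paste0(rep(2:5, each = 6), ":Ins:R:", 0:5)
  mh <- c("2:Del:M:1",
          "3:Del:M:1", "3:Del:M:2",
          "4:Del:M:1", "4:Del:M:2", "4:Del:M:3",
          "5:Del:M:1", "5:Del:M:2", "5:Del:M:3", "5:Del:M:4", "5:Del:M:5")
  c(del1, ins1, delr, insr, mh)
}

#' Classify a single-base substitution into its SBS96 channel
#'
#' Purine-centred contexts are folded onto the pyrimidine strand through the
#' reverse complement, so every unambiguous SNV maps to exactly one of the
#' 96 channels.
#'
#' @param triplet 3-base reference context with the substituted base in the
#'   middle.
#' @param alt alternate base.
#' @return channel label such as `"A[C>T]A"`.
#' @examples
#' classify_sbs("ACA", "T")  # "A[C>T]A"
#' classify_sbs("AAA", "G")  # "T[T>C]T"
#' @export
classify_sbs <- function(triplet, alt) {
  triplet <- check_dna(triplet, "triplet")
  alt <- check_dna(alt, "alt")
  if (nchar(triplet) != 3L) stop("triplet must have exactly 3 bases")
  if (nchar(alt) != 1L) stop("alt must be a single base")
  ref <- substr(triplet, 2, 2)
  if (ref == alt) stop("alt equals the reference base")
  if (ref %in% c("A", "G")) {
    triplet <- revcomp(triplet)
    alt <- comp_base(alt)
    ref <- substr(triplet, 2, 2)
  }
  paste0(substr(triplet, 1, 1), "[", ref, ">", alt, "]", substr(triplet, 3, 3))
}

# longest run of `base` containing/adjacent to a position range
run_length_at <- function(chars, idx) {
  b <- chars[idx]
  l <- idx
  while (l > 1L && chars[l - 1L] == b) l <- l - 1L
  r <- idx
  while (r < length(chars) && chars[r + 1L] == b) r <- r + 1L
  r - l + 1L
}

# number of full adjacent copies of `unit` in `chars` flanking [s, e]
# (the unit itself occupies s..e for deletions; for insertions s..e is the
# would-be location and copies are counted on both sides of the junction)
count_adjacent_copies <- function(chars, unit, left_end, right_start) {
  k <- length(unit)
  n <- length(chars)
  copies <- 0L
  i <- right_start
  while (i + k - 1L <= n && all(chars[i:(i + k - 1L)] == unit)) {
    copies <- copies + 1L
    i <- i + k
  }
  i <- left_end
  while (i - k + 1L >= 1L && all(chars[(i - k + 1L):i] == unit)) {
    copies <- copies + 1L
    i <- i - k
  }
  copies
}

# strip common prefix/suffix of a VCF-style ref/alt pair; returns the pure
# indel sequence, its kind, and the 1-based position of the first affected
# base relative to `pos` (position of the first ref_allele base)
normalize_indel_alleles <- function(pos, ref_allele, alt_allele) {
  r <- seq_chars(ref_allele)
  a <- seq_chars(alt_allele)
  # trim common suffix first, then prefix (standard left-anchored trimming)
  while (length(r) > 0L && length(a) > 0L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  off <- 0L
  while (length(r) > 0L && length(a) > 0L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    off <- off + 1L
  }
  if (length(r) > 0L && length(a) > 0L)
    stop("not a pure indel after allele trimming")
  if (length(r) == 0L && length(a) == 0L)
    stop("ref and alt alleles are identical")
  if (length(r) > 0L) {
    list(kind = "del", seq = paste(r, collapse = ""), start = pos + off)
  } else {
    # insertion occurs after position pos + off - 1
    list(kind = "ins", seq = paste(a, collapse = ""), after = pos + off - 1L)
  }
}

#' Classify a small insertion or deletion into its ID83 channel
#'
#' The event is left-aligned inside `window` before binning. One-bp events
#' are binned by the reference homopolymer run length; longer events by the
#' number of additional adjacent copies of the indel unit; >=2 bp deletions
#' with no adjacent copy but flanking microhomology go to the MH channels.
#' Precedence is repeat > microhomology > plain, which is unambiguous after
#' left alignment.
#'
#' @param window reference sequence around the event (long enough to count
#'   six repeat units on each side).
#' @param pos 1-based position within `window` of the first base of
#'   `ref_allele`.
#' @param ref_allele,alt_allele VCF-style alleles (shared anchor bases are
#'   trimmed) or bare alleles with one side empty.
#' @return channel label, e.g. `"4:Del:M:3"`.
#' @examples
#' classify_indel("GGATCAATCGG", 3, "ATCAA", "A")   # "4:Del:M:3"
#' @export
classify_indel <- function(window, pos, ref_allele, alt_allele) {
  window <- check_dna(window, "window")
  if (nchar(ref_allele) > 0) ref_allele <- check_dna(ref_allele, "ref allele")
  if (nchar(alt_allele) > 0) alt_allele <- check_dna(alt_allele, "alt allele")
  chars <- seq_chars(window)
  n <- length(chars)
  ev <- normalize_indel_alleles(pos, ref_allele, alt_allele)
  size <- nchar(ev$seq)
  # bins cap at 5+/6+ so repeat counting is truncated by the window; all we
  # strictly need is at least one base of flank on each side
  if (n < size + 2L)
    stop("window too short to count repeat units")

  if (ev$kind == "del") {
    s <- ev$start
    e <- s + size - 1L
    if (s < 1L || e > n) stop("deletion outside window")
    if (paste(chars[s:e], collapse = "") != ev$seq)
      stop("ref allele does not match window")
    # left-align
    while (s > 1L && chars[s - 1L] == chars[e]) {
      s <- s - 1L
      e <- e - 1L
    }
    unit <- chars[s:e]
    if (size == 1L) {
      run <- run_length_at(chars, s)
      base <- if (unit %in% c("A", "G")) comp_base(unit) else unit
      return(paste0("1:Del:", base, ":", min(run, 6L) - 1L))
    }
    copies <- count_adjacent_copies(chars, unit, s - 1L, e + 1L)
    lenbin <- min(size, 5L)
    if (copies >= 1L) return(paste0(lenbin, ":Del:R:", min(copies, 5L)))
    mh <- deletion_microhomology(window, s, e)
    if (mh >= 1L) {
      mhbin <- min(mh, size - 1L, 5L)
      return(paste0(lenbin, ":Del:M:", mhbin))
    }
    return(paste0(lenbin, ":Del:R:0"))
  }

  # insertion after position `after`
  j <- ev$after
  if (j < 0L || j > n) stop("insertion outside window")
  s <- ev$seq
  # left-align: shift while last inserted base equals the base left of the
  # junction
  while (j >= 1L && substr(s, size, size) == chars[j]) {
    s <- paste0(chars[j], substr(s, 1L, size - 1L))
    j <- j - 1L
  }
  unit <- seq_chars(s)
  if (size == 1L) {
    # run of the inserted base around the junction in the reference
    b <- unit
    run <- 0L
    i <- j
    while (i >= 1L && chars[i] == b) {
      run <- run + 1L
      i <- i - 1L
    }
    i <- j + 1L
    while (i <= n && chars[i] == b) {
      run <- run + 1L
      i <- i + 1L
    }
    base <- if (b %in% c("A", "G")) comp_base(b) else b
    return(paste0("1:Ins:", base, ":", min(run, 5L)))
  }
  copies <- count_adjacent_copies(chars, unit, j, j + 1L)
  paste0(min(size, 5L), ":Ins:R:", min(copies, 5L))
}

#' Build a per-sample mutation catalog over the SBS96 + ID83 channels
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (and optionally `consequence`); one row per variant call.
#' @param reference named character vector or `Biostrings::DNAStringSet`
#'   of reference sequences keyed by `chrom`.
#' @param sample_id label stored in the catalog.
#' @param flank number of reference bases fetched on each side of an indel
#'   for repeat counting.
#' @return object of class `mutation_catalog`: list with `sample_id`,
#'   `sbs_counts` (named integer, length 96), `id_counts` (length 83) and
#'   `unclassified` (data.frame of skipped variants with reasons).
#' @export
build_catalog <- function(variants, reference, sample_id = "sample",
                          flank = 60L) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (methods::is(reference, "DNAStringSet")) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  sbs <- stats::setNames(integer(96), enumerate_channels("sbs"))
  id <- stats::setNames(integer(83), enumerate_channels("id"))
  bad <- list()
  note <- function(i, reason) {
    bad[[length(bad) + 1L]] <<- data.frame(row = i, reason = reason,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    chrom <- as.character(v$chrom)
    refseq <- if (chrom %in% names(reference)) reference[[chrom]] else NULL
    if (is.null(refseq) || is.na(refseq)) {
      note(i, "reference sequence not found")
      next
    }
    ra <- toupper(v$ref)
    aa <- toupper(v$alt)
    if (grepl("[^ACGT]", ra) || grepl("[^ACGT]", aa)) {
      note(i, "ambiguous base in alleles")
      next
    }
    pos <- as.integer(v$pos)
    if (pos < 1L || pos + nchar(ra) - 1L > nchar(refseq)) {
      note(i, "position outside reference")
      next
    }
    if (substr(refseq, pos, pos + nchar(ra) - 1L) != ra) {
      note(i, "ref allele does not match reference")
      next
    }
    res <- try({
      if (nchar(ra) == 1L && nchar(aa) == 1L) {
        if (pos == 1L || pos == nchar(refseq))
          stop("no trinucleotide context at sequence edge")
        sbs[classify_sbs(substr(refseq, pos - 1L, pos + 1L), aa)] <-
          sbs[classify_sbs(substr(refseq, pos - 1L, pos + 1L), aa)] + 1L
      } else {
        lo <- max(1L, pos - flank)
        hi <- min(nchar(refseq), pos + nchar(ra) - 1L + flank)
        lab <- classify_indel(substr(refseq, lo, hi), pos - lo + 1L, ra, aa)
        id[lab] <- id[lab] + 1L
      }
      NULL
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      note(i, conditionMessage(attr(res, "condition")))
    }
  }
  structure(list(sample_id = sample_id, sbs_counts = sbs, id_counts = id,
                 unclassified = if (length(bad)) do.call(rbind, bad)
                                else data.frame(row = integer(0),
                                                reason = character(0))),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat("mutation catalog for", x$sample_id, "\n")
  cat("  SBS variants:", sum(x$sbs_counts),
      " ID variants:", sum(x$id_counts),
      " unclassified:", nrow(x$unclassified), "\n")
  invisible(x)
}

#' Write a mutation catalog as TSV (channels as rows)
#' @param x `mutation_catalog`.
#' @param path output file.
#' @export
write_catalog_tsv <- function(x, path) {
  stopifnot(inherits(x, "mutation_catalog"))
  df <- data.frame(channel = c(names(x$sbs_counts), names(x$id_counts)),
                   kind = rep(c("sbs", "id"), c(96L, 83L)),
                   count = c(unname(x$sbs_counts), unname(x$id_counts)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
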