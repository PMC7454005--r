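# Amplicon read pipeline: pair merging, per-read alignment against the
# amplicon reference, single-large-gap realignment for reads a global
# alignment cannot place, event extraction with indel left-alignment, and
# grouping of identical events with supporting-read counts.

default_align_params <- function() {
  list(match = 2, mismatch = -4, gap_open = 6, gap_ext = 1,
       min_score_frac = 0.5, seed_len = 20L, seed_mismatch = 2L)
}

#' Merge a forward/reverse read pair by overlap
#'
#' The reverse read is reverse-complemented and the longest overlap with at
#' most `max_mismatch_rate` disagreements is used; disagreeing bases take
#' the higher-quality call (the forward base when qualities are absent or
#' tied).
#'
#' @param read1,read2 read sequences (read2 in reverse orientation, as
#'   sequenced).
#' @param qual1,qual2 optional numeric per-base qualities.
#' @param min_overlap smallest acceptable overlap (default 10).
#' @param max_mismatch_rate highest tolerated disagreement rate in the
#'   overlap (default 0.1).
#' @return list with `merged` (logical), `sequence` and `provenance`.
#' @export
merge_pairs <- function(read1, read2, qual1 = NULL, qual2 = NULL,
                        min_overlap = 10L, max_mismatch_rate = 0.1) {
  read1 <- check_dna(read1, "read1")
  read2 <- check_dna(read2, "read2")
  r2 <- revcomp(read2)
  n1 <- nchar(read1)
  n2 <- nchar(r2)
  c1 <- seq_chars(read1)
  c2 <- seq_chars(r2)
  if (min(n1, n2) < min_overlap)
    return(list(merged = FALSE, sequence = NA_character_,
                provenance = "unmerged"))
  for (ov in seq(min(n1, n2), min_overlap)) {
    a <- c1[(n1 - ov + 1L):n1]
    b <- c2[1L:ov]
    mis <- which(a != b)
    if (length(mis) / ov <= max_mismatch_rate) {
      cons <- a
      if (length(mis)) {
        q1 <- if (is.null(qual1)) rep(0, n1) else qual1
        q2 <- if (is.null(qual2)) rep(0, n2) else rev(qual2)
        take2 <- q2[mis] > q1[n1 - ov + mis]
        cons[mis[take2]] <- b[mis[take2]]
      }
      merged <- paste0(substr(read1, 1L, n1 - ov),
                       paste(cons, collapse = ""),
                       substr(r2, ov + 1L, n2))
      return(list(merged = TRUE, sequence = merged,
                  provenance = "merged-pair", overlap = ov))
    }
  }
  list(merged = FALSE, sequence = NA_character_, provenance = "unmerged")
}

# walk two equal-length gapped alignment strings and emit raw indel events
events_from_gapped <- function(pat, subj, ref_start = 1L) {
  pc <- seq_chars(pat)
  sc <- seq_chars(subj)
  stopifnot(length(pc) == length(sc))
  refpos <- ref_start - 1L
  events <- list()
  i <- 1L
  n <- length(pc)
  while (i <= n) {
    if (pc[i] == "-") {            # deletion in read: consumes reference
      j <- i
      while (j < n && pc[j + 1L] == "-") j <- j + 1L
      events[[length(events) + 1L]] <- list(kind = "del",
                                            start = refpos + 1L,
                                            end = refpos + (j - i + 1L),
                                            seq = paste(sc[i:j], collapse = ""))
      refpos <- refpos + (j - i + 1L)
      i <- j + 1L
    } else if (sc[i] == "-") {     # insertion in read at current ref pos
      j <- i
      while (j < n && sc[j + 1L] == "-") j <- j + 1L
      events[[length(events) + 1L]] <- list(kind = "ins",
                                            pos = refpos,
                                            seq = paste(pc[i:j], collapse = ""))
      i <- j + 1L
    } else {
      refpos <- refpos + 1L
      i <- i + 1L
    }
  }
  events
}

# canonicalize one event by shifting it as far left as the reference allows
left_align_event <- function(ref, ev) {
  chars <- seq_chars(ref)
  if (ev$kind == "del") {
    s <- ev$start
    e <- ev$end
    while (s > 1L && chars[s - 1L] == chars[e]) {
      s <- s - 1L
      e <- e - 1L
    }
    ev$start <- s
    ev$end <- e
    ev$seq <- substr(ref, s, e)
  } else {
    j <- ev$pos
    s <- ev$seq
    k <- nchar(s)
    while (j >= 1L && substr(s, k, k) == chars[j]) {
      s <- paste0(chars[j], substr(s, 1L, k - 1L))
      j <- j - 1L
    }
    ev$pos <- j
    ev$seq <- s
  }
  ev
}

events_to_df <- function(events, ref) {
  if (length(events) == 0L)
    return(data.frame(kind = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      sequence = character(0)))
  rows <- lapply(events, function(ev) {
    ev <- left_align_event(ref, ev)
    if (ev$kind == "del") {
      data.frame(kind = "del", start = ev$start, end = ev$end,
                 length = ev$end - ev$start + 1L, sequence = ev$seq)
    } else {
      data.frame(kind = "ins", start = ev$pos, end = ev$pos,
                 length = nchar(ev$seq), sequence = ev$seq)
    }
  })
  do.call(rbind, rows)
}

#' Globally align one or more reads against an amplicon reference
#'
#' End-to-end alignment with affine gap penalties (defaults: match +2,
#' mismatch -4, gap open -6, gap extend -1), backed by
#' `Biostrings::pairwiseAlignment`. Indels are left-aligned during event
#' extraction, so equivalent gap placements yield identical event keys.
#'
#' @param reads named character vector of read sequences (names become read
#'   ids) or a single unnamed sequence.
#' @param ref `amplicon_ref` or sequence.
#' @param params alignment parameters, see `default_align_params()`.
#' @return list of `junction_alignment` objects (one per read) with fields
#'   `read_id`, `read`, `ref_name`, `score`, `score_frac`, `pattern`,
#'   `subject` (gapped strings), `realigned`.
#' @export
align_read <- function(reads, ref, params = default_align_params()) {
  refseq <- as_sequence(ref)
  refname <- if (inherits(ref, "amplicon_ref")) ref$name else "ref"
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  pat <- Biostrings::DNAStringSet(unname(vapply(reads, check_dna, "",
                                                "read")))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                                  mismatch = params$mismatch)
  aln <- Biostrings::pairwiseAlignment(pat, Biostrings::DNAString(refseq),
                                       type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = params$gap_open,
                                       gapExtension = params$gap_ext)
  pats <- as.character(Biostrings::alignedPattern(aln))
  subjs <- as.character(Biostrings::alignedSubject(aln))
  scores <- Biostrings::score(aln)
  out <- vector("list", length(reads))
  for (k in seq_along(reads)) {
    out[[k]] <- structure(list(
      read_id = names(reads)[k], read = toupper(reads[[k]]),
      ref_name = refname, ref = refseq,
      score = scores[k],
      score_frac = scores[k] / (params$match * nchar(reads[[k]])),
      pattern = pats[k], subject = subjs[k],
      ref_start = 1L, realigned = FALSE), class = "junction_alignment")
  }
  names(out) <- names(reads)
  out
}

#' @export
print.junction_alignment <- function(x, ...) {
  cat("junction_alignment", x$read_id, "vs", x$ref_name,
      sprintf("(score %.1f, frac %.2f%s)\n", x$score, x$score_frac,
              if (x$realigned) ", realigned" else ""))
  invisible(x)
}

#' Realign a read admitting one large gap
#'
#' Anchors the read's prefix and suffix on the reference with short seeds
#' and chooses the split maximising matched bases, producing an end-to-end
#' alignment whose only gap is a single (possibly very large) deletion or
#' insertion. This recovers reads spanning kilobase-scale deletions (e.g. a
#' distal simple join read aligned against the intact construct) that a
#' global affine alignment scores too poorly to place. Reads without
#' clipping realign to their original single-block alignment (idempotent).
#'
#' @param read read sequence.
#' @param ref `amplicon_ref` or sequence.
#' @param params see `default_align_params()`.
#' @param read_id read identifier.
#' @return `junction_alignment` (with `realigned = TRUE`) or `NULL` when no
#'   anchor can be placed (irrecoverable read).
#' @export
realign_softclip <- function(read, ref, params = default_align_params(),
                             read_id = "read") {
  read <- check_dna(read, "read")
  refseq <- as_sequence(ref)
  refname <- if (inherits(ref, "amplicon_ref")) ref$name else "ref"
  n <- nchar(read)
  L <- nchar(refseq)
  k <- min(params$seed_len, n)
  subj <- Biostrings::DNAString(refseq)
  pref_hits <- Biostrings::matchPattern(
    Biostrings::DNAString(substr(read, 1L, k)), subj,
    max.mismatch = params$seed_mismatch)
  suf_hits <- Biostrings::matchPattern(
    Biostrings::DNAString(substr(read, n - k + 1L, n)), subj,
    max.mismatch = params$seed_mismatch)
  bs <- Biostrings::start(pref_hits)          # candidate ref pos of read[1]
  es <- Biostrings::end(suf_hits)             # candidate ref pos of read[n]
  if (length(bs) == 0L || length(es) == 0L) return(NULL)
  if (length(bs) > 8L) bs <- bs[1:8]
  if (length(es) > 8L) es <- es[1:8]
  rchars <- seq_chars(read)
  fchars <- seq_chars(refseq)
  best <- NULL
  for (b in bs) for (e in es) {
    if (e < b) next
    span <- e - b + 1L
    gap <- span - n                            # >0 deletion, <0 insertion
    # prefix diagonal: read[i] vs ref[b + i - 1]
    idx <- b + seq_len(n) - 1L
    eqp <- idx <= L & rchars == ifelse(idx <= L, fchars[pmin(idx, L)], "")
    prefc <- c(0L, cumsum(eqp))
    # suffix diagonal: read[i] vs ref[e - n + i]
    idx2 <- e - n + seq_len(n)
    eqs <- idx2 >= 1L & rchars == ifelse(idx2 >= 1L, fchars[pmax(idx2, 1L)], "")
    sufc <- rev(c(0L, cumsum(rev(eqs))))       # sufc[i] = matches in i..n
    if (gap >= 0L) {
      iseq <- 0:n
      sc <- prefc[iseq + 1L] + sufc[iseq + 1L]   # suffix part is i+1..n
    } else {
      li <- -gap
      iseq <- 0:(n - li)
      sc <- prefc[iseq + 1L] + sufc[iseq + li + 1L]
    }
    top <- max(sc)
    i <- iseq[which.max(sc)]                   # leftmost optimal split
    cand <- list(b = b, e = e, gap = gap, split = i, matches = top)
    if (is.null(best) || top > best$matches) best <- cand
  }
  if (is.null(best) || best$matches < 0.5 * n) return(NULL)
  # build gapped strings for event extraction
  b <- best$b; e <- best$e; gap <- best$gap; i <- best$split
  if (gap > 0L) {
    pat <- paste0(substr(read, 1L, i), strrep("-", gap),
                  substr(read, i + 1L, n))
    sub <- substr(refseq, b, e)
  } else if (gap < 0L) {
    li <- -gap
    pat <- read
    sub <- paste0(substr(refseq, b, b + i - 1L), strrep("-", li),
                  substr(refseq, b + i, e))
  } else {
    pat <- read
    sub <- substr(refseq, b, e)
  }
  structure(list(read_id = read_id, read = read, ref_name = refname,
                 ref = refseq,
                 score = best$matches, score_frac = best$matches / n,
                 pattern = pat, subject = sub, ref_start = b,
                 realigned = TRUE),
            class = "junction_alignment")
}

#' Extract repair events and the read class from an alignment
#'
#' Emits one record per indel operation (a read with two deletions and two
#' insertions yields four records) and classifies the read as `precise`
#' (reference-identical up to substitutions), `deletion_only`,
#' `insertion_only`, `deletion_and_insertion`, or `soft_clipped` for reads
#' that required large-gap realignment.
#'
#' @param aln `junction_alignment`.
#' @return list with `class` and `events` (data.frame: kind, start, end,
#'   length, sequence; deletions use 1-based inclusive reference bounds,
#'   insertions the reference position immediately left of the junction).
#' @export
extract_events <- function(aln) {
  stopifnot(inherits(aln, "junction_alignment"))
  raw <- events_from_gapped(aln$pattern, aln$subject, aln$ref_start)
  events <- events_to_df(raw, aln$ref)
  cls <- if (aln$realigned) {
    "soft_clipped"
  } else if (nrow(events) == 0L) {
    "precise"
  } else if (all(events$kind == "del")) {
    "deletion_only"
  } else if (all(events$kind == "ins")) {
    "insertion_only"
  } else {
    "deletion_and_insertion"
  }
  list(class = cls, events = events)
}

#' Group identical events across reads
#'
#' Deletions group by (start, end); insertions by (position, length,
#' sequence). Counts over groups sum to the number of input event records.
#'
#' @param events data.frame with columns `read_id`, `kind`, `start`, `end`,
#'   `length`, `sequence`.
#' @return data.frame with one row per event group and `n_reads` support.
#' @export
group_events <- function(events) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) {
    return(data.frame(key = character(0), kind = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), sequence = character(0),
                      n_reads = integer(0)))
  }
  key <- ifelse(events$kind == "del",
                paste("del", events$start, events$end, sep = ":"),
                paste("ins", events$start, events$length, events$sequence,
                      sep = ":"))
  idx <- !duplicated(key)
  out <- events[idx, c("kind", "start", "end", "length", "sequence")]
  out$key <- key[idx]
  tab <- table(key)
  out$n_reads <- as.integer(tab[out$key])
  out <- out[order(-out$n_reads, out$key),
             c("key", "kind", "start", "end", "length", "sequence", "n_reads")]
  rownames(out) <- NULL
  out
}

#' Run the read pipeline: align, realign if needed, extract and group
#'
#' @param reads named character vector of (merged) read sequences.
#' @param ref `amplicon_ref`.
#' @param params see `default_align_params()`.
#' @return list with `per_read` (read_id, class, n_events, score_frac),
#'   `events` (one row per event record with read_id) and `groups`
#'   (see [group_events()]).
#' @export
call_junctions <- function(reads, ref, params = default_align_params()) {
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  # amplicon reads are heavily duplicated: align each distinct sequence once
  useq <- unique(unname(reads))
  idx <- match(reads, useq)
  alns <- align_read(stats::setNames(useq, paste0("u", seq_along(useq))),
                     ref, params)
  uinfo <- vector("list", length(useq))
  for (k in seq_along(alns)) {
    a <- alns[[k]]
    if (a$score_frac < params$min_score_frac) {
      ra <- realign_softclip(a$read, ref, params, read_id = a$read_id)
      if (!is.null(ra)) a <- ra
    }
    ex <- extract_events(a)
    cls <- if (a$score_frac < params$min_score_frac && !a$realigned)
      "unaligned" else ex$class
    uinfo[[k]] <- list(class = cls, events = ex$events,
                       score_frac = a$score_frac)
  }
  per_read <- data.frame(
    read_id = names(reads),
    class = vapply(uinfo, `[[`, "", "class")[idx],
    n_events = vapply(uinfo, function(u) nrow(u$events), 0L)[idx],
    score_frac = vapply(uinfo, `[[`, 0, "score_frac")[idx])
  ev_list <- lapply(seq_along(reads), function(k) {
    u <- uinfo[[idx[k]]]
    if (nrow(u$events) == 0L || u$class == "unaligned") return(NULL)
    cbind(u$events, read_id = names(reads)[k])
  })
  events <- do.call(rbind, ev_list)
  if (is.null(events))
    events <- data.frame(kind = character(0), start = integer(0),
                         end = integer(0), length = integer(0),
                         sequence = character(0), read_id = character(0))
  list(per_read = per_read, events = events, groups = group_events(events))
}

#' Read amplicon reads from FASTQ or FASTA
#' @param path file path (plain text).
#' @return named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq"
         else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write reads as FASTQ with constant quality
#' @param reads named character vector.
#' @param path output path.
#' @export
write_reads_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(unname(reads))
  names(ss) <- names(reads)
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                vapply(reads, function(r)
                                  strrep("I", nchar(r)), "")))
  invisible(path)
}
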