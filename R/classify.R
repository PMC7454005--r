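# Junction analytics: microhomology at deletion junctions, TMEJ calls,
# Poisson background cutoffs and templated-insertion origin classification.

#' Microhomology length at a deletion junction
#'
#' The microhomology (MH) of a deletion is the amount of identical sequence
#' shared by the two junction flanks, measured as the number of alternative
#' placements of an equal-length deletion that yield the same repaired
#' sequence, minus one. It equals the left-extension plus right-extension
#' of flanking identity: bases of the deleted prefix matching the right
#' flank plus bases of the left flank matching the deleted suffix.
#'
#' @param ref reference sequence.
#' @param del_start,del_end 1-based inclusive bounds of the deleted bases.
#' @return non-negative integer MH length.
#' @examples
#' deletion_microhomology("GGATCAATCGG", 4, 7)  # 3
#' @export
deletion_microhomology <- function(ref, del_start, del_end) {
  ref <- check_dna(ref)
  n <- nchar(ref)
  del_start <- as.integer(del_start)
  del_end <- as.integer(del_end)
  if (del_start < 1L || del_end > n || del_start > del_end)
    stop("deletion coordinates out of range")
  chars <- seq_chars(ref)
  r <- 0L
  while (del_end + 1L + r <= n && chars[del_start + r] == chars[del_end + 1L + r])
    r <- r + 1L
  l <- 0L
  while (del_start - 1L - l >= 1L && chars[del_start - 1L - l] == chars[del_end - l])
    l <- l + 1L
  l + r
}

#' TMEJ (polymerase theta) scar call for a deletion
#'
#' Deletions whose junction MH falls inside the window (default 3-6 bp) are
#' flagged as TMEJ scars; NHEJ junctions typically carry 0-2 bp.
#'
#' @param mh_length MH length in bp.
#' @param window inclusive `c(min, max)` MH window.
#' @return logical.
#' @export
call_tmej <- function(mh_length, window = c(3L, 6L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  mh_length >= window[1] & mh_length <= window[2]
}

#' Estimate the expected background read count per spurious event
#'
#' The default strategy takes the mean supporting-read count over event
#' groups at or below the median count, which is robust to a handful of
#' true high-count events dominating the table.
#'
#' @param counts supporting-read counts per event group.
#' @param strategy `"median_trim"` (default) or `"mean"`.
#' @return lambda estimate.
#' @export
estimate_background <- function(counts, strategy = c("median_trim", "mean")) {
  strategy <- match.arg(strategy)
  counts <- as.numeric(counts)
  if (length(counts) == 0L || anyNA(counts)) stop("no event groups")
  if (strategy == "mean") return(mean(counts))
  mean(counts[counts <= stats::median(counts)])
}

#' Poisson read-count cutoff for background filtering
#'
#' Returns the smallest supporting-read count `c` such that
#' `P(X >= c) <= 1 - level` for `X ~ Poisson(lambda)`. Event groups with
#' fewer supporting reads are considered PCR/sequencing background.
#'
#' @param lambda expected background reads per spurious event.
#' @param level confidence level, conventionally 0.90, 0.95 or 0.99.
#' @return integer cutoff (>= 1).
#' @examples
#' poisson_cutoff(1, 0.99)  # 5
#' poisson_cutoff(3, 0.95)  # 7
#' @export
poisson_cutoff <- function(lambda, level = 0.95) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("lambda must be a single non-negative number")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  max(1L, as.integer(stats::qpois(level, lambda)) + 1L)
}

# candidate origins of an insertion: exact full-length matches of the
# inserted sequence over both strands of each search reference
origin_candidates <- function(ins_seq, junction, refs, primary,
                              nearby_window) {
  pat <- Biostrings::DNAString(ins_seq)
  len <- nchar(ins_seq)
  out <- list()
  for (nm in names(refs)) {
    subj <- Biostrings::DNAString(refs[[nm]])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::matchPattern(p, subj)
      if (length(m) == 0L) next
      st <- Biostrings::start(m)
      en <- Biostrings::end(m)
      for (k in seq_along(st)) {
        if (nm == primary) {
          dist <- if (en[k] <= junction) junction - en[k]
                  else if (st[k] >= junction + 1L) st[k] - (junction + 1L)
                  else 0L
        } else {
          dist <- Inf
        }
        cls <- if (strand == "-") {
          "snapback"
        } else if (nm == primary && dist == 0L &&
                   (identical(c(st[k], en[k]), c(junction - len + 1L, junction)) ||
                    identical(c(st[k], en[k]), c(junction + 1L, junction + len)))) {
          "direct_repeat"
        } else if (is.finite(dist) && dist < nearby_window) {
          "nearby"
        } else {
          "distant"
        }
        out[[length(out) + 1L]] <- data.frame(
          ref = nm, strand = strand, start = st[k], end = en[k],
          dist = as.numeric(dist), class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(ref = character(0), strand = character(0),
                  start = integer(0), end = integer(0), dist = numeric(0),
                  class = character(0))
}

#' Classify the origin of a templated insertion (5-15 bp)
#'
#' Searches both strands of the supplied reference(s) for exact full-length
#' copies of the inserted sequence and assigns one of five origin classes:
#' `direct_repeat` (duplication of the sequence immediately flanking the
#' junction), `snapback` (reverse-complement copy, i.e. foldback priming in
#' cis), `nearby` (sense copy closer than `nearby_window` to the junction),
#' `distant` (sense copy further away or on another reference) or `random`
#' (no copy found). Insertions matching more than one class-inequivalent
#' origin are excluded as ambiguous by default (`ambiguity = "exclude"`);
#' `ambiguity = "precedence"` instead resolves them in the order
#' direct_repeat > snapback > nearby > distant.
#'
#' @param ins_seq inserted sequence.
#' @param junction 1-based reference position immediately left of the
#'   insertion point on the primary reference.
#' @param refs named character vector/list of search references; the first
#'   (or `primary`) is the amplicon the junction position refers to.
#' @param nearby_window bp separating `nearby` from `distant` (default 100).
#' @param length_bounds inclusive insertion-length bounds for the five-way
#'   scheme (default 5-15 bp).
#' @param ambiguity `"exclude"` or `"precedence"`.
#' @param primary name of the primary reference.
#' @return list with `class` (one of the five classes or `"excluded"`),
#'   `origin` (data.frame row describing the chosen copy, or NULL) and
#'   `candidates` (all copies found).
#' @export
classify_insertion_origin <- function(ins_seq, junction, refs,
                                      nearby_window = 100L,
                                      length_bounds = c(5L, 15L),
                                      ambiguity = c("exclude", "precedence"),
                                      primary = names(refs)[1]) {
  ambiguity <- match.arg(ambiguity)
  ins_seq <- check_dna(ins_seq, "insertion")
  if (is.character(refs) && is.null(names(refs)))
    stop("refs must be named")
  refs <- as.list(refs)
  len <- nchar(ins_seq)
  if (len < length_bounds[1] || len > length_bounds[2])
    stop("insertion length outside the five-way classification bounds; ",
         "use classify_short_insertion for short events")
  cand <- origin_candidates(ins_seq, junction, refs, primary, nearby_window)
  if (nrow(cand) == 0L)
    return(list(class = "random", origin = NULL, candidates = cand))
  classes <- unique(cand$class)
  prec <- c("direct_repeat", "snapback", "nearby", "distant")
  if (length(classes) > 1L && ambiguity == "exclude")
    return(list(class = "excluded", origin = NULL, candidates = cand))
  cls <- prec[min(match(classes, prec))]
  sel <- cand[cand$class == cls, , drop = FALSE]
  sel <- sel[order(sel$dist, sel$start), , drop = FALSE]
  list(class = cls, origin = sel[1L, ], candidates = cand)
}

#' Three-class scheme for short insertions (< 5 bp)
#'
#' Short insertions lack the specificity for full origin calling; the
#' flanking windows around the junction are searched for a sense copy
#' (`template`), a reverse-complement copy (`snapback`) or neither
#' (`undetermined`). Single-base insertions are always `undetermined`.
#'
#' @param ins_seq inserted sequence (shorter than the five-way minimum).
#' @param junction reference position immediately left of the insertion.
#' @param ref primary reference sequence.
#' @param window flanking window searched on each side (default 100 bp).
#' @return `"template"`, `"snapback"` or `"undetermined"`.
#' @export
classify_short_insertion <- function(ins_seq, junction, ref, window = 100L) {
  ins_seq <- check_dna(ins_seq, "insertion")
  ref <- check_dna(ref)
  len <- nchar(ins_seq)
  if (len < 2L) return("undetermined")
  lo <- max(1L, junction - window + 1L)
  hi <- min(nchar(ref), junction + window)
  flank <- substr(ref, lo, hi)
  if (grepl(ins_seq, flank, fixed = TRUE)) return("template")
  if (grepl(revcomp(ins_seq), flank, fixed = TRUE)) return("snapback")
  "undetermined"
}

#' Microhomology flags for a templated insertion
#'
#' `mh_init` is the longest stretch (within `min_mh`..`max_mh`) by which the
#' broken-end sequence (left flank of the junction) matches the bases
#' immediately 5' of the origin copy in its template orientation - the MH a
#' polymerase would use to prime synthesis at the origin. `mh_end` is the
#' longest suffix of the inserted sequence matching the bases immediately
#' right of the junction - the MH available to anneal the extended end for
#' joining. Values below `min_mh` report 0.
#'
#' @param ins_seq inserted sequence.
#' @param junction reference position immediately left of the insertion.
#' @param origin data.frame row as returned by
#'   [classify_insertion_origin()] (fields `ref`, `strand`, `start`, `end`).
#' @param refs named list of reference sequences.
#' @param min_mh,max_mh reported MH bounds (defaults 2 and 6 bp).
#' @return integer vector `c(mh_init, mh_end)`.
#' @export
insertion_mh_flags <- function(ins_seq, junction, origin, refs,
                               min_mh = 2L, max_mh = 6L) {
  if (is.null(origin)) stop("origin must be resolved (not random/excluded)")
  refs <- as.list(refs)
  oref <- refs[[origin$ref]]
  primary <- refs[[1L]]
  ins_seq <- check_dna(ins_seq, "insertion")
  left_flank <- substr(primary, max(1L, junction - max_mh + 1L), junction)

  template_5p <- function(b) {
    if (origin$strand == "+") {
      s <- origin$start - b
      if (s < 1L) return(NULL)
      substr(oref, s, origin$start - 1L)
    } else {
      e <- origin$end + b
      if (e > nchar(oref)) return(NULL)
      revcomp(substr(oref, origin$end + 1L, e))
    }
  }
  descending <- function(hi) if (hi >= min_mh) seq(hi, min_mh) else integer(0)
  mh_init <- 0L
  for (b in descending(min(max_mh, nchar(left_flank)))) {
    t5 <- template_5p(b)
    if (!is.null(t5) &&
        substr(left_flank, nchar(left_flank) - b + 1L, nchar(left_flank)) == t5) {
      mh_init <- b
      break
    }
  }
  mh_end <- 0L
  for (b in descending(min(max_mh, nchar(ins_seq)))) {
    if (junction + b > nchar(primary)) next
    if (substr(ins_seq, nchar(ins_seq) - b + 1L, nchar(ins_seq)) ==
        substr(primary, junction + 1L, junction + b)) {
      mh_end <- b
      break
    }
  }
  c(mh_init = mh_init, mh_end = mh_end)
}
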