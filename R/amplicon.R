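# Assay construct modelling: annotated amplicon references, motif search,
# in-silico PCR, I-SceI cleavage and distal simple joining. All coordinates
# are 1-based inclusive, matching how reporter-construct positions are
# conventionally printed.

ISCEI_MOTIF <- "TAGGGATAACAGGGTAAT"
# top-strand cut after motif position 9, bottom-strand cut after motif
# position 5: staggered cleavage leaving 4-nt 3' overhangs (motif bases 6-9)
ISCEI_TOP_CUT <- 9L
ISCEI_BOTTOM_CUT <- 5L

#' Construct an annotated amplicon reference
#'
#' @param name reference name.
#' @param sequence DNA sequence.
#' @param features optional data.frame with columns `label`, `start`, `end`
#'   (1-based inclusive) and optionally `strand`; feature bounds are
#'   validated against the sequence.
#' @return object of class `amplicon_ref`.
#' @export
amplicon_ref <- function(name, sequence, features = NULL) {
  sequence <- check_dna(sequence)
  if (is.null(features)) {
    features <- data.frame(label = character(0), start = integer(0),
                           end = integer(0), strand = character(0))
  }
  if (is.null(features$strand)) features$strand <- rep("+", nrow(features))
  stopifnot(all(c("label", "start", "end") %in% names(features)))
  bad <- features$start < 1L | features$end > nchar(sequence) |
    features$start > features$end
  if (any(bad)) stop("feature coordinates outside the reference")
  structure(list(name = name, sequence = sequence, features = features),
            class = "amplicon_ref")
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat("amplicon_ref", x$name, "-", nchar(x$sequence), "bp,",
      nrow(x$features), "features\n")
  invisible(x)
}

as_sequence <- function(x) {
  if (inherits(x, "amplicon_ref")) x$sequence else check_dna(x)
}

#' Find all exact occurrences of a motif on both strands
#'
#' @param sequence reference sequence or `amplicon_ref`.
#' @param motif unambiguous DNA motif.
#' @return data.frame with `start`, `end` (1-based, top-strand coordinates)
#'   and `strand`, sorted by start.
#' @export
find_motif <- function(sequence, motif) {
  seqc <- as_sequence(sequence)
  motif <- check_dna(motif, "motif")
  subj <- Biostrings::DNAString(seqc)
  hits <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") motif else revcomp(motif)
    m <- Biostrings::matchPattern(Biostrings::DNAString(p), subj)
    if (length(m)) {
      hits[[strand]] <- data.frame(start = Biostrings::start(m),
                                   end = Biostrings::end(m),
                                   strand = strand)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits)
         else data.frame(start = integer(0), end = integer(0),
                         strand = character(0))
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' In-silico PCR
#'
#' Requires each primer to match the template exactly once in productive
#' orientation (forward primer on the top strand 5' of the reverse primer's
#' reverse-complement match). The product spans the forward primer's 5' end
#' through the reverse primer's 5' end inclusive.
#'
#' @param template template sequence or `amplicon_ref`.
#' @param fwd_primer,rev_primer primer sequences (reverse primer given 5'->3'
#'   on the bottom strand, as synthesised).
#' @return product sequence with attributes `start` and `end` (template
#'   coordinates).
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer) {
  seqc <- as_sequence(template)
  fwd <- check_dna(fwd_primer, "forward primer")
  rev <- check_dna(rev_primer, "reverse primer")
  fhits <- find_motif(seqc, fwd)
  fhits <- fhits[fhits$strand == "+", , drop = FALSE]
  rhits <- find_motif(seqc, revcomp(rev))
  rhits <- rhits[rhits$strand == "+", , drop = FALSE]
  if (nrow(fhits) != 1L)
    stop("forward primer matches template ", nrow(fhits), " times (need 1)")
  if (nrow(rhits) != 1L)
    stop("reverse primer matches template ", nrow(rhits), " times (need 1)")
  if (fhits$start >= rhits$start)
    stop("primers are in inverted orientation on this template")
  prod <- substr(seqc, fhits$start, rhits$end)
  attr(prod, "start") <- fhits$start
  attr(prod, "end") <- rhits$end
  prod
}

#' Junction coordinate in "left:right" notation
#'
#' A junction between adjacent reference positions n and n+1 is printed as
#' `"(n+1):n"` (higher position first), the convention used for reporter
#' cut-site positions such as `"262:261"`.
#'
#' @param left,right adjacent reference positions.
#' @return object of class `junction_coord`.
#' @export
junction_coord <- function(left, right) {
  left <- as.integer(left)
  right <- as.integer(right)
  if (abs(left - right) != 1L) stop("junction positions must be adjacent")
  structure(list(left = left, right = right), class = "junction_coord")
}

#' @method format junction_coord
#' @export
format.junction_coord <- function(x, ...) paste0(x$left, ":", x$right)

#' @export
print.junction_coord <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a "left:right" junction string
#' @param s string such as `"262:261"`.
#' @return `junction_coord`.
#' @export
parse_junction <- function(s) {
  parts <- suppressWarnings(as.integer(strsplit(s, ":", fixed = TRUE)[[1L]]))
  if (length(parts) != 2L || anyNA(parts)) stop("malformed junction string")
  junction_coord(parts[1L], parts[2L])
}

#' Cleave a sequence at an I-SceI recognition site
#'
#' The 18-bp site is cut after motif position 9 on the top strand and after
#' position 5 on the bottom strand, leaving both fragments with 4-nt 3'
#' overhangs (motif bases 6-9, `ATAA`). Re-ligating the two ends of a single
#' cut reconstructs the input exactly.
#'
#' @param sequence sequence or `amplicon_ref` containing the site.
#' @param site_start 1-based start of the 18-bp recognition motif on the
#'   top strand.
#' @return object of class `cut_ends`: upstream/downstream fragment
#'   descriptions with their overhangs and the cut junction.
#' @export
isce1_cut <- function(sequence, site_start) {
  seqc <- as_sequence(sequence)
  site_start <- as.integer(site_start)
  if (site_start < 1L || site_start + nchar(ISCEI_MOTIF) - 1L > nchar(seqc))
    stop("site outside the sequence")
  if (substr(seqc, site_start, site_start + nchar(ISCEI_MOTIF) - 1L) !=
      ISCEI_MOTIF)
    stop("I-SceI motif not present at site_start")
  top_cut <- site_start + ISCEI_TOP_CUT - 1L      # last top base upstream
  bottom_cut <- site_start + ISCEI_BOTTOM_CUT - 1L # last paired base upstream
  overhang <- substr(seqc, bottom_cut + 1L, top_cut)
  structure(list(
    sequence = seqc,
    site_start = site_start,
    upstream = list(top_end = top_cut, duplex_end = bottom_cut,
                    overhang = overhang),
    downstream = list(top_start = top_cut + 1L, duplex_start = top_cut + 1L,
                      overhang_start = bottom_cut + 1L,
                      overhang = revcomp(overhang)),
    junction = junction_coord(top_cut + 1L, top_cut)
  ), class = "cut_ends")
}

#' @export
print.cut_ends <- function(x, ...) {
  cat("I-SceI cut at site", x$site_start, "- junction", format(x$junction),
      "overhang", x$upstream$overhang, "\n")
  invisible(x)
}

#' Religate the two ends of a single cut
#' @param cut `cut_ends`.
#' @return the reconstructed sequence.
#' @export
religate <- function(cut) {
  stopifnot(inherits(cut, "cut_ends"))
  paste0(substr(cut$sequence, 1L, cut$upstream$top_end),
         substr(cut$sequence, cut$downstream$top_start, nchar(cut$sequence)))
}

#' Join the upstream end of one cut to the downstream end of another
#'
#' Models distal end joining of two breaks on the same molecule: the
#' upstream fragment of cut A anneals to the downstream fragment of cut B
#' through their complementary 4-nt 3' overhangs, deleting the intervening
#' segment. The overhang sequence is retained once, so for two identical
#' same-orientation sites the deletion length equals the distance between
#' the two site starts and the joined product restores an intact
#' recognition site.
#'
#' @param cut_a `cut_ends` for the upstream (kept-left) break.
#' @param cut_b `cut_ends` for the downstream (kept-right) break on the same
#'   sequence.
#' @return list with `sequence` (joined product), `deletion_length` versus
#'   the intact reference, and `junction` (`junction_coord` in joined-product
#'   coordinates).
#' @export
simple_join <- function(cut_a, cut_b) {
  stopifnot(inherits(cut_a, "cut_ends"), inherits(cut_b, "cut_ends"))
  if (cut_a$sequence != cut_b$sequence)
    stop("cuts must come from the same reference sequence")
  if (cut_b$upstream$top_end < cut_a$upstream$top_end)
    stop("cut_b must lie downstream of cut_a")
  # the upstream 3' overhang must be complementary to the downstream
  # fragment's 3' overhang (identical top-strand sequence at both sites)
  up_oh <- cut_a$upstream$overhang
  down_oh_top <- substr(cut_b$sequence, cut_b$downstream$overhang_start,
                        cut_b$downstream$duplex_start - 1L)
  if (up_oh != down_oh_top)
    stop("incompatible overhangs: ", up_oh, " vs ", down_oh_top)
  seqc <- cut_a$sequence
  joined <- paste0(substr(seqc, 1L, cut_a$upstream$top_end),
                   substr(seqc, cut_b$downstream$top_start, nchar(seqc)))
  list(sequence = joined,
       deletion_length = nchar(seqc) - nchar(joined),
       junction = junction_coord(cut_a$upstream$top_end + 1L,
                                 cut_a$upstream$top_end))
}

read_fasta_ref <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Bundled synthetic reporter construct (EJ5-like)
#'
#' A 9406-bp synthetic stand-in for the chromosomally integrated distal
#' end-joining reporter: two same-orientation I-SceI sites at positions
#' 1758-1775 and 3530-3547, with the outer and nested junction PCR primer
#' sites placed so that the distal-joined product yields 597-bp and 429-bp
#' amplicons. The sequence is randomly generated (not the real reporter)
#' and is labelled synthetic.
#'
#' @return `amplicon_ref`.
#' @export
load_ej5_construct <- function() {
  path <- system.file("extdata", "ej5_synthetic.fa", package = "polqscars")
  seqs <- read_fasta_ref(path)
  sites <- find_motif(seqs[[1L]], ISCEI_MOTIF)
  amplicon_ref("ej5_synthetic", seqs[[1L]],
               data.frame(label = c("isce1_site_1", "isce1_site_2"),
                          start = sites$start, end = sites$end,
                          strand = sites$strand))
}

#' Bundled synthetic wild-type locus amplicon (HPRT-like)
#'
#' A 546-bp synthetic stand-in for the wild-type target-locus PCR product
#' used by the proximal end-joining assay, carrying the published primer
#' sequences at its ends and a CRISPR protospacer + NGG PAM with the blunt
#' cut site annotated as a feature.
#'
#' @return `amplicon_ref`.
#' @export
load_hprt_amplicon <- function() {
  path <- system.file("extdata", "hprt_synthetic.fa", package = "polqscars")
  seqs <- read_fasta_ref(path)
  amplicon_ref("hprt_synthetic", seqs[[1L]],
               data.frame(label = "cas9_cut", start = 266L, end = 267L,
                          strand = "+"))
}

#' Primers of the bundled assays
#'
#' Published primer sequences used with the bundled synthetic references:
#' the wild-type locus pair, the outer distal-junction pair and the nested
#' distal-junction pair.
#' @return named list of primer pairs.
#' @export
assay_primers <- function() {
  list(
    hprt = c(fwd = "TCTTACTGCTTGCTGAGGGC", rev = "TAATTTTGCAAGGGGGCCCA"),
    distal_outer = c(fwd = "GTCCCAAATCTGGCGGAG", rev = "GTAGCGGCTGAAGCACTG"),
    distal_nested = c(fwd = "AGGAAGGAAATGGGCGGGGA", rev = "AACTTCAGGGTCAGCTTGCC")
  )
}

#' Distal-joined reference amplicons
#'
#' Cuts both I-SceI sites of the synthetic reporter, joins the outer ends
#' (simple join) and amplifies the junction with the outer and nested primer
#' pairs.
#'
#' @return list with `joined` (full joined construct `amplicon_ref`),
#'   `deletion_length`, `outer` and `nested` amplicon `amplicon_ref`s, and
#'   the nested-amplicon cut-site junction (`junction_coord`).
#' @export
distal_joined_reference <- function() {
  ej5 <- load_ej5_construct()
  sites <- find_motif(ej5, ISCEI_MOTIF)
  cut1 <- isce1_cut(ej5, sites$start[1L])
  cut2 <- isce1_cut(ej5, sites$start[2L])
  jn <- simple_join(cut1, cut2)
  pr <- assay_primers()
  outer <- in_silico_pcr(jn$sequence, pr$distal_outer["fwd"],
                         pr$distal_outer["rev"])
  nested <- in_silico_pcr(jn$sequence, pr$distal_nested["fwd"],
                          pr$distal_nested["rev"])
  site_in_nested <- find_motif(as.character(nested), ISCEI_MOTIF)
  cutpos <- site_in_nested$start[1L] + ISCEI_TOP_CUT - 1L
  list(joined = amplicon_ref("ej5_distal_joined", jn$sequence),
       deletion_length = jn$deletion_length,
       junction = jn$junction,
       outer = amplicon_ref("distal_outer_amplicon", as.character(outer)),
       nested = amplicon_ref("distal_nested_amplicon", as.character(nested)),
       nested_cut = junction_coord(cutpos + 1L, cutpos))
}
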