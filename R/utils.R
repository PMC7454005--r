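# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars; Biostrings objects are used only at the
# boundaries (file IO, pattern matching, pairwise alignment).

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character scalar of unambiguous DNA (A/C/G/T).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Complement of single bases
#' @param x character vector of single bases.
#' @return complemented bases.
#' @export
comp_base <- function(x) {
  m <- c(A = "T", C = "G", G = "C", T = "A")
  out <- m[toupper(x)]
  if (anyNA(out)) stop("non-ACGT base in input")
  unname(out)
}

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty character scalar")
  if (grepl("[^ACGT]", toupper(x)))
    stop(what, " contains ambiguous (non-ACGT) bases")
  toupper(x)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# substring that errors instead of silently truncating
substr_strict <- function(x, start, end) {
  if (start < 1L || end > nchar(x) || start > end + 1L)
    stop("substring out of range")
  if (start > end) return("")
  substr(x, start, end)
}

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# round half away from zero (commercial rounding), used for cell counts
round_half_up <- function(x) floor(x + 0.5)
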