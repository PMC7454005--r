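# Assay-level analysis: annotate event groups with MH / TMEJ / insertion
# origin calls, apply the Poisson background filter, and build the
# frequency tables a scar analysis reports per sample.

#' Annotate event groups with junction analytics
#'
#' Deletion groups receive the junction MH length and a TMEJ flag;
#' insertion groups a short-insertion class (below the five-way minimum) or
#' an origin class with origin coordinates and MH-initiation/termination
#' flags.
#'
#' @param groups data.frame from [group_events()].
#' @param ref primary `amplicon_ref` (the alignment reference).
#' @param search_refs optional additional named references searched for
#'   insertion templates (e.g. the full construct, or a genome FASTA loaded
#'   by the caller).
#' @param tmej_window MH window flagged as TMEJ scars (default 3-6 bp).
#' @param nearby_window nearby/distant boundary (default 100 bp).
#' @param length_bounds five-way origin-calling length bounds (default
#'   5-15 bp).
#' @param min_mh,max_mh MH-flag bounds (defaults 2 and 6 bp).
#' @param ambiguity see [classify_insertion_origin()].
#' @return `groups` with columns `mh`, `tmej`, `origin_class`,
#'   `origin_start`, `origin_end`, `origin_strand`, `mh_init`, `mh_end`
#'   appended.
#' @export
annotate_groups <- function(groups, ref, search_refs = NULL,
                            tmej_window = c(3L, 6L), nearby_window = 100L,
                            length_bounds = c(5L, 15L),
                            min_mh = 2L, max_mh = 6L,
                            ambiguity = "exclude") {
  refseq <- as_sequence(ref)
  refname <- if (inherits(ref, "amplicon_ref")) ref$name else "ref"
  refs <- c(stats::setNames(list(refseq), refname), as.list(search_refs))
  n <- nrow(groups)
  groups$mh <- rep(NA_integer_, n)
  groups$tmej <- rep(NA, n)
  groups$origin_class <- rep(NA_character_, n)
  groups$origin_start <- rep(NA_integer_, n)
  groups$origin_end <- rep(NA_integer_, n)
  groups$origin_strand <- rep(NA_character_, n)
  groups$mh_init <- rep(NA_integer_, n)
  groups$mh_end <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    g <- groups[k, ]
    if (g$kind == "del") {
      mh <- deletion_microhomology(refseq, g$start, g$end)
      groups$mh[k] <- mh
      groups$tmej[k] <- call_tmej(mh, tmej_window)
    } else {
      len <- g$length
      if (len < length_bounds[1]) {
        groups$origin_class[k] <-
          classify_short_insertion(g$sequence, g$start, refseq,
                                   window = nearby_window)
      } else if (len > length_bounds[2]) {
        groups$origin_class[k] <- "unclassified"
      } else {
        oc <- classify_insertion_origin(g$sequence, g$start, refs,
                                        nearby_window = nearby_window,
                                        length_bounds = length_bounds,
                                        ambiguity = ambiguity,
                                        primary = refname)
        groups$origin_class[k] <- oc$class
        if (!is.null(oc$origin)) {
          groups$origin_start[k] <- oc$origin$start
          groups$origin_end[k] <- oc$origin$end
          groups$origin_strand[k] <- oc$origin$strand
          if (oc$class %in% c("distant", "nearby", "snapback")) {
            fl <- insertion_mh_flags(g$sequence, g$start, oc$origin, refs,
                                     min_mh = min_mh, max_mh = max_mh)
            groups$mh_init[k] <- fl[["mh_init"]]
            groups$mh_end[k] <- fl[["mh_end"]]
          }
        }
      }
    }
  }
  groups
}

#' Apply the Poisson background filter to event groups
#'
#' @param groups annotated or raw group table with `n_reads`.
#' @param level Poisson confidence level (0.90, 0.95 or 0.99 conventionally;
#'   chosen per sample).
#' @param lambda background rate; estimated from the groups with
#'   [estimate_background()] when NULL.
#' @param strategy lambda estimation strategy.
#' @return list with `groups` (plus logical `retained`), `lambda`, `cutoff`.
#' @export
filter_background <- function(groups, level = 0.95, lambda = NULL,
                              strategy = "median_trim") {
  if (is.null(lambda)) lambda <- estimate_background(groups$n_reads, strategy)
  cutoff <- poisson_cutoff(lambda, level)
  groups$retained <- groups$n_reads >= cutoff
  list(groups = groups, lambda = lambda, cutoff = cutoff)
}

pct <- function(x, n) if (n > 0) 100 * x / n else NA_real_

#' Summarise filtered junction calls into assay frequency tables
#'
#' Builds, from the per-read classes and the annotated/filtered groups, the
#' per-sample panels a scar analysis reports: the fraction of products with
#' no mutation, deletions stratified by junction MH with the TMEJ-flagged
#' fraction, insertions stratified by length and origin class, MH-initiated
#' and MH-ended templated-insertion fractions, and hotspot tables of
#' insertion junctions (in "left:right" notation) and template origins.
#'
#' Reads supporting background-filtered groups are excluded from every
#' denominator.
#'
#' @param calls result of [call_junctions()].
#' @param annotated annotated groups (from [annotate_groups()], after
#'   [filter_background()]; must contain `retained`).
#' @param assay `"proximal"` or `"distal"` (recorded in the output; the
#'   distal convention tabulates MH 0-4, the proximal 0-6).
#' @return list of data.frames: `overview`, `deletion_by_mh`,
#'   `insertion_by_length`, `origin_classes`, `mh_usage`,
#'   `insertion_hotspots`, `origin_positions`.
#' @export
summarize_assay <- function(calls, annotated, assay = c("proximal", "distal")) {
  assay <- match.arg(assay)
  if (nrow(calls$per_read) == 0L) stop("no reads to summarise")
  stopifnot("retained" %in% names(annotated))
  bad_keys <- annotated$key[!annotated$retained]
  ev <- calls$events
  key <- ifelse(ev$kind == "del",
                paste("del", ev$start, ev$end, sep = ":"),
                paste("ins", ev$start, ev$length, ev$sequence, sep = ":"))
  bad_reads <- unique(ev$read_id[key %in% bad_keys])
  pr <- calls$per_read[!(calls$per_read$read_id %in% bad_reads) &
                         calls$per_read$class != "unaligned", ]
  ev <- ev[!(ev$read_id %in% bad_reads), ]
  key <- key[!(calls$events$read_id %in% bad_reads)]
  n_tot <- nrow(pr)

  ann <- annotated[annotated$retained, ]
  evann <- merge(cbind(ev, key = key), ann,
                 by = "key", suffixes = c("", ".g"))

  n_precise <- sum(pr$class == "precise")
  dele <- evann[evann$kind == "del", ]
  inse <- evann[evann$kind == "ins", ]
  overview <- data.frame(
    assay = assay,
    n_reads = n_tot,
    pct_no_mutation = pct(n_precise, n_tot),
    pct_deletion_reads = pct(sum(pr$class %in%
                                   c("deletion_only", "soft_clipped")), n_tot),
    pct_insertion_reads = pct(sum(pr$class == "insertion_only"), n_tot),
    pct_complex_reads = pct(sum(pr$class == "deletion_and_insertion"), n_tot),
    pct_tmej_deletion = pct(length(unique(dele$read_id[dele$tmej])), n_tot))

  mh_max <- if (assay == "distal") 4L else 6L
  mh_bin <- pmin(dele$mh, mh_max)
  deletion_by_mh <- data.frame(mh = 0:mh_max)
  deletion_by_mh$label <- ifelse(deletion_by_mh$mh == mh_max,
                                 paste0(mh_max, "+"), deletion_by_mh$mh)
  deletion_by_mh$n_reads <- vapply(0:mh_max, function(m)
    length(unique(dele$read_id[mh_bin == m])), 0L)
  deletion_by_mh$pct_of_reads <- pct(deletion_by_mh$n_reads, n_tot)

  len_bins <- c("1", "2-4", "5-15", ">15")
  ins_bin <- cut(inse$length, c(0, 1, 4, 15, Inf), labels = len_bins)
  insertion_by_length <- data.frame(length = len_bins,
                                    n_reads = vapply(len_bins, function(b)
                                      length(unique(inse$read_id[ins_bin == b])),
                                      0L))
  insertion_by_length$pct_of_reads <- pct(insertion_by_length$n_reads, n_tot)

  five <- inse[!is.na(inse$origin_class) &
                 inse$origin_class %in% c("distant", "nearby", "snapback",
                                          "direct_repeat", "random",
                                          "excluded"), ]
  oc_levels <- c("distant", "nearby", "snapback", "direct_repeat", "random",
                 "excluded")
  n_five <- length(unique(five$read_id))
  origin_classes <- data.frame(origin_class = oc_levels,
                               n_reads = vapply(oc_levels, function(cl)
                                 length(unique(five$read_id[
                                   five$origin_class == cl])), 0L))
  origin_classes$pct_of_classified <- pct(origin_classes$n_reads, n_five)

  templ <- five[five$origin_class %in% c("distant", "nearby", "snapback"), ]
  n_templ <- length(unique(templ$read_id))
  mh_usage <- data.frame(
    metric = c("mh_initiated", "mh_ended", "mh_initiated_and_ended"),
    n_reads = c(length(unique(templ$read_id[templ$mh_init > 0])),
                length(unique(templ$read_id[templ$mh_end > 0])),
                length(unique(templ$read_id[templ$mh_init > 0 &
                                              templ$mh_end > 0]))))
  mh_usage$pct_of_templated <- pct(mh_usage$n_reads, n_templ)

  ins_groups <- ann[ann$kind == "ins", ]
  insertion_hotspots <- if (nrow(ins_groups)) {
    agg <- stats::aggregate(n_reads ~ start, data = ins_groups, sum)
    data.frame(junction = paste0(agg$start + 1L, ":", agg$start),
               n_reads = agg$n_reads,
               pct_of_reads = pct(agg$n_reads, n_tot))
  } else {
    data.frame(junction = character(0), n_reads = integer(0),
               pct_of_reads = numeric(0))
  }

  og <- ins_groups[!is.na(ins_groups$origin_start), ]
  origin_positions <- if (nrow(og)) {
    data.frame(origin_start = og$origin_start, origin_end = og$origin_end,
               strand = og$origin_strand, class = og$origin_class,
               n_reads = og$n_reads, pct_of_reads = pct(og$n_reads, n_tot))
  } else {
    data.frame(origin_start = integer(0), origin_end = integer(0),
               strand = character(0), class = character(0),
               n_reads = integer(0), pct_of_reads = numeric(0))
  }

  list(overview = overview, deletion_by_mh = deletion_by_mh,
       insertion_by_length = insertion_by_length,
       origin_classes = origin_classes, mh_usage = mh_usage,
       insertion_hotspots = insertion_hotspots,
       origin_positions = origin_positions)
}

#' One-call junction analysis for a sample
#'
#' Runs [call_junctions()], [annotate_groups()], [filter_background()] and
#' [summarize_assay()].
#'
#' @param reads named character vector of merged reads.
#' @param ref primary `amplicon_ref`.
#' @param assay `"proximal"` or `"distal"`.
#' @param ci_level Poisson confidence level for the noise filter.
#' @param lambda background rate override; when NULL it is estimated from
#'   the group table (pass 0 for known noise-free input).
#' @param ... passed to [annotate_groups()].
#' @param search_refs extra origin-search references.
#' @param align_params see `default_align_params()`.
#' @return list with `calls`, `groups` (annotated + retained flag),
#'   `lambda`, `cutoff`, `summary`.
#' @export
analyze_junctions <- function(reads, ref, assay = c("proximal", "distal"),
                              ci_level = 0.95, lambda = NULL,
                              search_refs = NULL,
                              align_params = default_align_params(), ...) {
  assay <- match.arg(assay)
  calls <- call_junctions(reads, ref, align_params)
  ann <- annotate_groups(calls$groups, ref, search_refs = search_refs, ...)
  if (nrow(ann) > 0L) {
    fb <- filter_background(ann, level = ci_level, lambda = lambda)
    ann <- fb$groups
    lambda <- fb$lambda
    cutoff <- fb$cutoff
  } else {
    ann$retained <- logical(0)
    lambda <- NA_real_
    cutoff <- NA_integer_
  }
  list(calls = calls, groups = ann, lambda = lambda, cutoff = cutoff,
       summary = summarize_assay(calls, ann, assay))
}
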