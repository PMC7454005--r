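# Junction read simulator: plants repair outcomes (deletions with target
# MH, templated insertions by origin class, NHEJ fill-in, precise joins)
# into an amplicon reference, emits reads with optional substitution error
# and Poisson background events, and carries per-read truth labels. Every
# planted event is re-measured with the package's own analytics before
# emission, so truth and measurement definitions cannot drift apart.

#' Find a deletion interval with an exact target microhomology
#'
#' Searches canonical (left-aligned) intervals of length `L` near the cut
#' junction whose junction MH equals `target_mh` exactly, preferring the
#' interval closest to the cut.
#'
#' @param ref `amplicon_ref` or sequence.
#' @param L deletion length.
#' @param target_mh required MH length.
#' @param cut reference position immediately left of the break junction
#'   (NULL searches the whole sequence).
#' @param max_dist how far from the cut the interval may lie (default 25).
#' @return list with `start`, `end`, `mh` or NULL when no such interval
#'   exists.
#' @export
plant_deletion <- function(ref, L, target_mh, cut = NULL, max_dist = 25L) {
  refseq <- as_sequence(ref)
  n <- nchar(refseq)
  if (L >= n) stop("deletion longer than the reference")
  chars <- seq_chars(refseq)
  starts <- seq_len(n - L + 1L)
  if (!is.null(cut)) {
    keep <- starts <= cut + 1L + max_dist & (starts + L - 1L) >= cut - max_dist
    starts <- starts[keep]
    dist <- abs(pmax(starts, pmin(starts + L - 1L, cut)) - cut)
    starts <- starts[order(dist)]
  }
  for (s in starts) {
    e <- s + L - 1L
    if (s > 1L && chars[s - 1L] == chars[e]) next  # not left-aligned
    if (deletion_microhomology(refseq, s, e) == target_mh)
      return(list(start = s, end = e, mh = target_mh))
  }
  NULL
}

measure_insertion <- function(ins, j, refseq, refs, nearby_window,
                              length_bounds, min_mh, max_mh) {
  oc <- classify_insertion_origin(ins, j, refs, nearby_window = nearby_window,
                                  length_bounds = length_bounds)
  # MH usage is defined for the trans/foldback templated classes only; for a
  # direct repeat the template flank coincides with the junction flank and
  # the measure is degenerate
  fl <- if (!is.null(oc$origin) &&
            oc$class %in% c("distant", "nearby", "snapback"))
    insertion_mh_flags(ins, j, oc$origin, refs, min_mh = min_mh,
                       max_mh = max_mh)
  else c(mh_init = 0L, mh_end = 0L)
  list(class = oc$class, origin = oc$origin,
       mh_init = fl[["mh_init"]], mh_end = fl[["mh_end"]])
}

#' Plant a templated (or random) insertion with a requested geometry
#'
#' Enumerates candidate origins compatible with the requested origin class,
#' insertion length and MH-initiation/termination values, and verifies each
#' candidate by classifying it back with [classify_insertion_origin()] and
#' [insertion_mh_flags()]; the event is only returned once the round trip
#' reproduces the request exactly.
#'
#' @param ref `amplicon_ref` or sequence.
#' @param origin_class one of `distant`, `nearby`, `snapback`,
#'   `direct_repeat`, `random`.
#' @param length insertion length.
#' @param mh_init,mh_end required MH flags (0 = none; only `distant`,
#'   `nearby` and `snapback` support non-zero values).
#' @param cut junction position (insertion is placed at the cut).
#' @param nearby_window,length_bounds,min_mh,max_mh classification
#'   parameters (must match the analysis settings).
#' @return list describing the event: `pos` (canonical junction), `seq`
#'   (canonical inserted sequence), `origin_class`, `mh_init`, `mh_end`,
#'   plus `origin_start`/`origin_end`/`origin_strand` for templated classes.
#' @export
plant_insertion <- function(ref, origin_class, length, mh_init = 0L,
                            mh_end = 0L, cut, nearby_window = 100L,
                            length_bounds = c(5L, 15L), min_mh = 2L,
                            max_mh = 6L) {
  refseq <- as_sequence(ref)
  refname <- if (inherits(ref, "amplicon_ref")) ref$name else "ref"
  refs <- stats::setNames(list(refseq), refname)
  n <- nchar(refseq)
  j <- as.integer(cut)
  len <- as.integer(length)
  ok_request <- function(ins, at = j) {
    # canonicalize to the left-aligned placement the pipeline reports, then
    # verify the measured class and MH flags reproduce the request
    can <- left_align_event(refseq, list(kind = "ins", pos = at, seq = ins))
    if (can$pos < 1L) return(NULL)
    m <- tryCatch(measure_insertion(can$seq, can$pos, refseq, refs,
                                    nearby_window, length_bounds, min_mh,
                                    max_mh),
                  error = function(e) NULL)
    if (is.null(m) || m$class != origin_class) return(NULL)
    if (m$mh_init != mh_init || m$mh_end != mh_end) return(NULL)
    ev <- list(pos = can$pos, seq = can$seq, origin_class = m$class,
               mh_init = m$mh_init, mh_end = m$mh_end,
               origin_start = NA_integer_, origin_end = NA_integer_,
               origin_strand = NA_character_)
    if (!is.null(m$origin)) {
      ev$origin_start <- m$origin$start
      ev$origin_end <- m$origin$end
      ev$origin_strand <- m$origin$strand
    }
    ev
  }

  if (origin_class == "random") {
    if (mh_init != 0L || mh_end != 0L)
      stop("random insertions cannot carry MH flags")
    for (try in seq_len(200L)) {
      ins <- random_dna(len)
      ev <- ok_request(ins)
      if (!is.null(ev)) return(ev)
    }
    stop("could not generate an unmatched random insertion")
  }
  if (origin_class == "direct_repeat") {
    if (j - len + 1L < 1L) stop("junction too close to the reference start")
    # duplication of the immediate left or right flank at the break
    for (side in c("left", "right")) {
      ins <- if (side == "left") substr(refseq, j - len + 1L, j)
             else substr(refseq, j + 1L, j + len)
      ev <- ok_request(ins)
      if (!is.null(ev)) return(ev)
    }
    stop("could not plant an unambiguous direct repeat at this junction")
  }

  # templated classes: enumerate candidate origin windows
  cand <- seq_len(n - len + 1L)
  if (origin_class == "nearby") {
    d_of <- function(o1) {
      o2 <- o1 + len - 1L
      if (o2 <= j) j - o2 else if (o1 >= j + 1L) o1 - (j + 1L) else 0L
    }
    keep <- vapply(cand, function(o) d_of(o) >= 1L && d_of(o) < nearby_window,
                   TRUE)
    cand <- cand[keep]
  } else if (origin_class == "distant") {
    d_of <- function(o1) {
      o2 <- o1 + len - 1L
      if (o2 <= j) j - o2 else if (o1 >= j + 1L) o1 - (j + 1L) else 0L
    }
    cand <- cand[vapply(cand, function(o) d_of(o) >= nearby_window, TRUE)]
  } else if (origin_class == "snapback") {
    cand <- cand[cand + len - 1L <= j]   # template upstream of the junction
  } else {
    stop("unknown origin class: ", origin_class)
  }
  for (o1 in cand) {
    o2 <- o1 + len - 1L
    ins <- if (origin_class == "snapback") revcomp(substr(refseq, o1, o2))
           else substr(refseq, o1, o2)
    if (grepl("[^ACGT]", ins)) next
    ev <- ok_request(ins)
    if (!is.null(ev)) return(ev)
  }
  stop("requested insertion geometry not realizable in this reference ",
       "(class ", origin_class, ", length ", len, ", mh_init ", mh_init,
       ", mh_end ", mh_end, ")")
}

#' Specification for a junction read simulation
#'
#' @param ref `amplicon_ref` used as the intact allele.
#' @param cut reference position immediately left of the induced break.
#' @param outcomes data.frame describing the outcome mixture: columns
#'   `name`, `type` (`precise`, `fillin`, `deletion`, `insertion`), `prop`,
#'   and the event parameters `L`, `mh`, `origin_class`, `len`, `mh_init`,
#'   `mh_end` (NA where not applicable). Proportions must sum to 1.
#' @param depth number of non-background reads.
#' @param error_rate per-base substitution error rate.
#' @param lambda Poisson mean read count per spurious background event.
#' @param n_background number of distinct spurious background events.
#' @return object of class `junction_sim_spec`.
#' @export
junction_sim_spec <- function(ref, cut, outcomes = default_outcomes(),
                              depth = 2000L, error_rate = 0,
                              lambda = 0, n_background = 0L) {
  stopifnot(inherits(ref, "amplicon_ref"), depth >= 1L)
  if (abs(sum(outcomes$prop) - 1) > 1e-8)
    stop("outcome proportions must sum to 1")
  structure(list(ref = ref, cut = as.integer(cut), outcomes = outcomes,
                 depth = as.integer(depth), error_rate = error_rate,
                 lambda = lambda, n_background = as.integer(n_background)),
            class = "junction_sim_spec")
}

#' Default outcome mixture for a proximal end-joining assay
#'
#' Roughly 90% precise joins (as observed for the proximal assay), a +1
#' fill-in insertion class, deletions over MH 0-4, and templated/random
#' insertions of 5-12 bp across the five origin classes.
#'
#' @return outcome data.frame for [junction_sim_spec()].
#' @export
default_outcomes <- function() {
  out <- data.frame(
    name = c("precise", "fillin",
             paste0("del_mh", 0:4),
             "ins_nearby", "ins_distant", "ins_snapback", "ins_direct",
             "ins_random"),
    type = c("precise", "fillin", rep("deletion", 5), rep("insertion", 5)),
    prop = c(0.90, 0.030, rep(0.010, 5), rep(0.004, 5)),
    L = c(NA, NA, 8, 10, 12, 14, 16, rep(NA, 5)),
    mh = c(NA, NA, 0:4, rep(NA, 5)),
    origin_class = c(rep(NA, 7), "nearby", "distant", "snapback",
                     "direct_repeat", "random"),
    len = c(rep(NA, 7), 8, 9, 8, 6, 10),
    mh_init = c(rep(NA, 7), 0, 0, 0, 0, 0),
    mh_end = c(rep(NA, 7), 0, 0, 0, 0, 0))
  stopifnot(abs(sum(out$prop) - 1) < 1e-9)
  out
}

apply_event <- function(refseq, kind, start, end, seq) {
  if (kind == "del") {
    paste0(substr(refseq, 1L, start - 1L),
           substr(refseq, end + 1L, nchar(refseq)))
  } else {
    paste0(substr(refseq, 1L, start), seq,
           substr(refseq, start + 1L, nchar(refseq)))
  }
}

add_errors <- function(read, rate) {
  if (rate <= 0) return(read)
  n <- nchar(read)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(read)
  pos <- sample.int(n, k)
  chars <- seq_chars(read)
  for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Simulate junction reads with planted truth
#'
#' @param spec `junction_sim_spec`.
#' @param seed integer seed; identical seeds give identical reads and truth.
#' @return list with `reads` (named character vector), `truth` (per-read
#'   data.frame: outcome, type, kind, start, end, length, sequence, mh,
#'   origin_class, mh_init, mh_end, background) and `events` (one row per
#'   planted event instance).
#' @export
simulate_reads <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "junction_sim_spec"))
  set.seed(seed)
  refseq <- spec$ref$sequence
  out <- spec$outcomes

  # instantiate each outcome as a concrete canonical event
  inst <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    o <- out[i, ]
    if (o$type == "precise") {
      inst[[i]] <- list(kind = "none")
    } else if (o$type == "fillin") {
      # +1 duplication of the base 5' of the staggered cut, then canonical
      ev <- left_align_event(refseq, list(kind = "ins", pos = spec$cut,
                                          seq = substr(refseq, spec$cut,
                                                       spec$cut)))
      inst[[i]] <- list(kind = "ins", start = ev$pos, end = ev$pos,
                        length = 1L, seq = ev$seq)
    } else if (o$type == "deletion") {
      pd <- plant_deletion(refseq, o$L, o$mh, cut = spec$cut)
      if (is.null(pd))
        stop("no deletion of length ", o$L, " with MH ", o$mh,
             " exists near the cut")
      inst[[i]] <- list(kind = "del", start = pd$start, end = pd$end,
                        length = o$L, seq = substr(refseq, pd$start, pd$end),
                        mh = pd$mh)
    } else {
      pi_ <- plant_insertion(spec$ref, o$origin_class, o$len,
                             mh_init = o$mh_init, mh_end = o$mh_end,
                             cut = spec$cut)
      inst[[i]] <- list(kind = "ins", start = pi_$pos, end = pi_$pos,
                        length = o$len, seq = pi_$seq,
                        origin_class = pi_$origin_class,
                        mh_init = pi_$mh_init, mh_end = pi_$mh_end)
    }
  }

  counts <- as.integer(stats::rmultinom(1L, spec$depth, out$prop))
  reads <- character(0)
  truth <- list()
  rid <- 0L
  emit <- function(read, row) {
    rid <<- rid + 1L
    id <- sprintf("read%05d", rid)
    reads[[id]] <<- read
    truth[[length(truth) + 1L]] <<- row
  }
  for (i in seq_len(nrow(out))) {
    ev <- inst[[i]]
    base_read <- if (ev$kind == "none") refseq
                 else apply_event(refseq, ev$kind, ev$start, ev$end, ev$seq)
    for (r in seq_len(counts[i])) {
      emit(add_errors(base_read, spec$error_rate),
           data.frame(outcome = out$name[i], type = out$type[i],
                      kind = if (ev$kind == "none") NA_character_ else ev$kind,
                      start = if (ev$kind == "none") NA_integer_ else ev$start,
                      end = if (ev$kind == "none") NA_integer_ else ev$end,
                      length = if (ev$kind == "none") NA_integer_ else ev$length,
                      sequence = if (ev$kind == "none") NA_character_ else ev$seq,
                      mh = if (is.null(ev$mh)) NA_integer_ else ev$mh,
                      origin_class = if (is.null(ev$origin_class))
                        NA_character_ else ev$origin_class,
                      mh_init = if (is.null(ev$mh_init)) NA_integer_
                                else ev$mh_init,
                      mh_end = if (is.null(ev$mh_end)) NA_integer_
                               else ev$mh_end,
                      background = FALSE))
    }
  }

  # spurious background events: distinct small indels with Poisson counts
  if (spec$n_background > 0L) {
    used <- vapply(inst, function(e)
      if (e$kind == "del") paste0("del:", e$start, ":", e$end) else "",
      "")
    placed <- 0L
    guard <- 0L
    while (placed < spec$n_background && guard < 50L * spec$n_background) {
      guard <- guard + 1L
      L <- sample(1:3, 1L)
      s <- sample.int(nchar(refseq) - L - 10L, 1L) + 5L
      ev <- left_align_event(refseq, list(kind = "del", start = s,
                                          end = s + L - 1L))
      key <- paste0("del:", ev$start, ":", ev$end)
      if (key %in% used) next
      used <- c(used, key)
      placed <- placed + 1L
      nb <- stats::rpois(1L, spec$lambda)
      if (nb == 0L) next
      base_read <- apply_event(refseq, "del", ev$start, ev$end, NULL)
      for (r in seq_len(nb)) {
        emit(add_errors(base_read, spec$error_rate),
             data.frame(outcome = paste0("bg_", key), type = "background",
                        kind = "del", start = ev$start, end = ev$end,
                        length = ev$end - ev$start + 1L,
                        sequence = substr(refseq, ev$start, ev$end),
                        mh = NA_integer_, origin_class = NA_character_,
                        mh_init = NA_integer_, mh_end = NA_integer_,
                        background = TRUE))
      }
    }
  }

  truth <- do.call(rbind, truth)
  truth <- cbind(read_id = names(reads), truth)
  rownames(truth) <- NULL
  events <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    ev <- inst[[i]]
    data.frame(outcome = out$name[i], kind = ev$kind,
               start = if (ev$kind == "none") NA_integer_ else ev$start,
               end = if (ev$kind == "none") NA_integer_ else ev$end,
               n_reads = counts[i])
  }))
  list(reads = unlist(reads), truth = truth, events = events, spec = spec)
}

#' Compare pipeline calls with simulator truth
#'
#' @param per_read pipeline per-read table ([call_junctions()]`$per_read`).
#' @param truth simulator truth table.
#' @return list with `confusion` (expected read class x called class),
#'   `per_class` (precision/recall per expected class) and `accuracy`.
#' @export
evaluate_calls <- function(per_read, truth) {
  if (nrow(truth) == 0L) stop("empty truth")
  if (!setequal(per_read$read_id, truth$read_id))
    stop("read ids of calls and truth do not match")
  m <- merge(truth, per_read, by = "read_id")
  expected <- ifelse(m$type == "precise", "precise",
              ifelse(m$type %in% c("fillin", "insertion"), "insertion_only",
                     "deletion_only"))
  confusion <- table(expected = expected, called = m$class)
  classes <- rownames(confusion)
  per_class <- data.frame(
    class = classes,
    recall = vapply(classes, function(cl) {
      idx <- expected == cl
      if (!any(idx)) return(NA_real_)
      mean(m$class[idx] == cl)
    }, 0),
    precision = vapply(classes, function(cl) {
      idx <- m$class == cl
      if (!any(idx)) return(NA_real_)
      mean(expected[idx] == cl)
    }, 0))
  list(confusion = confusion, per_class = per_class,
       accuracy = mean(expected == m$class))
}
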