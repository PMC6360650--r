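#' Re-segment a pooled stretch of signals into events
#'
#' Splits a signal vector into `n_events` contiguous, non-empty,
#' order-preserving intervals. Intervals are as equal as possible; when the
#' length is not divisible the remainder is assigned one signal at a time to
#' the leftmost events.
#'
#' @param signals Numeric vector of signal values.
#' @param n_events Number of events to produce (>= 1).
#' @return List of `n_events` numeric vectors covering `signals` in order.
#' @examples
#' lengths(resegment(rnorm(10), 3)) # 4 3 3
#' @export
resegment <- function(signals, n_events) {
  n_events <- as.integer(n_events)
  if (n_events < 1L) abort("`n_events` must be >= 1")
  L <- length(signals)
  if (L < n_events) {
    abort(sprintf("infeasible re-segmentation: %d signals cannot form %d non-empty events",
                  L, n_events))
  }
  q <- L %/% n_events
  r <- L %% n_events
  sizes <- rep.int(q, n_events)
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  vctrs::vec_chop(signals, sizes = sizes)
}

# ---- internal slot representation -------------------------------------------
# A read under correction is a list of "slots" in genomic/read order:
#   list(ref = <int or NA>, signals = <numeric or NULL>)
# Events carry signals; ref = NA marks an inserted event. Deletion
# placeholders carry a ref position but NULL signals.

slots_from_events <- function(ref_position, signals) {
  mapply(function(r, s) list(ref = r, signals = s),
         ref_position, signals, SIMPLIFY = FALSE)
}

slot_is_event <- function(slots) !vapply(slots, function(s) is.null(s$signals), logical(1))

# merge the inserted event at `i` into its smaller event flank (tie: upstream);
# deletion placeholders are skipped over when searching for flanks
merge_insertion_slot <- function(slots, i) {
  is_ev <- slot_is_event(slots)
  up <- i - 1L
  while (up >= 1L && !is_ev[up]) up <- up - 1L
  dn <- i + 1L
  while (dn <= length(slots) && !is_ev[dn]) dn <- dn + 1L
  has_up <- up >= 1L
  has_dn <- dn <= length(slots)
  if (!has_up && !has_dn) {
    abort("insertion event has no aligned flank to merge with")
  }
  use_up <- if (has_up && has_dn) {
    length(slots[[up]]$signals) <= length(slots[[dn]]$signals)
  } else {
    has_up
  }
  if (use_up) {
    slots[[up]]$signals <- c(slots[[up]]$signals, slots[[i]]$signals)
  } else {
    slots[[dn]]$signals <- c(slots[[i]]$signals, slots[[dn]]$signals)
  }
  slots[-i]
}

# re-segment the region around the deletion placeholder run starting at `i`.
# The group starts as one aligned event on each side and is widened
# symmetrically one event at a time until every output event can receive at
# least `min_signals` signals. Returns NULL if the whole read cannot satisfy
# the constraint.
resegment_deletion_region <- function(slots, i, min_signals) {
  n <- length(slots)
  j <- i
  while (j < n && is.null(slots[[j + 1L]]$signals)) j <- j + 1L
  lo <- i - 1L   # one upstream aligned event
  hi <- j + 1L   # one downstream aligned event
  if (lo < 1L || hi > n) {
    return(NULL) # deletion at the read boundary cannot be reconstructed
  }
  prefer_up <- TRUE
  repeat {
    region <- slots[lo:hi]
    pool <- unlist(lapply(region, `[[`, "signals"), use.names = FALSE)
    n_out <- hi - lo + 1L # every slot in the region owns one reference position
    if (length(pool) >= min_signals * n_out) break
    # widen by one event, alternating sides, falling back to whichever side
    # still has events
    if (prefer_up && lo > 1L) {
      lo <- lo - 1L
    } else if (hi < n) {
      hi <- hi + 1L
    } else if (lo > 1L) {
      lo <- lo - 1L
    } else {
      return(NULL)
    }
    prefer_up <- !prefer_up
  }
  refs <- vapply(slots[lo:hi], `[[`, integer(1), "ref")
  if (anyNA(refs) || any(diff(refs) != 1L)) {
    abort("internal error: deletion region is not a contiguous reference span")
  }
  pieces <- resegment(pool, hi - lo + 1L)
  new_slots <- mapply(function(r, s) list(ref = r, signals = s),
                      refs, pieces, SIMPLIFY = FALSE)
  c(slots[seq_len(lo - 1L)], new_slots,
    if (hi < n) slots[(hi + 1L):n] else list())
}

correct_slots <- function(slots, min_signals = 3) {
  # insertions first, then deletions (adjacent indels end up merged into the
  # same re-segmented region)
  repeat {
    ins <- which(vapply(slots, function(s) is.na(s$ref) && !is.null(s$signals), logical(1)))
    if (length(ins) == 0L) break
    slots <- merge_insertion_slot(slots, ins[1L])
  }
  repeat {
    del <- which(!slot_is_event(slots))
    if (length(del) == 0L) break
    slots <- resegment_deletion_region(slots, del[1L], min_signals)
    if (is.null(slots)) return(NULL)
  }
  slots
}

#' Correct a basecalled insertion by merging events
#'
#' The inserted event's signals are pooled with its smaller event flank
#' (upstream on ties, or the only available flank at a read end), removing one
#' event. Total signal count is conserved.
#'
#' @param events Event table for a single read; the inserted event has
#'   `ref_position = NA`.
#' @param ins_index Row index of the inserted event.
#' @return The corrected event table with one fewer row.
#' @export
correct_insertion <- function(events, ins_index) {
  validate_events(events)
  if (!is.na(events$ref_position[ins_index])) {
    abort("`ins_index` does not point at an inserted event (ref_position must be NA)")
  }
  slots <- slots_from_events(events$ref_position, events$signals)
  slots <- merge_insertion_slot(slots, ins_index)
  events_from_slots(slots, events$read_id[1L], events$strand[1L], base = NULL)
}

#' Correct a basecalled deletion by re-segmenting neighboring events
#'
#' Groups the aligned events flanking the deleted reference position (one on
#' each side to start), pools their signals, and re-segments them so that one
#' additional event is generated for the deleted position. The group is
#' widened symmetrically one event at a time until every output event can
#' receive at least `min_signals` signals; if the whole read cannot satisfy
#' this the read is uncorrectable and `NULL` is returned with a warning.
#'
#' @param events Event table for a single read with `ref_position` set.
#' @param del_ref_pos 0-based reference position missing from the read.
#' @param min_signals Minimum signals per output event (default 3).
#' @return The corrected event table with one more row, or `NULL`.
#' @export
correct_deletion <- function(events, del_ref_pos, min_signals = 3) {
  validate_events(events)
  if (del_ref_pos %in% events$ref_position) {
    abort("`del_ref_pos` is already covered by an event")
  }
  slots <- slots_from_events(events$ref_position, events$signals)
  at <- which(vapply(slots, `[[`, integer(1), "ref") > del_ref_pos)[1L]
  if (is.na(at) || at == 1L) {
    abort("deletion must be flanked by aligned events on both sides")
  }
  slots <- append(slots, list(list(ref = as.integer(del_ref_pos), signals = NULL)),
                  after = at - 1L)
  slots <- resegment_deletion_region(slots, at, min_signals)
  if (is.null(slots)) {
    warn("deletion region uncorrectable: not enough signals in the read")
    return(NULL)
  }
  events_from_slots(slots, events$read_id[1L], events$strand[1L], base = NULL)
}

events_from_slots <- function(slots, read_id, strand, base = NULL) {
  refs <- vapply(slots, `[[`, integer(1), "ref")
  tibble(
    read_id = read_id,
    strand = strand,
    ref_position = refs,
    base = if (is.null(base)) NA_character_ else base,
    signals = lapply(slots, `[[`, "signals"),
    event_id = seq_along(slots)
  )
}

#' Find homopolymer runs in a reference sequence
#'
#' @param reference Reference sequence.
#' @return Tibble with 0-based `ref_start`, `length` and `base` of every
#'   maximal single-nucleotide run.
#' @export
homopolymer_runs <- function(reference) {
  ref <- as_reference_chars(reference)
  r <- rle(ref)
  ends <- cumsum(r$lengths)
  tibble(ref_start = as.integer(ends - r$lengths),
         length = as.integer(r$lengths),
         base = r$values)
}

#' Share events across the middle of long homopolymer runs
#'
#' For a single-nucleotide run of length `L_r > 5`, the events of the middle
#' `L_r - 4` positions are pooled into one event shared by those positions
#' (the two outermost positions on each side keep their own events). Runs of
#' length 5 or less are left unchanged.
#'
#' @param events Corrected event table for a single read (one row per
#'   reference position).
#' @param run One row of [homopolymer_runs()] (or a list with `ref_start`,
#'   `length`).
#' @return The event table; shared rows repeat the pooled signals and carry a
#'   common `event_id`.
#' @export
apply_homopolymer_rule <- function(events, run) {
  L_r <- run$length
  if (L_r <= 5L) return(events)
  mid <- seq(run$ref_start + 2L, run$ref_start + L_r - 3L) # L_r - 4 positions
  idx <- which(events$ref_position %in% mid)
  if (length(idx) != length(mid)) return(events) # run not fully inside the read
  key <- paste(events$read_id[idx], events$event_id[idx])
  shared <- unlist(events$signals[idx][!duplicated(key)], use.names = FALSE)
  events$signals[idx] <- rep(list(shared), length(idx))
  events$event_id[idx] <- events$event_id[idx[1L]]
  events
}

#' Correct one read against its alignment
#'
#' Alignment-guided error correction of basecalling indels: inserted events
#' are merged into a flanking event, deleted reference positions gain an event
#' through local re-segmentation, soft-clipped read ends are excluded from
#' annotation, called bases are replaced by the reference bases over the
#' aligned span, and the homopolymer sharing rule is applied to runs longer
#' than 5. The total signal count over the aligned span is conserved.
#'
#' @param events Event table for one read, in read order (uncorrected;
#'   `ref_position` may be `NA`).
#' @param cigar CIGAR string of the read's alignment.
#' @param ref_start 0-based reference coordinate of the first aligned base.
#' @param reference Reference sequence.
#' @param min_signals Minimum signals per re-segmented event (default 3).
#' @param homopolymer Apply the homopolymer sharing rule (default TRUE).
#' @param .parsed,.runs Pre-computed CIGAR ops and homopolymer runs (internal,
#'   used by [correct_reads()] to batch work across reads).
#' @return Corrected event table with one row per aligned reference position
#'   (homopolymer-shared positions repeat their event), or `NULL` with a
#'   warning if the read is uncorrectable.
#' @export
correct_read <- function(events, cigar, ref_start, reference,
                         min_signals = 3, homopolymer = TRUE,
                         .parsed = NULL, .runs = NULL) {
  validate_events(events)
  ref <- if (is.character(reference) && length(reference) > 1L) reference
         else as_reference_chars(reference)
  if (is.null(.parsed)) .parsed <- parse_cigars(cigar)
  ops <- .parsed$ops[[1L]]
  lens <- .parsed$lens[[1L]]

  keep <- ops != "H"
  ops <- ops[keep]; lens <- lens[keep]
  # soft clips consume read events but are excluded from annotation
  if (length(ops) > 0L && ops[1L] == "S") {
    events <- events[-seq_len(lens[1L]), , drop = FALSE]
    ops <- ops[-1L]; lens <- lens[-1L]
  }
  if (length(ops) > 0L && ops[length(ops)] == "S") {
    nr <- nrow(events)
    events <- events[seq_len(nr - lens[length(lens)]), , drop = FALSE]
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  if (sum(lens[ops %in% c("M", "=", "X", "I")]) != nrow(events)) {
    abort("CIGAR does not match the number of read events")
  }

  slots <- vector("list", sum(lens))
  ev_i <- 0L; ref_cur <- as.integer(ref_start); k <- 0L
  for (oi in seq_along(ops)) {
    op <- ops[oi]; ln <- lens[oi]
    if (op %in% c("M", "=", "X")) {
      for (z in seq_len(ln)) {
        ev_i <- ev_i + 1L; k <- k + 1L
        slots[[k]] <- list(ref = ref_cur, signals = events$signals[[ev_i]])
        ref_cur <- ref_cur + 1L
      }
    } else if (op == "I") {
      for (z in seq_len(ln)) {
        ev_i <- ev_i + 1L; k <- k + 1L
        slots[[k]] <- list(ref = NA_integer_, signals = events$signals[[ev_i]])
      }
    } else if (op == "D" || op == "N") {
      for (z in seq_len(ln)) {
        k <- k + 1L
        slots[[k]] <- list(ref = ref_cur, signals = NULL)
        ref_cur <- ref_cur + 1L
      }
    } else {
      abort(sprintf("unsupported CIGAR op '%s'", op))
    }
  }
  slots <- slots[seq_len(k)]

  slots <- correct_slots(slots, min_signals = min_signals)
  if (is.null(slots)) {
    warn(sprintf("read %s uncorrectable: dropped from annotation", events$read_id[1L]))
    return(NULL)
  }
  out <- events_from_slots(slots, events$read_id[1L], events$strand[1L])
  out$base <- ref[out$ref_position + 1L]

  if (homopolymer) {
    runs <- .runs
    if (is.null(runs)) {
      runs <- homopolymer_runs(paste(ref, collapse = ""))
      runs <- runs[runs$length > 5L, , drop = FALSE]
    }
    span <- range(out$ref_position)
    for (ri in seq_len(nrow(runs))) {
      rn <- runs[ri, ]
      if (rn$ref_start >= span[1L] && rn$ref_start + rn$length - 1L <= span[2L]) {
        out <- apply_homopolymer_rule(out, rn)
      }
    }
  }
  out
}

#' Correct a set of reads against their alignments
#'
#' @param events Event table holding several reads (uncorrected).
#' @param alignments Tibble with one row per read: `read_id`, `cigar`,
#'   `ref_start` (0-based) and optionally `mapq`; see [read_alignments_sam()].
#' @param reference Reference sequence.
#' @param min_mapq Reads with `mapq` below this are skipped (default 0).
#' @inheritParams correct_read
#' @return Corrected event table over all correctable reads.
#' @export
correct_reads <- function(events, alignments, reference,
                          min_signals = 3, min_mapq = 0, homopolymer = TRUE) {
  validate_events(events)
  ref <- as_reference_chars(reference)
  runs <- homopolymer_runs(paste(ref, collapse = ""))
  runs <- runs[runs$length > 5L, , drop = FALSE]
  parsed_all <- parse_cigars(alignments$cigar)
  by_read <- split(events, events$read_id)
  out <- vector("list", length(by_read))
  for (i in seq_along(by_read)) {
    id <- names(by_read)[i]
    ai <- which(alignments$read_id == id)
    if (length(ai) == 0L) {
      warn(sprintf("read %s has no alignment: skipped", id))
      next
    }
    ai <- ai[1L]
    mq <- if ("mapq" %in% names(alignments)) alignments$mapq[ai] else NA
    if (!is.na(mq) && mq < min_mapq) next
    out[[i]] <- correct_read(
      by_read[[i]], alignments$cigar[ai], alignments$ref_start[ai], ref,
      min_signals = min_signals, homopolymer = homopolymer,
      .parsed = list(ops = parsed_all$ops[ai], lens = parsed_all$lens[ai]),
      .runs = runs)
  }
  bind_rows(out)
}

parse_cigars <- function(cigars) {
  list(ops = GenomicAlignments::explodeCigarOps(cigars),
       lens = GenomicAlignments::explodeCigarOpLengths(cigars))
}
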