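#' Pool normalized signals onto reference positions
#'
#' For every reference position, collects the signal values of all events
#' anchored at that position, separately for the modified sample (group 1) and
#' the control sample (group 2). A read contributes all signal values of the
#' event(s) it anchors at a position; a homopolymer-shared event contributes
#' its full signal vector to every position that shares it. Positions covered
#' by no read in a group get empty signal vectors.
#'
#' @param events1 Event table for the modified sample (group 1), with
#'   non-missing `ref_position`.
#' @param events2 Event table for the control sample (group 2).
#' @param reference Reference sequence (character string or Biostrings object).
#' @return A tibble with one row per reference position (0-based
#'   `ref_position` from 0 to `nchar(reference) - 1`): `ref_base`, list
#'   columns `signals1`/`signals2`, signal counts `m`/`n`, and distinct-read
#'   counts `n_reads1`/`n_reads2`.
#' @seealso [filter_low_coverage()]
#' @export
pool_position_signals <- function(events1, events2, reference) {
  ref <- as_reference_chars(reference)
  L <- length(ref)
  g1 <- pool_one_group(events1, L)
  g2 <- pool_one_group(events2, L)
  tibble(
    ref_position = 0:(L - 1L),
    ref_base = ref,
    signals1 = g1$signals,
    signals2 = g2$signals,
    m = g1$n_signals,
    n = g2$n_signals,
    n_reads1 = g1$n_reads,
    n_reads2 = g2$n_reads
  )
}

pool_one_group <- function(events, L) {
  if (nrow(events) == 0L) {
    return(list(signals = rep(list(numeric(0)), L),
                n_signals = integer(L), n_reads = integer(L)))
  }
  validate_events(events)
  pos <- events$ref_position
  if (anyNA(pos)) {
    abort("events with missing `ref_position` cannot be pooled; correct the reads first")
  }
  if (any(pos < 0L) || any(pos >= L)) {
    abort("coordinate error: event anchored outside the reference bounds")
  }
  lens <- lengths(events$signals)
  allsig <- unlist(events$signals, use.names = FALSE)
  sig_pos <- rep(pos, lens)
  o <- order(sig_pos)
  per_pos <- tabulate(sig_pos + 1L, nbins = L)
  signals <- vctrs::vec_chop(allsig[o], sizes = per_pos)

  rid <- as.integer(factor(events$read_id))
  key <- pos * (max(rid) + 1) + rid
  first <- !duplicated(key)
  n_reads <- tabulate(pos[first] + 1L, nbins = L)

  list(signals = signals, n_signals = per_pos, n_reads = n_reads)
}

#' Filter positions with insufficient read coverage
#'
#' Removes reference positions whose number of distinct contributing reads is
#' below `min_reads` in *either* group. Order is preserved; the operation is
#' idempotent.
#'
#' @param sites Pooled position table from [pool_position_signals()].
#' @param min_reads Minimum distinct reads required per group (default 5).
#' @return The filtered site table.
#' @export
filter_low_coverage <- function(sites, min_reads = 5) {
  stopifnot(min_reads >= 1)
  sites[sites$n_reads1 >= min_reads & sites$n_reads2 >= min_reads, , drop = FALSE]
}
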