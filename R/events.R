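#' Event tables
#'
#' Reads are represented as *event tables*: one row per event, where an event
#' is the contiguous run of raw current measurements attributed to one called
#' base. Columns:
#'
#' * `read_id` (character) — read identifier.
#' * `strand` (character) — `"+"` or `"-"`. Reverse-strand reads contribute to
#'   the reference position they align to; signal values are not remapped.
#' * `ref_position` (integer) — 0-based reference coordinate the event is
#'   anchored at, or `NA` for unaligned/uncorrected events.
#' * `base` (character) — called base, one of `A`, `C`, `G`, `T`.
#' * `signals` (list of numeric) — the event's signal values, each non-empty.
#' * `event_id` (integer, optional) — identifier of the underlying event
#'   within a read. After homopolymer sharing several positions can carry the
#'   same event; such rows repeat the signals and share `event_id`.
#'
#' @param read_id,strand,ref_position,base,signals Column values, recycled to
#'   a common length.
#' @param event_id Optional integer event identifiers; defaults to row order.
#' @return A tibble with the columns above.
#' @examples
#' event_table(read_id = "r1", strand = "+", ref_position = 0:1,
#'             base = c("A", "C"), signals = list(c(1, 2), 3))
#' @export
event_table <- function(read_id, strand = "+", ref_position = NA_integer_,
                        base, signals, event_id = NULL) {
  if (!is.list(signals)) signals <- list(signals)
  out <- tibble(
    read_id = as.character(read_id),
    strand = as.character(strand),
    ref_position = as.integer(ref_position),
    base = as.character(base),
    signals = signals
  )
  out$event_id <- if (is.null(event_id)) seq_len(nrow(out)) else as.integer(event_id)
  validate_events(out)
  out
}

validate_events <- function(events) {
  need <- c("read_id", "strand", "ref_position", "base", "signals")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) {
    abort(paste0("event table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(lengths(events$signals) < 1)) {
    abort("every event must have at least one signal value")
  }
  invisible(events)
}

# total signal count over distinct underlying events (homopolymer-shared rows
# are counted once)
total_signals <- function(events) {
  if ("event_id" %in% names(events) && anyDuplicated(paste(events$read_id, events$event_id))) {
    keep <- !duplicated(paste(events$read_id, events$event_id))
    sum(lengths(events$signals[keep]))
  } else {
    sum(lengths(events$signals))
  }
}

as_reference_chars <- function(reference) {
  if (inherits(reference, "DNAStringSet")) reference <- as.character(reference[[1L]])
  if (inherits(reference, "DNAString")) reference <- as.character(reference)
  if (!is.character(reference) || length(reference) != 1L) {
    abort("`reference` must be a single DNA sequence (character or Biostrings object)")
  }
  strsplit(toupper(reference), "", fixed = TRUE)[[1L]]
}
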