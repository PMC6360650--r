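#' Normalize raw signal values
#'
#' Per-read normalization of nanopore current measurements: the read median is
#' subtracted and values are standardized by the averaged absolute difference
#' from the median, then clipped to `[-clip, clip]`. With
#' `method = "mean_ad"` the scale is the mean absolute deviation from the
#' median; `method = "median_ad"` uses the median absolute deviation instead
#' (unscaled, i.e. no consistency constant).
#'
#' @param x Numeric vector of raw signal values (length >= 2, not constant).
#' @param method Scale estimator, `"mean_ad"` (default) or `"median_ad"`.
#' @param clip Symmetric clip bound for the normalized values (default 5).
#' @return Numeric vector of normalized, clipped signals. Before clipping the
#'   output has median 0 and (for `"mean_ad"`) mean absolute deviation 1.
#' @examples
#' normalize_signals(1:5)
#' @export
normalize_signals <- function(x, method = c("mean_ad", "median_ad"), clip = 5) {
  method <- match.arg(method)
  if (length(x) < 2L) {
    abort("degenerate scale: need at least 2 signal values to normalize")
  }
  med <- median(x)
  dev <- abs(x - med)
  s <- if (method == "mean_ad") mean(dev) else median(dev)
  if (!is.finite(s) || s <= 0) {
    abort("degenerate scale: signals are constant, normalization denominator is 0")
  }
  pmin(pmax((x - med) / s, -clip), clip)
}

#' Normalize an event table read by read
#'
#' Applies [normalize_signals()] to the pooled signals of each read (one
#' median and one scale per read, not per event) and writes the transformed
#' values back into the events. Homopolymer-shared rows (repeated
#' `event_id`s) are normalized once and re-shared.
#'
#' @param events Event table (see [event_table()]).
#' @inheritParams normalize_signals
#' @return The event table with normalized `signals`.
#' @export
normalize_reads <- function(events, method = c("mean_ad", "median_ad"), clip = 5) {
  method <- match.arg(method)
  validate_events(events)
  if (nrow(events) == 0L) return(events)

  key <- if ("event_id" %in% names(events)) {
    paste(events$read_id, events$event_id)
  } else {
    as.character(seq_len(nrow(events)))
  }
  first <- !duplicated(key)

  lens <- lengths(events$signals[first])
  allsig <- unlist(events$signals[first], use.names = FALSE)
  rid <- factor(events$read_id[first])
  sig_rid <- rep(as.integer(rid), lens)

  norm_by_read <- split(allsig, sig_rid)
  norm_by_read <- lapply(norm_by_read, normalize_signals, method = method, clip = clip)
  # split/unsplit preserves within-read order because sig_rid is the only key
  allsig[order(sig_rid)] <- unlist(norm_by_read, use.names = FALSE)

  new_first <- vctrs::vec_chop(allsig, sizes = lens)
  events$signals <- new_first[match(key, key[first])]
  events
}
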