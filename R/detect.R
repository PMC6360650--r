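#' Neighborhood-based non-redundant ranking
#'
#' Greedy suppression of redundant neighboring calls: sites are visited in
#' order of ascending combined p-value (ties broken by the leftmost position);
#' a site is suppressed if an already-accepted site lies within `window` bases
#' on either side. Accepted sites are re-ranked 1..N; suppressed sites get
#' `NA` rank. The accepted set does not depend on the input row order.
#'
#' @param sites Scored site table (needs `ref_position` and `log_p_combined`,
#'   or `log_p_single` as fallback).
#' @param window Suppression half-window in bases, 1 or 2 (default 2).
#' @return `sites` with an integer `rank` column added.
#' @export
neighborhood_rank <- function(sites, window = 2) {
  key <- if ("log_p_combined" %in% names(sites)) {
    sites$log_p_combined
  } else if ("p_combined" %in% names(sites)) {
    log(sites$p_combined)
  } else if ("log_p_single" %in% names(sites)) {
    sites$log_p_single
  } else {
    log(sites$p_single)
  }
  if (nrow(sites) == 0L) {
    sites$rank <- integer(0)
    return(sites)
  }
  pos <- sites$ref_position
  o <- order(key, pos, na.last = TRUE)
  offset <- min(pos) - 1L
  blocked <- logical(max(pos) - offset)
  rank <- rep(NA_integer_, length(pos))
  r <- 0L
  for (i in o) {
    if (is.na(key[i])) next
    p <- pos[i] - offset
    if (blocked[p]) next
    r <- r + 1L
    rank[i] <- r
    blocked[max(1L, p - window):min(length(blocked), p + window)] <- TRUE
  }
  sites$rank <- rank
  sites
}

#' Detect candidate modified positions from two groups of reads
#'
#' Runs the full detection pipeline on a modified-sample event table (group 1)
#' and a control event table (group 2): optional alignment-guided indel
#' correction, per-read signal normalization, pooling of signals onto
#' reference positions, coverage filtering, a per-position two-group test,
#' neighbor p-value combination, and neighborhood-based ranking. The result is
#' deterministic given the inputs.
#'
#' @param events1 Event table of the modified sample.
#' @param events2 Event table of the control sample.
#' @param reference Reference sequence.
#' @param test Single-base test: `"ks"` (default), `"u"` or `"t"`.
#' @param combiner Neighbor combination: `"stouffer"` (default), `"fisher"` or
#'   `"none"`.
#' @param k Neighbor half-window for combination (default 2).
#' @param weight_scheme Stouffer weight decay (see
#'   [combine_neighbor_pvalues()]).
#' @param min_reads Coverage filter: minimum distinct reads per group
#'   (default 5).
#' @param rank_window Suppression half-window for [neighborhood_rank()]
#'   (default 2).
#' @param normalize Normalize signals per read before pooling (default TRUE;
#'   set FALSE if the event tables are already normalized).
#' @param clip Clip bound for normalization (default 5).
#' @param alignments1,alignments2 Optional alignment tables (see
#'   [read_alignments_sam()]); when given, reads are corrected with
#'   [correct_reads()] after normalization.
#' @param min_signals Minimum signals per re-segmented event during correction.
#' @param ks_correction Apply the lattice continuity correction in the KS
#'   p-value (default TRUE).
#' @return A `poremod_sites` tibble: one row per coverage-passing reference
#'   position with `m`, `n`, `D`, `p_single`, `Z`, `p_combined`, their
#'   log-scale companions, and `rank` (NA = suppressed as redundant neighbor).
#'   Sorted by rank, suppressed sites last.
#' @examples
#' cfg <- scenario_config("MeanDif", reference_length = 300, n_modifications = 4,
#'                        reads_per_group = 8, seed = 1)
#' sim <- simulate_dataset(cfg)
#' detect_modifications(sim$reads1, sim$reads2, sim$reference, min_reads = 2)
#' @export
detect_modifications <- function(events1, events2, reference,
                                 test = c("ks", "u", "t"),
                                 combiner = c("stouffer", "fisher", "none"),
                                 k = 2,
                                 weight_scheme = c("exp2", "linear", "uniform"),
                                 min_reads = 5, rank_window = 2,
                                 normalize = TRUE, clip = 5,
                                 alignments1 = NULL, alignments2 = NULL,
                                 min_signals = 3, ks_correction = TRUE) {
  test <- match.arg(test)
  combiner <- match.arg(combiner)
  weight_scheme <- match.arg(weight_scheme)

  if (normalize) {
    events1 <- normalize_reads(events1, clip = clip)
    events2 <- normalize_reads(events2, clip = clip)
  }
  if (!is.null(alignments1)) {
    events1 <- correct_reads(events1, alignments1, reference, min_signals = min_signals)
  }
  if (!is.null(alignments2)) {
    events2 <- correct_reads(events2, alignments2, reference, min_signals = min_signals)
  }

  sites <- pool_position_signals(events1, events2, reference)
  sites <- filter_low_coverage(sites, min_reads = min_reads)
  if (nrow(sites) == 0L) {
    warn("no position passed the coverage filter; empty result")
    return(new_poremod_sites(empty_sites(), config = NULL))
  }
  sites <- score_sites(sites, test = test, ks_correction = ks_correction)
  sites <- combine_neighbor_pvalues(sites, method = combiner, k = k,
                                    weight_scheme = weight_scheme)
  sites <- neighborhood_rank(sites, window = rank_window)
  sites <- sites[order(is.na(sites$rank), sites$rank, sites$ref_position), ]
  sites$signals1 <- NULL
  sites$signals2 <- NULL
  new_poremod_sites(sites, config = list(
    test = test, combiner = combiner, k = k, weight_scheme = weight_scheme,
    min_reads = min_reads, rank_window = rank_window, normalize = normalize,
    clip = clip, min_signals = min_signals, ks_correction = ks_correction
  ))
}

empty_sites <- function() {
  tibble(ref_position = integer(), ref_base = character(),
         m = integer(), n = integer(),
         n_reads1 = integer(), n_reads2 = integer(),
         D = numeric(), p_single = numeric(), log_p_single = numeric(),
         Z = numeric(), p_combined = numeric(), log_p_combined = numeric(),
         rank = integer())
}

new_poremod_sites <- function(x, config = NULL) {
  structure(x, config = config,
            class = c("poremod_sites", class(tibble())))
}

#' @export
print.poremod_sites <- function(x, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    cat(sprintf("# Candidate modified sites (test = %s, combiner = %s)\n",
                cfg$test, cfg$combiner))
  }
  NextMethod()
}
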