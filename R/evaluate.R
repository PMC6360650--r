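#' Precision and recall at ranking percentiles
#'
#' Splits a ranked site list at percentile cuts of the total number of scored
#' positions and computes, at each cut, the precision (true hits / number of
#' predictions at the cut) and recall (true hits / number of true modified
#' positions). Predictions are the accepted (non-suppressed) sites in rank
#' order; a prediction is a hit if it lies within `tolerance` bases of a truth
#' position, each truth position matched at most once (greedily, in rank
#' order).
#'
#' @param sites Ranked site table (a `poremod_sites` result, or any tibble
#'   with `ref_position` plus `rank` or `p_combined`/`p_single` ordering).
#' @param truth Integer vector of true modified positions (0-based).
#' @param percentiles Fractions of the scored positions to cut at; default the
#'   simulation grid `c(0.1, 0.25, 0.5, 1, 2, 3, 4, 5)/100`. Use
#'   `pr_percentiles("extended")` for the grid with 10-30% cuts added.
#' @param tolerance Match tolerance in bases (default 0 = exact position).
#' @return A `poremod_pr` tibble: `percentile`, `n_predictions`,
#'   `n_true_hits`, `precision`, `recall`.
#' @export
precision_recall_at_percentiles <- function(sites, truth,
                                            percentiles = pr_percentiles(),
                                            tolerance = 0) {
  if (length(truth) == 0L) abort("empty truth set: recall is undefined")
  if (nrow(sites) == 0L) abort("empty site table")
  N <- nrow(sites)
  if ("rank" %in% names(sites)) {
    ranked <- sites[!is.na(sites$rank), , drop = FALSE]
    ranked <- ranked[order(ranked$rank), , drop = FALSE]
  } else {
    key <- if ("log_p_combined" %in% names(sites)) sites$log_p_combined
           else if ("p_combined" %in% names(sites)) sites$p_combined
           else sites$p_single
    ranked <- sites[order(key, sites$ref_position), , drop = FALSE]
  }
  pos <- ranked$ref_position
  # greedy matching in rank order: hit flag per prediction
  hit <- logical(length(pos))
  avail <- truth
  for (i in seq_along(pos)) {
    d <- abs(avail - pos[i])
    jm <- which.min(d)
    if (length(jm) == 1L && d[jm] <= tolerance) {
      hit[i] <- TRUE
      avail <- avail[-jm]
      if (length(avail) == 0L) {
        break
      }
    }
  }
  cum_hits <- cumsum(hit)
  out <- lapply(percentiles, function(pct) {
    np <- min(ceiling(pct * N), length(pos))
    nh <- if (np > 0L) cum_hits[np] else 0L
    tibble(percentile = pct, n_predictions = np, n_true_hits = nh,
           precision = if (np > 0L) nh / np else NA_real_,
           recall = nh / length(truth))
  })
  structure(bind_rows(out), class = c("poremod_pr", class(tibble())))
}

#' Percentile grids for ranked-site evaluation
#'
#' @param grid `"simulation"` (default): 0.1, 0.25, 0.5, 1, 2, 3, 4, 5 percent;
#'   `"extended"`: the same plus 10, 15, 20, 25, 30 percent (used for dense
#'   modification maps such as genome-wide CpG methylation).
#' @return Numeric vector of fractions.
#' @export
pr_percentiles <- function(grid = c("simulation", "extended")) {
  grid <- match.arg(grid)
  base <- c(0.1, 0.25, 0.5, 1, 2, 3, 4, 5)
  if (grid == "extended") base <- c(base, 10, 15, 20, 25, 30)
  base / 100
}

#' Average precision/recall curves over replicates
#'
#' @param pr_list List of `poremod_pr` tibbles on identical percentile grids
#'   (or one tibble with a `replicate` column).
#' @return A `poremod_pr` tibble of per-percentile arithmetic means, with
#'   `n_replicates` attached as a column.
#' @export
average_replicate_pr <- function(pr_list) {
  if (is.data.frame(pr_list)) {
    if (!"replicate" %in% names(pr_list)) abort("expected a list or a `replicate` column")
    pr_list <- split(as_tibble(pr_list), pr_list$replicate)
  }
  grids <- lapply(pr_list, function(x) x$percentile)
  if (length(unique(lapply(grids, function(g) signif(g, 12)))) != 1L) {
    abort("percentile grids differ between replicates")
  }
  prec <- rowMeans(do.call(cbind, lapply(pr_list, `[[`, "precision")))
  rec <- rowMeans(do.call(cbind, lapply(pr_list, `[[`, "recall")))
  structure(
    tibble(percentile = grids[[1L]],
           precision = prec, recall = rec,
           n_replicates = length(pr_list)),
    class = c("poremod_pr", class(tibble()))
  )
}

#' Benchmark detection methods on a simulation scenario
#'
#' Simulates `config$n_datasets` replicate datasets and, for each, runs the
#' shared part of the pipeline once (normalization, pooling, coverage filter)
#' and then scores every requested method, returning per-replicate
#' precision/recall at the percentile grid. Replicate `r` uses seed
#' `config$seed + r` so results are reproducible and replicates independent.
#'
#' @param config A [scenario_config()]; `n_datasets` controls the replicate
#'   count and `seed` must be set.
#' @param methods Named list of method specs, each a list with elements
#'   `test` (`"ks"`, `"u"`, `"t"`) and `combiner` (`"stouffer"`, `"fisher"`,
#'   `"none"`). Default: single-base KS and KS + weighted Stouffer.
#' @param percentiles Percentile grid (see [pr_percentiles()]).
#' @param tolerance Truth-match tolerance in bases (default 0).
#' @param min_reads,k,weight_scheme,rank_window Pipeline parameters as in
#'   [detect_modifications()].
#' @return Tibble with `replicate`, `method`, and the per-percentile PR
#'   columns.
#' @export
benchmark_scenario <- function(config,
                               methods = list(
                                 ks = list(test = "ks", combiner = "none"),
                                 stouffer = list(test = "ks", combiner = "stouffer")
                               ),
                               percentiles = pr_percentiles(),
                               tolerance = 0, min_reads = 5, k = 2,
                               weight_scheme = "exp2", rank_window = 2) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(config$seed)) abort("`config$seed` must be set for benchmarking")
  out <- vector("list", config$n_datasets)
  for (rep_i in seq_len(config$n_datasets)) {
    cfg <- config
    cfg$seed <- config$seed + rep_i
    cfg$n_datasets <- 1L
    sim <- simulate_dataset(cfg)
    ev1 <- normalize_reads(sim$reads1)
    ev2 <- normalize_reads(sim$reads2)
    pooled <- pool_position_signals(ev1, ev2, sim$reference)
    pooled <- filter_low_coverage(pooled, min_reads = min_reads)

    tests <- unique(vapply(methods, `[[`, character(1), "test"))
    scored_by_test <- lapply(setNames(tests, tests),
                             function(tt) score_sites(pooled, test = tt))
    res <- vector("list", length(methods))
    for (mi in seq_along(methods)) {
      ms <- methods[[mi]]
      sc <- combine_neighbor_pvalues(scored_by_test[[ms$test]],
                                     method = ms$combiner, k = k,
                                     weight_scheme = weight_scheme)
      sc <- neighborhood_rank(sc, window = rank_window)
      pr <- precision_recall_at_percentiles(sc, sim$truth,
                                            percentiles = percentiles,
                                            tolerance = tolerance)
      pr$replicate <- rep_i
      pr$method <- names(methods)[mi]
      res[[mi]] <- pr
    }
    out[[rep_i]] <- bind_rows(res)
    rm(sim, ev1, ev2, pooled, scored_by_test)
    gc(verbose = FALSE)
  }
  bind_rows(out)
}
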