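#' File-level pipeline commands
#'
#' Thin wrappers binding the pipeline to files on disk; these back the
#' `poremod` command-line script shipped in
#' `system.file("cli", "poremod", package = "poremod")`.
#'
#' `cmd_simulate()` writes, per replicate dataset, `group1.tsv` and
#' `group2.tsv` (event tables; group 1 = modified sample), `reference.fa`,
#' `pore_model.tsv`, `truth.bed`, and (with `indel_rate > 0`)
#' `alignments1.tsv`/`alignments2.tsv`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [scenario_config()]; `seed` must be set.
#' @return Invisibly, the dataset directories written.
#' @rdname cmd
#' @export
cmd_simulate <- function(out_dir, config) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(config$seed)) abort("`config$seed` must be set")
  dirs <- character(config$n_datasets)
  for (i in seq_len(config$n_datasets)) {
    cfg <- config
    cfg$seed <- config$seed + i
    cfg$n_datasets <- 1L
    d <- file.path(out_dir, sprintf("dataset_%03d", i))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    sim <- simulate_dataset(cfg)
    write_event_tsv(sim$reads1, file.path(d, "group1.tsv"))
    write_event_tsv(sim$reads2, file.path(d, "group2.tsv"))
    write_reference_fasta(sim$reference, file.path(d, "reference.fa"))
    write_pore_model(sim$pore_model, file.path(d, "pore_model.tsv"))
    write_truth_bed(sim$truth, file.path(d, "truth.bed"))
    if (!is.null(sim$alignments1)) {
      readr::write_tsv(sim$alignments1, file.path(d, "alignments1.tsv"), progress = FALSE)
      readr::write_tsv(sim$alignments2, file.path(d, "alignments2.tsv"), progress = FALSE)
    }
    write_run_log(file.path(d, "simulate.log"), c(
      list(command = "simulate", dataset = i), unclass(cfg)))
    dirs[i] <- d
  }
  invisible(dirs)
}

#' @param group1,group2 Event TSV paths (modified and control samples).
#' @param reference_fa Reference FASTA path.
#' @param out_prefix Output prefix; `<prefix>.sites.tsv` and `<prefix>.log`
#'   are written.
#' @param sam1,sam2 Optional SAM files; when given, reads are indel-corrected
#'   against the reference before pooling.
#' @param min_mapq Minimum mapping quality for SAM records.
#' @inheritParams detect_modifications
#' @rdname cmd
#' @export
cmd_detect <- function(group1, group2, reference_fa, out_prefix,
                       test = "ks", combiner = "stouffer", k = 2,
                       weight_scheme = "exp2", min_reads = 5, rank_window = 2,
                       normalize = TRUE, sam1 = NULL, sam2 = NULL,
                       min_mapq = 0, min_signals = 3) {
  for (f in c(group1, group2, reference_fa, sam1, sam2)) {
    if (!file.exists(f)) abort(sprintf("input file not found: %s", f))
  }
  events1 <- read_event_tsv(group1)
  events2 <- read_event_tsv(group2)
  reference <- read_reference_fasta(reference_fa)
  al1 <- if (!is.null(sam1)) read_alignments_sam(sam1, min_mapq) else NULL
  al2 <- if (!is.null(sam2)) read_alignments_sam(sam2, min_mapq) else NULL
  sites <- detect_modifications(
    events1, events2, reference, test = test, combiner = combiner, k = k,
    weight_scheme = weight_scheme, min_reads = min_reads,
    rank_window = rank_window, normalize = normalize,
    alignments1 = al1, alignments2 = al2, min_signals = min_signals)
  out <- paste0(out_prefix, ".sites.tsv")
  write_site_table(sites, out)
  write_run_log(paste0(out_prefix, ".log"), list(
    command = "detect", group1 = group1, group2 = group2,
    reference = reference_fa, test = test, combiner = combiner, k = k,
    weight_scheme = weight_scheme, min_reads = min_reads,
    rank_window = rank_window, normalize = normalize,
    n_sites = nrow(sites)))
  invisible(out)
}

#' @param sites_tsv Ranked site table path (from `cmd_detect`).
#' @param truth_bed Truth BED path.
#' @param out_tsv Output PR table path.
#' @param percentiles Percentile grid (see [pr_percentiles()]).
#' @param tolerance Truth-match tolerance in bases.
#' @rdname cmd
#' @export
cmd_evaluate <- function(sites_tsv, truth_bed, out_tsv,
                         percentiles = pr_percentiles(), tolerance = 0) {
  sites <- read_site_table(sites_tsv)
  truth <- read_truth_bed(truth_bed)
  pr <- precision_recall_at_percentiles(sites, truth,
                                        percentiles = percentiles,
                                        tolerance = tolerance)
  readr::write_tsv(pr, out_tsv, progress = FALSE)
  invisible(out_tsv)
}

#' @param events_tsv Uncorrected event TSV path.
#' @param sam SAM file with the reads' alignments.
#' @param out_tsv Output path for the corrected event table.
#' @rdname cmd
#' @export
cmd_correct <- function(events_tsv, sam, reference_fa, out_tsv,
                        min_signals = 3, min_mapq = 0) {
  events <- read_event_tsv(events_tsv)
  alignments <- read_alignments_sam(sam, min_mapq)
  reference <- read_reference_fasta(reference_fa)
  corrected <- correct_reads(events, alignments, reference,
                             min_signals = min_signals, min_mapq = min_mapq)
  write_event_tsv(corrected, out_tsv)
  invisible(out_tsv)
}

write_run_log <- function(path, fields) {
  fields$poremod_version <- as.character(utils::packageVersion("poremod"))
  fields$r_version <- R.version.string
  fields$time <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  lines <- vapply(names(fields), function(nm) {
    sprintf("%s\t%s", nm, paste(format(fields[[nm]]), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
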