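#' Read and write event tables as TSV
#'
#' The interchange format is a plain TSV with columns `read_id`, `strand`,
#' `ref_position` (0-based, empty for unaligned events), `base`, `signals`
#' (comma-separated values) and optionally `event_id` (present when
#' homopolymer-shared events must round-trip). Signals are written with full
#' double precision, so write/read round-trips are lossless.
#'
#' @param path File path.
#' @return `read_event_tsv()` returns an event table tibble.
#' @export
read_event_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    strand = readr::col_character(),
    ref_position = readr::col_integer(),
    base = readr::col_character(),
    signals = readr::col_character(),
    .default = readr::col_integer()
  ), progress = FALSE)
  df$signals <- lapply(strsplit(df$signals, ",", fixed = TRUE), as.numeric)
  if (!"event_id" %in% names(df)) {
    df$event_id <- stats::ave(seq_len(nrow(df)), df$read_id, FUN = seq_along)
  }
  validate_events(df)
  as_tibble(df)
}

#' @rdname read_event_tsv
#' @param events Event table to write.
#' @export
write_event_tsv <- function(events, path) {
  validate_events(events)
  out <- events
  out$signals <- vapply(events$signals,
                        function(s) paste(sprintf("%.17g", s), collapse = ","),
                        character(1))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write pore model tables
#'
#' TSV with columns `kmer`, `mean`, `sd`. On read, the table is checked to
#' cover all `4^k` k-mers with positive standard deviations.
#'
#' @param path File path.
#' @export
read_pore_model <- function(path) {
  pm <- readr::read_tsv(path, col_types = "cdd", progress = FALSE)
  k <- nchar(pm$kmer[1L])
  if (nrow(pm) != 4^k || anyDuplicated(pm$kmer) ||
      any(nchar(pm$kmer) != k)) {
    abort(sprintf("pore model must cover all %d %d-mers exactly once", 4^k, k))
  }
  if (any(pm$sd <= 0)) abort("pore model standard deviations must be positive")
  pm
}

#' @rdname read_pore_model
#' @param pore_model Pore model tibble.
#' @export
write_pore_model <- function(pore_model, path) {
  readr::write_tsv(pore_model, path, progress = FALSE)
  invisible(path)
}

#' Read a reference sequence from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return Single character string.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  as.character(seqs[[1L]])
}

#' @rdname read_reference_fasta
#' @param reference Reference sequence to write.
#' @param name Sequence name (default "ref").
#' @export
write_reference_fasta <- function(reference, path, name = "ref") {
  x <- Biostrings::DNAStringSet(reference)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read alignments from a SAM file
#'
#' Parses a SAM file (via Rsamtools) and returns one row per usable alignment:
#' secondary, supplementary and unmapped records are dropped, as are records
#' below `min_mapq`.
#'
#' @param path SAM file path.
#' @param min_mapq Minimum mapping quality (default 0).
#' @return Tibble with `read_id`, `strand`, `ref_name`, `ref_start` (0-based),
#'   `mapq`, `cigar`.
#' @export
read_alignments_sam <- function(path, min_mapq = 0) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !bitwAnd(b$flag, 0x4) & !bitwAnd(b$flag, 0x100) &
    !bitwAnd(b$flag, 0x800) & (is.na(b$mapq) | b$mapq >= min_mapq)
  tibble(
    read_id = b$qname[keep],
    strand = as.character(b$strand[keep]),
    ref_name = as.character(b$rname[keep]),
    ref_start = b$pos[keep] - 1L,
    mapq = b$mapq[keep],
    cigar = b$cigar[keep]
  )
}

#' Read and write truth positions as BED
#'
#' Modified positions are stored as 1-base half-open BED intervals on a single
#' reference sequence.
#'
#' @param path BED file path.
#' @export
read_truth_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  as.integer(GenomicRanges::start(gr) - 1L)
}

#' @rdname read_truth_bed
#' @param positions 0-based modified positions.
#' @param chrom Reference sequence name (default "ref").
#' @export
write_truth_bed <- function(positions, path, chrom = "ref") {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = positions + 1L, width = 1L)
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a ranked site table
#'
#' Writes the detection result as a BED-compatible TSV: `chrom`, `start`,
#' `end` (0-based half-open), `ref_base`, `m`, `n`, `D`, `p_single`, `Z`,
#' `p_combined`, `rank`, sorted by genomic position.
#'
#' @param sites A `poremod_sites` table from [detect_modifications()].
#' @param path Output path.
#' @param chrom Reference sequence name (default "ref").
#' @export
write_site_table <- function(sites, path, chrom = "ref") {
  out <- tibble(
    chrom = chrom,
    start = sites$ref_position,
    end = sites$ref_position + 1L,
    ref_base = sites$ref_base,
    m = sites$m, n = sites$n,
    D = sites$D, p_single = sites$p_single,
    Z = sites$Z, p_combined = sites$p_combined,
    rank = sites$rank
  )
  out <- out[order(out$start), ]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a ranked site table written by [write_site_table()]
#'
#' @param path File path.
#' @return Tibble with `ref_position` restored from the BED interval.
#' @export
read_site_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  df$ref_position <- as.integer(df$start)
  as_tibble(df)
}
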