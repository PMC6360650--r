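# Shared fixtures and independent oracles for the test suite.

# brute-force KS distance: evaluate |F1 - F2| at every pooled sample value
# (both ECDFs are right-continuous step functions, so the supremum over the
# real line is attained at one of these evaluations)
brute_ks_D <- function(x, y) {
  m <- length(x); n <- length(y)
  ts <- sort(unique(c(x, y)))
  max(vapply(ts, function(t) abs(sum(x <= t) * n - sum(y <= t) * m), numeric(1))) / (m * n)
}

# single-read event table over consecutive reference positions
make_read <- function(signals, ref_start = 0L, bases = NULL, read_id = "r1",
                      strand = "+") {
  n <- length(signals)
  if (is.null(bases)) bases <- rep("A", n)
  event_table(read_id = read_id, strand = strand,
              ref_position = seq(ref_start, length.out = n),
              base = bases, signals = signals)
}

# uncorrected single-read event table (no reference positions)
make_raw_read <- function(signals, bases = NULL, read_id = "r1") {
  n <- length(signals)
  if (is.null(bases)) bases <- rep("A", n)
  event_table(read_id = read_id, strand = "+",
              ref_position = rep(NA_integer_, n),
              base = bases, signals = signals)
}

random_string <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# lazily-computed scenario benchmarks shared between acceptance checks
.benchmark_cache <- new.env(parent = emptyenv())

cached_benchmark <- function(name, config, methods) {
  if (!exists(name, .benchmark_cache)) {
    assign(name, benchmark_scenario(config, methods = methods), .benchmark_cache)
  }
  get(name, .benchmark_cache)
}
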