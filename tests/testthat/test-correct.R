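test_that("resegment splits signals into contiguous near-equal events, remainder leftmost", {
  s <- rnorm(30)
  out <- resegment(s, 3)
  expect_equal(lengths(out), c(10L, 10L, 10L))
  expect_equal(unlist(out), s)

  out2 <- resegment(rnorm(10), 3)
  expect_equal(lengths(out2), c(4L, 3L, 3L))

  expect_error(resegment(rnorm(3), 4), "infeasible")
})

test_that("insertion correction merges into a flank and conserves signals", {
  mk <- function(sizes) {
    event_table(read_id = "r", strand = "+",
                ref_position = c(5L, NA, 6L),
                base = c("A", "C", "A"),
                signals = lapply(sizes, function(k) rnorm(k)))
  }
  ev <- mk(c(10, 6, 10))
  out <- correct_insertion(ev, 2L)
  expect_equal(nrow(out), 2L)
  expect_equal(sum(lengths(out$signals)), 26L)
  # tie in flank sizes: merged upstream, order of signals preserved
  expect_equal(out$signals[[1]], c(ev$signals[[1]], ev$signals[[2]]))

  ev2 <- mk(c(8, 4, 8))
  out2 <- correct_insertion(ev2, 2L)
  expect_equal(nrow(out2), 2L)
  expect_equal(sum(lengths(out2$signals)), 20L)

  # smaller downstream flank wins
  ev3 <- event_table(read_id = "r", strand = "+", ref_position = c(5L, NA, 6L),
                     base = "A", signals = list(rnorm(9), rnorm(2), rnorm(4)))
  out3 <- correct_insertion(ev3, 2L)
  expect_equal(lengths(out3$signals), c(9L, 6L))
})

test_that("insertion at a read end merges with the only available flank", {
  ev <- event_table(read_id = "r", strand = "+", ref_position = c(NA, 3L),
                    base = "A", signals = list(rnorm(4), rnorm(7)))
  out <- correct_insertion(ev, 1L)
  expect_equal(nrow(out), 1L)
  expect_equal(lengths(out$signals), 11L)
})

test_that("events cannot be empty", {
  expect_error(event_table(read_id = "r", strand = "+", ref_position = 1L,
                           base = "A", signals = list(numeric(0))),
               "at least one signal")
})

test_that("deletion correction generates one additional event and conserves signals", {
  ev <- event_table(read_id = "r", strand = "+", ref_position = c(4L, 6L),
                    base = "A", signals = list(rnorm(15), rnorm(15)))
  out <- correct_deletion(ev, 5L)
  expect_equal(nrow(out), 3L)
  expect_equal(out$ref_position, 4:6)
  expect_equal(lengths(out$signals), c(10L, 10L, 10L))
  expect_equal(unlist(out$signals), unlist(ev$signals))
})

test_that("deletion correction widens the neighbor group until events are large enough", {
  ev <- event_table(read_id = "r", strand = "+",
                    ref_position = c(2L, 3L, 5L, 6L),
                    base = "A",
                    signals = list(rnorm(9), rnorm(2), rnorm(2), rnorm(9)))
  # immediate flanks hold 4 signals for 3 events at >=3 signals each: widen
  out <- correct_deletion(ev, 4L, min_signals = 3)
  expect_equal(out$ref_position, 2:6)
  expect_equal(sum(lengths(out$signals)), 22L)
  expect_true(all(lengths(out$signals) >= 3L))
})

test_that("an unsatisfiable deletion region is reported as uncorrectable", {
  ev <- event_table(read_id = "r", strand = "+", ref_position = c(1L, 3L),
                    base = "A", signals = list(rnorm(2), rnorm(2)))
  expect_warning(out <- correct_deletion(ev, 2L, min_signals = 3), "uncorrectable")
  expect_null(out)
})

test_that("homopolymer sharing follows the L_r - 4 middle-positions rule", {
  mk_run <- function(L) {
    make_read(lapply(seq_len(L), function(i) rnorm(4)), ref_start = 0L,
              bases = rep("T", L))
  }
  # L_r = 7: middle 3 positions share one event
  out7 <- apply_homopolymer_rule(mk_run(7), list(ref_start = 0L, length = 7L))
  shared7 <- out7$event_id[out7$ref_position %in% 2:4]
  expect_equal(length(unique(shared7)), 1L)
  expect_equal(length(unique(out7$event_id)), 5L) # 4 individual + 1 shared
  expect_equal(lengths(out7$signals[out7$ref_position %in% 2:4]), rep(12L, 3))

  # L_r = 6: middle 2 positions share
  out6 <- apply_homopolymer_rule(mk_run(6), list(ref_start = 0L, length = 6L))
  expect_equal(length(unique(out6$event_id[out6$ref_position %in% 2:3])), 1L)

  # L_r = 5: unchanged
  in5 <- mk_run(5)
  expect_identical(apply_homopolymer_rule(in5, list(ref_start = 0L, length = 5L)), in5)
})

test_that("a read without indels passes through correction unchanged in span and counts", {
  ref <- "ACGTACGTACGTACGTACGT"
  sizes <- sample(3:8, 20, replace = TRUE)
  ev <- make_raw_read(lapply(sizes, rnorm), bases = strsplit(ref, "")[[1]])
  out <- correct_read(ev, "20M", 0L, ref)
  expect_equal(nrow(out), 20L)
  expect_equal(lengths(out$signals), sizes)
  expect_equal(out$base, strsplit(ref, "")[[1]])
})

test_that("soft-clipped read ends are excluded from annotation", {
  ref <- "ACGTACGTAC"
  ev <- make_raw_read(lapply(1:8, function(i) rnorm(5)))
  out <- correct_read(ev, "2S5M1S", 3L, ref)
  expect_equal(nrow(out), 5L)
  expect_equal(out$ref_position, 3:7)
  expect_equal(sum(lengths(out$signals)), 25L)
})

test_that("correction conserves signals, restores reference bases, and covers the span", {
  set.seed(31)
  ref <- paste0(random_string(40), "GGGGGGG", random_string(40)) # embeds L_r = 7 run
  refc <- strsplit(ref, "")[[1]]
  cfg <- scenario_config("MeanDif", alpha = 0, reference_length = nchar(ref),
                         n_modifications = 1, reads_per_group = 30,
                         indel_rate = 0.06, seed = 31)
  sim <- simulate_dataset(cfg, reference = ref)
  raw <- split(sim$reads1, sim$reads1$read_id)
  for (id in names(raw)) {
    al <- sim$alignments1[sim$alignments1$read_id == id, ]
    input_signals <- sum(lengths(raw[[id]]$signals))
    out <- correct_read(raw[[id]], al$cigar, al$ref_start, ref)
    # conservation over distinct events
    keep <- !duplicated(out$event_id)
    expect_equal(sum(lengths(out$signals[keep])), input_signals)
    # one event row per aligned reference position, consecutive
    span <- (nchar(ref) - 4) # full-context positions 2..L-3
    expect_equal(out$ref_position, 2:(nchar(ref) - 3))
    # bases restored from the reference
    expect_equal(out$base, refc[out$ref_position + 1])
    # homopolymer rule: middle 7 - 4 = 3 positions of the G run share an event
    run_mid <- 40 + 2 + 0:2
    expect_equal(length(unique(out$event_id[out$ref_position %in% run_mid])), 1L)
  }
})

test_that("correction is deterministic given the read and alignment", {
  set.seed(32)
  ref <- random_string(50)
  cfg <- scenario_config("MeanDif", alpha = 0, reference_length = 50,
                         n_modifications = 1, reads_per_group = 5,
                         indel_rate = 0.08, seed = 32)
  sim <- simulate_dataset(cfg, reference = ref)
  a <- correct_reads(sim$reads1, sim$alignments1, ref)
  b <- correct_reads(sim$reads1, sim$alignments1, ref)
  expect_identical(a, b)
})
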