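#' Build a synthetic pore model
#'
#' Generates a table of per-k-mer signal means and standard deviations
#' emulating an R9-style 5-mer pore model on the raw picoampere scale: means
#' drawn uniformly in `mean_range` and standard deviations uniformly in
#' `sd_range`. Deterministic given `seed`.
#'
#' @param k k-mer length (default 5; 4^k entries).
#' @param seed Integer seed (default 1).
#' @param mean_range,sd_range Uniform ranges for the k-mer signal mean and sd,
#'   in picoamperes.
#' @return Tibble with columns `kmer`, `mean`, `sd` covering all 4^k k-mers.
#' @export
make_pore_model <- function(k = 5, seed = 1, mean_range = c(60, 140),
                            sd_range = c(1, 3)) {
  stopifnot(k >= 1)
  bases <- c("A", "C", "G", "T")
  kmers <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                           stringsAsFactors = FALSE)))
  set.seed(seed)
  tibble(
    kmer = sort(kmers),
    mean = runif(length(kmers), mean_range[1], mean_range[2]),
    sd = runif(length(kmers), sd_range[1], sd_range[2])
  )
}

#' Generate a random reference sequence
#'
#' @param length Sequence length in bases.
#' @param seed Optional integer seed.
#' @return A single character string of A/C/G/T.
#' @export
make_reference <- function(length = 6184, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Simulation scenario configuration
#'
#' Bundles the parameters of the paired-sample signal simulation. The four
#' scenarios gate which perturbations a modification applies to the per-5-mer
#' signal distribution:
#' * `MeanDif` — the mean is scaled by `(1 + alpha)` at modified positions
#'   only; the sd is unchanged; no neighborhood effect.
#' * `STDDif` — the sd is scaled by `(1 + beta)` at modified positions only.
#' * `Mean_STDDif` — both, still without neighborhood effect.
#' * `Mean_STDDif_NE` — both, with the effect decaying onto neighbors within
#'   2 bases: the relative mean shift is `alpha / 2^d` and the relative sd
#'   inflation `beta / (d + 1)` at distance `d`, additive over nearby
#'   modifications.
#'
#' @param scenario One of `"MeanDif"`, `"STDDif"`, `"Mean_STDDif"`,
#'   `"Mean_STDDif_NE"`.
#' @param alpha Relative mean perturbation (default 0.2).
#' @param beta Relative sd perturbation (default 1).
#' @param n_modifications Number of modified positions per dataset
#'   (default 60).
#' @param reads_per_group Reads per group (default 100).
#' @param signals_range Inclusive range of per-position signal counts, drawn
#'   uniformly per position per read (default `c(5, 15)`).
#' @param reference_length Reference length in bases (default 6184).
#' @param noise_sd Additive Gaussian noise sd as a fraction of the k-mer sd
#'   (default 0.05; 0 disables noise).
#' @param indel_rate Per-event probability of injecting a basecalling indel
#'   error into the emitted reads (default 0 = reads emitted pre-aligned).
#' @param n_datasets Number of replicate datasets for benchmarking
#'   (default 1).
#' @param k k-mer length of the pore model (default 5).
#' @param seed Integer seed making the whole dataset reproducible.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("MeanDif", "STDDif", "Mean_STDDif",
                                         "Mean_STDDif_NE"),
                            alpha = 0.2, beta = 1, n_modifications = 60,
                            reads_per_group = 100, signals_range = c(5, 15),
                            reference_length = 6184, noise_sd = 0.05,
                            indel_rate = 0, n_datasets = 1, k = 5,
                            seed = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(alpha >= 0, beta >= 0, signals_range[1] >= 1,
            reference_length >= k)
  structure(list(scenario = scenario, alpha = alpha, beta = beta,
                 n_modifications = n_modifications,
                 reads_per_group = reads_per_group,
                 signals_range = signals_range,
                 reference_length = reference_length,
                 noise_sd = noise_sd, indel_rate = indel_rate,
                 n_datasets = n_datasets, k = k, seed = seed),
            class = "scenario_config")
}

#' Perturbation weights near modified positions
#'
#' Relative mean shift `w_a` and sd inflation `w_b` induced at `query` by the
#' modifications in `mod_positions`: a modification at distance `d <= radius`
#' contributes `alpha / 2^d` to `w_a` and `beta / (d + 1)` to `w_b`,
#' additively over multiple nearby modifications.
#'
#' @param mod_positions Integer vector of modified positions (0-based).
#' @param query Integer vector of query positions.
#' @param alpha,beta Perturbation scales.
#' @param radius Influence radius in bases (default 2).
#' @return Tibble with `position`, `w_a`, `w_b` for every query position.
#' @examples
#' perturbation_weights(10, 8:12, alpha = 0.2, beta = 1)
#' @export
perturbation_weights <- function(mod_positions, query, alpha = 0.2, beta = 1,
                                 radius = 2) {
  w_a <- numeric(length(query))
  w_b <- numeric(length(query))
  for (mp in mod_positions) {
    d <- abs(query - mp)
    near <- d <= radius
    w_a[near] <- w_a[near] + alpha / 2^d[near]
    w_b[near] <- w_b[near] + beta / (d[near] + 1)
  }
  tibble(position = query, w_a = w_a, w_b = w_b)
}

# per-position sampling distributions for one group.
# Positions are the 0-based centers with a full k-mer context.
position_distributions <- function(reference, pore_model, mod_positions,
                                   scenario, alpha, beta, modified) {
  ref <- as_reference_chars(reference)
  k <- nchar(pore_model$kmer[1L])
  half <- (k - 1L) %/% 2L
  L <- length(ref)
  centers <- half:(L - (k - half) )  # 0-based, full-context centers
  starts <- centers - half
  kmers <- substring(paste(ref, collapse = ""), starts + 1L, starts + k)
  idx <- match(kmers, pore_model$kmer)
  if (anyNA(idx)) abort("pore model does not cover all reference k-mers")
  mu <- pore_model$mean[idx]
  sd <- pore_model$sd[idx]

  w_a <- numeric(length(centers))
  w_b <- numeric(length(centers))
  if (modified && length(mod_positions) > 0L) {
    radius <- if (scenario == "Mean_STDDif_NE") 2L else 0L
    w <- perturbation_weights(mod_positions, centers, alpha = alpha,
                              beta = beta, radius = radius)
    w_a <- w$w_a
    w_b <- w$w_b
    if (scenario == "STDDif") w_a[] <- 0
    if (scenario == "MeanDif") w_b[] <- 0
  }
  tibble(ref_position = as.integer(centers),
         base = ref[centers + 1L],
         mean = mu * (1 + w_a),
         sd = sd * (1 + w_b),
         noise_base_sd = sd)
}

#' Simulate one nanopore read
#'
#' Draws, for every reference position with a full k-mer context, a uniform
#' number of signals in `signals_range` from
#' `N(E_k (1 + w_a), Delta_k (1 + w_b))` plus additive Gaussian noise with sd
#' `noise_sd * Delta_k`, where `(E_k, Delta_k)` come from the pore model and
#' the perturbation weights `(w_a, w_b)` are determined by the scenario (zero
#' for unmodified reads). Uses the current RNG state.
#'
#' @inheritParams scenario_config
#' @param reference Reference sequence.
#' @param pore_model Pore model tibble from [make_pore_model()].
#' @param mod_positions 0-based modified positions.
#' @param modified Simulate a read from the modified sample? (default TRUE).
#' @param read_id,strand Read metadata.
#' @return An event table with one event per covered reference position.
#' @export
simulate_read <- function(reference, pore_model, mod_positions = integer(),
                          scenario = "Mean_STDDif_NE", alpha = 0.2, beta = 1,
                          signals_range = c(5, 15), noise_sd = 0.05,
                          modified = TRUE, read_id = "read1", strand = "+") {
  dist <- position_distributions(reference, pore_model, mod_positions,
                                 scenario, alpha, beta, modified)
  simulate_read_from_dist(dist, signals_range, noise_sd, read_id, strand)
}

simulate_read_from_dist <- function(dist, signals_range, noise_sd,
                                    read_id, strand) {
  P <- nrow(dist)
  counts <- sample(seq(signals_range[1], signals_range[2]), P, replace = TRUE)
  tot <- sum(counts)
  sig <- rnorm(tot, rep(dist$mean, counts), rep(dist$sd, counts))
  if (noise_sd > 0) {
    sig <- sig + rnorm(tot, 0, rep(noise_sd * dist$noise_base_sd, counts))
  }
  tibble(
    read_id = read_id,
    strand = strand,
    ref_position = dist$ref_position,
    base = dist$base,
    signals = vctrs::vec_chop(sig, sizes = counts),
    event_id = seq_len(P)
  )
}

#' Simulate a paired modified/unmodified dataset
#'
#' Generates a reference sequence, a pore model, `n_modifications` modified
#' positions sampled without replacement among full-context positions, and
#' `reads_per_group` reads for each group: group 1 from the modified sample
#' (perturbed per the scenario), group 2 from the matched unmodified sample.
#' Fully reproducible from `config$seed`. With `indel_rate > 0` the emitted
#' reads additionally carry injected basecalling indel errors and an
#' `alignments` table (CIGARs) is returned for use with [correct_reads()].
#'
#' @param config A [scenario_config()].
#' @param reference Optional fixed reference sequence (generated otherwise).
#' @param pore_model Optional fixed pore model (generated otherwise).
#' @return List with `reads1` (modified group), `reads2` (control group),
#'   `truth` (0-based modified positions), `reference`, `pore_model`, and
#'   `alignments1`/`alignments2` when indels were injected.
#' @export
simulate_dataset <- function(config, reference = NULL, pore_model = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(pore_model)) {
    pm_seed <- if (is.null(config$seed)) 1L else config$seed
    pore_model <- make_pore_model(k = config$k, seed = pm_seed)
  }
  if (is.null(reference)) reference <- make_reference(config$reference_length)
  L <- nchar(reference)
  half <- (config$k - 1L) %/% 2L
  candidates <- half:(L - (config$k - half))
  if (config$n_modifications > length(candidates)) {
    abort("more modifications requested than available reference positions")
  }
  truth <- sort(sample(candidates, config$n_modifications))

  dist_mod <- position_distributions(reference, pore_model, truth,
                                     config$scenario, config$alpha,
                                     config$beta, modified = TRUE)
  dist_ctl <- position_distributions(reference, pore_model, truth,
                                     config$scenario, config$alpha,
                                     config$beta, modified = FALSE)

  gen_group <- function(dist, prefix) {
    reads <- vector("list", config$reads_per_group)
    for (r in seq_len(config$reads_per_group)) {
      reads[[r]] <- simulate_read_from_dist(
        dist, config$signals_range, config$noise_sd,
        read_id = sprintf("%s_%03d", prefix, r), strand = "+")
    }
    bind_rows(reads)
  }
  reads1 <- gen_group(dist_mod, "mod")
  reads2 <- gen_group(dist_ctl, "ctl")

  out <- list(reads1 = reads1, reads2 = reads2, truth = truth,
              reference = reference, pore_model = pore_model,
              config = config)
  if (config$indel_rate > 0) {
    inj1 <- inject_indels(reads1, config$indel_rate)
    inj2 <- inject_indels(reads2, config$indel_rate)
    out$reads1 <- inj1$events
    out$reads2 <- inj2$events
    out$alignments1 <- inj1$alignments
    out$alignments2 <- inj2$alignments
  }
  out
}

#' Inject basecalling indel errors into simulated reads
#'
#' Emulates segmentation errors: with probability `rate` an event's signals
#' are merged into the previous event and its base dropped (a deletion error),
#' and with probability `rate` an event with at least two signals is split in
#' two with a spurious base (an insertion error). Returns the corrupted event
#' table (with `ref_position` blanked, as for real uncorrected reads) and the
#' corresponding alignment CIGARs.
#'
#' @param events Pre-aligned event table (e.g. from [simulate_dataset()]).
#' @param rate Per-event error probability for each error type.
#' @return List with `events` and `alignments` (`read_id`, `strand`,
#'   `ref_start`, `cigar`, `mapq`).
#' @export
inject_indels <- function(events, rate = 0.02) {
  by_read <- split(events, events$read_id)
  ev_out <- vector("list", length(by_read))
  al_out <- vector("list", length(by_read))
  for (ri in seq_along(by_read)) {
    rd <- by_read[[ri]]
    rd <- rd[order(rd$ref_position), ]
    P <- nrow(rd)
    # ops per original position: "M", "D"; insertions recorded separately
    op <- rep("M", P)
    sig <- rd$signals
    base <- rd$base
    ins_after <- vector("list", P) # inserted events following position i
    u <- runif(P)
    # deletions: never the first or last aligned position, never adjacent
    for (i in 2:(P - 1)) {
      if (u[i] < rate && op[i - 1L] == "M") {
        op[i] <- "D"
        j <- i - 1L
        while (op[j] != "M") j <- j - 1L
        sig[[j]] <- c(sig[[j]], sig[[i]])
        sig[i] <- list(NULL)
      }
    }
    v <- runif(P)
    for (i in seq_len(P)) {
      if (op[i] == "M" && v[i] < rate && length(sig[[i]]) >= 2L) {
        cut <- sample(length(sig[[i]]) - 1L, 1L)
        ins_after[[i]] <- sig[[i]][(cut + 1L):length(sig[[i]])]
        sig[[i]] <- sig[[i]][seq_len(cut)]
      }
    }
    # assemble read events and cigar
    ops <- character(0); bases <- character(0); signals <- list()
    for (i in seq_len(P)) {
      if (op[i] == "D") {
        ops <- c(ops, "D")
      } else {
        ops <- c(ops, "M")
        bases <- c(bases, base[i])
        signals <- c(signals, sig[i])
        if (!is.null(ins_after[[i]])) {
          ops <- c(ops, "I")
          bases <- c(bases, sample(c("A", "C", "G", "T"), 1L))
          signals <- c(signals, list(ins_after[[i]]))
        }
      }
    }
    r <- rle(ops)
    cigar <- paste0(r$lengths, r$values, collapse = "")
    ev_out[[ri]] <- tibble(
      read_id = rd$read_id[1L], strand = rd$strand[1L],
      ref_position = NA_integer_, base = bases, signals = signals,
      event_id = seq_along(bases)
    )
    al_out[[ri]] <- tibble(read_id = rd$read_id[1L], strand = rd$strand[1L],
                           ref_start = min(rd$ref_position), cigar = cigar,
                           mapq = 60L)
  }
  list(events = bind_rows(ev_out), alignments = bind_rows(al_out))
}
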