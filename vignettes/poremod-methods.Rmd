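---
title: "Detecting DNA base modifications from paired nanopore signal distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting DNA base modifications from paired nanopore signal distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poremod)
```

## The problem and the model

Nanopore sequencers measure the ionic current while a k-mer (here, a 5-mer)
dwells in the pore, so the current distribution at a genomic position is a
fingerprint of the local sequence chemistry. A modified base (5mC, 6mA, or a
bulky synthetic adduct) perturbs that distribution — its mean, its spread, or
its shape — both at the modified position and, because every measurement
reflects a 5-mer, at positions within a couple of bases of it.

poremod detects such modifications *de novo*, without a trained model of any
particular modification, by comparing two samples that share a known
reference sequence: one carrying modifications, one a matched unmodified
control. The price of being training-free is that the method ranks *where*
signal distributions differ; it cannot say *which* modification is present.

The pipeline is:

1. **Event correction** (`correct_reads()`): basecalled reads carry
   insertion/deletion errors, so events (runs of raw signal assigned to one
   called base) are re-anchored against the reference alignment. Inserted
   events are merged into a flanking event; deleted positions regain an event
   by re-segmenting the signals of the neighboring events; for a
   single-nucleotide run of length $L_r > 5$ the middle $L_r - 4$ positions
   share one event, since individual dwell boundaries are not resolvable
   inside long homopolymers.
2. **Normalization** (`normalize_reads()`): per read, signals are centered by
   the read median and scaled by the mean absolute deviation from the median,
   then clipped to $[-5, 5]$. One location/scale per read — not per event —
   so that position-to-position contrasts are preserved.
3. **Pooling** (`pool_position_signals()`): each reference position collects
   the normalized signals of all events anchored there, separately per group,
   giving two per-position samples of sizes $m$ (modified) and $n$ (control).
   Positions with fewer than `min_reads` distinct reads in either group are
   dropped (`filter_low_coverage()`, default 5 reads).
4. **Per-position test** (`score_sites()`): by default the two-sample
   Kolmogorov-Smirnov statistic
   $D_{m,n} = \sup_x |F_{1,m}(x) - F_{2,n}(x)|$, sensitive to location,
   scale, and shape changes alike. Mann-Whitney U and Student's t are
   available as alternatives; they are more powerful for pure mean shifts and
   essentially powerless for pure variance changes.
5. **Neighbor combination** (`combine_neighbor_pvalues()`): the p-values of a
   position and its neighbors within $k = 2$ bases are combined with the
   weighted Stouffer statistic
   $Z = \sum_i w_i \Phi^{-1}(1 - p_i) / \sqrt{\sum_i w_i^2}$, center-heavy
   weights decaying with distance. Fisher's product method is available as an
   alternative; it weights all window positions equally, which is preferable
   when true sites cluster densely (e.g. CpG-saturated genomes) and
   counterproductive when they are isolated.
6. **Neighborhood ranking** (`neighborhood_rank()`): a significant site drags
   its neighbors' combined p-values down with it, so ranked output is pruned
   greedily — in order of ascending combined p, a site within ±2 bases of an
   already-accepted site is suppressed. Accepted sites are re-ranked 1..N.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 5 reads/group | coverage filter; below this the per-site test is unstable |
| `test` | `"ks"` | per-position two-group test; `"u"`, `"t"` for known mean-shift chemistry |
| `combiner` | `"stouffer"` | neighbor combination; `"fisher"` for dense modification maps, `"none"` to rank single-base p |
| `k` | 2 bases | combination half-window, matching the 5-mer footprint of the pore |
| `weight_scheme` | `"exp2"` ($w = 2^{-|d|}$) | Stouffer weight decay; `"linear"` ($1/(|d|+1)$) and `"uniform"` available |
| `rank_window` | 2 bases | suppression half-window in the non-redundant ranking |
| `clip` | 5 | normalization clip bound (scaled units) |
| `min_signals` | 3 | smallest event size produced by re-segmentation |

The `exp2` weights mirror the empirical decay of neighborhood perturbations
(halving per base, see the simulator below); positions at sequence ends, or
next to coverage-filtered positions, combine over the available truncated
window.

## What the simulator emulates — and what it does not

`simulate_dataset()` reproduces the benchmark conditions under which this
kind of detector is normally evaluated: a 6184-bp reference, 100 reads per
group, 60 modified positions sampled uniformly among full-context positions,
and per-position signal counts drawn uniformly from 5–15 per read. Each
position emits signals from $N(E_k(1 + w_a),\; \Delta_k(1 + w_b))$ where
$(E_k, \Delta_k)$ is the 5-mer pore model entry and the perturbation weights
depend on the scenario:

* `MeanDif` — $w_a = \alpha$ at modified positions only ($\alpha = 0.2$);
* `STDDif` — $w_b = \beta$ at modified positions only ($\beta = 1$);
* `Mean_STDDif` — both, no neighborhood effect;
* `Mean_STDDif_NE` — both, decaying onto neighbors within 2 bases as
  $w_a = \alpha/2^{d}$ and $w_b = \beta/(d+1)$, additive over nearby
  modifications.

Because no public pore-model table ships with the package, `make_pore_model()`
generates a *synthetic* one: means uniform on 60–140 pA and standard
deviations uniform on 1–3 pA, the scale of an R9-style 5-mer model. Two
consequences are worth keeping in mind when reading benchmark numbers.
First, at $\alpha = 0.2$ a modified 5-mer shifts by $0.2 E_k \approx$ 12–28
pA against a 1–3 pA spread — many standard deviations — so single-base tests
saturate on `MeanDif`-type scenarios; ordering claims between methods are
meaningful there mostly as ties. Second, the simulator draws signals
independently per position and per read from clean normals plus a small
additive noise term ($N(0, (0.05\Delta_k)^2)$ by default): real nanopore data
have autocorrelated dwell artifacts, basecaller-dependent segmentation noise,
strand biases, and k-mer models that are neither uniform nor independent
across neighboring positions. Passing the simulated benchmarks therefore
demonstrates the statistical machinery end to end; it does not by itself
guarantee field performance on real squiggle data.

Reads are emitted pre-anchored to the reference (the alignment is known by
construction). `indel_rate > 0` additionally corrupts reads with
basecalling-style indel errors (an event's signals absorbed by its neighbor,
or an event split around a spurious base) together with the matching CIGARs,
which is how the event-correction module is exercised and tested.

## Numerical choices

* **KS p-values.** The p-value uses the asymptotic Kolmogorov series
  $p = 2\sum_{j\ge1} (-1)^{j-1} e^{-2j^2\lambda^2}$. Evaluating it at the
  plain $\lambda = D\sqrt{mn/(m+n)}$ is systematically conservative at finite
  $m, n$ because $D$ lives on a lattice; with per-position coverages around
  $m \approx n \approx 1000$ (100 reads × 5–15 signals) the null p-values
  visibly depart from uniform. The default therefore applies a continuity
  correction of a quarter of the combined lattice step,
  $\lambda = (D + (1/m + 1/n)/4)\sqrt{mn/(m+n)}$, chosen against independent
  null simulations, where it restores uniformity (type-I error at the 1%
  level ≈ 1%). At very small per-site sample sizes (tens of signals) no
  continuous approximation can fix the discreteness of $D$ in the mid-range;
  tail behavior remains accurate. `correction = FALSE` gives the plain
  asymptotic value.
* **Log-scale p-values.** At these effect sizes KS p-values underflow double
  precision by hundreds of orders of magnitude ($D = 1$ at effective size 500
  gives $p \sim e^{-1000}$), and every saturated site would tie at 0. All
  single-base and combined p-values are therefore carried on the log scale
  (`log_p_single`, `log_p_combined`) through `qnorm(..., log.p = TRUE)` and
  friends, and ranking uses the log values. The user-facing
  `combine_stouffer()`/`combine_fisher()` also accept plain p-values, clamped
  into $[10^{-300}, 1 - 10^{-16}]$ with a warning at the boundaries.
* **KS D.** Computed in exact integer arithmetic (ECDF differences scaled by
  $mn$), evaluating after every tie group, so the supremum is exact rather
  than accumulated in floating point.
* **Re-segmentation.** The literature specifies *that* signals are
  re-segmented around indels, not *how*; poremod splits pooled signals into
  contiguous events of near-equal size, assigning the remainder leftmost —
  deterministic and unbiased along the read. Change-point-based splitting
  would be a natural extension.
* **Insertion merge direction.** An inserted event is merged into the smaller
  flanking event (upstream on ties), minimizing distortion of the larger,
  better-anchored neighbor.
* **Deletion widening.** The flank group starts as one event per side and
  widens one event at a time (alternating, starting upstream) until every
  output event can receive at least `min_signals = 3` signals; a read that
  cannot satisfy this is dropped from annotation with a warning.
* **Degenerate inputs.** Constant or length-<2 reads cannot be normalized
  (degenerate-scale error); zero pooled variance in the t test and fully tied
  samples in the U test return p = 1 with a warning; empty groups are
  test errors upstream of the pipeline and empty *results* (nothing passes
  coverage) return an empty table with a warning.

## Design choices where the design was open

* **Normalization before correction.** Correction permutes and regroups a
  read's signals but conserves them, so the read-level median/scale are
  invariant to the order; normalizing first means the corrector operates on
  final units. A `normalize` toggle exists for pre-normalized input.
* **Suppression semantics.** "Higher rank" in neighborhood ranking is read as
  *better (smaller) combined p-value*: the best site in a neighborhood is the
  accepted representative, ties broken to the leftmost position,
  deterministically.
* **Percentile denominators.** Percentile cuts are fractions of all scored
  (coverage-passing) positions; the prediction list at a cut is the accepted
  sites in rank order, capped at the accepted count. A suppressed true
  neighbor does not count as a hit at tolerance 0; evaluation tolerance is
  configurable (±1–2) to credit the accepted representative of a true site's
  neighborhood.
* **No multiple-testing correction.** Output is a ranked list, matching how
  such detectors are used and evaluated; an FDR column can be added trivially
  by the user (`p.adjust`) if a cutoff is needed.

## Benchmark scale

The packaged benchmarks (`benchmark_scenario()`, the test suite, and
`scripts/acceptance.R`) run 20 replicate datasets per scenario at the full
study geometry (6184 bp, 100 + 100 reads, 60 modifications) — enough for
the Monte-Carlo error of a mean recall to be a few percent while keeping a
complete run in minutes on one CPU. Replicate $r$ of a benchmark seeded $s$
uses seed $s + r$, so any replicate can be regenerated in isolation.

## Known limitations

* No modification typing: the method flags positions whose signal
  distributions differ, whatever the chemical cause.
* Pooled per-position samples are clustered by read: every signal of a read
  shares that read's estimated normalization median and scale, and the
  per-position tests treat the pool as i.i.d. The estimate noise shrinks with
  read length, so at the benchmark geometry (reads spanning ~6 kb) null
  p-values are calibrated (this is checked in the test suite); for references
  of a kilobase or less the single-base p-values become noticeably
  anti-conservative. The *ranking* — the primary output — is unaffected, but
  absolute p-value cutoffs on short references should be treated with
  caution.
* Reference-dependent: true indel variation between the sample and the
  reference will be "corrected" as if it were basecalling error; supply a
  sample-adjusted reference in that case.
* Reverse-strand reads contribute to their aligned positions without any
  signal-level remapping; strand-specific modifications are best analyzed
  per strand.
* FAST5/raw ingestion is out of scope: the canonical input is the event
  table TSV (one row per called base with its signal values), plus SAM/FASTA
  for correction.
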