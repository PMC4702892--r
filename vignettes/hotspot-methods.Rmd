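---
title: "Breakpoint hotspot detection: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint hotspot detection: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svhotspot)
```

## The problem and the model

A cohort of tumour genomes yields one *breakpoint profile* per sample: the
single-base positions where structural alterations (deletions, insertions,
inversions, tandem duplications, translocations, complex events) sever or
join DNA. `svhotspot` asks where breakpoints recur across samples more
often than a uniform-placement null would predict.

The procedure treats the *sample*, not the breakpoint, as the unit of
evidence. Each breakpoint is dilated into a flanking window (default
±10 kb, so ~20 kb total), absorbing the biological and technical
uncertainty in where a recurrent lesion lands. The genome is then
segmented at the sorted distinct window boundaries of all samples into
non-overlapping bins of unequal size — the finest partition on which
every sample's coverage status is constant, so a bin's *enrichment score*
(the number of distinct samples whose windows overlap it) is well defined
base by base. Bins hit by at least `min_samples = 2` samples form the
tested family.

Significance is assessed by randomization: every breakpoint of every
sample is independently relocated uniformly over the genome (chromosome
drawn proportional to length, position uniform within it), windows are
re-extended, and the *fixed* observed bins are re-scored. The per-bin
upper-tail empirical p-value with pseudocount is
$p = (1 + \#\{S^{*} \ge S\}) / (N + 1)$ over $N$ permutations, adjusted by
Benjamini–Hochberg step-up FDR across the tested bins; adjusted
$p < \alpha$ calls a hotspot, and book-ended significant bins are merged
into single reported regions.

Assumptions worth stating explicitly: breakpoints are exchangeable across
the genome under the null (no mappability, replication-timing or
chromatin covariates); samples are independent; and per-sample breakpoint
*counts* are ancillary — randomization conserves them exactly, so the test
is conditional on each sample's burden.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `flank` | 10,000 | bases | recurrence radius; ~20 kb windows match how breakpoint tracks are conventionally rendered and how precisely recurrent lesions co-localize |
| `n_perm` | 10,000 | permutations | p-value floor 1/10,001 ≈ 1e-4, small enough for genome-wide FDR at thousands of bins |
| `alpha` | 0.05 | — | conventional FDR level on adjusted p-values |
| `min_samples` | 2 | samples | a hotspot is by definition recurrent; singleton bins are not tested and do not dilute the correction family |
| `correction` | `"bh"` | — | step-up FDR; `"bonferroni"` gives the family-wise reading |
| `min_discordant`, `min_softclip` | 2, 2 | reads | discordant pairs detect the event, soft-clips place the breakpoint at base resolution; two of each removes most one-off artefacts |
| `max_size` | 10,000,000 | bases | events larger than 10 Mb (strictly; exactly 10 Mb survives) are overwhelmingly segmental artefacts or mis-joined calls |
| `germline_tolerance` | 100 | bases | alignment jitter between independent calls of the same germline event |
| `window` (compare) | 10,000 | bases | consistent with the hotspot flank: two single-base loci "overlap" when their dilated windows would |

## Decisions made where the design was open

* **Coordinates** are 0-based half-open everywhere, on disk and in
  memory; no operation mixes conventions.
* **Multiple-testing correction** is Benjamini–Hochberg step-up by
  default — the standard correction that yields a usable hotspot
  catalogue — with plain Bonferroni available behind the same flag, so
  either reading of "corrected p < 0.05" is reproducible. The adjustment
  itself is delegated to `stats::p.adjust`; the test suite checks it
  against an independently hand-rolled step-up oracle.
* **Fixed observed bins.** The null re-scores the bins obtained from the
  observed data rather than re-segmenting each permutation: per-bin
  p-values are then well defined and comparable across permutations.
  The alternative (re-segmenting per permutation and comparing bin-count
  spectra) is deliberately out of scope; see the calibration caveat
  below for what fixing the bins costs.
* **Per-bin versus pooled null.** Each tested bin is compared against its
  own permutation distribution by default; `pooled_null = TRUE` pools all
  tested bins' permuted scores into one genome-wide null instead.
* **Randomization scope.** Relocation is genome-wide with chromosome
  probability proportional to length; `within_chromosome = TRUE`
  preserves each breakpoint's chromosome when chromosome-level covariates
  should be held fixed. Event-type labels and per-sample counts are
  always preserved; event sizes are not, because only breakpoint
  positions enter the statistic.
* **Tie handling** counts permuted scores equal to the observed score as
  exceedances (conservative upper tail), and the `+1` pseudocount keeps
  p-values strictly positive in `[1/(N+1), 1]`.
* **Reproducibility.** One master seed draws one sub-seed per permutation
  up front; each permutation re-seeds from its own sub-seed, so results
  do not depend on evaluation order, and a fixed seed plus configuration
  makes the whole analysis bit-reproducible (the CLI records both in a
  run manifest).
* **Germline matching** (the subtraction filter) requires the same event
  type and every defined breakpoint — primary with primary, mate with
  mate — within the tolerance on the same chromosome; matching whole-event
  reciprocal overlap is reserved for a future mode. Blacklist filtering
  removes a record when any of its breakpoints falls inside an interval,
  because the breakpoint, not the event span, is the unit of record.
* **Breakpoint bookkeeping.** On disk, one record is one alteration; an
  intra-chromosomal event expands to two breakpoints (both ends), an
  insertion to one, an inter-chromosomal translocation to one per
  chromosome side (`profile_breakpoints(expand_mates = )` controls this).
  The simulator's returned profiles count one breakpoint per simulated
  event — its primary locus — so planted-locus ground truth stays exact;
  the mate loci exist on the records table so the size filter is
  exercised end to end.

## What the simulator emulates — and what it does not

`simulate_profiles()` generates per-sample profiles with (i) a uniform
background burden (`background_per_sample`, default 50 events on a
100 Mb three-chromosome toy genome of 50/30/20 Mb — large enough for
stable permutation nulls, small enough for seconds-scale runs), (ii)
optional planted hotspot loci, each hitting each sample independently
with probability `penetrance` within `center ± half_width`, (iii) an
event-type mixture (deletion-heavy by default), sizes from `size_range`
(1 kb–1 Mb) and read supports from `support_range` (2–20, i.e. calls
that pass the default support filter). `simulate_germline_pair()`
additionally copies a fixed fraction of each sample's records into a
pooled normal set with ≤50 bp jitter, labelling every cancer record
somatic or germline.

The simulator deliberately does **not** reproduce real-genome structure:
no mappability or gap structure, no chromatin- or replication-associated
breakpoint rate variation, no size spectra fitted to real cohorts, no
clustered rearrangement processes (chromothripsis), and planted loci are
independent across samples. Tests passing on simulations therefore
demonstrate algorithmic correctness and statistical behaviour *under the
stated null*, not robustness to the covariate structure of real tumour
genomes — on real data the uniform null is known to be optimistic, and a
covariate-aware null would be the natural extension.

## Numerical and degenerate-input choices

* Positions and lengths are stored as doubles (exact for integers well
  past any genome size); coordinate text I/O never uses scientific
  notation.
* Windows are clipped to `[0, chromosome length)`; a zero flank yields
  the single-base interval `[pos, pos + 1)`.
* Empty inputs degrade predictably: comment-only profiles parse to zero
  records, empty blacklists and empty interval sets are identities,
  zero-sample summary groups are dropped with a warning, and hotspot
  calling refuses fewer than two profiles (recurrence is undefined).
* Support columns absent from a profile file parse as 0, so unfiltered
  input is visibly rejected by the default support gate instead of
  silently passing.
* In reports, rows tie-break by label so output order is deterministic.

## Known limitations

**Marginal calls at `min_samples = 2` are anti-conservative.** The bins
are defined by the observed window boundaries, so every tested bin exists
*because* two or more samples already overlapped it; its fixed-bin
permutation p-value is bounded near the probability that the null
re-creates that coincidence (~0.03 at the default simulation conditions),
not uniformly distributed. With many such bins, the BH threshold sits in
the bulk of the p distribution, and uniform-background cohorts report at
least one (low-score, near-threshold) hotspot in roughly a fifth to a
third of runs — the acceptance script computes this rate
(`null_positive_run_fraction`) at 20 samples × 50 breakpoints, 100 Mb,
500 permutations. High-recurrence signals are unaffected: a 90%-penetrance
planted locus is recovered in essentially every replicate
(`planted_recovery_rate`), with scores far above background. In practice:
read score-2/3 hotspots at marginal q-values as candidates only, or raise
`min_samples`, use `correction = "bonferroni"`, or tighten `alpha`.

**Other limitations.** The uniform null ignores genomic covariates; bins
are not re-segmented per permutation; hotspots are not stratified by
event type; and profile-versus-profile comparison is directional by
design (query counts against a target are not symmetric).

## Problem sizes in the test suite

The suite validates segmentation against a per-base distinct-sample
coverage oracle on hundreds of random instances (≤20 regions, ≤3 samples,
chromosomes ≤10 kb), permutation placement over 10⁵–10⁶ relocations,
BH against a hand-rolled step-up on 1,000 random vectors, and the full
caller on 150 simulated cohorts (null calibration and planted recovery at
20 samples × 50 breakpoints, 500 permutations each) — sizes chosen so the
whole suite completes in a few minutes while keeping every statistical
check adequately powered.
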