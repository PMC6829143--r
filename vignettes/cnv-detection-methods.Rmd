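---
title: "Detecting copy-number variants with window classifiers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting copy-number variants with window classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvforest)
```

## The problem and the model

A tandem duplication or deletion changes how many copies of a sequence a
genome carries relative to the reference it is mapped to. In short-read
data the observable consequences are local: the per-base depth inside the
variant shifts (up for duplications, down for deletions), the depth
*discontinuity* at its edges inflates the spread of coverage in windows
that straddle a breakpoint, read pairs that span a breakpoint acquire
aberrant insert sizes ("improper" pairs), and reads crossing a junction
split-map (supplementary alignments). Classical callers threshold one of
these signals directly; that works at high coverage and fails as coverage
drops or when variants segregate at low frequency in pooled samples,
because each individual signal drowns in sampling noise.

cnvforest instead treats calling as supervised classification of genomic
sub-windows. Six statistics are computed per sub-window — standardized
mean and median coverage, SD and IQR of standardized coverage, and
standardized counts of improper-pair and supplementary reads — and the
feature vector for a focal sub-window concatenates these statistics for
the focal tile and `k` tiles on each side. A random forest learns the
joint, noisy signature from training data in which the truth is known,
because the training data are *simulated*: CNVs are planted in the
reference, a pool of haplotypes is built, and reads are generated at the
coverage of the sample under study.

Standardization is the load-bearing convention. Coverage is divided by the
contig-wide mean (for the mean, SD and IQR statistics) or contig-wide
median (for the median statistic), both computed over **all** bases of the
contig including zero-depth ones, so standardized coverage is distributed
around 1. Inside a CNV with `c` copies on carrier haplotypes at pool
frequency `f`, its expectation is `f·c + (1 − f)`. Count statistics are
divided by the contig-wide mean count per equally-sized window; the
convention for an empty baseline is that a zero count over a zero mean
standardizes to 1 (the window is "at expectation"), and a positive count
over a zero mean is reported as the raw count. Depth counts primary and
supplementary alignment portions of non-duplicate reads, with no
mapping-quality filter; the split portions of junction-spanning reads
cover real sequence, and counting them keeps simulated and BAM-derived
depth identical (this matches `samtools depth` defaults).

## The copy-number label

Besides the three-way class, each window carries a second label: the
pool-averaged copy number of the focal sequence,
`f·c + (1 − f)·1`, with `c = 0` for deletions — 0 for a fixed deletion,
0.5 for a deletion on half the chromosomes, 1.75 for a two-copy
duplication at 75% frequency, 3 for a fixed three-copy duplication. The
label lives on the discrete grid of multiples of `1/pool_size`, and the
package deliberately treats copy-number prediction as *classification over
that grid* rather than regression: the training design makes the grid
exhaustive, exact-match accuracy is then meaningful, and the forest needs
no linearity assumption across copy levels.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `window_size` | 50 bp | sub-window tile; small enough to resolve 100 bp CNVs, large enough for a stable median |
| `k` | 5 | flanking sub-windows per side (66 features); 10 is also supported — importance profiles show signal concentrated within ~5 tiles of the focal window, which is why 5 is the default |
| `n_estimators` | 100 | forest size; 500 gives indistinguishable accuracy (a tested invariant) at 5× the cost |
| `size_range` | 100–5000 bp | planted CNV lengths, uniform |
| `insert_mean`, `insert_sd` | 500, 50 bp | fragment model; fragments are truncated at ±3 SD, which also defines the improper-pair insert gate |
| `base_error` | 0.05 | per-base substitution rate, applied only when read sequences are materialized (see below) |
| `min_probability` | 0 / 0.95 | per-replicate probability cutoff before consensus voting |
| `min_support` | 0.9–0.95 | consensus fraction required to keep a CNV call |
| reciprocal overlap | 0.5 | interval-level match criterion in evaluation |
| merge gap | 1 window | interior misclassified windows tolerated when merging runs |

The single most important practical rule is **training/test match**: a
classifier trained at one coverage degrades badly when applied at a very
different coverage (a tested ordering), so training sets should be
simulated at the coverage — and pool size — of the sample being analyzed.

## What the simulator emulates, and what it does not

Reads are placed directly in reference coordinates through the haplotype→
reference lift map instead of being mapped by an external aligner. This
preserves every signal the classifier consumes — depth shifts with
sampling noise, improper pairs at fragments spanning junctions,
supplementary records for junction-crossing reads (emitted with
soft-clipped CIGARs so SAM round-trips are faithful) — while removing the
aligner dependency. It does *not* reproduce mapping artifacts:
multi-mapping in repeats, reference bias, GC bias, or chimeric
mis-mapping. Consequently a green test on simulated data establishes that
the statistics, labels, learner and consensus machinery behave as
designed; it does not establish robustness to repeat-dense regions, which
is why repeat masking (`apply_repeat_mask()`, modes `no_repeats` /
`with_repeats`) is a first-class preprocessing step for real data, and why
real alignments enter through the same `cnv_alignments` container via
`read_alignments()`.

Base-call errors (the 0.05 substitution rate of the underlying read
simulator design) are applied only when sequences are written out
(SAM/FASTQ export from a real reference): substitution errors do not move
any of the six statistics, which depend on positions and flags alone.
Small-scale divergence parameters (`mutation_rate`, `indel_fraction`) are
carried in the configuration for provenance but likewise do not alter
coordinates.

Carrier haplotypes for each CNV are drawn without replacement with the run
seed (the assignment scheme is otherwise unconstrained); truth CNVs are
forbidden from overlapping so that window labels are unambiguous; and
duplications default to two tandem copies unless configured otherwise.

## Labeling rule at CNV edges

A window takes a CNV's class when it overlaps the CNV by **more than half
the window width**; windows touched by 1 bp up to half their width stay
`normal` but carry a `breakpoint` audit flag. Majority overlap makes edge
windows — exactly the windows whose SD/IQR features fire — labeled by
their dominant content, and keeps the class partition unambiguous given
non-overlapping truth.

## The bootstrap-consensus filter

A single simulated training set imprints its own accidents on the
classifier, which surface as false positives on real data. The remedy is
re-simulation: `n` independent training sets (seeds `base_seed + r`) give
`n` independent classifiers; each window is classified `n` times; votes
with probability below `min_probability` are converted to `normal` (so the
support denominator stays fixed at `n`); the consensus class is the
plurality, with ties broken toward `normal` and then `deletion` —
deliberately conservative; and CNV calls supported by fewer than
`min_support` of replicates are reclassified `normal`. Raising either
cutoff can only shrink the call set (a tested monotonicity), and with
`n = 1`, `min_support = 0` the machinery reduces exactly to the single
classifier. "Bootstrap" here means re-simulation of training sets, not
resampling of one training set — the former is what generates independent
classifier errors.

## Numerical choices and degenerate inputs

* **Rounding**: the coverage baseline rounds half away from zero
  (`2.5 → 3`), stated because "nearest whole value" is ambiguous at `.5`.
* **Loess baseline**: local quadratic, span 0.75, predictions clamped to
  the training coverage range and snapped to the training copy grid.
* **Probability ties**: broken in the order normal > deletion >
  duplication.
* **Zero-coverage contigs** refuse to standardize (an error), and
  coverage so low that no read pair is drawn yields an empty stream with a
  warning — both are legitimate downstream states, not crashes.
* **Trailing partial tiles** are dropped, never padded, so all statistics
  are computed on equal-width windows; the width-weighted mean of
  standardized mean coverage over a full tiling is then exactly 1, a
  tested identity.
* **Determinism**: every stochastic stage (CNV placement via an
  order-statistics construction that samples uniformly among
  non-overlapping layouts, carrier assignment, read simulation, tree
  growing) is a pure function of its seed; the C++ forest uses its own
  xorshift generator so results do not depend on compiler-specific
  distributions, and fitted models are plain R data that `saveRDS()`
  round-trips bit-compatibly.

## Design decisions that were genuinely open

* **Improper-pair definition.** Defined as a primary paired alignment
  lacking the proper-pair flag, with a mate on another contig, or with
  |insert| outside `insert_mean ± 3·insert_sd` (estimated from the file
  itself for real BAMs). The ±3 SD gate mirrors the truncation of the
  simulated fragment distribution, so in simulation every improper pair
  lies within `insert_mean + 3·insert_sd` of a true breakpoint.
* **Count standardization denominator.** Contig-wide mean count per
  window-sized bin; a formula had to be chosen and this one makes the
  statistic coverage-invariant (doubling read multiplicity leaves all six
  statistics unchanged — a tested invariant).
* **Low-coverage baseline comparison.** At 0.5× the contig median depth is
  0 and the rounding baseline degenerates: almost every window rounds away
  from copy 1, so its *window-level* "true-positive rate" is high only
  because it calls nearly everything a CNV (false-positive rate near 1).
  The package therefore compares detectors where the comparison is
  meaningful — correct CNV *calls* after merging, at 50% reciprocal
  overlap — and that is the comparison the acceptance suite makes; the
  classifier's window-level rates are reported alongside.
* **Copy-number estimation design.** Estimating high copy numbers inside
  one contig is ill-posed with contig-wide standardization (planting many
  high-copy duplications inflates the contig's own baseline). The package
  follows the relative-coverage design instead: the target sequence (a
  gene, a viral genome) lives on its own contig and `window_stats()`
  accepts a *cross-contig normalizer*, expressing target coverage relative
  to a host chromosome. The copy-number acceptance world uses exactly
  this: targets at 0–20 genome copies against a CNV-free host contig.
* **Class imbalance** is handled by the training design (CNVs are planted
  densely), not by reweighting.
* **The CNN variant** of the classifier family is not implemented — no
  architecture is specified for it — but the algorithm enum
  (`random_forest`, `extra_trees`, `decision_tree`) leaves room for
  extension; all three implemented variants share one C++ splitter, and
  the forest matches an independent implementation (scikit-learn) to
  within a point of accuracy on a common benchmark table in the test
  suite.

## Known limitations

Breakpoints are resolved to window, not base-pair, precision; inversions,
translocations and mobile-element insertions are out of scope; GC and
mappability bias are not modeled; pooled copy-number labels assume the
frequency grid of the configured pool; and very large `k` with repeat
masking discards many windows near masked regions (flanks must exist on
both sides). The simulator's clean mapping model means performance numbers
on simulated repeat-free data are an upper bound for repeat-dense real
genomes.
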