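---
title: "Methods: repeat-aware Hi-C and FISH analysis of pericentromeric heterochromatin"
author: "pchDomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-aware Hi-C and FISH analysis of pericentromeric heterochromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pericentromeric heterochromatin (PCH) — the repeat-rich,
H3K9me2/3-marked chromatin flanking centromeres — coalesces from
multiple chromosomes into nuclear chromocenters. Standard Hi-C
pipelines discard most reads originating there, because repetitive DNA
produces multi-mapping alignments. This package implements a
repeat-aware analysis of the 3D organization of PCH:

1. classify each Hi-C read end as unique-PCH, multi-mapping-PCH,
   repeat-derived-PCH, unique-euchromatic, TE-filtered or other, and
   each pair accordingly;
2. partition unique PCH–PCH contacts over 100-kb windows into
   intra-arm, inter-arm and inter-chromosome classes by sequential
   exclusion, compare them with mappability-based and empirical
   expectations, and test exceptional arm pairs with a
   label-permutation null;
3. score euchromatic H3K9me2 islands (feature ±1 kb) and TE
   neighborhoods (insertion ±2 kb) for PCH-contact enrichment against
   a matched-resampling empirical null, with an exact binomial test at
   the cohort level;
4. quantify TE-induced H3K9me2 spread from strain-paired ChIP
   coverage; and
5. analyse quantitative FISH focus-distance distributions (natural
   threshold, overlap fractions, group tests).

A seed-deterministic synthetic-data layer generates every input format
with planted, recoverable structure, so the full pipeline is testable
without any external download.

## Coordinate conventions

Internally every interval lives in a `GRanges` (1-based, closed), the
native Bioconductor convention; BED and bedGraph conversion is
delegated to `rtracklayer` at the I/O layer, and pairs tables carry
1-based positions on disk. All scientific definitions below are stated
in widths and distances, which do not depend on the convention.

## Read-end and pair classification

An end is called from the precedence: canonical-TE filter first
(alignment to a TE library, supplied as a flag by the I/O layer), then
catalogued heterochromatic repeats (these alignments target a separate
repeat reference and carry no genomic position), then positional
calls: inside PCH, mapping quality ≥ 30 is unique and mapping quality
0 is multi-mapped (the value aligners assign to ambiguous placements);
inside the conservatively derived euchromatin, quality ≥ 30 is unique.
Everything else — including PCH ends with intermediate quality
(0 < MAPQ < 30) and ends in the 0.5-Mb boundary buffer — is `OTHER`
and excluded. Pairs of two non-unique PCH ends are discarded as
unlocatable; euchromatin–PCH pairs accept all three PCH categories at
the heterochromatic end, because the euchromatic end alone localizes
the contact.

Euchromatin is defined conservatively: each arm minus PCH minus a
0.5-Mb buffer inward of every PCH boundary (`eu_offset_bp`, default
500,000). Chromosomes listed as fully heterochromatic (the 4th and Y)
contribute no euchromatin; their arms are forced to be entirely PCH.

## PCH–PCH contacts

Unique PCH–PCH pairs are tallied over 100-kb windows tiled left to
right across each PCH interval, keeping the final partial window: the
windows define marginal weights and matrix layout, and dropping
partial tails would silently delete PCH mass. Same-arm pairs closer
than 10 kb are removed (local polymer neighborhood, not long-range
contact); separation is undefined across arms, so cross-arm pairs are
always retained, and same-window pairs surviving the filter count as
intra-arm.

The sequential exclusion proceeds: all pairs → intra-arm cells
excluded → intra-chromosome cells excluded. Expected class proportions
come from per-arm weights `w`: `2 w_a w_b` for `a ≠ b` and `w_a^2` for
the intra-arm aggregate, normalized over the classes a level allows.
Two weight sources are supported: the number of mappability-one bases
in each arm's PCH (the theoretical expectation; multiplied by mean
copy number under an equal sex ratio — autosomes 2, X 1.5, Y 0.5 —
when requested, as appropriate for unsexed embryo pools), and the
count of unique-PCH read ends per arm (the empirical expectation,
never sex-adjusted because ploidy is already in the counts).

Significance of a target arm pair uses a one-sided permutation test:
each of the 10,000 permutations shuffles the second-end arm labels
across the level-retained pairs, preserving both marginal arm
distributions; pairs falling into level-excluded classes after
shuffling leave that permutation's denominator. The permutation unit
is a design decision — the shuffle of second ends is the standard
contact-matrix null that holds marginals fixed — and is isolated in
one function so an alternative (e.g. window-label rotation) can be
substituted. The p-value uses the +1 pseudocount convention,
`p = (1 + #{perm ≥ obs}) / (1 + n_perm)`, so the smallest attainable
value at 10,000 permutations is 1/10,001 and zero is never reported.
An exact mode enumerates all `n!` pairings for small inputs and is
checked in the test suite against an independent enumeration oracle.

## Euchromatin–PCH contact scoring

For each query window, the informative pairs are those with one end
mapped uniquely inside the window; the statistic is the fraction whose
other end is any of the three PCH categories, with a per-arm breakdown
from unique-PCH other ends only. A pair with both unique ends inside
the same window is counted once in the denominator (its other end is
euchromatic either way). Windows with fewer than 1,000 informative
pairs are excluded — at that depth the fraction estimate is dominated
by sampling noise and boundary effects. No minimum-separation filter
applies here; that filter belongs to the PCH–PCH analysis.

The null is matched resampling: 200 independent sets of random
euchromatic regions, each mirroring the query set — one region per
query, on the same arm, of the same size (islands) or of a size drawn
from the same size-quantile bin (TEs, whose windows derive from
point-like insertion calls). Null regions never overlap any
H3K9me2-enriched interval, honouring "non-enriched" as a property of
the genome, not just of the query under test. The empirical p-value of
a query pools all non-excluded null fractions sharing its (arm,
size-quantile) stratum: `p = (1 + #{null ≥ obs}) / (1 + #null)`. The
stratification granularity is quartiles of the query set's window
sizes, computed separately per analysis; pooling across sets (rather
than set-level summaries) follows from the null being a population of
random regions. Nominal significance is p < 0.05 with no per-region
multiplicity correction; instead the cohort-level check asks whether
more regions reached significance than the 5% expected under the
null, with an exact binomial test under the two-sided
point-probability (minlike) convention — the sum of `P(X = j)` over
all `j` with `P(X = j) ≤ P(X = k)`. The minlike convention is the one
that reproduces the published cohort p-values from their printed
counts (e.g. 8 of 106 at the 5% null gives 0.26, where a one-sided
tail would give about 0.16). When two replicate pair sets are
analysed, each draws its own independent null ensemble, and the
query's unique end may be either mate (the definition is symmetric in
the two ends).

## TE-induced H3K9me2 spread

Enrichment around a TE is profiled on 1-kb bins over ±20 kb:
`log2((chip + 1) / (input + 1))` after scaling both tracks to a common
library size of 10^6 (reads-per-million), with bins overlapping other
annotated TEs or islands masked. The between-strain spread operator
compares the TE-carrying (focal) strain with the mean of the wildtype
strains: per side of the insertion, the spread extent is the maximal
contiguous run of bins starting at the anchor where the focal excess
exceeds `delta` (default 0.5 log2 units); the magnitude is the mean
percent increase `100·(2^(focal − wildtype) − 1)` over those bins; a
TE spreads if the total extent reaches 1 kb. The defaults (1-kb bins,
±20-kb extent, delta 0.5) bracket the scale of published spread
(average 4 kb, maximum 18 kb); the original between-strain operator's
exact smoothing and thresholds are not printed anywhere we could
consult, so this contiguous-run reconstruction is the package's own,
with every constant exposed as an argument. Averaging the wildtype
strains (rather than taking a per-strain minimum) is a documented
switch-point. Population frequencies of TEs with versus without PCH
contact are compared with group means and a Welch two-sample t-test on
the raw frequencies; frequency estimation itself is out of scope and
enters as a table.

## FISH distance statistics

The published distance histograms separate "overlapping" from
"non-overlapping" nuclei at a visually drawn threshold. The
reproducible surrogate implemented here estimates the kernel density
of the per-nucleus distances (Gaussian kernel, Silverman's
rule-of-thumb bandwidth) on [0, max]; if the density has two or more
modes, the natural threshold is the density minimum between the first
two. Boundary grid points count as modes when density falls away from
them (the near-zero peak of overlapping foci typically peaks at or
near zero); modes below 5% of the maximum density are discarded as
kernel wiggle, and two modes must be separated by a valley dipping
below 80% of the smaller peak — a prominence rule that rejects
shoulder artifacts, verified on simulated unimodal samples. A
unimodal distribution (wildtype-like) yields no threshold. A hard
floor of 30 nuclei keeps the density estimate meaningful (the
published panels used ≥ 70). Group comparisons use the two-sided
Mann–Whitney test on distances — divided by the nuclear radius when
the relative-distance mode is requested — and Fisher's exact test on
overlap counts at a single threshold shared by both groups (per-group
thresholds are reported but not tested). Overlap is strict:
`distance < threshold`.

## The synthetic-data layer

The simulators generate the statistical structure the analysis
assumes, at desk scale, deterministically from one seed.

**Toy genome.** Four major arms of 2.4 Mb each carrying a 0.5-Mb
centromere-proximal PCH block, plus a fully heterochromatic 0.4-Mb 4th
chromosome: 10 Mb in total, 24 PCH windows of 100 kb, and PCH at 24%
of the genome — proportionally comparable to a heterochromatin-rich
fly genome while small enough that every analysis runs in minutes. The
central 20% of each PCH block has mappability zero, emulating
unmappable satellite arrays. Islands and TEs are placed in derived
euchromatin only, either packed without overlap (`spaced`, for ChIP
profiling, where features must not invade each other's windows) or
i.i.d. uniform (`uniform`, the placement matched by the i.i.d. null
resampling and therefore the right design for calibration
experiments).

**Hi-C pairs.** The first end is uniform over the genome; the second
follows a mixture of an intra-arm power-law distance decay `s^(−α)`
(support from 1 kb, so the 10-kb separation filter is exercised), a
uniform cross-arm background of total weight 0.1 redistributed by any
planted arm-pair multipliers, and, for first ends inside a planted
query window with multiplier `m > 1`, a PCH-routed component of
probability `min(0.95, m·0.05)`. MAPQ emission: PCH ends become
repeat-derived with probability 0.05 (losing their position),
mid-quality (5–29) with 0.02, multi-mapped with 0.10 or when in a
zero-mappability segment; euchromatic ends are TE-filtered with 0.005
and mid-quality with 0.02. These rates exercise every category while
keeping roughly two thirds of PCH ends unique.

α = 1 is the default decay, consistent with polymer-physics
expectations for chromatin at these scales; under it the intra-arm
class dominates the level-all partition (≈ 0.93–0.95 here). For
euchromatin–PCH **calibration** runs the generator uses α = 2: the
steep decay confines intra-arm contacts locally, so euchromatic
windows contact PCH almost exclusively through the homogeneous
background term — the homogeneous-generation condition under which
matched resampling is expected to be calibrated. (Under α = 1 the
strong distance-to-PCH gradient interacts with the disjoint
query/null placement supports and inflates the tail by a few percent;
that is a property of the matched-null design under strong gradients,
not of the implementation, and the calibration experiment is defined
under homogeneity.)

**Planted arm-pair contacts.** The demonstration plants a 20×
multiplier on the 3L–4 cross weight. At 10^5 simulated pairs the toy
genome yields only a few hundred cross-chromosome unique PCH–PCH
pairs, and planting inflates the permutation null's own marginals; at
20× the observed proportion sits more than 1.5 null standard
deviations above the maximum of 100,000 permutations, so the
10,000-permutation test returns its minimum attainable p (1/10,001)
essentially always, while 10× reaches p < 0.05 but not reliably the
minimum. The multiplier was fixed at 20× from that power analysis
before the acceptance checks were frozen.

**ChIP tracks.** Input coverage is flat (100 per base). Enrichment is
planted directly on the scale the estimator measures: for a planted
log2 fold `p`, the chip value satisfies
`chip = (input + 1/k)·2^(p+ε) − 1/k` with `k` the common
reads-per-million factor and `ε` per-kb Gaussian log-noise (sd
`chipNoiseSd`); every track is brought to exactly the same total
(2×10^9) by a compensating block inside chr4 PCH, far outside any
profiled window. Equal totals make the normalization factor identical
across strains, so with zero noise the spread operator recovers the
planted extent (4 kb per side) and magnitude (100%) *exactly* — the
plant inverts the estimator, which is precisely what a recovery test
wants. With noise σ = 0.1 a single TE's 4-bin magnitude estimate has
≈ 8% standard deviation, so magnitude recovery is assessed on the mean
across the planted TEs (extent is still checked per TE, within one
bin). Shared islands are enriched fourfold in all strains; spread is
focal-only.

**FISH distances.** The mixture
`π·|N(0, 0.1)| + (1 − π)·N(1.5, 0.3)` µm (truncated at 0), with
π = 0.4 by default and nuclear radii `N(2.5, 0.3)` µm — a near-zero
overlapping peak against a ~1.5-µm background, the shape the
published bimodal panels display. π = 0 produces the wildtype-like
unimodal case.

**TE frequencies.** Exponential spectra truncated at 1 with group
means 9.7×10^-4 (with PCH contact, n = 14) and 9.6×10^-3 (without,
n = 92), the published group means and sizes.

What the simulators do *not* emulate: sequence-level artifacts (no
FASTQ, no aligner in the loop — classification inputs are
post-alignment abstractions), Hi-C ligation artifacts, copy-number
variation between strains, position-dependent mappability inside
euchromatin, overdispersed ChIP noise, and 3D image segmentation.
Passing tests therefore demonstrate the correctness and statistical
calibration of the analysis under its stated model, not robustness to
every artifact of real libraries.

## Problem sizes and numerical choices

The analyses ship with these study-condition sizes: territory
demonstration 10^5 pairs; null calibration 400 query regions of
1–4 kb, 200 null sets and 2.5×10^6 pairs (so every 3–6-kb window
clears the 1,000-pair floor); planted-recovery 25 regions of 12 kb,
5× multiplier and 3.5×10^6 pairs (≥ 5,000 informative pairs per
region); spread recovery 6 TEs; FISH 500 nuclei. Ties in the
permutation and empirical p-values are counted in the tail (≥), both
tests use the +1 pseudocount, and the binomial test follows
`stats::binom.test`'s minlike tie handling (point probabilities equal
up to a 10^-7 relative tolerance count as ties). Degenerate inputs are
errors where the result would be meaningless (empty matrix after
exclusion, all-zero weights, no euchromatic space for a null set,
fewer than 30 nuclei) and flagged result states where the method
defines them (regions under the pair floor).

## Known limitations

The spread operator is a reconstruction, not a reimplementation, of
the original between-strain method. The empirical permutation null is
one of several defensible exchange schemes; under extreme marginal
inflation its power is limited by the retained-pair count. Matched
resampling is only guaranteed calibrated under homogeneous contact
generation; with strong within-arm gradients it can be mildly
anticonservative, which real analyses mitigate exactly as the method
prescribes — by stratifying on chromosome and size quantile. The
FISH threshold is a KDE surrogate for a manual call; its bandwidth
rule is exposed and logged.
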