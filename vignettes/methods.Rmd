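---
title: "Methods: cohort copy-number, LOH and breed association in hscna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort copy-number, LOH and breed association in hscna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscna)
```

## The analysis problem

Canine histiocytic sarcoma (HS) is an aggressive dendritic-cell/macrophage
malignancy with a strongly elevated incidence in two breeds, the Bernese
Mountain Dog (BMD) and the Flat-Coated Retriever (FCR). On a 1-Mb BAC
array, each tumor is assayed against breed-matched reference DNA and
reported as per-clone log2 tumor:reference ratios. `hscna` implements the
cohort-level analysis of such data:

1. per-case copy-number aberration (CNA) calling from the log2 profile;
2. cohort penetrance (percent of aberrant cases gained/lost per 1-Mb
   interval) and recurrence classification;
3. microsatellite loss-of-heterozygosity (LOH) scoring from paired
   tumor/blood peak areas;
4. per-region breed association with permutation-based family-wise error
   (FWER) control;
5. PCA of the case-by-interval aberration matrix for population
   substructure.

Because no per-case raw data are publicly deposited for this tumor
cohort, the package ships a synthetic-cohort generator whose *planted*
structure encodes the published cohort frequencies; every pipeline stage
is exercised against that stated world.

## CNA calling

A case profile is processed per chromosome:

* **Smoothing.** A moving median of width `smoothing_window` (default 5
  clones) with symmetric windows that shrink, staying odd, at chromosome
  ends. Missing clones are excluded from each window rather than imputed.
  The original analysis used a published breakpoint smoother whose
  genetic-algorithm internals and settings are not reproducible from the
  text; the moving median is a documented stand-in behind a single
  interface (`smooth_profile()`), chosen because only the thresholds
  applied to the smoothed profile are documented. Whether thresholds were
  originally applied to smoothed or raw values is unstated; `hscna`
  applies them to smoothed values and records this in the run log.
* **Thresholding.** Gain where smoothed log2 >= log2(1.15) (~0.2016),
  loss where <= log2(0.85) (~-0.2345); these correspond to the published
  tumor:reference ratio cuts of 1.15:1 and 0.85:1.
* **Segment extraction.** Maximal runs of identical non-neutral state
  with at least `min_segment_clones` (default 2) members become segments.
  A k-clone run on the 1-Mb grid spans k Mb: `start_mb` is the first
  member clone's position and `end_mb` the last member's position + 1
  (half-open), matching how region sizes are quoted on this array design
  (a 47-53 Mb segment covered by clones 47..52 is "6 Mb").
* **Homozygous deletions.** A loss segment whose mean *raw* log2 falls
  below -1.0 is flagged; the raw mean is used because the published
  criterion is a per-locus ratio statement, not a smoothed quantity.

A case is *aberrant* iff it has at least one called segment; flat cases
are excluded from all downstream denominators.

Single-clone events cannot be called (`min_segment_clones = 2`), and the
window-5 median cannot recover runs shorter than 3 clones; both limits
are consequences of surveying the genome at 1 Mb and are treated as the
array's design resolution.

## Penetrance and recurrence

For every grid cell `[pos, pos+1)`, penetrance is the percentage of
aberrant cases with a segment of the given state overlapping the cell
(half-open overlap), rounded to one decimal. The denominator is the
aberrant stratum only. Cells at or above 30% are *recurrent*, at or above
50% *highly recurrent* (both inclusive). `merge_regions()` joins maximal
runs of adjacent qualifying cells with no gap tolerance; cohort region
*counts* are reported descriptively but never asserted, because the
original merging rule is unstated and a 50%-threshold merge can join or
split neighbouring sub-regions depending on convention.

## LOH scoring

For a microsatellite with two alleles, the allelic ratio is
AR = area(peak 1)/area(peak 2) and the allelic imbalance
AI = AR(tumor)/AR(blood). Deletion (LOH) is called when AI >= 1.5 or
AI <= 0.67, boundaries inclusive. Decisions made where the source is
silent:

* **Allele ordering.** Peak 1 is the shorter allele, applied identically
  to tumor and blood of a marker, so orientation cancels in AI.
* **Informativeness.** The germline must be heterozygous with two
  observed peaks and minor/major area >= 0.2 (stutter guard).
* **Threshold asymmetry.** 0.67 is used literally, as printed. Note
  1/1.5 = 0.667 != 0.67, so the thresholds are not exactly reciprocal:
  relabelling alleles maps AI to 1/AI and can flip the call only for AI
  inside [0.66, 0.68]; the test suite asserts label-swap stability only
  outside that band.
* Cases with no informative marker are *indeterminate*, excluded from
  cohort LOH percentages rather than counted negative.

## Breed association with permutation FWER control

Each region (either merged recurrent regions or an explicit region file)
yields a 2x2 table of breed x carrier status over aberrant cases, tested
with a two-sided Fisher's exact test using the point-probability rule
(sum of all table probabilities <= the observed table's, with 1e-7
relative tie tolerance). Degenerate margins return p = 1 with a warning
so genome scans survive monomorphic regions.

FWER control permutes *breed labels* (preserving each case's aberration
vector, hence inter-region correlation), records the minimum p across
regions per permutation, and sets the per-test cutoff to the
ceiling(alpha * n)-th smallest minimum p. A region is significant when
its observed p is strictly below the cutoff. Because label permutation
fixes both table margins, each region's p is a function of one cell
count only; p-values are precomputed per region and looked up, so 10,000
permutations cost a matrix product. The Fisher p distribution on finite
2x2 tables is discrete and conservative; with independent balanced
regions the empirical cutoff therefore sits ~1.2-1.4x above the Šidák
form 1-(1-alpha)^(1/m), which the property suite asserts as a band.

Epidemiology: ages are compared with a Mann-Whitney U test (midranks;
exact enumeration when both samples <= 8, else normal approximation with
tie-corrected variance and continuity correction; U is the smaller
one-sided statistic). Tumor location is collapsed to internal-organ
involvement yes/no for a 2x2 Fisher test, because the headline published
contrast is exactly that margin; a full 2x5 exact test is out of scope.

## PCA substructure

Aberrant cases are encoded per 1-Mb cell as -1 (loss), 0, +1 (gain); the
original feature encoding is unstated and this is the minimal
representation of penetrance-style data. Columns are centered, not
scaled (shared scale by construction); eigenvalues are squared singular
values over (n-1). Component signs are canonicalized by making each
component's largest-magnitude loading positive. Scores are tested
against binary groupings (geography, breed, location) with the same
Mann-Whitney machinery; the first 5 components are examined for
geography and the first 4 for breed/location, mirroring how the original
analysis reported them.

## The synthetic cohorts: what they emulate, what they do not

`fixture("F1")` builds a 104-case cohort (56 BMD + 30 FCR aberrant, 15
BMD + 3 FCR flat). Seven recurrent segments are planted with *exact*
carrier counts out of 86 so cohort penetrance at interior cells is a
deterministic ratio: CFA16 47-53 loss in 74 (86.0%), CFA16 41.8-44.2
loss in 73 (84.9%), CFA11 43-46 loss in 54 (62.8%, two carriers
homozygous at -1.2), CFA22 59-62 loss in 48 (55.8%), CFA26 36-40 loss in
35 (40.7%), CFA5 34-37 gain in 23 (26.7%), CFA31 20-26 loss in 53
(61.6%). Background (non-recurrent) CNA counts per aberrant case follow
a negative binomial calibrated so *total* counts target mean 30.7, sd
17.6; segment sizes follow gamma models targeting mean 32.5 Mb (loss)
and 23.1 Mb (gain); background segments avoid all planted loci and keep
3 Mb gaps so the smoother never merges them and penetrance at planted
cells is governed by planting alone. Probe noise is N(0, 0.05) per
clone; flat profiles are pure noise.

Numerical choices worth recording:

* **Planted magnitudes are ±0.45 log2** (ratios ~1.37 and ~0.73, i.e.
  single-copy change at roughly 63-73% tumor content), not a smaller
  value nearer the thresholds. This is forced by a margin analysis: the
  loss threshold is -0.2345, and for a 3-clone planted segment every
  member's window-5 median equals the plant value plus the maximum of ~3
  noise draws. At ±0.32 the margin is 1.7 sigma and ~12% of carriers of
  a 3-clone segment would be eroded, which is incompatible with
  recovering planted penetrance to one decimal; at ±0.45 the margin is
  4.3 sigma and the erosion probability is ~2e-5. The homozygous
  magnitude is -1.2.
* **Chromosome lengths** are approximate, rounded canFam2 autosome
  lengths bundled as a plain-text table; they only bound positions and
  lay out the grid.
* Cases drawing extreme background counts can saturate the genome;
  unplaceable segments are skipped, which truncates the extreme right
  tail of the count distribution slightly. Realized cohort means stay
  within the ±2 SE acceptance band across seeds.
* Ages are truncated normals (BMD 7.7 ± 1.9 on [2, 12]; FCR 8.6 ± 1.7 on
  [5, 12]); location category probabilities reproduce the published
  breed contrast (internal-organ involvement 0.87 BMD vs 0.48 FCR);
  geography is assigned independently of CNA structure (BMD France
  probability 33/101; FCR all USA).

`fixture("F2")` plants the 13 breed-associated loss regions at carrier
fractions 0.80 (FCR) vs 0.10 (BMD) with exact per-breed counts, plus the
seven F1 regions re-planted breed-balanced as decoys. Two deliberate
choices: planted extents are padded to a minimum of 3 grid clones (three
of the thirteen printed regions span only 1-2 Mb, below the smoother's
recovery limit; real lesions extend beyond the significant interval,
and the association scan still tests the *printed* coordinates), and the
background rate is light (mean 6 per case). The light background is a
variance argument: the breed contrast contributes a between-group
eigenvalue of roughly n_BMD n_FCR / n^2 x |delta|^2 ~ 11 to the PCA,
and the full F1 background model generates random long-segment
covariance with top eigenvalues of the same order, which would push the
breed component below rank 4. Region indicators are unaffected either
way because background avoids planted loci.

`fixture("F3")` describes 46 paired tumor/blood cases (26 BMD, 20 FCR)
genotyped at a synthetic 7-marker panel flanking the CFA11 CDKN2A/B
region, every case planted with LOH (AI drawn from [1.6, 2.8] or
[0.4, 0.62]) at 1-3 informative markers, plus 11 additional cases of
which 6 carry LOH. Blood heterozygosity is 0.75 per marker; paired cases
are guaranteed at least one informative marker. Balanced markers draw AI
from [0.85, 1.18], inside the no-call band with margin.

What a green test does **not** establish: the generator has no dye bias,
GC waves, segmentation-breakpoint uncertainty, stromal-contamination
gradients, or marker stutter; penetrance recovery on F1 shows the
pipeline arithmetic is right under the stated noise model, not that the
thresholds would perform identically on raw scanner output.

## Seeds and reproducibility

Identical `(fixture_spec, seed)` pairs produce byte-identical files.
Exact-count planting makes the deterministic acceptance quantities
(aberrant fraction, planted-locus penetrance, region counts, LOH counts)
seed-invariant; only the background-count mean and permutation cutoff
vary (mildly) with the seed. Every CLI stage writes its resolved
configuration, including the seed, next to its outputs.

## Known limitations

* The stand-in smoother is not the original segmentation algorithm; a
  faithful port could be substituted behind `smooth_profile()`.
* Region counting conventions (hence "31 recurrent regions"-style
  totals) are descriptive only.
* The permutation cutoff depends on the region inventory entering the
  scan; the published inventory is unknown, so the cutoff value itself
  is not a comparison surface.
* The 2x5 location-by-breed exact test, survival analysis, ploidy and
  purity estimation are out of scope.

## Worked example

```{r example, eval = FALSE}
library(hscna)
sim <- simulate_cohort(fixture("F1", seed = 42))
cohort <- call_cohort(sim$ratios, sim$map)
length(cohort$aberrant_ids)        # 86
track <- compute_penetrance(cohort, sim$map)
subset(track, chrom == "CFA16" & start_mb == 50)$pct_loss   # 86.0
summarize_cohort(cohort, sim$meta)
```
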