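---
title: "Detecting postzygotic mosaicism from twin allelic ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting postzygotic mosaicism from twin allelic ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(twinmosaic)
```

## The model

Monozygotic co-twins inherit the same germline genome, so at any locus their
expected alternative-allele fractions are equal: 0 for a homozygous-reference
genotype, 0.5 for a heterozygote, 1 for a homozygous-alternative genotype. A
mutation acquired *after* the twinning event is carried by only a fraction
$f$ of one twin's cells, and because an SNV sits on one of two haplotypes it
shifts that twin's expected allele fraction by $f/2$. The observable is the
**allelic ratio** $r = k / d$ (alternative reads $k$ out of depth $d$), and
the test statistic is the signed between-twin **allelic-ratio difference**

$$\Delta r = r_A - r_B \in [-1, 1],$$

computed with a fixed twin ordering. Read counts at a locus are modelled as
$k \sim \mathrm{Binomial}(d, f)$, so at moderate depth $\Delta r$ is noisy;
the design therefore sequences each twin on two platforms (a high-depth one,
about 40X, and a low-depth one, about 13X) and requires the signal to
replicate across them.

## The candidate filter chain

`detect()` applies five stages in a fixed order, recording the locus count
after each:

1. **Region restriction** (`filter_regions()`): keep loci inside
   high-confidence regions (GIAB-style BED) and outside repeat regions
   (RepeatMasker-style BED). Coordinates follow the format standards: BED is
   0-based half-open, VCF/TSV positions and all internal keys are 1-based.
2. **Double hom-ref removal** (`drop_double_homref()`): a locus where both
   twins are homozygous reference carries no between-twin information. A
   twin is called hom-ref when every one of its tracks supports it — by the
   genotype call where one is present, by `alt_count == 0` otherwise. This
   per-track rule uses genotype evidence when available without letting a
   missing call on one platform mask alternative reads on the other.
3. **Clear-call filter** (`clear_call_filter()`): keep loci where at least
   one twin is *clearly not mosaic*: its ratio lies within a tolerance
   (default 0.05, strict `<`) of the **same** canonical value (0, 0.5 or 1)
   on **both** platforms. The platform scope is a deliberate choice — the
   strictest reading of "clearly": a twin whose two platforms point at
   different canonical states is not a clear call.
4. **ARD threshold** (`threshold_filter()`): keep loci with
   $|\Delta r| > t$ on both platforms, strict inequality, default
   $t = 0.25$.
5. **Sign matching** (`classify_matching()`): a candidate is *matching* when
   $\Delta r$ has the same sign on both platforms, *nonmatching* on opposite
   signs. A zero ARD on either platform leaves the sign undefined and the
   locus out of both tallies (with $t > 0$ this cannot occur after stage 4;
   the case matters only for threshold sweeps at $t = 0$).

Loci called on one platform but absent from the other's input are dropped at
the join (`join_tracks()` intersects the four tracks by full locus key), as
are loci whose ref/alt alleles disagree between tracks and loci with zero
depth in any track — these have no comparable ratio. Multi-allelic records
and indels are skipped at parse time: the method addresses biallelic SNVs.

## Matching statistics

Under pure noise the two platforms' ARD signs agree independently with
probability 0.5, so `matching_test()` applies the exact two-sided binomial
test against 0.5 (for $p_0 = 0.5$ this is exactly twice the smaller tail)
with a Clopper–Pearson 95% interval, and `true_positive_estimate()` reports
the matching excess $2\,n_\text{match}/N - 1$: false positives split evenly
between signs, so the excess of matching over nonmatching loci estimates the
true-positive content of the candidate set. `threshold_sweep()` repeats
stages 4–5 over a grid of thresholds.

`heritability_bias()` is the closed-form companion example for twin
modelling: if mosaicism erodes the additive genetic correlations to
$r_{MZ}, r_{DZ}$ while a Falconer-style model still assumes $1$ and $0.5$,
the recovered additive variance is $2 a^2 (r_{MZ} - r_{DZ})$ — e.g. 0.3465
instead of 0.35 for a 1% erosion. It is an illustration, not a
variance-components fitter.

## Null calibration and a numerical subtlety

`simulate_fp_rate()` draws, per locus, independent alternative-read counts
$\mathrm{Binomial}(40, 0.5)$ and $\mathrm{Binomial}(13, 0.5)$ for both twins
and flags the locus when $|\Delta r| > t$ on both platforms — the chance of
calling a mosaic at a perfectly heterozygous locus by sampling error alone.
`exact_fp_rate()` is the enumeration companion; platforms are independent,
so the rate is a product of two per-platform tails.

One numerical choice deserves a note. At depth 40 and $t = 0.25$ the
threshold falls exactly on the count grid ($t \cdot d = 10$). The idealized
integer event $|k_A - k_B| > 10$ (computable via the convolution identity
$k_A - k_B + d \sim \mathrm{Binomial}(2d, 1/2)$) has probability 0.309% when
combined with the 13X platform. But the pipeline — like any implementation
that stores ratios — evaluates $|k_A/40 - k_B/40| > 0.25$ in double
precision, where part of the boundary mass $|k_A - k_B| = 10$ rounds one ulp
above 0.25 (e.g. $0.675 - 0.425 = 0.25000000000000006$): that event has
probability 0.356%. `exact_fp_rate(semantics = "ratio")` (the default)
enumerates the implemented predicate and is the oracle the simulation is
tested against; `semantics = "count"` gives the idealized bound. Off the
grid (any $t$ with $t \cdot d \notin \mathbb{Z}$) the two coincide. Both are
far below the 2% design bound at $t = 0.25$; the distinction matters only
when quoting the null rate to two digits.

The default null fixes depths at exactly 40 and 13; a truncated-Poisson
depth mode exists for robustness checks, and `require_sign_match = TRUE`
adds the sign-agreement condition (halving the rate) as a sensitivity
analysis — the reference null conditions on magnitudes only.

## Clustering permutation tests

`within_pair_cluster_test()` asks whether candidates sit closer together
than random draws from the background (the clear-call locus set): for each
permutation it samples $|C|$ loci from the background without replacement
and counts unordered same-chromosome pairs at distances inside each window
(defaults 101–500, 501–1000, 1001–5000, 5001–10000 bp, inclusive bounds;
identical positions are never a pair). The p-value uses the add-one
estimator $(1 + \#\{\text{perm} \ge \text{obs}\})/(n_\text{perm}+1)$, which
cannot return 0 and is conservative under ties.
`between_pair_cluster_test()` counts pair-1 candidates with at least one
pair-2 candidate within the window; its null resamples pair 2 from its
background (a switch resamples both — the choice of which set varies under
the null is genuinely open, and resampling one keeps the statistic's
conditioning simple).

## Category enrichment and the negative control

`category_enrichment()` tests each annotation category (the 14 VEP-style
consequence labels by default; loci may carry several) with a one-sided
Fisher exact test on the 2×2 table of candidates versus
background-minus-candidates — subtracting candidates keeps the strata
disjoint; percentages are still reported against the full background for
table-style output. One-sided is the natural test for an enrichment
question. P-values are adjusted with Benjamini–Hochberg across the
categories actually tested ($m = 14$ by default). Odds ratios use the
cross-product with a 0.5 continuity correction only when a cell is zero.

`control_comparison()` is the negative control: the same selection applied
to the two platforms of *one* individual, where every ARD is noise. With a
single track per "side", the clear-call condition reduces to either
platform's ratio sitting within tolerance of a canonical value. A calibrated
pipeline shows no enrichment here; a significant control points to
platform-specific artifacts rather than biology.

## The synthetic generator

`generate_twin_dataset()` emulates the data structure the pipeline consumes:
two co-twins × two platforms of per-locus read counts, with ground truth.
Defaults are fixed once as the package's study conditions:

* two chromosomes of 60 Mb; 20,000 variant loci placed uniformly over
  include-minus-exclude regions without replacement;
* shared germline genotype frequencies hom-ref 0.10 / het 0.70 /
  hom-alt 0.20 — heterozygotes dominate because the analysis background is
  the heterozygous set, with enough hom-ref loci to exercise that filter;
* 100 planted mosaics at cell fraction $f = 0.5$ (an early-embryonic scale
  event: a ±0.25 shift in the carrier's allele fraction), mutated twin
  chosen with probability 0.5; gains from 0, losses from 1, either direction
  from 0.5, all clamped to $[0,1]$;
* depths truncated-Poisson with means 40 and 13 (fixed-depth mode matches
  the calibration null exactly);
* baseline category probabilities follow genome-wide proportions of the 14
  consequence labels among heterozygous variants; multipliers of 1 (set a
  category's multiplier above 1 to plant enrichment among mosaics);
* no sequencing-error model by default (the calibration null is
  sampling-only); a per-read error rate is available as a knob.

Genotype calls are an idealized caller: the canonical value nearest the
twin's true fraction. Hotspots place a configurable share of mosaics inside
fixed-span windows (optionally at user-supplied centers, e.g. to co-locate
hotspots across two simulated pairs); infeasible spans error out.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: reference/mapping bias, PCR duplicates,
overdispersed (beta-binomial) counts, variant-caller genotype errors,
realistic linkage between annotation labels, or any joint distribution of
mosaic fraction and age. It validates the statistical machinery, not the
wet-lab error budget.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed; identical configurations
reproduce byte-identical outputs, and `run_full()` writes a manifest with
the seeds and file checksums. The test suite runs the calibration at 8–10
replicates of 50,000–200,000 loci, recall at ten seeds of 100,000 loci with
200 planted mosaics at $f = 1$, permutation calibration at 50 seeds × 199
permutations, and null matching pooled over a handful of seeds — sizes
chosen so each check has clear statistical power while the suite stays
interactive. The full-size calibration (1,000 × 893,581 loci) is a
single `simulate_fp_rate()` call away.

## Known limitations

* The clear-call + dual-threshold chain is deliberately stringent: under the
  null it admits roughly $10^{-4}$ of heterozygous loci, so small simulated
  genomes yield few null candidates — calibration statements about the
  matching fraction pool several seeds.
* The method detects only twin-discordant mosaicism at fractions large
  enough to clear the ARD threshold at both depths; pre-twinning or shared
  parental mosaicism is invisible by construction, and which twin mutated is
  not called — only the signed difference.
* `heritability_bias()` implements the closed-form illustration, not an
  ACE/ADE likelihood fit.
* Enrichment assumes the annotation table is complete for the background;
  absent loci count as unannotated.
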