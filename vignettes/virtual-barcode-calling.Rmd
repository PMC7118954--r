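---
title: "Virtual-barcode consensus calling of low-AF SNVs in cfDNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-barcode consensus calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vbcall)
```

## The problem

Circulating tumor DNA occupies a small fraction of the cell-free DNA
(cfDNA) in plasma, so somatic single-nucleotide variants of interest sit
at allelic fractions (AF) of 0.1–5% — at or below the raw per-base error
rate of the sequencer. Detecting them panel-wide (at every position of a
hybrid-capture panel, not just at hotspot lists) requires suppressing
three distinct noise layers:

1. **Read-level stochastic errors** — independent per-base miscalls.
2. **Stereotypical mutant-family-level artifacts** — recurrent, position-
   and substitution-specific errors (PCR stochasticity, oxidative and
   deamination damage; heavily skewed toward C>T/G>A) that survive
   consensus building and recur across unrelated samples.
3. **Stochastic mutant-family-level artifacts** — non-recurrent errors
   that also survive consensus, by chance.

UMI (unique molecular identifier) protocols address layer 1 by tagging
each original template molecule before amplification, at the cost of a
dedicated library design. `vbcall` implements the alternative this package
is built around: an *endogenous* barcode.

## The virtual barcode

cfDNA fragmentation is informative: a template is characterized by its
mapped fragment start, template length and strand. The **virtual
barcode** is the triple

> (fragment start, template length, strand of read 1)

within a chromosome. All read pairs sharing a barcode form a **virtual
family** (minimum two members; a lone pair is a **singleton**). The
family plays the role a UMI family plays in tagged protocols: a consensus
unit representing one original template. Because two distinct templates
occasionally share endpoints, a virtual family sometimes merges two or
more real (UMI) families; `compare_real_virtual()` quantifies this on
simulated UMI data: recovery rates are high, and mis-merged families are
dominated by the two-real-family case (both recomputed by the
acceptance script).

### Mate consolidation and the f value

Within a fragment, positions covered by both mates are **mate
consolidated**: agreeing mates contribute one vote, disagreeing mates
abstain (both reads are discarded at that position). A position covered by
one mate contributes that mate's base. Per family and position, the
**f value** is the fraction of non-abstaining member votes that are
non-reference; `f = 1.0` (unanimity) marks a *mutant family*. The
consensus allele is the unique plurality allele; a tie (or a reference
plurality) disqualifies the family from supporting any alternate allele —
a conservative choice for an event that is vanishingly rare at family
size ≥ 2.

A variant **singleton** is counted as *qualified* support only where at
least one `f = 1.0` family supports the same alternate allele.

Candidate sites are positions with at least one `f = 1.0` family; the
candidate's family-level AF is

> AF = (mutant families + qualified variant singletons) /
> (families + singletons covering the position).

## Noise statistics

`sample_stats()` summarizes each sample: the raw and mutant-family-level
error-position fractions, the **family degree** (position-summed family
count over position-summed read depth — its reciprocal tracks the median
family size), the panel-wide singleton ratio (singletons per family), and
the median family size. Family degree is defined panel-wide as a ratio of
sums rather than a mean of per-position ratios, making it robust to
zero-depth positions. Error positions are counted per position, not per
(position, allele). High-template samples have higher family degree,
smaller families, and measurably more mutant-family-level noise — the
gradient that motivates building the background database from both
low- and high-template samples.

## The polishing database

Stereotypical artifacts are identified from a cohort of background
samples (BGs): any (position, alternate allele) with an `f = 1.0`
observation in at least `min_occurrence = 6` BGs is **stereotypical**;
the rest are left to the downstream stochastic filters. Classification is
per allele, so a different substitution at a polishing position is never
polished.

For each stereotypical site the per-sample AFs are pooled (BGs plus an
optional extra cohort) and fitted by maximum likelihood against a fixed
candidate family of nine distributions: double Weibull, log-normal,
alpha, exponentially modified normal, minimum Weibull, noncentral t,
gamma, beta and Johnson SU. Each candidate is scored by AIC, BIC, the sum
of squared errors between fitted and empirical CDF at the sorted sample,
and the correlation R between fitted quantiles and the sorted sample; the
winner minimizes the rank sum of the four scores, with ties broken by
AIC. The four criteria are weighted symmetrically because no combination
rule is canonical; SSE and R are the two standard CDF- and quantile-based
goodness diagnostics. The candidate list is config-extensible.

The site's **AF cutoff** is the `confidence` quantile (default 0.99) of
the winning distribution. A candidate call at a database site passes
polishing only if its AF exceeds the cutoff — so a genuine mutation of
the same type at a noisy site remains callable.

### Small-cohort coverage calibration

With only ~10 AF observations per site, the plugin 0.99-quantile of a
fitted distribution under-covers: a future background draw exceeds it
noticeably more often than the nominal 1%, because parameter-estimation
noise is ignored. `build_background_db()`
therefore calibrates each site's working confidence by a seeded
parametric bootstrap (repeatedly refitting samples of the site's size
drawn from the fitted model and choosing the smallest working confidence
whose plugin quantile achieves the nominal predictive exceedance), and
additionally floors every cutoff at the largest background AF actually
observed at the site. Both corrections are deterministic given the DB
seed, apply only to DB construction (`af_cutoff()` itself remains the
plain quantile), and can be disabled with `calibrate = FALSE`. With large
fitting cohorts the calibration converges to the plugin quantile.

Degenerate sites (zero-variance AF samples, or fewer than `min_fit_n = 8`
values) fall back to the empirical quantile of the observed AFs and are
flagged `"empirical"` in the database.

The database also stores the **background template rate** — the
position-summed mutant-family count over the position-summed family count
across the BG cohort — used by the minimum-template filter below.

## Fine-tuning filters for stochastic artifacts

Applied in fixed order after polishing (the caller's audit table records
candidate counts at every stage):

**1. Ds / false-family ratio (FFR).** The Ds value of a supporting
template is the minimum distance from the variant to either end of the
template span. Supporting templates with `ds <= 2` or `ds >= 149`
(data-derived cutoffs for 150 bp reads; both config-exposed because they
are panel- and read-length-dependent) are *false families*; variant
singletons are subject to the same rule, since they have spans too. A
site *fully* supported by false templates (FFR = 1.0) is removed; false
templates are pruned from the updated template count either way. Whether
the high cutoff is template- or read-relative is ambiguous for ~166 bp
templates; we retain the verbatim value, which for short templates simply
never fires, and expose the semantics through configuration.

*Mate-overlap requirement.* On paired 150 bp reads over ~166 bp
templates, mate consolidation protects only the mate-overlap region:
where a single mate covers a position, a unanimous-error family can arise
without any veto, and in the simulator every spurious `f = 1.0` family
indeed sits in a single-covered end zone. The extreme-Ds cutoffs are a
data-derived proxy for exactly this geometry, so the false-family
definition also treats a supporting template whose variant is not covered
by both mates as false (`require_mate_overlap = TRUE`, configurable).
This decision was made from the mechanism, not fitted to any outcome; it
removes the dominant residual false-positive channel while costing a
~19% prune of genuine support — immaterial against supporting counts of
tens of templates, and visible only at the very lowest AFs.

**2. Variant-singleton ratio.** Real variants accumulate singleton
support in proportion to the sample's overall singleton ratio; artifact-
prone sites over-recruit singletons. Stage 1: a site whose
singletons-per-mutant-family ratio is at most 2.0 (the panel-wide bound
observed across background cohorts) always passes. Stage 2: the expected
singleton proportion is estimated from pooled counts of high-AF
(≥ 0.05) sites — falling back to the panel-wide proportion when fewer
than three exist — and each remaining site receives an exact binomial
exceedance p-value for its singleton count given its supporting
templates; Benjamini–Hochberg correction is applied across the sample's
stage-2 candidates and sites fail at adjusted p ≤ 0.01. The binomial
count model and BH procedure are this package's choices; only "FDR
correction" is canonical. Samples whose panel-wide singleton ratio
exceeds 2.0 (singleton-dominated libraries, e.g. exome-like data) skip
stage 2 entirely, which also covers the ultra-low-duplication case.

**3. Minimum template number.** Under an independent-trials model with
the cohort's background template rate r, the threshold k_min is the
smallest k with `P(Binom(n, r) >= k) <= 1 - confidence` at the site's
total template count n (default confidence 0.99; `r = 0` gives
`k_min = 1`). A site passes if its *updated* template count (post-Ds
pruning: surviving mutant families plus surviving qualified singletons)
reaches k_min.

## The simulator

`simulate_sample()` generates a synthetic hybrid-capture cfDNA sample
with exactly the statistical structure the pipeline assumes, emitting
pre-aligned read pairs (all-match CIGARs, correct flags and TLEN) so that
desk-scale testing does not depend on an external aligner, plus a
complete truth ledger (per-template records, per-read injected errors,
per-sample artifact activations). `write_sam()` materializes a
coordinate-sorted SAM byte-identically per seed; the in-memory and
file round trips are tested to agree exactly.

Default study conditions, chosen once as realistic for deep targeted
cfDNA sequencing and used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| panel | one 10 kb region | desk-scale stand-in for a capture panel |
| templates per site | 3000 | deep cfDNA input (reference-standard-like); BG cohorts use 1000 (control-like) |
| fragment length | round-normal, mode 166 bp, sd 25, bounded [100, 300] | cfDNA mono-nucleosomal peak |
| read length | 150 bp | common paired-end chemistry |
| singleton fraction | 0.2 | moderate duplication |
| family size | 2 + Geometric(0.55) | right-skewed, median 2 |
| per-base error rate | 0.001 | post-quality-filter Illumina-like (Q30) |
| error spectrum | C>T/G>A-skewed | PCR/damage-dominated profile |
| artifact sites | log-normal per-sample AF (meanlog log 0.02, sdlog 0.35), truncated at 0.4 | recurrent low-AF artifacts with a right-skewed spread |

What the generator does **not** emulate: base-quality variation (all
bases Q40), GC and capture bias, indel and mapping errors, strand-specific
damage asymmetries, inter-site error correlation, and real fragment-end
motif biases. Tests passing on this generator therefore demonstrate the
*algorithmic* behavior of the pipeline — partition correctness, error
suppression at the stated rates, calibration of the filters — not
performance on any particular instrument's data.

## Numerical and design choices

- Coordinates are 0-based half-open internally; 1-based only in VCF
  output.
- Strand in the barcode is read-1 orientation (F1R2 vs F2R1), the finest
  per-fragment strand notion available.
- Discordant pairs (TLEN 0 or above 1000 bp) are excluded; cfDNA
  templates are short and larger TLEN indicates artifacts. Default
  minimum mapping quality is 30 (multi-mapping reads in paralogous
  regions carry low MAPQ).
- Families are global per fragment key; a family covers a position iff
  at least one member read covers it (computed exactly, including orphan
  mates).
- Consensus ties contribute to no allele. Abstaining mates reduce the
  vote denominator rather than counting as reference.
- Maximum-likelihood fits use Nelder–Mead on log-transformed positive
  parameters with moment-based starts (closed form for the log-normal);
  a candidate whose fit fails is skipped with a warning, and a site where
  every candidate fails is an error.
- Quantiles without closed forms (exponentially modified normal) are
  inverted numerically; noncentral-t tail-precision warnings from R's
  `pnt` are suppressed as benign.
- AF cutoffs are clamped into (0, 1). Confidence levels are restricted
  to [0.8, 0.995] at the user surface.
- All simulation randomness flows from the config seed; the global RNG
  state is saved and restored, so library calls never perturb user code.
  Cohorts derive per-sample seeds as `seed + i`.

## Problem sizes used in the test suite

The packaged tests exercise the full pipeline at the default study
conditions: a 10 kb panel, ten background samples at 1000 templates/site,
and ten replicate case samples at 3000 templates/site with six spiked
variants at AF 1% (plus replicates at 0.1%), alongside
property-style checks at smaller sizes (clustering oracles at up to 1000
fragments, ≥ 10^5 family draws for the error-suppression bound, 50-repeat
fit-recovery panels at n = 300). These sizes were chosen to give stable
Monte-Carlo margins while keeping a full run at desk scale.

## Known limitations

- SNVs only: no indels, fusions, CNVs or TMB; multi-allelic positions are
  emitted one record per alternate allele.
- The polishing database must be built on the same panel and reference
  naming as the samples it polishes; a chromosome mismatch is an error.
- Sensitivity at AF 0.1% is input-limited: with 3000 templates per site,
  three mutant templates are expected, and a site whose support prunes
  below the template threshold is genuinely undetectable — deeper input,
  not a looser threshold, is the remedy.
- The small-cohort calibration targets predictive coverage of the cutoff
  under the *fitted* family; a badly mis-specified family on very few
  observations can still leak slightly above the nominal rate; the
  empirical-max floor bounds the damage.
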