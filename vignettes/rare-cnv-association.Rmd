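---
title: "Methods: rare-CNV case-control association with rarecnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-CNV case-control association with rarecnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecnv)
library(dplyr)
```

## Overview of the procedure

`rarecnv` analyses array-based CNV call sets from a case-control study in
six stages, each a pure function over tibbles:

1. **Array-metric sample QC** (`array_metric_qc()`): a sample is excluded
   when its genotype call rate falls below 95%, or when its per-sample
   LRR (log R ratio) or BAF (B allele frequency) standard deviation falls
   outside the batch mean ± 3 SD. Relatedness, ancestry and sex checks
   are accepted as a precomputed exclusion list (`exclude_samples`), not
   recomputed, since they require genotype-level data this package never
   sees.
2. **Raw-call filtering** (`filter_raw_calls()`): calls shorter than
   5 kb, spanning fewer than 5 probes, or below a caller-specific quality
   threshold are dropped before merging.
3. **Consensus merging** (`merge_consensus()`): within each
   (sample, chromosome, type) stratum, calls overlapping by at least one
   bp — transitively — form connected components; components supported by
   at least two distinct callers become one *stringent CNV* spanning the
   outermost union of the member calls.
4. **Region exclusion** (`apply_region_filters()`): stringent CNVs are
   removed when they touch a 100-kb buffered centromere/telomere window
   at all, or when more than 70% of their length lies in segmental
   duplications or immunoglobulin loci.
5. **CNV-count sample QC** (`cnv_count_qc()`): samples contributing more
   stringent CNVs than their batch mean + 3 SD are excluded (one-sided).
6. **Association** (`run_association()`): per-gene carrier counting,
   exact testing, pooled FDR control and rarity classification, with the
   burden table (`burden_table()`) and gene-set overrepresentation
   (`run_ora()`) alongside.

`run_cnv_pipeline()` chains the stages and records the per-stage funnel;
running the stage functions by hand with the same parameters produces
identical output, which the test suite asserts.

## The exact model

Carriers, not events, are the counting unit: for a gene $g$ and type
$t$, $a$ = number of case samples with ≥ 1 overlapping CNV of type $t$
(1 bp suffices), $c$ = the control analogue. Conditioning on the margins
of the resulting 2×2 table, the case-carrier cell follows Fisher's
noncentral hypergeometric distribution with odds ratio $\psi$:

$$P(X = k \mid \psi) = \frac{\binom{m}{k}\binom{n}{K-k}\psi^k}
   {\sum_j \binom{m}{j}\binom{n}{K-j}\psi^j},$$

with $m$ cases, $n$ controls and $K$ total carriers. The two-tailed p
sums $P(X = k \mid 1)$ over all $k$ whose point probability does not
exceed the observed one (a relative tolerance of $10^{-7}$ guards the
tie comparison against floating-point noise). The odds-ratio estimate is
the conditional MLE, the root of $E_\psi[X] = a$; it is $0$ or $\infty$
when $a$ sits at the boundary of the support. The 95% interval inverts
the one-sided tests: $P(X \ge a \mid \psi_{\text{low}}) = 0.025$ and
$P(X \le a \mid \psi_{\text{high}}) = 0.025$.

**Why carriers?** With a handful of carriers per gene, the per-sample
carrier indicator is the exchangeable unit; counting events would let a
single sample with two overlapping duplications count twice, breaking the
hypergeometric sampling model. The event-level reading is not offered:
every reported count is a distinct-sample count.

### Numerical conventions for the estimate and interval

All three roots are found on the odds-ratio scale with the search
bracketed in $(0, 1]$ or solved as the reciprocal of a root in $(0, 1]$,
stopping at the conventional `uniroot` tolerance
(`.Machine$double.eps^0.25` on the search variable). This stopping rule
is deliberately the one under which exact confidence bounds are
conventionally computed and published; for extreme tables the upper
bound is sensitive to it (for carrier counts 12/243 vs 1/2988 the
conventional search reports 6349.5 while a fully converged inversion
gives 6635.0 — the tail probability at the conventional bound is 0.0261
rather than 0.0250). `fisher_exact_2x2(..., ci_tol = 1e-10)` gives the
fully converged endpoints; the test suite verifies at that tolerance
that $P(X \ge a \mid \psi_{\text{low}})$ and
$P(X \le a \mid \psi_{\text{high}})$ sit within $10^{-6}$ of 0.025.
Degenerate tables (no carriers anywhere, or everyone a carrier) return
p = 1 with the estimate flagged `NA` rather than erroring, so
genome-wide scans never abort on an empty margin.

### Multiple testing and rarity

The test universe is every (gene, type) pair with at least one carrier
in either cohort; deletion and duplication universes receive **one
pooled** Benjamini-Hochberg correction, since they are reported together
and a per-type correction would understate the family. Rarity is a
strict threshold on the control carrier proportion
(`control_carriers / n_controls < 0.001`), evaluated on the post-QC
control count: 2 of 2,988 controls (0.067%) is rare, 3 (0.100%) is not.
The rare report keeps pairs with adjusted p ≤ 0.01; both thresholds are
`run_association()` arguments.

## Burden comparison

`burden_table()` builds the full type × length × genic grid. Length bins
are half-open upward — [5, 100) kb, [100, 500) kb, [500 kb, 1 Mb),
[1 Mb, ∞) — so that a 100,000-bp CNV falls in one bin only; "any"/"all"
marginal cells equal the sum of their partition cells by construction,
and the tests assert this conservation. Each cell compares observed
group counts against expected counts proportional to the group sample
sizes: the expected count for group 1 is rounded to the nearest integer
and the complement defined by subtraction, preserving the table margin,
and the 2×2 of observed vs expected is tested with the same two-tailed
exact test. This observed-vs-expected construction treats the expected
counts as if they were a realized comparison group; its p-values are
therefore descriptive rather than strictly calibrated, which is also why
the package reports them without a multiplicity correction.

## Gene-set overrepresentation

`run_ora()` takes the associated genes (by default those with adjusted
p below a relaxed threshold) as the query and **all genes overlapped by
at least one CNV in at least one sample** as the background — using all
annotated genes would overstate enrichment, because only CNV-accessible
genes could ever enter the query. The per-set p is the one-sided
hypergeometric upper tail (the standard overrepresentation reading of an
exact test; a two-sided variant is available), BH-corrected **within
each library** so that a large library cannot crowd out a small one.
Reported sets need at least 2 query hits and adjusted p ≤ 0.25 — a
deliberately permissive default appropriate for exploratory network
interpretation, not for confirmatory claims. Any GO-level restriction is
delegated to the supplied GMT files; the package does not traverse the
GO graph.

## Consensus-matching choices

"Same CNV seen by two callers" is operationalized as ≥ 1 bp overlap with
transitive closure — the most permissive deterministic reading, matching
the outermost-union definition of stringent breakpoints. Under
half-open coordinates, abutting calls (`[a,b)`, `[b,c)`) share no base
and never link. A stricter reciprocal rule is available
(`min_reciprocal_overlap`): calls link only when the intersection covers
at least that fraction of *both* calls; the default 0 reduces exactly to
the 1-bp rule. Size and probe filters apply to raw calls *before*
merging — the merged union span is never re-filtered, because a union
can only grow and re-filtering would reintroduce order dependence. The
merged record keeps the maximum member probe count for reporting only;
no downstream filter consumes it. Region filters apply to stringent
CNVs (after merging), matching the stage order of the workflow funnel;
filtering raw calls instead would let two half-artefact calls merge
into an interval that escapes both thresholds.

Components are found by a line sweep (sorted by start, a component
breaks where a call starts at or beyond the running maximum end), which
is exactly the connected-component structure of the interval overlap
graph; the suite checks equivalence against an independent $O(n^2)$
pairwise union-find oracle on a thousand random instances.

## Sample QC choices

SD bands use the sample standard deviation ($n-1$) and are computed
once per batch on all samples of that batch; the filter does not
re-iterate after exclusions, and the low-call-rate and SD criteria are
evaluated simultaneously on the full batch. A batch of one sample has no
defined SD: such samples pass the SD criteria with a logged warning
rather than being silently excluded. The CNV-count filter is one-sided —
only an *excess* of CNVs indicates a problematic sample; an unusually
quiet genome is not an artefact signature.

## What the generator emulates — and what it does not

`simulate_study()` emulates the statistical structure the pipeline must
survive: a small case cohort against a large control cohort (defaults
243 / 2,988), ~18 true CNVs per sample (Poisson), a length mixture with
weights (0.881, 0.108, 0.0075, 0.003) over the four length bins
(log-uniform within a bin, so ~88% of events are below 100 kb), 65%
deletions, three callers with per-caller sensitivity (defaults 0.92,
0.95, 0.90), rounded Gaussian breakpoint jitter (SD 300 bp, roughly a
probe spacing at the default density of one probe per kb), and
caller-specific false positives (2 per sample per caller). The default
genome is 5 × 30 Mb with 400 disjoint genes — large enough that genes
are multiply hit by common background CNVs, small enough for fast tests.

Structural guarantees, chosen so that planted truth is exact rather
than approximate:

* planted carriers are drawn from samples that pass the array-metric QC
  bands and carry at most an average background load, so planting never
  collides with either sample-QC filter;
* planted events sample their supporting-caller set conditional on ≥ 2
  callers, so a planted carrier count survives consensus exactly;
  background events use unconditional dropout;
* planted CNVs extend at most 20 kb beyond their target gene, capped so
  they can never reach a neighbouring gene, a buffered exclusion window,
  or (after jitter clipping) lose the 1-bp gene overlap;
* background events avoid planted loci, so control carrier counts at
  planted genes are exactly as configured;
* false positives are placed to overlap no other call of the same
  sample and type, making them single-caller by construction — the
  consensus stage must remove every one of them, and the tests assert
  it does.

Each random component (genome, manifest, placement, lengths, planting,
dropout, jitter, false positives, QC outliers) draws from its own
stream derived from the master seed, so changing one rate never
reshuffles another component — the suite asserts, for example, that
switching the false-positive rate leaves the true CNV set bit-identical.
Probe positions are implicit (`n_probes = floor(length × density)`);
simulating per-probe intensities (LRR/BAF signal, the callers' HMMs)
is out of scope, which means the generator cannot reproduce
intensity-driven artefact structure — wave effects, GC bias, batch-
correlated breakpoint errors. Passing tests therefore demonstrate that
the *statistical pipeline* is correct under its stated model, not that
any particular caller's output meets that model.

`simulate_qc_outliers()` plants call-rate outliers (call rate 0.90) and
CNV-count outliers; count outliers receive 12 background-SD of extra
disjoint events and are spread across batches, keeping a single outlier
from inflating its own batch's SD enough to mask itself.

## Problem sizes used by the validation suites

The full-scale recovery run uses the default study conditions
(243 / 2,988 samples, ~58,000 true CNVs, ~160,000 raw calls) with twelve
planted signals at carrier counts typical of rare associated genes
(4–12 case carriers against 0–2 control carriers). The null-calibration series uses 20 replicates at 50 / 200
samples on a 2 × 10 Mb genome with 60 genes — sizes chosen once as the
smallest at which the gene × type universe still holds ~100 tests per
replicate. The exhaustive p-value check enumerates every 2×2 table with
both row margins ≤ 40 (≈ 740,000 tables) against a direct
binomial-coefficient oracle.

## Known limitations

* The observed-vs-expected burden p-values are a descriptive convention
  (see above); group comparisons needing covariate adjustment should use
  a regression model outside this package.
* Chromosomes are treated as autosomal throughout; sex-chromosome copy
  number (and sex-aware carrier counting) is not modelled.
* The conventional CI stopping tolerance is the default for
  comparability with published exact intervals; use `ci_tol` when the
  bound itself is the quantity of interest.
* `bh_adjust()` wraps `stats::p.adjust(method = "BH")`; the direct
  step-up formula serves as the independent oracle in the tests, not as
  the implementation.
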