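---
title: "Methods: lncRNA discovery, signature derivation and qPCR quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA discovery, signature derivation and qPCR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncseek)
```

`lncseek` reimplements, as tested and reusable functions, the analysis
chain behind a paired-xenograft lncRNA discovery study: quantify a
metastatic/non-metastatic transcriptome pair, filter the catalog down to
lncRNAs, call fold-change differential transcripts, assess coding
potential of a candidate, derive an anchor-gene-associated expression
signature in an independent cohort, test that signature against concept
gene sets, and quantify validation qPCR. This vignette documents the
models, the numerical choices, and the synthetic-data design that makes
the pipeline testable without the original sequencing or clinical data.

## Catalog filtering

A transcript is an lncRNA candidate iff

1. its annotated biotype is not `protein_coding`;
2. its biotype is not one of the excluded small-RNA classes
   (`rRNA`, `tRNA`, `miRNA`, `snoRNA`, `other_small_rna`); and
3. its length is **strictly** greater than 200 nt — "longer than 200"
   is read literally, so a 200-nt transcript fails.

Rejected transcripts carry exactly one reason: the first failing filter
in the fixed order coding → excluded class → too short. Pseudogenes are
retained as candidates (known onco-suppressive pseudogene lncRNAs are
exactly the kind of hit the filter must not discard); biotype always
comes from the annotation and is never inferred from sequence —
coding-potential assessment is a separate downstream module. The list
of excluded classes is a documented superset of "other known classes of
RNAs" and is extendable through the `excluded_classes` argument.

## Quantification and paired differential calls

RPKM is the classic length- and depth-normalized abundance
`x[i,s] = 1e9 * c[i,s] / (N[s] * L[i])`. The mapped total `N[s]` is
taken from the input table, never recomputed as a column sum, so
quantifying a partial catalog keeps library-size semantics.

"Normalized to the root mean square for each sample" is implemented
literally: each sample's RPKM vector is divided by its RMS,
`sqrt(mean(x^2))`, so every normalized column has unit RMS (asserted to
`1e-9` in the tests). This makes the normalization scale-invariant per
sample and testable as an invariant.

Differential calls compare the two normalized columns per transcript:
`r = (x_met + pseudocount) / (x_nonmet + pseudocount)`. The default
threshold is 2.0 and **inclusive** (`r >= 2` up, `r <= 0.5` down): the
validation language "greater than 2-fold" is about qPCR confirmation,
and a reported ratio of 1.38 being below the significance threshold is
consistent with either convention, so the inclusive reading is the
default and the threshold is a knob. The default pseudocount is 0, with
explicit flags instead of silent correction: a transcript observed only
in the met sample is called up with an `infinite` flag; one absent from
both is `none`/`undefined`.

## Coding potential

The six-frame ORF scan defines an ORF as ATG through the next in-frame
stop (TAA/TAG/TGA), stop codon **included** in the length, minimum 75 nt
by default (the customary default of common ORF-finding tools; the
minimum is exposed because discovery runs rarely report it). Only
maximal ORFs are reported — the first ATG after the previous in-frame
stop anchors each ORF — with internal-ATG (nested) ORFs available behind
`report_nested = TRUE`. Coordinates are 0-based half-open; minus-strand
ORFs are reported in minus-strand coordinates with `minus_to_plus()` to
project them back. The brute-force position-by-position scanner in the
test suite is the scanner's oracle.

`coding_fraction()` is the fraction of transcript positions covered by
the **union** of reported ORFs on either strand. Note that a single
maximal 267-nt ORF in a 2,598-nt transcript covers about 10.3% of it;
published "at most X% coding" figures depend on unstated details of the
ORF definition (nested starts, stop-less 3' ORFs, per-strand maxima), so
this package fixes and documents the union-of-maximal-ORFs definition
rather than reverse-engineering any particular printed percentage.

The Fickett TESTCODE statistic uses the published lookup tables and
weights, embedded as package constants. For each base the position
parameter is `max(n1,n2,n3)/(min(n1,n2,n3)+1)` over the three codon
positions and the composition parameter is the base's overall frequency;
the eight table-converted probabilities are combined with the published
weights. Classification uses the fixed score cutoffs (≥ 0.95 coding,
≤ 0.74 non-coding, otherwise no opinion); the original method's p-value
formulation is out of scope — the score cutoffs are the implemented
surface. Sequences under 200 nt are scored but flagged low-confidence.

## Anchor signature: SAM

`dichotomize_by_anchor()` labels the `k` samples with the highest anchor
expression "high" and the `k` lowest "low" (default `k = 20`); boundary
ties break by sample-id lexicographic order so the split is
deterministic.

`sam_statistic()` computes the SAM relative difference per gene,
`d = (mean_high − mean_low) / (s + s0)`, with `s` the pooled two-sample
standard error and `s0` the fudge factor. By default `s0` is automated
in the original spirit: among the 5%-step percentiles of the `s`
distribution, pick the value minimizing the coefficient of variation of
the `d` spread (MAD) across 100 `s`-percentile windows; a fixed
percentile is available as an override. The null distribution comes
from high/low label permutations: when the number of distinct
assignments is at most `n_perm` they are all enumerated (making the
result seed-independent), otherwise `n_perm` (default 1000) random
assignments are drawn from a seeded stream.

Q-values use exceedance counting with a median-based FDR: at the cut
set by a gene's own `d`, the false-call estimate is the median across
permutations of the number of permuted `d` values at or beyond the cut
in the same tail, divided by the number of genes called at that cut;
the gene's q-value is the minimum FDR over all cuts at which it is
still called, which enforces monotonicity in the `|d|` ranking. The
null proportion π0 is fixed at 1 — a deliberately conservative choice
that keeps the estimator simple and can only inflate, never deflate,
q-values. The positively associated signature is the set with `d > 0`
and `q ≤ Q/100` at `Q = 0.5%`; the anchor gene is excluded from the
candidates before any statistic is computed, so it can never appear in
its own signature.

## Concept enrichment

Over-representation of the signature in a concept set is tested
one-sided (the analysis acts only on enrichment, never depletion):
`p = P(overlap ≥ a)` from the hypergeometric distribution over a stated
universe. The universe defaults to the genes eligible for the signature
stage — the cohort gene list minus the anchor — conditioning on testable
genes rather than the whole genome. The odds ratio is `(a·d)/(b·c)` with
the Haldane–Anscombe 0.5 correction applied to all four cells only when
some cell is zero, and flagged so exact-count consumers are not
surprised. A concept passes at `p < 1e-4` and `OR > 2`;
`summarize_battery()` reports per-concept-type pass counts by direction
with p and OR ranges among passers.

## qPCR: 2^−ΔΔCt

Replicate Cts are averaged per (sample, gene). The two endogenous
controls are combined by averaging their Cts — equivalent to
normalizing expression by their geometric mean, the standard
multi-reference convention, and symmetric in the two references (a
zero-noise table gives identical folds under either per-reference
convention). `ΔCt = Ct_target − mean(Ct_refs)`,
`ΔΔCt = ΔCt − mean(ΔCt over calibrator samples)`, and
`fold = 2^−ΔΔCt`: amplification efficiency is fixed at 2 and efficiency
correction is out of scope. Candidate validation is **strict**
(`fold > 2`), per "greater than 2-fold": a fold of exactly 2 fails.
Median centering subtracts the overall median on the log2 fold scale,
so it is a shift, idempotent, and matches "median-centered values"
display semantics with per-group min/median/max summaries.

## Synthetic-data design

The generators produce every input the pipeline consumes, with planted
truth returned alongside. Design choices that matter:

* **Count model.** Counts are negative-binomial around
  `abundance × length × depth / 1e9` (RPKM-scale abundance, so expected
  RPKM equals the drawn abundance). Dispersion 0 is the exact zero-noise
  limit: the expected counts themselves are returned (possibly
  fractional) so planted ratios survive the full pipeline exactly. The
  discovery data give no noise parameters, so the defaults here are
  explicit stand-ins: dispersion 0.05 (a moderate technical-scale
  value) and depth 2×10⁷ reads per sample.
* **Per-transcript sub-streams.** Every transcript draws from a stream
  keyed on `(seed, transcript_id)`, and the planting map is drawn over
  the id-sorted catalog, so reordering catalog rows changes nothing.
* **Abundance structure.** Planted differential lncRNAs sit at 10–100
  RPKM; the null background is log-uniform over 10–10⁴ RPKM. This
  mirrors real transcriptomes, where a stable high-abundance background
  dominates each sample's root mean square — which is precisely what
  makes per-sample RMS normalization usable. Without it, 153
  transcripts planted 4-fold up would skew the met sample's RMS and
  shift every ratio; with it the normalization factor stays within a
  few percent of 1 (computed analytically during design, verified by
  the recovery tests).
* **Recovery-experiment sizing.** At dispersion 0.05, the log2 ratio of
  two independent NB draws has SD ≈ 0.46, so a 2-fold cut sits ~2.2 SD
  from the null and each null transcript crosses it with ≈1.5%
  probability per tail. Two consequences, fixed at design time: the
  *exact*-recovery experiment ("153 up / 77 down recovered exactly"
  over the full 1,653-transcript catalog) runs at dispersion 0.005,
  where both the expected misses and expected chance crossings are
  below 0.1; the dispersion-0.05 recovery run instead uses a null
  background of 50 transcripts, sized so the expected number of chance
  crossings stays below one per tail, and its recovered counts are read
  as estimates, not exact values.
* **Cohort.** The anchor-associated signal is planted as a two-group
  mean shift — `assoc_effect_sd_units` (default 3) within-group SDs
  added to the top-`k` anchor samples — matching the dichotomized SAM
  design directly rather than a continuous correlation. Default
  dimensions, 10,000 genes × 131 samples with 402 associated genes,
  mirror the mined cohort's scale while staying desk-sized. The anchor
  row is generated but never a candidate.
* **Sequences.** Non-coding sequences are i.i.d. uniform; coding-biased
  sequences sample codons from a strongly 3-periodic skewed base table
  behind an ATG and before a stop, which gives TESTCODE position
  parameters deep in the coding bins.
* **Ct tables.** The inverse ΔΔCt model:
  `Ct = base − log2(expression) + noise`, references group-independent.
  Zero noise inverts exactly. The seven validation candidates ship with
  synthetic stand-in RNA-seq ratios (8.9 down to 2.7): the source
  figure prints bars, not numbers, so the values are chosen to respect
  the described ordering and the property that all seven exceed 2-fold
  — which is the only property downstream validation consumes.

## Problem sizes and determinism

The test suite runs the recovery experiments at the full study scale
(1,653-transcript catalog; 10,000 × 131 cohort with 1,000 permutations,
plus a 20-seed null-calibration sweep) because those sizes are what the
planted-truth claims are about; unit and property tests use smaller
instances (tens to hundreds of transcripts, 3-vs-3 toys with exhaustive
permutation enumeration) chosen to keep the oracle comparisons exact.
Every random draw in the package flows through `sub_seed()`, a rolling
hash of a base seed and a stream key; the pipeline fans a single global
seed out to per-stage sub-seeds hashed from stage names, so inserting
or toggling a stage never perturbs another stage's draws, and a full
`run_pipeline()` rerun is byte-identical.

## Limitations

The synthetic generators emulate the statistical structure the pipeline
assumes, not real sequencing: no GC or length bias, no batch effects,
no mapping ambiguity, Gaussian cohort noise, and a clean two-group
anchor association. Passing recovery tests therefore demonstrates that
the pipeline's arithmetic and decision rules are correct under the
stated model, not that the model captures every feature of real
xenograft RNA-seq or clinical cohorts. The paired design has one sample
per condition by construction, so fold-change calling is
replicate-free; replicate-aware differential testing is out of scope.
Enrichment assumes the concept sets and universe share one gene
namespace; identifier mapping is the caller's responsibility.
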