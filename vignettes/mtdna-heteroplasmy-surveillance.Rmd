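---
title: "mtDNA heteroplasmy surveillance: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mtDNA heteroplasmy surveillance: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitolineage)
```

## What this package models

Human mtDNA is a 16,569 bp circular multicopy genome; a cell carries
hundreds to thousands of copies, and a variant present on a fraction
of them is *heteroplasmic*, quantified by its heteroplasmy fraction
(HF) — operationally, the alternate-allele read fraction at a
position. Deep amplicon sequencing pushes the HF detection limit to
0.2%, where essentially every cultured line shows "universal
heteroplasmy": a background of low-level variants.

Reprogramming a fibroblast into an iPSC clone is genetically a
single-cell bottleneck: the clone inherits one cell's mitochondrial
population, so the clone-to-clone spread of a variant present at 24%
in the pooled parental culture can legitimately run from 0% to above
80%. Subsequent passaging adds neutral genetic drift, de novo
substitutions accumulate (dramatically faster in lines with crippled
mtDNA replication machinery, e.g. POLG mutants), and differentiation
into neuronal precursors adds another, milder round. The package
tracks all of this per variant and per clone, and flags functionally
dangerous passengers.

## The pipeline and its thresholds

| Parameter | Default | Units | Why |
|---|---|---|---|
| `depth_min` | 100 | reads | minimum retained depth for a callable site |
| base quality | ≥ 30 | phred | applied in the reader that builds counts; count tables are declared pre-screened, since quality cannot be re-derived from aggregates |
| `hf_min` | 0.002 | fraction | the 0.2% detection limit of the deep-sequencing design; also the presence threshold in segregation |
| `homoplasmy_min` | 0.95 | fraction | calls at or above 95% are reported homoplasmic |
| `strand_alpha` | 10⁻³ | — | two-sided Fisher exact p below which a call fails strand bias |
| `strand_both_hf` | 0.01 | fraction | calls at ≥ 1% HF must show alternate reads on both strands; lower-HF calls are exempt (a 0.05% variant at depth 10,000 may genuinely have ~2 reads per strand) |
| `score_cutoff` | 0.43 | — | disease-score threshold, strict inequality: nonsynonymous variants scoring > 0.43 are damaging |
| `rescue_hf` | 5 × 10⁻⁴ | fraction | sub-threshold trace scan used only for the re-emergence flag |
| `stable_band` | 0.05 | ΔHF | transmitted shifts within ±5 points are "stable" |

Design points worth stating explicitly:

* **Mono-allelic rule.** A position with two or more alternate alleles
  at ≥ `hf_min` has *all* its candidates flagged `multi_allelic` and
  failed — flagged, never silently dropped, so the audit trail
  survives.
* **Strand bias.** Manual browser inspection is not reproducible; the
  package substitutes a Fisher exact test on the 2×2 strand table plus
  the both-strands rule above. Degenerate tables (an empty margin,
  e.g. at near-homoplasmy) pass by convention: the test is
  uninformative there, not failed.
* **Presence means a PASS call at HF ≥ 0.002.** A variant collapsing
  from 53% to 0.65% across reprogramming still counts as transmitted
  (and is flagged `lost_to_trace` when the collapse is from ≥ 5% to
  < 1%). Only the re-emergence flag looks below the limit, because a
  variant seen in fibroblasts at 0.4–0.7%, absent in the iPSC, and
  back at 6% in the NPC is better explained as a sub-threshold
  survivor than as recurrent mutation.
* **Overlap tie-break.** For positions inside two genes
  (MT-ATP8/MT-ATP6, MT-ND4L/MT-ND4), the primary locus is the
  later-starting gene — the frame in which such variants are
  conventionally reported — and both assignments are retained in
  `all_loci` with an `ambiguous_locus` flag, since reporting
  conventions differ.
* **Light-strand genes** (MT-ND6 and eight tRNAs) are annotated on the
  reverse complement; codon 1 of a light-strand gene begins at its
  3′-most rCRS coordinate. Incomplete stop codons (completed to TAA by
  polyadenylation) are padded with A and treated as stops, so a
  substitution in a trailing T is a stop loss.
* **Plasmy and rounding.** HFs are reported to 4 decimals (0.01%);
  all comparisons use full precision.
* **Statistics.** "Rank-sum" is the Mann-Whitney U test, exact when
  the combined sample is ≤ 20 without ties, tie-corrected normal
  approximation otherwise; all tests two-sided at 0.05 with no
  multiple-testing correction (the design is a handful of planned
  comparisons, and the report says so). The age dichotomy puts donors
  ≥ 50 years in the old group. The adjusted R² uses the univariate
  formula 1 − (1 − R²)(n − 1)/(n − 2).

## The embedded reference

All coordinates are 1-based rCRS (NC_012920.1) positions, the `m.<pos>`
convention; the historical placeholder at 3107 is kept as `N` so
positions match the literature. The packaged sequence is
*reconstructed*: the build environment provides no verbatim copy of
NC_012920.1, so `data-raw/make_reference.R` derives it from the
superseded NC_001807.4 reference by reversing the documented indels
(309.1C, 315.1C, the absent 3107 placeholder, 16193.1C) and the
single-base differences along the haplogroup path separating the two
references. The result is validated hard: correct length, anchor bases
fixed by variant nomenclature at 40 positions, all 13 protein-coding
genes translating with legal starts and no internal stops under the
mitochondrial code, and the canonical protein changes (p.R340H,
p.A52T, p.L220P, p.S80F, p.L156P) reproducing exactly. The coding
complement is therefore fully constrained; an undocumented difference
at a non-coding position cannot be excluded, which would affect only
the reference base reported at that position, not coordinates or any
coding annotation. Non-human mitogenomes and alternative references
(RSRS) are out of scope.

Haplogroup *inference* is likewise out of scope: motifs are an input
(TSV of haplogroup, position, ref, alt), and the bundled table is a
simplified demonstration set. Back-mutations at motif positions are
conservatively kept private with a `back_mutation` flag. An optional
mask can exclude the homopolymeric C tracts (m.303–315,
m.16183–16194), off by default since there is no evidence the original
analysis excluded them.

Pathogenicity scores are inputs too (`read_score_lookup()`): the
package applies the > 0.43 decision rule but never computes scores.
In the bundled demonstration table only the m.7824C>T score (0.835) is
a published value; the rest are labelled placeholders. rRNA and
D-loop variants are never classed benign/damaging — summaries report
them as non-coding, giving the three-way benign/damaging/non-coding
breakdown.

## The simulator

`simulate_lineage()` generates lineage-structured pileups with known
truth under a deliberately minimal two-scale neutral model:

1. **Founder pool.** Eight variants at HFs 0.4%–50%
   (`default_founder_variants()`), emulating universal low-level
   heteroplasmy with a few substantial passengers.
2. **Bottleneck.** Each clone's founder cell draws
   HF = B/`n_seg`, B ~ Binomial(`n_seg` = 15, p₀). The small unit
   count, not the later drift, produces the broad clone spread
   (loss through high-HF clones from a 24% founder).
3. **Drift.** h ← Binomial(`n_copies` = 500, h)/`n_copies` per
   passaging generation (15 for reprogramming, 5 for differentiation).
   Neutral Wright-Fisher resampling: the mean is a martingale, the
   variance is h₀(1 − h₀)(1 − (1 − 1/N)ᵗ), and the fixation
   probability of a variant equals its current HF — all three laws are
   asserted in the tests at fixed seeds (20,000 replicates each).
4. **De novo events.** Poisson(`mu` × `polg_factor`) substitutions per
   generation at uniform random unused positions, starting at one copy
   (1/`n_copies`) and drifting thereafter. `mu` = 0.2 with
   `polg_factor` = 1 yields of order one detectable unique variant per
   clone; a mutator line is modelled by `polg_factor` > 1.
5. **Sequencing.** Depth ~ Poisson(stage mean: 15,000× fibroblast,
   7,000× iPSC, 6,000× NPC), split binomially between strands;
   templates drawn at the true HF; each base miscalled with
   probability `error_rate` = 10⁻³, split evenly across the three
   wrong bases. The 3107 placeholder receives no reads.

Choices where the literature gives no number: the bottleneck size
(15), copy number during passaging (500), generation counts (15/5) and
`mu` are plausible placeholders chosen once to reproduce the
qualitative behaviour above (passage counts in the 15–20 range are the
one documented quantity); they are configuration, not conclusions.
Selection is deliberately absent — the model drifts neutrally, with a
hook left in the configuration for future selection coefficients.

What the simulator does *not* emulate: read-level artifacts (NUMT
contamination, alignment error, PCR duplicates, strand-specific error
profiles), indels and macrodeletions, position-dependent coverage, or
selection. Passing the end-to-end tests therefore shows the pipeline's
logic is correct under idealized noise, not that real libraries are
free of artifact-driven calls — which is exactly why the strand filter
and audit trail exist.

## Numerical and degenerate-input conventions

* The caller is deterministic and invariant to pileup row order;
  output is sorted by position.
* Empty call sets, empty motifs (the rCRS's own haplogroup H2a2a1 has
  an empty motif by construction) and zero-record summaries are
  well-defined and return empty, correctly-shaped tables.
* A motif site with no coverage is `uncallable` and excluded from the
  haplotype-consistency denominator rather than failing it; an
  inconsistent haplotype warns (possible sample swap) and continues.
* Duplicate variant keys within one sample are a hard data error, not
  a silent merge.
* `rank_sum_test` on identical groups returns p = 1; a constant
  predictor in `linear_fit` is a degenerate-design error.
* Wilcoxon's exact branch is validated against full permutation
  enumeration; the Kruskal-Wallis H is validated against the
  rank-formula oracle exactly, and its chi-square p against full
  permutation enumeration at 4 observations per group — at 2 per
  group the chi-square approximation deviates from the exact
  permutation p by ~0.035, an inherent small-sample limitation worth
  knowing when group sizes are tiny.

## Problem sizes used in the tests

Monte-Carlo checks run at 10,000–20,000 replicates (bottleneck and
drift laws, fixation probability), 4,000 replicates for the type-I
error of the rank-sum test, and the end-to-end label-recovery check
uses 4 simulated lines × 3 clones with NPCs at the stage depths above
(≈ 230 eligible variant×pair events), recovering ≥ 99% of
transmitted/unique/non-transmitted labels for variants whose true HFs
on both sides lie outside [hf_min/2, 2·hf_min]. Near-threshold
variants are reported, not asserted: at a true HF of exactly 0.002,
binomial sampling at depth 7,000 puts the observed HF on either side
of the limit with near-equal probability, so no classifier can (or
should) be stable there.

## Known limitations

* SNVs only: no indels, no macrodeletion detection, no NUMT filtering,
  no realignment.
* Haplogroup motifs and pathogenicity scores are only as good as the
  supplied tables.
* The non-coding caveat on the reconstructed reference, above.
* Counting is per variant × lineage event; a substitution shared by
  two lines contributes one event to each, and summary tables state
  their totals rather than forcing any cross-line deduplication.
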