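---
title: "Methods: automated CNV scoring, score combination and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated CNV scoring, score combination and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvscore)
```

## The scoring procedure

`score_cnv()` evaluates a copy-number variant against the point-based
ACMG/ClinGen five-section standard to the extent position and public
annotation allow: Sections 1 and 3 completely, Section 2 except the
phenotype-dependent options, and option 4O from Section 4. Sections 4
(beyond 4O) and 5 — case literature, inheritance, family history — are out
of scope by construction: they require information about the patient, not
the variant. The result object therefore reports `unevaluated_options`
(loss `2J`/`2K`; gain `2I`–`2K`) so downstream users see exactly what was
not assessed rather than mistaking silence for negative evidence.

The engine's assumptions:

- CNVs are unstranded intervals on a single chromosome; all coordinates are
  1-based inclusive on disk and in memory, and chromosome names are
  normalized to the `chr`-prefixed dialect on input.
- Any positive overlap counts as overlap; there is no reciprocal-overlap
  threshold and no breakpoint uncertainty model.
- "Established" dosage sensitivity means a haploinsufficiency (HI) or
  triplosensitivity (TS) score of 3 by default. `engine_options(dosage_min_scores
  = c(1, 2, 3))` widens the search to lower-confidence records, which adds
  decided calls at some cost in accuracy; the recessive (30) and
  dosage-insensitive (40) codes never qualify.
- Per-gene evidence is resolved over **all** transcripts of the gene and the
  most severe option is kept (largest absolute points, ties broken toward
  the pathogenic direction, then by option id so results are deterministic).

### Section 2 structure

Section 2 emits at most one *dosage-line* evidence (2A/2B, the breakpoint
geometry options 2C–2E for losses, or the TS analogues for gains) and at
most one *benign-line* evidence (2F/2G for losses; 2C–2G for gains), plus
the gain-only flags 2H and 2L. The two lines are independent: the standard
treats dosage overlap and benign overlap as separate evidence rows, and the
engine may emit both. Within the dosage line, an established-region hit
(2A/2B) suppresses the geometry options for the same target, and the
predictor-based 2H is considered only when no established-HI evidence fired
at all — 2H is a weaker surrogate for the same claim, not an additive one.
Whether the standard caps Section 2 at one line or sums several is not
operationally specified anywhere we know of; the one-dosage-plus-one-benign
rule is this package's explicit, tested reading.

Loss 2G ("overlaps a benign region but includes additional material") is
resolved against the single overlapping benign record that covers the
largest fraction of the CNV, and "additional material" means at least one
protein-coding gene overlapped by the CNV but not by that record —
gene-level granularity, matching how Section 3 counts content. A partial
benign overlap that adds no protein-coding gene yields no benign-line
evidence at all: the standard's 2G is about extra material, and awarding it
points (even zero) without extra genes would misstate the evidence.

For gains, the benign comparisons check, per record and in this order:
identical protein-coding gene content (2C); CNV contained in the record
with breakpoints outside (2D) or potentially inside (2E) genes; record
contained in the CNV without (2F) or with (2G) additional protein-coding
genes; partial overlap with additional genes (2G). Across records the most
severe candidate is kept, with the same deterministic tie-break as above.

### Classification thresholds

`classify_score()` maps the summed score through P ≥ 0.99,
LP ∈ [0.90, 0.99), VUS ∈ (−0.90, 0.90), LB ∈ (−0.99, −0.90], B ≤ −0.99.
Published descriptions of the 5-tier bands leave two one-hundredth-wide
gaps, (−0.99, −0.98) and (0.98, 0.99), and disagree on whether the outer
boundaries are inclusive; this package closes the gaps toward LB/LP and
makes ±0.99 inclusive for B/P, consistent with the worked combination
example (0.9931 classifies P) and with how the boundary scores are used in
practice. The partition is total and monotone, which the tests assert
property-style.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dosage_min_scores` | `{3}` | HI/TS scores treated as established for 2A/2B |
| `benign_source` / `benign_flavor` | curated, outer | which benign-CNV record set backs 2F/2G |
| `maf_threshold` | 0.005 | minimum population frequency (fraction) for a benign record |
| `benign_type_filter` | both | search benign gains and losses for a loss CNV (the standard's recommendation) or losses only |
| `common_af_threshold` | 0.01 | allele frequency at which 4O fires |
| `hi_predictor_min` | 2 | concordant HI predictors required for 2H |
| `isv_ratio` (combiner) | 1 | weight of the ML term |

The default benign-database setting — curated records in their maximal
(outer) breakpoint representation, filtered at 0.5% population frequency,
both CNV types searched — is the configuration that best trades accuracy
against the fraction of CNVs decided in database-selection sweeps; the
unfiltered plain-record alternative is exposed as the `acmg-default`
preset. Frequency thresholds given as percentages at the CLI (`0.5%`) are
divided by 100 at parse time. 4O requires the CNV to be *contained* in a
common same-type population record, the same containment semantics as 2F;
plain overlap with a common variant is deliberately insufficient, since a
large CNV overlapping a small common variant shares little evidence with it.

## The score combination

`combine_scores()` implements `f_joint = ACMG + r * (p − 0.5)` and
classifies the joint score through the same thresholds. The ML probability
is always consumed, never computed: it arrives as a column or from any
provider; the bundled `gene_count_probability()` (a logistic curve over
overlapped protein-coding gene count) exists only so end-to-end runs need no
model file and makes no accuracy claim. Because `f_joint` is monotone in
`p`, band analyses only need the endpoints `p = 0` and `p = 1`:
`undecidable_band(r)` scans rule scores on a 0.01 grid (the granularity at
which such scores are reported) over ±1.5 and returns the largest symmetric
contiguous band where no probability can reach P or B — `[-0.48, 0.48]` at
`r = 1`, `[-0.98, 0.98]` at `r = 0`, empty at `r = 2`. The grid endpoints
±1.5 cover every total the default point sheet can produce.

`smallest_decisive_ratio()` searches the ratio grid upward in 0.01 steps;
for the (0.90, 0.99) example it returns 0.19, the first ratio at which the
joint score crosses 0.99. A second regime change near r ≈ 2 follows from
the same arithmetic: a score of 0 needs `r * (p − 0.5) ≥ 0.99`, i.e.
`r ≥ 1.98` at `p = 1` and `r ≈ 2.02` at `p = 0.99` — the often-quoted
breakpoint `r ≈ 1.99` sits between these endpoint values rather than
falling out of the formula exactly, which is why the package exposes the
sweep and band operations instead of hard-coding a second threshold.

## Evaluation conventions

With pathogenic as the positive class, only outright P and B predictions
are decided; LP, VUS and LB all count as *uncertain* (`tally()`), because
the likely categories do not carry enough conclusive evidence to act on.
`accuracy()` is correct/decided — uncertain calls enter neither numerator
nor denominator — and is reported as undefined (`NA`), not zero, when
nothing was decided. `unambiguous()` is decided/total. The McNemar–Bowker
test compares two methods on the same items after collapsing to the 3-class
Benign/Uncertain/Pathogenic view; off-diagonal pairs summing to zero are
skipped and reduce the degrees of freedom (the standard convention for the
test, stated here because it matters for small fixtures), and a table with
no discordant pairs is reported as inapplicable rather than dividing by
zero. `sweep_benign_db()` re-scores a labeled set under each of 4 benign
sources × (no filter + 6 thresholds) = 28 settings.

## The synthetic-fixture generator

`generate_annotation_bundle()` builds a three-chromosome toy genome (10 Mb
per chromosome, small enough that per-base brute-force test oracles stay
fast) with disjoint functional zones: background genes and a guaranteed
gene desert on chr1; dosage records, benign CNVs and population variants in
separate zones of chr2; a dense 60-gene cluster on chr3 for the gene-count
bands. Curated benign records are emitted in inner and outer coordinate
flavors (outer spanning inner) alongside independent plain record sets, and
record frequencies straddle all the sweep thresholds. One integer seed
drives everything through fixed per-file sub-seeds, so outputs are
byte-identical across runs and adding a record type never perturbs existing
files.

`generate_cnv_sets()` emulates the study-set structure: a *basic* set
(1 kb–5 Mb, copy numbers 1/3) whose members are constructed to hit specific
evidence — an established dosage region (2A), containment in a benign
record (2F for losses, the identical-content gain option 2C), a common
population variant (4O), the upper gene-count bands (3B/3C alternating), or
nothing at all (gene desert; exactly `{1B, 3A}`, hence VUS) — plus a
*large* set (> 5 Mb) and a *multiple* set (copy numbers 0/4). The planted
option and a truth label ride along with every basic CNV, which is the
module's core oracle: generate → load → score must re-emit every planted
option.

What the generator does **not** emulate: real size and frequency
distributions, label noise, overlapping evidence of competing kinds within
one CNV (zones are deliberately disjoint so planted expectations are
unambiguous), hg38 coordinates, or realistic gene density. Passing tests
therefore demonstrate that the rules, filters and statistics are computed
correctly — not that any particular accuracy level would be attained on
real clinical data, which depends on the annotation databases used.

## Numerical choices and degenerate inputs

- Boundary conventions: interval containment is inclusive; adjacent
  intervals do not overlap; Section 3 band lower bounds are inclusive.
- Tie-breaks everywhere are (|points| desc, points desc, option id asc),
  making every result order-independent and reproducible; query results are
  sorted by position.
- Scores at grid boundaries are compared exactly (no epsilon): grids are
  built as integer multiples of the step so 0.49 + 0.5 lands on the same
  double as the 0.99 threshold.
- Degenerate inputs: empty registries are valid (a CNV in an empty genome
  is `1B` + `3A`); an all-uncertain evaluation yields undefined accuracy;
  a diagonal paired table yields an inapplicable symmetry test; malformed
  annotation rows fail loading with row numbers and the offending
  transcript named.

## Problem sizes in the test suite

The suite runs the engine-versus-oracle comparison on 200 seeded random
CNVs over the toy genome, the database sweep on the 60-CNV basic set
(28 settings), and property checks on a few hundred random cases each —
sizes chosen so the whole suite completes in well under a minute while
still exercising every rule branch; the fixture zones guarantee coverage
that random sampling alone would miss.

## Known limitations

- Phenotype-dependent options are never scored (by design), so automated
  totals are conservative relative to full clinical interpretation.
- Exon-level refinements of the loss geometry options (e.g. whether a
  clipped 5' end involves coding sequence) are not modeled; geometry is
  resolved at transcript-span level with the 5' side given per transcript.
- The bundled probability provider is a toy; real combined classification
  requires an external model's probabilities.
- Loss 2G against multiple fragmented benign records considers only the
  best-covering record; a union-based reading would be more permissive.
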