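# cnvscore

Automated clinical interpretation of copy-number variants (CNVs) for
laboratory and research use. The package implements the point-based
ACMG/ClinGen five-section technical standard as an automated scoring engine,
blends the resulting rule-based score with a machine-learning pathogenicity
probability, and ships the evaluation machinery (accuracy, decided fraction,
confusion counts, paired McNemar–Bowker comparisons, benign-database sweeps)
plus a deterministic synthetic-fixture generator so the whole pipeline runs
and is tested without any external downloads.

## The scoring model

A CNV is a deletion (loss) or duplication (gain) of a genomic segment,
given as `chromosome:start-end` (1-based inclusive) plus its type. The
engine evaluates:

- **Section 1** — initial assessment of genomic content: option `1A` (0
  points) when the CNV overlaps a protein-coding gene or known functionally
  important element, `1B` (−0.60) otherwise.
- **Section 2** — overlap with established dosage-sensitive or benign
  regions: for losses `2A`/`2B` (complete/partial overlap of an established
  haploinsufficient gene or region), `2C`–`2E` (breakpoint geometry against
  a partially overlapped HI gene, resolved over all transcripts with the
  most severe kept), `2F` (completely contained within an established benign
  CNV, −1.00), `2G` (overlaps a benign CNV but extends over additional
  protein-coding genes), `2H` (concordant haploinsufficiency predictors);
  for gains the triplosensitivity analogues `2A`/`2B`, the benign-gain
  comparisons `2C`–`2G`, `2H` (HI gene fully contained) and `2L`
  (breakpoint inside a gene). Options needing patient phenotype (loss
  `2J`/`2K`, gain `2I`–`2K`) are reported as unevaluated, never guessed.
- **Section 3** — gene count: `3A`/`3B`/`3C` by the number of distinct
  protein-coding genes overlapped (loss bands 0–24 / 25–34 / ≥35; gain
  0–34 / 35–49 / ≥50).
- **Option 4O** — containment in common population variation (allele
  frequency ≥ 1% by default), −1.00.

Point values live in an editable YAML table
(`inst/extdata/scoring_acmg_default.yaml`). The summed score maps to the
5-tier classification: **P** (≥ 0.99), **LP** (0.90–0.99), **VUS**
(−0.90–0.90), **LB** (−0.99 to −0.90), **B** (≤ −0.99).

The combined classifier adds a machine-learning pathogenicity probability
`p` (consumed as input, e.g. from a gradient-boosted model) at weight `r`:

```
f_joint = ACMG_score + r * (p - 0.50)
```

Centring `p` at 0.5 means the ML term moves the score by at most `r/2`
either way, preserving the rule-based ranges.

## Worked example

```r
library(cnvscore)

# deterministic toy genome + labeled CNVs (no downloads)
spec   <- fixture_spec(seed = 1)
bundle <- generate_annotation_bundle(spec)
regs   <- scoring_registries(bundle)          # benign db: curated/outer, MAF >= 0.5%
sets   <- generate_cnv_sets(spec, bundle)

cnv <- sets$basic[1, ]
score_cnv(cnv_call(cnv$chrom, cnv$start, cnv$end, cnv$cnv_type, id = cnv$id), regs)
```

```
CNV basic0001: chr2:641194-843296 loss
evidence:
  1A   +0.00  protein-coding gene or functional element content
  2A   +1.00  complete overlap of HI gene (score 3)
  3A   +0.00  4 protein-coding genes overlapped
total score: +1.00 -> P
not evaluated automatically: 2J, 2K
```

The deletion completely overlaps an established haploinsufficient gene
(`2A`, +1.00), so the total reaches the pathogenic range. Combining a
rule-based score of 0.90 (LP on its own) with a confident ML probability:

```r
combine_scores(0.90, 0.99, isv_ratio = 0.19)
```

```
combined scores (r = 0.19)
 acmg_score isv_probability isv_ratio joint_score classification
        0.9            0.99      0.19      0.9931              P
```

The ML term lifts the variant over the 0.99 pathogenic threshold. Related
analyses: `undecidable_band(1)` returns `[-0.48, 0.48]`, the rule-score band
no probability can decide at `r = 1`; `ratio_sweep()` tallies
true/false/uncertain predictions across ratios; `sweep_benign_db()`
re-scores a labeled set under every benign-database source and frequency
threshold (4 sources × 7 settings = 28 rows).

A command-line interface wraps the same functions
(`exec/cnvscore classify|combine|evaluate|compare|sweep|fixtures`).

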