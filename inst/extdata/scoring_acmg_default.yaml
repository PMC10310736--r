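# Default CNV scoring table: per-option point values of the ACMG/ClinGen
# technical standard for copy-number variants, plus the 5-tier classification
# thresholds and the Section-3 gene-count bands.
#
# This file is data, not code: correcting a point value here never requires a
# code change. Loss options 2C-2E carry a single representative value each
# (the standard expresses them as ranges to be resolved case by case).
thresholds:
  pathogenic: 0.99        # score >= 0.99            -> P
  likely_pathogenic: 0.90 # 0.90 <= score < 0.99     -> LP
  likely_benign: -0.90    # -0.99 < score <= -0.90   -> LB
  benign: -0.99           # score <= -0.99           -> B
options:
  loss:
    "1A": { points: 0.00,  label: "contains protein-coding or other known functionally important elements" }
    "1B": { points: -0.60, label: "does NOT contain protein-coding or any known functionally important elements" }
    "2A": { points: 1.00,  label: "complete overlap of an established HI gene/genomic region" }
    "2B": { points: 0.00,  label: "partial overlap of an established HI genomic region" }
    "2C": { points: 0.90,  label: "partial overlap with the 5' end of an established HI gene" }
    "2D": { points: 0.30,  label: "partial overlap with the 3' end of an established HI gene" }
    "2E": { points: 0.45,  label: "both breakpoints within an established HI gene (intragenic)" }
    "2F": { points: -1.00, label: "completely contained within an established benign CNV region" }
    "2G": { points: 0.00,  label: "overlaps an established benign CNV region but includes additional genomic material" }
    "2H": { points: 0.15,  label: "two or more HI predictors suggest at least one gene in the interval is HI" }
    "3A": { points: 0.00,  label: "lowest gene-count band" }
    "3B": { points: 0.45,  label: "middle gene-count band" }
    "3C": { points: 0.90,  label: "highest gene-count band" }
    "4O": { points: -1.00, label: "overlap with common population variation" }
  gain:
    "1A": { points: 0.00,  label: "contains protein-coding or other known functionally important elements" }
    "1B": { points: -0.60, label: "does NOT contain protein-coding or any known functionally important elements" }
    "2A": { points: 1.00,  label: "complete overlap of an established TS gene/genomic region" }
    "2B": { points: 0.00,  label: "partial overlap of an established TS genomic region" }
    "2C": { points: -1.00, label: "identical in gene content to an established benign copy-number gain" }
    "2D": { points: -1.00, label: "smaller than established benign gain, breakpoints do not interrupt protein-coding genes" }
    "2E": { points: 0.00,  label: "smaller than established benign gain, breakpoints potentially interrupt protein-coding genes" }
    "2F": { points: -1.00, label: "larger than established benign gain, no additional protein-coding genes" }
    "2G": { points: 0.00,  label: "overlaps established benign gain but includes additional genomic material" }
    "2H": { points: 0.00,  label: "established HI gene fully contained within the gain" }
    "2L": { points: 0.00,  label: "one breakpoint within a gene" }
    "3A": { points: 0.00,  label: "lowest gene-count band" }
    "3B": { points: 0.45,  label: "middle gene-count band" }
    "3C": { points: 0.90,  label: "highest gene-count band" }
    "4O": { points: -1.00, label: "overlap with common population variation" }
# Lower bounds of the 3B and 3C gene-count bands (inclusive); 3A is below 3B.
gene_count_bands:
  loss: [25, 35]
  gain: [35, 50]
# Options that require patient phenotype or sequence-level evidence and are
# therefore never scored automatically; they are reported as unevaluated.
unevaluated:
  loss: ["2J", "2K"]
  gain: ["2I", "2J", "2K"]
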