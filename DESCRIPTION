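Package: cnvscore
Title: Automated ACMG/ClinGen Scoring of Copy-Number Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated evaluation of copy-number variants (CNVs) against the
    ACMG/ClinGen five-section technical standard: initial genomic content
    (Section 1), overlap with established dosage-sensitive or benign regions
    (Section 2), gene count (Section 3), and common population variation
    (option 4O), with the 5-tier Benign/Likely benign/VUS/Likely
    pathogenic/Pathogenic classification. Includes a combiner that blends the
    rule-based score with a machine-learning pathogenicity probability
    (f_joint = ACMG + r * (p - 0.5)), evaluation machinery (accuracy,
    unambiguous fraction, confusion counts, the McNemar-Bowker symmetry test,
    benign-database filtering sweeps), and a deterministic synthetic-fixture
    generator so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
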