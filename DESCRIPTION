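Package: famseg
Title: Family-Based Rare-Variant Prioritization and Segregation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based pipeline for prioritizing candidate disease
    variants in multiplex families sequenced by whole-exome sequencing,
    developed around dominant-model familial strabismus. It applies
    genotype-level quality control (sex-chromosome consistency, read
    depth, genotype quality, recurrent-indel flagging), a five-criterion
    rare-variant filter cascade (population allele frequency,
    loss-of-function or missense consequence, SIFT/PolyPhen-2
    deleteriousness, pLI gene constraint, developmental-process gene-set
    membership), pedigree-based segregation classification, and tiered
    evidence assignment by within-family segregation, cross-family
    recurrence, and phenotype gene-list intersection. A synthetic-cohort
    generator produces multi-family PED/VCF bundles with planted causal
    variants and criterion-targeted decoys so every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
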