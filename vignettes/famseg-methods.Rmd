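---
title: "Prioritizing rare variants in multiplex families: methods and design"
author: "famseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rare variants in multiplex families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

## The problem and the model

Comitant strabismus clusters strongly in families, but individual pedigrees
are too small for formal linkage or association. `famseg` implements the
pragmatic alternative used in family-based exome studies: a deterministic
rule cascade that narrows jointly-called exome variants down to a small
candidate set, followed by a qualitative segregation assessment under a
dominant, heterozygous inheritance model. The method makes three standing
assumptions:

* **Dominant-model inheritance.** Carriers are heterozygous or
  homozygous-alternate individuals; hemizygous male X carriers count as
  carriers. Recessive and compound-heterozygote models are out of scope.
* **Annotation is upstream.** Consequence terms, population allele
  frequencies and SIFT/PolyPhen-2 categories are consumed as VCF INFO
  fields; the package never re-derives them. The INFO key layout is
  declared in an `annotation_schema()` because annotator dialects differ.
* **Qualitative segregation.** No LOD scores or co-segregation Bayes
  factors: a family either shows the clean dominant pattern, a partial
  pattern, or is uninformative, and evidence tiers combine that with
  cross-family recurrence and curated phenotype gene lists.

## Genotype QC

Five rules discard individual genotype calls (the variant record itself is
never removed at this stage):

| rule | default | rationale |
|------|---------|-----------|
| `HET_X_MALE` | non-PAR X only | males are hemizygous on X; a het call is an artifact |
| `Y_IN_FEMALE` | — | any female Y call is an artifact |
| `LOW_DEPTH` | `DP < 10` reads | insufficient evidence for the genotype |
| `LOW_QUALITY` | `GQ < 90` (Phred) | the per-genotype quality, since the rule is applied per genotype; the field name is configurable for callers that encode it differently |
| `RECURRENT_INDEL` | carrier fraction ≥ 0.5 | indels recurring across most samples are alignment artifacts |

Boundary semantics are strict "fewer than": `DP = 10` and `GQ = 90` pass.
The recurrent-indel rule needs a whole-cohort first pass, so QC is
two-pass: flag recurrent indels, then sweep all calls. The 0.5 carrier
fraction is a package default — alignment-artifact indels typically recur
in most samples, and no consensus threshold exists; it is exposed in
`qc_config()`. Pseudoautosomal intervals default to GRCh37 PAR1/PAR2 and
are exempt from the het-X rule, since male heterozygosity there is
legitimate. A discarded genotype becomes *missing*, not homozygous
reference: absence of a reliable call is not evidence of the reference
allele, and this matters downstream where a missing affected genotype
makes a family less informative rather than a non-carrier.

Unknown-sex individuals pass the two sex-chromosome rules (they cannot be
evaluated) and are flagged for logging rather than discarded — silently
dropping their sex-chromosome calls would bias carrier counts.

## The filter cascade

Each criterion is a pure per-variant predicate, so the surviving set is
independent of application order; order only decides which criterion is
named "first failing" in the audit trace (the trace also lists all failing
criteria, so no information is lost).

* **Rarity** uses the ancestry-matched population frequency with `< 1e-3`
  exclusive. The threshold is a package default chosen to admit every
  reported frequency in the worked-example fixture (the largest is
  6.557e-4) while excluding polymorphisms; it is configurable. A variant
  with no frequency record is *private* and counts as rare — absence from
  the reference database is the strongest rarity signal available.
* **Consequence** keeps LoF (frameshift, stop-gained, canonical splice
  acceptor/donor) and missense, per the standard large-scale-exome
  definition. The most-severe-consequence reduction ships as a versioned
  severity table mirroring the VEP ordering, so "most severe" is
  reproducible without running an annotator; unknown terms rank below all
  known terms with a warning rather than an error.
* **Deleteriousness** applies to missense only (the criterion's own
  wording); LoF variants pass unconditionally. Either predictor suffices:
  SIFT `deleterious`/`deleterious_low_confidence` or PolyPhen-2
  `possibly_damaging`/`probably_damaging`. Low-confidence SIFT calls map
  to deleterious, matching how the categories are collapsed in published
  tables. A missense variant with neither predictor reported fails — the
  cascade demands positive evidence.
* **Constraint** is `pLI ≥ 0.9`, inclusive. Genes absent from the pLI
  table fail with a distinct `MISSING_PLI` reason: treating unscored genes
  as passing would let unmeasured genes through the one criterion meant to
  measure them. The pLI source (ExAC or gnomAD constraint files) is
  user-supplied; provenance is recorded, not enforced.
* **Developmental-process membership** is a flat gene-list lookup
  (GO:0032502, pre-expanded upstream). No ontology reasoning is bundled.
  Symbols match by exact upper-cased string; alias resolution is out of
  scope and mismatches surface in logs.

A sixth, structural requirement — at least one affected carrier after QC —
is pipeline plumbing rather than a stated criterion: a variant no affected
individual carries cannot be a familial candidate. It is reported under
its own `NO_AFFECTED_CARRIER` code so the audit trail distinguishes it
from the five annotation criteria.

Multiallelic sites are decomposed to one record per alt allele before
filtering, with per-allele INFO values split accordingly; this is the
package's choice (flagged in the record stream) since joint-called
pipelines differ here. Left-alignment of indels is assumed done upstream.

## Segregation and evidence tiers

For one variant in one family, counting only sequenced members with known
status, the rule table is:

* `uninformative` — fewer than two affected members have usable (post-QC,
  non-missing) genotypes;
* `complete` — ≥2 affected carriers, zero affected non-carriers, zero
  unaffected carriers;
* `none` — zero affected carriers;
* `partial` — otherwise.

"Complete" is deliberately the strictest reading of clear segregation.
Reduced penetrance — an unaffected carrier in an otherwise clean family —
is biologically plausible in strabismus, so tolerance of unaffected
carriers is a switch (`allow_unaffected_carriers`, default off) rather
than a silent policy. Unknown-status members are retained in the pedigree
but excluded from every count: they can neither confirm nor refute the
pattern.

Tiers: **credible** iff some family is `complete` or the gene has affected
carriers in ≥2 families; else **known_phenotype_gene** iff the gene is on
the HP:0000486 or literature list; else **weak**. Recurrence pools
distinct variants in the same gene (a per-variant recurrence is also
derivable from the evidence table), because cross-family evidence for a
gene does not require the identical allele; family counting is by family,
never by carrier count.

## The synthetic-cohort generator

The generator exists so every stage can be tested against known truth
without patient data. It emulates the statistical structure the cascade
assumes — not sequence-level reality:

* **Scale.** Default 18 families / 87 members / 53 affected / 34
  unaffected, matching the multiplex study design the defaults mirror.
  The fixed family layout (thirteen families of five, four of four, one
  extended family of six) is one concrete partition realizing those
  totals with ≥2 affected per family and dominant parent-to-child
  transmission wherever the structure allows.
* **Planted truth.** Six planted passers cover every tier route: clean
  segregation (all affecteds het, all unaffecteds reference), gene-level
  recurrence (one carrier in each of two families — neither family alone
  is clean, so the credible call must come from recurrence), partial
  segregation with and without phenotype-list membership. One decoy per
  failure mode violates exactly its targeted criterion (common frequency,
  low pLI, non-developmental gene, benign predictions, QC-killed carrier
  depth, no affected carrier) and satisfies all others, so the filter
  trace can be audited criterion-by-criterion.
* **Randomness.** Rare frequencies are log-uniform on [1e-6, 1e-3] with a
  0.3 chance of being private; common decoy/background frequencies are
  uniform on [0.01, 0.5]; genotype noise (low DP, low GQ, male-X het,
  missingness) is i.i.d. per call at configurable rates. Defaults are a
  few percent per axis — enough to exercise the QC rules on every run
  without overwhelming an 87-sample cohort. The model is deliberately
  simple: the pipeline under test is rule-based, and realistic LD,
  mutation-rate or read-level simulation would add nothing to its
  verification. Passing tests therefore demonstrate rule correctness, not
  performance on real exomes.
* **Determinism.** One integer seed drives all draws; the same
  configuration yields byte-identical files.

## Numerical and degenerate-input choices

* All report tables are sorted (variants by chromosome/position/alt/gene,
  audit rows by key/sample) so repeated runs are byte-identical.
* An empty variant stream, an empty candidate set, and an all-decoy truth
  table are valid inputs producing empty outputs (sensitivity is reported
  as not-applicable rather than 0/0).
* Thresholds act monotonically by construction: tightening `max_af` or
  raising `pli_threshold` can only shrink the candidate set, and raising
  QC thresholds can only discard more genotypes. The test suite asserts
  both properties.
* Frequency comparison is exclusive (`< max_af`), constraint inclusive
  (`≥ threshold`), exactly as the criteria are phrased.

## Verification problem sizes

The test suite verifies the cascade against an independent straight-line
oracle on 100 random cohorts of up to 50 variants × 10 samples, sweeps the
segregation rule table exhaustively for families of up to five members
(with a random sample of status patterns at the largest size), and runs
the full generate–run–score round trip across 20 seeds at the default
18-family scale. These sizes give exhaustive or near-exhaustive coverage
of the discrete rule space while keeping the default test run fast.

## Known limitations

* Dominant model only; no compound-heterozygote, recessive or de novo
  analysis.
* No relatedness or ancestry inference — the pedigree and the ancestry
  sidecar are trusted as given.
* Gene symbols are matched literally; annotation sources using different
  symbol vintages must be harmonized upstream.
* Segregation is qualitative; with very small families the `complete`
  tier can arise by chance, and nothing here quantifies that probability.
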