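# famseg

Family-based rare-variant prioritization and segregation analysis for
dominant-model whole-exome studies, developed around familial comitant
strabismus — multiplex families (two or more affected members) in which a
shared heterozygous coding variant is the candidate cause.

## What it does

Upstream tools produce a jointly-called, annotated multi-sample VCF and a
pedigree; `famseg` takes over from there:

1. **Genotype QC** — discards calls that are likely artifacts:
   heterozygous X-chromosome genotypes in males (outside the
   pseudoautosomal regions), any Y-chromosome genotype in a female, calls
   covered by fewer than 10 reads (`DP < 10`), calls with Phred-scaled
   genotype quality below 90 (`GQ < 90`), and indels recurring across a
   large fraction of samples. Discarded genotypes become *missing*, never
   homozygous reference.
2. **Filter cascade** — a variant is a candidate iff it is
   **rare** (ancestry-matched population allele frequency `< 1e-3`, or
   private), **LoF or missense** (LoF = frameshift, stop-gained, canonical
   splice site), **deleterious** if missense (SIFT deleterious *or*
   PolyPhen-2 possibly/probably damaging — either predictor suffices),
   in a **constrained gene** (pLI ≥ 0.9), in a **developmental-process
   gene** (GO:0032502 list), and carried post-QC by at least one affected
   individual. Every excluded variant gets an audit trace naming its
   failing criteria.
3. **Segregation & tiers** — each candidate is classified per family
   (*complete* = ≥2 affected carriers, no affected non-carrier, no
   unaffected carrier; *partial*; *none*; *uninformative* when fewer than
   two affected genotypes survive QC) and tiered: **credible** (complete
   segregation in a family, or the gene recurring in ≥2 families),
   **known_phenotype_gene** (gene on the HP:0000486 strabismus list or a
   literature list), else **weak**.
4. **Synthetic cohorts** — a generator emits PED + annotated VCF + resource
   tables + truth table for multi-family cohorts with planted causal
   variants and one decoy per failure mode, so the whole pipeline is
   testable against known ground truth. Defaults mirror the study scale:
   18 families, 87 individuals, 53 affected / 34 unaffected.

## Worked example

Simulate a noise-free cohort at the default scale and run the pipeline:

```r
library(famseg)
b <- generate_cohort(sim_config(seed = 1,
       noise_rates = c(low_dp = 0, low_gq = 0, het_x_male = 0, missing = 0)),
     "sim")
cfg <- run_config(vcf = b$paths$vcf, ped = b$paths$ped,
                  ancestry = b$paths$ancestry, pli = b$paths$pli,
                  go = b$paths$go, hpo = b$paths$hpo)
res <- run_pipeline(cfg, "out")
res$evidence[, c("gene", "per_family", "families_recurrent", "tier")]
```

```
  gene     per_family families_recurrent                 tier
  SEGA FAM01:complete                  1             credible
  SEGB FAM02:complete                  1             credible
  RECA  FAM03:partial                  2             credible
  RECA  FAM04:partial                  2             credible
  HPOA  FAM05:partial                  1 known_phenotype_gene
  HPOB  FAM06:partial                  1 known_phenotype_gene
 WEAKA  FAM07:partial                  1                 weak
 BG007  FAM05:partial                  1                 weak
```

8 of 53 variant records survive the cascade. `SEGA`/`SEGB` are credible by
clean within-family segregation; `RECA` is credible because the gene
recurs in two families even though neither family alone segregates
cleanly; `HPOA`/`HPOB` show partial segregation but sit on the phenotype
gene list; `WEAKA` (and one background survivor) carry only weak evidence.
The report bundle in `out/` has the candidate table, per-variant filter
trace, QC audit, evidence report (TSV + JSON), cohort summary and a run
manifest.

The package also ships ten published familial-strabismus risk variants as
a worked fixture:

```r
v <- example_risk_variants()
sum(is_rare(v$allele_freq, filter_config()))   # 10 — all rare or private
```

A command-line wrapper is installed at
`system.file("cli", "famseg", package = "famseg")` with subcommands
`run`, `simulate` and `validate`.

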