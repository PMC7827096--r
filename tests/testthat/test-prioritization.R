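test_that("consequence classes follow the LoF / missense / other partition", {
  expect_equal(classify_consequence("stop_gained"), "lof")
  expect_equal(classify_consequence("frameshift_variant"), "lof")
  expect_equal(classify_consequence("splice_acceptor_variant"), "lof")
  expect_equal(classify_consequence("missense_variant"), "missense")
  expect_equal(classify_consequence("synonymous_variant"), "other")
  expect_equal(classify_consequence(c("stop_gained", "intron_variant")),
               c("lof", "other"))
})

test_that("rarity admits frequencies below the threshold and private variants", {
  cfg <- filter_config()
  expect_true(is_rare(6.557e-4, cfg))
  expect_true(is_rare(NA_real_, cfg))
  expect_false(is_rare(0.5, cfg))
  expect_false(is_rare(1e-3, cfg))  # threshold is exclusive
})

test_that("deleteriousness needs either predictor for missense, neither for LoF", {
  expect_true(is_deleterious("deleterious", "benign", "missense"))
  expect_true(is_deleterious("tolerated", "probably_damaging", "missense"))
  expect_true(is_deleterious("tolerated", "possibly_damaging", "missense"))
  expect_true(is_deleterious("deleterious_low_confidence", "benign", "missense"))
  expect_false(is_deleterious("tolerated", "benign", "missense"))
  expect_false(is_deleterious(NA, NA, "missense"))  # no prediction, no evidence
  expect_true(is_deleterious(NA, NA, "lof"))        # criterion is missense-only
})

test_that("every published worked-example variant passes each per-variant criterion", {
  v <- example_risk_variants()
  expect_equal(nrow(v), 10L)
  cfg <- filter_config()
  dir <- tempfile(); dir.create(dir)
  writeLines(c("gene\tpLI", paste(v$gene, v$pLI, sep = "\t")),
             file.path(dir, "pli.tsv"))
  writeLines(v$gene, file.path(dir, "go.txt"))
  writeLines(c("ARID1B", "ARNT2", "COL4A1"), file.path(dir, "hpo.txt"))
  res <- load_resources(file.path(dir, "pli.tsv"), file.path(dir, "go.txt"),
                        file.path(dir, "hpo.txt"))
  cls <- classify_consequence(v$consequence, cfg$lof_terms)
  pass <- is_rare(v$allele_freq, cfg) &
    cls %in% c("lof", "missense") &
    is_deleterious(v$sift, v$polyphen, cls) &
    vapply(v$gene, function(g) isTRUE(as.logical(gene_passes_constraint(g, res))),
           logical(1)) &
    vapply(v$gene, gene_in_set, logical(1), named_set = "go_dev", resource = res)
  expect_equal(sum(pass), 10L)
})

test_that("run_cascade survivors match the generator truth table", {
  b <- generate_cohort(sim_config(seed = 21, noise_rates = noise_free),
                       file.path(tempdir(), "prio_truth"))
  co <- read_cohort_vcf(b$paths$vcf)
  ped <- mark_sequenced(parse_ped(b$paths$ped), co$samples)
  res <- run_cascade(co, ped, load_bundle_resources(b))
  planted <- b$truth[b$truth$decoy_mode == "none" & b$truth$intended_tier != "background", ]
  expect_true(all(planted$key %in% res$candidates$key))
  decoys <- b$truth[b$truth$decoy_mode != "none", ]
  expect_false(any(decoys$key %in% res$candidates$key))
})

test_that("excluded variants carry a trace naming first and all failing criteria", {
  b <- generate_cohort(sim_config(seed = 22, noise_rates = noise_free),
                       file.path(tempdir(), "prio_trace"))
  co <- read_cohort_vcf(b$paths$vcf)
  ped <- mark_sequenced(parse_ped(b$paths$ped), co$samples)
  res <- run_cascade(co, ped, load_bundle_resources(b))
  tr <- res$trace
  expect_true(all(nzchar(tr$first_fail[!tr$surviving])))
  expect_true(all(tr$first_fail[tr$surviving] == ""))
  # surviving <=> no criterion fails and an affected individual carries
  crit_cols <- c("RARE", "CONSEQUENCE", "DELETERIOUS", "PLI", "GO_DEV")
  no_fail <- apply(tr[, crit_cols] != "fail", 1, all)
  expect_equal(tr$surviving, no_fail & tr$carrier_ok)
  # first failing criterion is listed among all failing criteria
  multi <- !tr$surviving
  expect_true(all(mapply(function(ff, af) ff %in% strsplit(af, ",")[[1]],
                         tr$first_fail[multi], tr$all_fails[multi])))
})

test_that("a variant with no affected carrier is excluded with that reason", {
  states <- c(A1 = "hom_ref", A2 = "hom_ref", U1 = "het")
  co <- single_variant_cohort(states)
  ped <- founder_ped(names(states), c("affected", "affected", "unaffected"))
  dir <- tempfile(); dir.create(dir)
  writeLines(c("gene\tpLI", "GENE1\t0.99"), file.path(dir, "p.tsv"))
  writeLines("GENE1", file.path(dir, "g.txt"))
  writeLines("OTHER", file.path(dir, "h.txt"))
  res <- run_cascade(co, ped, load_resources(file.path(dir, "p.tsv"),
                                             file.path(dir, "g.txt"),
                                             file.path(dir, "h.txt")))
  expect_equal(nrow(res$candidates), 0L)
  expect_equal(res$trace$first_fail, "NO_AFFECTED_CARRIER")
})

test_that("the surviving set equals a brute-force intersection on random cohorts", {
  for (seed in 1:25) {
    rc <- random_small_cohort(seed)
    res <- run_cascade(rc$cohort, rc$ped, rc$resource)
    expect_setequal(res$candidates$key,
                    oracle_candidates(rc$cohort, rc$ped, rc$resource))
  }
})

test_that("tightening thresholds never enlarges the candidate set", {
  rc <- random_small_cohort(777)
  run_with <- function(max_af, pli) {
    run_cascade(rc$cohort, rc$ped, rc$resource,
                filt_conf = filter_config(max_af = max_af, pli_threshold = pli)
    )$candidates$key
  }
  loose <- run_with(1e-1, 0.5)
  for (p in list(c(1e-2, 0.5), c(1e-3, 0.5), c(1e-1, 0.9), c(1e-3, 0.99))) {
    expect_true(all(run_with(p[1], p[2]) %in% loose))
  }
})

test_that("candidate counts decompose by consequence class", {
  b <- generate_cohort(sim_config(seed = 23), file.path(tempdir(), "prio_sum"))
  co <- read_cohort_vcf(b$paths$vcf)
  ped <- mark_sequenced(parse_ped(b$paths$ped), co$samples)
  res <- run_cascade(co, ped, load_bundle_resources(b))
  s <- res$summary
  expect_equal(s$n_candidates, s$n_candidate_lof + s$n_candidate_missense)
  expect_equal(s$n_snv + s$n_indel, s$n_variants)
  expect_equal(s$n_coding_snv + s$n_noncoding_snv, s$n_snv)
  expect_equal(s$n_coding_indel + s$n_noncoding_indel, s$n_indel)
})

test_that("an empty variant stream yields empty outputs, not an error", {
  empty_vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=ctg1>",
               "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
               "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"c\">",
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"f\">",
               "##INFO=<ID=POP,Number=A,Type=String,Description=\"p\">",
               "##INFO=<ID=SIFT,Number=A,Type=String,Description=\"s\">",
               "##INFO=<ID=POLYPHEN,Number=A,Type=String,Description=\"q\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"),
             empty_vcf)
  co <- read_cohort_vcf(empty_vcf)
  ped <- founder_ped("S1", "affected")
  dir <- tempfile(); dir.create(dir)
  writeLines(c("gene\tpLI", "G\t0.99"), file.path(dir, "p.tsv"))
  writeLines("G", file.path(dir, "g.txt")); writeLines("G", file.path(dir, "h.txt"))
  res <- run_cascade(co, ped, load_resources(file.path(dir, "p.tsv"),
                                             file.path(dir, "g.txt"),
                                             file.path(dir, "h.txt")))
  expect_equal(nrow(res$candidates), 0L)
  expect_equal(res$summary$n_variants, 0L)
})
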