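test_that("the canonical family patterns classify as expected", {
  # two affected carriers, one unaffected non-carrier: clear segregation
  s <- seg_of(c("carrier", "carrier", "noncarrier"),
              c("affected", "affected", "unaffected"))
  expect_equal(s$status, "complete")
  expect_equal(s$affected_carriers, 2L)

  # 3 affected: 2 carriers + 1 non-carrier -> partial
  expect_equal(seg_of(c("carrier", "carrier", "noncarrier"),
                      rep("affected", 3))$status, "partial")

  # no affected carriers -> none
  expect_equal(seg_of(c("noncarrier", "noncarrier", "carrier"),
                      c("affected", "affected", "unaffected"))$status, "none")

  # fewer than two usable affected genotypes -> uninformative
  expect_equal(seg_of(c("carrier", "missing", "noncarrier"),
                      c("affected", "affected", "unaffected"))$status,
               "uninformative")
})

test_that("an unaffected carrier breaks complete segregation unless tolerated", {
  states <- c("carrier", "carrier", "carrier")
  statuses <- c("affected", "affected", "unaffected")
  expect_equal(seg_of(states, statuses)$status, "partial")
  expect_equal(seg_of(states, statuses, allow = TRUE)$status, "complete")
})

test_that("unknown-status and unsequenced members never enter the counts", {
  ids <- c("A1", "A2", "U1", "X1", "NS")
  co <- single_variant_cohort(c(A1 = "het", A2 = "het", U1 = "hom_ref",
                                X1 = "het", NS = "het"))
  ped <- founder_ped(ids, c("affected", "affected", "unaffected",
                            "unknown", "unaffected"))
  ped$sequenced[ped$individual_id == "NS"] <- FALSE
  s <- segregation_status(co, "ctg1:1000:A:G", ped, "FAM1")
  # the unknown-status carrier X1 and unsequenced carrier NS are invisible
  expect_equal(s$status, "complete")
  expect_equal(s$unaffected_carriers, 0L)
})

test_that("a variant absent from the family's calls is uninformative", {
  co <- single_variant_cohort(c(A1 = "het", A2 = "het"))
  ped <- founder_ped(c("A1", "A2"), c("affected", "affected"))
  expect_equal(segregation_status(co, "nope:1:A:G", ped, "FAM1")$status,
               "uninformative")
})

test_that("exhaustive enumeration reproduces the rule table for <= 5 members", {
  states <- c("carrier", "noncarrier", "missing")
  statuses <- c("affected", "unaffected")
  for (n in 2:5) {
    gt_grid <- expand.grid(rep(list(states), n), stringsAsFactors = FALSE)
    st_grid <- expand.grid(rep(list(statuses), n), stringsAsFactors = FALSE)
    # subsample the status patterns for n = 5 to keep the sweep quick but
    # cover every genotype configuration at least once
    st_rows <- if (n < 5) seq_len(nrow(st_grid)) else seq(1, nrow(st_grid), by = 3)
    for (si in st_rows) {
      stat <- unlist(st_grid[si, ], use.names = FALSE)
      for (gi in seq_len(nrow(gt_grid))) {
        g <- unlist(gt_grid[gi, ], use.names = FALSE)
        got <- seg_of(g, stat)$status
        expect_identical(got, oracle_segregation(g, stat),
                         label = sprintf("n=%d gt=%s st=%s", n,
                                         paste(g, collapse = ","),
                                         paste(stat, collapse = ",")))
      }
    }
  }
})

test_that("statuses are mutually exclusive and exhaustive", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:5, 1)
    s <- seg_of(sample(c("carrier", "noncarrier", "missing"), n, replace = TRUE),
                sample(c("affected", "unaffected"), n, replace = TRUE))
    expect_true(s$status %in% c("complete", "partial", "none", "uninformative"))
  }
})

test_that("gene-level recurrence counts families, not individuals", {
  cand <- data.frame(key = c("k1", "k2", "k3"), gene = c("FAT3", "FAT3", "KCNH2"),
                     carriers = c("F5_A,F5_B", "F9_A", "F7_A,F7_B"),
                     stringsAsFactors = FALSE)
  ped <- founder_ped(c("F5_A", "F5_B", "F9_A", "F7_A", "F7_B"),
                     rep("affected", 5))
  ped$family_id <- c("FAM5", "FAM5", "FAM9", "FAM7", "FAM7")
  rec <- cross_family_recurrence(cand, ped)
  expect_equal(unname(rec["FAT3"]), 2L)   # two families, pooling distinct variants
  expect_equal(unname(rec["KCNH2"]), 1L)  # two carriers, one family
  expect_equal(length(cross_family_recurrence(cand[0, ], ped)), 0L)
})

test_that("recurrence equals the brute-force family set union", {
  set.seed(5)
  for (i in 1:20) {
    n_cand <- sample(1:8, 1)
    peds <- founder_ped(sprintf("P%02d", 1:12), rep("affected", 12))
    peds$family_id <- sprintf("F%d", rep(1:4, each = 3))
    cand <- data.frame(
      key = sprintf("k%d", seq_len(n_cand)),
      gene = sample(c("GA", "GB"), n_cand, replace = TRUE),
      carriers = vapply(seq_len(n_cand), function(j) {
        paste(sample(peds$individual_id, sample(1:4, 1)), collapse = ",")
      }, character(1)), stringsAsFactors = FALSE)
    rec <- cross_family_recurrence(cand, peds)
    for (g in unique(cand$gene)) {
      fams <- unique(unlist(lapply(which(cand$gene == g), function(j) {
        ids <- strsplit(cand$carriers[j], ",")[[1]]
        peds$family_id[match(ids, peds$individual_id)]
      })))
      expect_equal(unname(rec[g]), length(fams))
    }
  }
})

test_that("tier assignment follows the credible / known-gene / weak ladder", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("gene\tpLI", "ARID1B\t0.999"), file.path(dir, "p.tsv"))
  writeLines("ARID1B", file.path(dir, "g.txt"))
  writeLines("ARID1B", file.path(dir, "h.txt"))
  res <- load_resources(file.path(dir, "p.tsv"), file.path(dir, "g.txt"),
                        file.path(dir, "h.txt"))
  # complete segregation in one family -> credible
  expect_equal(assign_tier("complete", 1L, "NOVELG", res), "credible")
  # gene recurring in two families -> credible even without complete segregation
  expect_equal(assign_tier(c("partial", "partial"), 2L, "NOVELG", res), "credible")
  # partial segregation in a phenotype-listed gene -> known_phenotype_gene
  expect_equal(assign_tier("partial", 1L, "ARID1B", res), "known_phenotype_gene")
  # partial segregation, unlisted gene -> weak
  expect_equal(assign_tier("partial", 1L, "NOVELG", res), "weak")
})

test_that("adding an affected carrier never demotes the tier", {
  dir <- tempfile(); dir.create(dir)
  writeLines(c("gene\tpLI", "G\t0.99"), file.path(dir, "p.tsv"))
  writeLines("G", file.path(dir, "g.txt")); writeLines("NOPE", file.path(dir, "h.txt"))
  res <- load_resources(file.path(dir, "p.tsv"), file.path(dir, "g.txt"),
                        file.path(dir, "h.txt"))
  rank <- c(weak = 1, known_phenotype_gene = 2, credible = 3)
  set.seed(7)
  for (i in 1:50) {
    n <- sample(3:5, 1)
    statuses <- c("affected", "affected", sample(c("affected", "unaffected"),
                                                 n - 2, replace = TRUE))
    g <- sample(c("carrier", "noncarrier"), n, replace = TRUE)
    # upgrade one affected non-carrier to carrier
    idx <- which(statuses == "affected" & g == "noncarrier")
    if (length(idx) == 0) next
    g2 <- g; g2[idx[1]] <- "carrier"
    tier_of <- function(gt) {
      st <- seg_of(gt, statuses)
      assign_tier(st$status, 1L, "G", res)
    }
    expect_true(rank[tier_of(g2)] >= rank[tier_of(g)])
  }
})
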