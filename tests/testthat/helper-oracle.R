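# Independent oracles: straight-line reimplementations of the QC rules,
# the filter criteria and the segregation rule table, written without
# reference to the package internals so they can cross-check them.

PAR1 <- c(60001, 2699520)
PAR2 <- c(154931044, 155260560)

# Straight-line five-rule QC + five-criterion cascade: returns the set of
# candidate variant keys for an in-memory cohort. Everything is computed
# with explicit loops and literal rules.
oracle_candidates <- function(cohort, ped, resource, min_depth = 10,
                              min_quality = 90, recurrent_frac = 0.5,
                              max_af = 1e-3, pli_threshold = 0.9) {
  v <- cohort$variants
  n_var <- nrow(v)
  samples <- cohort$samples
  sex <- setNames(ped$sex, ped$individual_id)[samples]
  sex[is.na(sex)] <- "unknown"
  status <- setNames(ped$status, ped$individual_id)[samples]

  # pass 1: recurrent indels
  recurrent <- rep(FALSE, n_var)
  for (i in seq_len(n_var)) {
    if (nchar(v$ref[i]) != nchar(v$alt[i])) {
      carriers <- 0
      for (s in seq_along(samples)) {
        g <- cohort$gt[i, s]
        if (!is.na(g) && (g == "het" || g == "hom_alt")) carriers <- carriers + 1
      }
      if (carriers / length(samples) >= recurrent_frac) recurrent[i] <- TRUE
    }
  }

  # pass 2: per-call discards
  gt <- cohort$gt
  for (i in seq_len(n_var)) {
    chrom <- sub("^chr", "", v$chrom[i])
    in_par <- chrom == "X" &&
      ((v$pos[i] >= PAR1[1] && v$pos[i] <= PAR1[2]) ||
         (v$pos[i] >= PAR2[1] && v$pos[i] <= PAR2[2]))
    for (s in seq_along(samples)) {
      g <- gt[i, s]
      if (is.na(g)) next
      drop <- FALSE
      if (chrom == "X" && !in_par && sex[s] == "male" && g == "het") drop <- TRUE
      if (chrom == "Y" && sex[s] == "female") drop <- TRUE
      if (!is.na(cohort$dp[i, s]) && cohort$dp[i, s] < min_depth) drop <- TRUE
      if (!is.na(cohort$gq[i, s]) && cohort$gq[i, s] < min_quality) drop <- TRUE
      if (recurrent[i]) drop <- TRUE
      if (drop) gt[i, s] <- NA
    }
  }

  # five per-variant criteria + affected-carrier requirement
  lof <- c("frameshift_variant", "stop_gained", "splice_acceptor_variant",
           "splice_donor_variant")
  keys <- character(0)
  for (i in seq_len(n_var)) {
    rare <- is.na(v$allele_freq[i]) || v$allele_freq[i] < max_af
    cls <- if (!is.na(v$consequence[i]) && v$consequence[i] %in% lof) "lof"
           else if (!is.na(v$consequence[i]) && v$consequence[i] == "missense_variant") "missense"
           else "other"
    csq_ok <- cls %in% c("lof", "missense")
    del_ok <- if (cls == "lof") TRUE else if (cls == "missense") {
      (!is.na(v$sift[i]) && v$sift[i] %in% c("deleterious", "deleterious_low_confidence")) ||
        (!is.na(v$polyphen[i]) && v$polyphen[i] %in% c("probably_damaging", "possibly_damaging"))
    } else TRUE
    score <- resource$pli[toupper(v$gene[i])]
    pli_ok <- !is.na(score) && score >= pli_threshold
    go_ok <- toupper(v$gene[i]) %in% resource$go_dev
    carrier <- FALSE
    for (s in seq_along(samples)) {
      g <- gt[i, s]
      if (!is.na(status[s]) && status[s] == "affected" && !is.na(g) &&
          (g == "het" || g == "hom_alt")) carrier <- TRUE
    }
    if (rare && csq_ok && del_ok && pli_ok && go_ok && carrier) {
      keys <- c(keys, v$key[i])
    }
  }
  keys
}

# Segregation rule table, restated independently for one family:
# `gtypes` is a character vector over {"carrier", "noncarrier", "missing"}
# aligned with `statuses` over {"affected", "unaffected"}.
oracle_segregation <- function(gtypes, statuses, allow_unaffected_carriers = FALSE) {
  aff <- statuses == "affected"
  usable <- gtypes != "missing"
  ac <- sum(aff & gtypes == "carrier")
  an <- sum(aff & gtypes == "noncarrier")
  uc <- sum(!aff & gtypes == "carrier")
  if (sum(aff & usable) < 2) return("uninformative")
  if (ac >= 2 && an == 0 && (allow_unaffected_carriers || uc == 0)) return("complete")
  if (ac == 0) return("none")
  "partial"
}

# Random in-memory cohorts for the oracle-equivalence checks.
random_small_cohort <- function(seed, max_variants = 50, max_samples = 10) {
  set.seed(seed)
  n_samp <- sample(4:max_samples, 1)
  n_var <- sample(5:max_variants, 1)
  samples <- sprintf("S%02d", seq_len(n_samp))
  ped <- data.frame(
    family_id = sample(c("FA", "FB"), n_samp, replace = TRUE),
    individual_id = samples, father_id = NA_character_, mother_id = NA_character_,
    sex = sample(c("male", "female", "unknown"), n_samp, replace = TRUE,
                 prob = c(0.45, 0.45, 0.1)),
    status = sample(c("affected", "unaffected", "unknown"), n_samp,
                    replace = TRUE, prob = c(0.5, 0.4, 0.1)),
    ancestry = "EUR", sequenced = TRUE, stringsAsFactors = FALSE)
  class(ped) <- c("fam_ped", "data.frame")

  genes <- sprintf("G%02d", 1:8)
  csq_pool <- c("missense_variant", "stop_gained", "frameshift_variant",
                "synonymous_variant", "intron_variant", "splice_acceptor_variant")
  chroms <- sample(c("ctg1", "ctg2", "X", "Y"), n_var, replace = TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1))
  pos <- ifelse(chroms == "X" & runif(n_var) < 0.3,
                sample(60001:2699520, n_var, replace = TRUE),  # some inside PAR1
                sample(3000000:9000000, n_var, replace = TRUE))
  is_indel <- runif(n_var) < 0.3
  ref <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
  alt <- ifelse(is_indel, paste0(ref, "T"),
                vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                       character(1)))
  variants <- data.frame(
    chrom = chroms, pos = pos, ref = ref, alt = alt,
    key = paste(chroms, pos, ref, alt, sep = ":"),
    variant_class = ifelse(is_indel, "indel", "SNV"),
    gene = sample(genes, n_var, replace = TRUE),
    consequence = sample(csq_pool, n_var, replace = TRUE),
    allele_freq = ifelse(runif(n_var) < 0.3, NA,
                         10^runif(n_var, -6, -0.5)),
    freq_population = "EUR",
    sift = sample(c("deleterious", "deleterious_low_confidence", "tolerated", NA),
                  n_var, replace = TRUE),
    polyphen = sample(c("probably_damaging", "possibly_damaging", "benign", NA),
                      n_var, replace = TRUE),
    stringsAsFactors = FALSE)
  variants <- variants[!duplicated(variants$key), , drop = FALSE]
  n_var <- nrow(variants)

  gt <- matrix(sample(c("hom_ref", "het", "hom_alt", NA), n_var * n_samp,
                      replace = TRUE, prob = c(0.55, 0.25, 0.1, 0.1)),
               nrow = n_var, dimnames = list(NULL, samples))
  dp <- matrix(sample(0:60, n_var * n_samp, replace = TRUE), nrow = n_var,
               dimnames = list(NULL, samples))
  gq <- matrix(sample(0:99, n_var * n_samp, replace = TRUE), nrow = n_var,
               dimnames = list(NULL, samples))
  cohort <- famseg:::new_cohort(variants, gt, dp, gq)

  pli <- setNames(round(runif(length(genes)), 3), genes)
  resource <- structure(list(pli = pli,
                             go_dev = sample(genes, 5),
                             hpo_strabismus = sample(genes, 2),
                             literature = character(0)),
                        class = "gene_resource")
  list(cohort = cohort, ped = ped, resource = resource)
}

# A tiny hand-built cohort around one variant: genotype states given per
# sample, autosomal, clean DP/GQ.
single_variant_cohort <- function(states, samples = names(states)) {
  variants <- data.frame(chrom = "ctg1", pos = 1000L, ref = "A", alt = "G",
                         key = "ctg1:1000:A:G", variant_class = "SNV",
                         gene = "GENE1", consequence = "missense_variant",
                         allele_freq = NA_real_, freq_population = NA_character_,
                         sift = "deleterious", polyphen = "probably_damaging",
                         stringsAsFactors = FALSE)
  gt <- matrix(unname(states), nrow = 1, dimnames = list(NULL, samples))
  dp <- matrix(50, nrow = 1, ncol = length(samples), dimnames = list(NULL, samples))
  gq <- matrix(99, nrow = 1, ncol = length(samples), dimnames = list(NULL, samples))
  famseg:::new_cohort(variants, gt, dp, gq)
}

founder_ped <- function(ids, statuses, family = "FAM1", sex = NULL) {
  ped <- data.frame(family_id = family, individual_id = ids,
                    father_id = NA_character_, mother_id = NA_character_,
                    sex = if (is.null(sex)) rep("male", length(ids)) else sex,
                    status = statuses, ancestry = "EUR", sequenced = TRUE,
                    stringsAsFactors = FALSE)
  class(ped) <- c("fam_ped", "data.frame")
  ped
}

noise_free <- c(low_dp = 0, low_gq = 0, het_x_male = 0, missing = 0)

# Package-side segregation call on a one-variant, one-family cohort built
# from abstract carrier states.
seg_of <- function(states, statuses, allow = FALSE) {
  ids <- sprintf("M%d", seq_along(states))
  gt <- c(carrier = "het", noncarrier = "hom_ref", missing = NA)[states]
  co <- single_variant_cohort(setNames(gt, ids))
  ped <- founder_ped(ids, statuses)
  segregation_status(co, "ctg1:1000:A:G", ped, "FAM1",
                     allow_unaffected_carriers = allow)
}

# Default resources for a generated bundle.
load_bundle_resources <- function(b) {
  load_resources(b$paths$pli, b$paths$go, b$paths$hpo)
}
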