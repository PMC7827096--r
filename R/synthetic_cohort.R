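# Synthetic multi-family cohort generator.
#
# Emits a complete analysis bundle — PED, annotated multi-sample VCF,
# ancestry sidecar, pLI table, gene lists, and a ground-truth table — with
# the statistical structure the pipeline assumes: multiplex nuclear/extended
# families, heterozygous dominant transmission of planted causal variants,
# private-to-rare population frequencies for planted variants, and i.i.d.
# genotype noise targeted at each QC rule. The default scale mirrors the
# study design this pipeline was built around: 18 families, 87 sequenced
# individuals, 53 affected and 34 unaffected.
#
# Each decoy variant is constructed to violate exactly one filter criterion
# while satisfying all others, so the audit trace can be checked
# criterion-by-criterion against the truth table.

DECOY_MODES <- c("common_af", "low_pli", "non_go_gene", "benign_predictions",
                 "qc_killed", "no_affected_carrier", "none")

# Criterion (or carrier-requirement code) each decoy mode is built to trip.
DECOY_EXPECTED_FAIL <- c(common_af = "RARE", low_pli = "PLI",
                         non_go_gene = "GO_DEV", benign_predictions = "DELETERIOUS",
                         qc_killed = "NO_AFFECTED_CARRIER",
                         no_affected_carrier = "NO_AFFECTED_CARRIER")

#' Describe one planted variant
#'
#' @param intended_tier `"credible_segregating"`, `"credible_recurrent"`,
#'   `"known_phenotype_gene"`, `"weak"` or `"decoy"`.
#' @param gene Gene symbol to plant the variant in.
#' @param target_families Integer indices of the carrier families.
#' @param decoy_mode The single criterion a decoy violates; `"none"` for
#'   non-decoys.
#' @param consequence Consequence term; default missense.
#' @return A `planted_variant` list.
#' @export
planted_variant <- function(intended_tier, gene, target_families,
                            decoy_mode = "none",
                            consequence = "missense_variant") {
  decoy_mode <- match.arg(decoy_mode, DECOY_MODES)
  if ((decoy_mode == "none") == (intended_tier == "decoy")) {
    stop("decoy_mode must be 'none' exactly when intended_tier is not 'decoy'")
  }
  structure(list(intended_tier = intended_tier, gene = toupper(gene),
                 target_families = as.integer(target_families),
                 decoy_mode = decoy_mode, consequence = consequence),
            class = "planted_variant")
}

#' Default planted-variant specification
#'
#' Six planted passers spanning every tier (two cleanly segregating, one
#' gene recurring in two families via distinct variants, two
#' partial-segregation variants in phenotype-listed genes, one weak) plus
#' one decoy per filter failure mode.
#'
#' @param n_families Number of families in the cohort (family indices are
#'   assigned cyclically when fewer than 13).
#' @return List of [planted_variant()]s.
#' @export
default_planted_spec <- function(n_families = 18L) {
  fam <- function(k) ((k - 1L) %% n_families) + 1L
  list(
    planted_variant("credible_segregating", "SEGA", fam(1)),
    planted_variant("credible_segregating", "SEGB", fam(2), consequence = "stop_gained"),
    planted_variant("credible_recurrent", "RECA", fam(3)),
    planted_variant("credible_recurrent", "RECA", fam(4)),
    planted_variant("known_phenotype_gene", "HPOA", fam(5)),
    planted_variant("known_phenotype_gene", "HPOB", fam(6)),
    planted_variant("weak", "WEAKA", fam(7)),
    planted_variant("decoy", "DECAF", fam(8), decoy_mode = "common_af"),
    planted_variant("decoy", "DECPLI", fam(9), decoy_mode = "low_pli"),
    planted_variant("decoy", "DECGO", fam(10), decoy_mode = "non_go_gene"),
    planted_variant("decoy", "DECPRED", fam(11), decoy_mode = "benign_predictions"),
    planted_variant("decoy", "DECQC", fam(12), decoy_mode = "qc_killed"),
    planted_variant("decoy", "DECCARR", fam(13), decoy_mode = "no_affected_carrier")
  )
}

#' Simulation configuration
#'
#' Defaults mirror the multiplex-strabismus study design: 18 families, 87
#' sequenced members, 53 affected / 34 unaffected, every family with at
#' least two affected members, dominant heterozygous transmission of
#' planted variants, and modest genotype noise on each QC axis.
#'
#' @param n_families Number of families.
#' @param family_sizes Integer vector (length `n_families`) of member
#'   counts; the default 18-family layout is thirteen families of five,
#'   four of four and one of six (87 members).
#' @param family_affected Affected members per family (>= 2 each).
#' @param family_size_range Size range used to draw `family_sizes` when not
#'   supplied for a non-default `n_families`.
#' @param affected_per_family_min Minimum affected members per family.
#' @param n_background_variants Unplanted variants with mixed frequencies
#'   and consequence classes.
#' @param planted List of [planted_variant()]s.
#' @param noise_rates Named fractions `low_dp`, `low_gq`, `het_x_male`,
#'   `missing` — i.i.d. per-call corruption rates targeting each QC rule.
#' @param seed Integer seed; identical configs give byte-identical bundles.
#' @return A `sim_config` list (validated).
#' @export
sim_config <- function(n_families = 18L, family_sizes = NULL,
                       family_affected = NULL, family_size_range = c(4L, 6L),
                       affected_per_family_min = 2L,
                       n_background_variants = 40L,
                       planted = default_planted_spec(n_families),
                       noise_rates = c(low_dp = 0.02, low_gq = 0.02,
                                       het_x_male = 0.01, missing = 0.01),
                       seed = 1L) {
  n_families <- as.integer(n_families)
  if (n_families < 1L) stop("sim_config: n_families must be >= 1")
  if (is.null(family_sizes)) {
    if (n_families == 18L) {
      family_sizes <- c(rep(5L, 13), rep(4L, 4), 6L)
      if (is.null(family_affected)) family_affected <- c(rep(3L, 13), rep(2L, 4), 6L)
    } else {
      family_sizes <- rep(seq(family_size_range[1L], family_size_range[2L]),
                          length.out = n_families)
    }
  }
  if (is.null(family_affected)) {
    family_affected <- rep(max(2L, affected_per_family_min), n_families)
  }
  if (length(family_sizes) != n_families || length(family_affected) != n_families) {
    stop("sim_config: family_sizes/family_affected must have length n_families")
  }
  if (any(family_affected < affected_per_family_min)) {
    stop("sim_config: a family has fewer affected members than affected_per_family_min")
  }
  if (any(family_affected > family_sizes)) {
    stop(sprintf("sim_config infeasible: family %d has %d affected but only %d members",
                 which(family_affected > family_sizes)[1L],
                 family_affected[which(family_affected > family_sizes)[1L]],
                 family_sizes[which(family_affected > family_sizes)[1L]]))
  }
  need <- c("low_dp", "low_gq", "het_x_male", "missing")
  if (!all(need %in% names(noise_rates))) {
    stop("sim_config: noise_rates must name low_dp, low_gq, het_x_male, missing")
  }
  noise_rates <- noise_rates[need]
  if (any(noise_rates < 0 | noise_rates > 1)) stop("sim_config: noise rates must lie in [0, 1]")
  for (p in planted) {
    if (any(p$target_families < 1L | p$target_families > n_families)) {
      stop(sprintf("sim_config infeasible: planted variant in %s targets family index outside 1..%d",
                   p$gene, n_families))
    }
  }
  structure(list(n_families = n_families, family_sizes = as.integer(family_sizes),
                 family_affected = as.integer(family_affected),
                 n_background_variants = as.integer(n_background_variants),
                 planted = planted, noise_rates = noise_rates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Build the pedigree table for one family: father + mother founders and
# size-2 children. Affected assignment is father first, then children, then
# (only if every member must be affected) the mother — dominant transmission
# from one affected parent wherever possible.
build_family <- function(fam_id, size, n_affected) {
  n_children <- size - 2L
  ids <- c("I.1", "I.2", if (n_children > 0L) paste0("II.", seq_len(n_children)))
  sex <- c("male", "female",
           if (n_children > 0L) rep(c("male", "female"), length.out = n_children))
  father <- c(NA, NA, rep("I.1", n_children))
  mother <- c(NA, NA, rep("I.2", n_children))
  status <- rep("unaffected", size)
  aff_order <- c(1L, seq_len(n_children) + 2L, 2L)  # father, children, mother last
  status[aff_order[seq_len(n_affected)]] <- "affected"
  uid <- paste0(fam_id, "_", ids)
  data.frame(family_id = fam_id, individual_id = uid,
             father_id = ifelse(is.na(father), NA, paste0(fam_id, "_", father)),
             mother_id = ifelse(is.na(mother), NA, paste0(fam_id, "_", mother)),
             sex = sex, status = status, ancestry = "EUR", sequenced = TRUE,
             stringsAsFactors = FALSE)
}

fmt_af <- function(af) sprintf("%.4g", af)

# Draw a rare allele frequency (log-uniform over [1e-6, 1e-3]) or mark the
# variant private with probability 0.3.
draw_rare_af <- function() {
  if (stats::runif(1) < 0.3) NA_real_ else 10^stats::runif(1, -6, -3)
}

#' Generate a synthetic cohort bundle
#'
#' Writes `families.ped`, `cohort.vcf`, `ancestry.tsv`, `pli.tsv`,
#' `go_genes.txt`, `hpo_genes.txt` and `truth.tsv` into `out_dir`.
#' Reproducible: the same `sim_config` yields byte-identical files.
#'
#' Planted non-decoy variants are heterozygous in the affected members of
#' their target families per their intended tier (all affecteds for clean
#' segregation; all-but-one for partial patterns; exactly one per family
#' for the recurrence route) and absent from unaffecteds. Each decoy
#' satisfies every criterion except the one its mode targets.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the file `paths`, the `truth` table and the
#'   pedigree.
#' @export
generate_cohort <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  fam_ids <- sprintf("FAM%02d", seq_len(config$n_families))
  ped <- do.call(rbind, Map(build_family, fam_ids, config$family_sizes,
                            config$family_affected))
  rownames(ped) <- NULL
  class(ped) <- c("fam_ped", "data.frame")
  samples <- ped$individual_id
  n_samp <- length(samples)
  male <- ped$sex == "male"

  # --- resource tables -------------------------------------------------
  planted_genes <- unique(vapply(config$planted, `[[`, character(1), "gene"))
  decoy_mode_of <- vapply(config$planted, `[[`, character(1), "decoy_mode")
  gene_mode <- stats::setNames(decoy_mode_of[match(planted_genes,
                              vapply(config$planted, `[[`, character(1), "gene"))],
                               planted_genes)
  tier_of <- vapply(config$planted, `[[`, character(1), "intended_tier")
  hpo_planted <- unique(vapply(config$planted[tier_of == "known_phenotype_gene"],
                               `[[`, character(1), "gene"))

  n_bg <- config$n_background_variants
  bg_genes <- sprintf("BG%03d", seq_len(max(n_bg, 1L)))[seq_len(n_bg)]
  bg_pli <- round(stats::runif(n_bg), 3)
  bg_in_go <- stats::runif(n_bg) < 0.5

  pli_tab <- data.frame(
    gene = c(planted_genes, bg_genes),
    pLI = c(ifelse(gene_mode[planted_genes] == "low_pli", 0.1, 0.99), bg_pli))
  go_genes <- sort(c(setdiff(planted_genes, names(gene_mode)[gene_mode == "non_go_gene"]),
                     bg_genes[bg_in_go]))
  hpo_genes <- sort(unique(c(hpo_planted,
                             bg_genes[seq_len(min(2L, n_bg))])))

  # --- variant construction -------------------------------------------
  contigs <- c("ctg1", "ctg2", "ctg3", "ctg4", "X", "Y")
  gt_mat <- NULL; dp_mat <- NULL; gq_mat <- NULL
  rows <- list(); truth <- list()
  pos_counter <- stats::setNames(rep(0L, length(contigs)), contigs)
  next_pos <- function(chrom) {
    pos_counter[chrom] <<- pos_counter[chrom] + 1L
    10000L + 1000L * pos_counter[chrom]
  }
  base_dp <- function(n) sample(20:60, n, replace = TRUE)
  base_gq <- function(n) sample(90:99, n, replace = TRUE)

  add_variant <- function(chrom, ref, alt, gene, csq, af, sift, polyphen,
                          carrier_idx, carrier_dp = NULL,
                          intended_tier = "background", decoy_mode = "none",
                          target_families = integer(0)) {
    pos <- next_pos(chrom)
    gt <- rep("0/0", n_samp)
    if (chrom == "Y") gt[!male] <- "./."
    gt[carrier_idx] <- "0/1"
    dp <- base_dp(n_samp); gq <- base_gq(n_samp)
    if (!is.null(carrier_dp)) dp[carrier_idx] <- carrier_dp
    rows[[length(rows) + 1L]] <<- list(chrom = chrom, pos = pos, ref = ref,
                                       alt = alt, gene = gene, csq = csq, af = af,
                                       sift = sift, polyphen = polyphen)
    gt_mat <<- rbind(gt_mat, gt); dp_mat <<- rbind(dp_mat, dp); gq_mat <<- rbind(gq_mat, gq)
    truth[[length(truth) + 1L]] <<- data.frame(
      key = variant_key(chrom, pos, ref, alt), gene = gene,
      intended_tier = intended_tier, decoy_mode = decoy_mode,
      target_families = paste(fam_ids[target_families], collapse = ","),
      expected_fail = if (decoy_mode == "none") "" else DECOY_EXPECTED_FAIL[[decoy_mode]],
      stringsAsFactors = FALSE)
    invisible(NULL)
  }

  fam_members <- function(fi) which(ped$family_id == fam_ids[fi])
  fam_affected <- function(fi) intersect(fam_members(fi), which(ped$status == "affected"))
  fam_unaffected <- function(fi) intersect(fam_members(fi), which(ped$status == "unaffected"))

  bases <- c("A", "C", "G", "T")
  for (k in seq_along(config$planted)) {
    p <- config$planted[[k]]
    ref <- sample(bases, 1L); alt <- sample(setdiff(bases, ref), 1L)
    csq <- p$consequence
    cls <- classify_consequence(csq)
    sift <- if (cls == "missense") "deleterious" else NA_character_
    polyphen <- if (cls == "missense") "probably_damaging" else NA_character_
    af <- draw_rare_af()
    carrier_dp <- NULL
    carriers <- integer(0)
    mode <- p$decoy_mode
    if (mode == "none") {
      for (fi in p$target_families) {
        aff <- fam_affected(fi)
        carriers <- c(carriers, switch(
          p$intended_tier,
          credible_segregating = aff,
          credible_recurrent = aff[1L],
          known_phenotype_gene = aff[-length(aff)],
          weak = aff[-length(aff)],
          stop(sprintf("unknown intended_tier '%s'", p$intended_tier))))
      }
    } else {
      fi <- p$target_families[1L]
      aff <- fam_affected(fi)
      carriers <- aff
      if (mode == "common_af") af <- stats::runif(1, 0.01, 0.5)
      if (mode == "benign_predictions") { sift <- "tolerated"; polyphen <- "benign" }
      if (mode == "qc_killed") carrier_dp <- 5L
      if (mode == "no_affected_carrier") carriers <- fam_unaffected(fi)
    }
    add_variant("ctg1", ref, alt, p$gene, csq, af, sift, polyphen,
                carriers, carrier_dp, intended_tier = p$intended_tier,
                decoy_mode = mode, target_families = p$target_families)
  }

  csq_pool <- c("synonymous_variant", "intron_variant", "missense_variant",
                "3_prime_UTR_variant", "stop_gained", "splice_region_variant")
  for (b in seq_len(n_bg)) {
    chrom <- sample(contigs, 1L, prob = c(0.22, 0.22, 0.22, 0.22, 0.08, 0.04))
    is_indel <- stats::runif(1) < 0.2
    ref <- sample(bases, 1L)
    alt <- if (is_indel) paste0(ref, sample(bases, 1L)) else sample(setdiff(bases, ref), 1L)
    csq <- sample(csq_pool, 1L)
    common <- stats::runif(1) < 0.5
    af <- if (common) stats::runif(1, 0.01, 0.5) else draw_rare_af()
    cls <- classify_consequence(csq)
    sift <- if (cls == "missense") sample(SIFT_LEVELS, 1L) else NA_character_
    polyphen <- if (cls == "missense") sample(POLYPHEN_LEVELS, 1L) else NA_character_
    eligible <- if (chrom == "Y") which(male) else seq_len(n_samp)
    n_carr <- max(0L, stats::rbinom(1L, length(eligible),
                                    if (common) 0.3 else 0.03))
    carriers <- sort(sample(eligible, min(n_carr, length(eligible))))
    add_variant(chrom, ref, alt, bg_genes[b], csq, af, sift, polyphen, carriers)
  }

  # --- genotype noise (i.i.d. per call) --------------------------------
  nr <- config$noise_rates
  n_var <- length(rows)
  if (any(nr > 0) && n_var > 0L) {
    chroms <- vapply(rows, `[[`, character(1), "chrom")
    for (v in seq_len(n_var)) {
      low_dp <- stats::runif(n_samp) < nr[["low_dp"]]
      dp_mat[v, low_dp] <- sample(0:9, sum(low_dp), replace = TRUE)
      low_gq <- stats::runif(n_samp) < nr[["low_gq"]]
      gq_mat[v, low_gq] <- sample(0:89, sum(low_gq), replace = TRUE)
      if (chroms[v] == "X") {
        hx <- male & stats::runif(n_samp) < nr[["het_x_male"]]
        gt_mat[v, hx] <- "0/1"
      }
      miss <- stats::runif(n_samp) < nr[["missing"]]
      gt_mat[v, miss] <- "./."
    }
  }

  # --- write bundle ----------------------------------------------------
  paths <- list(ped = file.path(out_dir, "families.ped"),
                vcf = file.path(out_dir, "cohort.vcf"),
                ancestry = file.path(out_dir, "ancestry.tsv"),
                pli = file.path(out_dir, "pli.tsv"),
                go = file.path(out_dir, "go_genes.txt"),
                hpo = file.path(out_dir, "hpo_genes.txt"),
                truth = file.path(out_dir, "truth.tsv"))
  writeLines(format_ped(ped), paths$ped)
  writeLines(c("sample_id\tpopulation", paste(samples, ped$ancestry, sep = "\t")),
             paths$ancestry)
  writeLines(c("gene\tpLI", paste(pli_tab$gene, pli_tab$pLI, sep = "\t")), paths$pli)
  writeLines(go_genes, paths$go)
  writeLines(hpo_genes, paths$hpo)
  truth <- do.call(rbind, truth)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famseg_synthetic_cohort",
    sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Most severe consequence\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Ancestry-matched population allele frequency\">",
    "##INFO=<ID=POP,Number=A,Type=String,Description=\"Frequency population\">",
    "##INFO=<ID=SIFT,Number=A,Type=String,Description=\"SIFT category\">",
    "##INFO=<ID=POLYPHEN,Number=A,Type=String,Description=\"PolyPhen-2 category\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t"))
  ord <- order(match(vapply(rows, `[[`, character(1), "chrom"), contigs),
               vapply(rows, `[[`, numeric(1), "pos"))
  body <- vapply(ord, function(v) {
    r <- rows[[v]]
    info <- sprintf("GENE=%s;CSQ=%s", r$gene, r$csq)
    if (!is.na(r$af)) info <- sprintf("%s;AF=%s;POP=EUR", info, fmt_af(r$af))
    if (!is.na(r$sift)) info <- sprintf("%s;SIFT=%s", info, r$sift)
    if (!is.na(r$polyphen)) info <- sprintf("%s;POLYPHEN=%s", info, r$polyphen)
    calls <- sprintf("%s:%d:%d", gt_mat[v, ], dp_mat[v, ], gq_mat[v, ])
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, "100", "PASS", info, "GT:DP:GQ",
            calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), paths$vcf)

  invisible(list(paths = paths, truth = truth, ped = ped))
}

#' Score a pipeline run against the generator's truth table
#'
#' Sensitivity is the fraction of planted non-decoy variants recovered in
#' the candidate set; specificity is the fraction of decoys correctly
#' rejected. Decoy audit rows check that each rejected decoy's failing
#' criteria include the criterion its mode targets. The confusion table
#' crosses intended tiers with assigned tiers for recovered variants.
#'
#' @param cascade_result Result of [run_cascade()].
#' @param evidence Result of [build_evidence()] on the same run.
#' @param truth Truth table from [generate_cohort()].
#' @return List: `sensitivity` (NA if no non-decoys planted), `specificity`
#'   (NA if no decoys), `decoys` (per-decoy audit), `confusion`
#'   (intended x assigned tier table), `unexpected` (candidate keys absent
#'   from the truth table, i.e. background variants that survived).
#' @export
evaluate_against_truth <- function(cascade_result, evidence, truth) {
  cand_keys <- cascade_result$candidates$key
  planted <- truth[truth$intended_tier != "background", , drop = FALSE]
  pos <- planted[planted$decoy_mode == "none", , drop = FALSE]
  dec <- planted[planted$decoy_mode != "none", , drop = FALSE]

  sensitivity <- if (nrow(pos)) mean(pos$key %in% cand_keys) else NA_real_
  specificity <- if (nrow(dec)) mean(!dec$key %in% cand_keys) else NA_real_

  trace <- cascade_result$trace
  decoys <- if (nrow(dec)) {
    data.frame(key = dec$key, decoy_mode = dec$decoy_mode,
               expected_fail = dec$expected_fail,
               rejected = !dec$key %in% cand_keys,
               observed_fails = trace$all_fails[match(dec$key, trace$key)],
               stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(0), decoy_mode = character(0),
               expected_fail = character(0), rejected = logical(0),
               observed_fails = character(0), stringsAsFactors = FALSE)
  }
  decoys$fail_matches <- mapply(function(exp, obs) {
    exp %in% strsplit(if (is.na(obs)) "" else obs, ",", fixed = TRUE)[[1L]]
  }, decoys$expected_fail, decoys$observed_fails, USE.NAMES = FALSE)

  assigned <- evidence$tier[match(pos$key, evidence$key)]
  assigned[is.na(assigned)] <- "not_recovered"
  intended <- sub("^credible_(segregating|recurrent)$", "credible", pos$intended_tier)
  confusion <- table(intended = intended, assigned = assigned)

  list(sensitivity = sensitivity, specificity = specificity, decoys = decoys,
       confusion = confusion,
       unexpected = setdiff(cand_keys, truth$key))
}
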