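# Genotype-level quality control.
#
# Five discard criteria are applied to every genotype call:
#   (1) HET_X_MALE     heterozygous X-chromosome genotype in a male (outside
#                      the pseudoautosomal regions, where male heterozygosity
#                      is legitimate)
#   (2) Y_IN_FEMALE    any non-missing Y-chromosome genotype in a female
#   (3) LOW_DEPTH      covered by fewer than `min_depth` reads (default 10)
#   (4) LOW_QUALITY    Phred-scaled genotype quality below `min_quality`
#                      (default 90)
#   (5) RECURRENT_INDEL indel carried by a large fraction of samples across
#                      the cohort (alignment-artifact signature)
# A discarded genotype is set to missing for all downstream logic — it is
# never reinterpreted as homozygous reference.

QC_REASONS <- c("HET_X_MALE", "Y_IN_FEMALE", "LOW_DEPTH", "LOW_QUALITY", "RECURRENT_INDEL")

# GRCh37 pseudoautosomal intervals on X (1-based inclusive).
default_par_regions <- function() {
  data.frame(chrom = c("X", "X"),
             start = c(60001, 154931044),
             end   = c(2699520, 155260560))
}

#' Genotype QC configuration
#'
#' @param min_depth Minimum read depth; genotypes with `DP < min_depth` are
#'   discarded. Default 10.
#' @param min_quality Minimum Phred-scaled genotype quality; genotypes with
#'   `GQ < min_quality` are discarded. Default 90.
#' @param recurrent_indel_fraction Carrier-fraction threshold at or above
#'   which an indel is flagged as a recurrent artifact. Default 0.5.
#' @param par_regions Data frame of pseudoautosomal intervals (`chrom`,
#'   `start`, `end`, 1-based inclusive) exempt from the het-X-male rule;
#'   defaults to GRCh37 PAR1/PAR2.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_depth = 10L, min_quality = 90L,
                      recurrent_indel_fraction = 0.5,
                      par_regions = default_par_regions()) {
  stopifnot(min_depth >= 0, min_quality >= 0,
            recurrent_indel_fraction > 0, recurrent_indel_fraction <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 min_quality = as.integer(min_quality),
                 recurrent_indel_fraction = recurrent_indel_fraction,
                 par_regions = par_regions),
            class = "qc_config")
}

norm_chrom <- function(chrom) toupper(sub("^chr", "", chrom, ignore.case = TRUE))

in_par <- function(chrom, pos, par_regions) {
  chrom <- norm_chrom(chrom)
  any(norm_chrom(par_regions$chrom) == chrom &
        par_regions$start <= pos & pos <= par_regions$end)
}

#' QC verdict for a single genotype call
#'
#' Pure function of its inputs. An individual of unknown sex passes the two
#' sex-chromosome checks (they cannot be evaluated); callers may log such
#' calls via the `unresolved_sex` attribute on the verdict.
#'
#' @param call List with `allele_pair` (`"hom_ref"`, `"het"`, `"hom_alt"` or
#'   `NA` for missing), `depth`, `quality`.
#' @param individual List or row with `sex` (`"male"`, `"female"`, `"unknown"`).
#' @param variant List or row with `chrom`, `pos`, `variant_class`.
#' @param config A [qc_config()].
#' @param recurrent Is this variant flagged by [flag_recurrent_indels()]?
#' @return List with `passed` (logical) and `reasons` (character subset of
#'   the five QC codes, empty iff passed).
#' @export
qc_genotype <- function(call, individual, variant, config = qc_config(),
                        recurrent = FALSE) {
  reasons <- character(0)
  missing_gt <- is.na(call$allele_pair)
  chrom <- norm_chrom(variant$chrom)
  unresolved <- FALSE
  if (!missing_gt && chrom %in% c("X", "Y") && individual$sex == "unknown") {
    unresolved <- TRUE
  }
  if (!missing_gt) {
    if (chrom == "X" && identical(individual$sex, "male") &&
        call$allele_pair == "het" && !in_par(variant$chrom, variant$pos, config$par_regions)) {
      reasons <- c(reasons, "HET_X_MALE")
    }
    if (chrom == "Y" && identical(individual$sex, "female")) {
      reasons <- c(reasons, "Y_IN_FEMALE")
    }
    if (!is.na(call$depth) && call$depth < config$min_depth) {
      reasons <- c(reasons, "LOW_DEPTH")
    }
    if (!is.na(call$quality) && call$quality < config$min_quality) {
      reasons <- c(reasons, "LOW_QUALITY")
    }
    if (isTRUE(recurrent)) reasons <- c(reasons, "RECURRENT_INDEL")
  }
  structure(list(passed = length(reasons) == 0L, reasons = reasons),
            unresolved_sex = unresolved)
}

#' Flag recurrent indels across the cohort
#'
#' An indel is flagged when the fraction of sequenced samples carrying a
#' non-reference genotype reaches `recurrent_indel_fraction`. SNVs are never
#' flagged — the criterion targets alignment artifacts specific to indels.
#' This is the first pass of the two-pass QC design: carrier fractions need
#' the whole cohort before any genotype is discarded.
#'
#' @param cohort A `fam_cohort`.
#' @param config A [qc_config()].
#' @return Character vector of flagged variant keys.
#' @export
flag_recurrent_indels <- function(cohort, config = qc_config()) {
  idx <- which(cohort$variants$variant_class == "indel")
  if (length(idx) == 0L) return(character(0))
  n_samples <- length(cohort$samples)
  carrier_frac <- vapply(idx, function(i) {
    sum(cohort$gt[i, ] %in% c("het", "hom_alt")) / n_samples
  }, numeric(1))
  cohort$variants$key[idx[carrier_frac >= config$recurrent_indel_fraction]]
}

#' Apply genotype QC to a whole cohort
#'
#' Runs the five discard criteria over every (variant, sample) call and sets
#' failing genotypes to missing. The per-call semantics are identical to
#' [qc_genotype()]; this is the vectorized cohort pass.
#'
#' @param cohort A `fam_cohort`.
#' @param ped A `fam_ped` (provides sex per sample; samples absent from the
#'   pedigree are treated as unknown sex).
#' @param config A [qc_config()].
#' @return List with `cohort` (genotypes discarded, i.e. set to `NA`),
#'   `audit` (data frame: `key`, `sample`, `reasons` comma-joined, one row
#'   per discarded genotype) and `recurrent_keys`.
#' @export
apply_qc <- function(cohort, ped, config = qc_config()) {
  empty_audit <- data.frame(key = character(0), sample = character(0),
                            reasons = character(0), stringsAsFactors = FALSE)
  if (nrow(cohort$variants) == 0L) {
    return(list(cohort = cohort, audit = empty_audit, recurrent_keys = character(0)))
  }
  recurrent_keys <- flag_recurrent_indels(cohort, config)
  sex <- ped$sex[match(cohort$samples, ped$individual_id)]
  sex[is.na(sex)] <- "unknown"
  chrom <- norm_chrom(cohort$variants$chrom)
  par_exempt <- vapply(seq_len(nrow(cohort$variants)), function(i) {
    chrom[i] == "X" && in_par(cohort$variants$chrom[i], cohort$variants$pos[i], config$par_regions)
  }, logical(1))

  gt <- cohort$gt
  present <- !is.na(gt)
  fail <- array("", dim = dim(gt))

  male <- matrix(rep(sex == "male", each = nrow(gt)), nrow = nrow(gt))
  female <- matrix(rep(sex == "female", each = nrow(gt)), nrow = nrow(gt))

  hetx <- present & gt == "het" & (chrom == "X" & !par_exempt) & male
  yfem <- present & (chrom == "Y") & female
  lowdp <- present & !is.na(cohort$dp) & cohort$dp < config$min_depth
  lowgq <- present & !is.na(cohort$gq) & cohort$gq < config$min_quality
  recur <- present & (cohort$variants$key %in% recurrent_keys)

  reason_mats <- list(HET_X_MALE = hetx, Y_IN_FEMALE = yfem, LOW_DEPTH = lowdp,
                      LOW_QUALITY = lowgq, RECURRENT_INDEL = recur)
  any_fail <- Reduce(`|`, reason_mats)

  audit <- data.frame(key = character(0), sample = character(0),
                      reasons = character(0), stringsAsFactors = FALSE)
  if (any(any_fail)) {
    idx <- which(any_fail, arr.ind = TRUE)
    reasons <- apply(idx, 1L, function(rc) {
      paste(QC_REASONS[vapply(reason_mats, function(m) m[rc[1L], rc[2L]], logical(1))],
            collapse = ",")
    })
    audit <- data.frame(key = cohort$variants$key[idx[, 1L]],
                        sample = cohort$samples[idx[, 2L]],
                        reasons = reasons, stringsAsFactors = FALSE)
    audit <- audit[order(audit$key, audit$sample), , drop = FALSE]
    rownames(audit) <- NULL
  }
  gt[any_fail] <- NA_character_
  cohort$gt <- gt
  list(cohort = cohort, audit = audit, recurrent_keys = recurrent_keys)
}
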