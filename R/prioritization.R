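# The five-criterion candidate-variant filter cascade.
#
# A QC-passed variant is a candidate when it
#   (RARE)        occurs rarely in the general population — ancestry-matched
#                 allele frequency below `max_af`, or absent (private);
#   (CONSEQUENCE) is loss-of-function (frameshift, nonsense, canonical
#                 splice-site) or missense;
#   (DELETERIOUS) if missense, is called deleterious by SIFT or damaging by
#                 PolyPhen-2 (either predictor suffices; LoF variants skip
#                 this check);
#   (PLI)         lies in a constrained gene, pLI >= `pli_threshold`;
#   (GO_DEV)      lies in a developmental-process gene;
# and is carried, after genotype QC, by at least one affected individual.
# Every criterion is a pure per-variant predicate, so the surviving set is
# invariant to application order; order only decides the "first failing"
# label in the audit trace.

CRITERIA <- c("RARE", "CONSEQUENCE", "DELETERIOUS", "PLI", "GO_DEV")

DEFAULT_LOF_TERMS <- c("frameshift_variant", "stop_gained",
                       "splice_acceptor_variant", "splice_donor_variant")

#' Filter cascade configuration
#'
#' @param max_af Rarity threshold on the ancestry-matched population allele
#'   frequency (exclusive: `AF < max_af` passes). Default 1e-3.
#' @param pli_threshold pLI constraint threshold (inclusive). Default 0.9.
#' @param lof_terms Consequence terms counted as loss-of-function.
#' @param require_go_dev Apply the developmental-process gene-set criterion.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_af = 1e-3, pli_threshold = 0.9,
                          lof_terms = DEFAULT_LOF_TERMS, require_go_dev = TRUE) {
  stopifnot(max_af > 0, max_af <= 1, length(lof_terms) > 0)
  structure(list(max_af = max_af, pli_threshold = pli_threshold,
                 lof_terms = lof_terms, require_go_dev = require_go_dev),
            class = "filter_config")
}

#' Classify a consequence term as LoF, missense or other
#'
#' @param term Most-severe consequence term (vectorized).
#' @param lof_terms Terms counted as loss-of-function.
#' @return Character vector over `{"lof", "missense", "other"}`.
#' @export
classify_consequence <- function(term, lof_terms = DEFAULT_LOF_TERMS) {
  out <- rep("other", length(term))
  out[term %in% lof_terms] <- "lof"
  out[term %in% "missense_variant"] <- "missense"
  out[is.na(term)] <- "other"
  out
}

#' Population rarity test
#'
#' A variant is rare when its ancestry-matched allele frequency is below
#' `max_af`, or when no frequency is reported (a private variant).
#'
#' @param allele_freq Numeric vector; `NA` = private.
#' @param config A [filter_config()].
#' @return Logical vector.
#' @export
is_rare <- function(allele_freq, config = filter_config()) {
  is.na(allele_freq) | allele_freq < config$max_af
}

#' Predicted deleteriousness (either-predictor rule)
#'
#' Applies only to missense variants: deleterious iff SIFT calls the variant
#' deleterious (including low-confidence) or PolyPhen-2 calls it possibly or
#' probably damaging. LoF variants pass unconditionally — the criterion's
#' wording restricts it to missense. A missense variant with neither
#' predictor reported fails (no evidence of deleteriousness).
#'
#' @param sift SIFT category (`deleterious`, `deleterious_low_confidence`,
#'   `tolerated` or `NA`), vectorized.
#' @param polyphen PolyPhen-2 category (`probably_damaging`,
#'   `possibly_damaging`, `benign` or `NA`), vectorized.
#' @param consequence_class From [classify_consequence()].
#' @return Logical vector.
#' @export
is_deleterious <- function(sift, polyphen, consequence_class) {
  sift_del <- !is.na(sift) & sift %in% c("deleterious", "deleterious_low_confidence")
  poly_del <- !is.na(polyphen) & polyphen %in% c("probably_damaging", "possibly_damaging")
  ifelse(consequence_class == "lof", TRUE, sift_del | poly_del)
}

# Per-variant criterion verdicts: a matrix of "pass"/"fail"/"not_applicable"
# over the five criteria. Pure function of the annotation table + resources.
criterion_verdicts <- function(variants, resource, config) {
  n <- nrow(variants)
  cls <- classify_consequence(variants$consequence, config$lof_terms)
  v <- matrix("pass", nrow = n, ncol = length(CRITERIA),
              dimnames = list(variants$key, CRITERIA))
  v[, "RARE"] <- ifelse(is_rare(variants$allele_freq, config), "pass", "fail")
  v[, "CONSEQUENCE"] <- ifelse(cls %in% c("lof", "missense"), "pass", "fail")
  del <- is_deleterious(variants$sift, variants$polyphen, cls)
  v[, "DELETERIOUS"] <- ifelse(cls == "missense", ifelse(del, "pass", "fail"),
                               "not_applicable")
  pli_ok <- vapply(variants$gene, function(g) {
    isTRUE(as.logical(gene_passes_constraint(g, resource, config$pli_threshold)))
  }, logical(1))
  v[, "PLI"] <- ifelse(pli_ok, "pass", "fail")
  if (config$require_go_dev) {
    go_ok <- vapply(variants$gene, gene_in_set, logical(1),
                    named_set = "go_dev", resource = resource)
    v[, "GO_DEV"] <- ifelse(go_ok, "pass", "fail")
  } else {
    v[, "GO_DEV"] <- "not_applicable"
  }
  v
}

# Affected carriers of each variant, post-QC, restricted to sequenced
# pedigree members with affected status.
affected_carriers <- function(cohort, ped) {
  aff <- ped$individual_id[ped$status == "affected" & ped$sequenced]
  aff <- intersect(cohort$samples, aff)
  lapply(seq_len(nrow(cohort$variants)), function(i) {
    st <- cohort$gt[i, aff]
    aff[!is.na(st) & st %in% c("het", "hom_alt")]
  })
}

#' Run the candidate-variant filter cascade
#'
#' Applies genotype QC first (discarded genotypes become missing before any
#' carrier logic), then evaluates the five per-variant criteria and the
#' affected-carrier requirement, and returns the surviving candidate set
#' with a full audit trace and cohort bookkeeping summary.
#'
#' @param cohort A `fam_cohort` from [read_cohort_vcf()].
#' @param ped A `fam_ped` covering the cohort samples.
#' @param resource A `gene_resource` from [load_resources()].
#' @param qc_conf A [qc_config()].
#' @param filt_conf A [filter_config()].
#' @return List with:
#'   \describe{
#'     \item{candidates}{annotation rows of surviving variants, plus a
#'       `carriers` column (comma-joined affected carrier sample ids).}
#'     \item{trace}{one row per variant: the five criterion verdicts,
#'       `carrier_ok`, `surviving`, `first_fail` (first failing criterion,
#'       `NO_AFFECTED_CARRIER`, or `""`), `all_fails`.}
#'     \item{summary}{cohort bookkeeping: unique SNV/indel counts,
#'       coding/noncoding split, candidate counts by consequence class.}
#'     \item{qc}{the [apply_qc()] result (post-QC cohort + audit).}
#'   }
#' @export
run_cascade <- function(cohort, ped, resource, qc_conf = qc_config(),
                        filt_conf = filter_config()) {
  qc <- apply_qc(cohort, ped, qc_conf)
  post <- qc$cohort
  variants <- post$variants

  if (nrow(variants) == 0L) {
    trace <- data.frame(key = character(0))
    return(list(candidates = cbind(variants, carriers = character(0)),
                trace = trace, summary = cohort_summary(post, character(0)), qc = qc))
  }

  verdicts <- criterion_verdicts(variants, resource, filt_conf)
  carriers <- affected_carriers(post, ped)
  carrier_ok <- lengths(carriers) > 0L
  crit_ok <- apply(verdicts != "fail", 1L, all)
  surviving <- crit_ok & carrier_ok

  first_fail <- apply(verdicts, 1L, function(v) {
    f <- CRITERIA[v == "fail"]
    if (length(f)) f[1L] else ""
  })
  first_fail[first_fail == "" & !carrier_ok] <- "NO_AFFECTED_CARRIER"
  all_fails <- apply(verdicts, 1L, function(v) paste(CRITERIA[v == "fail"], collapse = ","))
  all_fails <- ifelse(!carrier_ok,
                      ifelse(nzchar(all_fails),
                             paste0(all_fails, ",NO_AFFECTED_CARRIER"),
                             "NO_AFFECTED_CARRIER"),
                      all_fails)

  trace <- data.frame(key = variants$key, gene = variants$gene,
                      as.data.frame(verdicts, stringsAsFactors = FALSE),
                      carrier_ok = carrier_ok, surviving = surviving,
                      first_fail = first_fail, all_fails = all_fails,
                      stringsAsFactors = FALSE, row.names = NULL)

  candidates <- variants[surviving, , drop = FALSE]
  candidates$carriers <- vapply(carriers[surviving], paste, character(1), collapse = ",")
  candidates$pli <- unname(resource$pli[candidates$gene])
  ord <- order(candidates$chrom, candidates$pos, candidates$alt, candidates$gene)
  candidates <- candidates[ord, , drop = FALSE]
  rownames(candidates) <- NULL

  list(candidates = candidates, trace = trace,
       summary = cohort_summary(post, candidates$key), qc = qc)
}

# Figure-style cohort bookkeeping: unique SNV/indel totals, coding vs
# noncoding split, and candidates by consequence class.
cohort_summary <- function(cohort, candidate_keys) {
  v <- cohort$variants
  coding <- is_coding_consequence(v$consequence)
  cand <- v[v$key %in% candidate_keys, , drop = FALSE]
  cls <- classify_consequence(cand$consequence)
  list(
    n_variants = nrow(v),
    n_snv = sum(v$variant_class == "SNV"),
    n_indel = sum(v$variant_class == "indel"),
    n_coding_snv = sum(coding & v$variant_class == "SNV"),
    n_coding_indel = sum(coding & v$variant_class == "indel"),
    n_noncoding_snv = sum(!coding & v$variant_class == "SNV"),
    n_noncoding_indel = sum(!coding & v$variant_class == "indel"),
    n_candidates = nrow(cand),
    n_candidate_lof = sum(cls == "lof"),
    n_candidate_missense = sum(cls == "missense"),
    n_candidate_genes = length(unique(cand$gene))
  )
}
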