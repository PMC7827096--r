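# Within-family segregation classification, cross-family recurrence, and
# evidence tiers.
#
# Dominant model: a heterozygous or homozygous-alternate genotype counts as
# carrying (hemizygous male X carriers included). Only sequenced members
# with known affected status enter the counts; unknown-status and
# unsequenced members can neither confirm nor refute segregation.
#
# Status rule table for one (variant, family):
#   uninformative  fewer than 2 affected members with usable (post-QC,
#                  non-missing) genotypes
#   complete       >= 2 affected carriers, 0 affected non-carriers, and
#                  (unless unaffected carriers are tolerated) 0 unaffected
#                  carriers
#   none           0 affected carriers
#   partial        anything else (some affected carry, pattern imperfect)

SEG_STATUSES <- c("complete", "partial", "none", "uninformative")
TIERS <- c("credible", "known_phenotype_gene", "weak")

#' Segregation status of a variant within one family
#'
#' @param cohort A post-QC `fam_cohort` (discarded genotypes already missing).
#' @param key Variant key (`chrom:pos:ref:alt`).
#' @param ped A `fam_ped`; rows not in `family_id` are ignored.
#' @param family_id Family to evaluate.
#' @param allow_unaffected_carriers Tolerate unaffected carriers when calling
#'   complete segregation (reduced-penetrance model). Default `FALSE`
#'   (strict reading: clear segregation means no unaffected carrier).
#' @return List: `family_id`, `status`, `affected_carriers`,
#'   `affected_noncarriers`, `unaffected_carriers`, `untyped_affected`.
#' @export
segregation_status <- function(cohort, key, ped, family_id,
                               allow_unaffected_carriers = FALSE) {
  mem <- ped[ped$family_id == family_id & ped$sequenced &
               ped$status != "unknown", , drop = FALSE]
  i <- match(key, cohort$variants$key)
  counts <- list(ac = 0L, an = 0L, uc = 0L, untyped_aff = 0L, usable_aff = 0L)
  if (!is.na(i) && nrow(mem) > 0L) {
    ids <- intersect(mem$individual_id, cohort$samples)
    mem <- mem[mem$individual_id %in% ids, , drop = FALSE]
    st <- cohort$gt[i, mem$individual_id]
    carrier <- !is.na(st) & st %in% c("het", "hom_alt")
    usable <- !is.na(st)
    aff <- mem$status == "affected"
    counts$ac <- sum(aff & carrier)
    counts$an <- sum(aff & usable & !carrier)
    counts$uc <- sum(!aff & carrier)
    counts$untyped_aff <- sum(aff & !usable)
    counts$usable_aff <- sum(aff & usable)
  }
  status <- if (counts$usable_aff < 2L) {
    "uninformative"
  } else if (counts$ac >= 2L && counts$an == 0L &&
             (allow_unaffected_carriers || counts$uc == 0L)) {
    "complete"
  } else if (counts$ac == 0L) {
    "none"
  } else {
    "partial"
  }
  list(family_id = family_id, status = status,
       affected_carriers = counts$ac, affected_noncarriers = counts$an,
       unaffected_carriers = counts$uc, untyped_affected = counts$untyped_aff)
}

#' Cross-family recurrence per gene
#'
#' Counts, for each gene, the number of distinct families contributing at
#' least one affected carrier of any candidate variant in that gene. A
#' family counts once regardless of how many members carry, and distinct
#' variants in the same gene pool at the gene level.
#'
#' @param candidates Candidate table from [run_cascade()] (needs `gene` and
#'   `carriers` columns).
#' @param ped A `fam_ped` mapping samples to families.
#' @return Named integer vector: gene -> family count. Empty for an empty
#'   candidate set.
#' @export
cross_family_recurrence <- function(candidates, ped) {
  if (nrow(candidates) == 0L) return(stats::setNames(integer(0), character(0)))
  fam_of <- stats::setNames(ped$family_id, ped$individual_id)
  gene_fams <- lapply(split(candidates$carriers, candidates$gene), function(carr) {
    ids <- unlist(strsplit(carr[nzchar(carr)], ",", fixed = TRUE))
    unique(unname(fam_of[ids]))
  })
  vapply(gene_fams, length, integer(1))
}

#' Assign an evidence tier to a candidate
#'
#' `credible` when the variant shows complete segregation in at least one
#' family or its gene recurs in two or more families; otherwise
#' `known_phenotype_gene` when the gene intersects the strabismus phenotype
#' (HP:0000486) or literature gene lists; otherwise `weak`.
#'
#' @param statuses Per-family segregation statuses (character vector).
#' @param families_recurrent Gene-level family recurrence count.
#' @param gene Gene symbol.
#' @param resource A `gene_resource`.
#' @return One of `"credible"`, `"known_phenotype_gene"`, `"weak"`.
#' @export
assign_tier <- function(statuses, families_recurrent, gene, resource) {
  if (any(statuses == "complete") || families_recurrent >= 2L) return("credible")
  if (gene_in_set(gene, "hpo_strabismus", resource) ||
      gene_in_set(gene, "literature", resource)) return("known_phenotype_gene")
  "weak"
}

#' Build the evidence report for a candidate set
#'
#' For every candidate variant: per-family segregation statuses (in the
#' families with at least one affected carrier), gene-level cross-family
#' recurrence, and the assigned tier.
#'
#' @param candidates Candidate table from [run_cascade()].
#' @param cohort The post-QC `fam_cohort` (e.g. `res$qc$cohort`).
#' @param ped A `fam_ped`.
#' @param resource A `gene_resource`.
#' @param allow_unaffected_carriers Passed to [segregation_status()].
#' @return Data frame: `key`, `gene`, `per_family` (e.g.
#'   `"FAM12:complete;FAM13:partial"`), `families_recurrent`, `tier`.
#' @export
build_evidence <- function(candidates, cohort, ped, resource,
                           allow_unaffected_carriers = FALSE) {
  recurrence <- cross_family_recurrence(candidates, ped)
  fam_of <- stats::setNames(ped$family_id, ped$individual_id)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    carr <- strsplit(candidates$carriers[i], ",", fixed = TRUE)[[1L]]
    fams <- sort(unique(unname(fam_of[carr[nzchar(carr)]])))
    st <- lapply(fams, function(f) {
      segregation_status(cohort, candidates$key[i], ped, f,
                         allow_unaffected_carriers = allow_unaffected_carriers)
    })
    statuses <- vapply(st, `[[`, character(1), "status")
    gene <- candidates$gene[i]
    data.frame(
      key = candidates$key[i], gene = gene,
      per_family = paste(sprintf("%s:%s", fams, statuses), collapse = ";"),
      families_recurrent = unname(recurrence[gene]),
      tier = assign_tier(statuses, recurrence[gene], gene, resource),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(key = character(0), gene = character(0),
                      per_family = character(0), families_recurrent = integer(0),
                      tier = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
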