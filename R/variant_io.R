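# Multi-sample VCF reading and annotation parsing.
#
# The cascade consumes annotated VCFs: per-variant annotation as INFO keys
# (gene symbol, most-severe consequence, ancestry-matched allele frequency,
# SIFT and PolyPhen-2 categories) and per-genotype FORMAT fields GT/DP/GQ.
# The mapping from INFO keys to annotation slots is declared in an
# annotation schema rather than hard-coded, since annotated VCF dialects
# vary across annotators. Parsing itself is delegated to vcfR; this module
# decomposes multiallelic sites and normalizes annotation values.

SIFT_LEVELS     <- c("deleterious", "deleterious_low_confidence", "tolerated")
POLYPHEN_LEVELS <- c("probably_damaging", "possibly_damaging", "benign")

#' Default annotation schema
#'
#' Names the INFO keys holding each annotation slot. Override any entry to
#' match the dialect of your annotator.
#'
#' @param gene,consequence,af,pop,sift,polyphen INFO key names.
#' @return Named list used by [read_cohort_vcf()].
#' @export
annotation_schema <- function(gene = "GENE", consequence = "CSQ", af = "AF",
                              pop = "POP", sift = "SIFT", polyphen = "POLYPHEN") {
  list(gene = gene, consequence = consequence, af = af, pop = pop,
       sift = sift, polyphen = polyphen)
}

# Severity ranking table shipped with the package (VEP-style ordering).
severity_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "consequence_severity.tsv", package = "famseg")
      cache <<- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Select the most severe consequence term
#'
#' Ranks terms by the shipped VEP-style severity ordering and returns the
#' single highest-ranked term. Unknown terms rank below all known terms and
#' raise a warning, never an error. Deterministic: ties (duplicate terms)
#' resolve to the same term, and the result does not depend on input order.
#'
#' @param terms Non-empty character vector of consequence terms.
#' @return The single most severe term.
#' @examples
#' select_most_severe(c("missense_variant", "synonymous_variant"))
#' @export
select_most_severe <- function(terms) {
  terms <- terms[!is.na(terms) & nzchar(terms)]
  if (length(terms) == 0L) stop("select_most_severe() requires at least one term")
  sev <- severity_table()
  rank <- match(terms, sev$term)
  if (anyNA(rank)) {
    warning(sprintf("unknown consequence term(s) ranked least severe: %s",
                    paste(unique(terms[is.na(rank)]), collapse = ", ")))
    rank[is.na(rank)] <- nrow(sev) + match(terms[is.na(rank)], sort(unique(terms[is.na(rank)])))
  }
  terms[which.min(rank)]
}

#' Is a consequence term in a protein-coding sequence?
#'
#' @param term Character vector of consequence terms.
#' @return Logical; unknown terms count as noncoding.
#' @export
is_coding_consequence <- function(term) {
  sev <- severity_table()
  idx <- match(term, sev$term)
  out <- !is.na(idx) & sev$coding[ifelse(is.na(idx), 1L, idx)] == 1L
  out[is.na(idx)] <- FALSE
  out
}

variant_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

# Construct an in-memory cohort: a variant annotation table plus aligned
# genotype matrices (variants x samples). This is the container every
# downstream stage operates on.
new_cohort <- function(variants, gt, dp, gq) {
  stopifnot(nrow(variants) == nrow(gt), all(dim(gt) == dim(dp)), all(dim(gt) == dim(gq)))
  rownames(gt) <- rownames(dp) <- rownames(gq) <- variants$key
  structure(list(variants = variants, gt = gt, dp = dp, gq = gq,
                 samples = colnames(gt)),
            class = "fam_cohort")
}

#' @export
print.fam_cohort <- function(x, ...) {
  cat(sprintf("fam_cohort: %d variant record(s) x %d sample(s)\n",
              nrow(x$variants), length(x$samples)))
  cat(sprintf("  SNV: %d  indel: %d\n",
              sum(x$variants$variant_class == "SNV"),
              sum(x$variants$variant_class == "indel")))
  invisible(x)
}

# Map a diploid GT string to carrier state for alt allele `allele_idx`.
# Returns "hom_ref", "het", "hom_alt" or NA (missing). Genotypes carrying a
# different alt allele of the same site count as non-carriers of this one.
gt_state <- function(gt, allele_idx) {
  out <- rep(NA_character_, length(gt))
  known <- !is.na(gt) & !grepl("\\.", gt)
  alleles <- strsplit(gsub("\\|", "/", gt[known]), "/")
  n_alt <- vapply(alleles, function(a) sum(a == as.character(allele_idx)), integer(1))
  n_tot <- lengths(alleles)
  state <- ifelse(n_alt == 0L, "hom_ref", ifelse(n_alt == n_tot, "hom_alt", "het"))
  # haploid calls (e.g. male X): a single alt allele is hemizygous -> hom_alt
  out[known] <- state
  out
}

#' Read an annotated multi-sample cohort VCF
#'
#' Reads a VCF v4.x (plain or bgzipped) with FORMAT fields GT, DP and GQ and
#' the annotation INFO keys declared in `schema`. Multiallelic sites are
#' decomposed into one record per alt allele; per-allele INFO values
#' (comma-separated, Number=A) are split accordingly. Every emitted record
#' has all schema fields resolved or explicitly `NA` (absent). An absent
#' allele frequency marks a private variant.
#'
#' @param path Path to the VCF file.
#' @param schema Annotation schema from [annotation_schema()].
#' @return A `fam_cohort` object: `$variants` (one row per chrom/pos/ref/alt
#'   with gene, consequence, allele_freq, freq_population, sift, polyphen,
#'   variant_class, key), and matrices `$gt`, `$dp`, `$gq` with one column
#'   per VCF sample, in header order.
#' @export
read_cohort_vcf <- function(path, schema = annotation_schema()) {
  if (!file.exists(path)) stop(sprintf("VCF file not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    empty <- matrix(character(0), nrow = 0, ncol = ncol(vcf@gt) - 1L,
                    dimnames = list(NULL, colnames(vcf@gt)[-1L]))
    variants <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                           alt = character(0), key = character(0), variant_class = character(0),
                           gene = character(0), consequence = character(0),
                           allele_freq = numeric(0), freq_population = character(0),
                           sift = character(0), polyphen = character(0),
                           stringsAsFactors = FALSE)
    mode(empty) <- "character"
    num <- empty; mode(num) <- "numeric"
    return(new_cohort(variants, empty, num, num))
  }

  info_declared <- vcfR::queryMETA(vcf, element = "INFO")
  declared_ids <- sub("^INFO=ID=", "", vapply(info_declared, `[`, character(1), 1L))
  missing_keys <- setdiff(unlist(schema), declared_ids)
  if (length(missing_keys)) {
    stop(sprintf("annotation schema error: INFO field(s) not declared in VCF header: %s",
                 paste(missing_keys, collapse = ", ")))
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  samples <- colnames(vcf@gt)[-1L]

  info_field <- function(key) vcfR::extract.info(vcf, element = key)
  gene_v  <- info_field(schema$gene)
  csq_v   <- info_field(schema$consequence)
  af_v    <- info_field(schema$af)
  pop_v   <- info_field(schema$pop)
  sift_v  <- info_field(schema$sift)
  poly_v  <- info_field(schema$polyphen)

  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)

  rows <- vector("list", sum(n_alt))
  gt_rows <- matrix(NA_character_, nrow = sum(n_alt), ncol = length(samples),
                    dimnames = list(NULL, samples))
  dp_rows <- matrix(NA_real_, nrow = sum(n_alt), ncol = length(samples),
                    dimnames = list(NULL, samples))
  gq_rows <- dp_rows

  split_a <- function(x, i, k) {
    # per-allele (Number=A) values arrive comma-joined; scalars repeat
    if (is.na(x)) return(NA_character_)
    parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
    if (length(parts) >= k) parts[i] else parts[1L]
  }

  out_i <- 0L
  for (v in seq_len(nrow(fix))) {
    pos <- as.integer(fix$POS[v])
    for (a in seq_len(n_alt[v])) {
      out_i <- out_i + 1L
      alt <- alt_list[[v]][a]
      af_chr <- split_a(af_v[v], a, n_alt[v])
      af <- if (is.na(af_chr) || af_chr == "." || af_chr == "") NA_real_ else as.numeric(af_chr)
      csq <- split_a(csq_v[v], a, n_alt[v])
      if (!is.na(csq) && grepl("&", csq, fixed = TRUE)) {
        csq <- select_most_severe(strsplit(csq, "&", fixed = TRUE)[[1L]])
      }
      norm_cat <- function(x, levels) {
        x <- split_a(x, a, n_alt[v])
        if (is.na(x) || x == "." || x == "") return(NA_character_)
        x <- tolower(x)
        if (!x %in% levels) stop(sprintf("unrecognized predictor category '%s' at %s:%d", x, fix$CHROM[v], pos))
        x
      }
      rows[[out_i]] <- data.frame(
        chrom = fix$CHROM[v], pos = pos, ref = fix$REF[v], alt = alt,
        key = variant_key(fix$CHROM[v], pos, fix$REF[v], alt),
        variant_class = if (nchar(fix$REF[v]) != nchar(alt)) "indel" else "SNV",
        gene = toupper(split_a(gene_v[v], a, n_alt[v])),
        consequence = csq,
        allele_freq = af,
        freq_population = split_a(pop_v[v], a, n_alt[v]),
        sift = norm_cat(sift_v[v], SIFT_LEVELS),
        polyphen = norm_cat(poly_v[v], POLYPHEN_LEVELS),
        stringsAsFactors = FALSE
      )
      gt_rows[out_i, ] <- gt_state(gt_raw[v, ], a)
      dp_rows[out_i, ] <- dp_raw[v, ]
      gq_rows[out_i, ] <- gq_raw[v, ]
    }
  }
  variants <- do.call(rbind, rows)
  new_cohort(variants, gt_rows, dp_rows, gq_rows)
}
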