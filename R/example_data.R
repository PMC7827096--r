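# Worked-example fixture shipped with the package.

#' Published familial-strabismus risk variants (worked example)
#'
#' Ten heterozygous missense variants reported as risk variants in a
#' whole-exome study of multiplex familial strabismus, with their
#' ancestry-matched gnomAD allele frequencies (empty = private, not
#' reported in the database), SIFT/PolyPhen-2 categories and ExAC pLI
#' scores. Useful as a worked example for the per-variant filter
#' predicates: every row passes the default cascade (rarity below 1e-3 or
#' private; missense; deleterious by at least one predictor; pLI >= 0.9).
#'
#' @return Data frame with columns `gene`, `pLI`, `hgvs_c`, `protein`,
#'   `consequence`, `allele_freq` (numeric, `NA` = private), `population`,
#'   `sift`, `polyphen`.
#' @examples
#' v <- example_risk_variants()
#' cfg <- filter_config()
#' all(is_rare(v$allele_freq, cfg))
#' @export
example_risk_variants <- function() {
  path <- system.file("extdata", "strabismus_risk_variants.tsv", package = "famseg")
  v <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  v$allele_freq <- as.numeric(v$allele_freq)
  v
}
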