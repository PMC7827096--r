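# Gene-level resources consumed by the filter cascade: pLI constraint
# scores, the developmental-process gene set (GO:0032502), the strabismus
# phenotype gene set (HP:0000486) and an optional literature list. Symbols
# are matched by exact upper-cased symbol; no alias resolution.

#' Load gene-level resources
#'
#' @param pli_tsv Path to a TSV with header columns `gene` and `pLI` (extra
#'   columns ignored). Duplicate genes keep the maximum score, with a warning.
#' @param go_list Path to the developmental-process gene list, one symbol per
#'   line, `#` comments allowed.
#' @param hpo_list Path to the strabismus phenotype gene list, same format.
#' @param literature_list Optional path to a literature gene list.
#' @return A `gene_resource` list with `pli` (named numeric vector), and
#'   character sets `go_dev`, `hpo_strabismus`, `literature`.
#' @export
load_resources <- function(pli_tsv, go_list, hpo_list, literature_list = NULL) {
  tab <- utils::read.delim(pli_tsv, header = TRUE, stringsAsFactors = FALSE)
  names(tab) <- sub("^pli$", "pLI", names(tab), ignore.case = TRUE)
  if (!all(c("gene", "pLI") %in% names(tab))) {
    stop(sprintf("pLI table %s must have 'gene' and 'pLI' columns", pli_tsv))
  }
  if (nrow(tab) == 0L) stop(sprintf("pLI table %s is empty", pli_tsv))
  tab$gene <- toupper(tab$gene)
  tab$pLI <- as.numeric(tab$pLI)
  if (anyNA(tab$pLI) || any(tab$pLI < 0 | tab$pLI > 1)) {
    stop(sprintf("pLI table %s contains scores outside [0, 1]", pli_tsv))
  }
  if (anyDuplicated(tab$gene)) {
    warning(sprintf("duplicate pLI entries for %s; keeping the maximum score",
                    paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", ")))
    tab <- do.call(rbind, lapply(split(tab, tab$gene), function(g) g[which.max(g$pLI), ]))
  }
  pli <- stats::setNames(tab$pLI, tab$gene)

  read_gene_list <- function(path) {
    if (is.null(path)) return(character(0))
    lines <- trimws(readLines(path))
    unique(toupper(lines[!grepl("^(#|$)", lines)]))
  }
  structure(list(pli = pli,
                 go_dev = read_gene_list(go_list),
                 hpo_strabismus = read_gene_list(hpo_list),
                 literature = read_gene_list(literature_list)),
            class = "gene_resource")
}

#' Does a gene pass the pLI constraint filter?
#'
#' True iff the gene has a pLI score and it is at or above the threshold
#' (inclusive). Genes absent from the table fail conservatively; the reason
#' is distinguishable via `attr(, "reason")` (`MISSING_PLI` vs `LOW_PLI`).
#'
#' @param gene Gene symbol (case-insensitive).
#' @param resource A `gene_resource`.
#' @param pli_threshold Score threshold in `[0, 1]`; default 0.9.
#' @return Logical scalar with a `reason` attribute when `FALSE`.
#' @export
gene_passes_constraint <- function(gene, resource, pli_threshold = 0.9) {
  stopifnot(pli_threshold >= 0, pli_threshold <= 1)
  score <- resource$pli[toupper(gene)]
  if (is.na(score)) return(structure(FALSE, reason = "MISSING_PLI"))
  if (score >= pli_threshold) TRUE else structure(FALSE, reason = "LOW_PLI")
}

#' Case-insensitive gene-set membership
#'
#' @param gene Gene symbol.
#' @param named_set One of `"go_dev"`, `"hpo_strabismus"`, `"literature"`.
#' @param resource A `gene_resource`.
#' @return Logical scalar.
#' @export
gene_in_set <- function(gene, named_set, resource) {
  if (!named_set %in% c("go_dev", "hpo_strabismus", "literature")) {
    stop(sprintf("unknown gene set '%s'", named_set))
  }
  toupper(gene) %in% resource[[named_set]]
}
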