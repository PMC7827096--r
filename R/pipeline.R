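# End-to-end pipeline driver, configuration and report bundle.
#
# A run consumes an annotated cohort VCF, a PED file, an ancestry sidecar
# and the gene resource tables, and writes a deterministic report bundle:
# candidate table, filter-trace audit, QC audit, evidence report (TSV +
# JSON twin), cohort summary and a run manifest (config echo + input
# checksums + package version). All tables are sorted so identical inputs
# give byte-identical outputs.

#' Assemble a run configuration
#'
#' @param vcf,ped,ancestry,pli,go,hpo Paths to the input files.
#' @param literature Optional literature gene-list path.
#' @param annotation An [annotation_schema()].
#' @param qc A [qc_config()].
#' @param filters A [filter_config()].
#' @param allow_unaffected_carriers Segregation switch (reduced penetrance).
#' @param drop_invalid_families Exclude families failing the multiplex/trio
#'   validation from segregation reporting (they are always reported in the
#'   validation table either way). Default `FALSE`.
#' @return A `run_config` list.
#' @export
run_config <- function(vcf, ped, ancestry = NULL, pli, go, hpo,
                       literature = NULL,
                       annotation = annotation_schema(),
                       qc = qc_config(), filters = filter_config(),
                       allow_unaffected_carriers = FALSE,
                       drop_invalid_families = FALSE) {
  structure(list(vcf = vcf, ped = ped, ancestry = ancestry, pli = pli,
                 go = go, hpo = hpo, literature = literature,
                 annotation = annotation, qc = qc, filters = filters,
                 allow_unaffected_carriers = allow_unaffected_carriers,
                 drop_invalid_families = drop_invalid_families),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' The file may hold blocks `annotation:`, `qc:`, `filters:` and
#' `segregation:`; absent keys keep their defaults. Input paths given in an
#' `io:` block are overridden by paths passed directly to [run_pipeline()].
#'
#' @param path YAML file path.
#' @return Nested list of configuration blocks.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ann <- do.call(annotation_schema, as.list(cfg$annotation %||% list()))
  qc_args <- as.list(cfg$qc %||% list())
  if (!is.null(qc_args$par_regions)) {
    qc_args$par_regions <- do.call(rbind, lapply(qc_args$par_regions, as.data.frame))
  }
  qc <- do.call(qc_config, qc_args)
  filters <- do.call(filter_config, as.list(cfg$filters %||% list()))
  seg <- cfg$segregation %||% list()
  list(annotation = ann, qc = qc, filters = filters,
       allow_unaffected_carriers = isTRUE(seg$allow_unaffected_carriers),
       drop_invalid_families = isTRUE(seg$drop_invalid_families),
       io = cfg$io %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Run the full prioritization pipeline and write the report bundle
#'
#' Validates inputs (every referenced path must exist; every VCF sample must
#' appear in the PED — a cross-reference failure is a hard error listing the
#' offenders), applies genotype QC, the five-criterion cascade and
#' segregation tiering, and writes the report bundle into `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisible list with `candidates`, `evidence`, `trace`, `summary`,
#'   `validation` and the written `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  inputs <- c(vcf = config$vcf, ped = config$ped, ancestry = config$ancestry,
              pli = config$pli, go = config$go, hpo = config$hpo,
              literature = config$literature)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    stop(sprintf("input file(s) not found: %s",
                 paste(sprintf("%s (%s)", missing_in, names(missing_in)), collapse = ", ")))
  }

  ped <- parse_ped(config$ped)
  if (!is.null(config$ancestry)) ped <- read_ancestry(ped, config$ancestry)
  resource <- load_resources(config$pli, config$go, config$hpo, config$literature)
  cohort <- read_cohort_vcf(config$vcf, config$annotation)
  ped <- mark_sequenced(ped, cohort$samples)

  orphans <- setdiff(cohort$samples, ped$individual_id)
  if (length(orphans)) {
    stop(sprintf("VCF sample(s) absent from the pedigree: %s",
                 paste(orphans, collapse = ", ")))
  }
  struct_problems <- check_pedigree_structure(ped)
  if (length(struct_problems)) {
    stop(sprintf("pedigree structure error(s): %s",
                 paste(struct_problems, collapse = "; ")))
  }
  validation <- validate_multiplex(ped)
  seg_ped <- ped
  if (isTRUE(config$drop_invalid_families)) {
    bad <- validation$family_id[nzchar(validation$flags)]
    seg_ped <- ped[!ped$family_id %in% bad, , drop = FALSE]
  }

  res <- run_cascade(cohort, seg_ped, resource, config$qc, config$filters)
  evidence <- build_evidence(res$candidates, res$qc$cohort, seg_ped, resource,
                             allow_unaffected_carriers = config$allow_unaffected_carriers)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(candidates = file.path(out_dir, "candidates.tsv"),
                trace = file.path(out_dir, "filter_trace.tsv"),
                qc_audit = file.path(out_dir, "qc_audit.tsv"),
                evidence_tsv = file.path(out_dir, "evidence.tsv"),
                evidence_json = file.path(out_dir, "evidence.json"),
                summary = file.path(out_dir, "summary.json"),
                validation = file.path(out_dir, "family_validation.tsv"),
                manifest = file.path(out_dir, "manifest.json"))

  cand <- res$candidates
  cand_out <- data.frame(gene = cand$gene, chrom = cand$chrom, pos = cand$pos,
                         ref = cand$ref, alt = cand$alt,
                         consequence = cand$consequence,
                         AF = cand$allele_freq, population = cand$freq_population,
                         SIFT = cand$sift, PolyPhen2 = cand$polyphen,
                         pLI = cand$pli, carriers = cand$carriers,
                         stringsAsFactors = FALSE)
  write_tsv(cand_out, paths$candidates)
  trace <- res$trace[order(res$trace$key), , drop = FALSE]
  write_tsv(trace, paths$trace)
  write_tsv(res$qc$audit, paths$qc_audit)
  evidence <- evidence[order(evidence$key), , drop = FALSE]
  write_tsv(evidence, paths$evidence_tsv)
  jsonlite::write_json(evidence, paths$evidence_json, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(res$summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  write_tsv(validation, paths$validation)

  manifest <- list(
    tool = "famseg",
    version = as.character(utils::packageVersion("famseg")),
    inputs = lapply(stats::setNames(as.list(unname(inputs)), names(inputs)),
                    function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    config = list(qc = unclass(config$qc)[c("min_depth", "min_quality",
                                            "recurrent_indel_fraction")],
                  filters = unclass(config$filters),
                  allow_unaffected_carriers = config$allow_unaffected_carriers,
                  drop_invalid_families = config$drop_invalid_families))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(candidates = res$candidates, evidence = evidence,
                 trace = res$trace, summary = res$summary, qc = res$qc,
                 validation = validation, paths = paths))
}
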