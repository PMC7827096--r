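# Pedigree parsing, validation and queries.
#
# Pedigrees follow the standard 6-column PED convention (family, individual,
# father, mother, sex, phenotype) with plink codes: sex 1=male/2=female/
# 0=unknown; phenotype 2=affected/1=unaffected/0=unknown. Ancestry labels
# travel in a sidecar two-column TSV rather than a seventh PED column so the
# PED file stays strictly standard.

SEX_LEVELS    <- c("male", "female", "unknown")
STATUS_LEVELS <- c("affected", "unaffected", "unknown")

decode_sex    <- function(code) c(`1` = "male", `2` = "female", `0` = "unknown")[as.character(code)]
decode_status <- function(code) c(`2` = "affected", `1` = "unaffected", `0` = "unknown")[as.character(code)]
encode_sex    <- function(sex) c(male = "1", female = "2", unknown = "0")[sex]
encode_status <- function(status) c(affected = "2", unaffected = "1", unknown = "0")[status]

#' Parse a 6-column PED file into a pedigree table
#'
#' Reads a whitespace-delimited PED file (plink convention) and returns one
#' row per individual. Missing parents are coded `"0"` in the file and become
#' `NA`. Individuals are assumed sequenced (present in the cohort VCF) unless
#' later marked otherwise via [mark_sequenced()].
#'
#' @param path Path to a PED file, or a character vector of PED lines.
#' @return A data frame of class `fam_ped` with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`, `status`, `ancestry`
#'   (all `NA` until [read_ancestry()] is merged in) and `sequenced`.
#'   Row order follows the file; one pedigree is the subset of rows sharing a
#'   `family_id`.
#' @examples
#' ped <- parse_ped(c("FAM1 I.1 0 0 1 2", "FAM1 I.2 0 0 2 1",
#'                    "FAM1 II.1 I.1 I.2 1 2"))
#' ped$status
#' @export
parse_ped <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("PED input contains no records")
  fields <- strsplit(trimws(lines), "\\s+")
  n_col <- lengths(fields)
  bad <- which(n_col < 6L)
  if (length(bad)) {
    stop(sprintf("PED parse error at line %d: expected >= 6 columns, found %d",
                 bad[1L], n_col[bad[1L]]))
  }
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  sex_raw <- mat[, 5L]
  status_raw <- mat[, 6L]
  bad <- which(!sex_raw %in% c("0", "1", "2"))
  if (length(bad)) stop(sprintf("PED parse error at line %d: sex code '%s' is not 0/1/2",
                                bad[1L], sex_raw[bad[1L]]))
  bad <- which(!status_raw %in% c("0", "1", "2"))
  if (length(bad)) stop(sprintf("PED parse error at line %d: phenotype code '%s' is not 0/1/2",
                                bad[1L], status_raw[bad[1L]]))
  ped <- data.frame(
    family_id     = mat[, 1L],
    individual_id = mat[, 2L],
    father_id     = ifelse(mat[, 3L] == "0", NA_character_, mat[, 3L]),
    mother_id     = ifelse(mat[, 4L] == "0", NA_character_, mat[, 4L]),
    sex           = unname(decode_sex(sex_raw)),
    status        = unname(decode_status(status_raw)),
    ancestry      = NA_character_,
    sequenced     = TRUE,
    stringsAsFactors = FALSE
  )
  dup <- duplicated(ped[, c("family_id", "individual_id")])
  if (any(dup)) {
    stop(sprintf("PED validation error: duplicate individual '%s' in family '%s'",
                 ped$individual_id[dup][1L], ped$family_id[dup][1L]))
  }
  class(ped) <- c("fam_ped", "data.frame")
  ped
}

#' Serialize a pedigree table back to 6-column PED lines
#'
#' Inverse of [parse_ped()] for the six canonical columns; `ancestry` and
#' `sequenced` are not part of the PED format and are dropped.
#'
#' @param ped A `fam_ped` data frame.
#' @return Character vector of PED lines.
#' @export
format_ped <- function(ped) {
  paste(ped$family_id, ped$individual_id,
        ifelse(is.na(ped$father_id), "0", ped$father_id),
        ifelse(is.na(ped$mother_id), "0", ped$mother_id),
        encode_sex(ped$sex), encode_status(ped$status))
}

#' Read an ancestry sidecar table and attach population labels
#'
#' The sidecar is a two-column TSV with header `sample_id<TAB>population`.
#' Sample ids are matched against `individual_id`; unmatched sidecar rows
#' produce a warning, pedigree members without a sidecar row keep `NA`.
#'
#' @param ped A `fam_ped` data frame.
#' @param path Path to the sidecar TSV.
#' @return `ped` with its `ancestry` column filled in.
#' @export
read_ancestry <- function(ped, path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(tab))) {
    stop("ancestry sidecar must have header columns 'sample_id' and 'population'")
  }
  idx <- match(tab$sample_id, ped$individual_id)
  if (anyNA(idx)) {
    warning(sprintf("ancestry sidecar names %d sample(s) absent from the pedigree: %s",
                    sum(is.na(idx)), paste(utils::head(tab$sample_id[is.na(idx)], 5), collapse = ", ")))
  }
  ped$ancestry[idx[!is.na(idx)]] <- tab$population[!is.na(idx)]
  ped
}

#' Mark which pedigree members were sequenced
#'
#' Only sequenced members enter genotype QC and segregation arithmetic;
#' unsequenced members are retained for pedigree completeness.
#'
#' @param ped A `fam_ped` data frame.
#' @param samples Character vector of sample ids present in the cohort VCF.
#' @return `ped` with `sequenced` set to membership in `samples`.
#' @export
mark_sequenced <- function(ped, samples) {
  ped$sequenced <- ped$individual_id %in% samples
  ped
}

#' Validate the multiplex-family and trio requirements
#'
#' Flags families that do not meet the study design: fewer than two affected
#' members (`MULTIPLEX_FAIL`), or a proband whose two parents are not both
#' present and sequenced (`TRIO_FAIL`). The proband is taken as the first
#' affected member in file order. Flagged families are reported, never
#' dropped — exclusion is a policy decision left to the caller.
#'
#' @param ped A `fam_ped` data frame (one or many families).
#' @return Data frame with one row per family: `family_id`, `n_affected`,
#'   `flags` (comma-joined, `""` when clean).
#' @export
validate_multiplex <- function(ped) {
  fams <- unique(ped$family_id)
  rows <- lapply(fams, function(fam) {
    mem <- ped[ped$family_id == fam, , drop = FALSE]
    flags <- character(0)
    n_aff <- sum(mem$status == "affected")
    if (n_aff < 2L) flags <- c(flags, "MULTIPLEX_FAIL")
    # proband: first affected member whose parents are recorded (falling
    # back to the first affected founder when a family lists none)
    proband <- mem[mem$status == "affected", , drop = FALSE]
    with_parents <- !is.na(proband$father_id) | !is.na(proband$mother_id)
    if (any(with_parents)) proband <- proband[with_parents, , drop = FALSE]
    trio_ok <- FALSE
    if (nrow(proband) > 0L) {
      p <- proband[1L, ]
      parent_ok <- function(id) {
        !is.na(id) && id %in% mem$individual_id && mem$sequenced[mem$individual_id == id]
      }
      trio_ok <- parent_ok(p$father_id) && parent_ok(p$mother_id)
    }
    if (!trio_ok) flags <- c(flags, "TRIO_FAIL")
    data.frame(family_id = fam, n_affected = n_aff,
               flags = paste(flags, collapse = ","), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select pedigree members by affected status
#'
#' @param ped A `fam_ped` data frame.
#' @param status One of `"affected"`, `"unaffected"`, `"unknown"`.
#' @return The member rows with that status, order preserved.
#' @export
members_by_status <- function(ped, status) {
  status <- match.arg(status, STATUS_LEVELS)
  ped[ped$status == status, , drop = FALSE]
}

# Structural consistency of a pedigree table: parent references resolve
# within the family, parent sexes are coherent where known.
check_pedigree_structure <- function(ped) {
  problems <- character(0)
  for (fam in unique(ped$family_id)) {
    mem <- ped[ped$family_id == fam, , drop = FALSE]
    for (i in seq_len(nrow(mem))) {
      for (side in c("father", "mother")) {
        pid <- mem[[paste0(side, "_id")]][i]
        if (is.na(pid)) next
        j <- match(pid, mem$individual_id)
        if (is.na(j)) {
          problems <- c(problems, sprintf("%s: %s of %s ('%s') not a family member",
                                          fam, side, mem$individual_id[i], pid))
        } else {
          want <- if (side == "father") "male" else "female"
          if (mem$sex[j] != "unknown" && mem$sex[j] != want) {
            problems <- c(problems, sprintf("%s: %s '%s' is recorded as %s",
                                            fam, side, pid, mem$sex[j]))
          }
        }
      }
    }
  }
  problems
}
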