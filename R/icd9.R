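# Phenotype construction: ICD-9 normalization, group mapping, case labels.

#' Normalize raw ICD-9 code strings
#'
#' Canonical form: whitespace and the decimal point removed, letters upper
#' case, so `"174.9"` becomes `"1749"` and `"V10.3"` becomes `"V103"`.
#' Leading zeros are preserved (codes are matched as strings, never as
#' numbers).  The transformation is idempotent.
#'
#' @param code Character vector of raw ICD-9 codes.
#' @return Character vector of canonical codes.
#' @examples
#' normalizeICD9(c("174.9", "V10.3", " 038.0 "))
#' @export
normalizeICD9 <- function(code) {
  stopIfNot(is.character(code) || is.factor(code), "codes must be character")
  x <- toupper(gsub("[[:space:]]", "", as.character(code)))
  x <- gsub(".", "", x, fixed = TRUE)
  bad <- !nzchar(x) | !grepl("^[VE]?[0-9]+$", x)
  if (any(bad)) {
    stop(sprintf("malformed ICD-9 code(s): %s",
                 paste(unique(code[bad]), collapse = ", ")), call. = FALSE)
  }
  x
}

#' Map raw subject diagnoses to constituent groups
#'
#' Applies a [GroupMap-class] to a long table of `(subject_id, icd9)` rows.
#' Each mapped code contributes its group once per subject (set semantics);
#' codes absent from the map are counted and reported via a message, not an
#' error, and subjects whose codes all fail to map are simply absent from
#' the result (they become controls downstream).
#'
#' @param diagnoses `data.frame` with columns `subject_id` and `icd9`.
#' @param map A [GroupMap-class].
#' @return A [DiagnosisTable-class]; `unmappedCount()` returns the number
#'   of dropped rows.
#' @export
mapToGroups <- function(diagnoses, map) {
  stopIfNot(is(map, "GroupMap"), "map must be a GroupMap")
  stopIfNot(all(c("subject_id", "icd9") %in% colnames(diagnoses)),
            "diagnoses needs columns subject_id, icd9")
  if (nrow(diagnoses) == 0L) return(DiagnosisTable())
  code <- normalizeICD9(diagnoses$icd9)
  grp <- unname(codeToGroup(map)[code])
  unmapped <- sum(is.na(grp))
  if (unmapped > 0L) {
    message(sprintf("mapToGroups: %d of %d diagnosis rows had no group mapping and were dropped",
                    unmapped, length(grp)))
  }
  keep <- !is.na(grp)
  DiagnosisTable(diagnoses$subject_id[keep], grp[keep], nUnmapped = unmapped)
}

#' Assign case/control status for a mechanistic phenotype
#'
#' A subject is a case if and only if it carries at least one constituent
#' group of the phenotype; all other cohort subjects are controls.  Subjects
#' absent from the diagnosis table (no recorded mapped diagnosis) are
#' controls.
#'
#' @param dx A [DiagnosisTable-class].
#' @param def A [PhenotypeDefinition-class].
#' @param cohort Character vector of all analyzed subject ids.
#' @return Named factor with levels `control`, `case`, one entry per cohort
#'   subject.  A degenerate split (no cases or no controls) is flagged with
#'   a warning.
#' @export
assignPhenotype <- function(dx, def, cohort) {
  stopIfNot(is(dx, "DiagnosisTable"), "dx must be a DiagnosisTable")
  stopIfNot(is(def, "PhenotypeDefinition"), "def must be a PhenotypeDefinition")
  cohort <- as.character(cohort)
  stopIfNot(!anyDuplicated(cohort), "duplicate subject ids in cohort")
  p <- diagnosisPairs(dx)
  extra <- setdiff(unique(p$subject_id), cohort)
  if (length(extra)) {
    stop(sprintf("diagnosis table contains %d subject(s) not in the cohort roster (e.g. %s)",
                 length(extra), extra[1]), call. = FALSE)
  }
  caseIds <- unique(p$subject_id[p$group_id %in% constituentGroups(def)])
  y <- factor(ifelse(cohort %in% caseIds, "case", "control"),
              levels = c("control", "case"))
  names(y) <- cohort
  if (length(unique(y)) < 2L) {
    warning(sprintf("phenotype '%s': degenerate case/control split (%d cases / %d controls)",
                    phenotypeId(def), sum(y == "case"), sum(y == "control")))
  }
  y
}

#' Read a group map from TSV files
#'
#' @param codeFile TSV `icd9<TAB>group_id` (no header required; a header row
#'   `icd9	group_id` is tolerated).
#' @param phenotypeFile Optional TSV `group_id<TAB>phenotype_id`, one row per
#'   membership.
#' @return A [GroupMap-class].
#' @export
readGroupMap <- function(codeFile, phenotypeFile = NULL) {
  cg <- read.table(codeFile, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("icd9", "group_id"), colClasses = "character",
                   quote = "", comment.char = "")
  if (nrow(cg) && identical(tolower(cg$icd9[1]), "icd9")) cg <- cg[-1, , drop = FALSE]
  stopIfNot(nrow(cg) > 0L, "empty group map file")
  dup <- duplicated(normalizeICD9(cg$icd9))
  if (any(dup)) stop("ICD-9 codes mapped to more than one group: ",
                     paste(unique(cg$icd9[dup]), collapse = ", "), call. = FALSE)
  g2p <- if (is.null(phenotypeFile)) {
    data.frame(group_id = character(), phenotype_id = character())
  } else {
    gp <- read.table(phenotypeFile, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                     col.names = c("group_id", "phenotype_id"),
                     colClasses = "character", quote = "", comment.char = "")
    if (nrow(gp) && identical(tolower(gp$group_id[1]), "group_id")) gp <- gp[-1, , drop = FALSE]
    gp
  }
  GroupMap(setNames(cg$group_id, cg$icd9), g2p)
}

#' Read a subject diagnosis table (long TSV)
#'
#' @param path TSV `subject_id<TAB>icd9`, no header required.
#' @return `data.frame` with columns `subject_id`, `icd9` ready for
#'   [mapToGroups].
#' @export
readDiagnoses <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("subject_id", "icd9"), colClasses = "character",
                   quote = "", comment.char = "")
  if (nrow(df) && identical(tolower(df$subject_id[1]), "subject_id")) df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Derive phenotype definitions from a group map
#'
#' Builds one [PhenotypeDefinition-class] per phenotype id appearing in the
#' group-to-phenotype table of a [GroupMap-class].
#'
#' @param map A [GroupMap-class].
#' @return Named list of [PhenotypeDefinition-class] objects.
#' @export
phenotypesFromMap <- function(map) {
  g2p <- groupToPhenotype(map)
  stopIfNot(nrow(g2p) > 0L, "group map carries no phenotype memberships")
  ids <- sort(unique(g2p$phenotype_id))
  setNames(lapply(ids, function(id) {
    PhenotypeDefinition(id, g2p$group_id[g2p$phenotype_id == id])
  }), ids)
}

#' Read phenotype definitions from a YAML/JSON-style config
#'
#' The file maps phenotype ids to vectors of constituent group ids, e.g.
#' \preformatted{THROMBOSIS: [VENOUS, STROKE, AMI]}
#'
#' @param path Path to a YAML file.
#' @return Named list of [PhenotypeDefinition-class] objects.
#' @export
readPhenotypeDefs <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopIfNot(length(cfg) > 0L, "no phenotype definitions in file")
  setNames(lapply(names(cfg), function(id) PhenotypeDefinition(id, unlist(cfg[[id]]))),
           names(cfg))
}
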