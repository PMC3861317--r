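#' GenotypeMatrix: minor-allele dosage container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with SNPs as rows and
#' subjects as columns.  The single assay `"dosage"` holds minor-allele
#' copy counts (0, 1, 2 or `NA` for missing calls); `rowData()` carries
#' `gene`, `allele_major` and `allele_minor`; `colData()` carries subject
#' covariates (typically `age`, `gender`, `dataset`).  The minor allele is,
#' by construction of the readers, the less frequent allele in the loaded
#' cohort.
#'
#' @slot .  See [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object)) {
    msg <- c(msg, "assay 'dosage' is required")
  } else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L))) {
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    }
  }
  need <- c("gene", "allele_major", "allele_minor")
  if (!all(need %in% colnames(rowData(object)))) {
    msg <- c(msg, sprintf("rowData must contain %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(colnames(object))) msg <- c(msg, "subject ids must be unique")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "snp ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage Integer matrix of minor-allele dosages, SNPs in rows
#'   (rownames = SNP ids), subjects in columns (colnames = subject ids).
#' @param snpInfo `data.frame` with one row per SNP; columns `gene`,
#'   `allele_major`, `allele_minor` (missing columns are filled with `NA`).
#' @param subjectInfo `data.frame` of per-subject covariates (one row per
#'   subject, in column order of `dosage`).
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, 0L), 1, 4,
#'             dimnames = list("rs1", paste0("S", 1:4)))
#' gm <- GenotypeMatrix(d)
#' dosages(gm)
#' @export
GenotypeMatrix <- function(dosage, snpInfo = NULL, subjectInfo = NULL) {
  stopIfNot(is.matrix(dosage), "dosage must be a matrix")
  stopIfNot(!is.null(rownames(dosage)) && !is.null(colnames(dosage)),
            "dosage needs SNP rownames and subject colnames")
  storage.mode(dosage) <- "integer"
  if (is.null(snpInfo)) snpInfo <- data.frame(row.names = rownames(dosage))
  for (f in c("gene", "allele_major", "allele_minor")) {
    if (is.null(snpInfo[[f]])) snpInfo[[f]] <- NA_character_
  }
  rd <- DataFrame(snpInfo, row.names = rownames(dosage))
  cd <- if (is.null(subjectInfo)) {
    DataFrame(row.names = colnames(dosage))
  } else {
    DataFrame(subjectInfo, row.names = colnames(dosage))
  }
  new("GenotypeMatrix",
      SummarizedExperiment(assays = list(dosage = dosage), rowData = rd, colData = cd))
}

#' DiagnosisTable: subject-to-constituent-group memberships
#'
#' Set-semantic long table of `(subject_id, group_id)` pairs obtained by
#' mapping raw ICD-9 codes through a [GroupMap-class].  Duplicate pairs are
#' collapsed; the count of unmappable input codes is retained for
#' reporting.
#'
#' @slot pairs `data.frame` with character columns `subject_id`, `group_id`;
#'   unique rows.
#' @slot nUnmapped integer, number of input diagnosis rows whose code had no
#'   entry in the group map.
#' @export
setClass("DiagnosisTable",
         representation(pairs = "data.frame", nUnmapped = "integer"))

setValidity("DiagnosisTable", function(object) {
  p <- object@pairs
  if (!identical(colnames(p), c("subject_id", "group_id")))
    return("pairs must have columns subject_id, group_id")
  if (anyDuplicated(p)) return("duplicate (subject, group) pairs")
  if (length(object@nUnmapped) != 1L || is.na(object@nUnmapped) || object@nUnmapped < 0L)
    return("nUnmapped must be a single non-negative integer")
  TRUE
})

#' Construct a DiagnosisTable from subject/group pairs
#'
#' @param subject_id,group_id Character vectors of equal length.
#' @param nUnmapped Number of unmappable diagnosis rows dropped upstream.
#' @return A [DiagnosisTable-class] object.
#' @export
DiagnosisTable <- function(subject_id = character(), group_id = character(),
                           nUnmapped = 0L) {
  df <- unique(data.frame(subject_id = as.character(subject_id),
                          group_id = as.character(group_id),
                          stringsAsFactors = FALSE))
  df <- df[order(df$subject_id, df$group_id), , drop = FALSE]
  rownames(df) <- NULL
  new("DiagnosisTable", pairs = df, nUnmapped = as.integer(nUnmapped))
}

#' GroupMap: ICD-9 to constituent group to mechanistic phenotype mapping
#'
#' Many-to-one map from canonical ICD-9 code strings to constituent
#' diagnosis groups, plus a one-to-many map from groups to mechanistic
#' phenotypes (a group may feed several phenotypes, or none).
#'
#' @slot codeToGroup Named character vector: names are canonical ICD-9
#'   codes (see [normalizeICD9]), values are group ids.
#' @slot groupToPhenotype `data.frame` with columns `group_id`,
#'   `phenotype_id`, one row per membership.
#' @export
setClass("GroupMap",
         representation(codeToGroup = "character", groupToPhenotype = "data.frame"))

setValidity("GroupMap", function(object) {
  msg <- character()
  if (length(object@codeToGroup) == 0L) msg <- c(msg, "empty code map")
  if (is.null(names(object@codeToGroup)) || anyDuplicated(names(object@codeToGroup)))
    msg <- c(msg, "codes must be unique names of codeToGroup")
  g2p <- object@groupToPhenotype
  if (!identical(colnames(g2p), c("group_id", "phenotype_id")))
    msg <- c(msg, "groupToPhenotype must have columns group_id, phenotype_id")
  if (length(msg)) msg else TRUE
})

#' Construct a GroupMap
#'
#' @param codeToGroup Named character vector mapping canonical ICD-9 codes
#'   to group ids (names are normalized with [normalizeICD9]).
#' @param groupToPhenotype `data.frame` with columns `group_id`,
#'   `phenotype_id` (one row per membership); may be empty.
#' @return A [GroupMap-class] object.
#' @export
GroupMap <- function(codeToGroup,
                     groupToPhenotype = data.frame(group_id = character(),
                                                   phenotype_id = character())) {
  stopIfNot(length(codeToGroup) > 0L, "empty GroupMap")
  names(codeToGroup) <- normalizeICD9(names(codeToGroup))
  g2p <- unique(data.frame(group_id = as.character(groupToPhenotype$group_id),
                           phenotype_id = as.character(groupToPhenotype$phenotype_id),
                           stringsAsFactors = FALSE))
  rownames(g2p) <- NULL
  new("GroupMap", codeToGroup = codeToGroup, groupToPhenotype = g2p)
}

#' PhenotypeDefinition: a mechanistic phenotype as a set of groups
#'
#' A mechanistic phenotype (for example `THROMBOSIS`, or the cancer
#' groupings `ALL`, `CA`, `HEM`, `MET`, `SKN`) is defined by the set of
#' constituent diagnosis groups whose presence makes a subject a case.
#'
#' @slot id Character scalar phenotype id.
#' @slot groups Character vector of constituent group ids (non-empty).
#' @export
setClass("PhenotypeDefinition",
         representation(id = "character", groups = "character"))

setValidity("PhenotypeDefinition", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id)) return("id must be one non-empty string")
  if (length(object@groups) == 0L) return("constituent group set must be non-empty")
  if (anyDuplicated(object@groups)) return("duplicate constituent groups")
  TRUE
})

#' @rdname PhenotypeDefinition-class
#' @param id Phenotype id.
#' @param groups Character vector of constituent group ids.
#' @export
PhenotypeDefinition <- function(id, groups) {
  new("PhenotypeDefinition", id = as.character(id),
      groups = sort(unique(as.character(groups))))
}

#' OntologyAnnotation: flat gene-to-ontology term memberships
#'
#' Gene-level Biological Process style annotation, read from a two-column
#' export.  Terms are flat labels (no graph propagation).  Genes with no
#' annotation still belong to the Fisher universe.
#'
#' @slot geneSets Named list: gene id -> character vector of term ids.
#' @slot termNames Named character vector: term id -> descriptive name.
#' @export
setClass("OntologyAnnotation",
         representation(geneSets = "list", termNames = "character"))

setValidity("OntologyAnnotation", function(object) {
  if (length(object@geneSets) && is.null(names(object@geneSets)))
    return("geneSets must be named by gene id")
  TRUE
})

#' @rdname OntologyAnnotation-class
#' @param geneSets Named list of term-id character vectors.
#' @param termNames Named character vector of term descriptions.
#' @export
OntologyAnnotation <- function(geneSets, termNames = character()) {
  geneSets <- lapply(geneSets, function(x) sort(unique(as.character(x))))
  new("OntologyAnnotation", geneSets = geneSets, termNames = termNames)
}

#' Cohort: bundled synthetic or loaded study data
#'
#' Convenience container tying together the objects the pipeline consumes:
#' genotypes with covariates, the diagnosis table, the group map and the
#' phenotype definitions.
#'
#' @slot genotypes A [GenotypeMatrix-class].
#' @slot diagnoses A [DiagnosisTable-class].
#' @slot map A [GroupMap-class].
#' @slot phenotypes Named list of [PhenotypeDefinition-class] objects.
#' @slot spec List of generator/run parameters for provenance.
#' @export
setClass("Cohort",
         representation(genotypes = "GenotypeMatrix",
                        diagnoses = "DiagnosisTable",
                        map = "GroupMap",
                        phenotypes = "list",
                        spec = "list"))

setValidity("Cohort", function(object) {
  if (length(object@phenotypes) &&
      !all(vapply(object@phenotypes, is, logical(1), "PhenotypeDefinition")))
    return("phenotypes must be PhenotypeDefinition objects")
  dxSubj <- unique(object@diagnoses@pairs$subject_id)
  if (length(dxSubj) && !all(dxSubj %in% colnames(object@genotypes)))
    return("diagnosis table contains subjects absent from the genotype matrix")
  TRUE
})
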