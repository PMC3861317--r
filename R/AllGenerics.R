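# Generics, accessors and show methods.

#' @name mechphen-accessors
#' @title Accessors for mechphen data containers
#' @description Small accessor layer so downstream code never touches slots
#'   or assay internals directly.
#' @param x A mechphen container object.
#' @param ... Unused.
#' @return See the individual methods.
NULL

#' @rdname mechphen-accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname mechphen-accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x, ...) assay(x, "dosage"))

#' @rdname mechphen-accessors
#' @export
setGeneric("snpIds", function(x, ...) standardGeneric("snpIds"))

#' @rdname mechphen-accessors
#' @export
setMethod("snpIds", "GenotypeMatrix", function(x, ...) rownames(x))

#' @rdname mechphen-accessors
#' @export
setGeneric("subjectIds", function(x, ...) standardGeneric("subjectIds"))

#' @rdname mechphen-accessors
#' @export
setMethod("subjectIds", "GenotypeMatrix", function(x, ...) colnames(x))

#' @rdname mechphen-accessors
#' @export
setMethod("subjectIds", "DiagnosisTable", function(x, ...) unique(x@pairs$subject_id))

#' @rdname mechphen-accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname mechphen-accessors
#' @export
setMethod("geneIds", "GenotypeMatrix", function(x, ...) {
  setNames(as.character(rowData(x)$gene), rownames(x))
})

#' @rdname mechphen-accessors
#' @export
setGeneric("covariates", function(x, ...) standardGeneric("covariates"))

#' @rdname mechphen-accessors
#' @export
setMethod("covariates", "GenotypeMatrix", function(x, ...) {
  as.data.frame(colData(x))
})

#' @rdname mechphen-accessors
#' @export
setGeneric("diagnosisPairs", function(x, ...) standardGeneric("diagnosisPairs"))

#' @rdname mechphen-accessors
#' @export
setMethod("diagnosisPairs", "DiagnosisTable", function(x, ...) x@pairs)

#' @rdname mechphen-accessors
#' @export
setGeneric("unmappedCount", function(x, ...) standardGeneric("unmappedCount"))

#' @rdname mechphen-accessors
#' @export
setMethod("unmappedCount", "DiagnosisTable", function(x, ...) x@nUnmapped)

#' @rdname mechphen-accessors
#' @export
setGeneric("groupIds", function(x, ...) standardGeneric("groupIds"))

#' @rdname mechphen-accessors
#' @export
setMethod("groupIds", "GroupMap", function(x, ...) sort(unique(unname(x@codeToGroup))))

#' @rdname mechphen-accessors
#' @export
setMethod("groupIds", "DiagnosisTable", function(x, ...) sort(unique(x@pairs$group_id)))

#' @rdname mechphen-accessors
#' @export
setGeneric("codeToGroup", function(x, ...) standardGeneric("codeToGroup"))

#' @rdname mechphen-accessors
#' @export
setMethod("codeToGroup", "GroupMap", function(x, ...) x@codeToGroup)

#' @rdname mechphen-accessors
#' @export
setGeneric("groupToPhenotype", function(x, ...) standardGeneric("groupToPhenotype"))

#' @rdname mechphen-accessors
#' @export
setMethod("groupToPhenotype", "GroupMap", function(x, ...) x@groupToPhenotype)

#' @rdname mechphen-accessors
#' @export
setGeneric("phenotypeId", function(x, ...) standardGeneric("phenotypeId"))

#' @rdname mechphen-accessors
#' @export
setMethod("phenotypeId", "PhenotypeDefinition", function(x, ...) x@id)

#' @rdname mechphen-accessors
#' @export
setGeneric("constituentGroups", function(x, ...) standardGeneric("constituentGroups"))

#' @rdname mechphen-accessors
#' @export
setMethod("constituentGroups", "PhenotypeDefinition", function(x, ...) x@groups)

#' @rdname mechphen-accessors
#' @export
setGeneric("geneSets", function(x, ...) standardGeneric("geneSets"))

#' @rdname mechphen-accessors
#' @export
setMethod("geneSets", "OntologyAnnotation", function(x, ...) x@geneSets)

#' @rdname mechphen-accessors
#' @export
setGeneric("termNames", function(x, ...) standardGeneric("termNames"))

#' @rdname mechphen-accessors
#' @export
setMethod("termNames", "OntologyAnnotation", function(x, ...) x@termNames)

#' @rdname mechphen-accessors
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))

#' @rdname mechphen-accessors
#' @export
setMethod("genotypes", "Cohort", function(x, ...) x@genotypes)

#' @rdname mechphen-accessors
#' @export
setGeneric("diagnoses", function(x, ...) standardGeneric("diagnoses"))

#' @rdname mechphen-accessors
#' @export
setMethod("diagnoses", "Cohort", function(x, ...) x@diagnoses)

#' @rdname mechphen-accessors
#' @export
setGeneric("groupMap", function(x, ...) standardGeneric("groupMap"))

#' @rdname mechphen-accessors
#' @export
setMethod("groupMap", "Cohort", function(x, ...) x@map)

#' @rdname mechphen-accessors
#' @export
setGeneric("phenotypeDefs", function(x, ...) standardGeneric("phenotypeDefs"))

#' @rdname mechphen-accessors
#' @export
setMethod("phenotypeDefs", "Cohort", function(x, ...) x@phenotypes)

#' @rdname mechphen-accessors
#' @export
setMethod("covariates", "Cohort", function(x, ...) covariates(x@genotypes))

setMethod("show", "DiagnosisTable", function(object) {
  cat(sprintf("DiagnosisTable: %d (subject, group) pairs, %d subjects, %d groups",
              nrow(object@pairs), length(unique(object@pairs$subject_id)),
              length(unique(object@pairs$group_id))))
  if (object@nUnmapped > 0L) cat(sprintf(" (%d unmapped input rows)", object@nUnmapped))
  cat("\n")
})

setMethod("show", "GroupMap", function(object) {
  cat(sprintf("GroupMap: %d ICD-9 codes -> %d groups; %d group-phenotype memberships\n",
              length(object@codeToGroup), length(unique(object@codeToGroup)),
              nrow(object@groupToPhenotype)))
})

setMethod("show", "PhenotypeDefinition", function(object) {
  cat(sprintf("PhenotypeDefinition '%s': %d constituent groups\n",
              object@id, length(object@groups)))
})

setMethod("show", "OntologyAnnotation", function(object) {
  nterm <- length(unique(unlist(object@geneSets, use.names = FALSE)))
  cat(sprintf("OntologyAnnotation: %d genes, %d distinct terms\n",
              length(object@geneSets), nterm))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d subjects x %d SNPs; %d diagnosis pairs; phenotypes: %s\n",
              ncol(object@genotypes), nrow(object@genotypes),
              nrow(object@diagnoses@pairs),
              paste(names(object@phenotypes), collapse = ", ")))
})
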