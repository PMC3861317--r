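# Annotation and results IO.

#' Read a gene-to-ontology annotation table
#'
#' Expects a two-column TSV `gene_id<TAB>ontology_id` (an optional third
#' column carries the term name), the shape of a DAVID Biological Process
#' export.  Duplicate `(gene, term)` rows collapse to one membership.
#'
#' @param path Annotation TSV path.
#' @param genes Optional character vector of universe genes; genes listed
#'   here but absent from the file are kept with an empty annotation set so
#'   they still count in the Fisher universe.
#' @return An [OntologyAnnotation-class].
#' @export
readAnnotation <- function(path, genes = NULL) {
  stopIfNot(file.exists(path), sprintf("missing file: %s", path))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "", fill = TRUE,
                   colClasses = "character")
  stopIfNot(nrow(df) > 0L, "empty annotation file")
  stopIfNot(ncol(df) >= 2L, "annotation file needs two tab-separated columns")
  if (identical(tolower(df[1, 1]), "gene_id")) df <- df[-1, , drop = FALSE]
  sets <- split(df[[2]], df[[1]])
  nm <- character()
  if (ncol(df) >= 3L) {
    has <- nzchar(df[[3]])
    nm <- setNames(df[[3]][has], df[[2]][has])
    nm <- nm[!duplicated(names(nm))]
  }
  if (!is.null(genes)) {
    absent <- setdiff(genes, names(sets))
    sets <- c(sets, setNames(rep(list(character()), length(absent)), absent))
  }
  OntologyAnnotation(sets, nm)
}

#' Number of distinct ontology terms in an annotation universe
#'
#' The Fisher/FDR universe size `m`: the count of distinct terms annotating
#' at least one gene of the (optionally restricted) gene set.
#'
#' @param ann An [OntologyAnnotation-class].
#' @param genes Optional gene subset defining the universe.
#' @return Integer term count.
#' @export
ontologyUniverseSize <- function(ann, genes = NULL) {
  sets <- geneSets(ann)
  if (!is.null(genes)) sets <- sets[intersect(genes, names(sets))]
  length(unique(unlist(sets, use.names = FALSE)))
}

#' Write an association or enrichment result table
#'
#' Deterministic TSV writer: header row, one row per result, numeric
#' columns rendered at full double precision so a write/read round trip is
#' lossless to within 1e-15 relative error.  Enrichment tables are sorted
#' by `(fdr_q, fisher_p, ontology_id)` before writing.
#'
#' @param results `data.frame` of results (association or enrichment rows).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
  stopIfNot(is.data.frame(results), "results must be a data.frame")
  if (all(c("fdr_q", "fisher_p", "ontology_id") %in% colnames(results)) &&
      nrow(results) > 1L) {
    results <- results[order(results$fdr_q, results$fisher_p, results$ontology_id), ,
                       drop = FALSE]
  }
  writeTsv(results, path)
}

#' Read back a results TSV written by [writeResults]
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
readResults <- function(path) {
  readTsv(path)
}
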