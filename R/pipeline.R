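# End-to-end pipeline: qc -> association -> ranking -> enrichment.

#' Validate a pipeline run configuration
#'
#' @param cfg Named list (or YAML path) with fields: `genotypes` (PED/MAP
#'   prefix or dosage TSV), `genotypeFormat`, `diagnoses`, `groupMap`,
#'   `groupPhenotypes`, `covariates`, `annotation` (optional), `phenotypes`
#'   (character vector; default: all ids in the map), `models` (subset of
#'   additive/recessive/rg1/rg2/rec), `qc` (list for [qcThresholds]),
#'   `perm` (list for [permutationConfig]), `pCut`, `outDir`, `seed`.
#' @return Normalized configuration list; errors name the offending field.
#' @export
validateRunConfig <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  stopIfNot(is.list(cfg), "config must be a list or YAML path")
  defaults <- list(genotypeFormat = "ped_map", models = c("additive", "rg1"),
                   phenotypes = NULL, annotation = NULL, qc = list(),
                   perm = list(), pCut = 0.05, outDir = "mechphen_out",
                   seed = 1L)
  cfg <- modifyList(defaults, cfg)
  for (f in c("genotypes", "diagnoses", "groupMap", "groupPhenotypes", "covariates")) {
    stopIfNot(!is.null(cfg[[f]]), sprintf("config field '%s' is required", f))
  }
  known <- c("additive", "recessive", "rg1", "rg2", "rec")
  badModel <- setdiff(cfg$models, known)
  stopIfNot(length(badModel) == 0L,
            sprintf("config field 'models': unknown model '%s'", badModel[1]))
  pathFields <- c("diagnoses", "groupMap", "groupPhenotypes", "covariates")
  if (!is.null(cfg$annotation)) pathFields <- c(pathFields, "annotation")
  for (f in pathFields) {
    stopIfNot(file.exists(cfg[[f]]), sprintf("config field '%s': missing file %s",
                                             f, cfg[[f]]))
  }
  cfg$qc <- do.call(qcThresholds, cfg$qc)
  cfg$perm <- do.call(permutationConfig,
                      modifyList(list(seed = cfg$seed), cfg$perm))
  cfg
}

#' Run the full association and enrichment pipeline
#'
#' Stages: load inputs, SNP selection, per-phenotype association under the
#' configured models, gene ranking (forward models OR>1 filtered), and -
#' when an annotation file is supplied - the sequential enrichment scan.
#' All outputs are TSV files under `cfg$outDir`; the validated
#' configuration is serialized alongside them for provenance.  Reruns with
#' the same configuration and seed are byte-identical.
#'
#' @param cfg Configuration list or YAML path (see [validateRunConfig]).
#' @return Invisible list with the result tables (`qc`, `association`,
#'   `enrichment`).
#' @export
runPipeline <- function(cfg) {
  cfg <- validateRunConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  covars <- readCovariates(cfg$covariates)
  gm <- readGenotypes(cfg$genotypes, cfg$genotypeFormat, subjectInfo = covars)
  # PED/MAP carries no gene annotation; an optional snp_id<TAB>gene file
  # supplies it, otherwise each SNP ranks as its own gene
  if (!is.null(cfg$snpGenes)) {
    sg <- read.table(cfg$snpGenes, sep = "\t", header = FALSE,
                     col.names = c("snp_id", "gene"), colClasses = "character",
                     quote = "", comment.char = "")
    rowData(gm)$gene <- sg$gene[match(rownames(gm), sg$snp_id)]
  }
  noGene <- is.na(rowData(gm)$gene)
  if (any(noGene)) rowData(gm)$gene[noGene] <- rownames(gm)[noGene]
  map <- readGroupMap(cfg$groupMap, cfg$groupPhenotypes)
  dx <- mapToGroups(readDiagnoses(cfg$diagnoses), map)
  defs <- phenotypesFromMap(map)
  phen <- cfg$phenotypes %||% names(defs)
  badPhen <- setdiff(phen, names(defs))
  stopIfNot(length(badPhen) == 0L,
            sprintf("config field 'phenotypes': unknown phenotype '%s'", badPhen[1]))

  sel <- selectSNPs(gm, cfg$qc)
  writeResults(sel$report, file.path(cfg$outDir, "snp_qc_report.tsv"))
  gmSel <- gm[sel$retained, ]

  assoc <- list()
  for (ph in phen) {
    def <- defs[[ph]]
    y <- assignPhenotype(dx, def, subjectIds(gmSel))
    for (model in cfg$models) {
      tab <- if (model %in% c("additive", "recessive")) {
        runForwardAssociation(gmSel, y, model = model, phenotype = ph)
      } else {
        runReverseAssociation(gmSel, dx, def, model = model, cfg = cfg$perm)
      }
      writeResults(tab, file.path(cfg$outDir, sprintf("assoc_%s_%s.tsv", ph, model)))
      assoc[[paste(ph, model, sep = "_")]] <- tab
    }
  }

  enrich <- list()
  if (!is.null(cfg$annotation)) {
    for (key in names(assoc)) {
      tab <- orFilter(assoc[[key]])
      if (nrow(tab) == 0L || all(is.na(tab$p))) next
      ranked <- rankGenes(tab)
      ann <- readAnnotation(cfg$annotation, genes = ranked$gene)
      res <- sequentialScan(ranked, ann, pCut = cfg$pCut)
      writeResults(res, file.path(cfg$outDir, sprintf("enrichment_%s.tsv", key)))
      enrich[[key]] <- res
    }
  }
  cfgOut <- cfg
  cfgOut$qc$minHzma <- as.integer(cfgOut$qc$minHzma)
  yaml::write_yaml(cfgOut, file.path(cfg$outDir, "run_config.yaml"))
  invisible(list(qc = sel$report, association = assoc, enrichment = enrich))
}
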