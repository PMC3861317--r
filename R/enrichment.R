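# Sequential top-k ontology enrichment over ranked gene lists.

#' Rank genes by association p-value
#'
#' Collapses SNP-level association results to one row per gene at the
#' gene's best (minimum) p-value over its nsSNPs, sorted ascending with
#' ties broken by gene id.  In pooled mode each gene is ranked once at its
#' best p across the supplied phenotypes and the phenotype(s) attaining the
#' minimum are recorded.
#'
#' @param results Association `data.frame` (one model only) with columns
#'   `gene`, `p` and, for pooled mode, `phenotype_id`.  Forward-model
#'   results should be pre-filtered with [orFilter].
#' @param mode `"single_phenotype"` or `"pooled"`.
#' @return `data.frame` with columns `gene`, `p`, `source` (phenotype ids),
#'   ordered ascending by `(p, gene)`.
#' @export
rankGenes <- function(results, mode = c("single_phenotype", "pooled")) {
  mode <- match.arg(mode)
  stopIfNot(is.data.frame(results) && nrow(results) > 0L, "empty result set")
  stopIfNot(all(c("gene", "p") %in% colnames(results)), "results need gene and p columns")
  if (length(unique(results$model)) > 1L)
    stop("rank lists must come from a single model", call. = FALSE)
  res <- results[!is.na(results$p) & !is.na(results$gene), , drop = FALSE]
  stopIfNot(nrow(res) > 0L, "no usable p-values in result set")
  best <- tapply(res$p, res$gene, min)
  src <- vapply(names(best), function(g) {
    rows <- res[res$gene == g & res$p == best[[g]], , drop = FALSE]
    if (mode == "pooled" && "phenotype_id" %in% colnames(rows)) {
      paste(sort(unique(rows$phenotype_id)), collapse = ",")
    } else {
      paste(sort(unique(rows$phenotype_id %||% "")), collapse = ",")
    }
  }, character(1))
  out <- data.frame(gene = names(best), p = as.numeric(best), source = src,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-sided Fisher enrichment p-value
#'
#' Upper-tail hypergeometric probability `P(X >= a)` of observing `a`
#' annotated genes among the `k` selected, given `K` annotated genes in a
#' universe of `N`.
#'
#' @param k Number of selected (top-ranked) genes.
#' @param a Annotated genes among the selected.
#' @param N Universe size (all analyzed genes).
#' @param K Annotated genes in the universe.
#' @return Enrichment p-value.
#' @examples
#' ontologyFisher(k = 2, a = 2, N = 748, K = 2)  # 1 / choose(748, 2)
#' @export
ontologyFisher <- function(k, a, N, K) {
  stopIfNot(all(c(k, a, N, K) >= 0), "counts must be non-negative")
  stopIfNot(k <= N && K <= N && a <= min(k, K), "impossible contingency table")
  if (a == 0) return(1)
  phyper(a - 1, K, N - K, k, lower.tail = FALSE)
}

#' Sequential top-k enrichment scan
#'
#' For an ascending-p ranked gene list, sequentially selects the top
#' `k = 1, 2, ...` genes (all genes below the association cut-off
#' `pCut`, or a fixed `topN` in GWAS mode), computes the one-sided Fisher
#' enrichment p for every ontology at every `k`, and reports each
#' ontology's minimum Fisher p together with the selection size and the
#' association-p threshold attaining it.  Genes tied at a p boundary enter
#' together (`k` jumps across tie blocks).  Significance is declared at
#' Benjamini-Hochberg FDR < `fdrAlpha` with at least 2 annotated selected
#' genes.
#'
#' The scan minimum is anti-conservative by construction (it is an optimum
#' over nested tests); the FDR adjustment is over ontologies, not over the
#' scan, so treat the reported q-values as a ranking device.
#'
#' @param ranked Ranked gene list from [rankGenes].
#' @param ann An [OntologyAnnotation-class].
#' @param pCut Association p cut-off defining the deepest selection
#'   (default 0.05, strict `<`).
#' @param topN If non-`NULL`, scan the top `topN` genes regardless of
#'   `pCut` (ties at the boundary included).
#' @param fdrAlpha FDR significance level (default 0.05).
#' @return `data.frame` with one row per ontology term: `ontology_id`,
#'   `term_name`, `p_threshold`, `k_selected`, `a_annotated`,
#'   `total_annotated`, `fisher_p`, `fdr_q`, `significant`, `genes`.
#' @export
sequentialScan <- function(ranked, ann, pCut = 0.05, topN = NULL,
                           fdrAlpha = 0.05) {
  stopIfNot(is.data.frame(ranked) && nrow(ranked) > 0L, "empty ranked list")
  stopIfNot(is(ann, "OntologyAnnotation"), "ann must be an OntologyAnnotation")
  genes <- ranked$gene
  N <- length(genes)
  sets <- geneSets(ann)
  memberTerms <- lapply(genes, function(g) sets[[g]] %||% character())
  terms <- sort(unique(unlist(memberTerms, use.names = FALSE)))
  m <- length(terms)
  if (m == 0L) {
    message("no ontology terms annotate the ranked genes; nothing to scan")
    return(emptyEnrichment())
  }
  kMax <- if (is.null(topN)) {
    sum(ranked$p < pCut)
  } else {
    kk <- min(as.integer(topN), N)
    # include genes tied with the boundary p
    if (kk > 0L && kk < N) kk <- max(which(ranked$p <= ranked$p[kk]))
    kk
  }
  if (kMax == 0L) {
    message(sprintf("no genes below the association cut-off %g; enrichment skipped", pCut))
    return(emptyEnrichment())
  }
  # tie blocks: candidate k values are the ends of runs of equal p
  pSel <- ranked$p[seq_len(kMax)]
  blockEnds <- which(!duplicated(pSel, fromLast = TRUE))
  ann01 <- matrix(0L, N, m, dimnames = list(genes, terms))
  for (i in seq_len(N)) {
    t <- memberTerms[[i]]
    if (length(t)) ann01[i, t] <- 1L
  }
  Ktot <- colSums(ann01)
  cum <- apply(ann01[seq_len(kMax), , drop = FALSE], 2L, cumsum)
  if (kMax == 1L) cum <- matrix(cum, nrow = 1L, dimnames = list(NULL, terms))
  rows <- lapply(seq_len(m), function(j) {
    aVec <- cum[blockEnds, j]
    pVec <- phyper(aVec - 1, Ktot[j], N - Ktot[j], blockEnds, lower.tail = FALSE)
    pVec[aVec == 0] <- 1
    best <- which.min(pVec)
    kBest <- blockEnds[best]
    aBest <- aVec[best]
    selGenes <- genes[seq_len(kBest)]
    annGenes <- selGenes[ann01[seq_len(kBest), j] == 1L]
    data.frame(ontology_id = terms[j],
               term_name = unname(termNames(ann)[terms[j]]) %||% NA_character_,
               p_threshold = pSel[kBest],
               k_selected = kBest,
               a_annotated = as.integer(aBest),
               total_annotated = as.integer(Ktot[j]),
               fisher_p = pVec[best],
               genes = paste(annGenes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bhAdjust(out$fisher_p, m = m)
  out$significant <- out$fdr_q < fdrAlpha & out$a_annotated >= 2L
  out <- out[order(out$fdr_q, out$fisher_p, out$ontology_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("ontology_id", "term_name", "p_threshold", "k_selected", "a_annotated",
          "total_annotated", "fisher_p", "fdr_q", "significant", "genes")]
}

emptyEnrichment <- function() {
  data.frame(ontology_id = character(), term_name = character(),
             p_threshold = numeric(), k_selected = integer(),
             a_annotated = integer(), total_annotated = integer(),
             fisher_p = numeric(), fdr_q = numeric(),
             significant = logical(), genes = character(),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment over an ontology universe
#'
#' Step-up adjusted values `q_(i) = min_(j >= i) p_(j) * m / j`, capped at
#' 1, where `m` is the number of ontologies in the universe.  Terms absent
#' from the p-value list are implicitly at p = 1, so `m` may exceed the
#' list length.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Universe size, `m >= length(p)`.
#' @return Adjusted q-values, same order as `p`.
#' @examples
#' round(bhAdjust(c(2e-5, 3e-5, 3e-5), m = 2623), 2)
#' @export
bhAdjust <- function(p, m = length(p)) {
  stopIfNot(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  stopIfNot(m >= length(p), "universe size m smaller than the p-value list")
  if (length(p) == 0L) return(numeric())
  p.adjust(p, method = "BH", n = m)
}
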