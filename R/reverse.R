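# Reverse-genetics models: homozygote tallies with a stratified
# genotype-permutation null.

#' Split subjects by homozygote class
#'
#' The reverse-genetics statistics analyze only homozygotes: minor-allele
#' homozygotes (HZMA, dosage 2) versus common-allele homozygotes (HZCA,
#' dosage 0).  Heterozygotes and missing calls are excluded, since an
#' additive variant would show affected heterozygotes that attenuate the
#' homozygote contrast.
#'
#' @param dosages Named integer dosage vector (names = subject ids).
#' @return List with character vectors `hzma`, `hzca`, `excluded` and the
#'   counts `nHzma`, `nHzca`.
#' @export
splitHomozygotes <- function(dosages) {
  stopIfNot(!is.null(names(dosages)), "dosage vector must be named by subject id")
  hzma <- names(dosages)[!is.na(dosages) & dosages == 2L]
  hzca <- names(dosages)[!is.na(dosages) & dosages == 0L]
  excluded <- setdiff(names(dosages), c(hzma, hzca))
  list(hzma = hzma, hzca = hzca, excluded = excluded,
       nHzma = length(hzma), nHzca = length(hzca))
}

#' Constituent diagnoses occurring in multiple minor-allele homozygotes
#'
#' Returns the constituent groups of the phenotype carried by at least
#' `minCount` distinct HZMA subjects; only these "multiply-occurring"
#' diagnoses enter the tally (a diagnosis seen once among the homozygotes
#' carries no evidence of a shared mechanism).
#'
#' @param dx A [DiagnosisTable-class].
#' @param hzma Character vector of HZMA subject ids.
#' @param def A [PhenotypeDefinition-class].
#' @param minCount Minimum number of distinct HZMA carriers (default 2).
#' @return Character vector of qualifying group ids (possibly empty).
#' @export
multiplyOccurring <- function(dx, hzma, def, minCount = 2L) {
  stopIfNot(minCount >= 2L, "minCount must be >= 2")
  p <- diagnosisPairs(dx)
  p <- p[p$subject_id %in% hzma & p$group_id %in% constituentGroups(def), , drop = FALSE]
  if (nrow(p) == 0L) return(character())
  tab <- table(p$group_id)
  sort(names(tab)[tab >= minCount])
}

#' One-sided Fisher test of diagnosis excess among minor homozygotes
#'
#' Tests whether a constituent diagnosis is over-represented among HZMA
#' relative to HZCA subjects (2x2 carrier table, one-sided by default
#' because the filter's purpose is detecting HZMA excess).
#'
#' @param group Constituent group id.
#' @param dx A [DiagnosisTable-class].
#' @param split Homozygote split from [splitHomozygotes].
#' @param alternative `"greater"` (HZMA excess, default) or `"two.sided"`.
#' @return Fisher exact p-value.
#' @export
diagnosisFisher <- function(group, dx, split,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  p <- diagnosisPairs(dx)
  carriers <- unique(p$subject_id[p$group_id == group])
  a <- sum(split$hzma %in% carriers)
  b <- sum(split$hzca %in% carriers)
  tab <- matrix(c(a, length(split$hzma) - a,
                  b, length(split$hzca) - b), 2L, 2L, byrow = TRUE)
  fisher.test(tab, alternative = alternative)$p.value
}

#' Reverse-genetics tally statistic
#'
#' Model `rg1` tallies HZMA subjects carrying any multiply-occurring
#' constituent diagnosis; model `rg2` restricts the qualifying diagnoses to
#' those with a one-sided Fisher p below `fisherThreshold` against the
#' common homozygotes.  `rec` tallies every HZMA subject with any
#' constituent diagnosis (the recessive-permutation reference model).
#'
#' @param model `"rg1"`, `"rg2"` or `"rec"`.
#' @param dx A [DiagnosisTable-class].
#' @param split Homozygote split from [splitHomozygotes].
#' @param def A [PhenotypeDefinition-class].
#' @param fisherThreshold Fisher filter level for `rg2` (default 0.1).
#' @param minCount Minimum HZMA carrier count for a qualifying diagnosis.
#' @return List with `tally`, `qualifying` (group ids) and `model`.
#' @export
rgTally <- function(model = c("rg1", "rg2", "rec"), dx, split, def,
                    fisherThreshold = 0.1, minCount = 2L) {
  model <- match.arg(model)
  p <- diagnosisPairs(dx)
  if (model == "rec") {
    qual <- intersect(constituentGroups(def), unique(p$group_id))
  } else {
    qual <- multiplyOccurring(dx, split$hzma, def, minCount = minCount)
    if (model == "rg2" && length(qual)) {
      fp <- vapply(qual, diagnosisFisher, numeric(1), dx = dx, split = split)
      qual <- qual[fp < fisherThreshold]
    }
  }
  if (length(qual) == 0L) {
    return(list(tally = 0L, qualifying = character(), model = model))
  }
  carriers <- unique(p$subject_id[p$group_id %in% qual])
  list(tally = sum(split$hzma %in% carriers), qualifying = qual, model = model)
}

#' Permutation configuration for the reverse-genetics null
#'
#' @param B Number of permutations (default 10,000).
#' @param strata Covariate columns defining permutation strata (default
#'   study/dataset, age and gender; the empty vector collapses to a single
#'   stratum).
#' @param ageBinWidth Width in years of the age strata (default decades).
#' @param seed RNG seed (per-SNP streams are derived from it, so results
#'   are reproducible and independent of SNP order).
#' @param estimator `"plain"` (`count/B`, can return 0) or `"anchored"`
#'   (`(count+1)/(B+1)`, never 0; preferable for downstream ranking).
#' @param fisherThreshold Model-2 diagnosis filter level.
#' @param minCount Minimum HZMA carrier count for a qualifying diagnosis.
#' @return Validated configuration list.
#' @export
permutationConfig <- function(B = 10000L, strata = c("dataset", "age", "gender"),
                              ageBinWidth = 10, seed = 1L,
                              estimator = c("plain", "anchored"),
                              fisherThreshold = 0.1, minCount = 2L) {
  stopIfNot(B >= 1L, "B must be >= 1")
  list(B = as.integer(B), strata = strata, ageBinWidth = ageBinWidth,
       seed = as.integer(seed), estimator = match.arg(estimator),
       fisherThreshold = fisherThreshold, minCount = as.integer(minCount))
}

# Subjects x groups 0/1 membership matrix restricted to a phenotype's
# constituent groups (column order = sorted group ids).
buildGroupMatrix <- function(dx, def, subjects) {
  groups <- sort(constituentGroups(def))
  m <- matrix(0L, length(subjects), length(groups),
              dimnames = list(subjects, groups))
  p <- diagnosisPairs(dx)
  p <- p[p$subject_id %in% subjects & p$group_id %in% groups, , drop = FALSE]
  if (nrow(p)) m[cbind(match(p$subject_id, subjects), match(p$group_id, groups))] <- 1L
  m
}

# Stratum labels (1-based integers) from covariates; empty strata spec
# collapses to one stratum.
strataFactor <- function(covars, strataCols, ageBinWidth = 10) {
  if (length(strataCols) == 0L) return(rep(1L, nrow(covars)))
  parts <- lapply(strataCols, function(nm) {
    stopIfNot(nm %in% colnames(covars), sprintf("stratum covariate '%s' missing", nm))
    v <- covars[[nm]]
    if (nm == "age" || is.numeric(v)) floor(as.numeric(v) / ageBinWidth) else as.character(v)
  })
  f <- interaction(as.data.frame(parts), drop = TRUE, lex.order = TRUE)
  as.integer(f)
}

# Largest HZCA carrier count b at which the one-sided Fisher p for an HZMA
# carrier count a (sample sizes h vs n0) stays below `alpha`.  Entry -1:
# no b qualifies (includes a < minCount).  Memoized on (h, n0, alpha,
# minCount).
fisherBmaxCache <- new.env(parent = emptyenv())

fisherBmax <- function(h, n0, alpha = 0.1, minCount = 2L) {
  key <- paste(h, n0, alpha, minCount, sep = "_")
  hit <- fisherBmaxCache[[key]]
  if (!is.null(hit)) return(hit)
  pOne <- function(a, b) {
    # P(X >= a), X ~ Hypergeom(drawn h from a+b carriers among h+n0)
    phyper(a - 1, a + b, h + n0 - a - b, h, lower.tail = FALSE)
  }
  res <- vapply(0:h, function(a) {
    if (a < minCount) return(-1L)
    if (pOne(a, 0) >= alpha) return(-1L)
    lo <- 0L; hi <- as.integer(n0)
    if (pOne(a, hi) < alpha) return(hi)
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (pOne(a, mid) < alpha) lo <- mid else hi <- mid
    }
    lo
  }, integer(1))
  fisherBmaxCache[[key]] <- res
  res
}

#' Stratified permutation p-value for the reverse-genetics tallies
#'
#' Genotype labels are randomly reassigned among subjects within each
#' stratum `B` times, preserving per-stratum genotype counts (hence MAF);
#' for every permutation the qualifying-diagnosis set is re-derived from
#' the newly assigned homozygotes before the tally is recomputed.  The
#' p-value is the proportion of permutations whose tally equals or exceeds
#' the observed tally.
#'
#' @param dosage Named integer dosage vector for one SNP.
#' @param dx A [DiagnosisTable-class].
#' @param def A [PhenotypeDefinition-class].
#' @param covars Covariate `data.frame` with rownames = subject ids
#'   (required when `cfg$strata` is non-empty).
#' @param cfg Configuration from [permutationConfig].
#' @param stream Integer stream index (e.g. the SNP's position) mixed into
#'   the seed so per-SNP results are order-independent.
#' @return List: `tally` and `p` (named by model `rg1`, `rg2`, `rec`),
#'   `qualifying` (observed qualifying groups per model), `nHzma`, `B`.
#' @export
stratifiedPermutationP <- function(dosage, dx, def, covars = NULL,
                                   cfg = permutationConfig(), stream = 0L) {
  subjects <- names(dosage)
  stopIfNot(!is.null(subjects), "dosage vector must be named by subject id")
  split <- splitHomozygotes(dosage)
  if (split$nHzma == 0L) {
    return(list(tally = c(rg1 = NA_integer_, rg2 = NA_integer_, rec = NA_integer_),
                p = c(rg1 = NA_real_, rg2 = NA_real_, rec = NA_real_),
                qualifying = list(), nHzma = 0L, B = cfg$B,
                skipped = "no_minor_homozygotes"))
  }
  if (length(cfg$strata)) {
    stopIfNot(!is.null(covars), "covariates required for stratified permutation")
    covars <- covars[subjects, , drop = FALSE]
    strata <- strataFactor(covars, cfg$strata, cfg$ageBinWidth)
  } else {
    strata <- rep(1L, length(subjects))
  }
  gmx <- buildGroupMatrix(dx, def, subjects)
  geno <- as.integer(dosage)
  bmax <- fisherBmax(split$nHzma, split$nHzca, cfg$fisherThreshold, cfg$minCount)
  res <- cpp_strat_perm(gmx, geno, strata, cfg$B, cfg$minCount, bmax,
                        as.double(cfg$seed), as.double(stream))
  est <- if (cfg$estimator == "anchored") {
    (res$count_ge + 1) / (cfg$B + 1)
  } else {
    res$count_ge / cfg$B
  }
  qual1 <- multiplyOccurring(dx, split$hzma, def, cfg$minCount)
  qual2 <- if (length(qual1)) {
    fp <- vapply(qual1, diagnosisFisher, numeric(1), dx = dx, split = split)
    qual1[fp < cfg$fisherThreshold]
  } else character()
  list(tally = res$t_obs, p = setNames(as.numeric(est), names(res$count_ge)),
       qualifying = list(rg1 = qual1, rg2 = qual2),
       nHzma = res$n_hzma, B = cfg$B)
}

#' Run a reverse-genetics model over all SNPs
#'
#' @param gm A [GenotypeMatrix-class].
#' @param dx A [DiagnosisTable-class].
#' @param def A [PhenotypeDefinition-class].
#' @param model `"rg1"`, `"rg2"` or `"rec"` (recessive-permutation
#'   reference).
#' @param covars Covariate `data.frame` (defaults to `covariates(gm)`).
#' @param cfg Configuration from [permutationConfig].
#' @return `data.frame` with one row per SNP: `snp_id`, `gene`,
#'   `phenotype_id`, `model`, `n_hzma`, `tally`, `qualifying_groups`
#'   (comma-separated), `p`, `flag` (skip reason for SNPs without minor
#'   homozygotes).
#' @export
runReverseAssociation <- function(gm, dx, def, model = c("rg1", "rg2", "rec"),
                                  covars = NULL, cfg = permutationConfig()) {
  model <- match.arg(model)
  if (is.null(covars)) covars <- covariates(gm)
  d <- dosages(gm)
  genes <- geneIds(gm)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    r <- stratifiedPermutationP(d[i, ], dx, def, covars, cfg, stream = i)
    data.frame(snp_id = rownames(d)[i], gene = unname(genes[i]),
               phenotype_id = phenotypeId(def), model = model,
               n_hzma = r$nHzma,
               tally = as.integer(r$tally[[model]]),
               qualifying_groups = if (r$nHzma > 0L && model != "rec") {
                 paste(r$qualifying[[model]], collapse = ",")
               } else "",
               p = as.numeric(r$p[[model]]),
               flag = r$skipped %||% "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
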