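# Synthetic cohort generation.
#
# Diagnoses are drawn from a shared-frailty logistic model: subject i
# carries constituent group g with probability
#   plogis(alpha_g + betaAge * (age_i - ageRef)/10 + betaMale * male_i + u_i),
# u_i ~ N(0, sigma^2) shared across groups.  The frailty (plus the common
# covariate effects) induces within-subject diagnosis co-occurrence, so the
# "any constituent diagnosis" prevalence is below the independence value.
# Group intercepts alpha_g are calibrated so the marginal prevalences match
# the requested profile, and sigma is calibrated so the induced
# any-diagnosis prevalence matches its target.  Genotypes are drawn
# independently of diagnoses (null by construction); effects are planted
# explicitly with plantEffect().

#' Thrombosis-study cohort profile
#'
#' Default generation profile emulating the published population
#' characteristics of an African-American thrombosis cohort: n = 1,655,
#' 36.0% male, age 52.3 (SD 17.7), eight constituent diagnosis groups with
#' marginal prevalences 10.8% (long-term anticoagulation), 10.0% (stroke),
#' 9.0% (acute MI), 7.0% (venous thrombosis), 2.8% (thrombotic pulmonary
#' disease), 2.7% (other), 2.2% (arterial thrombosis), 1.9% (spontaneous
#' abortion), and 27.4% prevalence of any thrombosis diagnosis.
#'
#' @return Profile list for [cohortSpec].
#' @export
thrombosisProfile <- function() {
  list(
    name = "thrombosis",
    n = 1655L,
    groups = c(ANTICOAG = 0.108, STROKE = 0.100, AMI = 0.090, VENOUS = 0.070,
               PULMONARY = 0.028, OTHER_THROMB = 0.027, ARTERIAL = 0.022,
               SPONT_AB = 0.019),
    anyPrevalence = 0.274,
    phenotypes = list(THROMBOSIS = c("ANTICOAG", "STROKE", "AMI", "VENOUS",
                                     "PULMONARY", "OTHER_THROMB", "ARTERIAL",
                                     "SPONT_AB")),
    maleFraction = 0.360, ageMean = 52.3, ageSD = 17.7
  )
}

#' Cancer-study cohort profile
#'
#' Emulates a white European-American cancer cohort: n = 3,009, 56.5% male,
#' age 51.4 (SD 18.7); constituent groups CA (non-hematological primary,
#' 35.8%), HEM (hematological, 12.3%), MET (metastatic/secondary, 12.0%),
#' SKN (skin, 3.6%), with 42.4% any-cancer prevalence.  The mechanistic
#' phenotypes are the four groupings plus their union `ALL`.
#'
#' @return Profile list for [cohortSpec].
#' @export
cancerProfile <- function() {
  list(
    name = "cancer",
    n = 3009L,
    groups = c(CA = 0.358, HEM = 0.123, MET = 0.120, SKN = 0.036),
    anyPrevalence = 0.424,
    phenotypes = list(ALL = c("CA", "HEM", "MET", "SKN"),
                      CA = "CA", HEM = "HEM", MET = "MET", SKN = "SKN"),
    maleFraction = 0.565, ageMean = 51.4, ageSD = 18.7
  )
}

#' Build a cohort generation spec
#'
#' @param profile Profile list ([thrombosisProfile], [cancerProfile], or a
#'   custom list with the same fields).
#' @param n Cohort size override.
#' @param nSnps Number of SNPs (default 433, one per gene).
#' @param mafRange Minor allele frequency window (default 0.05-0.10).
#' @param betaAge Log-odds of each diagnosis per decade of age (default
#'   0.35: thrombotic and neoplastic disease risk rises with age).
#' @param betaMale Log-odds shift for male subjects (default 0.3).
#' @param frailtySD Shared-frailty SD; `NULL` (default) calibrates it to
#'   the profile's any-diagnosis prevalence.
#' @param datasets Named fractions of source-study membership (permutation
#'   stratum / covariate).
#' @param seed RNG seed (the generator is byte-deterministic given the
#'   spec).
#' @return Spec list for [generateCohort].
#' @export
cohortSpec <- function(profile = thrombosisProfile(), n = NULL,
                       nSnps = 433L, mafRange = c(0.05, 0.10),
                       betaAge = 0.35, betaMale = 0.3, frailtySD = NULL,
                       datasets = c(VGER = 0.26, VESPA = 0.74), seed = 1L) {
  stopIfNot(all(profile$groups >= 0 & profile$groups <= 1),
            "prevalences must lie in [0, 1]")
  if (!is.null(profile$anyPrevalence)) {
    stopIfNot(profile$anyPrevalence >= max(profile$groups),
              "any-diagnosis prevalence below its largest constituent")
  }
  spec <- profile
  if (!is.null(n)) spec$n <- as.integer(n)
  spec$nSnps <- as.integer(nSnps)
  spec$mafRange <- mafRange
  spec$betaAge <- betaAge
  spec$betaMale <- betaMale
  spec$frailtySD <- frailtySD
  spec$datasets <- datasets
  spec$seed <- as.integer(seed)
  spec
}

# --- frailty calibration ------------------------------------------------
# Expectation over covariates uses deterministic quantile grids (age) and
# the gender mix rather than the drawn subjects, so the calibration is a
# pure function of the spec and can be memoized.

calibCache <- new.env(parent = emptyenv())

# equal-probability quantile grid of N(0,1)
zGrid <- function(K = 64L) qnorm((seq_len(K) - 0.5) / K)

# baseline covariate linear predictors on a deterministic grid with weights
calibEtaGrid <- function(spec, K = 32L) {
  za <- zGrid(K)
  age <- truncAge(spec$ageMean + spec$ageSD * za)
  eta <- spec$betaAge * (age - spec$ageMean) / 10
  list(eta = c(eta + spec$betaMale, eta),
       w = c(rep(spec$maleFraction / K, K), rep((1 - spec$maleFraction) / K, K)))
}

truncAge <- function(age) pmin(pmax(round(age), 18), 95)

# mean over covariate grid x frailty grid of plogis(alpha + eta + u)
meanPrev <- function(alpha, etaGrid, u, wu) {
  # outer over (covariate cell, frailty node)
  pm <- plogis(outer(etaGrid$eta, u, "+") + alpha)
  sum((pm %*% wu) * etaGrid$w)
}

calibrateFrailty <- function(spec, K = 32L, Ku = 64L) {
  key <- paste(c(spec$groups, spec$anyPrevalence, spec$betaAge, spec$betaMale,
                 spec$maleFraction, spec$ageMean, spec$ageSD, spec$frailtySD),
               collapse = "_")
  hit <- calibCache[[key]]
  if (!is.null(hit)) return(hit)
  etaGrid <- calibEtaGrid(spec, K)
  zu <- zGrid(Ku)
  wu <- rep(1 / Ku, Ku)
  alphaFor <- function(sigma) {
    u <- sigma * zu
    vapply(spec$groups, function(pg) {
      if (pg <= 0) return(-Inf)
      uniroot(function(a) meanPrev(a, etaGrid, u, wu) - pg,
              lower = -25, upper = 10, tol = 1e-9)$root
    }, numeric(1))
  }
  anyFor <- function(sigma, alpha) {
    u <- sigma * zu
    keep <- is.finite(alpha)
    if (!any(keep)) return(0)
    noneP <- matrix(1, length(etaGrid$eta), length(u))
    for (a in alpha[keep]) {
      noneP <- noneP * (1 - plogis(outer(etaGrid$eta, u, "+") + a))
    }
    1 - sum((noneP %*% wu) * etaGrid$w)
  }
  if (!is.null(spec$frailtySD)) {
    sigma <- spec$frailtySD
  } else if (is.null(spec$anyPrevalence) || all(spec$groups <= 0)) {
    sigma <- 0
  } else {
    f <- function(s) anyFor(s, alphaFor(s)) - spec$anyPrevalence
    f0 <- f(0)
    if (f0 < 0) {
      stop(sprintf(
        "infeasible prevalence combination: independent draws give any-prevalence %.3f < target %.3f",
        f0 + spec$anyPrevalence, spec$anyPrevalence), call. = FALSE)
    }
    sigma <- if (abs(f0) < 1e-6) 0 else uniroot(f, lower = 0, upper = 6, tol = 1e-5)$root
  }
  res <- list(sigma = sigma, alpha = alphaFor(sigma))
  calibCache[[key]] <- res
  res
}

# --- generation ---------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws covariates, frailty-correlated constituent diagnoses calibrated to
#' the profile's marginal and any-diagnosis prevalences, and genotypes
#' independent of the diagnoses (a null cohort by construction).  A trivial
#' one-ICD-9-code-per-group map is attached so the full file pipeline can
#' run.
#'
#' @param spec Spec from [cohortSpec].
#' @return A [Cohort-class]; `spec(cohort)` additionally records the
#'   calibrated frailty SD and group intercepts.
#' @export
generateCohort <- function(spec = cohortSpec()) {
  cal <- calibrateFrailty(spec)
  withSeed(spec$seed, {
    n <- spec$n
    subj <- sprintf("S%05d", seq_len(n))
    age <- truncAge(rnorm(n, spec$ageMean, spec$ageSD))
    gender <- ifelse(runif(n) < spec$maleFraction, "M", "F")
    dataset <- names(spec$datasets)[
      1L + findInterval(runif(n), cumsum(spec$datasets) / sum(spec$datasets),
                        left.open = TRUE)]
    eta0 <- spec$betaAge * (age - spec$ageMean) / 10 +
      spec$betaMale * (gender == "M") + rnorm(n, 0, cal$sigma)
    G <- length(spec$groups)
    pairs <- vector("list", G)
    for (g in seq_len(G)) {
      a <- cal$alpha[g]
      carrier <- if (is.finite(a)) runif(n) < plogis(a + eta0) else rep(FALSE, n)
      pairs[[g]] <- data.frame(subject_id = subj[carrier],
                               group_id = rep(names(spec$groups)[g], sum(carrier)),
                               stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, pairs)
    dx <- DiagnosisTable(pairs$subject_id, pairs$group_id)

    maf <- runif(spec$nSnps, spec$mafRange[1], spec$mafRange[2])
    dosage <- matrix(rbinom(spec$nSnps * n, 2L, rep(maf, n)), spec$nSnps, n)
    snpIds <- sprintf("rs%06d", seq_len(spec$nSnps))
    dimnames(dosage) <- list(snpIds, subj)
    gm <- GenotypeMatrix(dosage,
                         snpInfo = data.frame(
                           gene = sprintf("G%04d", seq_len(spec$nSnps)),
                           allele_major = "A", allele_minor = "G",
                           row.names = snpIds, stringsAsFactors = FALSE),
                         subjectInfo = data.frame(age = age, gender = gender,
                                                  dataset = dataset,
                                                  row.names = subj,
                                                  stringsAsFactors = FALSE))
    map <- trivialGroupMap(spec)
    cohort <- new("Cohort", genotypes = gm, diagnoses = dx, map = map,
                  phenotypes = phenotypesFromMap(map),
                  spec = c(spec, list(calibratedSigma = cal$sigma,
                                      calibratedAlpha = cal$alpha)))
    validObject(cohort)
    cohort
  })
}

# one synthetic ICD-9 code per constituent group
trivialGroupMap <- function(spec) {
  groups <- names(spec$groups)
  codes <- sprintf("%03d0", 800 + seq_along(groups))
  g2p <- do.call(rbind, lapply(names(spec$phenotypes), function(ph) {
    data.frame(group_id = spec$phenotypes[[ph]], phenotype_id = ph,
               stringsAsFactors = FALSE)
  }))
  GroupMap(setNames(groups, codes), g2p)
}

#' Plant a genotype-diagnosis effect in a cohort
#'
#' Among the minor-allele homozygotes of one SNP, each subject
#' independently gains a target-group diagnosis with probability
#' `penetrance`; all other subjects are untouched.  Modes: `single_diagnosis`
#' gives every affected homozygote the same (first) target group;
#' `multi_diagnosis` draws one of the target groups per affected subject;
#' `random_diagnosis` draws from all groups in the cohort map.
#'
#' @param cohort A [Cohort-class].
#' @param snpId SNP whose homozygotes carry the effect.
#' @param mode Effect mode.
#' @param penetrance Probability in `[0, 1]`.
#' @param targetGroups Target group ids (required for single/multi modes).
#' @param seed RNG seed.
#' @return The modified [Cohort-class].
#' @export
plantEffect <- function(cohort, snpId,
                        mode = c("single_diagnosis", "multi_diagnosis",
                                 "random_diagnosis"),
                        penetrance = 0.5, targetGroups = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopIfNot(penetrance >= 0 && penetrance <= 1, "penetrance must be in [0, 1]")
  gm <- genotypes(cohort)
  stopIfNot(snpId %in% snpIds(gm), sprintf("unknown SNP '%s'", snpId))
  if (mode == "random_diagnosis") {
    targetGroups <- groupIds(groupMap(cohort))
  }
  stopIfNot(length(targetGroups) > 0L, "empty target group set")
  d <- dosages(gm)[snpId, ]
  hzma <- names(d)[!is.na(d) & d == 2L]
  stopIfNot(length(hzma) >= 1L, "SNP has no minor-allele homozygotes")
  withSeed(seed, {
    affected <- hzma[runif(length(hzma)) < penetrance]
    if (length(affected) == 0L) {
      cohort
    } else {
    gain <- switch(mode,
                   single_diagnosis = rep(targetGroups[1], length(affected)),
                   multi_diagnosis = targetGroups[sample.int(length(targetGroups),
                                                             length(affected),
                                                             replace = TRUE)],
                   random_diagnosis = targetGroups[sample.int(length(targetGroups),
                                                              length(affected),
                                                              replace = TRUE)])
    p <- diagnosisPairs(diagnoses(cohort))
    aug <- rbind(p, data.frame(subject_id = affected, group_id = gain,
                               stringsAsFactors = FALSE))
    cohort@diagnoses <- DiagnosisTable(aug$subject_id, aug$group_id,
                                       nUnmapped = unmappedCount(diagnoses(cohort)))
    validObject(cohort)
    cohort
    }
  })
}

#' Write a cohort to a directory of pipeline input files
#'
#' Emits `genotypes.ped`/`.map`, `genotypes_dosage.tsv`, `diagnoses.tsv`
#' (subject, ICD-9 code via the trivial map), `covariates.tsv`,
#' `icd9_groups.tsv` and `group_phenotypes.tsv`.
#'
#' @param cohort A [Cohort-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- genotypes(cohort)
  writePedMap(gm, file.path(dir, "genotypes"))
  writeDosageTsv(gm, file.path(dir, "genotypes_dosage.tsv"))
  cv <- covariates(gm)
  write.table(data.frame(subject_id = rownames(cv), cv, check.names = FALSE),
              file.path(dir, "covariates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  c2g <- codeToGroup(groupMap(cohort))
  g2c <- setNames(names(c2g), c2g)   # invert: one code per group
  p <- diagnosisPairs(diagnoses(cohort))
  write.table(data.frame(subject_id = p$subject_id, icd9 = unname(g2c[p$group_id])),
              file.path(dir, "diagnoses.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(icd9 = names(c2g), group_id = unname(c2g)),
              file.path(dir, "icd9_groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g2p <- groupToPhenotype(groupMap(cohort))
  write.table(g2p, file.path(dir, "group_phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(snp_id = snpIds(gm), gene = unname(geneIds(gm))),
              file.path(dir, "snp_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
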