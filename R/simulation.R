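# Operating characteristics: type-I error of the permutation tallies and
# ROC discrimination under spiked case-assignment scenarios.

#' Empirical type-I error of the reverse-genetics models
#'
#' Generates genotype-randomized null SNPs (labels shuffled, MAF spectrum
#' preserved: per-SNP MAF is drawn from `mafRange` and genotype counts from
#' Hardy-Weinberg proportions, conditioned on at least `minHzma` minor
#' homozygotes), scores each with the model-1 and model-2 permutation
#' p-values (`B` permutations, single stratum, plain `count/B` estimator)
#' against a fixed diagnosis table, and reports the fraction of SNPs with
#' `p <` each nominal level.
#'
#' @param dx A [DiagnosisTable-class] (genotypes are simulated, so any
#'   cohort diagnosis table defines the null).
#' @param def A [PhenotypeDefinition-class].
#' @param subjects Character vector of cohort subject ids.
#' @param nSnps Number of randomized SNPs.
#' @param B Permutations per SNP.
#' @param mafRange MAF window for the randomized SNPs (default 0.05-0.10).
#' @param minHzma Minimum minor-homozygote count (default 10).
#' @param levels Nominal levels at which rates are reported.
#' @param minCount,fisherThreshold Tally parameters (see [rgTally]).
#' @param seed RNG seed.
#' @return List: `rates` (`data.frame` level x model with binomial SEs),
#'   `pvalues` (`nSnps` x 2 matrix), `nHzma` (per-SNP homozygote counts).
#' @export
empiricalType1 <- function(dx, def, subjects, nSnps = 1000L, B = 1000L,
                           mafRange = c(0.05, 0.10), minHzma = 10L,
                           levels = c(0.1, 0.05, 0.01, 0.001),
                           minCount = 2L, fisherThreshold = 0.1, seed = 1L) {
  stopIfNot(length(subjects) >= 2L, "cohort too small")
  n <- length(subjects)
  gmx <- buildGroupMatrix(dx, def, subjects)
  counts <- withSeed(mixSeed(seed, 101L), {
    drawGenotypeCounts(nSnps, n, mafRange, minHzma)
  })
  hMax <- max(counts$n2)
  bmaxMat <- matrix(-1L, nSnps, hMax + 1L)
  combos <- unique(data.frame(h = counts$n2, n0 = n - counts$n2 - counts$n1))
  for (r in seq_len(nrow(combos))) {
    bm <- fisherBmax(combos$h[r], combos$n0[r], fisherThreshold, minCount)
    rows <- which(counts$n2 == combos$h[r] & (n - counts$n2 - counts$n1) == combos$n0[r])
    bmaxMat[rows, seq_len(combos$h[r] + 1L)] <-
      matrix(bm, length(rows), combos$h[r] + 1L, byrow = TRUE)
  }
  sim <- cpp_type1_sim(gmx, counts$n2, counts$n1, bmaxMat, as.integer(B),
                       as.integer(minCount), as.double(seed))
  pv <- sim[, c("p_rg1", "p_rg2"), drop = FALSE]
  colnames(pv) <- c("rg1", "rg2")
  rates <- do.call(rbind, lapply(levels, function(a) {
    # a cut-off of 1 admits every p-value (p <= 1 by construction)
    r1 <- if (a >= 1) 1 else mean(pv[, "rg1"] < a)
    r2 <- if (a >= 1) 1 else mean(pv[, "rg2"] < a)
    data.frame(level = a, rg1 = r1, rg2 = r2,
               se_rg1 = sqrt(r1 * (1 - r1) / nSnps),
               se_rg2 = sqrt(r2 * (1 - r2) / nSnps))
  }))
  list(rates = rates, pvalues = pv, nHzma = counts$n2)
}

# Per-SNP genotype counts: MAF uniform in mafRange, counts multinomial at
# Hardy-Weinberg proportions, redrawn until the minor-homozygote count
# reaches minHzma (the selection filter the analyzed SNP panels satisfy).
drawGenotypeCounts <- function(nSnps, n, mafRange, minHzma) {
  n2 <- integer(nSnps); n1 <- integer(nSnps)
  for (i in seq_len(nSnps)) {
    repeat {
      f <- runif(1, mafRange[1], mafRange[2])
      cnt <- drop(rmultinom(1, n, c(f^2, 2 * f * (1 - f), (1 - f)^2)))
      if (cnt[1] >= minHzma) break
    }
    n2[i] <- cnt[1]; n1[i] <- cnt[2]
  }
  list(n2 = n2, n1 = n1)
}

#' Spike additional cases into a sampled homozygote set
#'
#' Implements the four case-assignment scenarios used to characterize model
#' sensitivity: `kAdded` distinct subjects of the sample each gain one
#' constituent diagnosis they do not already carry (pre-existing diagnoses
#' are retained).
#'
#' * `random_uniform` - each spiked subject gets a group drawn uniformly
#'   from the constituent list;
#' * `frequency_weighted` - groups drawn with probability proportional to
#'   their carrier frequency in the full cohort;
#' * `already_present` - groups drawn uniformly from those already present
#'   among the sampled subjects (requires at least one such group);
#' * `same_random` - one uniformly drawn group is given to all spiked
#'   subjects.
#'
#' @param sample Character vector of sampled subject ids.
#' @param dx A [DiagnosisTable-class] for the full cohort.
#' @param def A [PhenotypeDefinition-class].
#' @param scenario One of the four scenario names (or `1:4`).
#' @param kAdded Number of subjects to spike (0 returns the input view).
#' @return List: `dx` (augmented [DiagnosisTable-class]), `spiked`
#'   (`data.frame` subject_id/group_id of the additions), `redraws`
#'   (scenario-3 redraw count).
#' @export
assignCases <- function(sample, dx, def,
                        scenario = c("random_uniform", "frequency_weighted",
                                     "already_present", "same_random"),
                        kAdded = 3L) {
  if (is.numeric(scenario)) {
    scenario <- c("random_uniform", "frequency_weighted",
                  "already_present", "same_random")[scenario]
  }
  scenario <- match.arg(scenario)
  groups <- constituentGroups(def)
  stopIfNot(length(groups) > 0L, "empty constituent list")
  stopIfNot(kAdded <= length(sample), "kAdded exceeds sample size")
  if (kAdded == 0L) return(list(dx = dx, spiked = data.frame(), redraws = 0L))
  p <- diagnosisPairs(dx)
  carried <- lapply(setNames(sample, sample), function(s) p$group_id[p$subject_id == s])
  infeasible <- function(msg) {
    stop(structure(class = c("mechphen_infeasible_spike", "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  redraws <- 0L
  if (scenario == "same_random") {
    # the identical (new) diagnosis must fit on kAdded subjects
    feasible <- groups[vapply(groups, function(g) {
      sum(!vapply(carried, function(cg) g %in% cg, logical(1))) >= kAdded
    }, logical(1))]
    if (length(feasible) == 0L) infeasible("no diagnosis can be placed on enough subjects")
    g <- feasible[sample.int(length(feasible), 1L)]
    lacking <- sample[!vapply(carried, function(cg) g %in% cg, logical(1))]
    who <- lacking[sample.int(length(lacking), kAdded)]
    add <- data.frame(subject_id = who, group_id = g, stringsAsFactors = FALSE)
  } else {
    presentPool <- sort(unique(p$group_id[p$subject_id %in% sample & p$group_id %in% groups]))
    if (scenario == "already_present" && length(presentPool) == 0L) {
      infeasible("scenario 'already_present' needs a diagnosis in the sample")
    }
    freq <- if (scenario == "frequency_weighted") {
      tab <- table(factor(p$group_id[p$group_id %in% groups], levels = groups))
      w <- as.numeric(tab)
      stopIfNot(sum(w) > 0, "no constituent carriers in the cohort to weight by")
      setNames(w, groups)
    } else NULL
    poolFor <- function(s) {
      base <- if (scenario == "already_present") presentPool else groups
      setdiff(base, carried[[s]])
    }
    assignable <- sample[vapply(sample, function(s) length(poolFor(s)) > 0L, logical(1))]
    if (length(assignable) < kAdded) {
      infeasible("fewer assignable subjects than kAdded")
    }
    redraws <- length(sample) - length(assignable)
    who <- assignable[sample.int(length(assignable), kAdded)]
    add <- do.call(rbind, lapply(who, function(s) {
      pool <- poolFor(s)
      g <- if (scenario == "frequency_weighted") {
        if (length(pool) == 1L) pool else base::sample(pool, 1L, prob = freq[pool])
      } else {
        pool[sample.int(length(pool), 1L)]
      }
      data.frame(subject_id = s, group_id = g, stringsAsFactors = FALSE)
    }))
  }
  aug <- rbind(p, add)
  list(dx = DiagnosisTable(aug$subject_id, aug$group_id, nUnmapped = unmappedCount(dx)),
       spiked = add, redraws = redraws)
}

#' Paired null/spiked permutation p-values under a case-assignment scenario
#'
#' Draws `nSamples` random samples of `sampleSize` subjects, treats each
#' sample as a SNP's minor-allele homozygote set (the rest of the cohort as
#' common homozygotes), and computes permutation p-values for the
#' recessive-permutation reference and both reverse-genetics models on the
#' unmodified cohort ("null") and on a copy where `kAdded` sampled subjects
#' gained a constituent diagnosis under `scenario` ("spiked").
#'
#' @param dx A [DiagnosisTable-class].
#' @param def A [PhenotypeDefinition-class].
#' @param subjects Cohort subject ids.
#' @param scenario Scenario name or index (see [assignCases]).
#' @param kAdded Spiked subjects per sample.
#' @param nSamples Number of paired draws.
#' @param sampleSize Homozygote sample size (default 13, the median
#'   minor-homozygote count of the low-MAF nsSNP panels this emulates).
#' @param B Permutations per p-value.
#' @param minCount,fisherThreshold Tally parameters.
#' @param seed RNG seed.
#' @return `data.frame` with columns `draw`, `model`, `p_null`, `p_spiked`,
#'   `t_null`, `t_spiked`.
#' @export
scenarioScores <- function(dx, def, subjects, scenario = "random_uniform",
                           kAdded = 3L, nSamples = 1000L, sampleSize = 13L,
                           B = 1000L, minCount = 2L, fisherThreshold = 0.1,
                           seed = 1L) {
  n <- length(subjects)
  stopIfNot(sampleSize >= 1L && sampleSize <= n, "invalid sample size")
  stopIfNot(kAdded <= sampleSize, "kAdded exceeds sample size")
  gmxNull <- buildGroupMatrix(dx, def, subjects)
  bmax <- fisherBmax(sampleSize, n - sampleSize, fisherThreshold, minCount)
  models <- c("rec", "rg1", "rg2")
  out <- vector("list", nSamples)
  for (i in seq_len(nSamples)) {
    res <- withSeed(mixSeed(seed, 2L * i), {
      # redraw samples on which the scenario cannot place its new cases
      # (e.g. no diagnosis present for scenario 3); redraws are rare and
      # counted implicitly by the attempt loop
      for (attempt in 1:100) {
        idx <- sample.int(n, sampleSize)
        sampleIds <- subjects[idx]
        aug <- tryCatch(assignCases(sampleIds, dx, def, scenario, kAdded),
                        mechphen_infeasible_spike = function(e) NULL)
        if (!is.null(aug)) break
      }
      stopIfNot(!is.null(aug), "could not draw a feasible sample for the scenario")
      gmxSpk <- buildGroupMatrix(aug$dx, def, subjects)
      null <- cpp_sample_perm(gmxNull, idx - 1L, as.integer(B),
                              as.integer(minCount), bmax,
                              as.double(seed), as.double(3L * i + 1L))
      spk <- cpp_sample_perm(gmxSpk, idx - 1L, as.integer(B),
                             as.integer(minCount), bmax,
                             as.double(seed), as.double(3L * i + 2L))
      data.frame(draw = i, model = models,
                 p_null = as.numeric(null$count_ge[models] / B),
                 p_spiked = as.numeric(spk$count_ge[models] / B),
                 t_null = as.integer(null$t_obs[models]),
                 t_spiked = as.integer(spk$t_obs[models]),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ROC area under the curve from paired p-value scores
#'
#' Mann-Whitney formulation with midrank ties:
#' `AUC = P(p_spiked < p_null) + 0.5 * P(tie)` - the probability that the
#' model ranks a spiked sample as more case-like (smaller p) than a null
#' sample.
#'
#' @param nullScores Null p-values.
#' @param caseScores Spiked p-values.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAUC(c(0.2, 0.8), c(0.1, 0.8))  # 0.625
#' @export
rocAUC <- function(nullScores, caseScores) {
  stopIfNot(length(nullScores) > 0L && length(caseScores) > 0L,
            "both score sets must be non-empty")
  r <- rank(c(-caseScores, -nullScores))   # higher rank = more case-like
  n1 <- length(caseScores); n0 <- length(nullScores)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC table across models for a scenario run
#'
#' @param scores Output of [scenarioScores].
#' @return `data.frame` with one row per model: `model`, `auc`, `n`.
#' @export
scenarioAUC <- function(scores) {
  models <- unique(scores$model)
  do.call(rbind, lapply(models, function(m) {
    s <- scores[scores$model == m, , drop = FALSE]
    data.frame(model = m, auc = rocAUC(s$p_null, s$p_spiked), n = nrow(s),
               stringsAsFactors = FALSE)
  }))
}
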