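# Synthetic cohort generator: calibration, determinism, planted effects.

test_that("zero-prevalence profiles give an empty diagnosis table", {
  prof <- thrombosisProfile()
  prof$groups[] <- 0
  prof$anyPrevalence <- NULL
  co <- generateCohort(cohortSpec(profile = prof, n = 100, nSnps = 2, seed = 1))
  expect_identical(nrow(diagnosisPairs(diagnoses(co))), 0L)
})

test_that("marginal group prevalences match the profile across seeds", {
  prof <- thrombosisProfile()
  pooled <- matrix(0, 0, length(prof$groups))
  for (s in 1:5) {
    co <- generateCohort(cohortSpec(seed = s, nSnps = 2))
    p <- diagnosisPairs(diagnoses(co))
    cnt <- table(factor(p$group_id, levels = names(prof$groups)))
    pooled <- rbind(pooled, as.numeric(cnt))
  }
  n <- prof$n * 5
  for (j in seq_along(prof$groups)) {
    tot <- sum(pooled[, j])
    pg <- prof$groups[j]
    se <- sqrt(pg * (1 - pg) * n)
    expect_lt(abs(tot - n * pg), 4 * se,
              label = sprintf("group %s count %d vs expected %.0f",
                              names(prof$groups)[j], tot, n * pg))
  }
})

test_that("cancer profile hits its any-cancer prevalence and sub-phenotype margins", {
  co <- generateCohort(cohortSpec(profile = cancerProfile(), seed = 5, nSnps = 2))
  subj <- subjectIds(genotypes(co))
  y <- assignPhenotype(diagnoses(co), phenotypeDefs(co)$ALL, subj)
  target <- 0.424
  expect_lt(abs(mean(y == "case") - target),
            3 * sqrt(target * (1 - target) / length(subj)))
  yCA <- assignPhenotype(diagnoses(co), phenotypeDefs(co)$CA, subj)
  expect_lt(abs(mean(yCA == "case") - 0.358), 3 * sqrt(0.358 * 0.642 / length(subj)))
})

test_that("generation is byte-deterministic under a fixed spec and seed", {
  spec <- cohortSpec(n = 120, nSnps = 10, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(generateCohort(spec), d1)
  writeCohort(generateCohort(spec), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  writeCohort(generateCohort(cohortSpec(n = 120, nSnps = 10, seed = 100)), d3)
  expect_false(identical(readLines(file.path(d1, "genotypes.ped")),
                         readLines(file.path(d3, "genotypes.ped"))))
})

test_that("null cohorts give uniform forward-model p-values", {
  co <- generateCohort(cohortSpec(n = 900, nSnps = 150, seed = 37))
  gm <- genotypes(co)
  y <- assignPhenotype(diagnoses(co), phenotypeDefs(co)$THROMBOSIS, subjectIds(gm))
  res <- runForwardAssociation(gm, y, model = "additive", phenotype = "THROMBOSIS")
  p <- res$p[!is.na(res$p)]
  expect_gt(length(p), 120)
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("infeasible prevalence combinations are rejected", {
  prof <- thrombosisProfile()
  prof$anyPrevalence <- 0.46   # above the independence bound ~0.374
  expect_error(generateCohort(cohortSpec(profile = prof, n = 50, nSnps = 2)),
               "infeasible")
})

test_that("planted effects respect penetrance bounds", {
  co <- smallCohort(seed = 41, n = 300, nSnps = 5)
  d <- dosages(genotypes(co))
  snp <- rownames(d)[which.max(rowSums(d == 2L, na.rm = TRUE))]

  co0 <- plantEffect(co, snp, "single_diagnosis", penetrance = 0,
                     targetGroups = "VENOUS", seed = 2)
  expect_identical(diagnosisPairs(diagnoses(co0)), diagnosisPairs(diagnoses(co)))

  co1 <- plantEffect(co, snp, "single_diagnosis", penetrance = 1,
                     targetGroups = "VENOUS", seed = 2)
  hzma <- colnames(d)[d[snp, ] == 2L]
  p1 <- diagnosisPairs(diagnoses(co1))
  carriers <- unique(p1$subject_id[p1$group_id == "VENOUS"])
  expect_true(all(hzma %in% carriers))

  expect_error(plantEffect(co, snp, "single_diagnosis", penetrance = 0.5,
                           targetGroups = character()), "empty target")
})

test_that("a planted single-diagnosis effect is recovered by the rg1 permutation test", {
  # fixed decision rule: planted SNP p must fall below the 5th percentile
  # of null-SNP p-values in >= 80% of seeds
  co <- generateCohort(cohortSpec(n = 1655, nSnps = 80, seed = 47))
  def <- phenotypeDefs(co)$THROMBOSIS
  subj <- subjectIds(genotypes(co))
  d <- dosages(genotypes(co))
  cfg <- permutationConfig(B = 400, strata = character(), seed = 11,
                           estimator = "anchored")

  nullP <- vapply(seq_len(nrow(d)), function(i) {
    stratifiedPermutationP(d[i, ], diagnoses(co), def, NULL, cfg,
                           stream = i)$p[["rg1"]]
  }, numeric(1))
  cut5 <- quantile(nullP, 0.05, na.rm = TRUE)

  # effect carriers comparable to the panels the tally models target
  # (median around 13 minor-allele homozygotes)
  eligible <- rownames(d)[rowSums(d == 2L, na.rm = TRUE) >= 12]
  hits <- 0L; trials <- 40L
  for (s in seq_len(trials)) {
    snp <- eligible[1 + (s %% length(eligible))]
    spiked <- plantEffect(co, snp, "single_diagnosis", penetrance = 0.4,
                          targetGroups = "STROKE", seed = 500 + s)
    p <- stratifiedPermutationP(dosages(genotypes(spiked))[snp, ],
                                diagnoses(spiked), def, NULL, cfg,
                                stream = 9000 + s)$p[["rg1"]]
    if (p <= cut5) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.8)
})
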