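# Reverse-genetics tallies and their stratified permutation null.

test_that("homozygote split partitions dosage classes", {
  d <- setNames(c(0L, 1L, 2L, 2L, 1L, NA), sprintf("S%d", 1:6))
  sp <- splitHomozygotes(d)
  expect_setequal(sp$hzma, c("S3", "S4"))
  expect_setequal(sp$hzca, "S1")
  expect_setequal(sp$excluded, c("S2", "S5", "S6"))
  expect_identical(sp$nHzma, 2L)

  withr::local_seed(3)
  dd <- setNames(sample(c(0:2, NA), 50, replace = TRUE), sprintf("P%02d", 1:50))
  sp2 <- splitHomozygotes(dd)
  expect_setequal(sp2$hzma, names(dd)[!is.na(dd) & dd == 2])
  expect_setequal(sp2$hzca, names(dd)[!is.na(dd) & dd == 0])
})

test_that("multiply-occurring selection keeps exactly the >=2-carrier diagnoses", {
  # 10 diagnoses among the homozygotes, 5 carried by more than one subject
  hzma <- sprintf("H%d", 1:6)
  multi <- sprintf("M%d", 1:5)
  single <- sprintf("U%d", 1:5)
  pairs <- rbind(
    expand.grid(subject_id = hzma[1:2], group_id = multi, stringsAsFactors = FALSE),
    data.frame(subject_id = hzma[3], group_id = single, stringsAsFactors = FALSE))
  dx <- DiagnosisTable(pairs$subject_id, pairs$group_id)
  def <- PhenotypeDefinition("PH", c(multi, single))
  expect_setequal(multiplyOccurring(dx, hzma, def), multi)

  # every diagnosis unique to one subject -> empty set, tally 0
  dxU <- DiagnosisTable(hzma[1:5], single)
  expect_identical(multiplyOccurring(dxU, hzma, def), character())
  sp <- list(hzma = hzma, hzca = character(), excluded = character(),
             nHzma = 6L, nHzca = 0L)
  expect_identical(rgTally("rg1", dxU, sp, def)$tally, 0L)

  expect_error(multiplyOccurring(dx, hzma, def, minCount = 1), ">= 2")
})

test_that("diagnosis Fisher filter matches hypergeometric enumeration", {
  dx <- DiagnosisTable(c("A", "B"), c("DVT", "DVT"))
  sp <- list(hzma = c("A", "B"), hzca = c("C", "D", "E", "F"))
  expect_equal(diagnosisFisher("DVT", dx, sp), 1 / 15, tolerance = 1e-12)

  # equal carriage rates carry no excess signal
  dxEq <- DiagnosisTable(c("A", "C"), c("DVT", "DVT"))
  spEq <- list(hzma = c("A", "B"), hzca = c("C", "D"))
  expect_gte(diagnosisFisher("DVT", dxEq, spEq), 0.5)

  withr::local_seed(17)
  for (i in 1:100) {
    h <- sample(2:8, 1); n0 <- sample(2:20, 1)
    a <- sample(0:h, 1); b <- sample(0:n0, 1)
    dxR <- DiagnosisTable(c(sprintf("H%d", seq_len(a)), sprintf("C%d", seq_len(b))),
                          rep("G", max(a + b, 1))[seq_len(a + b)])
    spR <- list(hzma = sprintf("H%d", seq_len(h)), hzca = sprintf("C%d", seq_len(n0)))
    got <- if (a + b > 0) diagnosisFisher("G", dxR, spR) else 1
    expect_equal(got, oracleFisherGreater(a, h - a, b, n0 - b), tolerance = 1e-12)
  }
})

test_that("tally nesting T(rg2) <= T(rg1) <= affected-HZMA count on random cohorts", {
  withr::local_seed(29)
  for (i in 1:300) {
    mc <- randomMiniCohort(n = sample(6:12, 1), nGroups = sample(2:5, 1),
                           pDx = runif(1, 0.1, 0.6), seed = sample.int(1e6, 1))
    sp <- splitHomozygotes(mc$dosage)
    t1 <- rgTally("rg1", mc$dx, sp, mc$def)$tally
    t2 <- rgTally("rg2", mc$dx, sp, mc$def)$tally
    trec <- rgTally("rec", mc$dx, sp, mc$def)$tally
    expect_lte(t2, t1)
    expect_lte(t1, trec)
    expect_lte(trec, sp$nHzma)
  }
})

test_that("C++ kernel tallies agree with the R reference on random cohorts", {
  withr::local_seed(41)
  for (i in 1:50) {
    mc <- randomMiniCohort(n = sample(8:30, 1), nGroups = sample(2:6, 1),
                           pDx = runif(1, 0.15, 0.5), seed = sample.int(1e6, 1))
    sp <- splitHomozygotes(mc$dosage)
    gmx <- mechphen:::buildGroupMatrix(mc$dx, mc$def, mc$subjects)
    bmax <- mechphen:::fisherBmax(sp$nHzma, sp$nHzca, 0.1, 2L)
    got <- mechphen:::cpp_observed_tallies(
      gmx, match(sp$hzma, mc$subjects) - 1L,
      match(sp$excluded, mc$subjects) - 1L, 2L, bmax)
    want <- refTallies(mc$dx, mc$def, mc$subjects, sp$hzma, sp$excluded)
    expect_identical(unname(got), unname(as.integer(want)),
                     info = sprintf("cohort %d", i))
  }
})

test_that("six-subject toy: tally 2 and exhaustive permutation p = 1/15", {
  dx <- DiagnosisTable(c("A", "B"), c("DVT", "DVT"))
  def <- PhenotypeDefinition("T", "DVT")
  dosage <- setNames(c(2L, 2L, 0L, 0L, 0L, 0L), c("A", "B", "C", "D", "E", "F"))
  sp <- splitHomozygotes(dosage)
  r1 <- rgTally("rg1", dx, sp, def)
  expect_identical(r1$tally, 2L)
  expect_identical(r1$qualifying, "DVT")
  r2 <- rgTally("rg2", dx, sp, def)   # Fisher 1/15 < 0.1 keeps DVT
  expect_identical(r2$tally, 2L)

  exact <- oracleExhaustiveP(dx, def, names(dosage), dosage)
  expect_equal(unname(exact["rg1"]), 1 / 15, tolerance = 1e-12)

  cfg <- permutationConfig(B = 50000, strata = character(), seed = 7)
  mc <- stratifiedPermutationP(dosage, dx, def, NULL, cfg)
  se <- sqrt((1 / 15) * (14 / 15) / cfg$B)
  expect_lt(abs(mc$p[["rg1"]] - 1 / 15), 3 * se)
  expect_lt(abs(mc$p[["rg2"]] - 1 / 15), 3 * se)
})

test_that("Monte-Carlo p matches exhaustive enumeration on small cohorts (rg1, rg2, rec)", {
  withr::local_seed(53)
  cfg <- permutationConfig(B = 50000, strata = character(), seed = 13)
  for (i in 1:6) {
    mc <- randomMiniCohort(n = 7 + (i %% 2), nGroups = 3,
                           pDx = runif(1, 0.2, 0.5), seed = 1000 + i)
    exact <- oracleExhaustiveP(mc$dx, mc$def, mc$subjects, mc$dosage)
    got <- stratifiedPermutationP(mc$dosage, mc$dx, mc$def, NULL, cfg)
    for (m in c("rg1", "rg2", "rec")) {
      se <- sqrt(max(exact[m] * (1 - exact[m]), 1e-6) / cfg$B)
      expect_lt(abs(got$p[[m]] - exact[[m]]), 3 * se + 1e-12)
    }
  }
})

test_that("a statistic constant under reassignment gives p = 1", {
  # every subject carries the same diagnosis: tally always |hzma|
  subjects <- sprintf("S%d", 1:8)
  dx <- DiagnosisTable(subjects, rep("G", 8))
  def <- PhenotypeDefinition("PH", "G")
  dosage <- setNames(c(2L, 2L, 2L, rep(0L, 5)), subjects)
  cfg <- permutationConfig(B = 2000, strata = character(), seed = 5)
  res <- stratifiedPermutationP(dosage, dx, def, NULL, cfg)
  expect_identical(unname(res$p["rg1"]), 1)
  expect_identical(unname(res$p["rec"]), 1)
})

test_that("permuted homozygotes never cross strata and SNPs without homozygotes are skipped", {
  subjects <- sprintf("S%02d", 1:12)
  dx <- DiagnosisTable(subjects[c(1, 2, 7, 8)], rep("G", 4))
  def <- PhenotypeDefinition("PH", "G")
  covars <- data.frame(dataset = rep(c("X", "Y"), each = 6),
                       row.names = subjects)
  # both homozygotes live in stratum X; stratified reassignment must keep
  # the HZMA count in X at 2 and in Y at 0, so the tally distribution
  # equals that of resampling 2 of the 6 X subjects: P(T = 2) = 1/15
  dosage <- setNames(c(2L, 2L, rep(0L, 10)), subjects)
  cfg <- permutationConfig(B = 30000, strata = "dataset", seed = 9)
  res <- stratifiedPermutationP(dosage, dx, def, covars, cfg)
  exact <- 1 / choose(6, 2)
  se <- sqrt(exact * (1 - exact) / cfg$B)
  expect_lt(abs(res$p[["rg1"]] - exact), 3 * se)

  # all-heterozygous SNP carries no homozygote signal
  dHet <- setNames(rep(1L, 12), subjects)
  skip <- stratifiedPermutationP(dHet, dx, def, covars, cfg)
  expect_identical(skip$skipped, "no_minor_homozygotes")
  expect_true(is.na(skip$p[["rg1"]]))
})

test_that("anchored estimator never returns zero and plain can", {
  dx <- DiagnosisTable(c("A", "B"), c("DVT", "DVT"))
  def <- PhenotypeDefinition("T", "DVT")
  dosage <- setNames(c(2L, 2L, rep(0L, 4)), c("A", "B", "C", "D", "E", "F"))
  plain <- stratifiedPermutationP(dosage, dx, def, NULL,
                                  permutationConfig(B = 5, strata = character(),
                                                    seed = 2, estimator = "plain"))
  anch <- stratifiedPermutationP(dosage, dx, def, NULL,
                                 permutationConfig(B = 5, strata = character(),
                                                   seed = 2, estimator = "anchored"))
  expect_gte(min(anch$p), 1 / 6)
  expect_true(all(plain$p >= 0))
})

test_that("runReverseAssociation returns one scored row per SNP with skip reasons", {
  co <- smallCohort(seed = 12, n = 200, nSnps = 8)
  def <- phenotypeDefs(co)$THROMBOSIS
  cfg <- permutationConfig(B = 200, seed = 4)
  res <- runReverseAssociation(genotypes(co), diagnoses(co), def,
                               model = "rg1", cfg = cfg)
  expect_identical(nrow(res), 8L)
  scored <- res$n_hzma > 0
  expect_true(all(!is.na(res$p[scored])))
  expect_true(all(res$flag[!scored] == "no_minor_homozygotes"))
  # deterministic under the same seed and order-independent streams
  res2 <- runReverseAssociation(genotypes(co), diagnoses(co), def,
                                model = "rg1", cfg = cfg)
  expect_identical(res, res2)
})
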