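# Independent oracles and fixture builders.  These deliberately avoid the
# code paths they check: hypergeometric tails are summed from binomial
# coefficients, BH is a literal step-up loop, and permutation p-values are
# exhaustive enumerations over all genotype assignments.

# Upper-tail hypergeometric P(X >= a) from first principles.
oracleHyperTail <- function(a, K, N, k) {
  if (a <= 0) return(1)
  xs <- a:min(k, K)
  if (length(xs) == 0 || xs[1] > min(k, K)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, k - xs) - lchoose(N, k)))
}

# One-sided Fisher p (excess in row 1) for table rbind(c(a, b), c(c, d)).
oracleFisherGreater <- function(a, b, c, d) {
  oracleHyperTail(a, K = a + c, N = a + b + c + d, k = a + b)
}

# Literal Benjamini-Hochberg step-up over a universe of m tests.
oracleBH <- function(p, m) {
  o <- order(p)
  ps <- p[o]
  nn <- length(p)
  q <- numeric(nn)
  cur <- 1
  for (i in nn:1) {
    cur <- min(cur, ps[i] * m / i)
    q[i] <- cur
  }
  q[order(o)]
}

# Exact HWE p by direct enumeration with lchoose (independent of the
# recurrence used by hweExactP).
oracleHWE <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  nRare <- min(nA, na)
  if (nRare == 0) return(1)
  hs <- seq(nRare %% 2, nRare, by = 2)
  logp <- vapply(hs, function(h) {
    homR <- (nRare - h) / 2
    homC <- n - h - homR
    # multinomial x 2^h; the allele-count constant cancels on normalization
    lfactorial(n) - lfactorial(homR) - lfactorial(h) - lfactorial(homC) +
      h * log(2)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  pObs <- pr[match(nAa, hs)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-9)]))
}

# All distinct assignments of a genotype multiset (n2 HZMA, n1 het, rest
# HZCA) to n subjects; returns list of list(hzma=, het=) index sets.
enumerateAssignments <- function(n, n2, n1 = 0) {
  out <- list()
  hzSets <- utils::combn(n, n2, simplify = FALSE)
  for (hz in hzSets) {
    rest <- setdiff(seq_len(n), hz)
    if (n1 == 0) {
      out[[length(out) + 1L]] <- list(hzma = hz, het = integer())
    } else {
      for (ht in utils::combn(rest, n1, simplify = FALSE)) {
        out[[length(out) + 1L]] <- list(hzma = hz, het = ht)
      }
    }
  }
  out
}

# Reference tally computation working directly on id sets through the
# exported R operations (never the C++ kernel).
refTallies <- function(dx, def, subjects, hzmaIds, hetIds,
                       minCount = 2L, fisherThreshold = 0.1) {
  hzca <- setdiff(subjects, c(hzmaIds, hetIds))
  split <- list(hzma = hzmaIds, hzca = hzca, excluded = hetIds,
                nHzma = length(hzmaIds), nHzca = length(hzca))
  c(rg1 = rgTally("rg1", dx, split, def, fisherThreshold, minCount)$tally,
    rg2 = rgTally("rg2", dx, split, def, fisherThreshold, minCount)$tally,
    rec = rgTally("rec", dx, split, def, fisherThreshold, minCount)$tally)
}

# Exhaustive permutation p-values for all three models on a small cohort.
oracleExhaustiveP <- function(dx, def, subjects, dosage,
                              minCount = 2L, fisherThreshold = 0.1) {
  n <- length(subjects)
  n2 <- sum(dosage == 2)
  n1 <- sum(dosage == 1)
  obs <- refTallies(dx, def, subjects,
                    subjects[dosage == 2], subjects[dosage == 1],
                    minCount, fisherThreshold)
  asn <- enumerateAssignments(n, n2, n1)
  tal <- vapply(asn, function(a) {
    refTallies(dx, def, subjects, subjects[a$hzma], subjects[a$het],
               minCount, fisherThreshold)
  }, numeric(3))
  c(rg1 = mean(tal["rg1", ] >= obs["rg1"]),
    rg2 = mean(tal["rg2", ] >= obs["rg2"]),
    rec = mean(tal["rec", ] >= obs["rec"]))
}

# Small random cohort fixture: diagnosis table over `groups`, genotypes
# for a single SNP.
randomMiniCohort <- function(n = 8, nGroups = 3, pDx = 0.35, seed = 1) {
  withr::local_seed(seed)
  subjects <- sprintf("P%02d", seq_len(n))
  groups <- LETTERS[seq_len(nGroups)]
  carry <- matrix(runif(n * nGroups) < pDx, n, nGroups)
  idx <- which(carry, arr.ind = TRUE)
  dx <- DiagnosisTable(subjects[idx[, 1]], groups[idx[, 2]])
  def <- PhenotypeDefinition("PH", groups)
  repeat {
    dosage <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.6, 0.2, 0.2))
    if (sum(dosage == 2L) >= 1L) break
  }
  names(dosage) <- subjects
  list(subjects = subjects, dx = dx, def = def, dosage = dosage)
}

# Tiny thrombosis-like cohort for pipeline and enrichment tests (fast).
smallCohort <- function(seed = 1, n = 400, nSnps = 40) {
  generateCohort(cohortSpec(profile = thrombosisProfile(), n = n,
                            nSnps = nSnps, seed = seed))
}
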