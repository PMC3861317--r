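# SNP selection: MAF window, minor-homozygote count, call rate, HWE.

#' QC thresholds for SNP selection
#'
#' @param mafMax Maximum minor allele frequency (exclusive); default 0.10,
#'   the low-frequency window the framework targets.
#' @param minHzma Minimum count of minor-allele homozygotes; default 10 so
#'   the homozygote-tally statistics have workable sample sizes.
#' @param callRateMin Minimum per-SNP call rate; default 0.98.
#' @param hweAlpha Hardy-Weinberg exact-test flag level; default 0.001.
#' @param hweExclude If `TRUE`, HWE failures are excluded rather than only
#'   flagged (flag-only is the default because departures at low MAF often
#'   reflect real structure rather than genotyping error).
#' @return List of validated thresholds.
#' @export
qcThresholds <- function(mafMax = 0.10, minHzma = 10L, callRateMin = 0.98,
                         hweAlpha = 0.001, hweExclude = FALSE) {
  stopIfNot(mafMax > 0 && mafMax <= 0.5, "mafMax must be in (0, 0.5]")
  stopIfNot(minHzma >= 1, "minHzma must be >= 1")
  stopIfNot(callRateMin >= 0 && callRateMin <= 1, "callRateMin must be in [0,1]")
  list(mafMax = mafMax, minHzma = as.integer(minHzma),
       callRateMin = callRateMin, hweAlpha = hweAlpha,
       hweExclude = isTRUE(hweExclude))
}

#' Minor allele frequency of a dosage vector
#'
#' `MAF = min(f, 1 - f)` with `f = sum(dosage) / (2 * n_nonmissing)`.
#'
#' @param dosages Integer vector of dosages (0/1/2, `NA` missing).
#' @return MAF in `[0, 0.5]`, or `NA` if all calls are missing.
#' @examples
#' minorAlleleFrequency(c(0, 0, 1, 2))  # 3/8
#' @export
minorAlleleFrequency <- function(dosages) {
  n <- sum(!is.na(dosages))
  if (n == 0L) return(NA_real_)
  f <- sum(dosages, na.rm = TRUE) / (2 * n)
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the allele counts, the p-value is the sum
#' of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.  Computed with
#' the Levene-Haldane recurrence for numerical stability; preferred over
#' the chi-square test because minor-homozygote counts are small by design
#' in this framework.
#'
#' @param nAA,nAa,naa Genotype counts (common homozygote, heterozygote,
#'   minor homozygote).
#' @return Exact p-value in `[0, 1]`; degenerate configurations (monomorphic
#'   samples) return 1.
#' @export
hweExactP <- function(nAA, nAa, naa) {
  counts <- c(nAA, nAa, naa)
  stopIfNot(all(counts >= 0) && all(counts == round(counts)),
            "genotype counts must be non-negative integers")
  n <- sum(counts)
  stopIfNot(n >= 1, "at least one genotype required")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  nRare <- min(nA, na)
  if (nRare == 0L) return(1)
  hetVals <- seq.int(nRare %% 2L, nRare, by = 2L)
  # Levene-Haldane: P(h+2)/P(h) = 4 * nhomR * nhomC / ((h+2)(h+1)), unnormalized
  logp <- numeric(length(hetVals))
  for (i in seq_along(hetVals)[-1]) {
    h <- hetVals[i - 1L]
    homR <- (nRare - h) / 2          # rare homozygotes at h
    homC <- (n - h - homR)           # common homozygotes at h
    logp[i] <- logp[i - 1L] + log(4 * homR * homC) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  pObs <- p[match(nAa, hetVals)]
  if (is.na(pObs)) stop("heterozygote count inconsistent with allele counts", call. = FALSE)
  min(1, sum(p[p <= pObs * (1 + 1e-9)]))
}

#' Apply SNP selection filters
#'
#' Retains SNPs with `MAF < mafMax`, at least `minHzma` minor-allele
#' homozygotes and call rate `>= callRateMin`; Hardy-Weinberg failures are
#' flagged (and excluded only when `hweExclude` is set).  The filters are
#' order-independent and the retained set is a deterministic function of
#' the matrix and thresholds.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param qc Thresholds from [qcThresholds].
#' @return List with `retained` (character vector of SNP ids, matrix order)
#'   and `report` (`data.frame`: snp_id, maf, hzma_count, call_rate, hwe_p,
#'   hwe_flag, excluded, reason).
#' @export
selectSNPs <- function(gm, qc = qcThresholds()) {
  d <- dosages(gm)
  nsnp <- nrow(d)
  maf <- apply(d, 1L, minorAlleleFrequency)
  hzma <- as.integer(rowSums(d == 2L, na.rm = TRUE))
  callRate <- rowMeans(!is.na(d))
  hwe <- vapply(seq_len(nsnp), function(i) {
    x <- d[i, ]
    if (all(is.na(x))) return(NA_real_)
    hweExactP(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
              sum(x == 2L, na.rm = TRUE))
  }, numeric(1))
  hweFlag <- !is.na(hwe) & hwe < qc$hweAlpha
  reason <- character(nsnp)
  addReason <- function(reason, which, tag) {
    ifelse(which, ifelse(nzchar(reason), paste(reason, tag, sep = ";"), tag), reason)
  }
  reason <- addReason(reason, is.na(maf), "all_missing")
  reason <- addReason(reason, !is.na(maf) & maf >= qc$mafMax, "maf")
  reason <- addReason(reason, hzma < qc$minHzma, "hzma_count")
  reason <- addReason(reason, callRate < qc$callRateMin, "call_rate")
  if (qc$hweExclude) reason <- addReason(reason, hweFlag, "hwe")
  excluded <- nzchar(reason)
  if (any(is.na(maf))) {
    warning(sprintf("%d SNP(s) with no non-missing calls dropped", sum(is.na(maf))))
  }
  retained <- rownames(d)[!excluded]
  if (length(retained) == 0L) warning("no SNPs pass the selection filters")
  list(retained = retained,
       report = data.frame(snp_id = rownames(d), maf = maf, hzma_count = hzma,
                           call_rate = callRate, hwe_p = hwe, hwe_flag = hweFlag,
                           excluded = excluded,
                           reason = ifelse(excluded, reason, ""),
                           stringsAsFactors = FALSE, row.names = NULL))
}
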