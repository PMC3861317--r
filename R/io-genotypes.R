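# Genotype, covariate and cohort file IO.
#
# Two text dialects are supported: PLINK text PED/MAP and a wide dosage TSV.
# Both are re-polarized on load so that dosage counts copies of the cohort
# minor allele.

#' Read genotypes into a GenotypeMatrix
#'
#' @param path For `format = "ped_map"`, the file prefix (reads
#'   `<path>.ped` and `<path>.map`) or the `.ped` path itself; for
#'   `format = "dosage_tsv"`, the TSV path.
#' @param format `"ped_map"` or `"dosage_tsv"`.
#' @param subjectInfo Optional covariate `data.frame` (rownames or column
#'   `subject_id` matching subjects) attached as `colData`.
#' @return A [GenotypeMatrix-class] with dosages counting minor-allele
#'   copies; on a 50/50 allele-frequency tie the lexicographically last
#'   allele is taken as minor so polarity is deterministic.
#' @export
readGenotypes <- function(path, format = c("ped_map", "dosage_tsv"),
                          subjectInfo = NULL) {
  format <- match.arg(format)
  gm <- switch(format,
               ped_map = readPedMap(path),
               dosage_tsv = readDosageTsv(path))
  if (!is.null(subjectInfo)) {
    if (!is.null(subjectInfo$subject_id)) {
      rownames(subjectInfo) <- subjectInfo$subject_id
      subjectInfo$subject_id <- NULL
    }
    missing <- setdiff(colnames(gm), rownames(subjectInfo))
    stopIfNot(length(missing) == 0L,
              sprintf("covariates missing for %d subject(s), e.g. %s",
                      length(missing), missing[1]))
    colData(gm) <- DataFrame(subjectInfo[colnames(gm), , drop = FALSE])
  }
  gm
}

readPedMap <- function(prefix) {
  prefix <- sub("\\.ped$", "", prefix)
  pedFile <- paste0(prefix, ".ped")
  mapFile <- paste0(prefix, ".map")
  stopIfNot(file.exists(pedFile), sprintf("missing file: %s", pedFile))
  stopIfNot(file.exists(mapFile), sprintf("missing file: %s", mapFile))
  mp <- read.table(mapFile, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "snp_id", "cm", "bp"))
  nsnp <- nrow(mp)
  lines <- readLines(pedFile)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  lens <- lengths(toks)
  bad <- which(lens != 6L + 2L * nsnp)
  if (length(bad)) {
    stop(sprintf("PED line %d has %d fields, expected %d (6 + 2 x %d SNPs)",
                 bad[1], lens[bad[1]], 6L + 2L * nsnp, nsnp), call. = FALSE)
  }
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  subj <- tok[, 2L]
  stopIfNot(!anyDuplicated(subj), "duplicate subject (IID) in PED")
  dosage <- matrix(NA_integer_, nsnp, length(subj),
                   dimnames = list(mp$snp_id, subj))
  amaj <- amin <- rep(NA_character_, nsnp)
  for (j in seq_len(nsnp)) {
    a1 <- tok[, 5L + 2L * j]
    a2 <- tok[, 6L + 2L * j]
    miss <- a1 == "0" | a2 == "0"
    alleles <- table(c(a1[!miss], a2[!miss]))
    if (length(alleles) > 2L) {
      stop(sprintf("SNP %s has %d distinct alleles (%s)", mp$snp_id[j],
                   length(alleles), paste(names(alleles), collapse = ",")),
           call. = FALSE)
    }
    if (length(alleles) == 0L) next  # all missing; caught by QC
    pol <- polarizeAlleles(alleles)
    amaj[j] <- pol["major"]; amin[j] <- pol["minor"]
    d <- if (is.na(pol["minor"])) {
      rep(0L, length(a1))             # monomorphic: zero minor copies
    } else {
      (a1 == pol["minor"]) + (a2 == pol["minor"])
    }
    d[miss] <- NA_integer_
    dosage[j, ] <- as.integer(d)
  }
  GenotypeMatrix(dosage,
                 snpInfo = data.frame(gene = NA_character_, allele_major = amaj,
                                      allele_minor = amin,
                                      row.names = mp$snp_id,
                                      stringsAsFactors = FALSE))
}

# Deterministic polarity: minor = least frequent allele; 50/50 ties go to
# the lexicographically last allele; monomorphic SNPs get minor = NA.
polarizeAlleles <- function(alleleCounts) {
  an <- names(alleleCounts)
  if (length(alleleCounts) == 1L) return(c(major = an[1], minor = NA_character_))
  if (alleleCounts[[1]] == alleleCounts[[2]]) {
    minor <- max(an); major <- min(an)
  } else {
    minor <- an[which.min(alleleCounts)]
    major <- an[which.max(alleleCounts)]
  }
  c(major = major, minor = minor)
}

#' Write a GenotypeMatrix as PLINK text PED/MAP
#'
#' @param gm A [GenotypeMatrix-class].
#' @param prefix Output prefix (`<prefix>.ped`, `<prefix>.map`).
#' @return The prefix, invisibly.
#' @export
writePedMap <- function(gm, prefix) {
  d <- dosages(gm)
  rd <- rowData(gm)
  mp <- data.frame(chrom = 1L, snp_id = rownames(d), cm = 0L, bp = seq_len(nrow(d)))
  write.table(mp, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  amin <- ifelse(is.na(rd$allele_minor), "B", as.character(rd$allele_minor))
  amaj <- ifelse(is.na(rd$allele_major), "A", as.character(rd$allele_major))
  cv <- covariates(gm)
  sex <- if (!is.null(cv$gender)) ifelse(cv$gender == "M", 1L, 2L) else 0L
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(ncol(d))) {
    g <- d[, i]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, amin, amaj))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, amin, amaj))
    row <- c(colnames(d)[i], colnames(d)[i], "0", "0",
             if (length(sex) > 1L) sex[i] else sex, "-9",
             as.vector(rbind(a1, a2)))
    writeLines(paste(row, collapse = " "), con)
  }
  invisible(prefix)
}

readDosageTsv <- function(path) {
  stopIfNot(file.exists(path), sprintf("missing file: %s", path))
  df <- readTsv(path, colClasses = "character")
  need <- c("snp_id", "gene", "allele_major", "allele_minor")
  stopIfNot(all(need %in% colnames(df)),
            sprintf("dosage TSV must start with columns %s", paste(need, collapse = ", ")))
  subjCols <- setdiff(colnames(df), need)
  stopIfNot(length(subjCols) > 0L, "dosage TSV has no subject columns")
  d <- as.matrix(df[, subjCols, drop = FALSE])
  d[d == "NA"] <- NA
  suppressWarnings(storage.mode(d) <- "integer")
  dimnames(d) <- list(df$snp_id, subjCols)
  toNa <- function(x) ifelse(x == "NA" | x == "", NA_character_, x)
  gm <- GenotypeMatrix(d, snpInfo = data.frame(
    gene = toNa(df$gene), allele_major = toNa(df$allele_major),
    allele_minor = toNa(df$allele_minor),
    row.names = df$snp_id, stringsAsFactors = FALSE))
  gm <- repolarize(gm)
  gm
}

# Enforce the minor-allele invariant after loading a dosage file whose
# polarity may not match the loaded cohort.
repolarize <- function(gm) {
  d <- dosages(gm)
  rd <- rowData(gm)
  for (i in seq_len(nrow(d))) {
    x <- d[i, ]
    n <- sum(!is.na(x))
    if (n == 0L) next
    f <- sum(x, na.rm = TRUE) / (2 * n)
    flip <- f > 0.5 ||
      (f == 0.5 && !is.na(rd$allele_minor[i]) && !is.na(rd$allele_major[i]) &&
         rd$allele_minor[i] < rd$allele_major[i])
    if (flip) {
      d[i, ] <- 2L - x
      tmp <- rd$allele_major[i]
      rd$allele_major[i] <- rd$allele_minor[i]
      rd$allele_minor[i] <- tmp
    }
  }
  assay(gm, "dosage") <- d
  rowData(gm) <- rd
  gm
}

#' Write a GenotypeMatrix as a wide dosage TSV
#'
#' @param gm A [GenotypeMatrix-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeDosageTsv <- function(gm, path) {
  rd <- rowData(gm)
  df <- data.frame(snp_id = rownames(gm),
                   gene = as.character(rd$gene),
                   allele_major = as.character(rd$allele_major),
                   allele_minor = as.character(rd$allele_minor),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(dosages(gm), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject covariate table
#'
#' @param path TSV with header columns `subject_id`, `age`, `gender`,
#'   `dataset`.
#' @return `data.frame` with rownames = subject ids.
#' @export
readCovariates <- function(path) {
  df <- readTsv(path)
  need <- c("subject_id", "age", "gender", "dataset")
  stopIfNot(all(need %in% colnames(df)),
            sprintf("covariate file needs columns %s", paste(need, collapse = ", ")))
  stopIfNot(!anyDuplicated(df$subject_id), "duplicate subject ids in covariate file")
  rownames(df) <- df$subject_id
  df$age <- as.numeric(df$age)
  df
}
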