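# Forward genetics: covariate-adjusted additive / recessive logistic models.

#' Fit a per-SNP logistic association model
#'
#' Multivariable logistic regression of case status on genotype, adjusting
#' for the supplied covariates.  `coding = "additive"` uses the minor-allele
#' dosage (0/1/2); `coding = "recessive"` codes minor-allele homozygotes as
#' 1 and everything else as 0.  Subjects with a missing dosage or covariate
#' are dropped (complete-case per SNP).  The genotype effect is reported as
#' an odds ratio with a Wald 95% confidence interval and p-value, matching
#' the standard GWAS toolchain output this table format mirrors.
#'
#' Non-convergence or (quasi-)complete separation - common for recessive
#' codings of rare homozygotes - is flagged and the p-value set missing by
#' default; with `firth = TRUE` a Firth-penalized fit is used instead.
#'
#' @param dosage Integer dosage vector, one entry per subject.
#' @param y Case/control factor from [assignPhenotype] (levels
#'   `control`, `case`), aligned with `dosage`.
#' @param covars Optional `data.frame` of covariates (e.g. `age`, `gender`,
#'   `dataset`), aligned with `dosage`.  Factor-like columns with a single
#'   observed level are dropped automatically.
#' @param coding `"additive"` or `"recessive"`.
#' @param firth Use Firth-penalized logistic regression as a separation
#'   fallback.
#' @return One-row `data.frame`: `model`, `or`, `ci_low`, `ci_high`, `p`,
#'   `beta`, `se`, `n`, `n_case`, `n_control`, `n_hzma`, `flag`.
#' @export
fitLogistic <- function(dosage, y, covars = NULL,
                        coding = c("additive", "recessive"), firth = FALSE) {
  coding <- match.arg(coding)
  stopIfNot(length(dosage) == length(y), "dosage and y lengths differ")
  y01 <- as.integer(y == "case")
  x <- if (coding == "recessive") as.integer(dosage == 2L) else as.integer(dosage)
  df <- data.frame(.y = y01, .g = x)
  if (!is.null(covars)) {
    stopIfNot(nrow(covars) == length(y), "covariate rows and y lengths differ")
    for (nm in colnames(covars)) {
      v <- covars[[nm]]
      if (!is.numeric(v)) v <- factor(v)
      df[[nm]] <- v
    }
  }
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  # drop constant covariate columns (e.g. a dataset factor with one level)
  for (nm in setdiff(colnames(df), c(".y", ".g"))) {
    if (length(unique(df[[nm]])) < 2L) df[[nm]] <- NULL
    else if (is.factor(df[[nm]])) df[[nm]] <- droplevels(df[[nm]])
  }
  out <- data.frame(model = coding, or = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, beta = NA_real_,
                    se = NA_real_, n = nrow(df),
                    n_case = sum(df$.y == 1L), n_control = sum(df$.y == 0L),
                    n_hzma = sum(dosage[cc] == 2L, na.rm = TRUE),
                    flag = "", stringsAsFactors = FALSE)
  if (out$n_case == 0L || out$n_control == 0L) {
    out$flag <- "degenerate_phenotype"
    return(out)
  }
  if (length(unique(df$.g)) < 2L) {
    out$flag <- "monomorphic_in_sample"
    return(out)
  }
  if (firth) return(firthRow(df, out))
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  beta <- coef(fit)[".g"]
  se <- sqrt(diag(vcov(fit))[".g"])
  separated <- !fit$converged || is.na(beta) || abs(beta) > 15 || se > 100
  if (separated) {
    out$flag <- "separation"
    if (!is.na(beta)) out$beta <- unname(beta)
    return(out)
  }
  out$beta <- unname(beta); out$se <- unname(se)
  out$or <- exp(out$beta)
  out$ci_low <- exp(out$beta - 1.959963984540054 * out$se)
  out$ci_high <- exp(out$beta + 1.959963984540054 * out$se)
  out$p <- 2 * pnorm(-abs(out$beta / out$se))
  out
}

# Firth-penalized logistic fit (Jeffreys-prior score adjustment); Wald
# inference on the penalized estimates.
firthRow <- function(df, out) {
  X <- stats::model.matrix(.y ~ ., data = df)
  y <- df$.y
  beta <- rep(0, ncol(X))
  for (iter in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    XtWX <- crossprod(X, XW)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) { out$flag <- "firth_singular"; return(out) }
    # hat diagonal of W^(1/2) X (X'WX)^-1 X' W^(1/2)
    Xs <- X * sqrt(w)
    H <- Xs %*% chol2inv(ch)
    h <- rowSums(H * Xs)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- chol2inv(ch) %*% U
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  vc <- chol2inv(chol(XtWX))
  j <- match(".g", colnames(X))
  out$beta <- beta[j]
  out$se <- sqrt(vc[j, j])
  out$or <- exp(out$beta)
  out$ci_low <- exp(out$beta - 1.959963984540054 * out$se)
  out$ci_high <- exp(out$beta + 1.959963984540054 * out$se)
  out$p <- 2 * pnorm(-abs(out$beta / out$se))
  out$flag <- "firth"
  out
}

#' Run a forward association model over all SNPs
#'
#' @param gm A [GenotypeMatrix-class].
#' @param y Case/control factor named by subject id (see
#'   [assignPhenotype]); subjects are matched by name.
#' @param covars Covariate `data.frame` with rownames = subject ids
#'   (defaults to `covariates(gm)` columns `age`, `gender`, `dataset` when
#'   present).
#' @param model `"additive"` or `"recessive"`.
#' @param phenotype Phenotype id recorded in the output.
#' @param firth Passed to [fitLogistic].
#' @return `data.frame` with one row per SNP: `snp_id`, `gene`,
#'   `phenotype_id`, plus the [fitLogistic] columns.
#' @export
runForwardAssociation <- function(gm, y, covars = NULL,
                                  model = c("additive", "recessive"),
                                  phenotype = "PHENOTYPE", firth = FALSE) {
  model <- match.arg(model)
  subj <- subjectIds(gm)
  stopIfNot(all(subj %in% names(y)), "case/control vector missing cohort subjects")
  y <- y[subj]
  if (is.null(covars)) {
    cv <- covariates(gm)
    covars <- cv[, intersect(c("age", "gender", "dataset"), colnames(cv)), drop = FALSE]
  } else {
    covars <- covars[subj, , drop = FALSE]
  }
  d <- dosages(gm)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    fitLogistic(d[i, ], y, covars, coding = model, firth = firth)
  })
  res <- do.call(rbind, rows)
  cbind(data.frame(snp_id = rownames(d), gene = unname(geneIds(gm)),
                   phenotype_id = phenotype, stringsAsFactors = FALSE),
        res)
}

#' Keep risk-direction associations (OR > 1)
#'
#' Enrichment analyses of the forward models use only SNPs whose odds ratio
#' exceeds 1 (strictly), since the aim is variants increasing phenotype
#' risk.  Reverse-genetics rows (no OR) pass through untouched.
#'
#' @param results Association `data.frame` from [runForwardAssociation] or
#'   [runReverseAssociation].
#' @return Filtered `data.frame`.
#' @export
orFilter <- function(results) {
  if (!"or" %in% colnames(results)) return(results)
  isForward <- results$model %in% c("additive", "recessive")
  keep <- !isForward | (!is.na(results$or) & results$or > 1)
  results[keep, , drop = FALSE]
}
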