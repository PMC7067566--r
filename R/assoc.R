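new_sumstats <- function(panel_rows, beta, se, p, n, design, excluded_ids) {
  out <- data.frame(
    chr = panel_rows$chrom, pos = panel_rows$pos, id = panel_rows$snp_id,
    ea = panel_rows$effect_allele, oa = panel_rows$other_allele,
    beta = beta, se = se, p = p, n = as.integer(n), design = design,
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded_ids
  class(out) <- c("sumstats", "data.frame")
  out
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats (%s design): %d SNPs, n = %d, median SE = %.4g, min p = %.3g\n",
              x$design[1L], nrow(x), x$n[1L], median(x$se), min(x$p)))
  ex <- attr(x, "excluded")
  if (length(ex)) cat(sprintf("  %d degenerate SNPs excluded\n", length(ex)))
  invisible(x)
}

# design matrix [intercept | covariates]; errors on rank deficiency
covariate_qr <- function(covariates, n) {
  M <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  qrM <- qr(M)
  if (qrM$rank < ncol(M))
    stop("covariate matrix is rank deficient after adding an intercept")
  qrM
}

#' Residualize a phenotype on covariates
#'
#' Least-squares residuals of `y` on `[intercept | covariates]`; the output
#' is orthogonal to the intercept and every covariate column. With no
#' covariates this is mean-centering.
#'
#' @param y Numeric vector.
#' @param covariates Numeric matrix/data frame (or `NULL`).
#' @return Numeric vector of residuals.
#' @export
residualize <- function(y, covariates = NULL) {
  qrM <- covariate_qr(covariates, length(y))
  as.numeric(qr.resid(qrM, y))
}

# Shared vectorized engine: per-SNP simple regression of y_res on x_res
# (Frisch-Waugh-Lovell), classical SEs, t reference with the stated df.
marginal_ols <- function(X_res, y_res, df) {
  sxx <- colSums(X_res^2)
  sxy <- as.numeric(crossprod(X_res, y_res))
  keep <- sxx > .Machine$double.eps * nrow(X_res)
  beta <- sxy / sxx
  rss <- sum(y_res^2) - beta * sxy
  rss[rss < 0] <- 0
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df)
  list(beta = beta, se = se, p = p, keep = keep)
}

#' Standard covariate-adjusted GWAS by per-SNP linear regression
#'
#' For each SNP, fits `y ~ intercept + SNP + covariates` by OLS and reports
#' the SNP coefficient, its classical standard error and the two-sided
#' t-test p-value. Implemented through exact Frisch-Waugh-Lovell
#' residualization of both the phenotype and the genotypes on the covariates,
#' with residual degrees of freedom `n - n_covariates - 2`; this is
#' numerically identical to the per-SNP full regression.
#'
#' SNPs that are monomorphic in the analysis sample (or collinear with the
#' covariates) are excluded from the output; their ids are recorded in the
#' `"excluded"` attribute and a message reports the count.
#'
#' @param genotypes A `geno_matrix` or counts matrix (columns named by SNP
#'   id), rows aligned with `y`.
#' @param y Numeric phenotype vector.
#' @param covariates Numeric matrix/data frame of covariates (or `NULL`).
#' @param snp_ids Optional subset of SNPs to test.
#' @return A `sumstats` data frame: `chr, pos, id, ea, oa, beta, se, p, n,
#'   design` with `design == "standard"`.
#' @export
ols_gwas <- function(genotypes, y, covariates = NULL, snp_ids = NULL) {
  counts <- as_counts(genotypes)
  panel <- if (inherits(genotypes, "geno_matrix")) genotypes$panel else NULL
  n <- length(y)
  if (nrow(counts) != n) stop("genotype rows and phenotype length differ")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2L) stop("need n > n_covariates + 2")
  if (!is.null(snp_ids)) {
    cols <- match(snp_ids, colnames(counts))
    if (anyNA(cols)) stop("some requested SNPs absent from genotypes")
    counts <- counts[, cols, drop = FALSE]
  }
  qrM <- covariate_qr(covariates, n)
  y_res <- as.numeric(qr.resid(qrM, y))
  df <- n - k - 2L

  m <- ncol(counts)
  beta <- se <- p <- numeric(m)
  keep <- logical(m)
  chunk <- max(1L, min(m, as.integer(1.5e7 / n)))
  start <- 1L
  while (start <= m) {
    cols <- start:min(m, start + chunk - 1L)
    X_res <- qr.resid(qrM, counts[, cols, drop = FALSE] * 1.0)
    fit <- marginal_ols(X_res, y_res, df)
    beta[cols] <- fit$beta; se[cols] <- fit$se; p[cols] <- fit$p
    keep[cols] <- fit$keep
    start <- cols[length(cols)] + 1L
  }

  ids <- colnames(counts)
  excluded <- ids[!keep]
  if (length(excluded))
    message(sprintf("ols_gwas: excluded %d degenerate SNP(s)",
                    length(excluded)))
  pr <- sumstats_panel_rows(panel, ids[keep])
  new_sumstats(pr, beta[keep], se[keep], p[keep], n, "standard", excluded)
}

# Per-SNP metadata for sumstats; synthesized when genotypes lack a panel.
sumstats_panel_rows <- function(panel, ids) {
  if (is.null(panel)) {
    data.frame(chrom = 1L, pos = seq_along(ids), snp_id = ids,
               effect_allele = "A", other_allele = "G",
               stringsAsFactors = FALSE)
  } else {
    panel[match(ids, panel$snp_id),
          c("chrom", "pos", "snp_id", "effect_allele", "other_allele")]
  }
}

#' Logistic GWAS for binary traits
#'
#' Per-SNP maximum-likelihood logistic regression
#' `y ~ intercept + SNP + covariates`; reports the log odds ratio, its Wald
#' standard error and the two-sided normal-reference p-value. SNPs showing
#' (quasi-)complete separation or non-convergence are excluded and recorded
#' in the `"excluded"` attribute.
#'
#' @inheritParams ols_gwas
#' @param y_binary Integer 0/1 outcome; both classes must be present.
#' @return A `sumstats` data frame with `design == "logistic"`.
#' @export
logistic_gwas <- function(genotypes, y_binary, covariates = NULL,
                          snp_ids = NULL) {
  counts <- as_counts(genotypes)
  panel <- if (inherits(genotypes, "geno_matrix")) genotypes$panel else NULL
  n <- length(y_binary)
  if (nrow(counts) != n) stop("genotype rows and phenotype length differ")
  if (length(unique(y_binary)) < 2L)
    stop("both outcome classes must be present")
  if (!is.null(snp_ids)) {
    cols <- match(snp_ids, colnames(counts))
    if (anyNA(cols)) stop("some requested SNPs absent from genotypes")
    counts <- counts[, cols, drop = FALSE]
  }
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  m <- ncol(counts)
  beta <- se <- p <- rep(NA_real_, m)
  keep <- logical(m)
  for (j in seq_len(m)) {
    x <- counts[, j]
    if (stats::sd(x) == 0) next
    M <- cbind(1, x, C)
    fit <- tryCatch(
      suppressWarnings(glm.fit(M, y_binary, family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    # Wald SE from the Fisher information at the MLE
    w <- fit$weights
    XtWX <- crossprod(M * sqrt(w))
    vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(vc)) next
    b <- fit$coefficients[2L]
    s <- sqrt(vc[2L, 2L])
    if (!is.finite(b) || !is.finite(s) || s > 30 || abs(b) > 30) next
    beta[j] <- b; se[j] <- s
    p[j] <- 2 * pnorm(-abs(b / s))
    keep[j] <- TRUE
  }
  ids <- colnames(counts)
  excluded <- ids[!keep]
  if (length(excluded))
    message(sprintf("logistic_gwas: excluded %d degenerate/separated SNP(s)",
                    length(excluded)))
  pr <- sumstats_panel_rows(panel, ids[keep])
  new_sumstats(pr, beta[keep], se[keep], p[keep], n, "logistic", excluded)
}

#' Sibling-difference GWAS
#'
#' The family-based design: phenotypes of all siblings are first residualized
#' jointly on age and sex (plus intercept); within each pair the residual
#' difference is then regressed on the genotype difference (with intercept),
#' SNP by SNP, with classical SEs and `n_pairs - 2` degrees of freedom.
#' Because both siblings share their parents, the within-pair difference
#' conditions out parental genotype — removing indirect parental effects and
#' assortative-mating signal from the estimates. Reversing the within-pair
#' order flips the sign of `beta` but leaves `|beta|`, `se` and `p`
#' unchanged.
#'
#' SNPs whose genotype difference is zero in every pair are excluded and
#' recorded in the `"excluded"` attribute.
#'
#' @param cohort A [simulate_offspring()] `family_cohort` with two offspring
#'   per family.
#' @param y1,y2 Phenotypes of sibling 1 and sibling 2 (one value per family).
#' @param covariates1,covariates2 Covariate matrices for the two siblings
#'   (same columns; or both `NULL`).
#' @param snp_ids Optional subset of SNPs to test.
#' @return A `sumstats` data frame with `design == "sib"`; `n` is the number
#'   of pairs.
#' @export
sib_diff_gwas <- function(cohort, y1, y2, covariates1 = NULL,
                          covariates2 = NULL, snp_ids = NULL) {
  stopifnot(inherits(cohort, "family_cohort"),
            length(cohort$offspring) == 2L)
  n_fam <- length(cohort$family_id)
  stopifnot(length(y1) == n_fam, length(y2) == n_fam)
  cov_all <- if (!is.null(covariates1))
    rbind(as.matrix(covariates1), as.matrix(covariates2))
  r <- residualize(c(y1, y2), cov_all)
  d_y <- r[seq_len(n_fam)] - r[n_fam + seq_len(n_fam)]

  X1 <- cohort$offspring[[1L]]
  X2 <- cohort$offspring[[2L]]
  if (!is.null(snp_ids)) {
    cols <- match(snp_ids, colnames(X1))
    if (anyNA(cols)) stop("some requested SNPs absent from the cohort")
    X1 <- X1[, cols, drop = FALSE]; X2 <- X2[, cols, drop = FALSE]
  }
  dX <- (X1 - X2) * 1.0
  dXc <- sweep(dX, 2L, colMeans(dX))
  dyc <- d_y - mean(d_y)
  df <- n_fam - 2L
  fit <- marginal_ols(dXc, dyc, df)
  ids <- colnames(X1)
  excluded <- ids[!fit$keep]
  if (length(excluded))
    message(sprintf("sib_diff_gwas: excluded %d SNP(s) with no within-pair variation",
                    length(excluded)))
  pr <- sumstats_panel_rows(cohort$panel, ids[fit$keep])
  new_sumstats(pr, fit$beta[fit$keep], fit$se[fit$keep], fit$p[fit$keep],
               n_fam, "sib", excluded)
}
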