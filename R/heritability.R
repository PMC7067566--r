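#' Haseman-Elston moment estimate of SNP heritability
#'
#' Regresses the pairwise cross-products of the standardized, residualized
#' phenotype on the off-diagonal entries of the standardized genetic
#' relationship matrix (GRM) built from the chosen SNPs; the slope (with
#' intercept) is the heritability estimate. The GRM is never formed
#' explicitly: all sums of off-diagonal products are obtained from
#' `m x m` crossproducts, so the cost is `O(n m^2)` in time and `O(m^2)` in
#' memory. The standard error is a delete-a-group jackknife over
#' individuals.
#'
#' The moment estimator is only consistent when the GRM SNPs are (close to)
#' uncorrelated, so the function insists on either an unlinked panel or an
#' explicit causal-SNP set (`causal_ids`), the situation the simulator
#' controls.
#'
#' @param genotypes A `geno_matrix`.
#' @param y Numeric phenotype.
#' @param covariates Covariate matrix/data frame or `NULL`; `y` is
#'   residualized on them and standardized before estimation, so the
#'   estimate is a proportion of the covariate-adjusted variance.
#' @param causal_ids SNP ids to build the GRM from; mandatory when the panel
#'   carries LD.
#' @param n_groups Number of jackknife groups.
#' @return Object of class `he_h2`: list with `h2`, `se`, `n`, `m`,
#'   `n_groups` and the leave-group-out estimates `loo`.
#' @export
h2_moment_estimate <- function(genotypes, y, covariates = NULL,
                               causal_ids = NULL, n_groups = 10L) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (is.null(causal_ids) && !panel_is_unlinked(genotypes$panel))
    stop("panel carries LD: supply `causal_ids` or use an unlinked panel ",
         "(the moment estimator is not valid on linked background SNPs)")
  counts <- genotypes$counts
  if (!is.null(causal_ids)) {
    cols <- match(causal_ids, colnames(counts))
    if (anyNA(cols)) stop("causal SNP(s) absent from genotypes")
    counts <- counts[, cols, drop = FALSE]
  }
  n <- nrow(counts); m <- ncol(counts)
  if (n < 10L) stop("too few individuals")
  yr <- standardize(residualize(y, covariates))

  mu <- colMeans(counts)
  sdv <- sqrt(colMeans(counts^2) - mu^2) * sqrt(n / (n - 1))
  ok <- sdv > 0
  if (!all(ok)) { counts <- counts[, ok, drop = FALSE]
                  mu <- mu[ok]; sdv <- sdv[ok]; m <- sum(ok) }

  groups <- rep(seq_len(n_groups), length.out = n)
  # per-group sufficient statistics (Z = standardized counts, A = ZZ'/m)
  C_g <- vector("list", n_groups)   # Z_g' Z_g
  u_g <- matrix(0, m, n_groups)     # Z_g' y_g
  s_g <- matrix(0, m, n_groups)     # colSums(Z_g)
  tr_g <- sya_g <- saa_g <- sy1_g <- sy2_g <- n_g <- numeric(n_groups)
  for (g in seq_len(n_groups)) {
    rows <- which(groups == g)
    Z <- sweep(sweep(counts[rows, , drop = FALSE] * 1.0, 2L, mu), 2L, sdv, "/")
    yg <- yr[rows]
    C_g[[g]] <- crossprod(Z)
    u_g[, g] <- as.numeric(crossprod(Z, yg))
    s_g[, g] <- colSums(Z)
    aii <- rowSums(Z^2) / m
    tr_g[g] <- sum(aii)
    sya_g[g] <- sum(aii * yg^2)
    saa_g[g] <- sum(aii^2)
    sy1_g[g] <- sum(yg)
    sy2_g[g] <- sum(yg^2)
    n_g[g] <- length(rows)
  }
  C <- Reduce(`+`, C_g)
  u <- rowSums(u_g)
  s <- rowSums(s_g)

  he_slope <- function(Cm, um, sm, tr, sya, saa, sy1, sy2, nn) {
    N <- nn * (nn - 1)
    SA <- sum(sm^2) / m - tr                   # sum over i != j of A_ij
    Sy <- sy1^2 - sy2
    P_Ay <- sum(um^2) / m - sya
    P_AA <- sum(Cm^2) / m^2 - saa
    (P_Ay - SA * Sy / N) / (P_AA - SA^2 / N)
  }
  h2 <- he_slope(C, u, s, sum(tr_g), sum(sya_g), sum(saa_g),
                 sum(sy1_g), sum(sy2_g), n)
  loo <- vapply(seq_len(n_groups), function(g) {
    he_slope(C - C_g[[g]], u - u_g[, g], s - s_g[, g],
             sum(tr_g) - tr_g[g], sum(sya_g) - sya_g[g],
             sum(saa_g) - saa_g[g], sum(sy1_g) - sy1_g[g],
             sum(sy2_g) - sy2_g[g], n - n_g[g])
  }, numeric(1))
  se <- sqrt((n_groups - 1) / n_groups * sum((loo - mean(loo))^2))
  structure(list(h2 = h2, se = se, n = n, m = m, n_groups = n_groups,
                 loo = loo),
            class = "he_h2")
}

#' @export
print.he_h2 <- function(x, ...) {
  cat(sprintf("Haseman-Elston h2 estimate: %.4f (jackknife SE %.4f; n = %d, m = %d)\n",
              x$h2, x$se, x$n, x$m))
  invisible(x)
}

#' Fit inverse proportionality of heritability to phenotypic variance
#'
#' If heritability differences across strata stem from environmental
#' variance alone (fixed genetic variance), then `h2_s = c / var_s`. This
#' fits the through-origin least-squares line of `h2` on `1 / variance`
#' (optionally with a free intercept) and reports per-stratum residuals; when
#' estimator SEs are supplied, a chi-square goodness-of-fit statistic
#' `sum((resid / se)^2)` with `n_strata - n_par` degrees of freedom judges
#' whether the inverse-proportionality hypothesis is consistent with the
#' estimates.
#'
#' @param h2_estimates Per-stratum heritability estimates (length >= 2).
#' @param variances Per-stratum adjusted phenotypic variances (> 0).
#' @param se Optional per-stratum SEs of the heritability estimates.
#' @param intercept Fit a free intercept instead of through-origin?
#' @return Object of class `invprop_fit`: `c` (and `intercept` if fitted),
#'   `fitted`, `residuals`, `rss`, and when `se` is given `chisq`, `df`,
#'   `p_value`.
#' @export
fit_inverse_proportionality <- function(h2_estimates, variances, se = NULL,
                                        intercept = FALSE) {
  if (length(h2_estimates) < 2L) stop("need at least 2 strata")
  if (any(variances <= 0)) stop("variances must be positive")
  x <- 1 / variances
  if (intercept) {
    fit <- lm.fit(cbind(1, x), h2_estimates)
    cf <- fit$coefficients
    fitted <- cf[1L] + cf[2L] * x
    out <- list(c = unname(cf[2L]), intercept = unname(cf[1L]))
    npar <- 2L
  } else {
    cval <- sum(x * h2_estimates) / sum(x^2)
    fitted <- cval * x
    out <- list(c = cval, intercept = 0)
    npar <- 1L
  }
  res <- h2_estimates - fitted
  out$fitted <- fitted
  out$residuals <- res
  out$rss <- sum(res^2)
  if (!is.null(se)) {
    out$chisq <- sum((res / se)^2)
    out$df <- max(length(res) - npar, 1L)
    out$p_value <- stats::pchisq(out$chisq, out$df, lower.tail = FALSE)
  }
  structure(out, class = "invprop_fit")
}

#' @export
print.invprop_fit <- function(x, ...) {
  cat(sprintf("inverse-proportionality fit: h2 = %.4g / variance%s, RSS = %.3g\n",
              x$c,
              if (x$intercept != 0) sprintf(" + %.4g", x$intercept) else "",
              x$rss))
  if (!is.null(x$chisq))
    cat(sprintf("  goodness of fit: chisq = %.3g on %d df (p = %.3g)\n",
                x$chisq, x$df, x$p_value))
  invisible(x)
}
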