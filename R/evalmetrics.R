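r_squared <- function(y, X) {
  n <- length(y)
  M <- cbind(rep(1, n), if (!is.null(X)) as.matrix(X))
  fit <- lm.fit(M, y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant phenotype")
  1 - sum(fit$residuals^2) / tss
}

#' Incremental R-squared of a polygenic score
#'
#' The gain in (unadjusted) R-squared when the score is added to a
#' covariates-only linear model of the trait, both models fit on the same
#' sample: `R2(covariates + score) - R2(covariates)`. Nonnegative in-sample,
#' and invariant under affine transforms of the score or of covariate
#' columns.
#'
#' @param y Numeric phenotype.
#' @param covariates Covariate matrix/data frame or `NULL`.
#' @param score Numeric polygenic score.
#' @return A single number.
#' @export
incremental_r2 <- function(y, covariates = NULL, score) {
  n <- length(y)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2L) stop("need n > n_covariates + 2")
  r_squared(y, cbind(if (!is.null(covariates)) as.matrix(covariates),
                     score = score)) -
    r_squared(y, covariates)
}

# AUC by the concordant-pair (rank) statistic, ties counted 1/2 — identical
# to trapezoidal ROC integration.
auc_rank <- function(y_binary, pred) {
  n1 <- sum(y_binary == 1L); n0 <- sum(y_binary == 0L)
  r <- rank(pred)
  (sum(r[y_binary == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Incremental AUC of a polygenic score for a binary trait
#'
#' AUC of the fitted probabilities from a logistic model with covariates plus
#' score, minus the AUC from covariates alone; AUCs are computed by the
#' rank (concordant-pair) statistic with ties counted one half. Invariant
#' under strictly monotone transforms of the score when no covariates are
#' present.
#'
#' @param y_binary Integer 0/1 outcome with both classes present.
#' @param covariates Covariate matrix/data frame or `NULL`.
#' @param score Numeric polygenic score.
#' @return A single number in `[-1, 1]`.
#' @export
incremental_auc <- function(y_binary, covariates = NULL, score) {
  if (length(unique(y_binary)) < 2L) stop("both classes must be present")
  fit_prob <- function(X) {
    M <- cbind(rep(1, length(y_binary)), if (!is.null(X)) as.matrix(X))
    suppressWarnings(glm.fit(M, y_binary, family = binomial()))$fitted.values
  }
  full <- fit_prob(cbind(if (!is.null(covariates)) as.matrix(covariates),
                         score = score))
  base <- if (is.null(covariates)) rep(0.5, length(y_binary))
          else fit_prob(covariates)
  auc_rank(y_binary, full) - auc_rank(y_binary, base)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Normal approximation with tie and continuity corrections; used
#' to compare per-iteration prediction-accuracy distributions.
#'
#' @param a,b Nonempty numeric vectors.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
}

#' Covariate-adjusted phenotypic variance per stratum
#'
#' Residualizes the pooled phenotype on the covariates, then computes the
#' residual variance within each stratum with a fourth-moment ("delta")
#' standard error: `SE^2 = (m4 - s^4 (n - 3) / (n - 1)) / n`.
#'
#' @param y Numeric phenotype.
#' @param covariates Covariate matrix/data frame or `NULL`.
#' @param strata Stratum label per individual.
#' @return Data frame with columns `stratum`, `n`, `variance`, `se`.
#' @export
stratum_adjusted_variance <- function(y, covariates = NULL, strata) {
  r <- residualize(y, covariates)
  labs <- unique(strata)
  out <- lapply(labs, function(s) {
    x <- r[strata == s]
    n <- length(x)
    if (n < 2L) stop("stratum of size < 2: ", s)
    v <- var(x)
    m4 <- mean((x - mean(x))^4)
    se <- sqrt(max(m4 - v^2 * (n - 3) / (n - 1), 0) / n)
    data.frame(stratum = s, n = n, variance = v, se = se,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
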