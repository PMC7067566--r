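#' Estimate the SE-matched standard-GWAS sample size n*
#'
#' For each grid sample size a standard GWAS is run on a random subsample of
#' the unrelated pool and the median effect-estimate SE recorded. Since the
#' per-SNP OLS standard error scales as `1 / sqrt(n)`, the inverse median SE
#' is linear in `sqrt(n)`; that line is fitted by least squares and inverted
#' at the sibling design's median SE. `n_star` is the smallest integer sample
#' size whose predicted median SE is at or below the sibling median SE —
#' the standard-GWAS size that matches the two designs' sampling noise, and
#' hence their prediction accuracy under a vanilla model with neither
#' indirect effects nor assortative mating.
#'
#' @param sib_stats A `sumstats` data frame from [sib_diff_gwas()].
#' @param pool A `geno_matrix` of the unrelated pool.
#' @param y Phenotypes of the pool.
#' @param covariates Covariates of the pool (or `NULL`).
#' @param grid Increasing integer grid of candidate sample sizes within the
#'   pool.
#' @param seed Integer seed for the grid subsampling.
#' @return Object of class `nstar_fit`: `grid_n`, `median_se`,
#'   `inv_median_se`, `slope`, `intercept`, `r` (correlation of
#'   `1/median_se` with `sqrt(n)`), `sib_median_se`, `n_star`.
#' @export
estimate_n_star <- function(sib_stats, pool, y, covariates = NULL,
                            grid = seq(1000L, 8000L, by = 500L),
                            seed = NULL) {
  stopifnot(inherits(sib_stats, "sumstats"), nrow(sib_stats) > 0L)
  grid <- sort(as.integer(grid))
  n_pool <- nrow(as_counts(pool))
  if (max(grid) > n_pool) stop("grid exceeds the pool size")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  with_seed(seed, {
    med_se <- vapply(grid, function(nn) {
      idx <- sample.int(n_pool, nn)
      ss <- ols_gwas(subset_individuals(pool, idx), y[idx],
                     if (!is.null(C)) C[idx, , drop = FALSE])
      median(ss$se)
    }, numeric(1))
    inv_se <- 1 / med_se
    fit <- lm.fit(cbind(1, sqrt(grid)), inv_se)
    a <- unname(fit$coefficients[1L]); b <- unname(fit$coefficients[2L])
    r <- cor(inv_se, sqrt(grid))
    sib_med <- median(sib_stats$se)
    if (b <= 0) stop("degenerate SE-vs-sqrt(n) fit (nonpositive slope)")
    root <- (1 / sib_med - a) / b
    n_star <- if (root <= 0) 1L else as.integer(ceiling(root^2))
    achievable <- 1 / (a + b * sqrt(c(min(grid), n_pool)))
    if (n_star > n_pool)
      stop(sprintf(paste0("sibling median SE %.4g is not achievable on this",
                          " pool (achievable median SE range ~[%.4g, %.4g])"),
                   sib_med, achievable[2L], achievable[1L]))
    structure(list(grid_n = grid, median_se = med_se, inv_median_se = inv_se,
                   slope = b, intercept = a, r = r,
                   sib_median_se = sib_med, n_star = n_star),
              class = "nstar_fit")
  })
}

#' @export
print.nstar_fit <- function(x, ...) {
  cat(sprintf(paste0("nstar_fit: n* = %d (sib median SE %.4g);",
                     " 1/SE ~ %.4g + %.4g sqrt(n), r = %.4f\n"),
              x$n_star, x$sib_median_se, x$intercept, x$slope, x$r))
  invisible(x)
}

#' @export
plot.nstar_fit <- function(x, ...) {
  plot(sqrt(x$grid_n), x$inv_median_se,
       xlab = "sqrt(sample size)", ylab = "1 / median SE",
       main = "SE matching of standard and sibling GWAS", ...)
  abline(x$intercept, x$slope, lty = 2)
  abline(h = 1 / x$sib_median_se, col = 2)
  points(sqrt(x$n_star), 1 / x$sib_median_se, pch = 19, col = 2)
  invisible(x)
}
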