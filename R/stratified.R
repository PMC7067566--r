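#' Default configuration for the stratified-GWAS experiment
#'
#' Two equally likely strata over a 30,000-strong unrelated cohort with the
#' same panel defaults as [sibcompare_config()]. Amplification and
#' environmental-variance multipliers are set through the `strata` data
#' frame (`a_mult`, `e_mult`).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `stratified_config`.
#' @export
stratified_config <- function(...) {
  cfg <- list(
    n_individuals = 30000L,
    m = 2000L, block_size = 10L, within_block_r = 0.9,
    maf_low = 0.05, maf_high = 0.5,
    m_causal = 500L, h2 = 0.5,
    strata = data.frame(label = c("A", "B"), a_mult = c(1, 1),
                        e_mult = c(1, 1), prob = c(0.5, 0.5),
                        stringsAsFactors = FALSE),
    n_iterations = 20L,
    prediction_n = 3000L,
    p_threshold = 1e-4,
    r2_threshold = 0.1, window_bp = 1000000L,
    ld_ref_n = 5000L,
    include_pooled = FALSE,
    binary = FALSE, binary_quantile = 0.8,
    h2_diagnostics = TRUE)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = c("stratified_config", "list"))
}

#' Run the stratified GWAS-and-prediction experiment
#'
#' Per resampling iteration: hold out an equal-size prediction set in every
#' stratum; from the remainder build one GWAS set per stratum plus a
#' "diverse" GWAS set of the same total size with equal per-stratum counts
#' (sizes matched exactly by down-sampling to the smallest stratum);
#' optionally also a pooled GWAS of all remaining individuals. Each GWAS is
#' clumped at `p_threshold`, turned into a score, and evaluated by
#' incremental R-squared (incremental AUC for a binarized trait) in every
#' prediction stratum. Per-stratum Haseman-Elston heritability and
#' covariate-adjusted phenotypic variance diagnostics are attached.
#'
#' @param config A [stratified_config()] list.
#' @param seed Master integer seed.
#' @return Object of class `stratified_experiment`: `accuracy` (data frame
#'   `iteration`, `gwas_set`, `pred_stratum`, `metric`, `value`, `n_snps`,
#'   `n`), `h2var` (data frame `iteration`, `stratum`, `h2`, `h2_se`,
#'   `variance`, `variance_se`, `n`), `config`.
#' @export
run_stratified_experiment <- function(config = stratified_config(),
                                      seed = NULL) {
  cfg <- config
  with_seed(seed, {
    seeds <- draw_sub_seeds(4L + cfg$n_iterations)
    panel <- make_snp_panel(cfg$m, cfg$maf_low, cfg$maf_high, cfg$block_size,
                            cfg$within_block_r, seed = seeds[1L])
    effects <- draw_effect_sizes(panel, cfg$m_causal, cfg$h2,
                                 strata = cfg$strata, seed = seeds[2L])
    geno <- simulate_unrelated(panel, cfg$n_individuals, seed = seeds[3L])
    ph <- assemble_phenotype(geno, effects, seed = seeds[4L])
    y <- ph$y
    covars <- as.matrix(ph[, c("sex", "age")])
    strat <- ph$stratum
    labs <- cfg$strata$label
    y_bin <- if (cfg$binary) binarize_trait(y, quantile = cfg$binary_quantile)
    gwas_fun <- if (cfg$binary) function(g, idx, snp_ids = NULL)
        logistic_gwas(subset_individuals(g, idx), y_bin[idx],
                      covars[idx, , drop = FALSE], snp_ids = snp_ids)
      else function(g, idx, snp_ids = NULL)
        ols_gwas(subset_individuals(g, idx), y[idx],
                 covars[idx, , drop = FALSE], snp_ids = snp_ids)
    eval_fun <- if (cfg$binary) function(idx, sc)
        incremental_auc(y_bin[idx], covars[idx, , drop = FALSE], sc)
      else function(idx, sc)
        incremental_r2(y[idx], covars[idx, , drop = FALSE], sc)
    metric <- if (cfg$binary) "incremental_auc" else "incremental_r2"

    acc <- list(); h2var <- list()
    for (it in seq_len(cfg$n_iterations)) {
      out <- with_seed(seeds[4L + it], {
        pred_idx <- lapply(labs, function(s) {
          rows <- which(strat == s)
          if (length(rows) <= cfg$prediction_n)
            stop("infeasible split: stratum ", s, " too small")
          sample(rows, cfg$prediction_n)
        })
        names(pred_idx) <- labs
        remain <- lapply(labs, function(s)
          setdiff(which(strat == s), pred_idx[[s]]))
        names(remain) <- labs
        G <- min(lengths(remain))
        G <- length(labs) * (G %/% length(labs))  # divisible total
        gwas_sets <- lapply(labs, function(s) sample(remain[[s]], G))
        names(gwas_sets) <- labs
        per <- G %/% length(labs)
        gwas_sets$diverse <- unlist(lapply(labs, function(s)
          sample(remain[[s]], per)), use.names = FALSE)
        if (cfg$include_pooled)
          gwas_sets$pooled <- unlist(remain, use.names = FALSE)

        ld_ref <- subset_individuals(
          geno, sample(unlist(remain, use.names = FALSE),
                       min(cfg$ld_ref_n, sum(lengths(remain)))))
        rows <- list()
        for (gs in names(gwas_sets)) {
          stats <- suppressMessages(gwas_fun(geno, gwas_sets[[gs]]))
          sel <- clump(stats, ld_ref, cfg$p_threshold,
                       r2_threshold = cfg$r2_threshold,
                       window_bp = cfg$window_bp)
          model <- build_score_model(stats, sel, cfg$p_threshold)
          for (s in labs) {
            stopifnot(!length(intersect(pred_idx[[s]], gwas_sets[[gs]])))
            sc <- score_individuals(
              subset_individuals(geno, pred_idx[[s]]), model)
            rows[[length(rows) + 1L]] <-
              data.frame(iteration = it, gwas_set = gs, pred_stratum = s,
                         metric = metric, value = eval_fun(pred_idx[[s]], sc),
                         n_snps = length(sel), n = length(pred_idx[[s]]),
                         stringsAsFactors = FALSE)
          }
        }
        hv <- NULL
        if (cfg$h2_diagnostics) {
          av <- stratum_adjusted_variance(
            y[unlist(remain)], covars[unlist(remain), , drop = FALSE],
            strat[unlist(remain)])
          hv <- do.call(rbind, lapply(labs, function(s) {
            idx <- gwas_sets[[s]]
            he <- h2_moment_estimate(subset_individuals(geno, idx), y[idx],
                                     covars[idx, , drop = FALSE],
                                     causal_ids = effects$causal_ids)
            a <- av[av$stratum == s, ]
            data.frame(iteration = it, stratum = s, h2 = he$h2,
                       h2_se = he$se, variance = a$variance,
                       variance_se = a$se, n = length(idx),
                       stringsAsFactors = FALSE)
          }))
        }
        list(acc = do.call(rbind, rows), h2var = hv)
      })
      acc[[it]] <- out$acc
      h2var[[it]] <- out$h2var
    }
    structure(list(accuracy = do.call(rbind, acc),
                   h2var = if (cfg$h2_diagnostics) do.call(rbind, h2var),
                   config = cfg, effects = effects),
              class = "stratified_experiment")
  })
}

#' @export
print.stratified_experiment <- function(x, ...) {
  a <- x$accuracy
  cat(sprintf("stratified_experiment: %d iterations, GWAS sets: %s\n",
              max(a$iteration), paste(unique(a$gwas_set), collapse = ", ")))
  print(summary(x))
  invisible(x)
}

#' @export
summary.stratified_experiment <- function(object, ...) {
  a <- object$accuracy
  agg <- stats::aggregate(value ~ gwas_set + pred_stratum, data = a, median)
  names(agg)[3L] <- paste0("median_", a$metric[1L])
  agg
}

#' @export
plot.stratified_experiment <- function(x, ...) {
  a <- x$accuracy
  boxplot(value ~ pred_stratum + gwas_set, data = a,
          xlab = "prediction stratum . GWAS set", ylab = a$metric[1L], ...)
  invisible(x)
}

#' Re-estimate ascertained SNP effects within each prediction stratum
#'
#' For SNPs ascertained in a discovery sample (disjoint from the strata used
#' here), re-estimates each SNP's effect separately in every stratum by a
#' standard covariate-adjusted GWAS, after orienting all SNPs so the
#' discovery effect is positive (the trait-increasing allele). Reports the
#' per-stratum mean re-estimated effect and the cross-stratum slope of the
#' first stratum's effects on the second's.
#'
#' Because the regressor (the second stratum's estimates) carries sampling
#' noise, the naive OLS slope is attenuated; the primary `slope` therefore
#' uses the standard errors-in-variables moment correction
#' `sum(bA * bB) / (sum(bB^2) - sum(se_B^2))`, with a jackknife-over-SNPs
#' standard error. The uncorrected slope is returned as `slope_naive`.
#'
#' @param selected_snps Character vector of ascertained SNP ids.
#' @param stats_discovery `sumstats` of the discovery GWAS (for
#'   orientation).
#' @param strata_data Named list (one element per stratum) of lists with
#'   elements `genotypes`, `y`, `covariates`, and optionally `ids`.
#' @param discovery_ids Optional individual ids of the discovery sample; an
#'   error is raised if they overlap any stratum's `ids`.
#' @return Object of class `stratum_effects`: `effects` (data frame of
#'   oriented per-SNP estimates and SEs per stratum), `per_stratum` (mean
#'   effects), `slope`, `slope_se`, `slope_naive`, `slope_pair`.
#' @export
reestimate_effects_by_stratum <- function(selected_snps, stats_discovery,
                                          strata_data,
                                          discovery_ids = NULL) {
  stopifnot(length(strata_data) >= 2L, !is.null(names(strata_data)))
  if (!is.null(discovery_ids)) {
    for (s in names(strata_data)) {
      ids <- strata_data[[s]]$ids
      if (is.null(ids)) ids <- rownames(as_counts(strata_data[[s]]$genotypes))
      if (length(intersect(discovery_ids, ids)))
        stop("ascertainment and re-estimation samples overlap in stratum ", s)
    }
  }
  di <- match(selected_snps, stats_discovery$id)
  if (anyNA(di))
    stop("selected SNP(s) absent from the discovery statistics")
  disc_beta <- stats_discovery$beta[di]
  disc_ea <- stats_discovery$ea[di]

  est <- lapply(names(strata_data), function(s) {
    d <- strata_data[[s]]
    ss <- suppressMessages(
      ols_gwas(d$genotypes, d$y, d$covariates, snp_ids = selected_snps))
    i <- match(selected_snps, ss$id)
    # express the discovery effect on this GWAS's effect allele, then
    # orient every SNP so its discovery effect is positive
    disc_aligned <- ifelse(disc_ea == ss$ea[i], disc_beta, -disc_beta)
    orient <- ifelse(disc_aligned >= 0, 1, -1)
    data.frame(snp_id = selected_snps, stratum = s,
               beta = orient * ss$beta[i], se = ss$se[i],
               stringsAsFactors = FALSE)
  })
  eff <- do.call(rbind, est)
  per_stratum <- stats::aggregate(beta ~ stratum, data = eff, mean)
  names(per_stratum)[2L] <- "mean_beta"
  per_stratum$se_mean <- vapply(per_stratum$stratum, function(s) {
    b <- eff$beta[eff$stratum == s]
    stats::sd(b) / sqrt(length(b))
  }, numeric(1))

  sa <- names(strata_data)[1L]; sb <- names(strata_data)[2L]
  bA <- eff$beta[eff$stratum == sa]; seA <- eff$se[eff$stratum == sa]
  bB <- eff$beta[eff$stratum == sb]; seB <- eff$se[eff$stratum == sb]
  ok <- is.finite(bA) & is.finite(bB)
  bA <- bA[ok]; bB <- bB[ok]; seB <- seB[ok]
  eiv_slope <- function(idx) {
    sum(bA[idx] * bB[idx]) / (sum(bB[idx]^2) - sum(seB[idx]^2))
  }
  slope <- eiv_slope(seq_along(bA))
  nsnp <- length(bA)
  loo <- vapply(seq_len(nsnp), function(j) eiv_slope(setdiff(seq_len(nsnp), j)),
                numeric(1))
  slope_se <- sqrt((nsnp - 1) / nsnp * sum((loo - mean(loo))^2))
  slope_naive <- sum(bA * bB) / sum(bB^2)

  structure(list(effects = eff, per_stratum = per_stratum,
                 slope = slope, slope_se = slope_se,
                 slope_naive = slope_naive, slope_pair = c(sa, sb)),
            class = "stratum_effects")
}

#' @export
print.stratum_effects <- function(x, ...) {
  cat(sprintf("stratum_effects: %d SNPs; slope %s-on-%s = %.3f (SE %.3f; naive %.3f)\n",
              sum(x$effects$stratum == x$slope_pair[1L]),
              x$slope_pair[1L], x$slope_pair[2L],
              x$slope, x$slope_se, x$slope_naive))
  print(x$per_stratum, row.names = FALSE)
  invisible(x)
}
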