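#' Default configuration for the sibling-versus-standard comparison
#'
#' Desk-scale defaults: a 30,000-strong unrelated pool, 4,000 sibling pairs,
#' a 2,000-SNP panel in blocks of 10 with adjacent haplotype correlation
#' 0.9, 500 causal SNPs and heritability 0.5. Any element can be overridden
#' through `...` (e.g. `run_sib_compare(sibcompare_config(am_strength = 0.4,
#' n_iterations = 10), seed = 1)`).
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `sibcompare_config`.
#' @export
sibcompare_config <- function(...) {
  cfg <- list(
    # simulation
    n_unrelated = 30000L, n_families = 4000L,
    m = 2000L, block_size = 10L, within_block_r = 0.9,
    maf_low = 0.05, maf_high = 0.5,
    m_causal = 500L, h2 = 0.5,
    rho_di = 0, indirect_scale = 0, eta = 0, am_strength = 0,
    sex_effect = 0,
    # design
    n_trait_replicates = 1L,
    n_iterations = 10L,
    thresholds = threshold_grid(),
    r2_threshold = 0.1, window_bp = 1000000L,
    nstar_grid = seq(1000L, 8000L, by = 500L),
    nstar_mode = "per_iteration",      # or "once"
    prediction_frac = 0.1,
    ld_ref_n = 5000L)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = c("sibcompare_config", "list"))
}

#' Run the sibling-versus-standard polygenic score comparison
#'
#' End-to-end experiment: simulate one cohort under the configured
#' generative model, then, per resampling iteration, (1) estimate the
#' SE-matched standard sample size `n*` ([estimate_n_star()]); (2) remove an
#' `n*`-sized estimation set from the unrelated pool and split the remainder
#' into prediction (`prediction_frac`) and discovery sets; (3) run the
#' discovery GWAS; (4) for each p-value threshold, clump and ascertain SNPs;
#' (5) re-estimate the ascertained SNPs' effects by a standard GWAS on the
#' `n*` set and by the sibling-difference GWAS on the families; (6) score
#' the prediction set with both weight sets over the identical SNP list;
#' (7) record both incremental R-squared values and their ratio.
#'
#' Discovery, estimation and prediction individuals are disjoint within an
#' iteration, and the sibling set never overlaps the unrelated pool.
#' Thresholds at which no SNP is ascertained produce explicit missing rows.
#'
#' With `n_trait_replicates > 1` the whole comparison is repeated over
#' independently redrawn traits (fresh causal effects and environmental
#' draws on the same genotypes; fresh cohorts when the model includes
#' indirect effects or assortative mating, since those shape the
#' genotype-phenotype structure of the parental generation). Replicates
#' refresh the sibling-GWAS estimation noise, which is otherwise a single
#' frozen realization shared by all iterations — the analogue of validating
#' the design over several simulated replicate traits rather than one.
#'
#' @param config A [sibcompare_config()] list.
#' @param seed Master integer seed; the whole experiment (simulation and all
#'   subsampling) is reproducible from it.
#' @param cohort Optionally, a pre-simulated [simulate_cohort()] object to
#'   reuse across scenario comparisons (its generative settings then
#'   override the simulation section of `config`).
#' @return Object of class `sib_compare`: list with `results` (data frame
#'   `replicate`, `iteration`, `p_threshold`, `n_snps`, `r2_standard`,
#'   `r2_sib`, `ratio`, `n_star`, `med_se_standard`, `med_se_sib`),
#'   `config`, `spousal_cor` (of the last replicate's cohort).
#' @export
run_sib_compare <- function(config = sibcompare_config(), seed = NULL,
                            cohort = NULL) {
  cfg <- config
  with_seed(seed, {
    rep_seeds <- draw_sub_seeds(2L * cfg$n_trait_replicates)
    fresh_each <- cfg$eta != 0 || cfg$am_strength != 0
    reps <- vector("list", cfg$n_trait_replicates)
    spousal <- NA_real_
    for (rep in seq_len(cfg$n_trait_replicates)) {
      if (rep == 1L) {
        if (is.null(cohort)) cohort <- sib_compare_cohort(cfg, rep_seeds[1L])
      } else if (fresh_each) {
        cohort <- sib_compare_cohort(cfg, rep_seeds[2L * rep - 1L])
      } else {
        eff_r <- draw_effect_sizes(cohort$panel, cfg$m_causal, cfg$h2,
                                   seed = rep_seeds[2L * rep - 1L])
        cohort <- cohort_with_new_trait(cohort, eff_r,
                                        seed = rep_seeds[2L * rep],
                                        sex_effect = cfg$sex_effect)
      }
      spousal <- cohort$spousal_cor
      d <- with_seed(rep_seeds[2L * rep] %% 2000000000L + 13L,
                     sib_compare_pipeline(cohort, cfg))
      d$replicate <- rep
      reps[[rep]] <- d
    }
    res <- do.call(rbind, reps)
    res <- res[, c("replicate", setdiff(names(res), "replicate"))]
    structure(list(results = res, config = cfg, spousal_cor = spousal),
              class = "sib_compare")
  })
}

# simulate the full cohort of a sib-compare run from its config
sib_compare_cohort <- function(cfg, seed) {
  with_seed(seed, {
    seeds <- draw_sub_seeds(3L)
    panel <- make_snp_panel(cfg$m, cfg$maf_low, cfg$maf_high,
                            cfg$block_size, cfg$within_block_r,
                            seed = seeds[1L])
    effects <- draw_effect_sizes(panel, cfg$m_causal, cfg$h2,
                                 rho_di = cfg$rho_di,
                                 indirect_scale = cfg$indirect_scale,
                                 eta = cfg$eta,
                                 am_strength = cfg$am_strength,
                                 seed = seeds[2L])
    simulate_cohort(panel, effects, cfg$n_unrelated, cfg$n_families,
                    seed = seeds[3L], sex_effect = cfg$sex_effect)
  })
}

# one replicate of the comparison: sibling GWAS once, then the configured
# number of resampling iterations; runs inside a seeded context
sib_compare_pipeline <- function(cohort, cfg) {
  {
    ph <- cohort$pheno
    unrel <- cohort$unrelated
    fam <- cohort$families
    u_rows <- which(ph$set == "unrelated")
    y_u <- ph$y[u_rows]
    cov_u <- as.matrix(ph[u_rows, c("sex", "age")])
    s1 <- which(ph$set == "sib" & ph$sib_index == 1L)
    s2 <- which(ph$set == "sib" & ph$sib_index == 2L)

    # the sibling set is fixed, so its GWAS is computed once per replicate
    sib_stats <- sib_diff_gwas(fam, ph$y[s1], ph$y[s2],
                               as.matrix(ph[s1, c("sex", "age")]),
                               as.matrix(ph[s2, c("sex", "age")]))
    n_pool <- length(y_u)
    it_seeds <- draw_sub_seeds(1L + cfg$n_iterations)
    nstar_once <- if (cfg$nstar_mode == "once")
      estimate_n_star(sib_stats, unrel, y_u, cov_u, grid = cfg$nstar_grid,
                      seed = it_seeds[1L])

    res <- vector("list", cfg$n_iterations)
    for (it in seq_len(cfg$n_iterations)) {
      res[[it]] <- with_seed(it_seeds[1L + it], {
        nf <- if (cfg$nstar_mode == "once") nstar_once
              else estimate_n_star(sib_stats, unrel, y_u, cov_u,
                                   grid = cfg$nstar_grid,
                                   seed = draw_sub_seeds(1L))
        n_star <- nf$n_star
        perm <- sample.int(n_pool)
        est_idx <- perm[seq_len(n_star)]
        rest <- perm[(n_star + 1L):n_pool]
        n_pred <- max(2L, round(cfg$prediction_frac * length(rest)))
        pred_idx <- rest[seq_len(n_pred)]
        disc_idx <- rest[(n_pred + 1L):length(rest)]
        stopifnot(!anyDuplicated(c(est_idx, pred_idx, disc_idx)))

        disc_stats <- ols_gwas(subset_individuals(unrel, disc_idx),
                               y_u[disc_idx],
                               cov_u[disc_idx, , drop = FALSE])
        ld_ref <- subset_individuals(
          unrel, sample(disc_idx, min(cfg$ld_ref_n, length(disc_idx))))
        est_geno <- subset_individuals(unrel, est_idx)
        pred_geno <- subset_individuals(unrel, pred_idx)
        y_pred <- y_u[pred_idx]
        cov_pred <- cov_u[pred_idx, , drop = FALSE]

        rows <- lapply(cfg$thresholds, function(thr) {
          sel <- clump(disc_stats, ld_ref, thr,
                       r2_threshold = cfg$r2_threshold,
                       window_bp = cfg$window_bp)
          sel <- intersect(sel, sib_stats$id)  # estimable in both designs
          if (!length(sel))
            return(data.frame(iteration = it, p_threshold = thr,
                              n_snps = 0L, r2_standard = NA_real_,
                              r2_sib = NA_real_, ratio = NA_real_,
                              n_star = n_star,
                              med_se_standard = NA_real_,
                              med_se_sib = NA_real_))
          est_stats <- suppressMessages(
            ols_gwas(est_geno, y_u[est_idx],
                     cov_u[est_idx, , drop = FALSE], snp_ids = sel))
          sel <- intersect(sel, est_stats$id)
          model_std <- build_score_model(est_stats, sel, thr)
          model_sib <- build_score_model(sib_stats, sel, thr)
          sc_std <- score_individuals(pred_geno, model_std)
          sc_sib <- score_individuals(pred_geno, model_sib)
          r2_std <- incremental_r2(y_pred, cov_pred, sc_std)
          r2_sib <- incremental_r2(y_pred, cov_pred, sc_sib)
          data.frame(iteration = it, p_threshold = thr,
                     n_snps = length(sel),
                     r2_standard = r2_std, r2_sib = r2_sib,
                     ratio = r2_sib / r2_std, n_star = n_star,
                     med_se_standard = median(est_stats$se),
                     med_se_sib = median(
                       sib_stats$se[match(sel, sib_stats$id)]))
        })
        do.call(rbind, rows)
      })
    }
    do.call(rbind, res)
  }
}

#' @export
print.sib_compare <- function(x, ...) {
  r <- x$results
  cat(sprintf("sib_compare: %d replicate(s) x %d iterations x %d thresholds (spousal r = %.3f)\n",
              max(r$replicate), max(r$iteration),
              length(unique(r$p_threshold)), x$spousal_cor))
  print(threshold_sweep(x))
  invisible(x)
}

#' Summarize the accuracy ratio across p-value thresholds
#'
#' Per-threshold median and central 80 percent interval of the
#' sibling/standard incremental-R-squared ratio, along with the median SNP
#' count — the number of SNPs in the score is nondecreasing as the threshold
#' is relaxed.
#'
#' @param report A [run_sib_compare()] result.
#' @return Data frame with one row per threshold: `p_threshold`,
#'   `n_iterations`, `n_missing`, `median_n_snps`, `median_ratio`,
#'   `ratio_q10`, `ratio_q90`.
#' @export
threshold_sweep <- function(report) {
  r <- report$results
  if (length(unique(r$p_threshold)) < 2L)
    stop("need results at >= 2 thresholds")
  out <- lapply(split(r, r$p_threshold), function(d) {
    ok <- is.finite(d$ratio)
    data.frame(p_threshold = d$p_threshold[1L],
               n_iterations = nrow(d), n_missing = sum(!ok),
               median_n_snps = median(d$n_snps),
               median_ratio = if (any(ok)) median(d$ratio[ok]) else NA_real_,
               ratio_q10 = if (any(ok))
                 quantile(d$ratio[ok], 0.1, names = FALSE) else NA_real_,
               ratio_q90 = if (any(ok))
                 quantile(d$ratio[ok], 0.9, names = FALSE) else NA_real_)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$p_threshold), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
summary.sib_compare <- function(object, ...) threshold_sweep(object)

#' @export
plot.sib_compare <- function(x, ...) {
  r <- x$results[is.finite(x$results$ratio), ]
  boxplot(ratio ~ factor(p_threshold), data = r,
          xlab = "discovery p-value threshold",
          ylab = "incremental R2 ratio (sib / standard)", ...)
  abline(h = 1, lty = 2)
  invisible(x)
}
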