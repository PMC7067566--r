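# A compact cohort reused by several experiment tests.
small_cfg <- function(...) {
  sibcompare_config(n_unrelated = 5000L, n_families = 1000L, m = 400L,
                    m_causal = 100L, n_iterations = 3L,
                    nstar_grid = seq(400L, 3000L, 400L), ld_ref_n = 1500L,
                    ...)
}

test_that("n* matching equalizes the median standard errors", {
  cfg <- small_cfg()
  p <- make_snp_panel(cfg$m, cfg$maf_low, cfg$maf_high, cfg$block_size,
                      cfg$within_block_r, seed = 200)
  eff <- draw_effect_sizes(p, cfg$m_causal, cfg$h2, seed = 201)
  coh <- simulate_cohort(p, eff, cfg$n_unrelated, cfg$n_families, seed = 202)
  ph <- coh$pheno
  u <- ph$set == "unrelated"
  s1 <- ph$set == "sib" & ph$sib_index == 1
  s2 <- ph$set == "sib" & ph$sib_index == 2
  sib <- sib_diff_gwas(coh$families, ph$y[s1], ph$y[s2],
                       sexage(ph[s1, ]), sexage(ph[s2, ]))
  nf <- estimate_n_star(sib, coh$unrelated, ph$y[u], sexage(ph[u, ]),
                        grid = cfg$nstar_grid, seed = 203)
  # linearity of 1/median SE in sqrt(n)
  expect_gte(nf$r, 0.99)
  # direct recomputation at n*: median SE within 5% of the sib median SE
  set.seed(204)
  idx <- sample(sum(u), nf$n_star)
  ss <- ols_gwas(subset_individuals(coh$unrelated, idx), ph$y[u][idx],
                 sexage(ph[u, ])[idx, ])
  expect_lt(abs(median(ss$se) / nf$sib_median_se - 1), 0.05)

  # self-consistency: a sib median SE equal to an observed grid SE maps back
  sib2 <- sib
  sib2$se <- sib$se * nf$median_se[4] / nf$sib_median_se
  nf2 <- estimate_n_star(sib2, coh$unrelated, ph$y[u], sexage(ph[u, ]),
                         grid = cfg$nstar_grid, seed = 203)
  expect_lt(abs(nf2$n_star / cfg$nstar_grid[4] - 1), 0.1)

  # an unreachable sib SE raises with the achievable range
  sib3 <- sib
  sib3$se <- sib$se / 50
  expect_error(estimate_n_star(sib3, coh$unrelated, ph$y[u],
                               sexage(ph[u, ]), grid = cfg$nstar_grid,
                               seed = 203),
               "achievable")
})

test_that("the sib-compare runner enforces disjointness, fairness and reproducibility", {
  cfg <- small_cfg(thresholds = c(1e-4, 1e-2))
  r <- run_sib_compare(cfg, seed = 210)
  d <- r$results
  expect_identical(nrow(d), 6L)  # 3 iterations x 2 thresholds
  # fairness is structural (same SNP list, same prediction set); check the
  # reported cells are coherent
  expect_true(all(d$n_snps[d$p_threshold == 1e-2] >=
                  d$n_snps[d$p_threshold == 1e-4]))
  ok <- is.finite(d$ratio)
  expect_true(all(abs(d$ratio[ok] - d$r2_sib[ok] / d$r2_standard[ok]) < 1e-12))
  # SE matching carried through to the ascertained SNPs
  expect_lt(abs(median(d$med_se_standard / d$med_se_sib, na.rm = TRUE) - 1),
            0.25)
  # bit-reproducibility of the full experiment
  r2 <- run_sib_compare(cfg, seed = 210)
  expect_identical(r$results, r2$results)
  # threshold_sweep summarises per threshold
  sw <- threshold_sweep(r)
  expect_identical(sw$p_threshold, c(1e-4, 1e-2))
  expect_true(all(diff(sw$median_n_snps) >= 0))
})

test_that("stratified runner: exchangeable strata are indistinguishable and splits are exact", {
  cfg <- stratified_config(n_individuals = 6000L, m = 300L, m_causal = 100L,
                           n_iterations = 6L, prediction_n = 600L,
                           ld_ref_n = 1500L, p_threshold = 1e-3,
                           h2_diagnostics = FALSE)
  r <- run_stratified_experiment(cfg, seed = 220)
  a <- r$accuracy
  expect_setequal(unique(a$gwas_set), c("A", "B", "diverse"))
  # exchangeability null: across-iteration accuracy distributions do not
  # differ between prediction strata (Bonferroni over GWAS sets)
  ps <- vapply(unique(a$gwas_set), function(gs) {
    rank_sum_test(a$value[a$gwas_set == gs & a$pred_stratum == "A"],
                  a$value[a$gwas_set == gs & a$pred_stratum == "B"])
  }, numeric(1))
  expect_gt(min(ps) * length(ps), 0.01)
  # reproducibility
  r2 <- run_stratified_experiment(cfg, seed = 220)
  expect_identical(r$accuracy, r2$accuracy)
})

test_that("pooling exchangeable strata into a larger GWAS does not hurt accuracy", {
  cfg <- stratified_config(n_individuals = 8000L, m = 300L, m_causal = 100L,
                           n_iterations = 4L, prediction_n = 800L,
                           ld_ref_n = 1500L, p_threshold = 1e-3,
                           include_pooled = TRUE, h2_diagnostics = FALSE)
  r <- run_stratified_experiment(cfg, seed = 221)
  a <- r$accuracy
  med <- tapply(a$value, a$gwas_set, median)
  single <- max(med[c("A", "B")])
  # the pooled GWAS has about twice the sample size of each stratum GWAS
  expect_gt(med[["pooled"]], single - 0.02)
})

test_that("per-stratum effect re-estimation recovers homogeneity and rejects overlap", {
  p <- unlinked_panel(m = 300, seed = 230)
  eff <- draw_effect_sizes(p, 150, h2 = 0.5, seed = 231)
  g <- simulate_unrelated(p, 9000, seed = 232)
  ph <- assemble_phenotype(g, eff, seed = 233)
  disc <- 1:4000; sA <- 4001:6500; sB <- 6501:9000
  ss <- ols_gwas(subset_individuals(g, disc), ph$y[disc],
                 sexage(ph)[disc, ])
  sel <- ss$id[order(ss$p)][1:60]
  sdat <- list(
    A = list(genotypes = subset_individuals(g, sA), y = ph$y[sA],
             covariates = sexage(ph)[sA, ]),
    B = list(genotypes = subset_individuals(g, sB), y = ph$y[sB],
             covariates = sexage(ph)[sB, ]))
  re <- reestimate_effects_by_stratum(sel, ss, sdat,
                                      discovery_ids = g$ids[disc])
  # homogeneous effects: cross-stratum slope = 1 within 2 SE
  expect_lt(abs(re$slope - 1), 2 * re$slope_se)
  # trait-increasing orientation: recoding every discovery SNP to its other
  # allele (swap EA/OA, negate beta) leaves the per-stratum means unchanged
  ss_fl <- ss
  ss_fl$beta <- -ss$beta
  ss_fl$ea <- ss$oa; ss_fl$oa <- ss$ea
  re_fl <- reestimate_effects_by_stratum(sel, ss_fl, sdat,
                                         discovery_ids = g$ids[disc])
  expect_equal(re_fl$per_stratum$mean_beta, re$per_stratum$mean_beta,
               tolerance = 1e-12)
  # ascertainment / re-estimation overlap is an error
  expect_error(
    reestimate_effects_by_stratum(sel, ss, sdat,
                                  discovery_ids = g$ids[c(disc, 4001L)]),
    "overlap")
})

test_that("configs validate their fields and YAML round-trips", {
  expect_error(sibcompare_config(nope = 1), "unknown config")
  expect_error(stratified_config(nope = 1), "unknown config")
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 7",
    "sibcompare:",
    "  n_unrelated: 1000",
    "  n_families: 200",
    "  n_iterations: 2",
    "  thresholds: [1.0e-4, 1.0e-2]",
    "stratified:",
    "  n_individuals: 2000",
    "  strata:",
    "    - {label: A, a_mult: 1.3, e_mult: 1.0, prob: 0.5}",
    "    - {label: B, a_mult: 1.0, e_mult: 1.0, prob: 0.5}"
  ), path)
  cfg <- read_config(path)
  expect_s3_class(cfg$sibcompare, "sibcompare_config")
  expect_identical(cfg$sibcompare$n_unrelated, 1000L)
  expect_equal(cfg$sibcompare$thresholds, c(1e-4, 1e-2))
  expect_identical(cfg$stratified$strata$label, c("A", "B"))
  expect_equal(cfg$stratified$strata$a_mult, c(1.3, 1))
  expect_identical(cfg$seed, 7L)
})

test_that("the simulated-trait design grid enumerates twelve traits", {
  d <- simulated_trait_designs()
  expect_identical(nrow(d), 12L)
  expect_setequal(unique(d$h2), c(0.1, 0.5))
  expect_setequal(unique(d$m_causal), c(10000L, 100000L))
  expect_identical(max(d$replicate), 3L)
})
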