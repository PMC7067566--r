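test_that("residualize matches the normal-equations projection oracle", {
  set.seed(60)
  y <- rnorm(30)
  C <- matrix(rnorm(60), 30, 2)
  r <- residualize(y, C)
  M <- cbind(1, C)
  oracle <- y - M %*% solve(crossprod(M), crossprod(M, y))
  expect_lt(max(abs(r - oracle)), 1e-9)
  # orthogonality to every covariate column
  expect_lt(max(abs(crossprod(M, r))) / sqrt(sum(y^2)), 1e-8)
  # no covariates: mean-centering
  expect_equal(residualize(y), y - mean(y))
  # exact linear dependence: zero residuals
  y2 <- 2 + 3 * C[, 1] - C[, 2]
  expect_lt(max(abs(residualize(y2, C))), 1e-10)
  expect_error(residualize(y, cbind(C, C[, 1])), "rank deficient")
})

test_that("ols_gwas matches the one-SNP-at-a-time full regression oracle", {
  sc <- tiny_scene(n = 50, m = 5, m_causal = 5, seed = 61, block_size = 1,
                   r = 0)
  C <- sexage(sc$pheno)
  ss <- ols_gwas(sc$geno, sc$pheno$y, C)
  for (j in 1:5) {
    fit <- summary(lm(sc$pheno$y ~ sc$geno$counts[, j] + C))
    co <- fit$coefficients[2, ]
    expect_lt(abs(ss$beta[j] - co[1]), 1e-8)
    expect_lt(abs(ss$se[j] - co[2]), 1e-8)
    expect_lt(abs(ss$p[j] - co[4]), 1e-8)
  }
  expect_identical(ss$n, rep(50L, 5))
})

test_that("p-values are consistent with beta/se under the t reference", {
  sc <- tiny_scene(n = 120, m = 30, seed = 62)
  ss <- ols_gwas(sc$geno, sc$pheno$y, sexage(sc$pheno))
  df <- 120 - 2 - 2
  expect_lt(max(abs(ss$p - 2 * pt(-abs(ss$beta / ss$se), df))), 1e-6)
})

test_that("null standard GWAS is calibrated at alpha = 0.05", {
  p <- unlinked_panel(m = 2000, seed = 63)
  g <- simulate_unrelated(p, 1500, seed = 64)
  set.seed(65)
  y <- rnorm(1500)
  C <- cbind(sex = rbinom(1500, 1, 0.5), age = runif(1500, 40, 70))
  ss <- ols_gwas(g, y, C)
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 0.01)
})

test_that("monomorphic SNPs are excluded, not emitted as NaN", {
  sc <- tiny_scene(n = 60, m = 10, m_causal = 5, seed = 66)
  sc$geno$counts[, 3] <- 1L
  expect_message(ss <- ols_gwas(sc$geno, sc$pheno$y, sexage(sc$pheno)),
                 "excluded 1")
  expect_equal(nrow(ss), 9)
  expect_false(sc$panel$snp_id[3] %in% ss$id)
  expect_identical(attr(ss, "excluded"), sc$panel$snp_id[3])
  expect_true(all(is.finite(ss$beta)))
})

test_that("logistic_gwas matches the 2x2 closed-form odds-ratio oracle", {
  # balanced table (40,10 / 10,40) encoded as a binary SNP
  x <- c(rep(1L, 50), rep(0L, 50))
  y <- c(rep(1L, 40), rep(0L, 10), rep(1L, 10), rep(0L, 40))
  counts <- matrix(x, 100, 1, dimnames = list(NULL, "s1"))
  ss <- logistic_gwas(counts, y)
  expect_lt(abs(ss$beta - log(16)), 1e-3)
  expect_lt(abs(ss$se - sqrt(1/40 + 1/10 + 1/10 + 1/40)), 1e-3)
})

test_that("null logistic GWAS is calibrated", {
  p <- unlinked_panel(m = 1000, seed = 67)
  g <- simulate_unrelated(p, 800, seed = 68)
  set.seed(69)
  y <- rbinom(800, 1, 0.3)
  ss <- logistic_gwas(g, y)
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 0.015)
})

test_that("logistic_gwas rejects single-class outcomes and drops separated SNPs", {
  counts <- matrix(rbinom(200, 2, 0.3), 100, 2,
                   dimnames = list(NULL, c("s1", "s2")))
  expect_error(logistic_gwas(counts, rep(1L, 100)), "both outcome classes")
  # perfect separation at s1
  y <- as.integer(counts[, 1] > 0)
  expect_message(ss <- logistic_gwas(counts, y), "excluded")
  expect_false("s1" %in% ss$id)
})

test_that("sib_diff_gwas matches brute-force OLS on the differenced data", {
  fx <- local({
    p <- tiny_panel(m = 15, seed = 70)
    g <- simulate_unrelated(p, 400, seed = 71, keep_haplotypes = TRUE)
    co <- mate_parents(rep(0, 400), 0, seed = 72)
    simulate_offspring(co, g, 2L, seed = 73)
  })
  n_fam <- 200L
  set.seed(74)
  y1 <- rnorm(n_fam) + fx$offspring[[1]][, 1] * 0.3
  y2 <- rnorm(n_fam) + fx$offspring[[2]][, 1] * 0.3
  C1 <- cbind(age = runif(n_fam, 40, 70), sex = rbinom(n_fam, 1, 0.5))
  C2 <- cbind(age = runif(n_fam, 40, 70), sex = rbinom(n_fam, 1, 0.5))
  ss <- sib_diff_gwas(fx, y1, y2, C1, C2)
  r <- residualize(c(y1, y2), rbind(C1, C2))
  dy <- r[1:n_fam] - r[n_fam + 1:n_fam]
  for (j in c(1, 5, 15)) {
    dx <- fx$offspring[[1]][, j] - fx$offspring[[2]][, j]
    fit <- summary(lm(dy ~ dx))$coefficients[2, ]
    i <- match(colnames(fx$offspring[[1]])[j], ss$id)
    expect_lt(abs(ss$beta[i] - fit[1]), 1e-8)
    expect_lt(abs(ss$se[i] - fit[2]), 1e-8)
    expect_lt(abs(ss$p[i] - fit[4]), 1e-8)
  }
  expect_identical(ss$n[1], n_fam)

  # identical phenotypes within every pair: all beta exactly 0
  ss0 <- sib_diff_gwas(fx, y1, y1, C1, C1)
  expect_lt(max(abs(ss0$beta)), 1e-12)

  # reversing the within-pair order flips both differences, so beta, se
  # and p are all invariant
  fx_rev <- fx
  fx_rev$offspring <- fx$offspring[2:1]
  ss_rev <- sib_diff_gwas(fx_rev, y2, y1, C2, C1)
  expect_equal(ss_rev$beta, ss$beta, tolerance = 1e-10)
  expect_equal(ss_rev$se, ss$se, tolerance = 1e-10)
  expect_equal(ss_rev$p, ss$p, tolerance = 1e-10)
})

test_that("null sibling GWAS is calibrated and unbiased under the vanilla model", {
  p <- unlinked_panel(m = 2000, seed = 75)
  g <- simulate_unrelated(p, 3000, seed = 76, keep_haplotypes = TRUE)
  co <- mate_parents(rep(0, 3000), 0, seed = 77)
  fam <- simulate_offspring(co, g, 2L, seed = 78)
  set.seed(79)
  y1 <- rnorm(1500); y2 <- rnorm(1500)
  ss <- sib_diff_gwas(fam, y1, y2)
  expect_lt(abs(mean(ss$p < 0.05) - 0.05), 0.01)
})

test_that("sib estimates are unbiased for direct effects under the vanilla model", {
  p <- unlinked_panel(m = 300, seed = 80)
  eff <- draw_effect_sizes(p, 200, h2 = 0.5, seed = 81)
  coh <- simulate_cohort(p, eff, n_unrelated = 2L, n_families = 3000L,
                         seed = 82)
  ph <- coh$pheno
  s1 <- ph$set == "sib" & ph$sib_index == 1
  s2 <- ph$set == "sib" & ph$sib_index == 2
  ss <- sib_diff_gwas(coh$families, ph$y[s1], ph$y[s2],
                      sexage(ph[s1, ]), sexage(ph[s2, ]))
  # the generative betas act on raw counts of a standardized trait; rescale
  scale_f <- sqrt(eff$h2) / sd(ph$g)
  idx <- match(eff$causal_ids, ss$id)
  dev <- ss$beta[idx] - eff$beta_direct * scale_f
  tstat <- mean(dev) / (sd(dev) / sqrt(length(dev)))
  expect_lt(abs(tstat), 2.5)
})

test_that("parental indirect effects inflate standard but not sibling estimates", {
  p <- unlinked_panel(m = 400, seed = 85)
  cmp_designs <- function(eta, rho, seed) {
    eff <- draw_effect_sizes(p, 300, h2 = 0.4, rho_di = rho,
                             indirect_scale = 1, eta = eta, seed = 86)
    coh <- simulate_cohort(p, eff, n_unrelated = 8000L, n_families = 3000L,
                           seed = seed)
    ph <- coh$pheno
    u <- ph$set == "unrelated"
    s1 <- ph$set == "sib" & ph$sib_index == 1
    s2 <- ph$set == "sib" & ph$sib_index == 2
    std <- ols_gwas(coh$unrelated, ph$y[u], sexage(ph[u, ]))
    sib <- sib_diff_gwas(coh$families, ph$y[s1], ph$y[s2],
                         sexage(ph[s1, ]), sexage(ph[s2, ]))
    sgn <- sign(eff$beta_direct)
    sgn[sgn == 0] <- 1
    i1 <- match(eff$causal_ids, std$id); i2 <- match(eff$causal_ids, sib$id)
    # oriented effects: positive means trait-increasing by the true sign
    data.frame(std = std$beta[i1] * sgn, sib = sib$beta[i2] * sgn)
  }
  ind <- cmp_designs(eta = 0.4, rho = 1, seed = 87)
  pv <- wilcox.test(ind$std, ind$sib, paired = TRUE,
                    alternative = "greater")$p.value
  expect_lt(pv, 0.01)
  expect_gt(mean(ind$std - ind$sib), 0)

  van <- cmp_designs(eta = 0, rho = 0, seed = 88)
  pv0 <- wilcox.test(van$std, van$sib, paired = TRUE)$p.value
  expect_gt(pv0, 0.01)
})
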