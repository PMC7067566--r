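test_that("incremental R2 handles perfect, null and known-correlation predictors", {
  set.seed(100)
  y <- rnorm(500)
  expect_equal(incremental_r2(y, NULL, y), 1.0)

  y2 <- rnorm(10000); s2 <- rnorm(10000)
  expect_lt(incremental_r2(y2, NULL, s2), 0.01)
  expect_gte(incremental_r2(y2, NULL, s2), 0)

  # bivariate normal with rho = 0.5: R2 = 0.25
  n <- 1e5
  x <- rnorm(n)
  yy <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  expect_lt(abs(incremental_r2(yy, NULL, x) - 0.25), 0.01)
  expect_error(incremental_r2(rep(1, 100), NULL, rnorm(100)), "constant")
})

test_that("incremental R2 is invariant under affine transforms", {
  set.seed(101)
  y <- rnorm(300)
  C <- cbind(a = rnorm(300), b = runif(300))
  s <- 0.4 * y + rnorm(300)
  base <- incremental_r2(y, C, s)
  expect_equal(incremental_r2(y, C, 3 * s - 7), base, tolerance = 1e-10)
  C2 <- cbind(a = 2 * C[, 1] + 5, b = -C[, 2])
  expect_equal(incremental_r2(y, C2, s), base, tolerance = 1e-10)
})

test_that("incremental AUC: separation, null and the hand-counted toy", {
  set.seed(102)
  yb <- rep(c(1L, 0L), each = 50)
  s <- c(rnorm(50, 5), rnorm(50, -5))
  expect_equal(incremental_auc(yb, NULL, s), 0.5)  # AUC 1.0 minus base 0.5

  yb2 <- rbinom(10000, 1, 0.4)
  expect_lt(abs(incremental_auc(yb2, NULL, rnorm(10000))), 0.02)

  # 6-observation toy: cases scores (3, 2, 1), controls (2.5, 0.5, 0.2);
  # concordant pairs: 3>all(3); 2>0.5,0.2; 1>0.5,0.2 -> 7 of 9
  yb3 <- c(1L, 1L, 1L, 0L, 0L, 0L)
  s3 <- c(3, 2, 1, 2.5, 0.5, 0.2)
  expect_equal(incremental_auc(yb3, NULL, s3), 7 / 9 - 0.5)
  expect_error(incremental_auc(rep(1L, 10), NULL, rnorm(10)), "both classes")
})

test_that("incremental AUC is invariant under monotone transforms of the score", {
  set.seed(103)
  yb <- rbinom(400, 1, 0.3)
  s <- rnorm(400) + yb
  expect_equal(incremental_auc(yb, NULL, exp(s)),
               incremental_auc(yb, NULL, s), tolerance = 1e-12)
})

test_that("rank_sum_test matches its contract and a permutation oracle", {
  expect_gt(rank_sum_test(1:10, 1:10), 0.9)
  expect_lt(rank_sum_test(1:20, 21:40), 1e-6)
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")

  set.seed(104)
  a <- rnorm(8); b <- rnorm(8, 0.8)
  p_obs <- rank_sum_test(a, b)
  pooled <- c(a, b)
  obs <- sum(rank(pooled)[1:8])
  perm <- replicate(8000, {
    ix <- sample(16, 8)
    abs(sum(rank(pooled)[ix]) - 68) >= abs(obs - 68)  # 68 = 8*17/2
  })
  expect_lt(abs(p_obs - mean(perm)), 0.02)
})

test_that("stratum_adjusted_variance recovers generative variance ratios", {
  set.seed(105)
  n <- 6000
  strata <- sample(c("A", "B"), n, replace = TRUE)
  C <- cbind(sex = rbinom(n, 1, 0.5), age = runif(n, 40, 70))
  y <- 0.01 * C[, 2] + rnorm(n, sd = ifelse(strata == "A", 1, 2))
  av <- stratum_adjusted_variance(y, C, strata)
  vA <- av$variance[av$stratum == "A"]; vB <- av$variance[av$stratum == "B"]
  expect_lt(abs(vB / vA - 4), 0.5)
  # identical strata: equal within 3 SE
  y2 <- rnorm(n)
  av2 <- stratum_adjusted_variance(y2, C, strata)
  expect_lt(abs(diff(av2$variance)), 3 * sqrt(sum(av2$se^2)))
  expect_error(stratum_adjusted_variance(y, C, replace(strata, 1, "C")),
               "size < 2")
})

test_that("the HE estimator is null-calibrated and responds to environmental noise", {
  p <- unlinked_panel(m = 400, seed = 110)
  g <- simulate_unrelated(p, 2000, seed = 111)
  set.seed(112)
  he0 <- h2_moment_estimate(g, rnorm(2000))
  expect_lt(abs(he0$h2), 3 * he0$se)

  eff <- draw_effect_sizes(p, 400, h2 = 0.5, seed = 113)
  ph <- assemble_phenotype(g, eff, seed = 114)
  he <- h2_moment_estimate(g, ph$y, sexage(ph))
  expect_lt(abs(he$h2 - 0.5), 3 * he$se)
  expect_lt(abs(he$h2 - 0.5), 0.12)

  # doubling the environmental variance drags h2 toward Vg / (Vg + 2 Ve)
  y_noisy <- ph$y + rnorm(2000, sd = sqrt(0.5))
  he2 <- h2_moment_estimate(g, y_noisy, sexage(ph))
  expect_lt(abs(he2$h2 - 1 / 3), 0.12)
})

test_that("the HE estimator refuses linked panels without causal flags", {
  sc <- tiny_scene(n = 300, m = 40, seed = 115)
  expect_error(h2_moment_estimate(sc$geno, sc$pheno$y), "LD")
  he <- h2_moment_estimate(sc$geno, sc$pheno$y,
                           causal_ids = sc$effects$causal_ids)
  expect_true(is.finite(he$h2))
})

test_that("inverse-proportionality fit: exact model, consistency and rejection", {
  v <- c(0.8, 1.0, 1.3, 1.9)
  h2 <- 0.4 / v
  fit <- fit_inverse_proportionality(h2, v)
  expect_equal(fit$c, 0.4, tolerance = 1e-12)
  expect_lt(fit$rss, 1e-24)

  # consistent case: residuals within noise
  set.seed(116)
  se <- rep(0.03, 4)
  h2n <- h2 + rnorm(4, 0, 0.02)
  fit2 <- fit_inverse_proportionality(h2n, v, se = se)
  expect_gt(fit2$p_value, 0.001)

  # gross violation: h2 increasing with variance is rejected
  fit3 <- fit_inverse_proportionality(c(0.3, 0.4, 0.5, 0.6),
                                      c(0.8, 1.0, 1.3, 1.9), se = se)
  expect_lt(fit3$p_value, 0.01)

  # free-intercept variant exposed
  fit4 <- fit_inverse_proportionality(h2, v, intercept = TRUE)
  expect_equal(fit4$c, 0.4, tolerance = 1e-8)
  expect_error(fit_inverse_proportionality(0.4, 1), "at least 2")
  expect_error(fit_inverse_proportionality(h2, c(-1, 1, 1, 1)), "positive")
})
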