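fake_stats <- function(id, chr, pos, p, beta = 0.1) {
  out <- data.frame(chr = chr, pos = pos, id = id, ea = "A", oa = "G",
                    beta = beta, se = 0.01, p = p, n = 100L,
                    design = "standard", stringsAsFactors = FALSE)
  class(out) <- c("sumstats", "data.frame")
  out
}

test_that("clumping keeps the most significant of two correlated SNPs", {
  # two perfectly correlated SNPs 10 kb apart
  set.seed(90)
  x <- rbinom(200, 2, 0.4)
  counts <- cbind(s1 = x, s2 = x)
  st <- fake_stats(c("s1", "s2"), 1L, c(100L, 10100L), c(1e-8, 1e-6))
  expect_identical(clump(st, counts, 1e-5), "s1")
  # a single passing SNP is returned as-is
  expect_identical(clump(st[1, ], counts, 1e-5), "s1")
  # empty candidate set is empty, not an error
  expect_identical(clump(st, counts, 1e-20), character(0))
  # missing reference SNP errors
  expect_error(clump(st, counts[, 1, drop = FALSE], 1e-5), "missing")
})

test_that("clumped output never contains a close correlated pair", {
  sc <- tiny_scene(n = 1200, m = 100, m_causal = 50, seed = 91,
                   block_size = 10)
  ss <- ols_gwas(sc$geno, sc$pheno$y, sexage(sc$pheno))
  sel <- clump(ss, sc$geno, 1e-2, r2_threshold = 0.1, window_bp = 1e6)
  expect_gt(length(sel), 0)
  pos <- sc$panel$pos[match(sel, sc$panel$snp_id)]
  if (length(sel) > 1) {
    cc <- cor(sc$geno$counts[, sel, drop = FALSE])^2
    for (i in seq_along(sel)) for (j in seq_along(sel)) {
      if (i < j && abs(pos[i] - pos[j]) <= 1e6)
        expect_lt(cc[i, j], 0.1)
    }
  }
  # idempotence: clumping the already-clumped set changes nothing
  ss_sel <- ss[ss$id %in% sel, ]
  class(ss_sel) <- class(ss)
  expect_identical(clump(ss_sel, sc$geno, 1e-2), sel)
})

test_that("candidate counts are monotone in the threshold grid", {
  sc <- tiny_scene(n = 800, m = 80, m_causal = 40, seed = 92)
  ss <- ols_gwas(sc$geno, sc$pheno$y, sexage(sc$pheno))
  n_sel <- vapply(threshold_grid(),
                  function(t) length(clump(ss, sc$geno, t)), integer(1))
  n_cand <- vapply(threshold_grid(), function(t) sum(ss$p <= t), integer(1))
  expect_true(all(diff(n_cand) >= 0))
  expect_true(all(diff(n_sel) >= 0))
})

test_that("threshold grid defaults and overrides behave", {
  g <- threshold_grid()
  expect_length(g, 7)
  expect_equal(g, 10^seq(-8, -2))
  expect_true(all(diff(g) > 0))
  expect_equal(threshold_grid(1e-4), 1e-4)
  expect_true(all(diff(threshold_grid(c(1e-2, 1e-6, 1e-4))) > 0))
})

test_that("score models build, score and round-trip", {
  st <- fake_stats(c("s1", "s2"), 1L, c(1L, 2L), c(1e-8, 1e-4),
                   beta = c(0.5, -1))
  expect_equal(build_score_model(st, character(0))$n_snps, 0)
  m1 <- build_score_model(st, "s1", 1e-6)
  expect_equal(m1$entries$weight, 0.5)
  expect_error(build_score_model(st, "nope"), "absent")

  counts <- matrix(c(2L, 0L, 0L, 2L), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  m2 <- build_score_model(st, c("s1", "s2"), 1e-2)
  expect_equal(unname(score_individuals(counts, m2)),
               c(0.5 * 2 + -1 * 0, 0.5 * 0 + -1 * 2))
  # empty model scores all zero
  expect_equal(unname(score_individuals(counts,
                                        build_score_model(st, character(0)))),
               c(0, 0))

  path <- tempfile(fileext = ".tsv")
  write_score_model(m2, path)
  m3 <- read_score_model(path)
  expect_equal(m3$entries$weight, m2$entries$weight, tolerance = 1e-11)
  expect_identical(m3$entries$snp_id, m2$entries$snp_id)
})

test_that("scores equal the brute-force loop oracle", {
  sc <- tiny_scene(n = 100, m = 20, seed = 93)
  ss <- ols_gwas(sc$geno, sc$pheno$y, sexage(sc$pheno))
  mod <- build_score_model(ss, ss$id, 1)
  s <- score_individuals(sc$geno, mod)
  oracle <- numeric(100)
  for (i in 1:100) for (k in seq_len(mod$n_snps))
    oracle[i] <- oracle[i] +
      mod$entries$weight[k] * sc$geno$counts[i, mod$entries$snp_id[k]]
  expect_lt(max(abs(s - oracle)), 1e-12)
})

test_that("consistent allele flips leave incremental R2 unchanged", {
  sc <- tiny_scene(n = 400, m = 20, seed = 94)
  ss <- ols_gwas(sc$geno, sc$pheno$y, sexage(sc$pheno))
  mod <- build_score_model(ss, ss$id, 1)
  s0 <- score_individuals(sc$geno, mod)
  mod_fl <- mod
  mod_fl$entries$effect_allele <- "G"   # the panel's other allele
  mod_fl$entries$weight <- -mod$entries$weight
  expect_message(s1 <- score_individuals(sc$geno, mod_fl), "flipped")
  # flipped-and-negated weights give the same score up to a constant
  expect_lt(diff(range((s1 - s0))), 1e-10)
  r2a <- incremental_r2(sc$pheno$y, sexage(sc$pheno), s0)
  r2b <- incremental_r2(sc$pheno$y, sexage(sc$pheno), s1)
  expect_equal(r2a, r2b, tolerance = 1e-10)
  # an allele matching neither panel allele errors
  mod_bad <- mod
  mod_bad$entries$effect_allele[1] <- "T"
  expect_error(score_individuals(sc$geno, mod_bad), "neither")
})
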