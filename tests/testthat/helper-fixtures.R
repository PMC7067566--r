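# Small in-code fixtures shared across test files.

tiny_panel <- function(m = 60L, block_size = 5L, r = 0.8, seed = 1L,
                       maf_low = 0.1, maf_high = 0.5, ...) {
  make_snp_panel(m, maf_low, maf_high, block_size = block_size,
                 within_block_r = r, seed = seed, ...)
}

unlinked_panel <- function(m = 200L, seed = 2L, maf_low = 0.1,
                           maf_high = 0.5) {
  make_snp_panel(m, maf_low, maf_high, block_size = 1L, within_block_r = 0,
                 seed = seed)
}

sexage <- function(ph) as.matrix(ph[, c("sex", "age")])

# A small ready-made analysis scene: genotypes, effects, phenotypes.
tiny_scene <- function(n = 500L, m = 60L, m_causal = min(20L, m), h2 = 0.5,
                       seed = 7L, r = 0.8, block_size = 5L) {
  panel <- tiny_panel(m = m, block_size = block_size, r = r, seed = seed)
  effects <- draw_effect_sizes(panel, m_causal, h2, seed = seed + 1L)
  geno <- simulate_unrelated(panel, n, seed = seed + 2L,
                             keep_haplotypes = TRUE)
  pheno <- assemble_phenotype(geno, effects, seed = seed + 3L)
  list(panel = panel, effects = effects, geno = geno, pheno = pheno)
}
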