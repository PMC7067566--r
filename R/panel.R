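#' Create a synthetic SNP panel with contiguous LD blocks
#'
#' Builds the marker map used by all simulation and analysis functions:
#' `m` biallelic SNPs on one chromosome, grouped into contiguous blocks of
#' `block_size` adjacent SNPs (the last block holds the remainder). The
#' effect-allele frequency is drawn once per block, uniformly on
#' `[maf_low, maf_high]`, so that the within-block haplotype copying process
#' of [simulate_unrelated()] attains an adjacent-SNP correlation of
#' `within_block_r` exactly.
#'
#' Positions are laid out so that SNPs within a block are `snp_spacing_bp`
#' apart while consecutive blocks are separated by `block_gap_bp`. With the
#' default gap of 2 Mb, distinct blocks fall outside the standard 1 Mb
#' clumping window; shrink the gap to place several blocks inside one window.
#' Blocks spill onto additional chromosomes before coordinates reach ~240
#' Mb, so large panels span several chromosomes like a real marker map.
#'
#' @param m Number of SNPs (positive integer).
#' @param maf_low,maf_high Bounds of the effect-allele frequency,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param block_size SNPs per LD block (positive integer).
#' @param within_block_r Target correlation between adjacent same-block
#'   haplotype alleles, in `[0, 1)`.
#' @param seed Integer seed; the panel is deterministic given the seed.
#' @param snp_spacing_bp Distance in bp between adjacent SNPs of a block.
#' @param block_gap_bp Distance in bp between the last SNP of a block and the
#'   first SNP of the next.
#' @param chrom Integer label of the first chromosome; further chromosomes
#'   are opened as needed so base-pair coordinates stay below ~240 Mb.
#'
#' @return An object of class `snp_panel`: a data frame with columns
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `maf`,
#'   `block_id`, carrying `within_block_r` as an attribute.
#' @export
#' @examples
#' p <- make_snp_panel(10, 0.1, 0.5, block_size = 5, within_block_r = 0.8,
#'                     seed = 1)
#' table(p$block_id)
make_snp_panel <- function(m, maf_low, maf_high, block_size,
                           within_block_r = 0, seed = NULL,
                           snp_spacing_bp = 1000L, block_gap_bp = 2000000L,
                           chrom = 1L) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m))
    stop("`m` must be a positive integer")
  if (length(block_size) != 1L || !is.finite(block_size) || block_size < 1 ||
      block_size != round(block_size))
    stop("`block_size` must be a positive integer")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  if (within_block_r < 0 || within_block_r >= 1)
    stop("`within_block_r` must be in [0, 1)")
  m <- as.integer(m); block_size <- as.integer(block_size)

  n_blocks <- as.integer(ceiling(m / block_size))
  block_id <- rep(seq_len(n_blocks), each = block_size)[seq_len(m)]
  within_idx <- stats::ave(seq_len(m), block_id, FUN = seq_along)

  maf_block <- with_seed(seed, runif(n_blocks, maf_low, maf_high))
  maf <- maf_block[block_id]

  # positions: dense within a block, a large gap between blocks; blocks
  # spill onto further chromosomes before coordinates overflow ~240 Mb
  chrom_cap <- 240000000
  block_sizes <- as.integer(table(block_id))
  block_chrom <- integer(n_blocks)
  block_start <- numeric(n_blocks)
  cur_chr <- as.integer(chrom); cur_pos <- 1
  for (b in seq_len(n_blocks)) {
    extent <- (block_sizes[b] - 1L) * snp_spacing_bp
    if (cur_pos + extent > chrom_cap) {
      cur_chr <- cur_chr + 1L
      cur_pos <- 1
    }
    block_chrom[b] <- cur_chr
    block_start[b] <- cur_pos
    cur_pos <- cur_pos + extent + block_gap_bp
  }
  pos <- as.integer(block_start[block_id] + (within_idx - 1L) * snp_spacing_bp)

  panel <- data.frame(
    snp_id = sprintf("snp%0*d", nchar(m), seq_len(m)),
    chrom = block_chrom[block_id],
    pos = pos,
    effect_allele = "A",
    other_allele = "G",
    maf = maf,
    block_id = as.integer(block_id),
    stringsAsFactors = FALSE
  )
  attr(panel, "within_block_r") <- within_block_r
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %d SNPs, %d LD blocks (adjacent r = %.2f), maf in [%.3f, %.3f]\n",
              nrow(x), length(unique(x$block_id)),
              attr(x, "within_block_r"), min(x$maf), max(x$maf)))
  invisible(x)
}

# TRUE when the panel carries no LD (singleton blocks or r = 0)
panel_is_unlinked <- function(panel) {
  r <- attr(panel, "within_block_r")
  is.null(r) || r == 0 || max(table(panel$block_id)) == 1L
}
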