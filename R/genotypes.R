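# Haplotype simulation: first-order copying process within each LD block.
# A latent uniform is reused from the previous SNP with probability r and
# refreshed otherwise; with a block-constant allele frequency this gives an
# adjacent-allele correlation of exactly r and independence across blocks.
# Haplotypes are stored as a raw (one byte per allele) 0/1 matrix to keep
# large founder generations affordable in memory.
sim_haplotypes <- function(panel, n_hap) {
  m <- nrow(panel)
  r <- attr(panel, "within_block_r")
  H <- matrix(as.raw(0L), n_hap, m)
  for (b in unique(panel$block_id)) {
    cols <- which(panel$block_id == b)
    u <- runif(n_hap)
    H[, cols[1L]] <- as.raw(u < panel$maf[cols[1L]])
    for (j in cols[-1L]) {
      if (r > 0) {
        refresh <- runif(n_hap) >= r
        if (any(refresh)) u[refresh] <- runif(sum(refresh))
      } else {
        u <- runif(n_hap)
      }
      H[, j] <- as.raw(u < panel$maf[j])
    }
  }
  colnames(H) <- panel$snp_id
  H
}

# integer matrix from a raw 0/1 haplotype block
hap_int <- function(H, rows, cols) {
  sub <- H[rows, cols, drop = FALSE]
  matrix(as.integer(sub), nrow = length(rows),
         dimnames = list(NULL, colnames(H)[cols]))
}

# allele counts (n x m integer) from a 2n x m raw haplotype matrix,
# built in column chunks to bound transient memory
counts_from_haplotypes <- function(H, chunk_cols = 256L) {
  n <- nrow(H) %/% 2L
  m <- ncol(H)
  odd <- seq.int(1L, 2L * n, by = 2L)
  counts <- matrix(0L, n, m)
  colnames(counts) <- colnames(H)
  start <- 1L
  while (start <= m) {
    cols <- start:min(m, start + chunk_cols - 1L)
    counts[, cols] <- hap_int(H, odd, cols) + hap_int(H, odd + 1L, cols)
    start <- cols[length(cols)] + 1L
  }
  counts
}

# weighted allele-count sum straight from haplotypes (no full count matrix)
score_from_haplotypes <- function(H, cols, beta, chunk_cols = 256L) {
  n <- nrow(H) %/% 2L
  odd <- seq.int(1L, 2L * n, by = 2L)
  out <- numeric(n)
  start <- 1L
  while (start <= length(cols)) {
    j <- start:min(length(cols), start + chunk_cols - 1L)
    cnt <- hap_int(H, odd, cols[j]) + hap_int(H, odd + 1L, cols[j])
    out <- out + as.numeric(cnt %*% beta[j])
    start <- j[length(j)] + 1L
  }
  out
}

new_geno_matrix <- function(panel, counts, haplotypes = NULL, ids = NULL) {
  if (is.null(ids)) ids <- rownames(counts)
  if (is.null(ids) && !is.null(counts))
    ids <- sprintf("ind%d", seq_len(nrow(counts)))
  if (!is.null(counts)) rownames(counts) <- ids
  structure(list(panel = panel, counts = counts, haplotypes = haplotypes,
                 ids = ids),
            class = "geno_matrix")
}

#' Simulate genotypes for unrelated individuals
#'
#' Draws `2 * n` haplotypes from the panel's block-LD copying process and sums
#' them into allele counts in \{0, 1, 2\}. Haplotypes are independent across
#' individuals and across LD blocks; within a block, adjacent SNP alleles on
#' one haplotype have correlation `within_block_r` (a first-order process, so
#' correlation decays geometrically with SNP distance inside the block).
#'
#' For an unlinked panel (`within_block_r = 0` or singleton blocks) with
#' `keep_haplotypes = FALSE`, counts are drawn directly as Binomial(2, maf),
#' which is the same distribution with less memory traffic.
#'
#' @param panel An [make_snp_panel()] object.
#' @param n Number of individuals (positive integer).
#' @param seed Integer seed.
#' @param keep_haplotypes Retain the phased `2n x m` 0/1 haplotype matrix
#'   (stored as type `raw`; rows `2i - 1`, `2i` belong to individual `i`)?
#'   Required downstream by [simulate_offspring()].
#' @param ids Optional character vector of individual ids.
#'
#' @return An object of class `geno_matrix`: list with elements `panel`,
#'   `counts` (n x m integer matrix), `haplotypes` (or `NULL`) and `ids`.
#' @export
simulate_unrelated <- function(panel, n, seed = NULL, keep_haplotypes = FALSE,
                               ids = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  n <- as.integer(n)
  with_seed(seed, {
    if (!keep_haplotypes && panel_is_unlinked(panel)) {
      counts <- matrix(rbinom(n * nrow(panel), 2L,
                              rep(panel$maf, each = n)),
                       nrow = n, ncol = nrow(panel))
      colnames(counts) <- panel$snp_id
      return(new_geno_matrix(panel, counts, NULL, ids))
    }
    H <- sim_haplotypes(panel, 2L * n)
    counts <- counts_from_haplotypes(H)
    new_geno_matrix(panel, counts, if (keep_haplotypes) H else NULL, ids)
  })
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs (%s haplotypes)\n",
              if (is.null(x$counts)) length(x$ids) else nrow(x$counts),
              nrow(x$panel),
              if (is.null(x$haplotypes)) "no" else "phased"))
  invisible(x)
}

# Accept either a geno_matrix or a bare counts matrix.
as_counts <- function(x) {
  if (inherits(x, "geno_matrix")) x$counts
  else if (is.matrix(x)) x
  else stop("expected a geno_matrix or a counts matrix")
}

# Allele counts for a subset of individuals, from counts when present or
# else rebuilt from the raw haplotypes.
counts_for_individuals <- function(g, idx, chunk_cols = 256L) {
  if (!is.null(g$counts)) return(g$counts[idx, , drop = FALSE])
  H <- g$haplotypes
  m <- ncol(H)
  odd <- 2L * idx - 1L
  cnt <- matrix(0L, length(idx), m)
  colnames(cnt) <- colnames(H)
  start <- 1L
  while (start <= m) {
    cols <- start:min(m, start + chunk_cols - 1L)
    cnt[, cols] <- hap_int(H, odd, cols) + hap_int(H, odd + 1L, cols)
    start <- cols[length(cols)] + 1L
  }
  rownames(cnt) <- g$ids[idx]
  cnt
}

# A founder pool kept as haplotypes only (no count matrix): the parental
# generation of simulate_cohort() at scale.
simulate_founder_pool <- function(panel, n, seed = NULL) {
  with_seed(seed, {
    H <- sim_haplotypes(panel, 2L * as.integer(n))
    new_geno_matrix(panel, NULL, H, sprintf("founder%d", seq_len(n)))
  })
}

# Subset individuals of a geno_matrix (drops haplotypes unless asked for).
subset_individuals <- function(g, idx, keep_haplotypes = FALSE) {
  hap <- NULL
  if (keep_haplotypes && !is.null(g$haplotypes)) {
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    hap <- g$haplotypes[rows, , drop = FALSE]
  }
  new_geno_matrix(g$panel, g$counts[idx, , drop = FALSE], hap, g$ids[idx])
}
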