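#' Simulate offspring genotypes by Mendelian transmission
#'
#' For every couple, each parent transmits — independently per LD block — one
#' of its two within-block haplotypes intact. Recombination is free between
#' blocks and absent within blocks, matching the block-LD model of the panel.
#' Mendelian consistency therefore holds at every SNP by construction (see
#' [mendelian_check()]).
#'
#' @param couples Data frame with integer columns `mother`, `father` indexing
#'   individuals of `parental_genotypes` (e.g. from [mate_parents()]).
#' @param parental_genotypes A `geno_matrix` with retained haplotypes
#'   (`keep_haplotypes = TRUE` in [simulate_unrelated()]).
#' @param n_offspring_per_family Offspring per couple (1 for an "unrelateds"
#'   panel, 2 for sibling pairs).
#' @param seed Integer seed.
#' @param keep_haplotypes Retain the offspring's phased haplotypes.
#' @param keep_parent_counts Store the couples' allele-count matrices in the
#'   cohort (needed by [mendelian_check()] and for parental-genotype
#'   diagnostics).
#'
#' @return An object of class `family_cohort`: list with `panel`,
#'   `family_id`, `offspring` (list of `n_offspring_per_family` count
#'   matrices, one row per family), optional `offspring_haplotypes`,
#'   `mother_counts`/`father_counts` (if kept) and the `couples` indices.
#' @export
simulate_offspring <- function(couples, parental_genotypes,
                               n_offspring_per_family = 2L, seed = NULL,
                               keep_haplotypes = FALSE,
                               keep_parent_counts = TRUE) {
  stopifnot(inherits(parental_genotypes, "geno_matrix"))
  if (is.null(parental_genotypes$haplotypes))
    stop("parental genotypes must retain haplotypes for transmission")
  stopifnot(all(c("mother", "father") %in% names(couples)),
            n_offspring_per_family >= 1L)
  panel <- parental_genotypes$panel
  H <- parental_genotypes$haplotypes
  n_fam <- nrow(couples)
  m <- nrow(panel)
  blocks <- split(seq_len(m), panel$block_id)

  transmit <- function(parent_idx) {
    # one gamete per family: per block pick haplotype 1 or 2 of the parent
    gam <- matrix(as.raw(0L), n_fam, m)
    base_row <- 2L * (parent_idx - 1L)
    for (cols in blocks) {
      pick <- sample.int(2L, n_fam, replace = TRUE)
      gam[, cols] <- H[base_row + pick, cols, drop = FALSE]
    }
    colnames(gam) <- panel$snp_id
    gam
  }

  gametes_to_counts <- function(mat, pat, chunk_cols = 256L) {
    cnt <- matrix(0L, n_fam, m)
    start <- 1L
    while (start <= m) {
      cols <- start:min(m, start + chunk_cols - 1L)
      cnt[, cols] <- hap_int(mat, seq_len(n_fam), cols) +
        hap_int(pat, seq_len(n_fam), cols)
      start <- cols[length(cols)] + 1L
    }
    colnames(cnt) <- panel$snp_id
    cnt
  }

  with_seed(seed, {
    offspring <- vector("list", n_offspring_per_family)
    off_hap <- if (keep_haplotypes) vector("list", n_offspring_per_family)
    for (k in seq_len(n_offspring_per_family)) {
      mat <- transmit(couples$mother)
      pat <- transmit(couples$father)
      cnt <- gametes_to_counts(mat, pat)
      rownames(cnt) <- sprintf("fam%d_sib%d", seq_len(n_fam), k)
      offspring[[k]] <- cnt
      if (keep_haplotypes) off_hap[[k]] <- list(maternal = mat, paternal = pat)
    }
    out <- list(panel = panel,
                family_id = sprintf("fam%d", seq_len(n_fam)),
                couples = couples,
                offspring = offspring,
                offspring_haplotypes = if (keep_haplotypes) off_hap,
                mother_counts = if (keep_parent_counts)
                  counts_for_individuals(parental_genotypes, couples$mother),
                father_counts = if (keep_parent_counts)
                  counts_for_individuals(parental_genotypes, couples$father))
    class(out) <- "family_cohort"
    out
  })
}

#' @export
print.family_cohort <- function(x, ...) {
  cat(sprintf("family_cohort: %d families, %d offspring each, %d SNPs\n",
              length(x$family_id), length(x$offspring), nrow(x$panel)))
  invisible(x)
}

#' Check Mendelian consistency of a family cohort
#'
#' Verifies, exhaustively over families and SNPs, that each offspring allele
#' count is achievable from the parental genotypes: the count must lie between
#' the number of parents homozygous for the effect allele and the number of
#' parents carrying at least one copy.
#'
#' @param cohort A [simulate_offspring()] cohort with parental counts kept.
#' @return `TRUE` invisibly if consistent, otherwise an error describing the
#'   first violation.
#' @export
mendelian_check <- function(cohort) {
  stopifnot(inherits(cohort, "family_cohort"))
  if (is.null(cohort$mother_counts))
    stop("cohort lacks parental counts; rerun with keep_parent_counts = TRUE")
  lo <- (cohort$mother_counts == 2L) + (cohort$father_counts == 2L)
  hi <- (cohort$mother_counts > 0L) + (cohort$father_counts > 0L)
  for (k in seq_along(cohort$offspring)) {
    o <- cohort$offspring[[k]]
    bad <- which(o < lo | o > hi, arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("Mendelian violation: family %d, SNP %d, offspring %d",
                   bad[1L, 1L], bad[1L, 2L], k))
  }
  invisible(TRUE)
}

# counts matrix of all offspring stacked (sib1 rows first, then sib2, ...)
offspring_counts <- function(cohort) {
  do.call(rbind, cohort$offspring)
}
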