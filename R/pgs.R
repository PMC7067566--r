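#' Greedy LD clumping of association results
#'
#' Among SNPs with `p <= p_threshold`, repeatedly takes the
#' smallest-p not-yet-removed SNP as an index SNP and removes all other
#' unselected candidates on the same chromosome within `window_bp` of it
#' whose squared sample correlation (computed on allele counts in the LD
#' reference) with the index is at least `r2_threshold`. Ties in p are broken
#' by (chromosome, position). Cross-chromosome pairs are never clumped; the
#' window is interpreted as +/- `window_bp` around the index SNP.
#'
#' @param stats A `sumstats` data frame.
#' @param ld_reference A `geno_matrix` covering every candidate SNP.
#' @param p_threshold Inclusion threshold on p.
#' @param r2_threshold Squared-correlation threshold for removal.
#' @param window_bp Physical window half-width in bp.
#' @return Character vector of selected SNP ids, sorted by (chromosome,
#'   position); empty when no SNP passes the threshold.
#' @export
clump <- function(stats, ld_reference, p_threshold, r2_threshold = 0.1,
                  window_bp = 1000000L) {
  cand <- stats[stats$p <= p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  ref <- as_counts(ld_reference)
  miss <- setdiff(cand$id, colnames(ref))
  if (length(miss))
    stop(sprintf("LD reference missing %d candidate SNP(s), e.g. %s",
                 length(miss), miss[1L]))
  ord <- order(cand$p, cand$chr, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  refX <- ref[, cand$id, drop = FALSE] * 1.0

  active <- rep(TRUE, nrow(cand))
  selected <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    selected[i] <- TRUE
    active[i] <- FALSE
    near <- which(active &
                    cand$chr == cand$chr[i] &
                    abs(cand$pos - cand$pos[i]) <= window_bp)
    if (length(near)) {
      r <- suppressWarnings(
        as.numeric(cor(refX[, i], refX[, near, drop = FALSE])))
      r[is.na(r)] <- 1  # a monomorphic reference column clumps with anything
      active[near[r^2 >= r2_threshold]] <- FALSE
    }
  }
  sel <- cand[selected, , drop = FALSE]
  sel$id[order(sel$chr, sel$pos)]
}

#' The p-value threshold grid for score construction
#'
#' Logarithmically spaced inclusion thresholds
#' `1e-8, 1e-7, ..., 1e-2`, optionally overridden.
#'
#' @param override Optional numeric vector replacing the default grid.
#' @return Strictly increasing numeric vector of thresholds.
#' @export
threshold_grid <- function(override = NULL) {
  if (is.null(override)) return(10^seq(-8, -2))
  sort(unique(as.numeric(override)))
}

#' Build a polygenic score model from summary statistics
#'
#' Weights are the estimated effects (`beta`; log odds ratios for the
#' logistic design) of the selected SNPs, aligned to the stored effect
#' alleles.
#'
#' @param stats A `sumstats` data frame.
#' @param selected Character vector of SNP ids (subset of `stats$id`).
#' @param p_threshold The threshold that produced the selection (metadata).
#' @return Object of class `score_model`: list with `entries` (data frame
#'   `snp_id`, `effect_allele`, `weight`), `p_threshold`, `source_design`,
#'   `n_snps`.
#' @export
build_score_model <- function(stats, selected, p_threshold = NA_real_) {
  idx <- match(selected, stats$id)
  if (anyNA(idx)) stop("selected SNP(s) absent from the summary statistics")
  entries <- data.frame(snp_id = stats$id[idx],
                        effect_allele = stats$ea[idx],
                        weight = stats$beta[idx],
                        stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(entries$snp_id), all(is.finite(entries$weight)))
  structure(list(entries = entries, p_threshold = p_threshold,
                 source_design = if (nrow(stats)) stats$design[1L] else NA,
                 n_snps = nrow(entries)),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model (%s design): %d SNPs at p <= %.3g\n",
              x$source_design, x$n_snps, x$p_threshold))
  invisible(x)
}

#' Compute polygenic scores
#'
#' Sum of effect-allele counts weighted by the model weights (plink-style
#' `--score` with summation). When the model's effect allele is the panel's
#' other allele the count is flipped to `2 - x` (and a message notes the
#' flips); such a consistent flip changes scores only by an affine
#' transform, leaving R-squared and AUC untouched.
#'
#' @param genotypes A `geno_matrix` (or counts matrix; then no allele
#'   checking is possible and weights are applied as stored).
#' @param model A [build_score_model()] object.
#' @return Numeric vector of scores, one per individual; all zeros for an
#'   empty model.
#' @export
score_individuals <- function(genotypes, model) {
  counts <- as_counts(genotypes)
  n <- nrow(counts)
  if (model$n_snps == 0L)
    return(setNames(numeric(n), rownames(counts)))
  idx <- match(model$entries$snp_id, colnames(counts))
  if (anyNA(idx))
    stop("score model SNP(s) absent from genotypes: ",
         model$entries$snp_id[which(is.na(idx))[1L]])
  w <- model$entries$weight
  if (inherits(genotypes, "geno_matrix")) {
    panel <- genotypes$panel
    prow <- match(model$entries$snp_id, panel$snp_id)
    same <- model$entries$effect_allele == panel$effect_allele[prow]
    flipped <- model$entries$effect_allele == panel$other_allele[prow]
    if (any(!same & !flipped))
      stop("effect allele matches neither panel allele for SNP ",
           model$entries$snp_id[which(!same & !flipped)[1L]])
    if (any(flipped)) {
      message(sprintf("score_individuals: flipped %d allele(s) to the panel coding",
                      sum(flipped)))
      # x' = 2 - x  =>  w * x' = -w * x + 2w
      w[flipped] <- -w[flipped]
    }
    offset <- 2 * sum(model$entries$weight[flipped])
  } else offset <- 0
  out <- as.numeric(counts[, idx, drop = FALSE] %*% w) + offset
  setNames(out, rownames(counts))
}
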