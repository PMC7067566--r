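#' Draw per-SNP direct and indirect effect sizes
#'
#' Samples the generative parameters of the trait. A random subset of
#' `m_causal` panel SNPs is declared causal; direct effects are i.i.d.
#' `N(0, h2 / m_causal)` and non-causal SNPs have no effect. Indirect
#' (parentally mediated) effects are built to have sample correlation exactly
#' `rho_di` with the direct effects and standard deviation
#' `indirect_scale * sd(beta_direct)`; with `indirect_scale = 0` they are all
#' zero.
#'
#' The returned model also carries the phenotype-level knobs consumed by
#' [assemble_phenotype()] and the cohort simulators: `eta`, the standard
#' deviation contributed by the standardized mid-parent indirect score;
#' `am_strength`, the target spousal phenotype correlation; and `strata`, a
#' data frame of stratum labels with amplification (`a_mult`) and
#' environmental (`e_mult`) multipliers plus sampling probabilities.
#'
#' @param panel An [make_snp_panel()] object.
#' @param m_causal Number of causal SNPs, at most `nrow(panel)`.
#' @param h2 Narrow-sense heritability of the standardized trait, in `[0, 1]`.
#' @param rho_di Target correlation between direct and indirect effects,
#'   in `[-1, 1]`.
#' @param indirect_scale Ratio of sd(indirect) to sd(direct); `0` disables
#'   indirect effects.
#' @param seed Integer seed.
#' @param eta Phenotype weight of the standardized parental indirect score.
#' @param am_strength Target spousal phenotype correlation in `[0, 1)`.
#' @param strata Data frame with columns `label`, `a_mult`, `e_mult`, `prob`
#'   (and optionally a `rule` attribute, see [assign_strata()]); defaults to a
#'   single stratum with unit multipliers.
#'
#' @return An object of class `effect_model`.
#' @export
draw_effect_sizes <- function(panel, m_causal, h2, rho_di = 0,
                              indirect_scale = 0, seed = NULL,
                              eta = 0, am_strength = 0, strata = NULL) {
  stopifnot(inherits(panel, "snp_panel"))
  if (m_causal < 1 || m_causal > nrow(panel))
    stop("`m_causal` must be between 1 and the panel size")
  if (h2 < 0 || h2 > 1) stop("`h2` must be in [0, 1]")
  if (abs(rho_di) > 1) stop("`rho_di` must be in [-1, 1]")
  if (indirect_scale < 0) stop("`indirect_scale` must be nonnegative")
  if (am_strength < 0 || am_strength >= 1)
    stop("`am_strength` must be in [0, 1)")
  if (is.null(strata))
    strata <- data.frame(label = "all", a_mult = 1, e_mult = 1, prob = 1,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("label", "a_mult", "e_mult", "prob") %in% names(strata)),
            all(strata$a_mult > 0), all(strata$e_mult > 0))
  m_causal <- as.integer(m_causal)

  with_seed(seed, {
    causal_ids <- sort(sample(panel$snp_id, m_causal))
    beta_direct <- if (h2 == 0) rep(0, m_causal)
                   else rnorm(m_causal, 0, sqrt(h2 / m_causal))
    if (indirect_scale > 0 && stats::sd(beta_direct) > 0) {
      # exact-sample-correlation construction: rho * z(beta) + sqrt(1-rho^2)
      # * z(residual of a fresh normal on beta)
      e <- rnorm(m_causal)
      e_res <- e - mean(e) -
        cov(e, beta_direct) / var(beta_direct) * (beta_direct - mean(beta_direct))
      z_b <- standardize(beta_direct)
      z_e <- standardize(e_res)
      beta_indirect <- (rho_di * z_b + sqrt(1 - rho_di^2) * z_e) *
        indirect_scale * stats::sd(beta_direct)
    } else {
      beta_indirect <- rep(0, m_causal)
    }
    structure(list(causal_ids = causal_ids,
                   beta_direct = setNames(beta_direct, causal_ids),
                   beta_indirect = setNames(beta_indirect, causal_ids),
                   h2 = h2, rho_di = rho_di, indirect_scale = indirect_scale,
                   eta = eta, am_strength = am_strength, strata = strata),
              class = "effect_model")
  })
}

#' @export
print.effect_model <- function(x, ...) {
  cat(sprintf(paste0("effect_model: %d causal SNPs, h2 = %.3g, eta = %.3g",
                     " (rho_di = %.2f), am = %.2f, %d strata\n"),
              length(x$causal_ids), x$h2, x$eta, x$rho_di, x$am_strength,
              nrow(x$strata)))
  invisible(x)
}

#' True genetic score of each individual
#'
#' Weighted sum of effect-allele counts over the causal SNPs,
#' `g_i = sum_j beta_j X_ij`; non-causal SNPs contribute nothing.
#'
#' @param genotypes A `geno_matrix` (or counts matrix with SNP-id colnames).
#' @param effects An [draw_effect_sizes()] model.
#' @param which `"direct"` or `"indirect"` effect vector.
#' @return Numeric vector, one score per individual.
#' @export
genetic_score <- function(genotypes, effects, which = c("direct", "indirect")) {
  which <- match.arg(which)
  if (inherits(genotypes, "geno_matrix") && is.null(genotypes$counts) &&
      !is.null(genotypes$haplotypes)) {
    # haplotype-backed matrix (founder pools): score without materializing
    # the full count matrix
    H <- genotypes$haplotypes
    missing <- setdiff(effects$causal_ids, colnames(H))
    if (length(missing))
      stop("causal SNPs absent from genotypes: ",
           paste(head(missing, 3L), collapse = ", "))
    beta <- if (which == "direct") effects$beta_direct
            else effects$beta_indirect
    out <- score_from_haplotypes(H, match(effects$causal_ids, colnames(H)),
                                 beta)
    names(out) <- genotypes$ids
    return(out)
  }
  counts <- as_counts(genotypes)
  missing <- setdiff(effects$causal_ids, colnames(counts))
  if (length(missing))
    stop(sprintf("causal SNPs absent from genotypes: %s%s",
                 paste(head(missing, 3L), collapse = ", "),
                 if (length(missing) > 3L) ", ..." else ""))
  beta <- if (which == "direct") effects$beta_direct else effects$beta_indirect
  # chunk over rows: counts may be a large integer matrix
  n <- nrow(counts)
  out <- numeric(n)
  cols <- match(effects$causal_ids, colnames(counts))
  chunk <- max(1L, min(n, as.integer(2e7 / length(cols))))
  start <- 1L
  while (start <= n) {
    end <- min(n, start + chunk - 1L)
    out[start:end] <- as.numeric(
      counts[start:end, cols, drop = FALSE] %*% beta)
    start <- end + 1L
  }
  names(out) <- rownames(counts)
  out
}
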