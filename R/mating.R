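#' Pair parents into couples, optionally with assortative mating
#'
#' Splits the parental pool at random into two equal mating sides and pairs
#' them. Under random mating (`am_strength = 0`) the pairing is a random
#' bijection. Under positive assortative mating the two sides are rank-matched
#' on phenotype after adding Gaussian noise: if both sides receive noise of
#' variance `tau2` and are matched exactly by rank of the noisy values, the
#' spousal phenotype correlation is approximately
#' `var(y) / (var(y) + tau2)`, so `tau2 = var(y) * (1 / am_strength - 1)`
#' targets `am_strength`. One calibration iteration refines `tau2` from the
#' realized correlation; the attempt closest to the target is kept. The whole
#' procedure is deterministic given the seed.
#'
#' @param parent_phenotypes Numeric vector of parental phenotypes (even
#'   length).
#' @param am_strength Target spousal phenotype correlation in `[0, 1)`.
#' @param seed Integer seed.
#' @return A data frame with integer columns `mother` and `father` (indices
#'   into `parent_phenotypes`; each parent used exactly once) and attribute
#'   `spousal_cor`, the realized spousal phenotype correlation.
#' @export
mate_parents <- function(parent_phenotypes, am_strength = 0, seed = NULL) {
  n <- length(parent_phenotypes)
  if (n < 2L || n %% 2L != 0L)
    stop("need an even number (>= 2) of parents")
  if (am_strength < 0 || am_strength >= 1)
    stop("`am_strength` must be in [0, 1)")
  with_seed(seed, {
    perm <- sample.int(n)
    side_a <- perm[seq_len(n %/% 2L)]
    side_b <- perm[(n %/% 2L + 1L):n]
    ya <- parent_phenotypes[side_a]
    yb <- parent_phenotypes[side_b]

    pair_by_rank <- function(tau2) {
      na <- ya + rnorm(length(ya), 0, sqrt(tau2))
      nb <- yb + rnorm(length(yb), 0, sqrt(tau2))
      data.frame(mother = side_a[order(na)], father = side_b[order(nb)])
    }

    if (am_strength == 0) {
      couples <- data.frame(mother = side_a, father = side_b)
    } else {
      vy <- stats::var(parent_phenotypes)
      tau2 <- vy * (1 / am_strength - 1)
      cand <- pair_by_rank(tau2)
      c1 <- cor(parent_phenotypes[cand$mother], parent_phenotypes[cand$father])
      # refine once through the noisy-rank relation c = v / (v + tau2):
      # solve the effective v from (c1, tau2), then re-solve tau2 for the
      # target correlation
      c1c <- min(max(c1, 1e-6), 1 - 1e-6)
      v_eff <- c1c * tau2 / (1 - c1c)
      tau2b <- max(v_eff * (1 / am_strength - 1), 0)
      cand2 <- pair_by_rank(tau2b)
      c2 <- cor(parent_phenotypes[cand2$mother],
                parent_phenotypes[cand2$father])
      couples <- if (abs(c2 - am_strength) < abs(c1 - am_strength)) cand2
                 else cand
      # rank matching orders couples by phenotype; shuffle so that any
      # downstream split of the couple list is phenotype-agnostic
      couples <- couples[sample.int(nrow(couples)), , drop = FALSE]
      rownames(couples) <- NULL
    }
    attr(couples, "spousal_cor") <- suppressWarnings(
      cor(parent_phenotypes[couples$mother], parent_phenotypes[couples$father]))
    couples
  })
}
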