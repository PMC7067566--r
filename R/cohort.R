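#' Simulate a full study cohort: unrelated individuals plus sibling pairs
#'
#' Runs the whole generative pipeline behind the sibling-versus-standard
#' comparison: a founder generation of `2 * (n_unrelated + n_families)`
#' unrelated parents is simulated from the panel, given phenotypes under the
#' vanilla formula (unit multipliers, no indirect term), and paired by
#' [mate_parents()] (optionally assortatively, `effects$am_strength`).
#' `n_unrelated` couples contribute one offspring each (the "unrelateds"
#' pool, standard-GWAS style) and `n_families` couples contribute a sibling
#' pair each; exactly one pair per family is retained. Offspring phenotypes
#' are assembled jointly — one shared standardization — and, when
#' `effects$eta != 0`, receive the parental indirect component.
#'
#' Note that the unrelateds are themselves offspring of (possibly
#' assortatively mated) parents, so standard GWAS run on them picks up
#' indirect parental effects and assortative-mating signal exactly as in the
#' designs this package studies; the sibling-difference design conditions
#' both away.
#'
#' @param panel An [make_snp_panel()] object.
#' @param effects An [draw_effect_sizes()] model.
#' @param n_unrelated Number of single-offspring couples (unrelateds pool).
#' @param n_families Number of sibling-pair couples.
#' @param seed Integer seed; the cohort is bit-reproducible given the seed.
#' @param sex_effect,sex_prob,age_range Covariate generation, see
#'   [assemble_phenotype()].
#'
#' @return Object of class `pgs_cohort`: list with `unrelated` (a
#'   `geno_matrix`), `families` (a `family_cohort`), `pheno` (one row per
#'   offspring: `individual_id`, `set` in \{"unrelated", "sib"\},
#'   `family_id`, `sib_index`, `y`, `sex`, `age`, `stratum`, `g`), `panel`,
#'   `effects` and `spousal_cor` (realized parental phenotype correlation).
#' @export
simulate_cohort <- function(panel, effects, n_unrelated, n_families,
                            seed = NULL, sex_effect = 0, sex_prob = 0.5,
                            age_range = c(40, 70)) {
  stopifnot(inherits(panel, "snp_panel"), inherits(effects, "effect_model"),
            n_unrelated >= 1L, n_families >= 0L)
  with_seed(seed, {
    seeds <- draw_sub_seeds(6L)
    n_couples <- n_unrelated + n_families
    founders <- simulate_founder_pool(panel, 2L * n_couples,
                                      seed = seeds[1L])
    g_f <- genetic_score(founders, effects, "direct")
    # founder phenotype: vanilla formula, used only as the mating trait
    z_g <- standardize(g_f)
    z_e <- standardize(with_seed(seeds[2L], rnorm(length(g_f))))
    y_f <- sqrt(effects$h2) * z_g + sqrt(1 - effects$h2) * z_e

    couples <- mate_parents(y_f, effects$am_strength, seed = seeds[3L])
    idx_u <- seq_len(n_unrelated)
    idx_f <- if (n_families > 0L) n_unrelated + seq_len(n_families)
             else integer(0)

    off_u <- simulate_offspring(couples[idx_u, , drop = FALSE], founders,
                                n_offspring_per_family = 1L,
                                seed = seeds[4L], keep_parent_counts = FALSE)
    fam <- if (n_families > 0L)
      simulate_offspring(couples[idx_f, , drop = FALSE], founders,
                         n_offspring_per_family = 2L, seed = seeds[5L],
                         keep_parent_counts = TRUE)

    parent_ind <- NULL
    if (effects$eta != 0) {
      gi <- genetic_score(founders, effects, "indirect")
      pi_all <- gi[couples$mother] + gi[couples$father]
      parent_ind <- c(pi_all[idx_u],
                      if (n_families > 0L) rep(pi_all[idx_f], 2L))
    }
    founders$haplotypes <- NULL  # release founder memory

    u_counts <- off_u$offspring[[1L]]
    rownames(u_counts) <- sprintf("unrel%d", seq_len(n_unrelated))
    unrelated <- new_geno_matrix(panel, u_counts)

    g_off <- c(genetic_score(unrelated, effects, "direct"),
               if (n_families > 0L)
                 genetic_score(offspring_counts(fam), effects, "direct"))
    ids <- c(rownames(u_counts),
             if (n_families > 0L)
               unlist(lapply(1:2, function(k) rownames(fam$offspring[[k]]))))
    names(g_off) <- ids

    stratum <- with_seed(seeds[6L],
                         assign_strata(effects, n = length(g_off)))
    ph <- with_seed(seeds[6L] %% 2000000000L + 1L, {
      assemble_phenotype_core(g_off, effects, stratum, parent_ind,
                              sex_effect, sex_prob, age_range)
    })
    pheno <- cbind(
      data.frame(
        individual_id = ids,
        set = c(rep("unrelated", n_unrelated),
                rep("sib", 2L * n_families)),
        family_id = c(rep(NA_character_, n_unrelated),
                      rep(if (n_families > 0L) fam$family_id else character(0),
                          2L)),
        sib_index = c(rep(NA_integer_, n_unrelated),
                      rep(1:2, each = n_families)),
        stringsAsFactors = FALSE),
      ph)

    structure(list(unrelated = unrelated, families = fam, pheno = pheno,
                   panel = panel, effects = effects,
                   spousal_cor = attr(couples, "spousal_cor")),
              class = "pgs_cohort")
  })
}

#' @export
print.pgs_cohort <- function(x, ...) {
  n_fam <- if (is.null(x$families)) 0L else length(x$families$family_id)
  cat(sprintf(paste0("pgs_cohort: %d unrelateds, %d sibling pairs, %d SNPs",
                     " (spousal phenotype r = %.3f)\n"),
              nrow(x$unrelated$counts), n_fam, nrow(x$panel), x$spousal_cor))
  invisible(x)
}

#' Redraw a trait on an existing cohort's genotypes
#'
#' Keeps the simulated genotypes (unrelateds and families) and assembles a
#' fresh phenotype under a new effect model — the in-silico analogue of
#' simulating several replicate traits on one genotyped cohort. Only
#' available for models without indirect effects or assortative mating,
#' since those alter (or depend on) the parental generation, which is not
#' retained.
#'
#' @param cohort A [simulate_cohort()] object.
#' @param effects A fresh [draw_effect_sizes()] model with `eta == 0`.
#' @param seed Integer seed for the environmental and covariate draws.
#' @inheritParams simulate_cohort
#' @return The cohort with `pheno` and `effects` replaced.
#' @export
cohort_with_new_trait <- function(cohort, effects, seed = NULL,
                                  sex_effect = 0, sex_prob = 0.5,
                                  age_range = c(40, 70)) {
  stopifnot(inherits(cohort, "pgs_cohort"), inherits(effects, "effect_model"))
  if (effects$eta != 0 || effects$am_strength != 0)
    stop("trait replicates on a fixed cohort require eta = 0 and ",
         "am_strength = 0 (the parental generation is not retained)")
  ph <- cohort$pheno
  n_fam <- if (is.null(cohort$families)) 0L
           else length(cohort$families$family_id)
  g_off <- c(genetic_score(cohort$unrelated, effects, "direct"),
             if (n_fam > 0L)
               genetic_score(offspring_counts(cohort$families), effects,
                             "direct"))
  with_seed(seed, {
    stratum <- assign_strata(effects, n = length(g_off))
    core <- assemble_phenotype_core(g_off, effects, stratum, NULL,
                                    sex_effect, sex_prob, age_range)
    cohort$pheno <- cbind(ph[, c("individual_id", "set", "family_id",
                                 "sib_index")], core)
    cohort$effects <- effects
    cohort
  })
}

#' Enumerate the simulated-trait validation designs
#'
#' The simulation grid used to validate the sibling-versus-standard pipeline:
#' heritability 0.1 or 0.5, crossed with 10K or 100K causal SNPs, with three
#' replicates per setting — twelve simulated traits in total.
#'
#' @param h2 Heritability settings.
#' @param m_causal Causal-SNP counts.
#' @param replicates Replicates per parameter combination.
#' @return Data frame with one row per simulated trait: `h2`, `m_causal`,
#'   `replicate`.
#' @export
simulated_trait_designs <- function(h2 = c(0.1, 0.5),
                                    m_causal = c(10000L, 100000L),
                                    replicates = 3L) {
  out <- expand.grid(replicate = seq_len(replicates), m_causal = m_causal,
                     h2 = h2, KEEP.OUT.ATTRS = FALSE)
  out[, c("h2", "m_causal", "replicate")]
}
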