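#' Assign individuals to strata
#'
#' Two assignment rules are supported, configured through the `rule`
#' attribute of `effects$strata` (default `"independent"`):
#' \describe{
#'   \item{independent}{stratum drawn i.i.d. with the `prob` column,
#'     independently of the phenotype — the sex/age analogue.}
#'   \item{collider}{a collider variable `c = lambda * y + sqrt(1 - lambda^2)
#'     * noise` is thresholded at its empirical quantiles into equal-sized
#'     groups — the adult-SES analogue, in which stratum membership is partly
#'     caused by the trait (range restriction). Requires unit `a_mult` and
#'     `e_mult`, since the trait must exist before the stratum does.}
#' }
#'
#' @param effects An [draw_effect_sizes()] model carrying the `strata` table.
#' @param n Number of individuals (independent rule).
#' @param y Phenotype vector (collider rule).
#' @param lambda Correlation of the collider with the phenotype (collider
#'   rule), in `[-1, 1]`.
#' @param seed Integer seed.
#' @return Character vector of stratum labels.
#' @export
assign_strata <- function(effects, n = NULL, y = NULL, lambda = 0.6,
                          seed = NULL) {
  st <- effects$strata
  rule <- attr(st, "rule")
  if (is.null(rule)) rule <- "independent"
  with_seed(seed, {
    if (rule == "independent") {
      stopifnot(!is.null(n))
      sample(st$label, n, replace = TRUE, prob = st$prob)
    } else if (rule == "collider") {
      stopifnot(!is.null(y))
      if (any(st$a_mult != 1) || any(st$e_mult != 1))
        stop("collider-based strata require unit multipliers")
      cv <- lambda * standardize(y) + sqrt(1 - lambda^2) * rnorm(length(y))
      qs <- quantile(cv, probs = seq(0, 1, length.out = nrow(st) + 1L))
      qs[1L] <- -Inf; qs[length(qs)] <- Inf
      st$label[cut(cv, qs, labels = FALSE, include.lowest = TRUE)]
    } else stop("unknown stratum rule: ", rule)
  })
}

# Core phenotype construction shared by assemble_phenotype() and the cohort
# simulators. All standardizations are empirical over the supplied sample:
#   y = a_s * sqrt(h2) * z_g + eta * z_ind + e_s * sqrt(1 - h2) * z_eps
# where z_g = (g - mean g) / sd g and z_eps likewise for eps ~ N(0, 1).
assemble_phenotype_core <- function(g, effects, stratum, parent_indirect,
                                    sex_effect, sex_prob, age_range) {
  n <- length(g)
  st <- effects$strata
  a <- st$a_mult[match(stratum, st$label)]
  e <- st$e_mult[match(stratum, st$label)]
  if (anyNA(a)) stop("stratum labels not found in the effect model's strata")
  z_g <- standardize(g)
  eps <- rnorm(n)
  z_eps <- standardize(eps)
  y <- a * sqrt(effects$h2) * z_g + e * sqrt(1 - effects$h2) * z_eps
  if (effects$eta != 0) {
    if (is.null(parent_indirect))
      stop("indirect effects requested (eta != 0) but no parental indirect ",
           "scores supplied; unrelated individuals without simulated parents ",
           "cannot receive an indirect component")
    y <- y + effects$eta * standardize(parent_indirect)
  }
  sex <- rbinom(n, 1L, sex_prob)
  age <- runif(n, age_range[1L], age_range[2L])
  if (sex_effect != 0) y <- y + sex_effect * (sex - mean(sex))
  data.frame(y = y, sex = sex, age = age, stratum = stratum, g = g,
             stringsAsFactors = FALSE)
}

#' Assemble phenotypes from genotypes and an effect model
#'
#' Computes the trait value
#' `y = a_s * sqrt(h2) * z_g + eta * z_ind + e_s * sqrt(1 - h2) * z_eps`,
#' where `z_g` is the sample-standardized true genetic score, `z_eps` the
#' sample-standardized environmental draw, `z_ind` the sample-standardized
#' parental (mother + father) indirect genetic score, and `a_s`, `e_s` the
#' amplification and environmental multipliers of the individual's stratum.
#' With unit multipliers and `eta = 0` this reduces exactly to
#' `sqrt(h2) * z_g + sqrt(1 - h2) * z_eps`, so the trait has sample variance
#' ~1 and a genetic share of variance equal to `h2` up to Monte-Carlo noise.
#'
#' Sex (Bernoulli) and age (uniform) covariates are generated alongside; an
#' optional additive mean sex effect can be injected via `sex_effect`.
#'
#' @param genotypes A `geno_matrix`, or a numeric vector of precomputed true
#'   genetic scores.
#' @param effects An [draw_effect_sizes()] model.
#' @param stratum Optional character vector of stratum labels (recycled
#'   labels must exist in `effects$strata`); defaults to an
#'   [assign_strata()] draw under the model's rule.
#' @param parent_indirect Optional numeric vector: per-individual sum of the
#'   two parents' indirect genetic scores. Mandatory when `effects$eta != 0`.
#' @param seed Integer seed (environmental draws, covariates, stratum
#'   assignment).
#' @param sex_effect Additive mean effect of sex on `y` (default 0).
#' @param sex_prob Bernoulli probability of `sex == 1`.
#' @param age_range Uniform range of age.
#'
#' @return A data frame with columns `individual_id`, `y`, `sex`, `age`,
#'   `stratum` and `g` (the true genetic score, kept for diagnostics).
#' @export
assemble_phenotype <- function(genotypes, effects, stratum = NULL,
                               parent_indirect = NULL, seed = NULL,
                               sex_effect = 0, sex_prob = 0.5,
                               age_range = c(40, 70)) {
  g <- if (is.numeric(genotypes)) genotypes
       else genetic_score(genotypes, effects, "direct")
  ids <- names(g)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_along(g))
  with_seed(seed, {
    if (is.null(stratum)) {
      rule <- attr(effects$strata, "rule")
      if (!is.null(rule) && rule == "collider") {
        # assign on the unit-multiplier trait, then rebuild identically:
        # with unit multipliers the stratum does not alter generation
        stratum <- rep(effects$strata$label[1L], length(g))
      } else {
        stratum <- assign_strata(effects, n = length(g))
      }
    }
    ph <- assemble_phenotype_core(g, effects, stratum, parent_indirect,
                                  sex_effect, sex_prob, age_range)
    rule <- attr(effects$strata, "rule")
    if (!is.null(rule) && rule == "collider")
      ph$stratum <- assign_strata(effects, y = ph$y)
    cbind(data.frame(individual_id = ids, stringsAsFactors = FALSE), ph)
  })
}

#' Dichotomize a quantitative trait
#'
#' Returns 1 where `y` strictly exceeds the threshold. A quantile
#' specification is resolved on the supplied vector, e.g. `quantile = 0.8`
#' marks roughly the top 20 percent as cases (the liability-threshold view of
#' a binary outcome such as hypertension from diastolic blood pressure).
#'
#' @param y Numeric vector.
#' @param threshold Absolute threshold (ignored when `quantile` given).
#' @param quantile Optional quantile in (0, 1) at which to place the
#'   threshold.
#' @return Integer 0/1 vector.
#' @export
binarize_trait <- function(y, threshold = NULL, quantile = NULL) {
  if (!is.null(quantile)) {
    if (quantile <= 0 || quantile >= 1) stop("`quantile` must be in (0, 1)")
    threshold <- stats::quantile(y, quantile, names = FALSE)
  }
  if (is.null(threshold)) stop("supply `threshold` or `quantile`")
  as.integer(y > threshold)
}
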