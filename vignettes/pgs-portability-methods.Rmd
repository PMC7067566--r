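---
title: "Models and methods behind pgsport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pgsport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pgsport)
```

# The problem

Polygenic scores (PGS) — weighted sums of trait-associated allele counts —
are widely used for phenotypic prediction, and their accuracy is usually
discussed in terms of genetic ancestry. But prediction accuracy can also vary
*within* a single ancestry group: across strata defined by sample
characteristics such as sex, age or socio-economic status, and across GWAS
designs (standard GWAS in unrelated individuals versus sibling-difference
GWAS). `pgsport` provides a fully synthetic, end-to-end reimplementation of
that analysis logic: a forward genetic simulator with the relevant
complications (stratum-specific genetic amplification or environmental
variance, indirect parental genetic effects, assortative mating), the two
GWAS designs, clumping + p-value-threshold score construction, incremental
R²/AUC evaluation, and the experiment harnesses that compare strata and
designs under controlled conditions. Everything runs from seeds; no external
data are used.

# Generative model

## Genotypes

A panel of `m` biallelic SNPs is laid out in contiguous LD blocks of
`block_size` SNPs, spilling onto further chromosomes whenever coordinates
would pass ~240 Mb. Haplotypes are simulated by a first-order
copying process: within a block the latent uniform driving each allele is
reused from the previous SNP with probability `within_block_r` and refreshed
otherwise. With the allele frequency constant within a block (drawn once per
block from `[maf_low, maf_high]`), adjacent alleles on a haplotype have
correlation exactly `within_block_r`, decaying geometrically with distance
inside the block and vanishing across blocks. This is deliberately the
simplest LD model that gives clumping something real to do — a tunable local
r² and a physical distance scale — while making "unlinked panel" an exactly
attainable special case (`within_block_r = 0` or singleton blocks), which
the moment-based heritability estimator requires. Real human LD (variable
block lengths, allele-frequency-dependent r², long-range structure) is not
emulated, so tests passing here say nothing about LD-driven portability
failures; that axis is intentionally out of scope.

Block gaps default to 2 Mb, i.e. beyond the 1 Mb clumping window, so blocks
are also the units of clumping; shrinking `block_gap_bp` places several
blocks in one window when cross-block window behaviour needs exercising.

## Effects and phenotype

`m_causal` SNPs are causal with direct effects
$\beta_j \sim N(0, h^2/m_\text{causal})$ and zero for the rest. The genetic
score of individual $i$ is $g_i = \sum_j \beta_j X_{ij}$ on allele counts.
The phenotype is assembled as

$$ y = a_s \sqrt{h^2}\, z_g \;+\; \eta\, z_\text{ind} \;+\;
   e_s \sqrt{1-h^2}\, z_\varepsilon $$

where $z_g$ and $z_\varepsilon$ are the *sample*-standardized genetic and
environmental components, so that with unit multipliers and no indirect term
the trait has variance one and the genetic share of variance is exactly
$h^2$ up to Monte-Carlo noise. The stratum multipliers implement the two
competing explanations for accuracy differences across strata:

* `a_mult` ("amplification"): genetic effects scaled by $a_s$ with perfect
  effect correlation across strata — the within-stratum heritability becomes
  $a_s^2 h^2 / (a_s^2 h^2 + e_s^2 (1-h^2))$ while the cross-stratum
  re-estimated effect slope is $a_A/a_B$;
* `e_mult`: pure environmental-variance scaling, under which heritability is
  inversely proportional to the adjusted phenotypic variance — the
  hypothesis `fit_inverse_proportionality()` tests.

Strata are assigned either independently of the phenotype (the sex/age
analogue) or by thresholding a collider $c = \lambda y + \sqrt{1-\lambda^2}
\epsilon$ at its empirical quantiles (the adult-SES analogue, which induces
range restriction; unit multipliers are enforced there because the trait
must exist before the stratum does). Sex (Bernoulli) and age (uniform on
40–70, a biobank-like recruitment window) are generated as covariates; an
optional additive sex effect is available but defaults to zero so the
standardization formula holds exactly.

## Families, indirect effects, assortative mating

`simulate_cohort()` always creates offspring from an explicit parental
generation: founders are simulated, given vanilla phenotypes, paired by
`mate_parents()`, and transmit — independently per LD block — one intact
within-block haplotype each (free recombination between blocks, none within,
Mendelian by construction). One offspring per couple forms the "unrelateds"
pool; designated couples contribute exactly one sibling pair each. Because
the unrelateds are themselves children of the simulated parents, standard
GWAS on them absorbs indirect parental effects and assortative-mating
signal, while the sibling-difference design conditions both away — the
mechanism the design comparison is about.

Indirect parental effects are parameterized as a second per-SNP effect
vector with sample correlation exactly `rho_di` with the direct effects and
standard deviation `indirect_scale` times that of the direct effects. The
offspring phenotype receives $\eta\, z_\text{ind}$ where $z_\text{ind}$
standardizes the mother-plus-father indirect genetic score, so $\eta$ is
directly the standard-deviation contribution of the indirect channel. This
follows the verbal model of indirect effects mediated through parents; it is
the package's own parameterization and is not claimed to reproduce any
specific published formal model. The scenario default used in the
comparison tests, $\eta = 0.3$ with $\rho_{di} = 0.8$, was chosen once as a
moderately strong genetic-nurture channel (9% of phenotypic variance),
strong enough to separate the designs without dominating the trait.

Assortative mating pairs the two halves of the founder pool by rank of
phenotype plus Gaussian noise. If both sides receive noise of variance
$\tau^2$ and are matched exactly by rank, the spousal phenotype correlation
is $\mathrm{var}(y)/(\mathrm{var}(y)+\tau^2)$; inverting this for the target
`am_strength` gives the starting $\tau^2$, and one calibration iteration
refits the effective variance from the realized correlation. The procedure
is deterministic given the seed and hits the target within Monte-Carlo
noise. Only one generation of assortment is simulated — enough to induce
the cross-locus correlations that inflate standard-GWAS estimates, but
weaker than the multi-generation equilibrium; directional claims are
therefore tested, not magnitudes.

# Association designs

`ols_gwas()` is the standard design: per-SNP OLS of the phenotype on allele
count plus covariates, implemented by exact Frisch–Waugh–Lovell
residualization with residual degrees of freedom $n - k - 2$, which is
numerically identical to the per-SNP full regression (the unit tests hold it
to an `lm()` refit at $10^{-8}$). `logistic_gwas()` fits per-SNP
maximum-likelihood logistic regressions with Wald standard errors; its
weights are log odds ratios. `sib_diff_gwas()` residualizes all siblings'
phenotypes jointly on age and sex, then regresses within-pair residual
differences on genotype differences, with `n_pairs - 2` degrees of freedom.

Standard errors are analytic everywhere, chosen for speed and determinism
over permutation-based empirical SEs; the SE-matching step consumes
whichever SEs these functions produce, so the contract "matched median SE
implies matched prediction accuracy under the vanilla model" is exercised
end to end regardless. Degenerate SNPs (monomorphic, no within-pair
variation, separated in the logistic fit) are excluded with a message and
recorded in an attribute, never emitted as NaN rows. Two-sided p-values use
the t reference for the linear designs and the normal reference for the
logistic Wald statistic.

# Score construction and evaluation

Clumping is the greedy plink-style procedure: among SNPs at or below the
p-value threshold, repeatedly take the most significant remaining SNP as an
index and remove unselected candidates within ±1 Mb on the same chromosome
with squared count-correlation ≥ 0.1 in the LD reference (ties in p broken
by position; the index-centered interpretation of the window is assumed).
Scores are *sums* of weighted counts (plink's sum-vs-average ambiguity is
resolved as SUM; the two differ by an affine transform, which neither R² nor
AUC sees). Allele flips between a score file and a panel are applied
automatically (count ↦ 2 − count) with a message.

Prediction accuracy is incremental R² — the gain in unadjusted R² when the
score joins a covariates-only linear model — and incremental AUC for binary
traits, computed by the concordant-pair rank statistic with ties counted
one half (exactly equivalent to trapezoidal ROC integration). Accuracy
distributions across resampling iterations are compared with the two-sided
Mann–Whitney test (normal approximation, tie and continuity corrections).

## Heritability diagnostics

`h2_moment_estimate()` is a Haseman–Elston regression: pairwise products of
the standardized, covariate-residualized phenotype regressed (with
intercept) on off-diagonal entries of the standardized-genotype GRM. All
pair sums are reduced to `m × m` crossproducts, so the GRM is never formed
($O(nm^2)$ time, $O(m^2)$ memory), and the SE is a ten-group
delete-a-group jackknife over individuals. The estimator is only valid when
the GRM SNPs are essentially uncorrelated, so it refuses linked panels
unless an explicit causal set is supplied — the situation the simulator
controls. It stands in for summary-statistic heritability methods (LD score
regression), which need realistic genome-scale LD this simulator does not
provide.

`fit_inverse_proportionality()` fits $h^2_s = c/\mathrm{var}_s$ through the
origin on per-stratum estimates (a free-intercept toggle is provided, since
either reading of a "simple linear regression" dashed line is defensible)
and, given estimator SEs, judges consistency by
$\chi^2 = \sum_s (r_s/\mathrm{se}_s)^2$. Under environmental-variance-only
differences the fit is consistent; under amplification it is rejected —
the package's in-silico version of the argument that environmental variance
alone does not explain accuracy differences.

# The experiment harnesses

`run_stratified_experiment()` holds out equal-size prediction sets per
stratum, builds per-stratum GWAS sets of exactly equal size (down-sampling
to the smallest stratum) plus a "diverse" set of the same total size with
equal per-stratum counts, runs GWAS → clump → score → evaluate in every
prediction stratum, and attaches per-stratum HE heritability and adjusted
phenotypic variance. `reestimate_effects_by_stratum()` orients ascertained
SNPs so the discovery effect is positive and re-estimates them per stratum;
because the regressor in the cross-stratum slope carries sampling noise, the
naive OLS slope is attenuated (by roughly 20% at the default re-estimation
sizes), so the primary slope applies the standard errors-in-variables
moment correction
$\sum b_A b_B / (\sum b_B^2 - \sum \mathrm{se}_B^2)$ with a
jackknife-over-SNPs SE; the naive slope is also reported.

`run_sib_compare()` reproduces the standard-versus-sibling design: discovery
GWAS in a large unrelated set; SNP ascertainment by clumping at each
threshold of the grid $10^{-8}, \dots, 10^{-2}$; effect re-estimation both
by a standard GWAS on an `n*`-sized unrelated set and by the
sibling-difference GWAS; scoring of a held-out prediction set with both
weight sets over the *identical* SNP list; and the ratio of incremental R²
values. `estimate_n_star()` exploits the $1/\sqrt{n}$ law of OLS standard
errors: the inverse median SE is linear in $\sqrt{n}$ over a subsample
grid, and inverting the fitted line at the sibling design's median SE gives
the standard-GWAS size `n*` with matched sampling noise — and hence matched
prediction accuracy under the vanilla model. The grid is refitted per
iteration by default (cheap, and it propagates subsampling uncertainty); a
fit-once mode is provided. Discovery, estimation and prediction sets are
asserted disjoint every iteration, and thresholds with empty ascertainment
yield explicit missing cells, never zero-filled ratios.

One subtlety matters for validating the vanilla equivalence of the two
designs: the sibling set is fixed, so its GWAS — and therefore the noise in
the sibling weights — is a single frozen realization shared by every
resampling iteration. With a few hundred score SNPs that frozen draw moves
a whole run's mean ratio by a few percent in either direction, and an
across-iteration confidence interval cannot see it. `run_sib_compare()`
therefore supports trait replicates (`n_trait_replicates`): the comparison
is repeated over independently redrawn traits — fresh causal effects and
environmental draws on the same genotyped cohort (fresh cohorts when
indirect effects or assortative mating are active, since those shape the
parental generation) — which refreshes the sibling estimation noise
between replicates, mirroring validation over several simulated replicate
traits. The design-equivalence check uses six replicates of five
iterations.

The indirect-effect and assortative-mating scenario runs use a fully
polygenic trait (every panel SNP causal, per-SNP discovery
non-centrality around five) rather than the sparse default architecture.
This is not a convenience: the gap between the designs operates through
the noise-to-signal ratio of the estimated weights, so it is expressed
when the score carries weakly estimated SNPs — the regime of highly
polygenic traits, and the reason the gap widens as the p-value threshold
is relaxed. Under the sparse default (500 causal SNPs at these sample
sizes) every ascertained SNP is estimated almost without error in both
designs and the two scores converge regardless of mechanism; a correct
implementation would show nothing there.

# Problem sizes and defaults

The study conditions are desk-scale by design — only ratios and contracts
matter, not biobank magnitudes: 30,000 unrelateds, 4,000 sibling pairs,
2,000 SNPs in blocks of 10 with adjacent haplotype correlation 0.9, 500
causal SNPs, $h^2 = 0.5$, an `n*` grid of 1,000–8,000 by 500, 10
resampling iterations by default (six trait replicates of five iterations
for the vanilla design-equivalence validation, 20 for the stratified
experiment). Founder haplotypes are stored
as raw bytes and parental count matrices are never materialized, keeping
the peak footprint of the default cohort near one gigabyte. The
heritability-recovery experiment in `scripts/acceptance.R` uses an unlinked
all-causal panel of 2,000 SNPs and 10,000 individuals, averaged over 10
seeds, at the two simulated heritabilities (0.5, 0.1).

# Numerical choices and degenerate inputs

Seeds are mandatory arguments of every stochastic entry point and are
consumed through a local RNG scope, so calls do not disturb the caller's
RNG stream and identical configuration plus seed gives bit-identical
output. Constant vectors standardize to zero rather than NaN (so $h^2 = 0$
traits are pure environment). Clumping ties in p are broken by (chromosome,
position); a monomorphic LD-reference column is treated as clumped with
anything. Empty score models score everyone zero. `incremental_r2` refuses
constant phenotypes; `rank_sum_test` refuses empty samples; sibling GWAS
excludes SNPs with no within-pair variation. Oracle tolerances in the test
suite: $10^{-8}$ for linear-regression paths against `lm()` refits,
$10^{-6}$ for logistic against `glm()`, $10^{-12}$ for pure arithmetic
(scores, genetic values).

# Known limitations

* No population structure or stratification confounding, no PCs; the
  covariates are sex and age only.
* Hard genotype calls only; no imputation dosages.
* One generation of assortative mating; no gene–environment interaction
  beyond the stratum multipliers; no sibling-to-sibling indirect effects.
* The LD model is first-order within fixed-size blocks; conclusions about
  clumping behaviour under realistic LD (e.g. MHC-like regions) do not
  follow.
* The HE moment estimator is restricted to unlinked or causal-flagged
  panels and is not a general heritability method.
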