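---
title: "Mapping proportion-type preference phenotypes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping proportion-type preference phenotypes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefqtl)
```

This vignette explains the statistical machinery behind `prefqtl`: what each
stage assumes, which parameters matter, how the synthetic-data generator is
calibrated, and where the genuinely open design choices were resolved.

## The phenotype and why it needs a mixed model

Each backcross male is tested in repeated two-female choice trials; the
phenotype is the number of "courtship minutes" directed toward
*H. melpomene* females, `minutes_mel`, out of his total
`n = minutes_mel + minutes_cyd`. Males differ enormously in how much they
court at all (totals of a handful to dozens of minutes), so treating the
proportion as Gaussian would both mis-weight males and ignore its
mean–variance relationship. Males with `n = 0` carry no information about
the proportion and are excluded by every scan (the generator produces such
males naturally, mirroring real screens where some males never court).

The scan model at a genome position with genotype-probability covariate
$g_i = P(\text{het}_i)$ is a binomial GLMM:

$$y_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
  \mathrm{logit}(p_i) = \beta_0 + \beta_1 g_i + u_i, \qquad
  u_i \sim N(0, \sigma^2),$$

with one binomial row per male, so the random intercept $u_i$ is an
observation-level effect absorbing overdispersion (behavioral consistency
within males beyond binomial noise). Regressing on the genotype
*probability* rather than a hard call is the mixed-model analogue of
Haley–Knott regression: positions between markers remain informative in
proportion to what the flanking markers say.

**LOD convention.** The scan reports
$\mathrm{LOD} = (\ell_{\text{full}} - \ell_{\text{null}})/\ln 10$, where
the null model drops $\beta_1$ and is fitted once per phenotype vector.
The likelihood-ratio statistic $2\Delta \ln L = 2\ln(10)\,\mathrm{LOD}$ is
reported alongside wherever models are compared (`fit_multiqtl`,
`compare_groups`); the two scales are never conflated.

**Likelihood evaluation.** The scalar random intercept makes the marginal
likelihood a product of one-dimensional integrals, which are evaluated by
Gauss–Hermite quadrature (21 nodes by default, 15 in the heavy simulation
loops; accuracy was checked against adaptive `integrate()` to 1e-6 and
against an independent mixed-model implementation to 1e-4 on shared test
problems). Optimization is BFGS on $(\beta, \log\sigma)$ with an analytic
gradient and relative tolerance 1e-10, refined by Nelder–Mead if the first
pass reports non-convergence; scan positions warm-start from their
neighbour on the same chromosome. Positions with a constant covariate get
LOD 0 by convention, and non-converged positions are flagged in the result
rather than dropped.

## Genotype probabilities

`compute_genoprob` implements the standard two-state forward–backward
algorithm for a backcross: prior 1/2 at the chromosome start, Haldane
transition probability $r(d) = \tfrac12(1 - e^{-2d/100})$ across a gap of
$d$ cM, and an emission model in which the observed code equals the truth
with probability $1 - \texttt{error\_rate}$ (default 0.001, exposed as a
parameter) while missing codes are uninformative. The evaluation grid is
the union of marker positions and whole-cM steps. Posteriors were verified
against exhaustive path enumeration on small chromosomes, and the
implementation satisfies the expected symmetries (P(het) = 1/2 at the
midpoint of equally spaced discordant flanks; monotone decay toward the
prior away from a lone marker).

Both sexes are treated identically: the design this emulates analyzes only
backcross males, so no special sex-chromosome state space is provided — a
documented limitation for designs where it matters. Input genotypes are
assumed already phased onto parental lines and cleaned of the
map-construction masking step; `read_cross` performs structural validation
only.

## Permutations

Significance thresholds shuffle *whole phenotype rows* across individuals,
keeping (`minutes_mel`, `minutes_cyd`, `n_trials`) together. This is the
only permutation unit that respects the random-intercept grouping — the
per-male totals travel with the male. The threshold at level $\alpha$ is
the $1-\alpha$ empirical quantile of the per-permutation genome-wide max
LOD. Permutation orders are drawn up front from the seed and depend only
on the number of individuals, so the same seed yields the same shuffles on
any marker grid — which is what makes "a one-chromosome threshold cannot
exceed the full-genome threshold on identical data" an exact, testable
statement rather than a stochastic one.

## Multi-QTL model, penalized LOD, effect sizes

`fit_multiqtl` starts from the saturated GLMM over the detected loci
(all pairwise interactions, random intercept always retained) and
simplifies stepwise: the interactions are tested jointly first, then
singly, dropping nonsignificant terms at 0.05; main effects are retained
and characterized by drop-one tests. Model parsimony is scored by
$\mathrm{pLOD}_a(\gamma) = \mathrm{LOD}(\gamma) - T\,|\gamma|$ with $T$
the permutation threshold, and the per-QTL $\Delta\mathrm{pLOD}$ compares
the retained model to the model eliminating that QTL.

`support_interval` returns the smallest contiguous interval around the
per-chromosome peak where the LOD stays within 1.5 (configurable) of the
maximum, with peak ties broken toward the lowest cM.

`effect_size` converts the QTL into the field's effect scale: the
difference between het and hom class means as a percentage of the
parental-species gap. Two genuinely open choices are both exposed:

* **Class membership.** Model fits use genotype probabilities, but class
  means need discrete classes, so males are classified by the
  maximum-posterior call; calls with $P(\text{het}) \in [0.45, 0.55]$ are
  excluded from class means as ambiguous. Explicit calls can be supplied
  instead — e.g. genotypes inferred from a linked dominant color-pattern
  marker in follow-up males without sequence data.
* **Weighting.** The default class mean pools minutes
  ($\sum y / \sum n$), weighting males by how much information they carry;
  the unweighted per-male mean is always reported alongside. The 95% CI is
  a normal approximation on the log-odds of the pooled proportion.

The per-cue post hoc analysis (`per_cue_effects`) models
$\sqrt{\text{minutes}/\text{trial}}$ toward each female type separately as
a linear function of the locus genotypes, with drop-one F tests,
Bonferroni correction across the loci × species tests, and Levene checks
of residual variance across genotype groups (grouped by the number of
heterozygous loci per male, giving $k-1 = 3$ numerator df for three loci).
The square-root transform stabilizes the variance of small counts; the
Gaussian linear model is adequate here because this analysis asks about
raw courtship *amounts*, not the proportion.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline's
operating characteristics are measured:

* **Design**: 139 males, 21 chromosomes of 50 cM with markers every 5 cM —
  a deliberately regular stand-in for a RAD-based linkage map of a genome
  where 1 cM corresponds to roughly a quarter megabase.
* **Meiosis**: two-state Markov chain with Haldane (no-interference)
  recombination. The no-interference choice is pinned by the package's own
  LD checkpoints: 4.8 cM must convert to a 4.6% per-generation decline
  (Haldane), not 4.8% (Kosambi). Kosambi remains available for
  sensitivity analysis in the deterministic arithmetic.
* **Marker noise**: symmetric hom↔het flips at rate 0.001 and independent
  missingness at 5% — typical RAD-like rates.
* **Trials and totals**: trials per male are $1 + \mathrm{Poisson}(4.3)$,
  giving a median of 5 trials; total courtship minutes are
  $\mathrm{Poisson}(1.65 \times \text{trials})$, calibrated so the median
  fraction of trial time spent courting is about 0.11 (15-minute trials).
  The *distribution* of totals is not constrained by the emulated design —
  only its median activity level is — so both knobs are explicit
  parameters rather than baked-in constants.
* **Parental means**: default (0.05, 0.95). The emulated study measures
  but does not print them; they are configuration, never hard-coded into
  any estimator.
* **Planted QTLs and overdispersion**: each genotype class has a target
  mean proportion — the all-hom baseline sits at the parental midpoint
  minus half the summed QTL shifts, and each het QTL adds
  $\text{effect}/100 \times \text{gap}$. Overdispersion is logit-normal
  (default SD 0.8, a moderately overdispersed behavioral phenotype), and
  the class location $\mu(g)$ is solved numerically so that
  $E[\mathrm{logit}^{-1}(\mu(g) + \sigma Z)]$ equals the target. This
  mean-preserving construction is what makes "the unconditional effect
  estimator is unbiased" an exact property of the generator rather than an
  approximation that degrades as $\sigma$ grows; the cost is that the
  implied logit-scale coefficients are class-specific rather than exactly
  additive, which is invisible at the effect sizes used here.

What the generator does *not* emulate: sequence-level data (reads, RAD
loci), map-construction error, linked or epistatic QTL architectures
beyond what is planted, selection, or multi-generation pedigrees. Passing
tests therefore demonstrate correctness of the estimators under a clean
backcross with known truth — not robustness to map error or to phenotype
distributions far from the binomial-logit-normal family.

The four-population frequency generator plants complete local
introgression (`p2 := p3`) at a controlled fraction of sites over a shared
low-frequency background, constructed so the f_d denominator has the same
distribution at introgressed and non-introgressed sites — making the
expected windowed f_d equal the planted fraction exactly.

## Admixture windows

`windowed_fd` computes, per half-open physical window $[s, s + w)$
(defaults 100 kb width, 20 kb step, minimum 1 site — a reading of the
windowing conventions this analysis is normally run with),

$$D = \frac{\sum(\mathrm{ABBA} - \mathrm{BABA})}{\sum(\mathrm{ABBA} + \mathrm{BABA})},
\qquad
f_d = \frac{\sum(\mathrm{ABBA} - \mathrm{BABA})}{\sum(\mathrm{ABBA}_D - \mathrm{BABA}_D)},$$

where the denominator substitutes the dynamic donor frequency
$p_D = \max(p_2, p_3)$ for both $p_2$ and $p_3$. Windows with too few
sites or a non-positive denominator are emitted with `fd = NA` rather than
dropped, and negative values are reported rather than clipped — clipping
would bias genome-wide medians toward zero exactly where the statistic is
noisiest.

## Beavis-effect simulations

`run_beavis` keeps the genotype column fixed, simulates phenotypes at each
true effect on the grid (default 5–40% in 5% steps), and evaluates the
single-locus LOD against the genome-wide threshold passed in. Assessing
significance at the focal locus only — rather than re-running a
genome-wide scan per replicate — keeps 1,000–10,000-replicate grids
tractable; because the threshold supplied is the *genome-wide* one, the
per-replicate significance criterion is the same one the real analysis
applies at that locus. The estimated effect uses the identical
minutes-weighted estimator as `effect_size`, so empirical and simulated
effects are directly comparable. The implementation reproduces the three
diagnostic properties of the winner's curse: conditional means exceed
unconditional means, the inflation shrinks as true effects grow, and the
unconditional mean tracks the truth.

## Problem sizes used by the test suite

The simulation-based tests run at sizes chosen to give stable Monte-Carlo
verdicts on a desktop: 200 replicates of the full 139-male, 21-chromosome
recovery experiment on a 5-cM scan grid; 1,000 Beavis replicates per
effect-size cell; 60–100 permutations where only the coherence of
thresholds (not their third decimal) is at stake. All stochastic stages
take explicit integer seeds and are bit-reproducible under them.

## Known limitations

* Two-state backcross only: no F2/intercross state space, no phasing, no
  map estimation.
* The GLMM assumes a single random intercept per male; trial-level
  structure (e.g. day effects within males) is not modeled.
* `scan_subset` conditions on hard genotype calls at the conditioning
  locus; individuals ambiguous there are necessarily assigned to one side.
* The permutation null assumes exchangeability of males; family structure
  within the backcross would violate it.
* f_d input is assumed pre-polarized (outgroup-derived frequencies);
  ascertainment and coverage filters are upstream of this package.
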