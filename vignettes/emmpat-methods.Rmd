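---
title: "Evolutionary mixed-model association testing: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary mixed-model association testing: models, priors, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmpat)
```

## The problem

Resequencing a candidate gene in a cohort yields dozens to hundreds of
variants, most of them rare.  Testing each variant separately squanders
power on poorly estimated coefficients; collapsing rare alleles into a
burden score throws away the possibility that some rare alleles matter
much more than others.  This package pools information across variants
using population genetics: if purifying selection has acted on the
phenotype (or on a genetically correlated trait), a variant's fitness
effect — predictable, in distribution, from its population frequency —
carries information about the magnitude and direction of its phenotype
effect.

## The model

For individual $i$ with covariates $x_i$, genotypes $g_{ij} \in \{0,1,2\}$
(derived-allele counts) and quantitative trait $y_i$:

$$y_i = x_i' b + \sum_j g_{ij} \beta_j + e_i, \qquad e_i \sim (0, \sigma_e^2).$$

Per-variant effects are modelled as a population:

$$\beta_j = \alpha + \delta\, \hat s_j + \epsilon_j, \qquad
  \epsilon_j \sim (0,\; \delta^2 v_j + \sigma_\beta^2),$$

where $\hat s_j$ is the predicted (selection-coefficient-scale) fitness
effect of variant $j$ given its observed allele count, and $v_j$ the
variance of that prediction.  $\alpha$ is a mean effect per derived
allele; $\delta$ converts fitness units into phenotype units; and
$\sigma_\beta^2$ is the variance of effects unexplained by fitness —
the fallback that keeps the model valid (an equal-weight
variance-component model in the style of Kwee et al.) when fitness and
phenotype are unrelated.  Only the first two moments are used: the
marginal model is

$$E[y] = Xb + G(\alpha + \delta \hat s), \qquad
  \mathrm{Var}[y] = G\,\mathrm{diag}(\delta^2 v_j + \sigma_\beta^2)\,G' +
  \sigma_e^2 I,$$

fit by Gaussian quasi-maximum-likelihood.  Carriers of many rare alleles
therefore shift in mean *and* gain variance, and both channels contribute
to the test.  The `split` mode (`model_spec(delta_mode = "split")`)
estimates separate $\delta$'s in the mean and the variance as a
robustness check; the nested `single` mode ties them.

The variance function multiplying $v_j$ is held constant in the effect
level: effects at a given true fitness are assumed homoscedastic.  A
fitness-dependent variance function would be a straightforward extension
but is deliberately out of scope here.

## The fitness prior

The prior $(\hat s_j, v_j)$ is computed once per cohort (it depends on
genetic history, not the phenotype):

1. take a distribution of fitness effects (DFE) — a point mass at
   neutrality plus a gamma distribution of deleterious magnitudes — and a
   demographic history;
2. simulate the candidate region forward in time many times
   (`simulate_population`), recording every segregating variant's true
   $s$ and population frequency $q$;
3. for an observed count $k$ out of $n$ chromosomes, weight every
   pseudo-variant by $\binom{n}{k} q^k (1-q)^{n-k}$ and report the
   weighted mean and variance of $s$ (`conditional_moments`).  This
   binomial-sampling shortcut replaces exact count matching (which is
   retained behind `exact = TRUE` for validation) and uses every
   simulated variant at every count.

In multi-ethnic cohorts much variation is private to one group, so each
variant is assigned an **origin stratum** — the one where its observed
frequency is highest, the assignment most skeptical of rarity — and its
prior is computed from that stratum's pseudo-data at the
stratum-specific count (`assign_origin`, `build_prior`).  If no
pseudo-variant supports a count (weights underflow to zero), the nearest
supported count is used and a warning raised.

The forward simulator is per-site and unlinked: mutations arrive as
Poisson events on an infinite-sites locus, enter as single copies in the
offspring generation, then evolve by deterministic genic selection
$q' = q(1+s)/(1+qs)$ (multiplicative fitness, no dominance) and binomial
drift, with fixed and lost sites dropped.  Linkage is ignored throughout;
for frequency-conditional moments of $s$ the impact of linkage
disequilibrium is modest for a single short gene, and no linkage-based
quantity is ever computed from the simulation.  A burn-in of
$10 \times 2N_{\text{anc}}$ generations precedes the epoch schedule.

Internally runs are *4Ns-rescaled* (`rescale_factor`, default 10 in the
shipped configuration): sizes divided by $R$, selection coefficients,
mutation rate and growth rates multiplied by $R$, durations divided by
$R$.  This preserves $4Ns$ and $4N\mu$ — hence diffusion-scale frequency
dynamics — at a fraction of the cost.  What it cannot represent are
population frequencies below $1/(2N/R)$: the ultra-rare tail of the site
frequency spectrum is truncated, so rescaled populations have fewer
segregating sites than a full-scale population with the same parameters
(tens rather than low hundreds for a gene-sized locus), while
heterozygosity-weighted summaries, which are dominated by variants above
$\sim 10^{-3}$ frequency, are essentially unaffected.  Rescaled
deleterious coefficients are truncated at $-0.95$ so the selection update
stays defined; such variants are effectively lethal either way.

### The equilibrium oracle

At constant population size the simulator can be checked analytically:
under Poisson Random Field theory the frequency density of variants with
scaled coefficient $\sigma = 4Ns$ is Wright's sojourn density
$\propto (1-e^{-\sigma(1-q)}) / (q(1-q)(1-e^{-\sigma}))$, with limit
$1/q$ at neutrality.  `prf_conditional_moments` mixes this over the DFE
and the binomial sampling kernel by deterministic quadrature
(equal-probability gamma bins in $s$; log-warped Gauss–Legendre panels in
$q$ to absorb the $1/q$ singularity).  The test suite holds the
quadrature to three significant digits against a plain dense-grid Bayes
computation, and holds the forward simulator to the oracle within Monte
Carlo error — a genuinely independent check, since the simulator never
evaluates the sojourn density.

## Estimation, testing, interpretation

**Profiling.**  At each variance evaluation the linear mean parameters —
covariate effects, per-class $\alpha$, and in the split mode the
mean-model $\delta$ — are profiled out exactly by generalized least
squares, leaving at most a handful of free parameters per class
($\delta$, $\sigma_\beta^2$, and the shared $\sigma_e^2$).  All inner
products under $V^{-1}$ are reduced to an $m \times m$ system via the
matrix-determinant identity, so the per-evaluation cost scales with the
number of variants, not $n^3$.  Analytic gradients (checked against
finite differences in the test suite) drive a BFGS search from three
starting points: a null start, a start from the ordinary-least-squares
fit of the mean model, and a perturbed copy.  Positivity is enforced by
parameterizing $\log \sigma_e^2$ and softplus$^{-1}(\sigma_\beta^2)$.
Convergence is declared at relative log-likelihood change below $10^{-9}$
($10^{-8}$ in permutation refits) with a small gradient norm;
non-convergence is flagged on the result, never thrown.

**Testing.**  The global null (no variant affects any aspect of the
phenotype) is tested by a likelihood-ratio statistic calibrated by
permutation: genotype vectors are swapped only between members of the
same stratum, which preserves each variant's per-stratum counts — and
therefore the entire fitness prior — exactly.  Implementation detail:
the swap is carried out as the inverse permutation of the
phenotype/covariate rows, which leaves every genotype cross-product
cache valid across permutations.  Refits are warm-started at the
observed optimum and fall back to the standard multi-start search if
they fail to converge.  The p-value uses the add-one convention,
$(1 + \#\{T_b \ge T\})/(B+1)$.

**BLUPs and decomposition.**  Per-variant effect estimates are empirical
BLUPs with elementwise Wald 95% prediction intervals (variance and
scaling parameters treated as known; covariate-coefficient uncertainty
propagated).  Perfectly correlated variants share their joint effect
evenly rather than being pruned.  `attributable_variance` reports the
sample variance of per-individual BLUP genetic values over the
covariate-adjusted phenotypic variance — a within-stratum quantity when
stratum terms are in the covariates.  `fitness_split` reports the
parameter-based decomposition into a fitness-related portion
($\mathrm{Var}_i(\sum_j \tilde g_{ij} \hat\delta \hat s_j) +
\hat\delta^2\,\mathrm{mean}_i(\sum_j \tilde g_{ij}^2 v_j)$, genotypes
centered within strata) and a fitness-independent portion
($\hat\alpha^2$- and $\hat\sigma_\beta^2$-weighted analogues).  The two
summaries answer different questions and are reported separately, never
summed into each other.  Defining the split through expected variances
of the two independent components (rather than through realized BLUPs)
is a documented implementation choice; it is invariant to the scale
convention of $\hat s$ beyond the product $\hat\delta \hat s$.

## The synthetic cohort generator and its calibration

`power_scenarios()` carries the generative parameter sets used
throughout: a baseline ($\gamma = -7.0$, $\sigma_\beta = 0.012$,
$\alpha = 0.007$, residual SD 0.22) in which the fitness-related and
fitness-independent components each explain about 0.84% of phenotypic
variance, plus high/low variations of each parameter, a zero-correlation
scenario, and a pure null.  Effects are generated as
$\beta_j = \alpha + \gamma T(s_j) + \epsilon_j$; robustness knobs
(`robustness_knobs`) supply sign-preserving $|s|$-power transforms with
the variance of $T(s)$ rescaled to the linear case, a 50/50 random-sign
mixture, standardized-log-normal (skewed) deviations, a fraction of
exactly-null variants, and analysis-side-only DFE misspecification.
Cohorts draw genotypes by Hardy–Weinberg sampling from the population
frequencies; phenotypes add Gaussian residuals.

The shipped DFE/demography defaults (`default_popgen.yaml`) are
approximations to published fits: gamma shape 0.184 with mean
deleterious $|s| \approx 0.042$ for new coding mutations, a neutral
point mass of 0.1, the canonical human per-site mutation rate
$2\times10^{-8}$, and an expansion-only size history (ancestral 8,000
diploids growing 2.5-fold over the last 1,600 generations to 20,000) —
a reasonable shape for an African-ancestry-majority cohort, and one that
keeps deleterious variants at the low frequencies purifying selection
implies (an out-of-Africa bottleneck relaxes selection and lets
deleterious alleles drift upward; with it, burden-style tests become
unrealistically powerful on synthetic data).  The locus length (10,200
sites) was then fixed, once, so that the simulated gene reproduces the
polymorphism summaries that the baseline variance shares imply: a
heterozygosity sum $\sum_j 2q_j(1-q_j) \approx 2.3$ and a
fitness-weighted sum $\sum_j 2q_j(1-q_j)s_j^2 \approx 8.5\times10^{-6}$,
which together put both baseline variance shares at $\approx 0.84\%$
(verified over 800 replicate populations: fitness share
$0.83 \pm 0.03$, fitness-independent share $\approx 0.88$).

What the generator does **not** emulate: linkage disequilibrium and
recombination hotspots; the ultra-rare frequency class removed by
rescaling (so absolute site counts are below what a full-scale
simulation would give, and tests on synthetic data see the same signal
spread over fewer variants — absolute power levels on synthetic cohorts
therefore run above what a full-scale population with identical variance
shares would give, while orderings between methods are preserved);
sequencing error and missingness; and case-control or extreme-phenotype
ascertainment.  Passing tests demonstrate calibration and relative
power under the stated generative model, not performance guarantees on
any particular real cohort.

The per-population fitness share is heavy-tailed (a single moderately
deleterious variant that drifted to modest frequency can dominate
$\sum 2q(1-q)s^2$), with an SD of roughly 0.7 around the 0.84 mean.
Averages over populations are therefore the meaningful quantity; the
reproduction script averages ~220 populations × 2 cohorts
(standard error ≈ 0.05), and smaller averages should not be
over-interpreted.

## Problem sizes in the shipped checks

The test suite runs the type-I-error study at 50 replicates × 99
permutations and the baseline power comparison at 40 replicates × 99
permutations on cohorts of 1,000 (the permutation cache and analytic
gradients make a refit ≈ 60 ms, so these complete in minutes);
parameter recovery uses 100 replicates at $n = 2000$, $m = 100$.  These
sizes were chosen to give binomial Monte-Carlo bands tight enough to be
informative while keeping the default check runs desk-scale; all
tolerances in the tests are the corresponding 99% Monte-Carlo bands,
computed from the design, not fitted to outcomes.

## Numerical and degenerate-input choices

* Monomorphic genotype columns are dropped with a message; duplicated
  columns are retained (the model splits their effect).
* Covariate designs must be full rank; variants collinear with
  covariates get flagged `NA` OLS estimates.
* The dense and inner-form likelihood paths agree to $10^{-8}$ and the
  inner form is selected automatically whenever $m < n$.
* A residual variance that underflows (phenotype exactly fit by
  covariates) is flagged as degenerate rather than producing infinite
  likelihoods silently.
* Ties in `assign_origin` break by the declared stratum order; ties in
  the diagnostic table's frequency ordering break by estimated effect
  size.
* Permutation p-values can never be zero (add-one convention), and
  permutation refits that fail entirely are dropped from the null sample
  with the effective $B$ reported.

## Known limitations

Only quantitative traits under prospective sampling are supported —
binary, censored, or retrospectively ascertained designs distort the
random-effect distribution and need generalized or sampling-corrected
machinery.  Effects are additive (no dominance or epistasis), and
between-variant effect correlations (spatial structure along the gene or
protein) are not modelled.  The asymptotic distribution of the LRT is
deliberately not relied on; inference is permutation-based and
stratum-aware, with local-ancestry-resolved permutation for admixed
samples left to future work.
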