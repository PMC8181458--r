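---
title: "Simulating GWAS power and score portability in two-way admixed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating GWAS power and score portability in two-way admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Genome-wide association studies are overwhelmingly run in single-ancestry
cohorts, and their results — both individual variant associations and
polygenic scores — transfer poorly across populations. Admixed populations
(African Americans, Chileans, and many others) carry chromosomes from two or
more diverged source populations, so a variant that drifted to near-fixation
in one source population, and is therefore almost undetectable there, segregates
at intermediate frequency in the admixed group. `admixpower` provides a
mechanistic forward simulation of this situation and asks, under equal
sample sizes: how much discovery power does an admixed cohort gain over its
source populations, how well do its associations replicate across
populations, and how well do polygenic-score weights transfer?

Everything is simulated from a small set of interpretable parameters; no
external data are required.

# The generative model

## Ancestry

Each admixed individual's global ancestry fraction $\theta_i$ (share of the
genome from Population 1) is drawn from a Beta distribution parameterized by
its mean $m$ and variance $v$:

$$\theta_i \sim \mathrm{Beta}\!\left(a,\; \tfrac{1-m}{m}a\right),
\qquad a = m\left(\tfrac{m(1-m)}{v} - 1\right),$$

the method-of-moments shapes, so the Beta has mean exactly $m$ and variance
exactly $v$ (this requires $0 < v < m(1-m)$; `beta_shapes_from_moments()`
rejects anything else). The default $m = 0.75$ mirrors the average West
African ancestry fraction reported for African Americans. **The ancestry
variance $v$ is a genuinely free parameter of the model** — there is no
canonical published value — and we default it to $v = 0.02$, which gives an
ancestry spread (SD $\approx 0.14$) typical of what global-ancestry
estimates in African-American cohorts look like. Several results are
sensitive to $v$ (see *Limitations*), and it is exposed everywhere
(`admixture_spec()`, config key `ancestry.variance`, CLI flag `--anc-var`).

Local ancestry at each of $n$ LD-independent loci is binomial: each of the
two haplotype copies descends from Population 1 with probability
$\theta_i$, independently across loci and copies. Draws of $\theta$ are
clipped to $[10^{-6}, 1-10^{-6}]$ so downstream regressions stay
well-posed. The source populations themselves are the degenerate cases
$\theta \equiv 1$ and $\theta \equiv 0$ (`ancestral_spec()`), and they pass
through exactly the same genotype and phenotype machinery as the admixed
cohort — that guarantees the three cohorts share locus frequencies and
architecture within a repetition.

## Genotypes

Ancestral allele frequencies are uniform on $[0.001, 0.999]$ (a
common-variant design; the narrow support keeps the Balding–Nichols Beta
shapes finite). Present-day frequencies in the two source populations are
independent Balding–Nichols draws

$$p_{1s}, p_{2s} \sim \mathrm{Beta}\!\left(p_s\tfrac{1-F}{F},\;
(1-p_s)\tfrac{1-F}{F}\right),$$

with mean $p_s$ and variance $p_s(1-p_s)F$. The per-locus $F$ is either a
fixed value (used for the $F_{ST}$ sweeps) or the *flexible* form

$$F_{ST} = F_{ST}^G + (1 - \mathrm{MAF}_a)\,\delta,
\qquad \mathrm{MAF}_a = \min(p_s, 1-p_s),$$

with background $F_{ST}^G = 0.2$ and increment $\delta = 0.3$: ancestrally
rarer variants drift further apart, as expected under a bottleneck. Causal
loci get the trait $F_{ST}$; non-causal loci always get the background
value. The result is clamped to $[10^{-4}, 1-10^{-4}]$ because a large
background plus the increment can formally exceed 1, which would make the
Beta shapes non-positive. Population frequencies may hit exact fixation (0
or 1); only causal loci lost in *both* populations are redrawn, since an
allele absent everywhere cannot carry an effect. Genotype dosages are then
two Bernoulli haplotype draws at $p_{1s}$ or $p_{2s}$ according to each
haplotype's local ancestry.

A Weir–Cockerham estimator (`wc_fst()`) is included purely as a validation
oracle: simulated cohorts at fixed $F \in \{0.1, 0.2, 0.5, 0.8\}$ must
return the generative value within $\pm 0.02$ (and do, in the test suite).

## Trait architecture

$w$ of the $n$ loci are causal. Weight magnitudes are $|N(0,1)|$; the
*sign* is where ancestry enters: positive with probability
$p_{1s}/(p_{1s}+p_{2s})$, so alleles common in Population 1 tend to raise
the trait. This single device creates directional differentiation of the
trait between the source populations and a positive trait–ancestry
correlation in the admixed group. The printed form of this sign probability
in the source material is ambiguous; we adopted the normalized fraction
(the only reading that is always a valid probability) and expose the capped
ratio $\min(p_1/p_2, 1)$ as `sign_mode = "ratio"` for sensitivity analysis.

The true polygenic score is the plain additive sum
$\mathrm{PRS}_i = \sum_s g_{is} w_s$ — no dominance, no epistasis, no
effect-size heterogeneity across ancestries.

## Environment and heritability

The non-genetic score has two modes:

* `gaussian_anc` (default): $e_i = \theta_i \epsilon_{1i} +
  (1-\theta_i)\epsilon_{2i}$ — each individual mixes two ancestral Gaussian
  noise sources in proportion to ancestry;
* `linear_anc`: $e_i = \lambda\theta_i + \epsilon_i$, with the $\lambda$
  term alone explaining a configured fraction (`env_anc_fraction`, up to
  $1-h^2$, default tested at 0.10) of total phenotypic variance.

No closed-form scaling rule is imposed. Instead the free scales are solved
*empirically per simulated cohort* so that
$\mathrm{Var}(e) = \mathrm{Var}(\mathrm{PRS})(1-h^2)/h^2$ exactly — the
realized narrow-sense heritability equals the target by construction, which
the tests verify to $\pm 0.02$. In `linear_anc` the noise is orthogonalized
against $\theta$ in-sample so the variance split is exact rather than
approximate. The admixed cohort's environmental variance is reused for the
two source cohorts (whose own genetic variance is smaller, since ancestry
variation amplifies PRS variance in the admixed group); this keeps all
three phenotypes on a single scale, at the cost that the *local*
heritability inside a source cohort is somewhat below the nominal $h^2$. In
a homogeneous cohort both environment modes reduce to plain Gaussian noise
at that shared variance.

Quantitative phenotypes are $y = \mathrm{PRS} + e$. Dichotomous phenotypes
apply a liability threshold at the *empirical* $(1-K)$-quantile of $y$
(prevalence $K$, default 0.05): exactly $\mathrm{round}(NK)$ cases, ties
broken by rank. We use the empirical quantile rather than a Gaussian
threshold because the liability is a finite mixture, not Gaussian.

## Association testing and summaries

Each locus is tested marginally: OLS for quantitative traits, maximum-
likelihood logistic regression for dichotomous ones, two-sided Wald test on
the dosage term (Wald rather than LRT — conventional GWAS practice). Global
ancestry $\theta$ is included as a fixed-effect covariate *only in the
admixed cohort*; source cohorts have constant ancestry. Loci monomorphic in
the analyzed sample, below the (inclusive, per-cohort) MAF threshold, or —
for logistic fits — non-convergent (separation; $|\hat\beta| > 30$ or no
convergence in 100 Newton steps at tolerance $10^{-8}$) are flagged
untested and count as non-significant. Power is the proportion of causal
loci with $p \le \alpha$ (all causal loci in the denominator); the false
positive rate is the same proportion over the non-causal loci.

For speed, all loci are fitted jointly: the linear scan residualizes the
phenotype and every dosage column on the covariates (Frisch–Waugh), and the
logistic scan runs Newton–Raphson in lock-step across loci with closed-form
$2\times2$/$3\times3$ information solves, retiring converged loci from the
active set. Both are verified in the test suite to match per-locus `lm()` /
`glm()` output exactly; those single-locus fits remain the independent
oracle and are never the engine.

# The experiment pipelines

All pipelines derive every random stream from one master seed via a tagged
hash (`derive_seed()`), so any repetition is reproducible in isolation and
results are independent of execution order.

**Power grid** (`run_power_grid()`): for each cell (sample size, $F_{ST}$,
$h^2$, trait type) and repetition, simulate the three cohorts under a
shared architecture, scan, and record per-population power and FPR plus the
ratio of admixed power to the mean of the two source powers. Repetitions
with zero mean source power leave the ratio `NA` and are counted in a
message rather than silently dropped.

**Replication** (`replication_experiment()`): high-polygenicity design
(1000 causal loci), MAF filter 5% per cohort, loci restricted to those
common in *both* training cohorts. Discover at $\alpha$ in one population's
training cohort (default $N = 10{,}000$), re-test exactly those loci in the
*other* population's independent test cohort (default $N = 1{,}000$) at the
same $\alpha$ (the replication threshold is not separately specified
anywhere authoritative; we equate it with the discovery threshold). Both
directions are recorded and compared by a one-sided Wilcoxon rank-sum test
across repetitions; because repetitions share architectures across
populations, a paired signed-rank variant is exposed via `paired = TRUE`.

**PRS transferability** (`prs_transferability()`): per-locus training
betas from each population's scan become score weights; selected loci are
those passing the training MAF filter and the stringency
($\alpha \in \{0.05, 5\cdot10^{-4}, 5\cdot10^{-6}, 5\cdot10^{-8}\}$),
either restricted to truly causal loci (`true_positives`) or not
(`all_positives`). Accuracy is the Pearson correlation between estimated
and true PRS in an independent test cohort, reported as the full
$3\times3$ train-by-test matrix of means across repetitions with bootstrap
(n = 1000) 95% CIs of the mean.

**Ancestry–trait power** (`ancestry_trait_power_estimate()`): a
genotype-free side calculation — draw $\theta$, assign case status from a
logistic model in $\theta$ whose intercept is solved numerically to hit the
target incidence, test `trait ~ theta` by logistic regression, and report
the fraction of significant repetitions. At zero ancestry effect this
returns approximately $\alpha$ (calibration test included).

# Default problem sizes

The shipped defaults and test/acceptance runs use desk-scale versions of
the study design: cohorts of 1,000 (10,000 for training in the replication
and PRS pipelines), 1,000 loci, 50 repetitions for calibration quantities
and 20 for the heavier pipelines. These sizes were chosen so the full suite
completes comfortably on a laptop while keeping Monte-Carlo error well
inside the assertion tolerances; sample sizes up to $10^6$ are reachable
through the same functions if you have the memory and patience.

# Design choices where the design was open

* **Beta parameterization of ancestry.** Parameterized directly by
  $(m, v)$ via method of moments; validated by closed-form moment identities.
* **Sign probability.** Normalized $p_1/(p_1+p_2)$ (see above), `"ratio"`
  mode for sensitivity.
* **Heritability by empirical scaling.** Realized $h^2$ equals the target
  exactly in-sample instead of relying on a theoretical variance formula
  that the finite mixture would only satisfy in expectation.
* **Liability threshold at the empirical quantile.** Exact case counts;
  shift-invariant.
* **Replication re-test in an independent test cohort** of 1,000 rather
  than the reciprocal training cohort (the "train on 10,000, test on
  1,000" design).
* **Replication/PRS locus counts.** These pipelines default to all 1,000
  loci causal; a separate null-locus pool is available by setting
  `n_causal < n_loci`.
* **Untested loci count as non-significant** with the full locus set in
  power/FPR denominators, so flagged separation cannot inflate power.
* **Chilean-like preset** (`fixture_cohorts("chilean-small")`): background
  $F_{ST} = 0.18$ between the source populations; the ancestry moments
  (mean 0.55, variance 0.02) are preset assumptions, not published values.

# What the generator does and does not emulate

The simulation captures the core mechanism — divergence-driven allele
frequency differences, their intermediacy in admixed genomes, ancestry-
correlated environments, and liability-threshold traits. It deliberately
omits: linkage disequilibrium (loci are independent by construction, so
nothing about tagging, fine-mapping, or clumping transfers), realistic site
frequency spectra, more than two source populations, post-admixture
selection or drift, dominance/epistasis/G×E, ascertained case-control
sampling (cohorts are population samples with cohort prevalence), and
estimated (noisy) ancestry — $\theta$ is known exactly. Passing tests
therefore demonstrate the internal consistency of this mechanism, not a
calibrated forecast for any real cohort.

# Known limitations

Two results are materially sensitive to the free ancestry variance $v$.

First, the *direction* of cross-population replication asymmetry. The
mechanism that would make admixed-discovered signals replicate better in
Population 1 than the reverse is a stringency effect: correcting for
$\theta$ costs the admixed cohort per-locus discovery power, so its
discoveries are a more strictly selected (larger-effect) set. That cost
scales with the spread of $\theta$. At the default $v = 0.02$ the admixed
cohort's ancestry is concentrated enough that the two replication
directions are statistically indistinguishable at $F_{ST} = 0.5$; at
$v = 0.05$ the admixed-first advantage appears clearly. Users studying
replication asymmetry should treat $v$ as a first-order input and choose
it to match the ancestry spread of their target population.

Second, PRS accuracy measured *in the admixed test cohort*:
Pearson accuracy there is mechanically
inflated, because both the true and the estimated score share a large
$\theta$ component there (ancestry variation amplifies true-PRS variance).
With the default $v = 0.02$, the cell-swap comparison
$r(\text{train admixed} \to \text{test Pop1})$ vs
$r(\text{train Pop1} \to \text{test admixed})$ comes out *in favor of the
latter* — the admixed-test column of the matrix dominates everything. The
robust admixed-training advantage is the within-test-population comparison:
admixed-trained weights predict better in either source population than the
*other* source population's weights do, which holds across all settings we
tested and is asserted in the test suite. Only at very small ancestry
variance ($v \lesssim 0.002$) does the cell-swap comparison also favor
admixed training. Readers comparing scores across differently-variable
test cohorts should prefer the within-cohort comparison.

Logistic scans at low prevalence flag a nontrivial fraction of rare loci
as separated; these are reported untested rather than penalized, matching
the flag-don't-penalize design, and the per-locus results agree with
`glm()` wherever both converge.

# A worked example

```{r, eval = FALSE}
library(admixpower)

arch <- simulate_architecture(n_loci = 1000, n_causal = 100,
                              fst_causal = 0.5, seed = 1)
cohorts <- simulate_three_cohorts(arch, n = 1000, h2 = 0.5, seed = 2)
scans <- lapply(cohorts, scan_cohort)
sapply(scans, function(s) power_estimate(s, arch$causal_idx, 0.05)$power_mean)
```

See the README for the printed output of this example and for how to rerun
the full acceptance computation.
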