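---
title: "Models and methods behind pccollide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pccollide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pccollide)
```

`pccollide` studies a specific failure mode of principal-component
adjustment in admixed-population GWAS: later PCs that capture local genomic
features instead of genome-wide ancestry become collider variables, and
adjusting for them creates spurious associations. This vignette documents
the generative model, the closed-form theory, the numerical choices, and
what the synthetic experiments do and do not establish.

## The generative model

Every simulation is built from four layers.

**Admixture proportions.** Each individual carries a global ancestry
proportion $\pi_i \in [0,1]$, the fraction of their genome inherited from
ancestral population 1. The default law is $\mathrm{Beta}(8, 2)$ — mean
$\mu_\pi = 0.8$, variance $V_\pi \approx 0.0145$ (SD $\approx 0.12$) — which
emulates the wide spread of African ancestry proportions observed in
African American cohorts. A point-mass family provides the homogeneous
$V_\pi = 0$ limit, and a two-point family a minimal heterogeneous
population.

**Local ancestry.** At variant $j$, individual $i$ carries
$a_{ij} \in \{0,1,2\}$ allele copies from population 1. The default
(`mode = "independent"`) draws $a_{ij} \sim \mathrm{Binomial}(2, \pi_i)$
independently across variants — the exact assumption under which the
closed-form theory is derived, since the theory involves only $\pi$ and
allele frequencies. A Markov mode with a configurable ancestry-switch rate
per megabase is available for positional realism (tract structure), but no
quantitative claim in the package depends on it.

**Genotypes.** Each allele copy from population $k$ carries the counted
allele with probability $p_{jk}$, so
$g_{ij}\mid\pi_i \sim \mathrm{Binomial}(2,\, q_j(\pi_i))$ with
$q_j(\pi) = \pi p_{j1} + (1-\pi)p_{j0}$. Ancestral frequencies for
synthetic panels come from a Balding–Nichols model with $F_{ST} = 0.2$
(the scale of West African–European divergence) around ancestral
frequencies drawn uniformly on $[0.1, 0.9]$; frequencies are clipped to
$[0.01, 0.99]$ so every variant stays polymorphic. Variants sit on six
synthetic chromosomes at 10 kb spacing by default.

**Latent features.** The empirical phenomenon that motivates the package —
one PC loading on variants in several regions across several chromosomes —
is emulated by the minimal structure that produces it: a per-individual
latent indicator $f_i \sim \mathrm{Bernoulli}(c)$ that shifts both
ancestral allele frequencies by $+s$ (carriers) or $-s$ (non-carriers)
inside every region of the feature simultaneously. This makes all feature
variants mutually correlated through $f$, across regions and chromosomes,
without modelling haplotypes, inversions, or selection — which is exactly
the point: the downstream consequences depend only on the correlation
structure, not its biological origin. Defaults ($c = 0.5$, $s = 0.45$, two
0.15 Mb regions on different chromosomes) give within-feature genotype
correlations around 0.85, strong enough that the feature owns PC2 while
genome-wide ancestry owns PC1 in a cohort of 1,000 individuals and ~7,200
variants. These scales were fixed once, by checking that the designed
phenomenon manifests, before any downstream test was written.

**Traits.** $y_i = \beta_1 g_{ij^*} + \beta_\pi \pi_i + \varepsilon_i$,
$\varepsilon_i \sim N(0, 1)$: a single causal variant plus an optional
direct ancestry effect. The conventional effect-size grid
$\beta \in \{0, 0.25, 0.5, 1, 2, 4, 8\}$ is accepted throughout.

## Closed-form expected effect sizes

Writing $\Delta_j = p_{j1} - p_{j0}$ and
$\bar q_j = p_{j0} + \Delta_j \mu_\pi$, the model implies

$$E[g_j] = 2\bar q_j,\qquad
  \mathrm{Cov}(g_j, \pi) = 2\Delta_j V_\pi,\qquad
  \mathrm{Var}(g_j) = 2\bar q_j(1-\bar q_j) + 2\Delta_j^2 V_\pi,$$
$$\mathrm{Cov}(g_1, g_2) = 4\Delta_1\Delta_2 V_\pi .$$

The last identity is the heart of confounding by ancestry: two unlinked
variants are marginally correlated exactly when both are differentiated
($\Delta_1, \Delta_2 \neq 0$) and the population is heterogeneous
($V_\pi > 0$).

The extraneous covariate
$z \propto w_1\,\mathrm{std}(g_1) + w_2\,\mathrm{std}(g_2) + \text{noise}$
mimics a PC that captures two specific genotypes; its moments propagate
linearly (population standardization — the large-sample target of the
sample-standardized `make_collider_covariate()`).

`expected_coefficient()` then solves the population normal equations of the
regression of $y$ on (intercept, $g_{\text{test}}$, covariates) assembled
from these moments. We deliberately compute expectations this way rather
than transcribing scalar bias formulas: the normal-equation route is
algebraically equivalent, covers every covariate set uniformly, and is
robust to transcription error. Its correctness is established empirically
by `monte_carlo_oracle()`, which regenerates cohorts through the package's
own samplers and averages OLS fits — agreement within 4 Monte-Carlo
standard errors across a 12-setting validation grid
(`theory_validation_grid()`) is part of the test suite.

Key consequences, each encoded as a test:

* Adjusting for the true $\pi$ (or, in practice, $\hat\pi$ or PC1) yields
  exactly unbiased estimates at both the causal and the neutral variant,
  even when an extraneous covariate is also included — at the causal
  variant.
* Without adjustment, the neutral variant inherits bias
  whenever $\beta_1 \Delta_1 \Delta_2 V_\pi \neq 0$ or
  $\beta_\pi \Delta_2 V_\pi \neq 0$; at large $n$ this becomes a spurious
  genome-wide-significant association.
* With $(\pi, z)$ adjustment, the neutral variant is biased whenever $z$ is
  conditionally correlated with both genotypes given $\pi$ and
  $\beta_1 \neq 0$ — collider bias. The magnitude is proportional to
  $\beta_1$ and increases with the strength of the $z$–genotype
  correlations.

### A note on the role of $V_\pi$ in the collider path

Confounding requires heterogeneity; the collider path, as constructed here,
does not. Because `make_collider_covariate()` builds $z$ directly from the
two genotypes, the collider bias persists even at $V_\pi = 0$ — the classic
collider structure needs no admixture. Moreover, with the construction
weights held fixed, increasing $V_\pi$ slightly *shrinks* the collider bias:
heterogeneity moves genotype variance onto the ancestry axis, which the
$\pi$ term in the model already absorbs, diluting the conditional
correlation between $z$ and each genotype. The statement "collider bias
grows with ancestral heterogeneity" is recovered when the *conditional*
covariances $\mathrm{Cov}(g_j, z \mid \pi)$ are held fixed while $V_\pi$
varies — the natural parametrization when $z$ is a PC estimated from data,
whose correlation with the variants it captures is an observed quantity.
Both facts are verified in the test suite: the collider entry of
`bias_table()` is strictly monotone (decreasing) over the $V_\pi$ grid at
fixed weights, while the unadjusted confounding entry is strictly
increasing.

## PCA, pre-processing and diagnostics

PCA standardizes genotypes by
$x_{ij} = (g_{ij} - 2\hat p_j)/\sqrt{2\hat p_j(1-\hat p_j)}$ — the binomial
scaling used by the standard genotype-PCA tools — and factorizes
$X = UDV^\top$ through an eigendecomposition of the smaller Gram matrix
($XX^\top$ or $X^\top X$), which is exact, and is verified against a direct
`svd()` to $10^{-6}$ relative tolerance in the tests. Scores are unit-norm
columns of $U$; loading signs follow the largest-magnitude-entry-positive
convention since PCs are sign-ambiguous.

Pre-processing regimes mirror standard practice: a minor-allele-frequency
filter at 0.01; exclusion of catalogued high-LD regions (the shipped
build-38 table covers the LCT, HLA, and inversion regions among others;
boundaries are 1-based inclusive, and BED input is converted from its
0-based half-open convention); and greedy sliding-window LD pruning
($r^2 < 0.1$ within 0.5 Mb by default — the stricter threshold that admixed
panels need). The pruning scan keeps the leftmost variant of any
conflicting pair; the tie rule is a free choice made for determinism and
order-independence, and the postcondition — no kept pair within the window
at or above the threshold — is asserted by brute force in the tests.
$r^2$ is computed on dosages (composite LD), matching the unphased data
model.

`pc_genotype_correlation()` computes the Pearson correlation of every PC
with every panel variant (not only those used in the PCA, matching how the
diagnostic is plotted genome-wide), and `detect_loading_peaks()` automates
the visual inspection: maximal runs of variants with
$|\mathrm{corr}| \geq 0.3$, merged within 0.5 Mb. On the planted-feature
cohort, PC1 correlates with $\pi$ above 0.99 under all four regimes; PC2
peaks sit exactly on the planted regions under no pre-processing and under
exclusion-only (when the exclusion list misses the planted regions — the
synthetic analogue of excluding previously catalogued regions while the
features in *this* dataset lie elsewhere); pruning removes every later-PC
peak, because each planted region fits inside one pruning window and
collapses to a single representative variant.

## Association testing and summary statistics

Per-variant OLS with shared covariates is computed by residualizing $y$ and
all genotype columns against the covariates once (QR), which is exactly the
full-model OLS per variant. Wald statistics are referred to the standard
normal: at the sample sizes used (thousands), the difference from the $t$
reference is negligible, and the choice is recorded here for
reproducibility. Standard errors are model-based. Genotypes collinear with
the covariates are flagged and their p-values set missing; the
spurious-association counter ignores missing p-values.

Spurious associations are counted at the chromosome level — the number of
non-causal chromosomes with at least one variant below the threshold —
because neighbouring variants in LD rise and fall together. Thresholds
follow convention: $5\times10^{-8}$ (array-scale default) and
$5\times10^{-9}$ (whole-genome sequence preset). The genomic inflation
factor $\lambda$ is the median Wald $\chi^2$ over the null median 0.4549;
the tests confirm it stays within $[0.95, 1.05]$ while a collider-induced
spurious locus is genome-wide significant — a single biased locus cannot
move a median over $10^4$ variants, which is why $\lambda$ cannot detect
collider bias.

### Common cause versus common effect: why the collider testbed uses an artificial covariate

Two superficially similar conditioning variables behave oppositely. The
latent feature $f$ is a *common cause* of its regions' genotypes: a PC that
estimates $f$ accurately (as PC2 does here, correlation ≈ 0.99 with ~30
feature variants) *blocks* the cross-region path when conditioned on, so a
trait caused by a feature-resident variant shows **fewer**, not more,
partner-region associations after adjusting for that PC. Collider bias
requires conditioning on a *common effect* of the tested and causal
genotypes — which is what `make_collider_covariate()` constructs (z is a
function of $g_1$ and $g_2$, which are conditionally independent given
$\pi$), and what a real PC becomes when it is a noisy, few-variant mixture
rather than a precise latent-factor estimate. The package therefore
reproduces the collider-induced spurious association through the
artificial-covariate construction (the same device as the
sequencing-cohort style simulation: a "PC" built from the causal variant
and one partner variant on another chromosome), while the latent-feature
cohort serves the diagnostic claims (loading peaks, the effect of
exclusion and pruning, PC1's robustness). With a single latent factor per
feature, adjusting for the naive PC2 in our generator does not induce the
partner-region hit; this is a known, documented divergence between the
minimal generator and feature-capturing PCs estimated from real admixed
data, where the PC-variant correlations are weaker and the common-effect
channel can dominate.

## Experiment orchestration

`run_experiment()` executes the full factorial design — replicate × causal
variant class × effect size × adjustment strategy — deterministically from
one master seed, recording per-cell spurious counts, $\lambda$, and the
causal-variant estimate; failures are recorded per cell without aborting
the run. Causal-variant classes follow the loading/frequency-difference
rules (top-10 |loading| per chromosome per PC; low-loading
$|\text{loading}| < 0.0008$ with $|\Delta| > 0.6$ or $< 0.005$); the
loading threshold is calibrated to array-scale panels (loadings are
unit-norm, so typical magnitude is $1/\sqrt{m}$) and should be rescaled for
small synthetic panels, as the tests do. Desk-scale defaults (n = 2,000,
6 × 2,000 variants, 50 replicates) keep a full factorial in the
ten-minute range; larger designs — cohorts of many thousands and hundreds
of causal variants — remain available through the config.

## Numerical choices and degenerate inputs

* **Seeds.** One integer seed expands into per-stage child seeds through a
  Lehmer-style mix with a stage-label hash (`child_seed()`), recorded in
  the cohort's `seed_record`; every sampler restores the caller's RNG
  state.
* **Constant covariates** (e.g., $\pi$ in a homogeneous population) are
  dropped from normal equations, as OLS would absorb them into the
  intercept; genuinely collinear designs raise an error naming the pair.
* **Zero-variance genotypes** error inside PCA (they cannot be
  standardized), correlate 0 with a flag in diagnostics, and count as
  $r^2 = 0$ in pruning.
* **Tolerances.** 4 Monte-Carlo SEs for stochastic checks; $10^{-10}$ for
  closed-form identities; $10^{-6}$ relative for factorization
  equivalence.

## What the synthetic experiments do not show

The generator reproduces the statistical skeleton the theory needs —
heterogeneous admixture, ancestry-differentiated frequencies, multi-region
correlated features, single-causal-variant traits — and none of the texture
of real data: physical LD decaying with distance, phased haplotypes,
recombination maps, more than two ancestral populations, genotyping error,
relatedness, or polygenic traits. Consequences worth keeping in mind: LD
pruning succeeds here whenever feature regions fit inside a pruning window,
whereas in real admixed data features can span windows and resist even
strict pruning; and with a single causal variant the collider bias appears
at one partner locus, whereas real traits with many causal variants could
aggregate many such paths. Passing tests therefore validate the mechanism
and the implementation, not the claim that any particular pruning setting
suffices for a given real dataset.
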