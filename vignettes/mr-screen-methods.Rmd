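---
title: "Methods: two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mrscreen implements a two-sample Mendelian randomisation (MR) screen: a small
genetic instrument for one exposure (the motivating application is a
four-variant instrument for morning plasma cortisol at the *SERPINA6/A1*
cortisol-binding-globulin locus) is tested against a panel of summary-level
GWAS outcomes (42 circulating cytokines, chemokines and growth factors), with
pleiotropy-robust sensitivity estimators, heterogeneity and instrument-strength
diagnostics, and Bonferroni-classified reporting. This vignette documents the
statistical model, every tunable that matters, the synthetic-data generator
used for validation, and the package's numerical conventions.

## The instrumental-variable model

A genetic variant is a valid instrument when it (1) associates with the
exposure (relevance), (2) shares no confounder with the outcome
(independence), and (3) affects the outcome only through the exposure
(exclusion restriction). In the two-sample design the variant–exposure
associations $\hat\beta_{Xj} \pm \sigma_{Xj}$ and variant–outcome associations
$\hat\beta_{Yj} \pm \sigma_{Yj}$ come from non-overlapping GWAS samples of the
same ancestry, both in standard-deviation units of their trait.

Each variant contributes a Wald ratio

$$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}, \qquad
  \mathrm{se}(\hat\theta_j) = \sigma_{Yj} / |\hat\beta_{Xj}|,$$

the standard error keeping only the first-order term of the delta expansion —
exposure-side uncertainty is ignored, which is accurate for strong instruments
(per-variant $F \gtrsim 30$) and is the convention the estimator suite is built
on. `wald_ratios()` refuses variants with $\hat\beta_{Xj} = 0$ by name.

## Estimators

**IVW (multiplicative random effects).** With weights
$w_j = \mathrm{se}(\hat\theta_j)^{-2}$,

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j}, \qquad
  Q = \sum_j w_j (\hat\theta_j - \hat\theta)^2, \qquad
  \phi = \max\!\left(1, \frac{Q}{J-1}\right),$$

and $\mathrm{se}(\hat\theta) = \sqrt{\phi / \sum_j w_j}$. The estimate is
algebraically identical to the slope of zero-intercept weighted least squares
of $\hat\beta_Y$ on $\hat\beta_X$ with weights $\sigma_Y^{-2}$ — the test
suite asserts this identity exactly on random fixtures. The overdispersion
factor $\phi$ is floored at 1 so that under-dispersion can never shrink the
fixed-effect standard error (the convention of the widely used MR packages).
A consequence, quantified by the package's own calibration simulations, is
that the IVW test is *conservative* at small $J$: at the screen's $J = 4$
design the type-I error at nominal 0.05 is about 0.037–0.038, because
$P(\text{reject}) = E\!\left[2\Phi(-z_{0.975}\sqrt{\max(1, Q/3)})\right]$
with $Q \sim \chi^2_3$. We regard a conservative primary test as the right
default for a multi-outcome screen and do not remove the floor. P-values use
the standard normal reference; Cochran's $Q$ is referred to $\chi^2_{J-1}$.

**Simple and weighted median.** The simple median uses the midpoint
convention at even $J$. The weighted median sorts the ratios, forms the
cumulative normalised weights $s_j = \sum_{k \le j} w'_k - w'_j/2$, and
linearly interpolates $\hat\theta_{(j)}$ against $s_j$ at $s = 0.5$; with
equal weights it reduces exactly to the simple median. Both use a parametric
bootstrap SE (default `n_boot = 1000`): each replicate redraws
$\theta^*_j \sim N(\hat\theta_j, \mathrm{se}(\hat\theta_j)^2)$ with weights
held fixed, and the SE is the SD of the replicate medians. Medians are
consistent when valid variants carry at least half the (weight) mass.

**MR-Egger.** Weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$ *with*
an intercept, after orienting every variant so $\hat\beta_X \ge 0$. Under the
InSIDE assumption (pleiotropic effects independent of instrument strength) the
slope is the causal effect and the intercept the mean directional pleiotropic
effect; the intercept's p-value is the pleiotropy test. Standard errors carry
the same $\max(1, \cdot)$ overdispersion floor with $J - 2$ denominator and
use the $t_{J-2}$ reference — the small-$J$ regression convention. Note the
intercept is only identified in the exposure-increasing orientation: if
effect alleles are coded with random signs, orientation flips cancel
directional pleiotropy on average. The generator's `positive_gamma` option
exists exactly to emulate the usual reporting convention in which the effect
allele is the exposure-increasing one.

**MR-PRESSO.** For each variant the leave-one-out IVW slope
$\hat\theta_{-j}$ gives an out-of-sample residual
$r_j = \hat\beta_{Yj} - \hat\theta_{-j}\hat\beta_{Xj}$, and
$\mathrm{RSS} = \sum_j r_j^2 \sigma_{Yj}^{-2}$. The global test simulates
`n_sim` replicate datasets ($\beta^*_{Xj} \sim N(\hat\beta_{Xj},
\sigma_{Xj}^2)$, $\beta^*_{Yj} \sim N(\hat\theta_{-j}\hat\beta_{Xj},
\sigma_{Yj}^2)$), recomputes the RSS identically, and reports the add-one
Monte-Carlo p-value $(1 + \#\{\mathrm{RSS}^* \ge \mathrm{RSS}\})/(n_{sim}+1)$,
never below $1/(n_{sim}+1)$. Per-variant outlier p-values compare each
residual contribution with its simulated counterparts,
Bonferroni-multiplied by $J$; flagged variants are removed for an
outlier-corrected IVW estimate, and the distortion test compares that shift
against removing random variant sets of the same size. Because the simulated
outcomes are drawn around the *varying* leave-one-out slopes, the reference
RSS distribution is stochastically inflated and the global test is
conservative — the package's calibration run measures a null rejection rate
of roughly 0.01–0.02 at nominal 0.05 with $J = 10$, and essentially 0 at
$J = 4$, where the outlier test also has limited power (the function warns
at $J = 4$). This mirrors the behaviour of the original implementation and
is reported rather than "corrected".

## Harmonisation

Exposure and outcome rows are matched by rsid and re-oriented to the
exposure's effect allele: identical coding is kept; swapped coding negates
the outcome beta and reflects its EAF; coding that matches only after strand
complement (A↔T, C↔G) is complemented first. Palindromic variants (A/T, G/C)
are *retained* under a forward-strand assumption and flagged
`is_palindromic`, matching the motivating screen's policy of making no
palindromic exclusions; the flag supports post-hoc filtering. Irreconcilable
allele pairs are dropped with a logged reason, so shared = harmonised +
dropped always holds. Harmonisation is an involution, and flipping an outcome
file's reported orientation changes nothing downstream. Duplicate rsids keep
the first occurrence, deterministically.

## Instrument construction and strength

`select_instruments()` applies the genome-wide threshold ($p < 5\times
10^{-8}$ by default) and an optional locus window (the motivating instrument
lies within 1000 kB of *SERPINA6/A1*). `ld_prune()` takes a user-supplied
$r^2$ matrix — the package deliberately bundles no reference panel — and
greedily keeps the best-p variant, discarding everything at $r^2 \ge 0.3$
against it, ties broken by rsid so the result is order-invariant. Strength
diagnostics: per-variant $F_j = (\beta_j/\sigma_j)^2$ with arithmetic mean,
and variance explained $r^2_j = 2\,\mathrm{eaf}_j(1-\mathrm{eaf}_j)\beta_j^2$
for standardised traits, falling back to $F_j/(F_j + n - 2)$ when EAF is
missing; the two agree asymptotically and per-variant values are summed,
which is valid for uncorrelated instruments. Because "~1% variance explained"
is ambiguous between proportion and percent in informal reporting,
diagnostics print both.

## The synthetic-data generator

`simulate_pair()`/`simulate_panel()` draw minor-allele frequencies uniformly
on `maf_range` (default 0.1–0.5: common variants, as a clumped instrument
would contain), scale true effects $\gamma_j$ so
$\sum_j 2p_j(1-p_j)\gamma_j^2$ equals `target_r2` exactly, and use the
standardised-trait closed form $\sigma = 1/\sqrt{2p(1-p)n}$ for both GWAS
standard errors — appropriate because both sides of the motivating screen
report SD-unit effects. Observed effects add Gaussian sampling noise, the
outcome mean being $\theta\gamma_j + \alpha_j$ with $\alpha_j$ from one of
four pleiotropy models: none (exclusion restriction holds by construction),
balanced, directional under InSIDE, or InSIDE-violated ($\alpha_j$ correlated
with $\gamma_j$ at a chosen $\rho$ — precisely the condition MR-Egger needs
intact, enabling negative-control experiments). Defaults are the motivating
study's conditions: $J = 4$, $n_X = 25314$, $n_Y = 8293$,
`target_r2 = 0.0095`, 42 outcomes named after the real cytokine panel.
Outcome allele coding is scrambled by default (swaps and strand complements;
palindromic pairs are only swapped so the forward-strand assumption stays
exact), which keeps harmonisation exercised in every end-to-end test.

What the generator does *not* emulate: LD between instrument variants (the
motivating instrument is four mutually uncorrelated SNPs), sample overlap
between the two GWASs, non-Gaussian effect-size distributions, allele
frequency mismatch between samples, and missingness. Passing tests therefore
validate the estimators and plumbing under the stated sampling model, not
robustness to those additional real-data pathologies.

## Screening and reporting

`run_screen()` classifies each outcome by its IVW p-value only: green
(`significant`) below the Bonferroni threshold $\alpha/m$ (0.05/42 = 0.00119
at the defaults), blue (`suggestive`) below $\alpha$, red otherwise;
sensitivity estimators are reported alongside but never drive classification.
$m$ defaults to the number of outcomes supplied but is overridable, since a
screen may fix $m$ even when outcomes come from different GWASs. Outcomes
with no overlapping variants produce a `no_overlap` row rather than aborting.
Per-outcome, per-method random streams derive from
`derive_seed(master, outcome, method)` (a 31-ary string hash modulo
$2^{31}-1$), so adding, removing or permuting outcomes never perturbs another
outcome's bootstrap or PRESSO draws, and repeated runs are bitwise identical.

## Numerical conventions and validation designs

* $z_{0.975}$ is fixed at 1.959964 so printed confidence limits reproduce
  exactly across platforms; Egger uses $t_{J-2}$ quantiles instead.
* Two-sided normal p-values are floored at $10^{-300}$ so extreme test
  statistics never produce an invalid $p = 0$ in generated data.
* All Monte-Carlo p-values use the add-one estimator and are bounded below
  by $1/(n_{sim}+1)$.
* LD pruning breaks p-value ties lexicographically by rsid; duplicate rsids
  keep the first row.

The validation suite's simulation designs (chosen once, for statistical
interpretability at tractable size): type-I error and Cochran's-Q calibration
use 2000 replicates of the default four-variant design under $\theta = 0$;
parameter recovery uses $\theta = 0.5$ with $J = 50$ and `target_r2 = 0.1`,
keeping mean per-variant $F \approx 50$ — the same strength class as the
motivating instrument; Egger-intercept recovery uses $J = 20$ candidates,
`target_r2 = 0.05`, $\mu_\alpha = \tau = 0.05$, `positive_gamma = TRUE`, with
the pipeline's own $p < 5\times10^{-8}$ selection applied first (unselected
near-zero-$\gamma$ variants would otherwise flip orientation and dilute the
intercept); PRESSO power and calibration use $J = 10$ (power at $J = 4$ is
limited, as the function itself warns) with 200 and 500 instruments
respectively. `scripts/acceptance.R` recomputes all of these from scratch at
a caller-supplied seed.

## Known limitations

First-order Wald SEs understate uncertainty for weak instruments (a
second-order option is deliberately not the default); the IVW and median
tests use normal references, anti-conservative at very small $J$ but
dominated in practice by the overdispersion floor's conservatism; the
weighted-median bootstrap holds weights fixed, slightly understating weight
uncertainty; the PRESSO global test is conservative as discussed;
correlated-instrument (generalised) IVW, mode-based estimators, multivariable
MR and Steiger filtering are out of scope.
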