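---
title: "Statistical methods behind fosnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind fosnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosnet)
```

`fosnet` analyses brain-wide c-Fos⁺ cell-density tables from 2 × 2
(stimulation × time) cohort designs. This vignette documents the models,
the numerical choices, and the reasoning behind design decisions that
were genuinely open — the things a maintainer or reviewer would want
stated rather than reverse-engineered from code.

## The per-region density model

Each region is modelled independently with a negative binomial GLM
(NB2, log link):

$$y_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
\log \mu_i = \beta_0 + \beta_1\,\mathrm{stim}_i + \beta_2\,\mathrm{time}_i
 + \beta_3\,\mathrm{stim}_i\,\mathrm{time}_i, \qquad
\mathrm{Var}(y_i) = \mu_i + \mu_i^2/\theta .$$

The response is a *density* (cells/mm²) — a count divided by a
region-specific area — and is generally non-integer. The NB2
log-likelihood is therefore evaluated in its Gamma-function form, which
is well-defined for any non-negative real response; formally this is a
quasi-likelihood extension of the NB model. The alternative (rounding to
pseudo-counts) was rejected because the area normalisation differs
across regions, so rounding would distort regions unequally.

Assumptions worth stating: densities are independent across animals
within a region; the dispersion $\theta$ is constant across the four
groups within a region but is estimated separately per region (regions
differ enormously in mean density, and a shared dispersion would let
high-density regions dominate); sex is recorded in the data model but
not entered in the design, which contains exactly the two stated fixed
factors and their interaction.

### Fitting and the Wald covariance

`fit_nb_glm()` alternates iteratively reweighted least squares for
$\beta$ at fixed $\theta$ with a one-dimensional golden-section
maximisation of the profile likelihood in $\log\theta$ over
$[-7, 25]$ (i.e. $\theta$ from ~9·10⁻⁴ to ~7·10¹⁰; the upper end of the
range behaves as effectively-Poisson). Convergence is declared when the
log-likelihood changes by less than $10^{-10}$ (relative); the linear
predictor is clamped to $[-30, 30]$ to keep `exp` finite. Starting
values are the log sample mean for the intercept and a method-of-moments
dispersion. The Wald covariance of $\beta$ is the inverse of the
numerically evaluated observed information of the *joint*
$(\beta, \log\theta)$ likelihood, so dispersion uncertainty propagates
into the coefficient standard errors; if that Hessian is not invertible
the expected information $(X'WX)^{-1}$ at the fitted $\theta$ is used.

An all-zero response cannot identify a log-scale mean; the fit returns
an intercept at a small floor with a warning and is flagged degenerate
rather than erroring, so one silent region cannot abort a brain-wide
screen.

### The omnibus test and its reference distribution

The omnibus statistic is the deviance (likelihood-ratio) comparison of
the full factorial model against the intercept-only model. Two reference
distributions are offered:

* `"lr"` (default): the deviance difference, with $\theta$ held at the
  full-model estimate, divided by its degrees of freedom and by the
  full-model deviance per residual degree of freedom, referred to
  $F(3,\, n-4)$.
* `"lr_chisq"`: the classical likelihood-ratio statistic with each
  model's dispersion profiled, referred to $\chi^2_3$. `"wald"`: the
  joint Wald chi-square on the three non-intercept coefficients.

The F form is the default because the asymptotic chi-square reference is
measurably anticonservative at cohort sizes like $n = 22$: with the
dispersion estimated from the same small sample, the $\chi^2_3$ and Wald
variants reject a true null at 2–6× the nominal rate in our null
simulations, while the F form — which lets the observed residual
deviance calibrate the denominator, exactly as the F-test does for
Gaussian ANOVA — is close to uniform. The package's FDR-control test
(`tests/testthat/test-acceptance.R`) depends on this calibration, and
any user screening ~20-animal cohorts should too. Follow-up Wald tests
(main effects, interaction, simple main effects) analogously use a
$t(n-p)$ rather than normal reference.

### Influence exclusion

Following the screening protocol, observations with generalised Cook's
distance above 0.5 are excluded and the model is refit **once** (no
iteration: the threshold is part of the protocol, an iteration policy is
not, and iterated outlier deletion at $n \approx 22$ can cascade). The
one-step distance is
$D_i = r_{P,i}^2\, h_i \,/\, \big(p\,(1-h_i)^2\big)$ with $r_{P,i}$ the
Pearson residual and $h_i$ the weighted-least-squares leverage; tests
verify it against exact leave-one-out refits. Two consequences are
documented rather than hidden: (i) after exclusion a region may fail the
minimum-per-group rule and is then reported `excluded_post_cook`; (ii)
conditioning on outlier removal shifts the null distribution of the
protocol-level p-values slightly below uniform — this is a property of
the protocol itself, so the package's null-uniformity test exercises the
omnibus test with the exclusion step disabled, while FDR control is
tested on the full protocol.

### Multiplicity, percent change, banding

Omnibus p-values are Benjamini–Hochberg adjusted across regions at
Q = 0.01 (`bh_fdr()` is a thin wrapper over `stats::p.adjust`). Only the
omnibus layer is corrected; follow-ups use α = 0.05 uncorrected, and are
reported only for omnibus-significant regions. Percent change is
computed per time level from the group means of the observations
actually used (post-exclusion); with the saturated factorial design
these equal the fitted cell means. Direction bands follow the reporting
convention `−` (< 0 %), `+` (0–200 %), `++` (201–500 %), `+++` (> 500 %),
gated on the relevant follow-up: the simple main effect of stimulation
within the time level when the interaction is significant, otherwise the
stimulation main effect.

## Connectivity networks

Within each group, regions are Pearson-correlated across animals over
pairwise-complete observations (missing cells are dropped per pair; each
pair's complete-observation count $n$ is stored and used in its own
test). P-values come from the exact transform
$t = r\sqrt{(n-2)/(1-r^2)}$ with $n-2$ df, two-tailed — two-tailed
because the pipeline's central readout is significant *anticorrelation*,
which a one-tailed positive test could never flag. At the design's
$n = 6$ and α = 0.005 the implied critical $|r|$ is ≈ 0.94: only
near-perfect covariation can form an edge, which is why brain-wide
c-Fos networks are dominated by the strong global animal-level scaling
of c-Fos expression.

Degenerate pairs (zero variance, or fewer than 3 complete observations)
are flagged: $r$ is stored as 0 and $p$ as 1, making them permanent
non-edges instead of errors.

**Edge filtering.** The default filter is the *conjunction* of the raw
threshold $p < \alpha$ (α = 0.005) and a BH step-up at q = 0.05 over all
$R(R-1)/2$ pair p-values. The combined convention is kept configurable
(`alpha_only`, `fdr_only`, `conjunction`) because published descriptions
of "significance plus FDR" edge filtering vary and are sometimes
ambiguous; the conjunction reduces to whichever filter binds, and tests
verify the three variants nest. Signed network density is the edge count
of the requested sign divided by $R(R-1)/2$ — at $R = 115$ the
denominator is 6555 — and active/sham density ratios and edge-count
deltas summarise modulation. The mean Pearson coefficient is reported
both over all defined pairs and over significant edges, since either
convention appears in practice and they differ materially.

## Co-expression analysis

PV⁺/c-Fos⁺ co-expression is expressed as
$100 \cdot \mathrm{copositive} / \mathrm{pv}$ per animal and
higher-order region, missing (not zero) when no PV⁺ cells were counted.
Each time cohort is analysed with a two-factor (stimulation × region)
between-cells ANOVA. **Region is treated as a between-cells factor** —
each animal contributes one value per region but animal identity is not
modelled. A repeated-measures treatment would be defensible biologically,
but the between-cells layout is what yields the familiar
$F(1,\, N - 2R)$ stimulation test (e.g. $F(1, 56)$ for 2 × 7 cells with
5 animals per stimulation group), and is stated prominently so users can
judge the independence assumption for themselves. Sums of squares are
Type III via `car::Anova` with sum-to-zero contrasts; on balanced
layouts this coincides with the classical decomposition, which the tests
verify against a direct cell-means oracle. Percentages are unweighted by
PV counts. Effect sizes are absolute Hedge's g,
$|g| = |J\,(\bar x_a - \bar x_b)/s_p|$ with
$J = 1 - 3/(4N - 9)$; zero pooled variance yields 0 for equal means and
a flagged `Inf` otherwise.

## The synthetic cohort generator

`generate_cohort()` emulates the data structure the analyses assume:
four groups (default 6/6 acute, 5/5 chronic — two chronic animals fewer,
as happens when samples are lost), 115 regions, overdispersed
count-derived densities with log-scale group effects, and a planted
inter-regional dependence structure. Each animal draws a latent
multivariate normal with the configured copula correlation, maps it to
uniforms, and inverts the per-region NB2 CDF
(`nb_inverse_cdf()`, backed by `qnbinom`). A Gaussian copula over NB
marginals was chosen over, say, common-factor Poisson mixtures because
it lets planted correlations — including *negative* ones, the pipeline's
central phenomenon — be specified directly as a matrix, per group if
desired. Two caveats are intrinsic: the copula correlation is not the
Pearson correlation of the resulting counts (recovery tests therefore
assert sign and ordering, not equality), and with discrete marginals
the attainable dependence is bounded away from ±1.

Non-PSD copula matrices are rejected before sampling; an explicit
eigenvalue-clipping projection (`nearest_psd_correlation()`) is
available behind `repair_copula = TRUE` but never applied silently,
because a silent repair would corrupt the planted truth that recovery
tests compare against. All randomness flows from the single `seed`;
generation saves and restores the caller's RNG state.

Defaults were fixed once: baseline density 200 cells/mm² (a mid-range
value for c-Fos⁺ densities across regions), dispersion θ = 2 (marked
overdispersion; a conventional choice, since activity-mapping reports
rarely publish dispersion estimates). What the generator does *not*
emulate: spatial structure within regions, cell coordinates, segmentation
or registration error, sex effects, and the long-tailed global scaling
of real cohorts beyond what the copula induces — so passing recovery
tests demonstrates correctness of the statistics, not realism of any
particular biological effect size.

## Problem sizes in the test suite

The statistical guarantees are exercised at the design's own scale:
null calibration of the pairwise filter on 200 replicate 115-region
cohorts at n = 6; FDR control of the omnibus screen on 200 replicate
30-region null cohorts at 6/6/5/5; coefficient recovery on 100 seeds at
200 animals per group; oracle-equivalence checks (BH enumeration,
ANOVA sums of squares, t-CDF integration, exhaustive permutation,
leave-one-out Cook refits) at desk scale. All seeds are fixed in the
tests, making every stochastic check reproducible.

## Known limitations

* The NB screen tests each region marginally; no attempt is made to
  model the strong inter-regional correlation that the connectivity
  stage itself demonstrates, so region-level q-values should be read as
  marginal FDR control.
* Cook's-distance exclusion is one-pass by design; pathological
  configurations with multiple co-masking outliers may retain them.
* At n = 5–6 per group the edge filter detects only near-perfect
  correlations; network densities at this scale are best interpreted
  comparatively (active vs sham under the identical filter), which is
  how the package reports them.
* The two-factor ANOVA's independence assumption across regions within
  an animal is a simplification, documented above.
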