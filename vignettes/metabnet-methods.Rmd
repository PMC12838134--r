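---
title: "metabnet: statistical methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metabnet: statistical methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind each pipeline stage,
why the defaults are what they are, what the synthetic generator does and
does not cover, and the numerical choices a careful user should know about.
The quick-start walkthrough is in the README; here the emphasis is on
*why*.

## 1. The measurement model

A feature's observed peak area in injection $j$ is modeled as

$$
y_{gj} \;=\; 2^{\,\mu_g + \delta_{g,c(j)} + \sigma_b e_{gj}}
\cdot d(t_j) \cdot \varepsilon_{gj},
$$

where $\mu_g$ is the feature's mean log2 intensity, $\delta_{g,c}$ an
additive condition effect on the log2 scale, $\sigma_b$ the between-subject
biological SD, $d(t)$ a smooth multiplicative drift in normalized injection
order $t$, and $\varepsilon$ multiplicative log-normal analytical noise with
$\mathbb{E}[\varepsilon]=1$ and a specified CV (the log-scale SD is
$\sigma_\ell=\sqrt{\log(1+\mathrm{CV}^2)}$ with mean offset
$-\sigma_\ell^2/2$, so the CV is exact, not approximate). Values are
censored missing-not-at-random with probability
$\operatorname{logit}^{-1}((m - \log_2 y)/s)$ — low-abundance values vanish
first, the dominant missingness mechanism in LC-MS.

QC-pool injections sit at the cohort-average level on the *raw* scale
(the pool is a physical mixture, so
$\text{pool}_g = \mu_g + \log_2\!\big(\tfrac1n\sum_c n_c 2^{\delta_{g,c}}\big)$),
diluted injections scale linearly with relative concentration, and blanks
sit at a small fraction of the pool level (contaminant features at 50 %).

## 2. Feature QC filters

Retention requires all three, with **strict** inequalities so that boundary
values fail deterministically:

| statistic | rule | default | rationale |
|---|---|---|---|
| dilution correlation $r$ | $r > 0.7$ | 0.7 | genuine analytes dilute proportionally; undetected diluted areas count as 0, preserving the monotone decline |
| QC repeatability CV | $\mathrm{CV} < 30\,\%$ | 30 % | standard untargeted repeatability bound |
| biological/blank ratio | ratio $> 3$ | 3 | signal must exceed background threefold; an undetected blank gives ratio $\infty$ (passes) |

Design decisions worth calling out:

* **Blank ratio uses means** (mean biological / mean blank), not medians:
  with only a handful of blanks a median is unstable, and a single large
  blank measurement *should* drag a feature toward failure.
* **Filters run after drift correction.** The CV criterion measures
  repeatability the instrument could achieve after correction, which is the
  quantity carried into the statistics; running filters first would discard
  features for drift the next stage removes. Filtering is idempotent: a
  second pass retains everything the first kept.
* **Undefined statistics fail their criterion** (e.g. fewer than three
  detected dilution levels, fewer than two QC areas): a feature whose
  quality cannot be demonstrated is not kept, and the report carries a flag
  naming the reason.

## 3. LOESS drift correction

Per biological matrix and feature, QC-pool intensity is regressed on
injection order with `stats::loess` (tricube weights, degree 1,
span 0.75, `surface = "direct"`), the fit is evaluated at every injection
order, and each intensity is divided by $\hat f(t)/\hat f(t_\text{mid})$.
Normalizing at the run midpoint keeps corrected intensities on their
original scale instead of rescaling to the (arbitrary) fitted level at
order 0.

Numerical choices:

* **Linear extrapolation beyond the QC range.** `predict.loess` does not
  extrapolate; orders before the first / after the last QC (blanks, the
  dilution series) are continued linearly using the fitted slope at the run
  ends, estimated by a finite difference with step
  $h=\max(10^{-3}\Delta,10^{-6})$.
* **Degree 1 everywhere.** A local line reproduces an exactly linear drift
  *exactly*, which the tests exploit; degree 2 buys little on smooth decay
  and is less stable with ~10 QC points.
* **Guard rails.** Fewer than `min_qc = 5` QC points in a matrix skips the
  whole table with a warning; a feature whose QC trace has fewer than 5
  detected points, or whose fitted curve dips non-positive, is left
  uncorrected and listed in `attr(, "uncorrected_features")`. The
  direct-surface solver can emit benign rank warnings (pseudoinverse use)
  when a local window is nearly collinear; these are suppressed because the
  fitted values remain well defined.

## 4. Normalization and imputation

Biological samples are log2-transformed and median-centered within each
condition: every sample is shifted so its median equals the condition's
common target, the median of the condition's sample medians. This removes
per-sample loading differences without moving conditions relative to each
other (between-condition contrasts are a downstream question for the test,
not the normalizer).

Missing values are imputed from a per-condition multivariate normal fitted
by EM. Because metabolites typically outnumber samples, the M-step
covariance is shrunk toward its diagonal,
$S \leftarrow (1-\lambda)S + \lambda\,\mathrm{diag}(S)$, with default
$\lambda = p/(p+n)$ — heavier shrinkage the worse the $p\!:\!n$ ratio, and
vanishing as samples accumulate. Each missing block is then filled with a
**single stochastic draw** from the conditional normal given the sample's
observed values (a tiny $10^{-10}$ ridge keeps the conditional covariance
factorizable). A draw, rather than the conditional mean, preserves variance
so downstream tests are not anti-conservative; a single draw (rather than
multiple imputation) keeps the pipeline deterministic under one seed.
Observed values are never modified, and `$imputed` records exactly which
cells were filled.

## 5. Differential abundance

For each stage-vs-Control contrast, the moderated t-test shrinks
per-metabolite pooled variances $s_g^2$ (on $d$ df) toward a prior $s_0^2$
with weight $d_0$, estimated across metabolites by matching the moments of
$\log s_g^2$ to a scaled-F model via digamma/trigamma identities
(`trigamma_inverse` is a Newton iteration). The statistic

$$
\tilde t_g=\frac{\overline{x}_{gA}-\overline{x}_{gB}}
{\tilde s_g\sqrt{1/n_A+1/n_B}},\qquad
\tilde s_g^2=\frac{d_0 s_0^2 + d\, s_g^2}{d_0+d},
$$

is referred to $t_{d_0+d}$ (normal when $d_0=\infty$). `prior_df = 0`
recovers the ordinary pooled t-test; the suite verifies both limits and
checks the full moderation against an established independent
implementation at $10^{-8}$.

FDR control is adaptive Benjamini–Hochberg: classical BH multiplied by the
Pounds robust estimator $\hat\pi_0=\min(1,\,2\bar p)$ and capped at 1.
Pounds–Cheng was chosen over spline/smoother estimators because it is
closed-form, monotone, never unstable on small families, and coincides with
the conservative $\hat\pi_0=1$ whenever the p-value histogram is flat. Each
contrast is its own adjustment family. A metabolite is significant iff
$|\log_2 \mathrm{FC}| \ge 1$ **and** adjusted $p \le 0.01$ (both boundaries
inclusive); fold changes are reported signed, $-k$ for $k$-fold down.

## 6. Co-occurrence networks

Within a group, species are kept when mean relative abundance
$> 0.01\,\%$ (strict) and prevalence $\ge 40\,\%$; metabolites when detected
— on the **pre-imputation** mask, imputed values must not manufacture
prevalence — in $\ge 40\,\%$ of group samples. Correlations use log10
metabolite intensities on pairwise-complete samples (≥ 3, else the pair is
skipped and flagged).

Significance is a two-sided add-one permutation test,
$p = (1 + \#\{|r_\pi| \ge |r_\text{obs}|\})/(B+1)$, $B = 1000$, which is
exactly level-valid by exchangeability regardless of the abundance
distributions — the reason a permutation test is used at all, since species
abundances are heavy-tailed and zero-inflated. An edge requires
$p < 0.05$ **and** $|r| > 0.3$, both strict. The retention rule keys on
Pearson $r$ by default (Spearman is always reported alongside): the edge
magnitude threshold refers to linear association on the analysis scales,
and the permutation test already supplies distributional robustness.
Pairs failing the $|r|$ gate skip their permutation test entirely — they can
never be retained — and because every pair permutes under its own child
seed, `derive_seed(master, pair_index)`, the shortcut cannot change any
result. Networks are bipartite by construction; nodes carry group-vs-control
signed fold changes when a control group is supplied.

## 7. Reproducibility and seed discipline

One master seed drives everything through `derive_seed(seed, stream)`
(an affine hash modulo the prime $2^{31}-1$): manifest randomization,
feature parameters, latent factors, taxa draws, analytical noise, the
imputation draw, and every per-pair permutation. Identical config + seed
reproduces every output file byte for byte; the test suite asserts this at
the pipeline level.

## 8. Numerical fine print

* **GraphML round trips at $10^{-12}$, not bit-exactly**: igraph's writer
  serializes reals with 15 significant digits, so re-imported attributes
  agree to ~$3\times10^{-15}$ relative error. The TSV edge list preserves
  full `write.table` precision.
* **Exact boundary fixtures**: the QC filter tests construct peak areas in
  integer/dyadic arithmetic so that `cor()` returns exactly the double
  `0.7`, the CV exactly `30`, and the blank ratio exactly `3` — strictness
  at the boundary is tested with `identical()`, not tolerances.
* **Exact-CV noise**: the generator's log-normal noise uses
  $\sigma_\ell=\sqrt{\log(1+\mathrm{CV}^2)}$ with the $-\sigma_\ell^2/2$
  mean correction, so "10 % CV" is a property, not an approximation.
* **Planted correlations are targets on the analysis scales** (species
  relative abundance vs log10 intensity). Planted species are built directly
  on the shared latent factor as a low-σ log-normal around 1.5 % and the
  remaining species are closed to the residual mass, which keeps columns
  summing to exactly 100 while attenuating the realized correlation by only
  $\sigma/\sqrt{e^{\sigma^2}-1}\approx 0.99$ at $\sigma=0.2$ (plus a small
  further attenuation from analytical noise on the metabolite side).

## 9. Generator scope and limitations

The generator covers what the pipeline's correctness depends on: QC
acquisition structure, smooth monotone(±wiggle) multiplicative drift,
exact-CV log-normal noise, logistic MNAR censoring, additive log2 condition
effects, latent-factor microbe–metabolite coupling, compositional closure.

What it deliberately does **not** model, and what passing tests therefore do
not demonstrate:

* chromatographic reality — peak shapes, co-elution, adduct/isotope
  degeneracy, retention-time warping between runs;
* batch structure beyond a single continuous run (no inter-batch jumps, no
  column changes), and only one biological matrix per table;
* ecological structure in the microbiome beyond single-factor coupling — no
  species–species interaction networks, no compositional spurious-
  correlation pathologies beyond closure itself;
* cohort realism — no covariates, confounders, or sample-size imbalance
  beyond what the config specifies; condition effects are homoscedastic on
  the log2 scale.

Statistical limitations of the pipeline itself: the single-draw imputation
understates imputation uncertainty relative to multiple imputation (a
deliberate trade for determinism); the MVN model is misspecified under
strong MNAR, so imputed values near the detection limit are optimistic; the
permutation test's $p<0.05$ gate means the expected null edge rate sits just
under 5 % — at typical group sizes the $|r|>0.3$ gate is not the binding
constraint (the 5 % permutation critical $|r|$ at $n=35$ is ≈ 0.33), so
co-occurrence networks at these thresholds are exploratory screens, not
confirmatory claims.

## 10. Default problem sizes

The defaults — 20 samples per condition, 200 features, 60 species, QC
cadence 10, four-level dilution series in triplicate, four blanks, 30 %
drift amplitude, 10 % analytical CV, $\sigma_b=0.8$ log2 — describe a small
but realistic single-matrix cohort and run the full pipeline in seconds to a
few minutes on one CPU. They are study conditions, not tuning knobs: the
test suite runs against these defaults (tightening only what a given
property needs, e.g. zero noise to test exactness) rather than against
settings chosen to make assertions pass.
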