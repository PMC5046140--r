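---
title: "Regionalizing habitat suitability and chemical quality of a medicinal plant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regionalizing habitat suitability and chemical quality of a medicinal plant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(habsuit)
```

## The problem

Where should a medicinal plant be harvested or cultivated so that it both
*grows well* and *accumulates its active compounds*? `habsuit` answers this
with a two-track regionalization built around Masson's pine
(*Pinus massoniana*), whose needles are a traditional herbal medicine whose
quality is tracked through four compounds: shikimic acid, procyanidins,
total flavonoids and total lignans.

The pipeline has two suitability surfaces:

1. **Growth suitability** — a presence–background maximum-entropy species
   distribution model fitted to sample-site locations against the landscape
   background.
2. **Quality suitability** — a fuzzy standardization of each ecological
   factor through a membership function fitted to an equal-weight
   *aggregative indicator* of the four compound contents, combined by a
   weighted overlay whose weights come from the distribution model's
   variable contributions (the "objective weight" route).

The two maps are overlaid into a production map, masked to land-cover
classes that can host the species (coniferous forest), classified into
highly suitable / marginally suitable / unsuitable, and validated by RMSE
between the quality map and the observed indicator at the sample sites.

## The maximum-entropy model

Among all probability distributions $p$ on the background cells whose
feature expectations match the presence sample,
$\mathbb{E}_p[f_j] = \bar f_j$, the maximum-entropy solution is the Gibbs
distribution $p_\lambda(x) \propto \exp(\lambda^\top f(x))$. We fit
$\lambda$ by minimizing the L1-regularized negative log-likelihood

$$J(\lambda) = -\lambda^\top \bar f + \log \tfrac1N \sum_{x \in \text{bg}}
e^{\lambda^\top f(x)} + \sum_j \beta_j |\lambda_j|$$

with proximal gradient descent and backtracking line search, so $J$
decreases monotonically; iteration stops when the generalized-gradient
infinity norm falls below $10^{-6}$ or after 500 iterations (the best
iterate is returned with a warning).

Design choices that matter:

* **Features**: linear + quadratic per variable, scaled to $[0,1]$ over the
  training range (hinge features available, off by default). This is the
  small-sample regime the method is chosen for; full Maxent-style feature
  auto-selection is deliberately not replicated.
* **Regularization**: the per-class multiplier `beta` (default 0.1) is
  scaled by each feature's presence-sample standard error,
  $\beta_j = \beta \cdot s_j/\sqrt{n}$. A flat penalty of 0.1 on
  $[0,1]$-scaled features would exceed the typical presence/background
  feature mean-shift and null every coefficient; the standard-error scaling
  is how Maxent-family software actually tightens the L1 bound.
* **Display scale**: `predict(type = "logistic")` applies
  $\tau r/(1-\tau+\tau r)$ with $\tau = 0.5$ and $r$ the raw density scaled
  by $e^H$ (entropy of the fitted background distribution), so a model with
  no information displays 0.5 everywhere.
* **Contributions**: permutation importance — the drop in training AUC when
  one variable is permuted across presence and background rows (mean of 10
  permutations, fixed seed), normalized to sum to 100. This is simpler and
  model-agnostic compared with path-gain bookkeeping, and directly
  comparable with published contribution tables.
* **Train/test AUC**: a 75/25 random presence split with a fixed seed;
  split proportions are a convention, not an estimate.

## The K-t membership function

Each ecological factor is standardized to a $[0,1]$ suitability through the
K-t (K-th parabolic, "ridge") fuzzy distribution with support $(a, d)$,
plateau $[b, c]$ and limb exponent $K$:

$$\mu(x) = \begin{cases}
0 & x \le a \text{ or } x \ge d\\
\left(\frac{x-a}{b-a}\right)^K & a < x < b\\
1 & b \le x \le c\\
\left(\frac{d-x}{d-c}\right)^K & c < x < d.
\end{cases}$$

This is the conventional reading of a five-parameter $(a,b,c,d,K)$ ridge
distribution and is consistent with the published calibration shipped as
`masson_membership_params()` (e.g. a negative $a$ for precipitation simply
means the fitted rising limb extends below the physical range). Threshold
calculation inverts each monotone limb in closed form:
$x_{\text{low}} = a + (b-a)\,\mathrm{cut}^{1/K}$,
$x_{\text{high}} = d - (d-c)\,\mathrm{cut}^{1/K}$.

```{r kt}
feb <- params_from_table(masson_membership_params(), "temp_feb")
kt_membership(c(6.5, 20.8, 33.6), feb)   # plateau, falling midpoint (0.5^13), edge
membership_thresholds(feb, 0.5^13)
```

Four stand-in families (trapezoidal, gaussian, two sigmoids) support
family selection by penalized curve fitting
(`select_membership_family()`, penalty $RSS \cdot n/(n-p)$); the K-t family
is the default because it is the one the calibration retains.

### Fitting memberships to the indicator

`fit_membership()` estimates $(a,b,c,d,K)$ from (factor, indicator) pairs
by multi-start Nelder–Mead least squares on a constrained parameterization
($a \le b \le c \le d$ by log-gaps, $K > 0$ by log). Numerical choices:

* **Quantile binning** (20 bins, bin means) stabilizes the noisy
  site-level relationship before fitting; unbinned fitting is available.
* **Rescaling**: the binned response is min–max rescaled to $[0,1]$.
  The indicator at a site reflects *all* factors, so the conditional mean
  given one factor is an affine compression of that factor's membership
  (amplitude roughly its overlay weight); the membership families have a
  fixed plateau at 1, so the envelope must be mapped onto their codomain
  before fitting.
* **Soft bounds** keep the fitted support within twice the observed factor
  span and $K \in [1/50, 50]$; without them the optimizer can push the
  plateau arbitrarily far outside the data when the signal is weak.

## Indicator, overlay, classification, validation

The aggregative indicator is the equal-weight mean of the four compound
contents after per-compound min–max normalization (z-score squashing is an
option). Equal weights reflect the premise that all four compounds matter
equally; custom weights are accepted for sensitivity analysis.

The quality map is the convex combination $\sum_i w_i \mu_i$ of the
standardized factor rasters, with $w$ the normalized contribution table.
Growth and quality combine by cellwise **minimum** by default — a site must
satisfy both — with product and mean as alternatives; published accounts of
such overlays rarely state the rule, so it is explicit and configurable
here. Cells whose land-cover class is not allowed become nodata before area
accounting.

Classification cutoffs are not part of the published record; the defaults
`t_high = 0.7`, `t_low = 0.4` are explicit, configurable numbers (a
quantile-based alternative exists) because reproducible class areas require
explicit cutoffs. Class percentages are computed over classified
(non-nodata) cells and always partition 100; the reported "suitable total"
is the union of the top two classes. Validation is
$\mathrm{RMSE} = \sqrt{\tfrac1n\sum (p_i - o_i)^2}$ between the quality map
extracted at the sample sites and the observed indicator — the only
observable quantity available at the sites.

## The synthetic study system

Because the original field samples and environmental layers are not
deposited, the package ships a generator with known ground truth. Defaults
define the study conditions used throughout the tests:

* a 100×100 grid of five factors (April/June precipitation, February/August
  mean temperature, altitude), each a Gaussian random field: white noise
  convolved with a Gaussian kernel (autocorrelation length 8 cells),
  variance-normalized, rescaled to means/spreads placed against the
  published K-t calibration;
* true factor weights = the published contributions normalized
  (0.034, 0.139, 0.258, 0.439, 0.130);
* 200 sample points drawn with probability proportional to true composite
  suitability (field sampling concentrates where the species thrives);
* all four compound contents = per-compound scale × composite suitability
  + Gaussian noise (sd 0.05 on the suitability scale), truncated at zero —
  one shared composite truth so the equal-weight indicator is well-posed;
* a land-cover mosaic of coniferous forest (60%), farmland (25%), water
  (10%) and urban (5%), generated by quantile-thresholding a smoothed field;
* full determinism from one master seed via the documented splitting rule
  `split_seed()`.

What the generator does *not* emulate: climate physics, cross-factor
spatial correlation, regional trends, measurement-protocol artifacts of
HPLC, or any real geography. Passing recovery tests therefore demonstrate
the pipeline's internal consistency, not its accuracy on real landscapes.

### What end-to-end recovery can and cannot show

Tests fitting a membership to *single-factor* data (indicator =
that factor's membership + noise, sd 0.05, n = 200) recover the plateau to
within ~2% of the factor range. The *end-to-end* setting is fundamentally
harder: the indicator carries factor $i$'s signal with amplitude $w_i$, and
presence-biased sampling induces explaining-away (a sampled site with an
unfavourable factor must be favourable elsewhere), which partially cancels
the marginal relationship. For the weakest factors
($w_i \approx 0.03$–$0.14$) the conditional relationship between the
factor and the composite indicator is statistically indistinguishable from
noise at these sample sizes — no curve-fitting estimator can localize their
plateaus precisely, and permutation importance has a noise floor that
inflates near-zero weights. The recovery harness reflects this honestly:
the dominant temperature factors recover plateaus within a few percent of
range and weights within ±0.05, while the weak factors do not; the
validation RMSE of the assembled quality map stays near 0.12, the scale of
the published figure. The limiting factor is information in the data, not
the optimizer.

One related caveat: min–max normalization stretches the observed indicator
relative to the true suitability scale, so even a perfect map validated
against a noiseless indicator shows a small positive RMSE from the affine
mismatch.

## Problem sizes and determinism

Unit tests run on 25–50 cell grids with 60–200 points; the recovery
harness uses the full study conditions (100×100, 200 points, 2000
background cells, 20 seeds) and completes in about two minutes on one CPU.
Every stochastic step takes an explicit seed, and the pipeline's stages
communicate only through files, so each stage is independently replayable;
each output directory carries a `manifest.json` recording the MD5 hash of
the configuration that produced every artifact.

## Known limitations

* No reprojection: all layers must share a coordinate system; alignment
  handles extent and resolution only (bilinear for continuous layers,
  nearest-neighbour for categorical).
* The fuzzy stage fits each factor marginally; a joint (backfitting)
  estimator could sharpen weak-factor recovery but is outside the published
  procedure this package follows.
* Classification cutoffs and the growth×quality combination rule are
  package conventions, not published values; results that depend on them
  should report them.
* The area table of the published regionalization is reproduced as printed
  (its stated area unit is internally inconsistent with national scope);
  the package never adjudicates units, reporting areas in the grid's own
  units.
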