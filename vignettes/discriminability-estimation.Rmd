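---
title: "Estimating the number of discriminable odor mixtures: methods and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the number of discriminable odor mixtures: methods and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorspace)
```

## The problem

How many olfactory stimuli can a human discriminate?  One influential
experimental design approaches the question combinatorially: mixtures of
`N` distinct odorous molecules are drawn from a library of `C`
components, pairs of mixtures sharing `O` components (distance
`D = N - O`) are presented in three-alternative forced-choice (3-AFC)
trials, and the observed relationship between distance and
discriminability is converted into a single resolution-like number — a
difference limen `d` — which is then plugged into a sphere-packing
formula to count how many mutually discriminable mixtures fit into the
space of all `choose(C, N)` possible mixtures.

`odorspace` implements that full pipeline, together with the statistical
machinery needed to probe it: exact packing bounds, exact binomial
hypothesis tests, limen estimation by regression and interpolation, and
systematic sensitivity sweeps over every incidental parameter the
estimate depends on.  The central scientific point the package makes
quantitative is that this estimator is *inconsistent*: its output moves
systematically — over tens of orders of magnitude — with sample sizes
and significance criteria that a robust estimate should be indifferent
to.

## The packing model

Mixtures are fixed-size subsets of a component library, so the stimulus
space is isomorphic to a constant-weight binary code.  A ball of radius
`r` around a mixture contains

$$\mathrm{ball}(r) = \sum_{x=0}^{r} \binom{N}{x}\binom{C-N}{x}$$

mixtures (replace `x` of the `N` components with `x` of the `C - N`
unused ones).  If pairs at distance greater than `d` are discriminable
and pairs within `d` are not, the number `z` of mutually discriminable
stimuli is the size of a code with minimum distance exceeding `d`, which
is bracketed by two classical bounds:

* **Hamming-type upper bound**: `z <= choose(C, N) / ball(d/2)` —
  non-overlapping balls of radius `d/2` must fit in the space;
* **Gilbert–Varshamov-type lower bound**: `z >= choose(C, N) / ball(d)`
  — a maximal code must cover the space with radius-`d` balls.

The upper bound is what the headline "trillions" computation evaluates;
interpreting it as a lower bound is a category error the bounds
machinery here makes impossible to repeat silently.  At the worst case
`d = N = 30`, `C = 128`:

```{r}
packing_bounds(stimulus_space(128, 30), 30)
```

The lower bound sensibly reaches 1 (an anosmic subject perceives one
stimulus); the upper bound stays at 4561, which is why it cannot be a
lower bound.  Exact maximal packings are known only for a few small
parameter sets, so the package reports bounds, never "the" packing
number (see the enumeration tests for small spaces, where the bounds
provably bracket greedily constructed packings).

### Numerical choices

* **Exact integer combinatorics.** `choose(128, 30)` is about 1.5e29 and
  the library-size sweeps reach `choose(10^6, 30)` at 1.7e165; doubles
  cannot represent these integers, so all counts use an
  arbitrary-precision integer type built into the package (base-10^4
  limbs, schoolbook arithmetic, exact long division).  Ratios are
  divided exactly and floored, the standard convention for Hamming-type
  bounds; unrounded `log10` values are reported alongside.
* **Fractional radii.** An estimated limen is generally non-integer, and
  the upper bound needs `ball(d/2)`.  `ball` at fractional radius is
  interpolated linearly in `log(ball)` between the neighbouring integer
  radii: volumes grow geometrically, so geometric interpolation is the
  natural choice and produces smooth `z(d)` curves.  Linear-scale
  interpolation is available (`interp = "linear"`) and always gives a
  slightly larger volume (convexity), hence a slightly smaller `z`.
* **`big_log10`** combines the top sixteen decimal digits in double
  precision, so log-scale results are accurate to ~1e-15 — far below
  any tolerance used here.

## Significance testing

Discrimination performance is tested against chance (1/3 for 3-AFC)
with the exact one-sided binomial tail, `P(X >= k)` — the framework
asks only whether performance *exceeds* chance, so no two-sided or
approximate variant is used.  Ties at `p == alpha` count as
significant, matching the "smallest k with tail <= alpha" construction
of the critical count.  Bonferroni and Holm corrections are available;
the uncorrected analysis is the default because that is the analysis
choice the sensitivity sweeps interrogate.

Two discreteness facts matter for interpretation:

* a single 3-AFC trial can never reach significance at conventional
  levels (`p = 1/3` even when correct), so `critical_fraction` returns
  `NA` ("unattainable") rather than a number;
* the *attained* size of the exact test is below the nominal `alpha`
  (at `T = 20`, `alpha = 0.05`, chance 1/3 it is 0.0376).  The
  calibration tests therefore compare observed rejection rates to the
  exact attained size, not to the nominal level.

## Limen estimation

Per-class fractions (of significant units, or of correct responses)
are regressed on percent overlap with an unweighted ordinary
least-squares line, and the limen is the overlap `o*` where the line
crosses the threshold (0.5 by default), converted to components as
`d = N (1 - o*/100)`.  `d` is kept fractional; no rounding occurs
before the ball interpolation.  Weighting by units per class is
available but off by default, matching the plain
regression-and-interpolation procedure the pipeline emulates.

The estimator is made *total* by clamping: when the fitted slope is
non-negative (discriminability not decreasing with overlap —
pathological under the framework's premise) or the crossing falls
outside `[0, 100]`, `o*` clamps to the boundary consistent with the
overall level of the data, flagged with `clamped = TRUE`.  The clamps
route degenerate inputs to the framework's exact extremes: all units
significant gives `d = 0` and `z = choose(C, N)`; none significant
gives `d = N` and the worst-case bound.

Fitting a straight line to a sigmoid-shaped curve is itself a source of
bias: the OLS crossing sits closer to the grid centre than the true
half-maximum when the curve saturates at both ends.  This bias is a
property of the emulated procedure, not of this implementation; the
parameter-recovery tests quantify it (errors of 0–4 percent-overlap
points under the default design) rather than hide it.  Per-`N` fits are
the default; overlap is always expressed as a percentage of `N`, which
lets one psychometric parameterization serve all mixture sizes.

## Sensitivity analysis

`extrapolate_counts` answers "what if the experiment had tested more
units, performing similarly": each unit's fraction correct is held
fixed and its counts rescaled (rounding half away from zero);
a bootstrap mode resamples outcomes instead.  The deterministic mode is
the default reproduction path because "perform similarly" is a
statement about expectations; the bootstrap mode adds uncertainty
bands.

`sweep_alpha_T` and `sweep_alpha_S` rerun the full pipeline over grids
of significance level crossed with tests per class (per-subject axis)
or subjects per pair (per-pair axis), labelling each cell by its
nearest landmark on the log scale: the framework's smallest possible
value `z(d = N)`, the commonly cited order of magnitude of
discriminable colors (configurable, default 1e7 — no canonical value
exists), one trillion, and the "All" ceiling `choose(C, N)`.  The
sweeps make the inconsistency assertable as a monotonicity property:
on graded (above-chance but imperfect) data, `z` never decreases as
`alpha`, `T` or `S` grows, and both the "smallest possible" and "All"
regimes are reachable from one dataset.

`consistency_curve` traces the estimate against sample size.  Two
caveats discovered in its design are worth recording.  First, with a
sharp psychometric step the curve is flat over a severalfold range
around the observed design, but under extreme deterministic
extrapolation even step data drift upward: sampling noise frozen into
the observed fractions (chance-level classes where some units happened
to score above 1/3) is eventually declared significant at any fixed
`alpha`.  The flatness tests therefore compare curves over a 4-fold
sample-size range, where the contrast between step-like and graded data
is clean.  Second, the "true" crossing point of the significance curve
itself moves with the number of trials per unit — that is the
inconsistency, and it is why recovery tests define their target as the
crossing at the design's own sample size.

`z_vs_library_size` evaluates the worst-case growth of the estimate
with the library size `C`: even under the poorest measurable
performance (`d = N`), the bound passes 1e21 at `C = 2000` and 1e61 at
`C = 10^6` — the numerator's combinatorial explosion guarantees
astronomical answers regardless of the data, which is the structural
critique in one plot.

## The synthetic generator

`generate_trials` emulates the canonical study layout: `S = 26`
subjects, mixtures of `N` in {10, 20, 30} components from a `C = 128`
library, about six overlap classes per `N` spanning 0 to near-100%
overlap, `T = 20` pairs per class, one 3-AFC judgment per subject per
pair.  Performance follows a chance-adjusted logistic in *percent*
overlap:

$$p(o) = \tfrac13 + (p_{\max} - \tfrac13)\,
  \mathrm{logistic}\!\left(\frac{m + u - o}{s}\right)$$

with defaults `p_max = 0.95`, midpoint `m = 50`, scale `s = 8`, and
per-subject midpoint shifts `u ~ N(0, 5)` — values chosen once as a
plausible psychophysical profile: strong but imperfect performance on
disjoint mixtures, half-maximal chance-corrected performance near 50%
overlap (the region where the published critical overlap falls), and
moderate subject heterogeneity.  Heterogeneity enters only through the
midpoint; that is the minimal structure needed to exercise per-subject
analyses, and deliberately not a claim about the real population.

What the generator does *not* emulate: component identities and their
chemistry (classes suffice for the whole pipeline; explicit component
sets are drawn only on request, for distance tests), intensity
matching, correlations between pairs sharing components, learning or
fatigue across trials, and any non-logistic shape of the true
psychometric function.  Passing tests on synthetic data therefore
validate the *statistical machinery* — calibration, recovery,
monotonicity, the regime map — not any empirical claim about human
olfaction.

## Problem sizes in the test suite

Tests run the full pipeline at the canonical design size (26 subjects,
20 pairs per class, 6 classes, `N = 30`), use ~1e4 units for the
type-I calibration check, enumerate spaces up to `C = 12`, `N = 4`
exhaustively against the combinatorial formulas, and sweep 4 x 4
parameter grids — sizes chosen so the whole suite completes in seconds
while leaving every statistical tolerance comfortably powered.

## Limitations

* Only bounds on the packing number are computed; exact maximal
  constant-weight codes are known only for small parameters, and the
  package makes no attempt to extend them.
* The limen method is deliberately the emulated one (OLS +
  interpolation); no sigmoidal psychometric fitting or confidence
  intervals on `o*` are provided beyond the bootstrap machinery.
* The worst-case packing count under some conventions is 4 rather
  than 1 (depending on how codes of distance exactly `N` are counted);
  the package reports the covering-argument value `max(1, ...)` and
  does not implement the alternative convention.
* Reproducing the published empirical numbers (critical overlap ≈ 51%,
  `z ≈ 2e12` at `alpha = 0.05`, `T = 20`) requires the original
  trial-level dataset, which is not redistributable here; the pipeline
  accepts any table in the documented CSV schema.
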