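---
title: "Classical response-surface designs versus adaptive Bayesian optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classical response-surface designs versus adaptive Bayesian optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsmbo)
```

## The problem

Process development for alkaline wood delignification asks a classic
optimization question: which combination of digestion temperature
(120–160 °C), time (60–180 min), and liquid-to-solid ratio (5–10)
maximizes cellulose yield while keeping the pulp within dissolving-pulp
quality targets — kappa number at most 6.57 (about 1 % residual lignin)
and intrinsic viscosity between 400 and 600 mL/g?

Two methodologies compete for the experimental budget. The classical
route runs a pre-planned three-level design (here a 15-run Box–Behnken
design with three center replicates), fits second-order polynomial
response-surface models, and reads the optimum off the fitted surfaces.
The adaptive route encodes the goal as a single scalar objective and
lets a Bayesian-optimization loop choose each next experiment from the
data so far. `rsmbo` implements both routes end to end, plus the
simulation machinery needed to study how initialization and measurement
noise affect the adaptive route, all on synthetic ground-truth surfaces
so that every claim is checkable against a known optimum.

## The penalized objective and the constrained search space

The scalar objective rewards cellulose yield $Y$ (%) and penalizes
quality violations linearly:

$$g(Y, K, \eta) = Y - w_1 \max(0, K - 6.57) - w_2 \max(0, K - 10)
 - w_3 \max(0, 400 - \eta) - w_4 \max(0, \eta - 600)$$

with default weights $w_1 = 0.2$, $w_2 = 1.8$, $w_3 = 1.0$,
$w_4 = 0.1$. The two kappa thresholds make mild lignin excess cheap and
serious excess expensive; the viscosity window is asymmetric because
viscosity below 400 mL/g (over-degraded cellulose) is much worse than
viscosity above 600 (insufficient cooking can be fixed downstream).
Inside all targets, $g$ is exactly the yield.

The low-severity corner of the box — cool, short, dry digestions that
cannot produce acceptable pulp — is excluded a priori by the linear
constraint

$$\frac{T - 120}{20} + \frac{\tau - 60}{60} + \frac{R - 5}{2.5} \ge 1,$$

whose scaled coefficients are the half-ranges of the three factors. The
excluded set is a corner simplex of exactly $1/48$ of the box volume
(`excluded_volume_fraction()` computes this analytically by
inclusion–exclusion, and a Monte-Carlo check is part of the test
suite); the remaining feasible region is convex.

## Designs and G-efficient initialization

`box_behnken()` and `ccf_design()` generate the two three-level designs
used throughout, in coded units with exact affine conversion to natural
units (`to_coded()` / `to_natural()`). Initialization subsets for the
adaptive loop are ranked by G-efficiency,

$$G = 100 \cdot \frac{p/N}{\max_{x \in \text{candidates}}
  f(x)^\top (F^\top F)^{-1} f(x)},$$

the ratio of the ideal average leverage $p/N$ to the worst
prediction-variance leverage over the admissible candidate locations,
under an intercept-plus-main-effects model. `select_g_optimal_subsets()`
enumerates all $k$-subsets exhaustively (at most $\binom{15}{8} = 6435$)
and returns every subset tied with the maximum within a relative
tolerance of $10^{-6}$ — ties are genuine here because the candidate
set is symmetric, and the tolerance absorbs floating-point differences
between symmetric leverages. The $2^3$ factorial corner set is the
unique G-optimal choice at $k = 8$ (efficiency 100 %); at $k = 5$ the
optima are the two half-fraction corner sets plus the center point.

## Second-order regression with hierarchical elimination

`fit_second_order()` fits the full ten-term quadratic by ordinary least
squares on coded factors and reports the standard design-of-experiments
diagnostics: $R^2$, predictive $R^2_{pred} = 1 - \mathrm{PRESS}/SS_{tot}$
with PRESS computed from the hat-diagonal shortcut
$e_i / (1 - h_{ii})$, hat diagonals, and externally studentized
residuals for outlier flagging (default threshold $|t| > 3$; the
threshold is a convention, chosen so that a single wild observation in
a 15-run design is flagged while ordinary noise is not).
`backward_eliminate()` removes, one at a time, the least significant
removable term with $p > 0.10$, refitting after each removal; a linear
term is protected while any retained significant interaction or
quadratic term involves it, so the reduced model is always
hierarchy-closed. Elimination order (single worst p-value per
iteration) is a deterministic convention. Kappa number is modelled on
the $\log_{10}$ scale, which is natural for a response that varies
multiplicatively over an order of magnitude; predictions back-transform
positively.

For leave-one-out metrics the selected term set is held fixed and only
the coefficients are refit per fold — re-running selection inside each
fold of a 14-point fit is unstable and answers a different question.

## Gaussian-process regression and MAP hyperparameters

The adaptive loop models the objective with a Gaussian process with
Matérn-5/2 covariance and anisotropic length scales. Inputs are
normalized to the unit cube over the declared factor ranges and outputs
standardized before fitting; hyperparameters (per-dimension length
scales, signal variance, noise variance) maximize the log marginal
likelihood plus log prior, with L-BFGS-B from 8 quasi-random starts and
analytic gradients. Numerical safety comes from a jitter ladder
($10^{-10}$ to $10^{-6}$) on the Cholesky factorization.

Priors, on the normalized scales: Gamma(3, 6) on each length scale
(mean 0.5 — functions that vary over about half the design range), and
Gamma(1.5, 15) on the noise variance. The noise prior deserves a note:
with 15 observations the marginal likelihood barely identifies the
noise variance, and under a nearly flat prior the MAP estimate can
collapse to $\approx 10^{-4}$, i.e. the GP interpolates its own
measurement noise, which roughly doubles its leave-one-out error. The
Gamma(1.5, 15) prior (mode 0.033 of the output variance) is weakly
informative against that collapse yet is overwhelmed by genuinely
noise-free data — in the zero-noise simulation cells the fitted noise
still goes to zero and interpolation quality is unaffected. Both priors
are configurable.

## Noisy expected improvement and the proposal rule

With noisy observations the incumbent "best value so far" is itself
uncertain. The acquisition is the noisy expected improvement: draw
joint posterior samples of the latent objective at all previous
experiment conditions, take each sample's maximum as an incumbent
$g_{\max,s}$, and average the closed-form expected improvement at the
candidate against those incumbents (default 128 draws, seeded). When
the fitted noise variance is zero the incumbent distribution collapses
and the classic expected improvement is recovered exactly — this
equivalence is tested. No fantasy conditioning is applied: the
acquisition uses the unconditioned posterior at the candidate, matching
the plain expectation form.

Acquisition maximization is derivative-free and deterministic given the
seed: a quasi-random screen of 4096 points (feasibility-filtered, so
infeasible conditions are simply never proposed), followed by local
polish of the top 10 by box-constrained L-BFGS-B with rejection of any
polished point that leaves the feasible region. The final iteration of
a campaign maximizes the posterior mean instead — a pure exploitation
step, since there is no budget left to learn from.

`run_bo()` ties these together: evaluate the oracle at the
initialization runs, then refit–propose–evaluate for `n_adaptive`
iterations, recording conditions, responses, objective, acquisition
value, and the running best.

## The synthetic ground truths

Because the original raw measurements are not available, the package
ships calibrated synthetic surfaces as its experiment oracles; they are
first-class, tested code.

**Extraction surface** (`make_extraction_truth()`): a full quadratic
over $T \in [150, 190]$ °C, $\tau \in [40, 160]$ min, $R \in [4, 8]$,
constructed as $y(x) = y_{\max} - s\,(x - x^*)^\top A (x - x^*)$ in
coded units with the shape matrix $A$ fixed and the scale $s$ solved
from the center anchor. Its anchors: maximum 12.7 % at
(172 °C, 97 min, ratio 6) and 11.8 % at the domain center. Both anchor
points sit close together near the center, so any quadratic satisfying
them is steep along their connecting direction and extrapolates to
strongly negative values at remote corners — the same behavior an
empirical quadratic shows far outside its data. This makes the
simulated optimization landscape genuinely hard: corner-heavy
initializations start from deeply suboptimal values.

**Pilot surfaces** (`make_pilot_truth()`): yield, kappa, and viscosity
each decay logistically in a severity variable
$s = w_T (T-120)/40 + w_\tau (\tau-60)/120$, with response-specific
weights encoding the chemistry: viscosity loss (cellulose
depolymerization) is most temperature-sensitive ($w_T = 1.3$),
delignification benefits most from long times ($w_\tau = 1.1$ for
kappa), and yield sits in between. Yield additionally gains a small
bonus in liquid-to-solid ratio and its sigmoid (amplitude 9 %-points,
midpoint severity 1.35, slope 4.5) places the transition from
hemicellulose/lignin removal into cellulose degradation inside the
region the optimization cares about — deliberately *not* a quadratic,
so the comparison between the quadratic and GP surrogates is not rigged
in favor of either. Calibrated anchors (verified by grid search in the
tests): maximum yield 56.3 % at the mildest wet conditions
(120 °C, 60 min, ratio 10), penalized-objective optimum at
approximately (131 °C, 176 min, ratio 10) with yield ≈ 54 %, kappa just
above its soft target, and viscosity just inside 600 mL/g.

Default measurement noise, as independent Gaussian standard deviations:
0.4 %-points on yield (it is derived from three separate analytical
measurements), 0.25 on kappa, and 8 mL/g on viscosity (titration and
capillary-viscometry repeatability). `cellulose_yield()` implements the
conversion from raw pulp measurements: lignin % = kappa / 6.57,
hemicellulose % = 100 − alkali resistance, both as percentages of
screened pulp mass — the mass-basis interpretation is a documented
choice.

What the generators do *not* emulate: outliers and recovery failures
(every synthetic run succeeds), drifts between campaign days,
correlated measurement errors across responses, and input-condition
uncertainty. Tests passing on these surfaces therefore demonstrate
correctness of the machinery and qualitative reproduction of the design
trade-offs, not quantitative agreement with any particular wood.

## The simulation study

`run_study()` reproduces the initialization/noise experiment: for each
initialization size 4–8, enumerate the G-optimal subsets of the 15
unique CCF candidate locations, split each cell's 200 repetitions as
evenly as possible across the tied designs (earlier designs in
lexicographic order receive the extras), and simulate 20-experiment
sequences at three noise levels (0, 0.25, 0.5 %-points — evenly spaced
across the stated range, including both endpoints). The default grid
books exactly 3000 sequences and 60,000 simulated experiments.
Convergence is always tracked on the *noiseless* truth at the visited
conditions, so measurement error can delay but never fake progress.
Seeds derive deterministically from the base seed and the cell indices,
so any cell can be reproduced in isolation.

The full 200-repetition study is a compute job, not a test; the test
suite and the acceptance script run scaled-down grids (10 and 3
repetitions over sizes {5, 8} and noises {0, 0.5}), which already show
the two qualitative effects: sequences initialized with 5 runs
(including the informative center point) reach 99 % of the known
optimum by the final exploitation step in the median, while corner-only
8-run initializations typically do not within 20 experiments, and
added noise never accelerates the median convergence.

## The pilot campaign and the model comparison

`default_pilot_dataset()` builds the canonical synthetic campaign: the
15-run Box–Behnken table, plus a Bayesian-optimization campaign that
starts from 5 of those runs and adds 10 adaptive experiments — 25 runs
in total. The 5 initialization runs are a fixed, a-priori diverse
selection spanning digestion severity and ratio (including the mild,
long, dilute condition that process knowledge marks as promising);
they are deliberately not chosen by a design-optimality criterion,
mirroring how initialization is done when prior domain knowledge
exists. Measurement noise is keyed to condition and replicate, so the
runs shared between the two campaigns carry identical measurements, as
one physical experiment would.

`loocv_rmse_comparison()` then compares a quadratic and a GP model of
cellulose yield (the GP deliberately fitted to yield only, without
penalty terms, but otherwise configured exactly as in the optimization
loop). Each model is trained on its own 15 runs; predictions at its own
training locations are leave-one-out (fixed terms, refit coefficients
for the quadratic; re-estimated MAP hyperparameters per fold for the
GP), predictions elsewhere are full-model extrapolations. RMSEs are
reported over three row-wise regions: all 25 runs, the *target* subset
(measured kappa and viscosity inside their quality windows), and the
*near-optimum* subset (time > 110 min, temperature 130–150 °C). On the
default dataset the quadratic is more accurate globally — it benefits
from a balanced space-filling design — while the GP is more accurate
near the optimum, where the adaptive campaign concentrated its runs
and the true surface bends in a way a global quadratic cannot follow.
An empty region reports `NA`, never zero.

## Numerical conventions

Problem sizes were chosen so the whole suite runs comfortably on a
single CPU: grids of ~50k points for anchor verification, 40 sequences
in the scaled-down study, 16 GP MAP fits in the model comparison. Other
conventions: coded/natural conversion is exact to $10^{-12}$;
rank-deficient design matrices raise errors naming the collinear terms
(G-efficiency reports 0 with a `singular` flag instead, since subset
enumeration must survive degenerate subsets); ties in acquisition
screening resolve to the first index, which is deterministic because
the screens are seeded; and every random procedure in the package takes
an explicit seed and restores the caller's RNG state.

## Limitations

The GP-versus-quadratic comparison is a single-campaign contrast at a
fixed seed, not a distributional claim; the simulation study is the
place where repetition supports distributional statements. MAP
hyperparameters (rather than full marginalization) understate GP
predictive uncertainty slightly. The constraint handling rejects
infeasible candidates rather than modelling feasibility, which is
appropriate only because the constraint is known a priori. And the
synthetic surfaces, while calibrated to the documented anchors, remain
smooth idealizations of pulping chemistry.
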