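---
title: "Two-stage hospital efficiency analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage hospital efficiency analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospeff)
```

## The problem

Public hospital systems consume a large share of health budgets, and the
question a regulator asks is rarely "how much does hospital A spend" but
"how much less *could* it spend while treating the same patients". hospeff
answers that question for a panel of decision-making units (DMUs) — here
hospital-years with three inputs (beds, health workers excluding
physicians, physicians) and two outputs (case-mix-weighted inpatient
episodes, outpatient episodes) — in two stages: a non-parametric frontier
stage (DEA and the Malmquist index) and a parametric second stage relating
the resulting inefficiency to environmental factors through a censored
regression.

## Stage one: input-oriented DEA

For a target DMU with inputs $x_0 \in \mathbb{R}^3_{>0}$ and outputs
$y_0 \in \mathbb{R}^2_{\ge 0}$, the Farrell input efficiency under
constant returns to scale (CRS) is the optimum of the envelopment linear
program

$$\min_{\theta,\lambda}\ \theta
\quad\text{s.t.}\quad
\sum_i \lambda_i x_{si} \le \theta x_{s0},\ s = 1,2,3;\qquad
\sum_i \lambda_i y_{ri} \ge y_{r0},\ r = 1,2;\qquad \lambda \ge 0 .$$

Adding the convexity constraint $\sum_i \lambda_i = 1$ gives the variable
returns to scale (VRS) model, whose score is *pure* technical efficiency.
Scale efficiency is the ratio $SE = \theta_{CRS} / \theta_{VRS} \le 1$,
so $TE = PTE \times SE$ decomposes overall technical efficiency into a
managerial and a scale component. Returns to scale are classified from
the CRS intensity-weight sum: $\sum\lambda > 1$ decreasing, $< 1$
increasing, $= 1$ constant. DMUs with positive weights in an optimal
solution are the target's *peers* — the best practices it is benchmarked
against.

Assumptions worth remembering: DEA is deterministic (all distance to the
frontier is read as inefficiency, none as noise), relative (at least one
DMU is always efficient), and sensitive to input/output selection and to
outliers. The package deliberately offers no bootstrap or stochastic
frontier; its scope is the classical two-stage design.

### The LP kernel

Envelopment LPs are tiny (5–6 rows, tens of columns) but notoriously
degenerate: the zero right-hand sides of the input rows create massive
pivot ties. The package therefore carries its own dense two-phase simplex
with Bland's anti-cycling rule (`simplex_lp()`), which is immune to that
degeneracy at a speed cost that is irrelevant at this scale. Tolerances:
pivoting/optimality $10^{-9}$; returns-to-scale classification $10^{-6}$
on $|\sum\lambda - 1|$; both sit far below the 4-decimal precision at
which scores are conventionally reported. Scores are clipped to $[0,1]$
only for within-period self-evaluations (noise above 1 is truncated);
cross-period distances are never clipped.

The optimal $\lambda$ of a degenerate LP need not be unique, so peer
*lists* can differ between solvers at equal scores. `slack_max = TRUE`
runs the standard second phase (maximize total slack at fixed
$\theta^*$) when a canonical vertex is wanted; the default reports the
Bland vertex, which is deterministic for a fixed input ordering.

## Stage one, continued: the Malmquist index

Productivity change between adjacent years $t, t+1$ uses four Farrell
distances $D^a(x^b, y^b)$ (frontier period $a$, data period $b$),
computed with the same CRS LP — cross-period values may exceed 1:

$$M = \left[\frac{D^t(x^{t+1},y^{t+1})}{D^t(x^t,y^t)}\cdot
\frac{D^{t+1}(x^{t+1},y^{t+1})}{D^{t+1}(x^t,y^t)}\right]^{1/2}
= ECH \times TECH,$$

with $ECH = D^{t+1}(x^{t+1},y^{t+1}) / D^t(x^t,y^t)$ the catch-up and
$TECH$ the frontier shift. $ECH$ further splits into a pure component
$PECH$ (ratio of within-period VRS scores; no cross-period VRS LPs are
needed) and a scale component $SECH = ECH / PECH$. Values above one mean
improvement throughout, which forces the distances to be Farrell
efficiencies rather than their Shephard reciprocals; the packaged
reference tables are only mutually consistent under that convention.

Design choices made where the convention is genuinely open:

* **Averaging.** Whole-period per-DMU values and cross-DMU summaries are
  *geometric* means, the natural choice for a multiplicative index; the
  per-DMU whole-period efficiency change then telescopes to
  $(\theta_{last}/\theta_{first})^{1/(P-1)}$, which is exactly how the
  packaged panel and decomposition tables reconcile (H17:
  $(1/0.7614)^{1/4} = 1.071$; H36: $(0.8954/0.5815)^{1/4} = 1.114$).
  `run_malmquist(average = "arithmetic")` is available for comparison.
* **Pairs.** Adjacent years only; no fixed-base or chained variants.
* **Balance.** A DMU missing from any requested year aborts the run with
  the missing cell named — cross-period distances of an unbalanced panel
  would silently compare different hospital sets.

## Stage two: censored regression

CRS scores pile up at 1, so they are transformed to inefficiency
$u = 1/\theta - 1 \ge 0$, exactly 0 for efficient units: a left-censored
response. The Tobit model treats observed inefficiency as
$\max(x'\beta + \varepsilon, 0)$, $\varepsilon \sim N(0, \sigma_e^2)$;
a *negative* coefficient therefore means the covariate improves
efficiency. Covariates follow the environmental-factor convention:
activity ratio `Z1`, sole-hospital flag `Z2`, catchment shares of
over-65s `Z3` and infants `Z4`, bed turnover `Z5`, bed occupation `Z6`,
average stay `Z7`, and mutually exclusive size dummies `D1`–`D3` with
the small (< 200 beds) group carried by the constant.

Two estimators are provided:

* `fit_tobit_pooled()` — maximum likelihood on $(\beta, \log\sigma_e)$
  with analytic gradients, a least-squares start plus two deterministic
  perturbations (best likelihood kept), and standard errors from the
  observed information. The log-scale parameterization enforces
  $\sigma_e > 0$ without constraints.
* `fit_tobit_re()` — adds a DMU-level random intercept
  $u_g \sim N(0, \sigma_u^2)$, integrated out by *adaptive*
  Gauss–Hermite quadrature: nodes are recentred at each group's posterior
  mode and rescaled by its curvature (found by a vectorized Newton
  iteration). Plain quadrature centred at the prior misplaces its nodes
  whenever a group's data shift the posterior, and at this panel size the
  resulting likelihood error is orders of magnitude above the $10^{-4}$
  stability we require between 12 and 24 nodes; the adaptive rule meets
  it with the default 12. One start fixes $\sigma_u$ near zero, so the
  fitted marginal likelihood can never fall below the pooled one.

Model selection fits a grid of candidate covariate sets (the six
packaged ones by default) and ranks by the Wald $\chi^2$ over all
non-constant coefficients — the statistic censored-regression software
conventionally prints — with log-likelihood reported alongside. A
candidate whose design matrix is rank deficient fails alone, with the
collinear columns named. `vif_report()` screens multicollinearity by the
auxiliary-regression definition $VIF_j = 1/(1-R^2_j)$.

## The synthetic generator as an oracle

Because the raw input/output matrix behind the packaged score tables is
not published, correctness is demonstrated on synthetic panels with
*exact* ground truth. The construction makes the true score a theorem
rather than an approximation: efficient DMUs get log-normal input bundles
$x_e$ and frontier outputs $y = Bx$ for a fixed positive technology
matrix $B$; each inefficient DMU takes a frontier point inside the cone
spanned by the efficient bundles and inflates its inputs radially by
$1/\theta_{true}$. Under CRS, any feasible contraction below
$\theta_{true}$ would need outputs $B w \ge B x_f$ from inputs
$w < x_f$ — impossible for positive $B$ — so the DEA score equals
$\theta_{true}$ exactly (the suite checks $10^{-6}$; observed error is
$\sim 10^{-14}$). Annual frontier drift multiplies outputs by a constant
factor, making the Malmquist frontier-shift component recover that
factor exactly while the catch-up term stays at 1.

Default conditions mirror the study shape: 39 DMUs, 5 years, inefficient
scores drawn from a Beta(8, 3.7) (mean 0.69, sd 0.13, matching the
dispersion of the packaged 2019 scores), drift 1.07 (the packaged
overall frontier-shift average), and a regression DGP whose coefficients
equal the packaged model-6 estimates with $\sigma_e = 0.15$,
$\sigma_u = 0.10$. Under the generator's covariate distributions those
coefficients imply a censoring share of roughly 13–17% — consistent with
the 5–8 frontier hospitals per year the reference panel shows. The
`rts = "vrs"` regime generates a concave technology (productivity
decaying with scale); there the radial construction bounds the VRS score
from above rather than pinning it, so VRS checks are invariant-based
(nesting, hull enumeration on small slices) rather than exact.

What the generator does *not* emulate: measurement error in routine
hospital statistics, case-mix coding drift, entry/exit of units, serial
correlation in covariates beyond a mild log-normal wobble, and
correlated input mixes. Passing tests therefore certify the estimators
on clean data satisfying the models' own assumptions, not robustness of
the two-stage design to real-data pathologies.

## Numerical and testing choices

* Sample (n−1) standard deviation is the summary default (the common
  statistical-software convention); population sd is a flag.
* Fixtures store printed values verbatim (4 decimals for scores, 3 for
  indices) and are never re-rounded on load. Two known print
  inconsistencies are preserved as printed: one hospital's 2019 CRS
  score differs by $10^{-4}$ between the score table and the panel
  table, and one model column carries an evident sign typo on `Z1`.
  The reference year of the factor table is implicit in its source and
  recorded as 2019; the small-size bed bound, garbled in print, is
  recorded as 200.
* Degenerate inputs (all DMUs identical) yield all-efficient slices by
  design, not an error.
* Test problem sizes: envelopment properties run on 5–20 DMU slices with
  enumeration oracles (every basic solution of the LP checked
  exhaustively), recovery sweeps on the 39 × 5 study shape, pooled
  recovery at n = 2000, and the closed two-stage loop at 200 DMUs —
  sizes at which the whole suite completes in about a minute.

## Known limitations

No DEA bootstrap or Simar–Wilson correction (the second stage inherits
the classical caveat that DEA scores are estimated, not observed); no
output orientation, super-efficiency or slack-based measures; no
reproduction of the reference coefficient table, whose underlying
five-year covariate panel is unpublished — structural parity (195
observations, 39 groups of 5) is asserted on synthetic panels instead.
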