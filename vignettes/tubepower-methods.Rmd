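---
title: "Methods: simulation-based power analysis for WHO tube bioassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-based power analysis for WHO tube bioassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(tubepower)
```

## Why simulate?

A WHO tube synergism test compares 24-hour mortality between two arms — a
pyrethroid-only exposure and a pyrethroid–PBO exposure — each arm consisting
of a handful of tubes with roughly 25 mosquitoes per tube. If tube counts
were independent binomial draws, power would be a textbook calculation. In
practice they are not: replicate tubes run side by side on the same day
disagree more than binomial sampling allows, and entire testing days drift
up or down together because of rearing batch, temperature, handling, and
other shared conditions. Both effects inflate the variance of the arm-level
mortality estimate, and the second one is not reduced by adding tubes within
a day. No closed-form power formula accommodates this two-level
overdispersion together with the boundary behaviour of mortalities near
100%, so the package estimates power by Monte Carlo: simulate the assay many
times under explicit assumptions, analyse each simulated assay exactly as a
real one would be analysed, and count rejections.

## The data-generating model

For a tube on testing day $d$ in an arm with assumed true mortality $p$:

$$
\mathrm{logit}(p_{\text{tube}}) = \mathrm{logit}(p) + \delta_d + \varepsilon_{\text{tube}},
\qquad
\delta_d \sim N(0, \sigma_b^2),
\qquad
\varepsilon_{\text{tube}} \sim N(0, \sigma_w^2),
$$

$$
n_{\text{dead}} \sim \mathrm{Binomial}(n_{\text{exposed}},\, p_{\text{tube}}).
$$

* $\sigma_w$ is the **within-day** (intra-assay, tube-to-tube) SD on the
  logit scale; $\sigma_b$ is the **between-day** (inter-assay) SD.
* With a single testing day the day effect is identically zero — a one-day
  experiment cannot distinguish a day shift from the arm mean, and the
  simulator consumes no random numbers for it.
* Arm mortalities of exactly 0 or 1 sit at infinity on the logit scale;
  those tubes are simulated deterministically (all dead or all alive),
  again consuming no random numbers. This keeps streams aligned between
  degenerate and non-degenerate arms at a given seed.
* Tubes are allocated to days as evenly as possible, with any remainder
  given to the earliest days (`day_allocation()`).

### Independent versus shared day effects

`simulate_dataset()` defaults to drawing the day effects **independently in
each arm** (`day_effects = "independent"`). The alternative
(`day_effects = "shared"`) gives both arms a common $\delta_d$, which acts
like pairing: the day shift cancels out of the between-arm comparison, and
splitting tubes over days then costs almost nothing. The independent default
reflects the pessimistic — and, for unpaired assay conduct, realistic —
situation in which the two arms do not share identical day conditions, and
it is what produces the practically important warning that spreading a fixed
number of tubes over more testing days *reduces* power. Users who genuinely
run both arms simultaneously under tightly shared conditions can switch to
`"shared"`.

## The analysis applied to each simulated assay

Deaths and exposures are pooled per arm and compared with the binomial
likelihood-ratio test of the one-factor logistic GLM. This model is
saturated in the arm factor, so its MLEs are the observed arm mortality
proportions and no iterative fitting is needed; the test statistic is twice
the log-likelihood difference between the two-proportion and pooled models,
referred to $\chi^2_1$. Terms of the form $0 \log 0$ are taken as 0, which
handles 0% and 100% arms exactly. The package's implementation is verified
in the test suite against `stats::glm` + `lmtest::lrtest` and against a
direct `dbinom` oracle.

The analysis deliberately *ignores* the day structure, exactly as the
standard two-proportion analysis of such assays does. Power estimates
therefore describe the procedure actually used in practice, with the
between-day variance acting as unmodelled overdispersion. The realized
type-I error of this asymptotic test at 4 tubes $\times$ 25 mosquitoes per
arm is about 0.056 at nominal $\alpha = 0.05$ under a pure binomial null
(the suite checks the simulator against this by exact enumeration over all
$101 \times 101$ outcome pairs).

## Power, MDD, and sample-size searches

`estimate_power()` returns the rejection fraction over `replicates`
simulated assays with its binomial Monte-Carlo standard error.
Reproducibility is controlled by a single integer seed; grid cells and
search points derive independent sub-seeds from it deterministically, so a
whole grid is bit-reproducible and individual cells can be recomputed in
isolation.

`min_detectable_difference()` scans the mortality difference upward on a
2.5-percentage-point grid from the chosen reference mortality and reports
the first difference whose estimated power reaches the target (default
80%) — a first-crossing rule on the grid, not an interpolation. A scan
truncated by the 100% mortality ceiling warns and reports the result as not
achievable. `min_tubes_for_difference()` does the analogous upward scan
over tubes per arm and skips (with a warning) candidate designs with fewer
tubes than testing days.

`simulation_grid()` / `power_grid()` evaluate full factorial designs —
the default grid spans 21 differences $\times$ 7 tube counts $\times$ 5 day
counts $\times$ 5 within-day SDs $\times$ 5 between-day SDs = 18,375
cells — with `save_grid()` / `load_grid()` caching results as CSV plus a
JSON metadata sidecar, and `grid_lookup()` raising a typed condition
(`tubepower_not_precomputed`) for cells outside the cache.

## Variance components from real data

`estimate_variance_components()` fits an intercept-only binomial GLMM on
the logit scale with a random intercept for day and an observation-level
random intercept for tube (tube labels carry no identity across days), via
the Laplace approximation in `lme4::glmer`. Boundary estimates of 0 are
reported as such — a singular fit is a legitimate outcome, not an error —
while genuine convergence failures are raised as errors. A constant
response short-circuits to zero components with the intercept-only binomial
likelihood. Companion summaries: `coefficient_of_variation()` (per-day CoV
of tube proportions; overall CoV of daily means by default, or pooled) and
`conditional_r_squared()` using the latent logistic residual variance
$\pi^2/3$. `variance_report()` bundles all three into JSON.

Single-study estimates of $\sigma_w$ from 25-mosquito tubes are noisy
(individual relative errors up to ~50% occur at 50 days $\times$ 8 tubes),
and at $\sigma_b = 0$ the between-day estimate piles at exactly zero in
about half of fits with a nonzero tail reaching ~0.1; both behaviours are
characterized and asserted in the test suite.

## Defaults and their rationale

| Argument | Default | Rationale |
|---|---|---|
| `mosquitoes_per_tube` | 25 | standard tube occupancy for this assay |
| `tubes_per_arm` | — (required) | 4 is standard practice; kept explicit |
| `within_day_sd` | 0.25 | field-realistic intra-assay logit SD |
| `between_day_sd` | 0.60 | field-realistic inter-assay logit SD |
| `alpha` | 0.05 | conventional two-sided level |
| `power_target` | 0.80 | conventional design target |
| MDD grid step | 0.025 | 2.5 pp resolution; finer is spurious at feasible replicate counts |
| `day_effects` | `"independent"` | unpaired assay conduct; see above |

## Numerical choices

* Simulation is vectorized: each replicate's arm totals come from
  matrix-shaped Normal and binomial draws, so 10,000-replicate power
  estimates run in well under a second per cell.
* Log-likelihoods omit the binomial coefficients, which cancel in the
  ratio; the statistic is floored at 0 to absorb round-off.
* Sub-seeds are derived as
  `((base %% 2147483647) + 104729 * index) %% 2147483646 + 1`, keeping
  every cell inside the valid seed range with a large prime stride.

## Limitations

* Results are conditional on the assumed variance components; when in
  doubt, estimate them from local data and pass them in.
* The logit-normal form of the random effects is an assumption, not an
  estimate; heavy-tailed day effects would degrade power further.
* The MDD is reported on the simulation grid; it is a grid point, not a
  root-found threshold.
* Mortalities are analysed raw; no abatement/correction for control
  mortality is applied.
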