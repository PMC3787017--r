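---
title: "Models and methods: formalin-test dose-response and isobolographic synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: formalin-test dose-response and isobolographic synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flinchfit)
```

# The behavioral readout

Formalin injected into the rat hind paw evokes a biphasic flinching
response. The second phase reflects ongoing afferent input plus central
sensitization, and its early part — 15 to 40 minutes post-injection,
"phase 2A" — is where supraspinally mediated antinociception (opioids,
descending noradrenergic/serotonergic modulation) is quantified. The
package reduces per-animal, time-binned flinch counts to a phase-2A total
(`phase2a_total()`), then expresses each animal's response as percent
inhibition relative to the mean total of the *concurrently tested* vehicle
group:

$$I = 100 \cdot \frac{\bar{V} - T}{\bar{V}}$$

Design choices worth stating explicitly:

* **Half-open window.** The scoring window is $[15, 40)$ minutes. Automated
  counters bin finely, so the convention only matters for coarse bins; a
  half-open interval guarantees no count is attributed to two adjacent
  windows. Bins partially overlapping the window contribute proportionally
  to their overlap.
* **Concurrent-vehicle normalization.** The dataset schema carries a
  `session` key, and every treated animal is normalized against the vehicle
  animals of its own session. Behavioral baselines drift between cohorts;
  pooling vehicle groups across sessions would leak that drift into the
  treatment effect.
* **Negative inhibition is retained.** An animal flinching more than the
  vehicle mean gets a negative percent inhibition. The 0–100 constraint
  belongs to the dose-response *model*, not to the data; clipping would
  bias group means upward at low doses.

# The constrained dose-response model

Percent inhibition is modeled by the variable-slope sigmoid with floor and
ceiling fixed at 0 and 100:

$$E(d) = \frac{100}{1 + 10^{\,h(\log_{10}\mathrm{ED}_{50} - \log_{10} d)}}$$

Only two parameters are free: $\log_{10}\mathrm{ED}_{50}$ (the dose of
half-maximal inhibition, in log10 mg/kg) and the Hill slope $h > 0$
(steepness; $h = 1$ is a simple one-site curve, larger $h$ steeper). Fixing
the asymptotes encodes two assumptions: vehicle-level responding at
vanishing dose, and complete suppression of flinching at saturating dose.
Both hold for efficacious analgesics in this assay; for a compound with a
ceiling below 100% the model will bias the ED50 upward, which is a known
limitation, not a bug.

`fit_ed50()` minimizes unweighted squared error over *per-animal* points
(not dose means), by Levenberg–Marquardt nonlinear least squares. Numerical
choices:

* **Initialization** is deterministic: $\log_{10}\mathrm{ED}_{50}$ starts at
  the dose whose group mean response is nearest 50%, $h$ at 1. Monotone
  data cannot mislead this start, and determinism makes fits reproducible
  bit-for-bit (inputs are canonically sorted first, so row order is
  irrelevant).
* **Bounds.** $h \in [0.1, 10]$, preventing degenerate step-function fits
  on sparse 4-dose designs; $\log_{10}\mathrm{ED}_{50}$ is confined to the
  dosed range ±3 decades.
* **Confidence interval.** The 95% CI is computed on the log scale —
  asymptotic SE of $\log_{10}\mathrm{ED}_{50}$ from the fit covariance,
  $t$ critical value with $n - 2$ degrees of freedom — and back-transformed,
  giving the asymmetric linear-scale intervals familiar from commercial
  dose-response software. This is an approximation of those packages'
  (undocumented) defaults, and the tests treat published CIs as validation
  guides rather than exact targets.
* **Failure is explicit.** Non-convergence or a singular covariance leaves
  `converged = FALSE` and/or an absent CI; downstream verdicts then return
  `"indeterminate"` rather than guessing.

A fit requires at least three distinct positive doses. On noise-free data
the fitter recovers generating parameters to four decimals, and on noisy
data it matches a brute-force grid search oracle (the test suite checks
both).

# Synergy evaluation

## Fixed-dose design

The dose-response of drug A is re-measured in the presence of a constant,
individually subefficacious dose of drug B. `fixed_dose_shift()` declares a
significant potentiation when the ED50s shift with *non-overlapping* 95%
CIs — a conservative rule (stricter than a nominal 5% test) that matches
standard practice in this literature. Touching intervals are `"no_shift"`.

## Fixed-ratio (isobolographic) design

Serial dilutions of a constant A:B mixture (ratio $r$ parts A per part B)
are tested, and the observed mixture ED50 is compared with the Loewe
additivity prediction. With the components' ED50s known, the fractional
multiplier and additive ED50 are

$$F = \frac{r}{r + \mathrm{ED}_{50}^A/\mathrm{ED}_{50}^B}, \qquad
Z_{add} = F\,\mathrm{ED}_{50}^A + (1 - F)\,\mathrm{ED}_{50}^B.$$

Both $Z_{add}$ and the observed combination fit live on the **total
mixture dose** axis (component doses summed). The additive point is then
always bracketed by the component ED50s and moves monotonically from
$\mathrm{ED}_{50}^B$ to $\mathrm{ED}_{50}^A$ as $r$ grows — properties the
test suite verifies — and the analysis is invariant to relabeling
(A↔B, $r$↔$1/r$). Dose-response figures in this field sometimes label the
mixture axis by one component's dose; total dose is the Loewe-consistent
choice and is what every function here means by a combination dose.

The additive point's 95% CI uses the delta method: each component SE is
recovered from its 95% CI half-width on the linear scale (averaging the
two half-widths when the back-transformed interval is asymmetric), and

$$\mathrm{Var}(Z_{add}) = F^2\,\mathrm{Var}(A) + (1-F)^2\,\mathrm{Var}(B),
\qquad Z_{add} \pm 1.96\,\mathrm{SE}.$$

A Monte-Carlo resampling oracle (independent normals for the two
components) reproduces these endpoints within 2%. Log-scale variance
combination would be an equally defensible convention; the linear-scale
form was chosen because the additivity equation itself is linear in the
component ED50s.

`isobologram()` returns the categorical verdict — `"synergistic"` when the
observed CI lies entirely below the additive CI, `"antagonistic"` for the
mirror case, `"additive"` on any overlap (touching bounds included),
`"indeterminate"` when a CI is missing — together with the interaction
index $Z_{obs}/Z_{add}$ as a continuous effect size (< 1 synergy,
1 additivity, > 1 antagonism).

# Ex vivo transporter occupancy

At the end of behavioral testing, transporter occupancy is inferred from
the slowing of radioligand association in cortical homogenates: the bound
signal is read over a 3-minute time course (initial-rate regime, so the
course is essentially linear), the initial rate $v$ is the OLS slope, and

$$\mathrm{occupancy\%} = 100\left(1 - \frac{v}{\overline{v}_{vehicle}}\right).$$

Notes:

* The regression keeps a **free intercept** by default — filtration assays
  carry a nonzero time-zero background; an origin-constrained variant is
  available (`origin = TRUE`).
* Negative slopes can only arise from noise in an association assay and are
  floored at 0 with a warning; negative *occupancies* (a treated animal
  binding faster than the vehicle average) are retained, because group
  summaries near 0% legitimately straddle zero.
* Normalization is **per session** by default, mirroring the behavioral
  concurrent-vehicle rule, with a pooled option.
* A historical report-sheet form of the equation that divides only the
  constant by the vehicle mean is preserved behind `literal = TRUE`; it is
  not scale-invariant and exists purely for archival fidelity.

# The synthetic-data generator

No raw per-animal data accompany studies of this design, so the package
ships generators that emulate their statistical structure with known
ground truth.

* **Flinch counts are negative-binomial.** Animal-to-animal variability in
  phase-2A totals is much larger than Poisson; a negative binomial with
  size (dispersion) 10 around a vehicle mean of 150 flinches produces group
  SEMs of the magnitude formalin-test figures display at $n = 8$ per
  group. Both are configuration knobs; no headline result depends on the
  vehicle mean, since percent inhibition is scale-invariant.
* **Group means follow the model.** At dose $d$ the expected count is
  $\bar{V}(1 - E(d)/100)$ with $E$ the constrained sigmoid at the
  configured true ED50 and Hill slope (default 1.5, a typical steepness
  for this assay).
* **Default designs.** Single-drug doses default to the 4-point geometric
  series $\mathrm{ED}_{50}\cdot\{0.125, 0.5, 2, 8\}$ (about 4–96%
  predicted inhibition at $h = 1.5$). Combination arms are dosed at
  $Z_{add}\cdot\{0.125, 0.5, 2, 8\}$ on total dose — centered on the
  *additive prediction*, the design an experimenter blind to the
  interaction would choose. The morphine-like experiments used for
  parameter-recovery checks use the canonical 0.3/1/3/10 mg/kg ladder.
* **Interaction is one dial.** A combination arm's true total-dose ED50 is
  $\iota \cdot Z_{add}$: $\iota = 1$ generates exact Loewe additivity,
  $\iota < 1$ synergy, $\iota > 1$ antagonism — the minimal model that can
  exercise all three verdicts. The combination's Hill slope defaults to
  the mean of the component slopes.
* **Binding courses.** Vehicle animals bind at a base rate (50 signal/min
  over a background of 5); an animal at true occupancy $\theta$ at
  $v_0(1-\theta/100)$. Every slope carries multiplicative lognormal noise
  with mean 1 and CV 0.1, and four readings at 0–3 min lie exactly on the
  noisy line. Noise therefore lives between animals, not between time
  points — adequate for testing the occupancy arithmetic, though it makes
  each animal's within-course regression exact.

Everything is deterministic under the configured seed, and generated
datasets pass unchanged through the same validators and analysis functions
as CSV data.

**What passing tests on these data do and do not show.** The generators
reproduce the *statistical skeleton* of a real study: overdispersed counts,
sigmoid group means, per-animal normalization, between-animal assay noise.
They do not emulate dropped animals, within-session time trends, partial
efficacy ceilings, pharmacokinetic interactions between mixture components,
or counter mis-scoring. Calibration results (e.g. "≥ 90% additive verdicts
under exact additivity") therefore validate the inferential machinery, not
any claim about a particular compound pair in vivo.

# Problem sizes used in the checks

The shipped checks use study-scale simulations chosen to mirror the designs
they emulate: 200 replicate single-drug experiments (4 doses × 8 animals)
for parameter recovery, 100 replicate fixed-ratio experiments per
interaction level for verdict calibration, and 100 simulated animals for
occupancy round-trips. Null calibration at $\iota = 1$ yields the
"additive" verdict in ≳ 90% of replicates, and $\iota = 0.33$ (the
magnitude implied by the 3:1 worked example, observed/additive ≈ 2.4/7.4)
flips a large majority to "synergistic"; a small fraction of replicates
(~5%) return "indeterminate" when a component fit's slope pins at its
bound and the CI degenerates — reported honestly rather than coerced.

# In vitro arithmetic

Fold selectivity between transporters is $10^{|\Delta \mathrm{pIC}_{50}|}$
rounded to **one significant figure**, half away from zero on the leading
digit (so $10^{1.5} = 31.6 \to 30$); ties report fold 1 and no preferred
transporter rather than an arbitrary one. Potencies stay on the
$-\log_{10}$ molar scale end to end. Unbound concentrations are
`total × fu` with the unbound fraction validated into $(0, 1]$. The
Cheng–Prusoff relation between pKi and pIC50 is deliberately out of scope:
the two scales are reported side by side, never interconverted.

# Known limitations

* The two-parameter constrained sigmoid cannot represent partial-efficacy
  ceilings or biphasic dose-response; such data will fit poorly
  (large `residual_sd`) rather than fail loudly.
* Asymptotic CIs undercover slightly at 4-dose, 8-animal designs; the
  verdict rules inherit that approximation.
* The additive CI's linear-scale delta method is one defensible convention
  among several; published additive CIs built by other software may differ
  by a few percent.
* Occupancy inference assumes the radioligand's initial rate scales
  linearly with free transporter density and that dosing does not alter
  nonspecific binding.
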