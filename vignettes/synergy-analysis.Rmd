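---
title: "Quantifying fixed-ratio drug synergy: median-effect, CI, and independence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fixed-ratio drug synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyci)
```

## The problem

Combination chemotherapy screens ask a deceptively simple question: does a
drug pair do more together than you would expect from each drug alone? The
answer depends entirely on what "expect" means, and `synergyci` implements
the three reference frames most often used for plate-based viability
screens of a fixed-ratio combination:

* the **median-effect / Combination Index (CI)** framework, which judges a
  combination against Loewe dose additivity using each agent's own
  dose-effect curve;
* **Bliss Independence**, which judges it against probabilistic
  independence of the two inhibition events; and
* **Highest Single Agent (HSA)**, the weakest reference, which only asks
  whether the combination beats its better component.

The packaged worked example is a quercetin (Q) + gemcitabine (GEM) screen
in MDA-MB-231 triple-negative breast cancer cells: single-agent series at
0–100 µM (Q) and 0–10 µM (GEM), plus a fixed 10:1 combination ladder
(Q10+GEM1 … Q100+GEM10), with a redox/apoptosis marker panel alongside.

## Models

### Median-effect model and CI

Each dose-effect series is summarised by the mass-action median-effect
equation

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m, \qquad f_u = 1 - f_a,$$

where $f_a$ is the fraction of cells affected (inhibited), $D_m$ the dose
producing 50% effect and $m$ the sigmoidicity. Taking logs makes the model
linear, so `fit_median_effect()` is an unweighted OLS on
$(\log_{10} D,\ \log_{10} f_a/f_u)$; the regression correlation $r$ is
reported as the usual conformity diagnostic. Points with $f_a$ outside
$[0.01, 0.99]$ and the dose-0 anchor are excluded before fitting — the
log-odds diverge at the extremes, and a clamped $f_a = 0$ carries no usable
information. $f_a$ is computed from the mean viability per dose, matching
the granularity at which plate screens are usually reported.

For a combination delivering component doses $(D_1, D_2)$ at observed
effect $f_a$, the Combination Index is

$$\mathrm{CI} = \frac{D_1}{D_{x1}} + \frac{D_2}{D_{x2}}
  + \alpha\,\frac{D_1 D_2}{D_{x1} D_{x2}},$$

with $D_{xi}$ the single-agent dose giving the same effect and $\alpha = 0$
(mutually exclusive action, the default) or $\alpha = 1$ (mutually
non-exclusive). CI < 1 is synergy, CI > 1 antagonism; a configurable band
$|\mathrm{CI} - 1| \le 0.05$ is reported as additive so that exact
additivity is a non-empty class under floating point. The fixed-ratio
construction treats the mixture as a single agent at total dose
$D_1 + D_2$: `fa_ci_curve()` fits the combination's own median-effect
curve, reads off the total dose for each $f_a$ on the grid (default 0.25
to 0.90 in steps of 0.05), splits it by the mixing weights and evaluates
CI. The Dose-Reduction Index $\mathrm{DRI}_i = D_{xi}/D_i$ expresses the
same comparison as a fold dose saving per agent.

### Independence references

Bliss treats the two inhibition events as independent:
$E_{\exp} = E_A + E_B - E_A E_B$ and $\Delta\mathrm{Bliss} =
E_{obs} - E_{\exp}$, positive for synergy. HSA expects
$\max(E_A, E_B)$. Both operate on inhibition fractions, never viability.
`synergy_table()` evaluates both per combination dose pair, using the
single-agent effects measured at exactly the matching component doses
(the fixed-ratio design guarantees those doses exist; linear interpolation
is available behind a flag for designs that do not). Note that the CI and
Bliss frames need not agree — they answer different questions — and the
package reports both rather than reconciling them.

### Dose-response (4PL) and absolute IC50

`fit_four_pl()` fits the four-parameter logistic
$V(D) = b + (t - b) / (1 + (D/e)^h)$ to mean viabilities, including the
dose-0 anchor (where the model equals its upper asymptote $t$). The
absolute IC50 — the dose where the fitted curve crosses 50% of control —
has the closed form $e\,((t - 50)/(50 - b))^{1/h}$ and is undefined when
the curve never crosses 50; `absolute_ic50()` then returns `NA` with a
warning rather than extrapolating.

## Numerical choices

* **4PL optimisation.** The SSE surface of a 6–9-point 4PL is multimodal
  enough to trap a single-start optimiser. The fit therefore multi-starts
  an L-BFGS-B search over Hill slopes {0.5, 1, 2, 4} and two lower-asymptote
  starts ({0, min mean}), inside the box bottom ∈ [0, min mean], top ∈
  [0.9·max, 1.1·max + 5], hill ∈ (0.1, 10], ec50 ∈ [min positive dose/10,
  10·max dose], then polishes the best basin with Levenberg–Marquardt for
  machine-precision convergence. Starts are nudged strictly inside the box
  because both optimisers can freeze a parameter that begins exactly on a
  bound. On noise-free 4PL data this recovers the generating parameters to
  better than 1e-6 relative with SSE at machine zero.
* **Loewe root.** The additivity residual $D_1/D_{x1}(f_a) +
  D_2/D_{x2}(f_a) - 1$ is strictly decreasing in $f_a$ for positive slopes,
  so `loewe_effect()` brackets $f_a \in [10^{-9}, 1-10^{-9}]$ and bisects
  to a bracket width of 1e-12 (≤ 200 iterations).
* **Grouping.** Combination identity is the unordered agent pair plus the
  mixing ratio rounded to 6 significant digits, so dose-column float
  jitter cannot split a series; series construction is invariant to row
  permutation.
* **Degenerate inputs.** Raw signals without a control well refuse to
  normalise; viabilities above 100% are retained but flagged; a
  median-effect slope $m \le 0$ on inhibition data is returned flagged
  unreliable rather than silently used.

## The simulator: what it emulates, and what it does not

`synthetic_config()` + `simulate_screen()` generate well-level screens
with known ground truth, defaulting to the study conditions of the worked
example: median-effect parameters for Q ($D_m = 96.35$ µM, $m = 0.922$)
and GEM ($D_m = 4.787$ µM, $m = 0.838$) taken from the packaged
single-agent series fits, a 10:1 fixed ratio, the 0–100 µM / 0–10 µM dose
ladders, biological triplicates, and 5% multiplicative noise
($V \cdot e^{\mathcal N(0,\sigma)}$, $\sigma = \ln(1+\mathrm{CV})$, which
keeps viability positive and the CV directly interpretable). Combination
ground truth is selectable: `loewe` (solves the additivity equation, true
CI = 1), `bliss` (true $\Delta$Bliss = 0) or `potency_shift` with strength
$s$ (Loewe effect at $s$-scaled doses, true CI = $1/s$ at every effect
level — a clean, parameterised synergy truth).

Closure tests exercise equal single-agent slopes ($m_A = m_B$): a Loewe
mixture of equal-slope median-effect drugs is itself exactly median-effect
(with $D_{m,\mathrm{mix}}^{-1} = w_1/D_{m1} + w_2/D_{m2}$), so the
combination fit introduces no model error and CI closure holds to 1e-6.
With unequal slopes the mixture is only approximately log-linear and the
residual reflects that approximation, not a defect in the CI arithmetic —
the packaged Q/GEM parameters are a case in point.

The simulator emulates multiplicative plate noise and the fixed-ratio
design only. It does not model plate spatial effects, growth kinetics,
assay-specific background, or replicate-level normalisation artefacts, so
green tests here demonstrate correctness of the analysis machinery, not
robustness to every failure mode of real plates.

Marker panels draw replicates around configured group means (default: the
worked example's ROS folds 1/1.6/2.4/2.8, caspase-3 folds 1/2.1/3.0/3.6,
apoptosis 2.8/24.6/38.4/44.2%); qPCR Ct tables are built so the
2^-ΔΔCt method recovers the configured fold changes exactly at zero noise
(reference gene at Ct 15, control target at Ct 25). ΔCt is averaged over
per-replicate paired differences, the standard bookkeeping.

## The packaged worked example

The installed tables carry the published group means of the Q+GEM screen
(each repeated over n = 3, SD 0, control stored as printed at 98% without
re-normalisation). Three of the five combination conditions have no
published viability; the file stores synthetic stand-ins (64/48/30%,
flagged in the file name and documentation) chosen to show the mild
positive Bliss deviation the screen describes qualitatively. Several
published headline numbers are mutually inconsistent with the published
series — the GEM IC50 (17.2 µM) sits far above what a 4PL through the
printed GEM viabilities supports, and the printed high-dose combination
pairs imply negative Bliss deviations. `reproduce_published_example()` therefore
reports computed and published values side by side and never forces
agreement:

```{r}
rep <- reproduce_published_example()
rep
```

The problem sizes throughout the test-suite and the acceptance script —
5–9-dose series, 14-point Fa-CI grids, 100 sham fits, 50 stochastic
repetitions at CV 5% — were chosen as the smallest designs at which each
property is cleanly identified; all run in seconds.

## Known limitations

* Fixed-ratio designs only: no checkerboard CI, no ZIP/Loewe response
  surfaces.
* No confidence intervals on 4PL or median-effect parameters, and no
  inferential group statistics (ANOVA and post hoc tests are deliberately
  out of scope; summaries report mean, SD, n).
* 2^-ΔΔCt assumes ~100% amplification efficiency (no Pfaffl correction).
* Quadrant percentages are inputs; no FCS gating.
```
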