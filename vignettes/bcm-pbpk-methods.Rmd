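---
title: "Closed-chamber PBPK modelling of bromochloromethane: model, estimation and sensitivity methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-chamber PBPK modelling of BCM: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

## Closed-chamber system

A bolus of bromochloromethane (BCM) vapor is injected at time zero into a
sealed 9 L recirculating chamber holding 3 rats. The chamber amount
$A_{ch}$ (mg) obeys

$$\frac{dA_{ch}}{dt} = N\,Q_P\left(\frac{C_{art}}{P_b} - C_{ch}\right) - k_{loss}A_{ch},
\qquad C_{ch} = A_{ch}/V_{ch},$$

where $N$ is the number of rats, $Q_P$ the alveolar ventilation (L/hr),
$P_b$ the blood:air partition coefficient, and $k_{loss}$ a first-order
wall/leak loss. Exhaled air is at alveolar equilibrium $C_{art}/P_b$ (no
dead-space or respiratory bypass term). All rats are identical, so one
rat's tissue equations are integrated and scaled by $N$ in the chamber
exchange and in the mass balance.

## Flow-limited tissue compartments

Seven compartments: lung and blood are algebraic (quasi-steady-state),
and five perfused tissues — adipose, rapidly perfused, slowly perfused,
liver, kidney — carry ODE states. Each tissue is flow-limited: venous
blood leaving tissue $t$ is at equilibrium $C_t/P_t$ with the tissue.

$$V_t\frac{dC_t}{dt} = Q_t\left(C_{art} - \frac{C_t}{P_t}\right) - \mathrm{Met}_t,$$

with $\mathrm{Met}_t$ nonzero only in liver and kidney. The algebraic
bloods are

$$C_{ven} = \frac{1}{Q_C}\sum_t Q_t \frac{C_t}{P_t}, \qquad
C_{art} = \frac{Q_C C_{ven} + Q_P C_{ch}}{Q_C + Q_P/P_b}.$$

Cumulative bookkeeping states (amount metabolized in liver and kidney,
amount through the linear pathway, amount lost from the chamber) close the
mass balance identically:
$A_{ch} + N\sum_t V_t C_t + N(A_{met,l}+A_{met,k}) + A_{lost} = A_{ch}(0)$.
The test suite verifies this to better than $10^{-6}$ relative on every
simulated condition (in practice it holds at machine precision).

## Metabolic hypotheses

Whole-body metabolism is split 94.8% liver / 5.2% kidney, applied to the
whole bracketed rate (so the maximum velocity is a body-level constant
split by fixed organ shares):

**Two-pathway** (CYP2E1 Michaelis–Menten + first-order GST conjugation):

$$\mathrm{Met}_l = 0.948\left(\frac{V_{max}[C_{liv}]}{K_m + [C_{liv}]} + k_{GST}[C_{liv}]V_{liv}\right)$$

**Two-binding-site** (one enzyme, active + effector site):

$$\mathrm{Met}_l = 0.948\,\frac{V_{max1}[C_{liv}] + CL_2[C_{liv}]^2}{K_{m1} + [C_{liv}]}$$

The second law is asymptotically linear with slope $0.948\,CL_2$ at high
substrate and reduces exactly to single-site Michaelis–Menten at
$CL_2 = 0$; the first reduces the same way at $k_{GST} = 0$, and the two
then coincide — a degeneracy the tests exploit as an internal consistency
check.

# Parameters

Defaults describe an adult Fischer 344 rat and BCM.

| symbol | meaning | default | units |
|---|---|---|---|
| BW | body weight | 0.25 | kg |
| QCC | cardiac output coefficient ($Q_C = QCC\cdot BW^{0.75}$) | 15 | L/hr/kg^0.75 |
| QV | ventilation:perfusion ratio ($Q_P = QV\cdot Q_C$) | 1.7 | — |
| q (adipose, slow, kidney, liver) | flow fractions of $Q_C$ | 0.082, 0.257, 0.138, 0.242 | — |
| V (slow, liver, kidney, adipose) | volume fractions of BW | 0.674, 0.044, 0.0075, 0.112 | — |
| $P_b$ | blood:air partition | 41.5 | — |
| $P_t$ (liver, rapid, kidney, slow, adipose) | tissue:blood partitions | 0.7, 0.7, 0.7, 0.267, 7.8 | — |
| $V_{ch}$, $N$, $k_{loss}$ | chamber volume, rats, loss | 9 L, 3, 0.025/hr | |
| $V_{max}, K_m, k_{GST}$ | two-pathway constants | 3.8, 0.35, 4.7 | mg/hr, mg/L, 1/hr |
| $V_{max1}, K_{m1}, CL_2$ | two-site constants | 3.7, 0.3, 0.047 | mg/hr, mg/L, L/hr |

Closure conventions, decided once and enforced by constructors:

- The four named flow entries are fractions of cardiac output and the
  rapidly perfused compartment closes the flow balance,
  $q_{rap} = 1 - \sum q_i = 0.281$, so perfusion totals exactly $Q_C$ —
  required for the venous mass balance to be consistent.
- The rapidly perfused volume closes the tissue balance at 91% of body
  weight, $V_{rap} = (0.91 - \sum V_i)\,BW = 0.0725\,BW$; blood is the
  remaining 9% of BW and, being algebraic, carries no chemical state.
- ppm to mg/L conversion uses the 25 °C, 1 atm molar volume (24.45 L/mol)
  with MW(CH2BrCl) = 129.38 g/mol from standard atomic masses.
- The chamber gas volume is used as printed (9 L), with no subtraction of
  animal volume.

# Synthetic data generator

`generate_chamber_dataset()` emulates the structure of digitized
vapor-uptake experiments: five depletion series with initial
concentrations 200, 500, 1000, 2000 and 4000 ppm — spanning the range from
below to far above metabolic saturation, which is what makes $K_m$ and the
linear constant jointly identifiable — sampled every 0.1 hr from 0.1 to
6 hr. The first sample is at 0.1 hr rather than zero to emulate post-bolus
chamber mixing. Observation noise is multiplicative lognormal
($c_{obs} = c_{model}e^{\varepsilon}$, $\varepsilon \sim N(0, cv^2)$,
default CV 5%): since fitting operates on the natural log of the data,
log-additive noise is the natural conjugate error model.

What the generator does **not** emulate: the error structure of curve
digitization (correlated, heteroscedastic reading errors), the actual
observation times of the historical experiments (not published), inter-rat
variability, or any drift in chamber loss. Passing recovery tests
therefore demonstrate that the estimation machinery inverts the model
correctly under a known error model — not that the historical parameter
values are unbiased for real rats.

# Estimation

The cost is the log-space sum of squares over all observations of all
series, with the model solved at the exact observation times (dense solver
output, no grid interpolation):

$$\mathrm{cost}(\theta) = \sum_{s}\sum_{j}\left(\ln c^{model}_{s}(t_{sj};\theta) - \ln c^{obs}_{sj}\right)^2.$$

Non-positive observations are excluded (their count is reported).
Minimization is Nelder–Mead simplex over $\log\theta$, which enforces
positivity without constraints and equalizes scales across constants
spanning two orders of magnitude. Defaults: relative cost-change tolerance
$10^{-10}$, at most 2000 evaluations per run, the user's start plus 5
restarts jittered componentwise by $U(0.5, 2)$ under a fixed seed, and one
simplex restart ("polish") from the incumbent. The implementation's
simplex exposes only a cost-change tolerance, so the polish restart stands
in for a separate simplex-size criterion: a fresh simplex that cannot
improve the incumbent by more than the tolerance (or $10^{-12}$ absolute,
whichever is larger — the cost is exactly zero at the optimum of noise-free
data) is taken as convergence.

The per-series error report follows the printed convention of the original
gas-uptake analyses: `abs_err` is the **two-norm of the residual vector
divided by the number of observations** (not the conventional
$\sqrt{\|d\|^2/n}$ root-mean-square), on the ppm scale; `rel_err` divides
by the series' initial concentration. This is deliberate and documented in
`?rmse_report`.

A finite-difference Hessian of the cost (`cost_hessian`) provides a local
identifiability check: at the noise-free optimum of the default
five-concentration design it is positive definite for both hypotheses.

# Sensitivity analysis

Normalized local coefficients $S(t) = (p/y(t))\,\partial y(t)/\partial p$
for chamber air and liver concentration, any scalar parameter
(metabolic, flow, volume, partition, chamber). Two routes:

- **central finite differences** on the full simulation (default), relative
  step $h = 10^{-4}$;
- a **forward-sensitivity ODE** integration of the augmented system with
  the analytic state Jacobian, implemented for the two-pathway metabolic
  constants, used as an independent oracle — the two agree to better than
  $10^{-4}$ relative wherever $|S| > 10^{-6}$.

Numerical choices: the finite-difference route integrates at tighter
tolerances (rtol $10^{-12}$, atol $10^{-14}$) than plain simulation because
the difference quotient divides solver noise by $2h$; where
$|y(t)| < 10^{-12}$ mg/L the normalization is singular (the liver starts
clean) and $S$ is defined as 0, which also gives $S(0) = 0$ for every
parameter since the initial state is parameter-free. Signed coefficients
are emitted; peak detection uses $|S|$ and reports the grid argmax on the
0.02 hr output grid. The 500 ppm bolus — just below saturation — is the
canonical sensitivity experiment and the CLI default.

`sensitivity_surface()` recomputes the time course across a user range of
the parameter (e.g. $V_{max} \in [2.5, 4.5]$ mg/hr around the optimized
3.8) to show the stability of the sensitivity structure under parameter
variability. `identifiability_check()` stacks sensitivity columns and
reports the smallest singular value, condition number and same-sign flags:
columns that are all of one sign cannot sum to zero, and a strictly
positive smallest singular value rules out exact collinearity.

# Numerical contract

- Stiff integration: `lsoda` on a compiled C right-hand side; rtol
  $10^{-8}$, atol $10^{-10}$ (mg / mg·L$^{-1}$); default output 0–6 hr at
  0.02 hr. An R-language copy of the right-hand side (`pbpk_rhs`) backs a
  fixed-step RK4 oracle test (dt $10^{-4}$ hr over 0.5 hr, agreement
  $10^{-5}$ relative) and the forward-sensitivity system.
- Metabolism terms clamp concentrations at zero because stiff solvers
  probe slightly negative values near the origin.
- Degenerate inputs: a zero bolus yields the identically zero trajectory;
  solver failures raise a distinct condition class (CLI exit 3) separate
  from validation errors (exit 2).

# Problem sizes used by the test suite

Unit and property tests run on coarse designs (2–3 series, observations
every 0.5 hr) chosen so each property is exercised well away from solver
tolerance; the end-to-end recovery checks use the full study design
(5 series × 60 observations). The noisy-recovery study uses 20 replicate
seeds at CV 5% with single-start fits from 1.5×-displaced values; its
median per-parameter error is reported against a 10% target (25% is
treated as failure).

# Known limitations

- Local (one-at-a-time) sensitivity only; no Sobol/Morris global indices.
- Flow-limited tissues only; no diffusion limitation, no open-chamber
  (constant-concentration), oral or dermal routes.
- Rats are identical and physiology is constant over the experiment.
- At high exposures the linear term dominates arithmetically in both
  hypotheses, so the fraction of metabolism through the GST (or
  second-site) route is reported by the pipeline but no claim about its
  in-vivo share is asserted.
- Setting a single flow or volume via `set_model_param()` is a local
  perturbation: derived totals are deliberately not re-closed, matching
  how one-at-a-time sensitivity treats correlated physiological inputs.
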