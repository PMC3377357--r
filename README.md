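# bcmpbpk

Physiologically based pharmacokinetic (PBPK) modelling of bromochloromethane
(BCM, CH2BrCl) closed-chamber gas uptake in rats, with competing metabolic
hypotheses, metabolic parameter estimation, and local
sensitivity/identifiability analysis.

## The problem

BCM is a volatile water-disinfection by-product. Its in-vivo metabolism is
measured with closed-chamber (vapor-uptake) experiments: rats breathe in a
sealed 9 L recirculating chamber, a BCM bolus is injected at time zero, and
the decline of the chamber concentration over ~6 hours quantifies whole-body
uptake and metabolism. The observed depletion curves cannot be described by
a single saturable pathway; a linear component persists at high
concentrations. Two mechanistic explanations are equally compatible with
such data, and this package implements both so they can be fit and compared:

- **Two-pathway model** — saturable CYP2E1 oxidation plus first-order
  glutathione-S-transferase (GST) conjugation:

  `Met_l = 0.948 * ( Vmax*C_liv / (Km + C_liv) + kGST*C_liv*V_liv )`

- **Two-binding-site model** — one enzyme (CYP2E1) with an active and an
  effector site, giving atypical kinetics that become linear (slope `CL2`)
  at high substrate:

  `Met_l = 0.948 * ( Vmax1*C_liv + CL2*C_liv^2 ) / (Km1 + C_liv)`

The kidney term is analogous with the 0.052 share. Both laws plug into the
same seven-compartment flow-limited PBPK core (lung and blood algebraic via
a steady-state assumption; adipose, rapidly/slowly perfused, liver, kidney
as ODE states) coupled to the chamber balance with first-order wall loss.

The package provides, for both hypotheses:

- stiff simulation of chamber experiments (`simulate_chamber`, compiled C
  right-hand side under deSolve's `lsoda`, machine-precision mass balance);
- synthetic multi-concentration datasets emulating the digitized
  vapor-uptake experiments (`generate_chamber_dataset`, five series spanning
  200–4000 ppm, optional multiplicative lognormal noise);
- estimation of the three metabolic constants per hypothesis by Nelder–Mead
  minimization of the natural-log least-squares cost over all series
  (`fit_metabolic_params`), with per-series error reports (`rmse_report`);
- normalized local sensitivity coefficients `S(t) = (p/y) dy/dp` for
  chamber air and liver concentration (`sensitivity_timecourse`), 3-D
  sensitivity surfaces over a parameter-variability range
  (`sensitivity_surface`), and rank/conditioning identifiability
  diagnostics (`identifiability_check`);
- a command-line surface (`bcm_cli`, wrapper in `inst/cli/bcmpbpk.R`) with
  `generate`, `simulate`, `fit`, `sense`, `surface` and `recover`
  subcommands driven by JSON/YAML configs.

## Worked example

```r
library(bcmpbpk)

# 500 ppm bolus, 3 rats, 9 L chamber, two-pathway metabolism
cfg <- chamber_config(c0_ppm = 500, metabolic = metabolic_two_pathway())
sim <- simulate_chamber(cfg, t_end = 6)
head(sim[, c("time_hr", "chamber_ppm", "c_liver", "a_met_liver")], 4)
#>   time_hr chamber_ppm c_liver a_met_liver
#> 1    0.00       500.0   0.000     0.00000
#> 2    0.02       472.6   3.926     0.06143
#> 3    0.04       447.7   5.964     0.13365
#> 4    0.06       424.8   7.350     0.20867
```

The chamber declines from 500 ppm as the rats absorb and metabolize BCM;
liver concentration rises to a few mg/L within minutes while the cumulative
amount metabolized (`a_met_liver`, mg per rat) accumulates.

Parameter recovery on noise-free synthetic data (five series, 200–4000 ppm)
returns the generating constants from a 1.5x-displaced start:

```r
ds <- generate_chamber_dataset(metabolic_two_pathway(), noise_cv = 0)
fit <- fit_metabolic_params(ds, "two_pathway", start = c(3.8, 0.35, 4.7) * 1.5)
signif(fit$estimates, 5)
#> Vmax   Km kGST
#> 3.80 0.35 4.70
```

with per-series errors (two-norm of the residual over the number of
observations, divided by the series' initial concentration for the relative
version) at numerical zero. Sensitivity of the liver concentration to Vmax
at 500 ppm peaks early, which is why a 2-hour experiment measuring liver
tissue would pin Vmax down better than a 6-hour chamber curve:

```r
s <- sensitivity_timecourse(cfg, "Vmax", "liver_concentration")
max(abs(s$S))                    #> 5.694
s$t_hr[which.max(abs(s$S))]      #> 1.54  (hours)
```

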