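---
title: "The splanchsim whole-body glucose model: structure, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The splanchsim whole-body glucose model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(splanchsim)
```

## The model

`splanchsim` couples two layers.

**Circulation.** Eight compliant blood compartments (systemic arteries,
superior mesenteric capillary bed, hepatic sinusoids, splenic/coeliac bed,
kidney, somatic tissues, systemic veins, lungs) are joined by thirteen
resistive vessel segments into one closed circuit obeying Kirchhoff's laws.
Each compartment obeys a linear pressure-volume law `P = (V - V0)/C`; each
segment carries flow `Q = dP/R`; the two ventricles are constant pressure
sources in series with their outflow resistances. Total blood volume is
5 L. The only actively controlled resistance is the superior mesenteric
artery (SMA): `R_SMA = R0 * Km / (Km + GLP1)`, sensed on the GLP-1
concentration in the mesenteric capillary bed. Everything else -
the fall in hepatic arterial flow when portal flow rises, the
post-prandial drop in aortic pressure as blood shifts into the splanchnic
bed - emerges passively from the network.

**Species.** Glucose (mM), insulin (pM), glucagon (nM) and GLP-1 (nM) are
tracked as amounts per compartment; the distribution volume of each
compartment is three times its blood volume (blood is one third of the
rapidly equilibrating extracellular space). Advection between compartments
uses the donor (upwind) concentration of the signed blood flow. Sources
and sinks:

* intestinal absorption into the mesenteric capillary bed: a saturable
  SGLT1 term (Km 17 mM on lumen glucose) plus paracellular diffusion
  `P_gl * A * (C_lumen - C_cap)` where `P_gl` (um/s) is the headline
  permeability knob and `A` an implicit mucosal exchange factor;
* hepatic net glucose uptake (NHGU): GLUT2/glucokinase flux saturable in
  sinusoidal glucose (Km 20 mM), multiplied by insulin (Km 200 pM) and a
  GLP-1 boost factor, minus glucagon-driven
  gluconeogenesis/glycogenolysis (Km 2 nM), treated as substrate-unlimited
  over hours;
* peripheral disposal: an insulin- and GLP-1-dependent GLUT4 pathway
  (Km 2.5 mM glucose) and an insulin-independent GLUT1 pathway
  (Km 1.3 mM);
* renal spill above the SGLT2 reabsorption ceiling (filtration fraction
  0.1, Tm 1.2 mmol/min);
* secretion into the mesenteric capillary compartment: insulin driven by
  systemic arterial glucose and GLP-1, glucagon suppressed by systemic
  glucose, GLP-1 driven by *splanchnic* capillary glucose (Km 20 mM) -
  the location of the glucose sensor is the central asymmetry of the
  model;
* first-order degradation in the hepatic and systemic territories.

A 50 g glucose dose (277.5 mmol) enters the intestinal lumen at a constant
rate over 20 minutes starting at t = 100 min, bypassing gastric emptying.
Scenarios expose four knobs: the GLP-1 glucose sensitivity (0.1-100), the
paracellular permeability `P_gl` (0-0.16 um/s), the portosystemic shunt
resistance (40 = closed, 0.005 = wide open) and the presinusoidal
(portal-vein) resistance (0.005 normal, 0.02-0.025 in NASH).

```{r}
res <- run_scenario(preset_scenario("normal"))
head(res$series[, c("time", "glc_sys_art", "flow_sma", "rate_nhgu")])
```

## Parameters, units and the calibration layer

The published parameter table that this model re-implements is internally
inconsistent: resistances, metabolic coefficients and loss rates printed
with second-based units contradict the printed flows (an SMA resistance of
1 mmHg s/ml between a 105 mmHg aorta and a ~1.5 mmHg capillary bed would
carry 6 L/min, not 500 ml/min), hormone loss rates of order 1 s^-1
contradict the stated 2-3 min half-lives, and GLP-1 concentrations are
quoted in both pM and nM for the same state. The package therefore keeps
two layers (see `default_parameters()` and its `nominal` element):

* **verbatim values** wherever they are coherent: all Km values, the
  venous-side resistances (portal 0.005, hepatic vein 0.001, shunt 0.4,
  renal/somatic vein 0.01, vena cava 0.001 mmHg s/ml), distensibilities,
  filtration fraction and renal Tm, the gavage protocol;
* **calibrated values** for the arterial resistances, ventricular pump
  pressures, unstressed volumes, secretion coefficients, degradation
  rates and metabolic capacities.

The calibration is a one-time, documented procedure with fixed targets,
all taken from resting human physiology as the source describes it:
cardiac output 5.5 L/min, mean aortic pressure 105 mmHg, fasting SMA flow
~600 ml/min, hepatic artery ~700 ml/min, portal pressure ~1.5 mmHg,
fasting systemic glucose 5 mM, fasting systemic insulin 29 pM, fasting
splanchnic GLP-1 ~10 nM at high secretory drive, glucagon ~0.25 nM
systemic, and a splanchnic:systemic concentration ratio of 2 for all three
hormones. Arterial resistances and unstressed volumes follow analytically
from the design flows and pressures (the formulas are in `R/params.R`);
the secretion/degradation constants were fixed by a damped fixed-point
iteration against the equilibrated model and are frozen in the defaults.

Units: the internal clock is minutes; vessel resistances stay in
mmHg s/ml (flows computed in ml/s and converted by 60 at the volume
derivative); glucose in mM, insulin in pM, glucagon and GLP-1 in nM.
GLP-1's internal unit is nM with the SMA half-effect at the verbatim
1 nM; the figure-axis pM labels of the source are treated as mislabelled
nM, consistent with its own text ("systemic arterial GLP-1 10-20 nM").
"Distensibility (mmHg^-1)" is read as fractional volume change per mmHg,
so absolute compliance = distensibility x initial volume; the printed
"Sys compliance" maps to the somatic tissue bed and "Somatic vein
compliance" to the systemic venous pool. The ventricular pump entries
(290/850, units unstated) are recorded in the nominal layer but the
working pump pressures are calibration constants.

## Design choices in the open gaps

**Beta-cell glucose response.** Insulin secretion uses a Hill form
`G^n/(G^n + 17^n)` with n = 2 by default (n = 1 selectable via
`secretion$beta_cell_exponent`), half-maximal at 17 mM for any n. With
n = 1 the fasting-to-feeding secretion contrast at a ~7-8 mM glucose peak
is under 1.3x, and the only way to clear the absorbed load is to inflate
the static disposal and gluconeogenesis coefficients until fasting
glucose turnover reaches tens of mmol/min. The cooperative form mirrors
the sigmoidal glucose dependence of glucose-stimulated insulin release
and the model's own n in {1, 2} device for glucagon suppression.

**Hormone kinetics: gradient over half-life.** With instantaneous
distribution into the 3x-blood extracellular pool, a 2-3 min whole-pool
half-life and the factor-2 splanchnic:systemic fasting gradient cannot
hold simultaneously (the gradient pins secretion at
`conc_sys x SMA plasma flow`; the half-life pins it at
`ln 2 / t_half x pool`). The calibration keeps the gradient - it shapes
every disease contrast in the model - so effective whole-pool half-lives
come out near 15-25 min, i.e. a few minutes in plasma-equivalent terms
once the 3x dilution is considered. Consequences: hormone responses to
the gavage are smoother and later than in the source, and portosystemic
shunting raises the normalized systemic insulin:glucose ratio by tens of
percent rather than the source's factor 2-5, because hepatic first-pass
extraction is capped at ~20% of a pass. Insulin degradation is therefore
placed 8:1 hepatic:systemic to maximize the shunt effect within the
constraint.

**Phase sampling.** `extract_phase_values()` samples the feeding value at
maximal systemic glucose from the gavage onward and the fasting value at
minimal systemic glucose *before* the gavage. The slow insulin tail can
push glucose transiently below fasting after absorption ends; sampling
that undershoot as "fasting" would leak feeding-phase `P_gl` dependence
into the fasting response surfaces, whose interaction coefficient should
classify as zero.

**Response surfaces.** `fit_quadratic_surface()` rescales both predictors
to [0, 1] before fitting, because the source's interaction coefficients
mix axis units; only the sign/zero classification of `c` is comparable,
not the magnitude.

## Numerics

The system is permanently stiff: compartment pressure time constants
(C/sum(1/R) down to ~5e-4 min) coexist with ~20-min hormone pools on a
180-min horizon. The default integrator is the BDF method of `deSolve`
(`lsode` family) with rtol 1e-8 / atol 1e-10; `lsoda`'s automatic
switching is a selectable alternative but its non-stiff starter crawls
when integration starts exactly at the fasting steady state. The
integration restarts at the gavage on/off discontinuities so no step
straddles them. Halving the tolerances moves every reported peak by less
than 0.1% (asserted in the test suite). Equilibration integrates
gavage-free in 400-min legs until the maximum relative derivative falls
below 1e-8 per minute; the fasting state is unique in practice (two-start
agreement to 1e-6 is asserted). Michaelis-Menten terms clamp negative
concentrations at zero; the glucagon-driven hepatic output term is
deliberately not glucose-limited (the liver acts as an unlimited
short-term source). Output cadence is 0.25 min.

Problem sizes: 41 state variables; a full scenario is one equilibration
plus a 180-min simulation (~4 s); the sensitivity analyses use a
6-point permeability sweep and a 3x3 sensitivity-by-permeability grid,
sizes chosen so the whole suite and the acceptance script each run in a
few minutes on one core.

## What the scenarios emulate - and what they do not

The scenario presets are the package's synthetic study conditions: a
healthy high GLP-1 secretor (`normal`), GLP-1-deficient secretion at the
bottom of the sweep range (`low_glp1`, sensitivity 0.1), and NASH
hemodynamics (`nash_shunt`: wide-open portosystemic shunt, presinusoidal
resistance 4x normal). They emulate duodenal-gavage glucose tolerance
tests in an otherwise steady adult: no gastric emptying, no neural or
humoral reflexes (explicitly none are modelled - the hepatic arterial
buffer response in the output is purely mechanical), no meal mixtures, no
glycogen-store accounting, no multi-day adaptation. Passing tests
therefore show that the coupled hemodynamic-incretin-metabolic mechanism
behaves as designed under these idealized conditions; they do not show
that the parameter values transfer to real patients.

## Known limitations

* **Portal pressure excursion.** With the verbatim venous resistances in
  s-units the portal-to-sinusoid drop is at most ~0.2 mmHg at 2 L/min,
  so the source's 1.5 -> 7.5 mmHg portal pressure rise is unreachable;
  the model's portal pressure stays near 1.5-1.7 mmHg. A minute-based
  reading of the venous resistances would reproduce the excursion but
  breaks the fasting pressure and nothing else; the shunt-flow behaviour
  depends only on resistance ratios and survives either reading.
* **Shunt flow at high presinusoidal resistance.** Raising presinusoidal
  resistance with an open shunt raises shunt flow (direction reproduced),
  but the magnitude saturates near ~850 ml/min because the shunt fraction
  is already ~85% and total splanchnic inflow is SMA-limited; the
  source's 1600 ml/min would require a higher feeding SMA flow than the
  GLP-1 mechanism can produce here.
* **Fasting glucose turnover** is ~2-4x physiological: the spec's
  multiplicative Michaelis-Menten factors give at most a ~3-5x
  fasting-to-feeding disposal contrast at a 7-8 mM peak, so clearing the
  absorbed load requires elevated static capacity. The fasting
  insulin-dependent rate and net hepatic output are correspondingly
  above the source's printed (non-steady) fasting values, which do not
  balance to a steady state as printed.
* Insulin dynamic range during the gavage (~2x) is far below the
  source's claimed >100-fold metabolic range, for the reasons above.
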