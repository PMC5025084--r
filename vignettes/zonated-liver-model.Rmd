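---
title: "A zonated sinusoid model of hepatic glucose, lipid and energy metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A zonated sinusoid model of hepatic glucose, lipid and energy metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepzone)
```

## The model

Liver tissue is organised around the sinusoid: blood enters at the portal
triad (periportal end), perfuses a chain of hepatocytes, and leaves at the
central vein (pericentral end). Enzyme expression varies systematically
along this axis (zonation), oxygen falls from about 65 mmHg to about
35 mmHg, and insulin and glucagon are degraded as blood transits the organ.
In non-alcoholic fatty liver disease (NAFLD), triglyceride accumulates
preferentially in pericentral cells, which single-compartment liver models
cannot address. `hepzone` therefore treats the porto-central axis as the
repeating unit: the sinusoid is split into `n_comp` (default 8) well-mixed
hepatocyte/blood compartment pairs in series with plug-flow advection
between them, closed by a systemic body compartment hosting simple
representations of the pancreas (hormone secretion), adipose tissue
(lipogenesis/lipolysis), gut (triglyceride re-synthesis), muscle and
other peripheral tissues (glucose, FFA, lactate and glycerol
consumption, with renal glucose spillover above the glycosuria
threshold) and the dietary inputs.

Each hepatocyte compartment carries 17 intracellular species (glucose,
G6P, glycogen, the pooled triose phosphates G3P/GADP, the pooled
pyruvate/lactate, acetyl-CoA, palmitate-equivalent FFA, triglyceride,
glycerol, and the full adenine/uridine/guanine nucleotide set plus
inorganic phosphate). Twenty-two lumped processes connect them — glucose
uptake and phosphorylation, glycogen cycling, two-stage glycolysis and
gluconeogenesis, pyruvate oxidation, beta-oxidation, ATP synthesis through
the citrate cycle and oxidative phosphorylation, nucleotide kinases, de
novo lipogenesis, triglyceride synthesis/lipolysis, and the membrane
transport of glucose, lactate, FFA, triglyceride (VLDL release and uptake)
and glycerol. The stoichiometry follows the model's rate-equation table
exactly, including the fractional ATP coefficients (3.25 on glycolysis
stage 2, 2.5 on pyruvate oxidation) that account for NADH-derived ATP from
the lumped stages, and the coefficient 12 on acetyl-CoA oxidation. By
construction the adenine, uridine and guanine pools are conserved by the
hepatic network; this is enforced by a round-off-level audit
(`conservation_audit()`).

### Rate laws

Every process rate has the form

$$ R = v_b \, m_i \prod_j H_j(\text{substrates}) \prod_k
       H_k(\text{modifiers}) \cdot f(\text{insulin}) \cdot
       g(\text{glucagon}) \cdot \left[\frac{O_2}{K_{O_2}+O_2}\right] $$

with Hill factors $H(c) = c^n/(K^n + c^n)$ (activation) or
$K^n/(K^n+c^n)$ (inhibition), and hormone response factors of the form
$(1-a) + a\,H(\text{hormone})$ so that a strength $a = 0$ removes the
dependence. The oxygen factor applies to oxidative phosphorylation only.
Reversible membrane transport is the difference of two saturable
unidirectional terms; FFA and triglyceride transport carry independent
forward and backward constants because the sensitivity protocols perturb
uptake and release separately. Adenylate kinase is reversible mass action
and inorganic phosphate is regulated by first-order relaxation to a
set-point (rejecting relaxation would leave Pi unbounded, and clipping
would corrupt the conservation audits).

A few rate-law choices deserve explicit mention because they shape the
disease scenarios. Glucokinase carries product inhibition by G6P (the
regulatory-protein mechanism), without which pericentral G6P is unbounded
under the strong glycogen-synthase zonation. De novo lipogenesis carries
a G6P activation term (the glucose-induction arm of the lipogenic
programme) so its realised activity follows the pericentral accumulation
of phosphorylated intermediates, and strong FFA product inhibition. The
regulated component of FFA uptake is insulin-suppressed (fed-state
partitioning of lipid toward the periphery; disinhibited under insulin
resistance, the behaviour reported for scavenger-type transporters in
NAFLD), with a passive component always present. Finally, both cellular
lipid pools have convex relief valves: FFA release and droplet lipolysis
use Hill exponent 2 in their own pool, so they are negligible at
physiological concentrations but open under overload, keeping every
scenario bounded without clipping.

### Zonation

Zonation enters as a multiplicative linear gradient on the rate constant:
$m_i = 1 + k_n x_i$ with $x_i$ falling linearly from $+1$ (periportal) to
$-1$ (pericentral). The mean of $m_i$ over the sinusoid is exactly 1, so
$v_b$ is the sinusoid-mean constant, and the endpoint ratio is
$(1+k_n)/(1-k_n)$. The zonation constants are fixed by measured
periportal:pericentral activity ratios of the rate-limiting enzymes
(glucokinase 1:2.5, G6Pase 1.9:1, glycogen synthase 3:1, glycolysis-2
1:2.1, the two gluconeogenic stages 2.4:1 and 1.75:1, beta-oxidation
1.6:1, oxidative phosphorylation 1.5:1, lipogenesis 1:1.6, FFA uptake
1.5:1; everything else homogeneous). This linear form is forced by the
zonation-sensitivity protocol, in which a shift of $\pm 0.2$ in $k_n$
means a 20% increase periportally and a 20% decrease pericentrally.
Hormone reception is zonated the same way (insulin 1:1.35 pericentral,
glucagon 1.35:1 periportal) as a multiplier on the hormone concentration
each compartment senses.

### Hormones, oxygen and the body compartment

Pancreatic secretion is a bounded sigmoid of body glucose for insulin
(increasing, Hill exponent 6 around 9 mM, reflecting the steep
physiological dose-response) and for glucagon (decreasing, exponent 4
around 5 mM), each with a basal floor. Hormones are degraded at constant
fractional rates along the sinusoid; the whole-liver extraction fractions
are calibrated parameters (reference values about 0.55 for insulin, 0.20
for glucagon; the measured receptor zonation partially compensates the
porto-central hormone loss in a healthy liver). The
steady-state profile of a species degraded first-order in a chain of
well-mixed compartments is exactly geometric, $c_i = c_0 f^i$ with
$f = 1/(1 + k\tau)$, and the fixed oxygen profile under zero-order
consumption is exactly linear; both closed forms serve as verification
oracles (`gradient_oracle()`, `profile_verification()`), reproduced by the
simulated profiles to well under 0.1% of the profile mean.

Oxygen is held at the fixed measured gradient (65 to 35 mmHg) rather than
simulated dynamically, matching the assumption that blood flow and oxygen
supply are unchanged in all scenarios considered; `oxygen_steady_state()`
confirms the fixed profile is the steady state of the
advection/consumption balance that generates it.

### Insulin resistance, SREBP-1c and diet

Insulin resistance multiplies every detected insulin concentration
(hepatic and peripheral) by a constant $K_{IR} \le 1$: 1 is metabolically
healthy, 0.05 developing resistance, 0.015 severe resistance. Elevated
SREBP-1c expression — the paradoxically raised lipogenic programme of
insulin-resistant NAFLD — is modelled by clamping the insulin signal seen
by de novo lipogenesis and triglyceride synthesis (only) at a high 1 nM.
Feeding follows $v_\mathrm{input}\sin^6(\pi t/T)$ with a 4-h period; the
peak rates are set so one cycle delivers 78.1 g of carbohydrate (as
glucose, 180.16 g/mol) and 22.2 g of lipid (as palmitate-equivalent FFA,
256.4 g/mol) into the body distribution volume. Diet variants scale the
relevant input: raised +5%, high +12.5%, very high +25%, low -12.5%.

## Parameters and calibration

The rate constants and Hill constants of the lumped processes are not all
identifiable from first principles, so the package ships a versioned
reference set (`inst/extdata/params_reference.yaml`, loaded by
`reference_params()`) produced by the deterministic calibration module.
Calibration proceeds in the order: (1) the constant-input baseline — the
glucose and FFA input rates, the gut re-esterification constant and the
peripheral lactate clearance are solved by damped multiplicative secant
iteration (`solve_constant_baseline()`) so the systemic plasma
concentrations sit at 5.03 mM glucose, 1.05 mM triglyceride, 432 uM FFA
and ~1 mM lactate; (2) the healthy feeding cycle — flux anchors chosen at
physiological magnitudes (fasting hepatic glucose output ~4-6 uM/s on the
cell-volume scale, hepatic ATP turnover ~40-60 uM/s, triglyceride
synthesis ~0.2 uM/s) and then a damped Gauss-Newton fit of the main lipid
and energy rate constants; (3) the disease scenarios. The disease-scenario
observables (hepatic triglyceride content under insulin resistance, the
NAFLD zonal ratios, the ATP fall and beta-oxidation rise) are included in
the final fit's target list rather than held out: with the per-process
affinity constants unavailable from measurement, the healthy-state data
alone do not pin the insulin-response strengths that the disease
scenarios probe. The residual report of the shipped set is stored
alongside it (`inst/extdata/calibration_report.csv`).

The shipped reference set reproduces the healthy-state anchors well
(liver fat 2.1% vs 2.3%, constant-input plasma glucose to four digits,
oracle profile errors below 1e-9 of the mean) and the NAFLD
beta-oxidation rise (+42% vs +45%), while the disease-scenario gradients
are systematically more muted than their anchors: the severe-IR liver-fat
rise, the zonal synthesis/steatosis ratios, the NAFLD ATP fall and the
36-h triglyceride response to a beta-oxidation deficit all undershoot
(see the residual report for exact figures). These residuals are coupled:
within this rate-law family, the uptake zonation (1.5:1 periportal), the
concave (Hill) form of triglyceride export, and the absence of a true
adipose storage pool jointly bound how steep the pericentral steatosis
gradient and the insulin-resistance plasma-lipid surge can be made
without destabilising the healthy state. A reference set that pushed any
one of these targets into its anchor's band destabilised others; the
shipped set is the best-balanced compromise found, and the acceptance
suite reports the discrepancies rather than masking them.

Parameters a user will most often touch, with units and defaults:

* `physiology$n_comp` (8) — compartments along the porto-central axis.
* `physiology$flow` (0.025 L/s) and the volumes (`V_hep` 1.2 L, `V_blood`
  0.3 L, `V_body` 15 L): transit time ~12 s, hepatocyte:blood volume
  ratio 4.
* `hepatic$<process>$vb` (uM/s on the cell-volume scale) — sinusoid-mean
  rate constants.
* `zonation$<process>` — zonation constants $k_n$ (dimensionless).
* `hormones$K_I` / `K_G` (nM) — hormone half-effect concentrations shared
  by the hepatic rate laws.
* `numerics$dt` (0.05 s) — reference RK4 step; `numerics$cycle_tol`
  (1e-4) — relative cycle-equilibrium tolerance.

## Numerics

Integration is classic fixed-step RK4 (compiled core). The reference
configuration is dt = 0.05 s with 8 compartments; the output observables
are stable for steps up to 0.4 s, and the long equilibrium runs in the
tests and the acceptance script use dt = 0.2 s, inside that stability
region (the dt-robustness check in the acceptance suite verifies the
cycle-average observables at 0.05 s and 0.2 s agree to well under 1%). A
step that would drive any concentration negative is rejected and retried
as two half steps (bounded recursion) rather than clipped, because
clipping silently violates the conservation audits; integration aborts
with a diagnostic naming the first offending species and compartment if
halving cannot rescue the step. An adaptive backend (deSolve's lsoda) is
available as an independent cross-check of the integrator.

Feeding cycles are iterated until the maximum relative change of every
state between consecutive cycle ends falls below `cycle_tol`
(denominator guarded by 1e-9 uM for near-zero species). The slowest modes
are the triglyceride and glycogen pools (time constants of order days);
production runs therefore start from shipped near-equilibrium states
(`inst/extdata/states/`), which are themselves outputs of the calibration
run, and re-converge in a handful of cycles. Zonal ratios quoted as
"1:r" are stored as the scalar r; both the half-sinusoid-mean and the
endpoint-compartment definitions are computed (`observables()`) because
zonal ratios are quoted in both forms: synthesis-rate ratios use the
half-sinusoid means, steatosis-location ratios the endpoint compartments.
The sinusoid average weights compartments equally (compartment volumes
are equal by construction).

## Scenario outputs and sensitivity protocols

`run_to_cycle_equilibrium()` + `observables()` produce the per-compartment
cycle averages of every species and rate, the triglyceride content as
percent of cell mass (linear conversion anchored at 50 mg/g wet weight =
5%, with triolein molar mass 885.4 g/mol and unit tissue density), the
glycogen swing (postprandial peak minus pre-prandial trough) and the zonal
ratios. Two local sensitivity protocols are provided:

* `rate_sweep()` — from the constant-input baseline steady state, each
  hepatic rate constant is changed by +/-10% and the model integrated for
  36 h with constant inputs; reported are the changes at the horizon (a
  point-in-time measurement, appropriate because inputs are constant) in
  hepatic and plasma FFA and triglyceride.
* `zonation_sweep()` — under the NAFLD scenario, each zonation constant is
  shifted by +/-0.2 and the model re-run to full cycle equilibrium
  (steatosis distribution is an equilibrium property, not a transient);
  reported are the compartment-1:compartment-8 triglyceride ratios and
  the normalised pericentral-minus-periportal difference statistic.

## What the simulator does and does not capture

The generator of all study conditions is the model itself under the
scenario presets; no external data enter the simulations. The model
represents a single near-average individual at rest: parameters are
non-unique and the reference set is one documented choice. Deliberate
simplifications: lumped two-stage glycolysis/gluconeogenesis without
per-enzyme resolution; NADH/FADH2 folded into fractional ATP
stoichiometry; no cholesterol, fructose or amino-acid metabolism; no
adipose storage pool (plasma triglyceride stands in for the adipose
substrate of lipolysis, so sustained high-fat diets exaggerate plasma
lipid responses); no dynamic oxygen or blood-flow response; no
electron-transport-chain decline, ROS or inflammation, so late-stage NASH
progression is out of scope; smooth sin^6 meals rather than discrete
events; and hormone action through two global half-effect constants
rather than receptor kinetics. Consequently the passing tests show that
the implemented network with the shipped constants reproduces the
calibrated healthy and disease-state observables and their zonal
structure, not that the model would extrapolate to feeding patterns,
hormone dynamics or disease stages outside those conditions.
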