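---
title: "Modelling Wnt-driven metabolic patterning in tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Wnt-driven metabolic patterning in tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(wntpattern)
```

## The model

Xenograft colon tumours stained for PDK activity (phospho-PDH) and for Wnt
effectors (LEF-1, beta-catenin) show a regular spotted array: discrete
clusters of strongly glycolytic cells embedded in tissue that relies more on
oxidative phosphorylation. `wntpattern` implements a reaction–diffusion
model of this heterogeneity built around a Gierer–Meinhardt activator–
inhibitor pair: Wnt activity `W` is a short-range, autocatalytic activator
(`D_W` small) whose targets include its own long-range inhibitor `W_I`
(`D_WI` large, e.g. SFRP/DKK family proteins). Wnt activity sets the
metabolic programme of two live cell populations — oxidative `P_o` and
glycolytic `P_g` — which proliferate logistically, switch programmes, die
when nutrient `N` runs out (into a dead pool `P_d`), and move randomly.

The reaction terms, per unit (time in units of the 1-day proliferation
time, space in units of the roughly 40 um Wnt-inhibitor diffusion length):

* proliferation `(1/tau) N P (1 - P_tot)` with `P_tot = P_o + P_g + P_d`
  (dead cells occupy space); glycolytic proliferation carries the
  Michaelis–Menten Wnt dependence `W/(alpha_W + W)`;
* metabolic switching `(1/tau_og) chi_W chi_N* P_o` (OXPHOS to glycolysis,
  allowed only above the nutrient floor `N_g*`) and
  `(1/tau_go) chi_W* P_g` back, with `chi_W` the tanh switch centred on
  `W*` ([wnt_switch()], [nutrient_gates()]);
* starvation death `mu (1 - chi_N) P` below `N*`, feeding `P_d`;
* Wnt dynamics `kappa_W N P_g W^2/(a + b W_I) + S_W (P_o + P_g) - mu_W W`;
* inhibitor dynamics `kappa_WI W^2 (P_o + P_g) - mu_WI W_I`;
* nutrient uptake, decay, and an angiogenic source (below).

All parameter values are the published mock and dnLEF sets
(`mock_params()`, `dnlef_params()`; YAML copies under
`system.file("params", package = "wntpattern")`).

## The angiogenic nutrient coupling

Glycolytic cells secrete lactate, which drives angiogenesis; the model
represents this as a bulk nutrient source and a Dirichlet boundary value
that both increase with the total glycolytic population. The printed form
normalises the glycolytic integral by the domain area. Implemented
literally, that closure admits no amplitude under which the model can both
(i) establish a tumour from the boundary-seeded initial condition and
(ii) collapse when therapy removes the glycolytic population — the two
behaviours the model is used to demonstrate. The package therefore
normalises the coupling by the live-cell mass:

```
N_S = N_s * ((1 - alpha_N) * f + alpha_N),   N_b = N_S / N_s,
f   = int(P_g) / max(int(P_o + P_g + P_d), live_floor * V).
```

`f` is the *glycolytic share* of the tumour bulk (dead cells still occupy
perfused tissue, so they count in the denominator — during cytotoxic
therapy the flood of dead cells dilutes the glycolytic share and with it
the vascular support, which is what lets a sufficiently hard glycolytic
hit starve the whole tumour): vascular support tracks
how glycolytic the tumour is, not how large it is. Both printed endpoint
identities survive (`N_S = N_s alpha_N` with no glycolysis; `N_S = N_s` at
full glycolytic occupancy), `N` stays of order one so the thresholds
`N* = 0.07` and `N_g* = 0.1` are meaningful, and the small-mass guard
`live_floor` (default 5 % of the domain volume) prevents a vanishing
glycolytic remnant from sustaining full vascular support. This is the one
deliberate structural choice in the package and everything downstream
(patterning, dnLEF phenotype, therapy collapse) depends on it; it is
exposed through `nutrient_source(..., integral_live =)` so the plain
domain-normalised closure remains available.

## Solver

`simulate_model()` advances the equations with an operator-split scheme:
reactions are explicit, diffusion is implicit through dimensionally split
dense solves `(I - dt D L)^-1` per axis (unconditional in the diffusion
CFL; the conservative Neumann stencil preserves field totals to machine
precision), and the nutrient additionally treats its linear uptake and
decay pointwise-implicitly. All fields carry no-flux boundaries except
`N`, whose Dirichlet frame is re-imposed every step. Explicit reaction
stability requires `dt` below about `2/(gamma_N mu)`; the default
`dt = 5e-4` is conservative and `2e-3` is used for the long steady-state
runs. Negative undershoots (possible at `O(dt^2)` in the explicit reaction
substep) are clipped to zero and the clipped mass is reported. The core
loop is compiled (RcppArmadillo); 2D and 3D grids are supported, with
`central_slice()` extracting the mid-plane view used to compare 3D runs
with stained sections.

Default analysis scale: 2D `96 x 96` to `128 x 128` over the `12 x 12`
domain (pixel size 3.75–5 um at the 40 um calibration), `dt = 2e-3`,
integration to `t = 150` with early exit once the maximum relative field
change drops below `1e-5` per unit time; three seeds per condition (the
mock run typically converges between `t = 70` and `t = 120`). The spike
cores are one to two pixels wide at this resolution, so absolute Wnt-spot
areas carry a resolution dependence on top of the thresholding
dependence discussed below.

## What the simulations produce

From cells seeded near the boundary, the system ignites: while nutrient is
still high, local Wnt fluctuations grow autocatalytically into an array of
narrow Wnt spikes surrounded by saturated glycolytic plateaus, denser near
the vascularised boundary. The realised state is a large-amplitude spike
pattern: linear analysis (`homogeneous_steady_state()`, `dispersion()`)
shows the uniform glycolytic state is *stable* at the published parameters
— the pattern is subcritical, a familiar property of Gierer–Meinhardt
kinetics without saturation — while raising the nonlinear Wnt production
`kappa_W` to about 20 crosses a genuine Turing onset with preferred
wavelength close to one nondimensional unit (about 40 um). The
theory/simulation consistency checks therefore compare parameter sets on
both sides of that onset rather than the baseline set alone.

Quantitatively, the spotted statistics measured by the spot pipeline on
simulated fields reproduce the published orderings (dnLEF spots larger and
sparser than mock in every seed; Wnt-activity spots smaller than
glycolytic spots) but sit above the published absolute spot sizes: the
simulated glycolytic plateaus are broader and more confluent than the
printed simulation averages, which were obtained with manually chosen
per-image thresholds that are not recorded. The reproduction script
reports the package's numbers under its single documented convention —
Otsu threshold with a top-5-percent quantile fallback where Otsu is
degenerate (spike-like fields), 15 um hull grouping — rather than tuning
thresholds per target; the mock glycolytic plateaus are in fact so
confluent that their top-of-range components merge into large connected
regions, which is the main source of the size overestimate.

## Spot quantification

The image pipeline mirrors standard IHC spot analysis: threshold
([binarize()], Otsu or manual, with a median noise filter and small-
component removal), connected components, convex-hull grouping of
components closer than about two cell diameters ([detect_spots()]),
per-spot geometry and nearest-neighbour statistics ([spot_statistics()];
cells per spot uses a nominal 44 um^2 cell so that a 309 um^2 cluster is
about seven cells), serial-section overlap by hull intersection
([overlap_analysis()]), and a Cochran–Mantel–Haenszel association test
over concentric distance-to-boundary strata ([cmh_association()]; the
stratification partially absorbs the radial gradient in spot density that
a pooled 2x2 table would confound). Simulated fields enter the same
pipeline through [field_to_image()]/[field_spots()].

The synthetic generator ([make_spot_image()], [make_serial_pair()])
produces dark disks on a lighter background with controlled radius,
spacing, noise, radial background gradient and inter-section overlap, plus
exact ground truth. Disk geometry is deliberately idealised — closed-form
truth beats morphological realism for validating the pipeline; recovery
on noiseless images is exact in count and within pixelation error (< 5 %)
in area, and count recovery stays >= 95 % up to noise sd 10. What these
tests do *not* establish is performance on real DAB stains with uneven
illumination, touching clusters of irregular shape, or section-to-section
deformation.

## Therapy simulations

[apply_therapy()] adds targeted death rates (`mu_Po`, `mu_Pg`) to a
patterned state, then lets the system recover. Killing either population
transiently shrinks the tumour with full recovery at modest dose;
eradication happens sooner and at lower dose when the glycolytic
population is targeted, because removing `P_g` collapses the angiogenic
share and starves the whole tumour, whereas removing `P_o` leaves the
glycolytic core and its vascular support intact.

[combo_params()] models XAV939 as `S_W -> xav_factor * S_W` with `D_W` and
`D_WI` increased linearly in the Wnt reduction — slopes calibrated so the
dnLEF `S_W` ratio reproduces the dnLEF diffusivities exactly — and DCA as
an increased glycolysis-to-OXPHOS switch rate `1/tau_go`.
[eradication_threshold()] bisects for the weakest Wnt reduction that still
eradicates at a given DCA rate. In this reconstruction the Wnt spikes are
the tumour's life line: once they collapse, the glycolytic share and with
it the nutrient boundary value fall below the death threshold everywhere,
so eradication occurs at milder Wnt reductions than the roughly 27 %
reported for the published implementation — the bisection reports the
package's own boundary, computed, not transcribed.

The in vitro variant ([invitro_params()], [simulate_colony()]) removes
angiogenesis entirely (fixed gel-boundary nutrient, no bulk source) and
adds explicit cross-feeding: a by-product field `L` produced with the
glycolytic nutrient flux, consumed by oxidative cells, and counted as
auxiliary fuel in their proliferation. The by-product coefficients
(`D_L = 1`, `c_prod = c_feed = mu_L = 1`, `beta_L = 0.5`) are plausible
round values chosen once — the printed account does not fix them — so the
in vitro combination index is a calibration-level quantity with a wide
tolerance, not a sharp validation. DCA dosing in vitro follows the
printed convention verbatim, including sub-baseline switch rates.

## Numerical and degenerate-input choices

* Steady-state detection: maximum relative field change per unit time
  below `1e-6` (`simulate_model(conv_tol=)`); long pattern runs use `1e-5`.
* Divergence guard: any field above `1e6` aborts with the field named.
* Newton steady-state search uses damped steps, analytic Jacobians
  (cross-checked against finite differences at `1e-6`), 24 multistarts,
  and reports all distinct nonnegative roots; some regimes only admit the
  zero state and are reported as such.
* The global angiogenic coupling enters the linearisation only at `k = 0`
  (it is a mean-field term); finite-`k` modes see the local Jacobian.
* Empty masks, single spots (no nearest neighbour), and strata with zero
  margins degrade gracefully (warnings, `NA` statistics, dropped strata).
* `mantelhaen.test` requires two strata; a single stratum uses the
  closed-form CMH statistic.

## Known limitations

The model inherits the idealisations of its source: no explicit PDK/HIF/
lactate fields in vivo (Wnt stands in as the effective switch), oxygen
assumed sufficient, a cubic domain with square symmetry artefacts, and no
mechanics. The subcritical character of the baseline pattern means linear
dispersion under-predicts where patterns occur; absolute spot sizes
depend on the (unrecorded) segmentation thresholds of the original
analysis; and the in vitro cross-feeding coefficients are package
choices. Conclusions that rest only on orderings (dnLEF vs mock, P_g- vs
P_o-targeting, synergy vs independence) are robust to all of these;
absolute spot geometry is not.
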