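---
title: "Methods: simulating and analyzing hemoglobin and Hb:Hp disposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing hemoglobin and Hb:Hp disposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemopk)
```

# Scope

`hemopk` implements the full measurement and analysis chain of an
intravascular hemoglobin (Hb) exposure study in a haptoglobin (Hp)-replete
species: a kinetic simulator of Hb infusion, Hp binding and clearance that
stands in for the animal experiment; the spectral and chromatographic assays
that turn plasma samples into free and Hp-bound heme concentrations;
non-compartmental pharmacokinetic (NCA) estimation with mean ± SEM group
summaries; and per-cell quantification of Hb:Hp endocytosis from two-channel
fluorescence images. Everything is deterministic given a seed, and every
synthetic-data generator returns its ground truth so that recovery can be
scored.

# The kinetic model

All concentrations are micromolar heme equivalents (one Hb tetramer = 4
hemes), so a 4 g Hb bolus is `hb_grams_to_umol_heme(4)` ≈ 248.2 µmol heme.
Hp is expressed in µM heme-binding-site equivalents; at the default
capacity constant one gram of Hp neutralizes the heme content of one gram
of Hb, matching paired 4 g/4 g dosing.

The plasma compartment (volume $V$) evolves as

$$
\begin{aligned}
\frac{d[\mathrm{Hb}]}{dt} &= \frac{In_{Hb}(t)}{V}
  - k_{on}[\mathrm{Hb}][\mathrm{Hp}] - k_{el,f}[\mathrm{Hb}] \\
\frac{d[\mathrm{Hp}]}{dt} &= \frac{In_{Hp}(t)}{V}
  - k_{on}[\mathrm{Hb}][\mathrm{Hp}] \\
\frac{d[\mathrm{HbHp}]}{dt} &= k_{on}[\mathrm{Hb}][\mathrm{Hp}]
  - E([\mathrm{HbHp}])
\end{aligned}
$$

with zero-order infusions ($In$): Hb over the first 10 min, Hp (when dosed)
over the following 10 min. Complex elimination $E$ is either first-order
($k_{el,c} \cdot C$) or saturable Michaelis–Menten
($V_{max} C / (K_m + C)$). A cumulative-elimination state is integrated
alongside so heme mass balance can be checked at machine precision at any
output time.

Modeling assumptions, and why:

* **Binding is irreversible** ($k_{off} = 0$). The Hb:Hp interaction is
  effectively non-dissociating on a 60 h time scale, so a single
  bimolecular association term suffices.
* **One equation set for dimeric and multimeric Hp.** In vivo disposition
  of the two phenotypes is indistinguishable here; the phenotype only
  changes the forward SEC model (retention times and peak widths).
* **Free-Hb loss is one first-order rate** ($k_{el,f}$), lumping renal
  filtration and extravasation. The large *apparent* unbound volume seen in
  NCA output is an emergent artifact of rapid binding (little free Hb is
  ever measurable), not a modeled physical compartment.
* **No Hp synthesis or turnover** over 60 h. Glucocorticoid pre-treatment
  is emulated purely as an elevated basal Hp concentration, since its
  pharmacokinetic effect operates through Hp availability.
* **Saturable clearance is one admissible mechanism**, not a claim: the
  exogenous-Hp arms use Michaelis–Menten elimination because high complex
  loads show a two-phase log decline (a shallow early phase steepening to
  log-linear decay), which receptor-pool saturation reproduces.

## Default parameters

The defaults define the bundled reference study (seven arms in
`reference_study_arms()` / `inst/extdata/reference_study.yaml`) and were
fixed once, by forward simulation at design time, to be physiologically
sensible for a ~10 kg Beagle-scale subject and to reproduce the magnitudes
characteristic of this study design; they are not fit to any dataset.

| parameter | default | units | rationale |
|---|---|---|---|
| `plasma_volume_L` | 0.8 | L | Beagle plasma volume; the complex's Vc should land here |
| `hb_dose_g` | 4 | g | 40 ml of a 10 g/dl stock |
| `k_on` | 0.2 | L/(µmol·h) | fast enough that excess Hp binds most Hb during/shortly after infusion, slow enough that a transient free phase is measurable |
| `k_el_free` | 0.8 | 1/h | free-Hb disappearance (renal + extravasation), sub-hour half-life |
| `k_el_complex` | ln(2)/12 | 1/h | ≈ 12 h complex half-life (first-order arms) |
| `vmax`, `km` | 13, 150 | µM/h, µM | saturable mode: terminal rate `vmax/km` ≈ 0.087/h with visible early saturation at ~300 µM loads |
| `basal_hp_uM` | 90 (untreated), 280 (glucocorticoid arms) | µM sites | ~1.4 mg/ml plasma Hp at baseline; strong acute-phase induction binds ~90% of the dose |
| `noise_cv` | 0.1 | – | multiplicative lognormal assay error |
| `loq_uM` | 1 | µM | sub-LOQ samples are reported missing |
| `schedule_h` | 22 points, 0–60 h | h | baseline + 5 min + 20 further draws |

## Numerical choices

Integration uses `deSolve::lsoda` with relative tolerance 1e-8 (absolute
1e-10), run piecewise between infusion breakpoints with the infusion rate
frozen per segment, so the stiff solver never steps across a rate
discontinuity. Sampling times are included exactly in the output grid.
Per-subject seeds are `study seed + subject index`; measurement error is
lognormal with unit mean (`meanlog = -sdlog²/2`).

# Spectral heme speciation

A plasma sample's absorbance spectrum is modeled as a Beer–Lambert
superposition of ferrous (oxy/deoxy), ferric and hemichrome heme.
`fit_species()` solves the multi-component system by **non-negative** least
squares over a fitting window (default 500–650 nm, the Q-band region that
distinguishes the three species); negative heme concentrations are
unphysical, and the non-negativity constraint is what keeps noisy fits
stable. Total heme is the sum of the species. The pre-dose sample is the
blank: `blank_correct()` subtracts it (interpolating if the grids differ)
to remove turbidity and background interference.

The packaged extinction table is a **synthetic stand-in**: smooth
Gaussian-band curves with the recognizable peak positions of oxyHb
(541/577 nm), deoxyHb (555 nm), metHb (500/630 nm) and hemichrome
(535/565 nm). It exercises and validates the solver (round trips are exact
to ≤ 1e-6 relative by construction) but is not a measured reference table;
`read_extinction_table()` swaps in a real one for quantitative work. Oxy-
and deoxy-ferrous heme are lumped into one basis spectrum by default
(`four_species = TRUE` separates them), matching how ferrous heme is
reported in this assay.

# SEC partitioning

Free Hb and the Hb:Hp complex separate by size: free Hb elutes at 20.7 min
on the reference column; the dog complex at 17.7 min; human dimeric Hp
complex about 0.5 min earlier (17.2 min); multimeric complexes as a broad
doublet at 14.7/15.1 min. `integrate_peaks()` uses fixed, phenotype-specific
windows rather than automatic peak detection — retention times are stable
and fixed windows are auditable; edges are configurable. Within each window
a straight baseline connecting the window endpoints is subtracted, the
residual integrated by trapezoids, and negative areas clipped to zero.

The partition applies the printed formulas literally:
`percent free = area_free / (area_free + area_bound) × 100`, then
`free = total × pct/100` and `bound = total − free`, so free + bound equals
the spectrophotometric total *exactly*. A single molar A405 response factor
is assumed for heme in free Hb and in the complex, which is what makes the
area ratio a concentration ratio.

One window choice deserves a note: the multimeric elution profile is
described as lying between 12 and 16 min, but with a primary peak at
15.1 min and a realistic peak width (σ = 0.6 min) about 7% of its area
falls beyond 16 min. The default multimeric window is therefore 12–17.5 min
(≈ ±4σ around both peaks); truncating at 16 min would bias the bound
fraction by several percent and break the forward/inverse round-trip
guarantee of ≤ 0.5% absolute.

# Non-compartmental analysis

Per subject: Cmax (ties to the earlier time), linear trapezoidal AUC over
non-missing observations, terminal slope $k$ from OLS on ln(C) vs t,
extrapolation $C_{last}/k$, and then

$$CL = \mathrm{dose}/AUC_{0-\infty}, \quad
  V_c = \mathrm{dose}/C_{max}, \quad
  t_{1/2} = \ln 2 \cdot V_c / CL.$$

Two conventions are deliberate:

* **The half-life is reported as $\ln 2 \cdot V_c/CL$** (equivalently
  $\ln 2 \cdot AUC_{0-\infty}/C_{max}$), the reporting convention of the
  study design this reproduces — *not* the conventional $\ln 2 / k$. The
  conventional value is also returned (`t_half_lambda_h`) as a diagnostic.
  The four identities (`auc_0_inf = auc_0_clast + auc_clast_inf`,
  `CL·AUC = dose`, `Vc·Cmax = dose`, `t½·CL = ln2·Vc`) hold exactly by
  construction and are asserted in the tests.
* **Terminal-point selection** defaults to a best-adjusted-r² search over
  the last 3–8 positive observations at or after tmax (ties resolved
  toward more points), mirroring common lambda-z practice and fully
  reproducible; `n_fixed` forces a fixed count over the last n positive
  points.

Below-LOQ values are missing (never zero) for the slope and C_last; the
recorded zero at t = 0 is kept for the AUC; missing intermediate samples
are spanned by a single trapezoid. Group summaries report mean and
SEM = sd/√n per parameter; a failed subject yields a diagnostic record and
is excluded (and counted), never a crash.

Note that with a 10-min infusion, `Vc = dose/Cmax` carries a small upward
bias even on noise-free data (concentration decays during the infusion), so
parameter-recovery checks allow ~6% on Vc while CL recovers within 2%.

# What the simulator does and does not emulate

The generator reproduces: the seven-arm dosing design (4 g Hb ± 4 g Hp,
10 + 10 min infusions), the 22-point schedule, near-complete binding when
Hp is abundant, biphasic decline of high complex loads, fast free-Hb
disappearance, proportional assay error and LOQ censoring, and the
phenotype-specific chromatographic geometry. It does **not** emulate:
endogenous Hp resynthesis, inter-subject kinetic variability (subjects
differ only in measurement error), non-heme chromophores or scatter beyond
a smooth blank, column drift, or clumped/overlapping cells in the imaging
module. Passing tests therefore demonstrate correctness of the analysis
chain under its stated model, not robustness to every artifact of real
data.

A consequence worth flagging: in the exogenous-Hp arms the administered Hp
(plus basal) exceeds the heme dose, so free Hb falls below the 1 µM LOQ
within tens of minutes and fewer than three quantifiable terminal points
remain — per-subject NCA of the free phase is then reported as not
analyzable rather than forced. This mirrors the real observation that with
abundant Hp no unbound Hb may be detectable. The free/bound contrast is
therefore quantified on the glucocorticoid (endogenous-Hp) arms, where a
measurable free tail exists.

# Endocytosis quantification

The imaging module is a minimal, transparent equivalent of the usual
CellProfiler recipe: global Otsu threshold on the nuclear channel →
connected components → area filter → each nucleus dilated by 8 px (the
perinuclear region where internalized Hb:Hp accumulates) → per-cell mean
green intensity minus a scalar experiment background, floored at zero. The
background is estimated from no-probe control samples as the mean
cell-region green signal, so faint cell-associated autofluorescence is
subtracted together with the camera floor. Touching nuclei are *not* split
(no watershed): the generator guarantees separation, and clumped real data
are out of scope. The synthetic generator places non-overlapping disk
nuclei and deposits each cell's probe signal uniformly over the dilated
nucleus region, so the measured per-cell mean estimates the generated
intensity directly; at SNR ≥ 10 recovery is within 5% and counts are
exact.

# Problem sizes and reproducibility

The bundled analyses use the study-scale sizes throughout: 4–6 subjects
per arm, 22 samples per subject, 1 nm spectral grid over 450–700 nm,
0.02 min chromatogram grid, and 192–256 px images with 10–12 cells;
oracle-equivalence checks use 1000 randomized profiles. `run_study()` is
deterministic per seed down to the written CSVs, and
`scripts/acceptance.R --seed N --out f.json` recomputes every headline
quantity from scratch.

# Known limitations

* The synthetic extinction table supports validation, not quantitation of
  real spectra.
* NCA assumes the terminal phase is log-linear; under strong saturation the
  "terminal" window within 60 h still curves slightly, and the best-r²
  search will pick the late log-linear stretch.
* The measurement chain models one response factor per detector; detector
  nonlinearity and column calibration are out of scope.
* Prednisone dosing itself is not modeled (only its effect, elevated basal
  Hp), so dose inconsistencies in glucocorticoid regimens are moot here.
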