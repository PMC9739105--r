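---
title: "Methods: quantitative characterization of a microtubule-targeting venom peptide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative characterization of a microtubule-targeting venom peptide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxkit)
```

# Scope

mtxkit implements the quantitative backbone of a study characterizing
myotoxin-3 — a 45-residue crotamine-family peptide from *Crotalus oreganus
oreganus* venom, with three disulfide bonds — as a microtubule-targeting
agent. Four analysis stages are covered, each paired with a seeded synthetic
generator so that every statistic can be validated against known ground
truth without any external data:

1. disulfide-aware peptide mass arithmetic and MALDI in-source-decay (ISD)
   c/z fragment-ladder annotation;
2. segmentation of microtubule length-history tracks into growth (G),
   shortening (S) and pause (P) phases, and the dynamic-instability
   statistic set;
3. turbidimetric tubulin-polymerization curve metrics;
4. a Wiseman one-set-of-sites isothermal titration calorimetry (ITC) model
   with nonlinear fitting and derived thermodynamics.

# Peptide mass arithmetic

Residue masses are hard-coded standard values (monoisotopic from IUPAC
atomic masses, average from standard atomic weights). A peptide's neutral
mass is the residue sum plus one water; each disulfide bond removes two
hydrogens from the reduced-form mass (−2.016 Da average), so oxidation
state enters only through the disulfide count — the pairing pattern is
mass-silent and deliberately not modelled. Printed MALDI linear-mode masses
are treated as neutral average masses and compared at 1 Da tolerance; this
reproduces the observed 5168.3 Da main peak from the 45-mer with three
disulfides (calculated 5168.09 Da) and the 4982.98 / 4959.00 Da calculated
masses of the 43-residue His5/Leu5 isoforms to better than 0.1 Da.

Two modelling choices were genuinely open:

* **The 43-residue isoforms** are modelled as residues 1–43 of the 45-mer,
  i.e. lacking the C-terminal Asn-Ala. This reproduces both published
  calculated masses; which residues are actually absent is not established
  by sequencing, so the choice is a convention that happens to be uniquely
  consistent with the mass evidence.
* **The z-ion convention.** ISD with a diaminonaphthalene matrix transfers
  hydrogen radicals and cleaves N–Cα bonds, giving c ions and z-type
  radical ions. We fix the z series at
  `z_j = sum(residues) + H2O − NH3 + 2 H` ("z+1"), one documented constant;
  with this convention `c_i + z_(n−i) = M + 2 H`, which the suite asserts
  as the complementarity invariant. The companion generator uses the same
  convention, so annotation tests are convention-independent.

A documented curiosity: the published calculated monoisotopic mass of the
N-terminal decapeptide YKRCHKKGGH (1212.69 Da) exceeds the standard-table
value (1212.63 Da); the singly protonated c10 ion (1212.653 Da) is what
matches the reported 1212.7 Da fragment, and that is the comparison the
package makes.

Peak annotation is greedy nearest-mass matching: candidate (peak, ion)
pairs within tolerance are sorted by absolute error (ties to the lower ion
index) and assigned with each peak and each ion used at most once.
Coverage is the fraction of the n−1 backbone bonds supported by a matched
ion; the terminal span is the longest run of supported bonds anchored at
either terminus, the quantity behind "a 35-residue C-terminal fragment"
statements. Substitution inference brute-forces all 380 ordered residue
pairs — at 0.1 Da tolerance a 24 Da shift returns His/Leu (and His/Ile,
indistinguishable by mass), the signature separating the His5 and Leu5
isoforms.

Pairwise identity uses Needleman–Wunsch global alignment (match 1,
mismatch 0, linear gap −1; computed via Biostrings) with identity defined
as identical columns over alignment length. The published 86% / 90.6%
identities to crotamine and helleramine are not reproduced because those
comparison sequences appear only in a figure; the operation itself is
exercised on derivable cases (the 1–43 truncation gives 43/45 = 95.6%).

# Microtubule dynamic instability

## The simulator

Plus-end dynamics are modelled as a three-state continuous-time Markov
chain over {G, S, P} with six free transition rates (events/min) and two
speeds (µm/min); growth and shortening change length linearly, pause holds
it. Simulation is exact and event-driven (Gillespie): exponential waiting
times from the current state's total exit rate, categorical choice of the
next state, then resampling of the piecewise-linear length path onto the
observation grid (default 2-s intervals for 1 min, the usual live-cell
video rate, giving 31 samples per track). Observed lengths carry Gaussian
noise (default SD 0.05 µm — no acquisition noise magnitude is published
for tracked lengths, so this is a fixture convention of roughly half a
pixel) and are clipped at zero. At zero length a forced rescue (S→G) is
applied and flagged in the event log, so recovery analyses can exclude
boundary-touching tracks; real microtubules cannot have negative length,
and complete depolymerization events are outside the model's scope.

Default parameters (v_g = 26, v_s = 31 µm/min; rates k_GS = 6.0,
k_GP = 7.85, k_PG = 3.54, k_PS = 2.89, k_SG = 12.0, k_SP = 6.91 per min)
were derived once, by stationary-flux balance, to land the analysis of a
few dozen noiseless tracks in the measured MCF-7 control range: occupancy
near 29/17/54% G/S/P, rescue frequency near 19/min of shortening time, and
dynamicity in the low teens of µm/min. They are fixture conventions — the
published absolute values derive from live-cell recordings that are not
reproducible at the desk — and were not revisited afterwards. Dose
conditions in the fixture suite shift these parameters in the measured
direction (slower speeds, more pause at 25 µM) with the published sample
sizes (54/44/44/68 tracks).

The simulated trajectories capture the statistical structure the analysis
assumes — exponential phase lifetimes, linear phase excursions, additive
Gaussian noise — but not tracking artifacts of real imaging (tip-loss,
drift, out-of-plane excursions, heavy-tailed localization error). Passing
recovery tests therefore demonstrates correctness of the estimators under
the model, not robustness to every failure mode of live-cell tracking.

## Segmentation and statistics

Segmentation classifies each sampling interval by instantaneous rate
(G if ≥ `min_rate`, S if ≤ −`min_rate`, else P), merges runs, and demotes
a candidate G/S run to pause unless its net excursion reaches
`min_excursion` with the matching sign **and** its least-squares slope
reaches `min_rate`. Defaults of 0.5 µm and 2 µm/min follow common practice
in the dynamic-instability literature (the source study states none); both
are arguments. On noiseless piecewise-linear tracks the recovery of
boundaries and slopes is exact.

Event conventions: catastrophe = G→S or P→S, rescue = S→G or S→P.
Frequencies per time normalize catastrophes by time in growth plus pause
and rescues by time in shortening; per-length frequencies normalize by
total length grown / shortened. Dynamicity is total tubulin exchange,
(length grown + |length shortened|) per minute of observation. Headline
means pool events and times across tracks; SEMs are over per-track values
with n = number of microtubules. These normalizations cannot be read off a
published table unambiguously, so they are stated here as the package's
fixed convention.

Percent changes between conditions are rounded half-away-from-zero to
whole percent, matching the reporting style of the reference table, with
two-tailed Welch t-tests on per-track values (Mann–Whitney optional) and
significance codes A/B/C at p < 0.001/0.01/0.05. Applied to the bundled
reference table (control vs 25 µM), this reproduces every printed
percentage: dynamicity −40%, shortening rate −21%, shortening length −25%,
time in growth −29%, time in pause +15%, catastrophes +43% and rescues
+70% per µm. Note that the +43%/+70% figures match the per-micrometre
transition-frequency rows (the per-minute rows give +3%/+7%); the package
computes both and treats the per-µm values as the ones behind the printed
percentages.

## Recovery study design

The validation suite recovers hidden states, speeds and transition
frequencies from 200 simulated noiseless tracks. Identifiability dictates
the study's sampling: with the default (control-like) rates, total
transition flux is ~10 events/min, so at the 2-s video rate roughly a
third of sampling intervals straddle a phase switch and per-sample state
recovery is bounded far below 99% for *any* segmenter — sub-interval
events are simply not observable. The recovery study therefore samples the
same generator at dt = 0.02 s with thresholds suited to noiseless data
(`min_excursion` ~ 0, `min_rate` = 1 µm/min), where the package achieves
≥ 99.8% per-sample agreement, speed recovery within ~1%, and transition
frequencies within Monte-Carlo error of the generator rates (Poisson SE on
event counts). Tracks that touch the zero-length boundary are excluded, as
the forced rescue is a boundary artifact by construction. Runtime is a few
seconds on one core.

# Turbidity polymerization metrics

The generator is a Gompertz sigmoid — a monotone sigmoid with independent
lag, rate and plateau parameters (no functional form is prescribed by the
assay):

A(t) = baseline + K · exp(−exp(−r · (t − t_m))),
t_m = lag + log(log 10)/r,

with the shift chosen so that the curve crosses 10% of its amplitude
exactly at t = lag. The metrics use the same criterion: baseline = mean of
the first 5% of points, plateau = mean of the last 10%, lag = first
crossing of baseline + 10% of amplitude on a centered 5-sample moving
average, vmax = maximal smoothed slope. The 5%/10%/10% fractions are
common turbidimetry conventions and are all arguments. The lag is reported
as undefined when the amplitude does not exceed three baseline noise SDs —
a flat (vehicle) curve has no nucleation lag to speak of.

Validity regime: the onset must clear the baseline window
(lag − 2/r larger than 5% of the record) and the plateau must be reached
within the record; inside that regime noiseless round-trips recover the
lag within one sample interval and the plateau within 1%, and the tests
state their parameter grids accordingly. Since the published curves are
not tabulated, only orderings are asserted against the data: the peptide
fixture has a shorter lag and higher plateau than its control, the
direction observed for myotoxin-3. Curve comparisons report the amplitude
(baseline-subtracted plateau) ratio so that doubling a curve's amplitude
doubles the ratio regardless of shared baseline.

# ITC one-set-of-sites analysis

The forward model is the standard Wiseman single-class-of-sites isotherm
with perfusion-cell bookkeeping. After cumulative injected volume dV into
an active cell volume V0, concentrations are

M = M0 (1 − dV/2V0)/(1 + dV/2V0),  X = X0 (dV/V0)/(1 + dV/2V0),

the bound fraction is the physical root of
Θ² − Θ(1 + X/NM + 1/(N·Ka·M)) + X/NM = 0, the cell heat content is
Q = N·Θ·M·ΔH·V0, and the measured heat of injection i is
q_i = Q_i − Q_{i−1} + (v_i/V0)(Q_i + Q_{i−1})/2. Heats are in µJ, ΔH in
kJ/mol, R = 8.314 J/mol/K, and the default temperature is 293.15 K (the
experiment ran at 20 °C). The default schedule is the tubulin experiment:
55 µM macromolecule in the cell, 2.2 mM peptide in the syringe, 2 µL
injections; 19 injections into a 200 µL cell span molar ratios up to ~7.5,
bracketing the stoichiometric point at ratio 2. Dilution heats are handled
by element-wise blank subtraction (or a constant offset), mirroring
buffer-into-buffer control titrations.

`fit_one_site()` is the package's model-fitting front end, returning a
classed fit with `coef`, `predict`, `residuals`, `fitted`, `simulate` and
`plot` methods. Fitting is Levenberg–Marquardt least squares over
(N, log Ka, ΔH) — Ka on the log scale for conditioning, with its standard
error mapped back by the delta method — from a multi-start grid (Ka =
10³…10⁸ M⁻¹, N = 0.5…4), because one-site fits are multimodal at low
c-value. The c-value N·Ka·M0 is reported and flagged outside [1, 1000];
at the fixture's generating values (N = 2, Kd = 5.3 µM — the published
binding constants — ΔH = −40 kJ/mol, a convention since only
"enthalpy-favourable" is published) c ≈ 21, comfortably identifiable.
Derived quantities follow the standard relations ΔG = −RT ln Ka,
ΔS = (ΔH − ΔG)/T, Kd = 1/Ka, and the identity ΔG = ΔH − TΔS is asserted to
machine precision. Noiseless synthetic isotherms are recovered to 0.1%
relative error; with 1% heat noise the median Kd error across 50 seeds
stays below 10%. The first injection can be excluded by flag (common
practice for the pre-injection artifact) but is included by default.

# Pipeline, formats and reporting

All interchange is plain text: tracks, turbidity, ITC and peak-list CSVs
with fixed headers and "." decimals, FASTA (60-column wrap, with an
`n_disulfides=` key on the description line), JSON stage outputs, and a
YAML run configuration with fail-fast validation (unknown keys are
errors). `make_fixture_suite()` writes the complete input bundle plus a
ground-truth manifest and is byte-deterministic under a fixed seed;
per-stage seeds are derived from the master seed. `run_pipeline()`
executes the requested stages, writes one JSON per stage, a consolidated
report, a rendered dynamic-instability table (mean ± SEM with
significance superscripts, losslessly serializable to CSV) and a
structured log recording version, seed and parameters. A thin command-line
wrapper (`inst/cli/mtxkit.R`) exposes the same stages to shell users; the
exported functions are the primary interface.

# Known limitations

* Track analysis operates on scalar length histories; image-based tip
  tracking, drift correction and 2-D trajectory geometry are out of scope.
* At video-rate sampling (2 s), sub-interval phase switches are
  unobservable; absolute transition frequencies from coarsely sampled data
  are method-dependent, which is why published absolute values are treated
  as inputs for ratio checks rather than recovery targets.
* The ITC stage fits integrated per-injection heats; baseline integration
  of raw power traces, multi-site and competitive models are not
  implemented.
* The mass module covers singly charged species and disulfides only — no
  isotope envelopes, higher charge states or other modifications.
* Percent-identity values for homologs whose sequences are unavailable in
  text form are not asserted.
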