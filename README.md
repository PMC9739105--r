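# mtxkit

Quantitative analysis toolkit for characterizing crotamine-family venom
peptides as microtubule-targeting agents (MTAs), built around myotoxin-3 —
a 45-residue, triply disulfide-bonded cationic peptide from *Crotalus
oreganus oreganus* venom that promotes tubulin polymerization, penetrates
cells, and damps microtubule dynamic instability.

It is written for biophysicists and venom-peptide researchers who need the
four quantitative stages of such a characterization as reusable, tested
code:

* **Peptide mass spectrometry** — disulfide-aware monoisotopic/average
  masses (each S–S bond removes 2 H), MALDI in-source-decay c/z
  fragment-ladder computation and annotation (coverage, terminal span),
  residue-substitution inference from mass shifts (the 24 Da His/Leu
  signature that separates the myotoxin-3 isoforms), and global-alignment
  percent identity.
* **Microtubule dynamic instability** — segmentation of length-vs-time
  tracks into growth/shortening/pause phases and the full statistic set:
  rates and length changes per event, percent time per phase, catastrophe
  and rescue frequencies per minute and per micrometre, and dynamicity

  dynamicity = (Σ length grown + Σ |length shortened|) / total time,

  with condition comparisons (percent change, Welch t-test, significance
  codes).
* **Turbidimetric polymerization** — lag time (10%-amplitude criterion),
  plateau and maximal rate of A350 time courses, and condition
  comparisons.
* **ITC binding** — the Wiseman one-set-of-sites isotherm with
  perfusion-cell corrections, blank subtraction, Levenberg–Marquardt
  fitting of (N, Ka, ΔH) with multi-start initialization, and derived
  ΔG = −RT ln Ka, ΔS = (ΔH − ΔG)/T.

A seeded synthetic-data module (three-state Gillespie track simulator,
Gompertz turbidity curves, one-site isotherms, fragment spectra) generates
every input with known ground truth, so the whole pipeline is testable
end-to-end without downloads. See `vignettes/mtxkit-methods.Rmd` for the
models, conventions and their rationale.

## Worked example

```r
library(mtxkit)

## the oxidized 45-residue peptide: average mass matches the 5168.3 Da
## MALDI main peak within 1 Da
myotoxin3_peptide("45H")
#> <peptide myotoxin-3 45H> 45 residues, 3 disulfide bond(s)
#>  YKRCHKKGGHCFPKTVICLPPSSDFGKMDCRWKWKCCKKGSVNNA
#>   mass: 5164.4623 Da (mono), 5168.092 Da (average)

## dynamic-instability percent changes, control vs 25 uM peptide, from the
## bundled reference measurements (mean values per parameter)
compare_conditions(reference_condition("control"), reference_condition("25uM"))
#> <mt_comparison> percent change vs control
#>   growth_rate        -22%
#>   shortening_rate    -21%
#>   growth_length      -40%
#>   shortening_length  -25%
#>   pct_time_G         -29%
#>   pct_time_S         +2%
#>   pct_time_P         +15%
#>   cat_per_min        +3%
#>   res_per_min        +7%
#>   cat_per_um         +43%
#>   res_per_um         +70%
#>   dynamicity         -40%

## one-site ITC fit of a synthetic isotherm at the tubulin schedule
## (55 uM cell, 2.2 mM syringe, 2 uL injections), generated at the
## published binding constants N = 2, Kd = 5.3 uM
truth <- binding_params(N = 2, Ka = 1 / 5.3e-6, dH = -40)
tit <- simulate_itc(truth, itc_schedule(), noise_sd = 2, seed = 1)
fit_one_site(tit)
#> <itc_fit> one-set-of-sites
#>   N  = 1.987 +/- 0.017 sites
#>   Kd = 5.41e-06 M (Ka = 1.85e+05 +/- 1.3e+04 1/M)
#>   dH = -40.20 +/- 0.45 kJ/mol; dG = -29.56 kJ/mol; dS = -36.31 J/mol/K
```

The comparison output reads: at 25 µM peptide, overall microtubule
dynamicity falls 40% (14.4 → 8.65 µm/min), time in growth falls 29% while
time in pause rises 15%, and per-micrometre catastrophe and rescue
frequencies rise 43% and 70% — the quantitative signature of a
dynamics-damping MTA. The ITC fit recovers the generating stoichiometry
and affinity from a realistically noisy isotherm.

For file-based work, `make_fixture_suite("fixtures", seed = 1)` writes a
complete input bundle (tracks, turbidity, ITC, spectra, FASTA, manifest)
and `run_pipeline("config.yaml")` — or the thin CLI wrapper
`Rscript inst/cli/mtxkit.R <stage> ...` — executes the stages and writes
JSON reports plus a rendered dynamic-instability table.

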