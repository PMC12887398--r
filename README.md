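# stemopen

Quantitative analysis of protein-driven RNA hairpin remodeling.

Small structured RNAs are recognized by innate-immune receptors through
their fold, not just their sequence: a 15-nt stem–loop (stem bases 1–4
paired with 12–15) is the active conformation, and a nucleic-acid-binding
protein that opens the stem can silence the ligand without touching the
receptor. Establishing that mechanism quantitatively takes four
measurements and one simulation, and this package implements the complete
analysis chain for all of them, together with seeded synthetic-data
generators so every stage is testable without instrument data:

* **Binding isotherms** — fluorescence anisotropy / FRET titrations fit
  with the exact single-site ligand-depletion model
  `fb = [(P+L+Kd) − √((P+L+Kd)² − 4PL)] / 2L`, required because the probe
  concentration (40 nM) is comparable to Kd (`fit_kd`).
* **Thermal melts** — two-state van't Hoff model
  `fu(T) = 1/(1+exp[(ΔH/R)(1/T − 1/Tm)])` with linear baselines and dye
  quenching; Tm from the smoothed first-derivative extremum
  (`derivative_tm`, `fit_melt`), and transition amplitudes vs protein
  dose cross-checked against `1 − fb` (`amplitude_vs_dose`).
* **NMR chemical-shift perturbations** —
  `CSP = √(ΔδH² + ΔδN²/36)` per amide, titration tracking, and
  mean + n·SD flagging of interface residues (`compute_csp`,
  `flag_perturbed`).
* **Structural collective variables** — Kabsch superposition RMSD and the
  stem coordination number `CN = Σᵢ∈A Σⱼ∈B (1 − xᵢⱼ⁶)/(1 − xᵢⱼ¹²)`,
  `x = (r − d₀)/r₀`, `r₀ = 3 Å`, between bases 1–4 and 12–15
  (`kabsch_rmsd`, `coordination_number`, `base_pair_distances`).
* **Well-tempered metadynamics** — Gaussian hills (1 kJ/mol every 0.2 ps,
  widths 0.5 Å and 10, bias factor γ = 15, 300 K) tempered as
  `w = w₀·exp(−V/kB(γ−1)T)`, deposited by an overdamped Langevin sampler
  on toy two-basin landscapes; free-energy surfaces via
  `F = −γ/(γ−1)·V`, watershed basin detection, and the hairpin/open gap
  ΔG (`run_wt_metadynamics`, `fes_from_hills`, `basin_delta_g`).

File formats are plain text throughout: delimited tables for titrations,
melts and shift tables, PLUMED-style HILLS/COLVAR logs, gridded FES text,
and PDB (via bio3d) for conformers.

## Worked example

```r
library(stemopen)

## binding: simulate a 40 nM hairpin-probe anisotropy titration and refit
truth  <- binding_truth(kd = 23.7, probe_total = 40,
                        obs_free = 0.079, obs_bound = 0.055)
series <- gen_titration(truth, titrant_grid(23.7),
                        noise_spec(sd = 0.0012, seed = 7))
fit_kd(series)
#> <binding_fit> model=depletion converged=TRUE
#>   Kd = 22.49 +/- 11.5
#>   obs_free = 0.07869, obs_bound = 0.05841, residual rms = 0.0012

## melt: derivative-based Tm from a noisy synthetic melt curve
curve <- gen_melt(melt_truth(tm = 71.5, dh_vh = 50), seq(25, 95, 1),
                  noise_spec(sd = 4, seed = 3))
derivative_tm(curve)$tm
#> [1] 70.95932

## NMR: flag the perturbed interface residues at the 1.9 reference ratio
apo  <- gen_apo_shift_table()
tabs <- gen_shift_tables(shift_perturbation_spec(), apo, noise_spec(0, 1))
states <- vapply(tabs, function(t) attr(t, "state"), "")
compute_csp(apo, tabs[[which(states == "1.9")]])
#> <csp_result> 118 residues vs state 1.9; threshold 0 ppm
#>   flagged: 84, 85, 86, 100, 101

## metadynamics: recover a constructed 9.86 kcal/mol hairpin/open gap
pot <- hairpin_landscape(delta_g_kcal = 9.86)
out <- metad_until_converged(pot, metad_params(), seed = 1,
                             chunk_steps = 1e6, max_chunks = 6)
fes <- fes_from_hills(out$hills, grid = out$grid, tail_average = 10)
basin_delta_g(fes, find_basins(fes))
#> <basin_report> delta_g (minima convention) = 9.714 kcal/mol
#>   hairpin basin: (1.03, 60.3) F = 9.714; open basin: (7.99, 5.2) F = 0.000; barrier 14.59
```

The single-replicate Kd carries a wide asymptotic error — at 5% read
noise in the depletion regime the isotherm midpoint is genuinely soft;
the calibration tests therefore judge the *median* over 100 seeded
replicates, which recovers the truth to within the experimental error
bars. The ΔG report reads: the stem-open basin (high RMSD, low
coordination number) sits 9.71 kcal/mol below the hairpin basin on the
reconstructed surface, versus the 9.86 built into the landscape.

A full end-to-end demo (all stages, manifest with seeds and file hashes)
is one call — `run_pipeline(default_config(seed = 1))` — or, from a
shell, `Rscript inst/scripts/stemopen-pipeline.R --seed 1 --out-dir run`.

## Layout

```
R/                  binding, melt, nmr_csp, structure_cv, metadynamics,
                    fes, synthetic generators, io, pipeline
src/metad.cpp       Langevin + hill-deposition core (Rcpp)
tests/testthat/     unit, property and recovery suites
vignettes/          models-and-methods vignette
scripts/            acceptance script
inst/scripts/       command-line pipeline wrapper
```
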