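---
title: "Models and methods: quantifying protein-driven RNA hairpin remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying protein-driven RNA hairpin remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemopen)
```

stemopen implements the quantitative arms of a common experimental design
in RNA–protein biophysics: a small RNA hairpin (here a 15-mer whose stem
pairs bases 1–4 with 12–15) is titrated with a nucleic-acid-binding
protein, and one asks (i) how tightly the protein binds, (ii) whether
binding remodels the hairpin, and (iii) how large the thermodynamic
preference for the remodeled state is. Each section below states the model
the package fits, its assumptions, and the numerical choices that matter.
Every synthetic-data default named here is also the condition under which
the test suite and `scripts/acceptance.R` exercise the pipeline.

## Binding: single-site isotherm with ligand depletion

Fluorescence anisotropy and FRET titrations hold a labeled probe at a
fixed total concentration $L$ (40 nM by default) and vary the protein
total $P$. Because $L$ is comparable to the dissociation constant
($K_d \sim 20$ nM for the hairpin probe), the free-ligand approximation
fails and the bound probe fraction must come from the exact 1:1 mass
balance,

$$
f_b \;=\; \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}}{2L},
$$

implemented in `fraction_bound()` in the multiply-conjugate form
$f_b = 2P / \bigl(P + L + K_d + \sqrt{(P+L+K_d)^2 - 4PL}\bigr)$, which
avoids catastrophic cancellation at $P \gg L$ and passes continuously into
the hyperbolic limit $P/(P + K_d)$ as $L \to 0$. The observable is a
population-weighted linear mix of the free and bound endpoint signals;
quantum-yield reweighting of anisotropy is deliberately ignored because
the fitted quantity of interest — the midpoint — is carried by the
endpoints, and the direction of the signal change (anisotropy falls when
the hairpin opens and the label gains local mobility; FRET intensity rises
when the ends separate) is set purely by the endpoint values.

`fit_kd()` runs Levenberg–Marquardt least squares over
$(K_d, \text{obs}_\text{free}, \text{obs}_\text{bound})$ with a
deterministic initialization: endpoints from the first and last points,
$K_d$ from the concentration nearest half signal change, with a fallback
start at the geometric mean of the grid. Standard errors are asymptotic by
default (a residual bootstrap is behind `n_boot`), matching common
practice for such fits. A Hill-form alternative is provided because
plate-reader software often reports logistic fits; the depletion form is
the default since the probe concentration is not negligible. Degenerate
series (flat signal, $K_d$ on the positivity bound) are flagged, never
silently returned.

```{r binding-example}
truth <- binding_truth(kd = 23.7, probe_total = 40,
                       obs_free = 0.079, obs_bound = 0.055)
series <- gen_titration(truth, titrant_grid(23.7),
                        noise_spec(sd = 0.0012, seed = 7))
fit_kd(series)
```

The generator defaults encode the study conditions: probe 40 nM; a
decreasing anisotropy titration starting at 0.079 for the folded hairpin
probe (bound endpoint 0.055, a plausible remodeled-probe value); an
increasing one (0.05 to 0.15) for duplex DNA, where complex mass dominates
the signal; and FRET intensity rising from 1.0 to 3.0 on opening. The
instrument noise level is not a published quantity, so it is a free
`noise_spec()` argument everywhere; recovery tests use 5% of the dynamic
range, a typical plate-reader figure.

## Thermal melts: two-state van't Hoff with baselines and quenching

Melt curves follow a two-state model with linear folded/unfolded
baselines and an optional linear thermal-quench factor for the dye:

$$
S(T) = \bigl[(1 - a f_u)\,B_f(T) + a f_u\,B_u(T)\bigr]
       \bigl(1 - q\,(T - T_\min)\bigr),
\qquad
f_u(T) = \frac{1}{1 + e^{(\Delta H/R)(1/T - 1/T_m)}}
$$

with temperatures in kelvin internally and Celsius at every interface.
The amplitude scale $a$ models the pre-melting loss of folded probe at a
given protein dose: a probe already remodeled by bound protein
contributes no transition, so $a = 1 - f_b(\text{dose})$, which
`amplitude_vs_dose()` inverts into a cross-check between the melt and
binding modules. At saturating dose the model reduces to baselines times
quench — a monotonically decreasing trace with no transition, which the
derivative analysis must report as "no transition" rather than a spurious
$T_m$.

$T_m$ is reported primarily from the extremum of the first derivative
(mirroring how such data are usually displayed), computed after
Savitzky–Golay smoothing with a moving quadratic over an odd window
(default 5 points; differentiating noisy data needs regularization). The
extremum is refined sub-grid by a parabolic vertex through the three
points around the peak. A peak is only accepted if it is interior and
prominent (peak at least 25% above the interior-edge derivative
magnitude); this is what rejects quench-dominated monotone scans. The
van't Hoff fit (`fit_melt()`) is the secondary estimate; on noiseless
curves the two agree within a grid step. Defaults for synthetic melts:
$T_m = 71.5$ °C, $\Delta H = 50$ kcal/mol (a plausible van't Hoff
enthalpy for a 4-bp-stem hairpin; the study quantity is $T_m$, not
$\Delta H$), baselines $100 + 0.1T$ and $300 + 0.2T$, scanned 25–95 °C at
1 °C steps to mimic a 1 °C/min ramp.

## NMR: chemical-shift perturbations

Amide CSPs between two titration states are the dispersion-weighted
two-dimensional shift change

$$
\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + \Delta\delta_N^2 / 36},
$$

the factor 36 compensating the roughly six-fold wider ^15^N dispersion.
The reference state is a configurable titrant ratio (default 1.9, the
ratio at which such comparisons are typically made mid-titration).
Residues missing from either table propagate as missing — zero-imputation
would fake "unperturbed". Flagging uses the standard corrected-threshold
rule: mean + $n_\sigma$·SD over all CSPs (default $n_\sigma = 1$), with
one outlier-rejection pass so a handful of genuinely shifted residues do
not inflate the background estimate. The generator produces
fast-exchange population-averaged tables, $\delta = (1 - f_b)\delta_{apo}
+ f_b \delta_{bound}$, with $f_b$ from the same depletion mass balance at
each ratio's RNA concentration (protein 68 µM; the NMR-regime $K_d$ is
not a published quantity and defaults to 1 µM, a weak-µM regime typical
for a truncated construct at high concentration). Fast exchange is the
appropriate regime for shifts that track continuously across a titration;
a slow-exchange mode is out of scope.

```{r csp-example}
apo <- gen_apo_shift_table()
tables <- gen_shift_tables(shift_perturbation_spec(), apo, noise_spec(0, 1))
states <- vapply(tables, function(t) attr(t, "state"), "")
compute_csp(apo, tables[[which(states == "1.9")]])
```

## Structural observables

Two collective variables characterize the hairpin-to-open transition:

* **Backbone RMSD** from a reference conformer after optimal rigid
  superposition (`kabsch_rmsd()`; SVD with the proper-rotation
  correction, atoms matched one-to-one by residue and name; default
  selection P, O5', C5', C4', C3', O3').
* **Stem coordination number** between bases 1–4 and 12–15
  (`coordination_number()`): the sum over cross-group atom pairs of the
  rational switching function $s(r) = \bigl[1 - x^6\bigr]/\bigl[1 -
  x^{12}\bigr]$, $x = (r - d_0)/r_0$, with $r_0 = 3.0$ Å. $d_0$ defaults
  to 0 Å, the conventional choice when only $r_0$ is specified. For the
  6/12 exponents the implementation uses the exact simplification
  $1/(1 + x^6)$, which also removes the $x = 1$ singularity analytically.
  The atom selection within each residue group (all atoms vs
  base-centroid-only) is configurable because conventions vary.

Per-pair interstrand distances (`base_pair_distances()`) are measured
between per-residue base-centroid pseudo-atoms, a deliberately
atom-model-agnostic choice.

The conformer generator builds parametric, deterministic geometries — a
closed hairpin with paired base centroids exactly 3 Å apart and an open
state with the distal arm extended far from the stem — not force-field
structures. The collective-variable operators only need controllable
contact/separation structure, and a parametric build keeps every test
exact and seedless. Consequences: the geometries are not A-form RNA, and
nothing here reflects sequence-dependent thermodynamics.

## Well-tempered metadynamics on a toy landscape

The biasing protocol is standard well-tempered metadynamics: Gaussian
hills of initial height $w_0 = 1$ kJ/mol deposited every 0.2 ps
(100 sampler steps at the 2 fs-equivalent bookkeeping timestep), widths
0.5 Å on the RMSD axis and 10 on the dimensionless coordination number,
bias factor $\gamma = 15$ at 300 K, with heights tempered as

$$
w = w_0\, e^{-V(s)/k_B(\gamma - 1)T}.
$$

The microscopic sampler is overdamped Langevin dynamics directly on the
two collective variables over analytic toy potentials. All-atom dynamics
is out of scope here; the biasing mathematics — deposition, tempering,
reconstruction — is independent of the microscopic engine, and a 2D
sampler makes convergence achievable in seconds. Anisotropic hills are
treated as separable (no cross term). Per-step bias forces are
interpolated from a gradient grid updated at each deposition, but each
deposited height is computed from the *exact* sum over all previous
hills, so the HILLS log is exactly replayable: re-evaluating the logged
bias reproduces every height to floating-point accuracy. A per-step
drift cap (ten thermal step lengths) keeps the explicit update stable
against the stiff quartic confining walls; it is inactive in the
landscape interior. Trajectories that leave the domain box by more than
ten hill widths abort with a diagnostic.

The default two-basin landscape places a hairpin well at (RMSD 1.0 Å,
CN 60) and a stem-open well at (8.0 Å, 5), Gaussian well widths (1.0 Å,
15) — chosen once so that both basins are resolvable by the prescribed
hill widths — with a configurable depth difference (default 9.86
kcal/mol, open below hairpin) and quartic walls outside the box
$[-2, 12] \times [-40, 110]$. Mobilities (0.002, 0.8) in CV units$^2$
per kJ/mol per step give thermal step sizes of about 0.1 Å and 2 CN
units.

## Free-energy surfaces and basins

The FES is the well-tempered estimator
$F(s) = -\tfrac{\gamma}{\gamma-1} V(s)$, converted to kcal/mol
(1 kcal = 4.184 kJ) and min-shifted to zero. `sum_hills()` evaluates the
accumulated bias on a grid (default 200×200 over the hill centers padded
by five widths; a grid coarser than half a hill width records a
resolution warning). `fes_from_hills(tail_average = M)` averages the
estimator over $M$ checkpoints spread across the last half of the
deposition history — the standard fluctuation-damping practice,
implemented as a single weighted grid sum.

Basins are local minima under 8-neighbor comparison; every node is
assigned to a minimum by steepest descent, and basin pairs whose
separating saddle rises less than `min_barrier` (default 1 kcal/mol)
above the shallower minimum are merged into the deeper one. All ties
break to the lowest node index, making the analysis fully deterministic.
The reported gap is the difference of basin minima — the number one reads
off a 2D map — with a Boltzmann-integrated alternative
(`convention = "integral"`) computed alongside, since either convention
is defensible for a single scalar summary; both appear in the
`basin_report`. The hairpin/open identification takes the two *deepest*
basins and labels them by RMSD. Two numerical points matter at long run
times: bias accumulates on the soft-wall shelves outside the domain box,
so basin analysis is restricted to the box (the `grid` returned by
`metad_until_converged()`); and convergence is declared when the gap
computed from the half-history agrees with the full history within
`tol_kcal` (default 0.3 kcal/mol).

```{r metad-example, eval = FALSE}
pot <- hairpin_landscape(delta_g_kcal = 9.86)
out <- metad_until_converged(pot, metad_params(), seed = 1,
                             chunk_steps = 1e6, max_chunks = 6)
fes <- fes_from_hills(out$hills, grid = out$grid, tail_average = 10)
basin_delta_g(fes, find_basins(fes))
```

## Problem sizes, determinism, and what the tests do not show

Recovery checks run at desk scale, chosen to hold the statistical error
of each estimate well inside the tolerance it is tested against: 100
replicate titrations or melts per condition, and metadynamics runs of
1–6 million sampler steps (10,000–60,000 hills; the two-basin gap
stabilizes after about two million steps under the default landscape).
The harmonic-well validation, which compares the reconstructed surface
against ½ks² pointwise, uses gentler hills (w0 = 0.1 kJ/mol, pace 200,
γ = 6) and averages three independent replicas, because pointwise
agreement at a third of thermal energy demands lower deposition ripple
than a basin-gap readout does.

Every stochastic element — generator noise, the Langevin sampler, the
bootstrap — flows from explicit integer seeds, and identical seeds give
bit-identical outputs (the sampler consumes R's RNG stream, so chunked
runs continue a single stream).

The synthetic generators encode exactly the statistical structure the
estimators assume: Gaussian i.i.d. read noise (nothing in the data
motivates a heavier-tailed model), strictly two-state melting, strictly
fast-exchange averaging, strictly 1:1 binding. Passing recovery tests
therefore demonstrates the correctness and calibration of the estimators
under their own assumptions — not that real titrations are free of
pipetting drift, that real melts lack intermediate states, nor that a
real free-energy landscape has only two basins. The toy landscape mirrors
the topology of a hairpin-opening surface, not its microscopic origin:
recovering its constructed gap validates the deposition/reconstruction
machinery, and says nothing about force-field accuracy.

## Known limitations

* Anisotropy additivity ignores quantum-yield differences between free
  and bound probe; strongly yield-shifted systems would need the
  intensity-weighted form.
* No $\Delta C_p$ term and no multi-transition deconvolution in melts.
* CSP module does no peak tracking/assignment transfer and no
  per-residue $K_d$ fitting; it consumes assigned shift tables.
* The metadynamics engine is 2D-CV-space only — by design, not a
  limitation of the biasing code, but it cannot expose CV-quality
  problems (hidden slow degrees of freedom) that all-atom work must
  confront.
* Basin gaps from minima differences carry grid-interpolation error of
  order the node spacing times the local gradient; the 200×200 default
  keeps this far below the reported tolerances.
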