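# dimerlab

Quantitative characterization of small intertwined protein homodimers, built
around the solution-NMR study of the lambda bacteriophage lytic developmental
protein Orf63 — a 63-residue protein that folds as an obligate dimer of two
α-helices and one β-strand per protomer, all making extensive intermolecular
contacts. The package reimplements, as tested reusable R code, the complete
desk analysis such a study needs:

* **Surface and interface** — deterministic Shrake–Rupley solvent-accessible
  surface areas (golden-spiral sampling, Chothia-style heavy-atom radii),
  PISA-style decomposition of the dimer interface into per-residue buried
  areas (ΔASA), salt-bridge detection with relative side-chain accessibility,
  and backbone hydrogen-bond detection.
* **Ensemble geometry** — Kabsch superposition, NMR-ensemble precision as
  average RMSD to the iteratively refined mean structure, dihedral-window
  secondary-structure assignment, helix-axis fitting (bisector construction)
  and inter-helix angles.
* **CSP mapping** — weighted amide chemical-shift perturbations between free
  and ligand-bound states, `d = sqrt(0.5 * (ΔδH² + (0.14·ΔδN)²))`, with a
  significance threshold (default 0.05 ppm), titration saturation checks, and
  export of CSPs into PDB B-factors for structure colouring.
* **Binding and stability fits** — 1:1 fluorescence-polarization binding
  isotherms (protomer-denominated, hyperbolic or exact tracer-depletion),
  two-state thermal melts (van't Hoff) and chemical denaturation
  (linear extrapolation, `Cm = ΔG0/m`), all with asymptotic uncertainties.
* **Conservation profiling** — per-column class fractions (nonpolar / acidic
  / basic), information content and strict `> 80%` conservation flags over a
  homolog alignment, with majority-rule consensus.
* **Synthetic data with ground truth** — seeded generators for every input
  the pipeline consumes (a C2-symmetric toy dimer with an inter-chain
  β-seam, Gaussian-scatter ensembles, shift tables with a planted binding
  site, FP titrations, melts, alignments), so every stage is testable with
  no downloads.

A `run_pipeline()` orchestrator (plus the thin CLI wrapper in
`inst/scripts/dimerlab.R`) runs any subset of stages from one declarative
config and writes a JSON + text report.

## Worked example

```r
library(dimerlab)

toy <- make_toy_dimer()               # deterministic C2 homodimer + ground truth
toy$structure
#> <structure3d 'toy_dimer': 1 model(s), 2 chain(s), 360 atoms>

interface_analysis(toy$structure, 1, "A", "B")
#> <interface_report: 8/8 interface residues, buried 179/179 A^2, complex-wide 358 A^2>
```

The two protomers bury 179 Å² each — identical within sampling error, as the
exact C2 symmetry of the construction demands — across 8 interface residues
per chain (ΔASA > 0.1 Å²).

```r
ens <- perturb_ensemble(toy$structure, 0.45, 0.75, 20, seed = 2)
ensemble_rmsd(ens$structure, selection(atom_class = "backbone"))$mean_rmsd
#> [1] 0.7624  # closed-form expectation: sigma*sqrt(3)*sqrt(19/20) = 0.760

fp  <- simulate_fp_titration(kd = 3.1, seed = 1)   # 10 nM tracer, 2% noise
fit <- fit_fp_binding(fp$conc, fp$polarization)
fit
#> <binding_fit (hyperbolic): Kd = 2.95 +/- 0.28 uM, P 48.6 -> 150.3 mP>
confint(fit)
#> lower upper
#>  2.30  3.78
```

A single noisy titration generated at Kd = 3.1 µM fits back to
2.95 ± 0.28 µM with a 95% interval covering the truth; the Monte-Carlo suite
in the tests shows the estimator is unbiased to a few percent. Denaturation
fits behave the same way:

```r
m <- simulate_melt(tm = 75, dh = 300, noise_sd = 0.3, seed = 1)
fit_two_state_thermal(m$temperature, m$signal)
#> <two_state_fit (thermal): Tm = 75.06 +/- 0.12 C, dH = 299 kJ/mol>

u <- simulate_urea(dg0 = 25, m = 10, noise_sd = 0.15, seed = 1)
fit_two_state_chemical(u$denaturant, u$signal)
#> <two_state_fit (chemical): Cm = 2.503 +/- 0.011 M, dG0 = 25.6 kJ/mol, m = 10.24 kJ/mol/M>
```

To run the whole pipeline on a generated input bundle:

```r
write_synthetic_bundle("demo", seed = 3)
# then configure paths in a list or YAML file and
# run_pipeline(config)  — see ?run_pipeline and ?validate_run_config
```

Analyses of the deposited Orf63 ensemble (PDB 8DSB: ordered-region protomer
ASA near 4109 Å², ~1215 Å² buried over 27 interface residues, 0.8 / 1.1 Å
backbone / heavy-atom ensemble precision, the ~16° inter-helix angle, the
E36–K47 inter-chain salt bridge at ~77% side-chain accessibility) run through
the same functions once the entry is cached with `fetch_pdb("8DSB")`; the
corresponding tests skip, rather than fail, when no cached copy exists.

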