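---
title: "Methods: surface, geometry, CSP, fits and conservation in dimerlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface, geometry, CSP, fits and conservation in dimerlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

dimerlab characterizes small intertwined homodimers of the kind exemplified
by the phage lambda Orf63 lytic developmental protein: a 63-residue chain
whose first 11 and last 9 residues are disordered, leaving a 43-residue
folded protomer (native 12–54) of two α-helices and one β-strand that
dimerizes through an antiparallel inter-chain β-sheet. This vignette records
the models each stage implements, the defaults and why they were chosen, and
what the synthetic data do and do not establish.

## Structures, numbering and selections

Coordinates are held as one atom table plus a `[atoms × 3 × models]` array;
all models of an ensemble must share a topology, which is checked on read
(for PDB input the per-MODEL atom counts are compared up front so the error
can name the offending model). Parsing and writing go through bio3d;
alternate locations are resolved to the highest-occupancy conformer, ties to
the first encountered, which keeps reads deterministic. Hydrogens are kept on
read — NMR depositions include them — but are excluded from surface areas and
heavy-atom statistics.

Deposited construct numbering rarely matches native numbering: the study
construct carries an N-terminal 6xHis-Flag tag that shifts every residue by
+14 (native E36 is E50 in the file). All user-facing residue ranges are
native and pass through a `numbering_map(offset)`; the offset default is 14
to match that construct, and 0 wherever synthetic data (numbered natively)
are in play. `ordered_region()` encodes the native 12–54 default.

## Solvent accessibility and the interface

`compute_sasa()` is a Shrake–Rupley implementation: each heavy atom is
covered with `n_points` samples on a golden-section spiral at radius
`r + probe`; the accessible area is the exposed fraction times
`4π(r+probe)²`. The spiral is deterministic, so areas are exactly
reproducible and a lone atom recovers the analytic sphere area exactly.
Defaults: probe 1.4 Å (water), `n_points = 960`, Chothia-style radii
(carbonyl/carboxylate C 1.76 Å, other C 1.87 Å, N 1.65 Å, O 1.40 Å,
S 1.85 Å), matching the heavy-atom conventions of PISA-class tools without
promising parity with any one radii set. Two numerical facts matter when
interpreting areas: per-atom areas are quantized in units of
`4π(r+probe)²/n_points` (~0.13 Å² at the default), and the orientation of the
spiral makes totals very weakly orientation-dependent — the test suite runs
its rigid-motion-invariance check at `n_points = 3000`, the density at which
that discretisation falls below 0.1% of the total.

`interface_analysis()` computes per-residue buried area as
`ΔASA = SASA(chain set alone) − SASA(complex)`, clamped at zero, and flags
interface residues at `ΔASA > 0.1 Å²`; the cutoff exists purely to suppress
sampling quantization and is configurable. Buried totals are sums over each
chain set. The engine is cross-checked in the tests against a deliberately
plain brute-force reimplementation at `n_points = 10000`.

Relative side-chain accessibility divides a residue's side-chain SASA in the
full assembly by its side-chain SASA in a Gly-X-Gly reference tripeptide
*carved from the structure*: the residue in its observed conformation plus
the backbone atoms of its two sequence neighbours (glycine equivalents). The
conventional alternative — a stored table from ideal extended tripeptides —
requires an all-residue side-chain template library and mixes geometry
conventions; the carved reference uses the same engine and radii as the
numerator, makes an isolated residue exactly 100% accessible by
construction, and is deterministic. The price is mild conformation
dependence of the reference; for the exposure classification this module
feeds (e.g., whether an ionic pair is mostly solvent-exposed), that is well
inside the ±10-percentage-point band such statements carry. Whether a
published "ASA of a residue" is side-chain or whole-residue relative
accessibility is often unstated; side-chain is this package's default
reading.

Salt bridges are Asp/Glu carboxylate-O to Lys/Arg side-chain-N pairs within
4.0 Å (His excluded by default, configurable), annotated with the acidic
residue's relative accessibility. Backbone hydrogen bonds use N···O ≤ 3.5 Å,
plus H···O ≤ 2.5 Å and N–H···O ≥ 120° when the amide proton is present;
sequence neighbours (|i−j| ≤ 1) are excluded as trivial.

## Ensemble precision and fold geometry

`kabsch_superpose()` is the standard SVD solution with the determinant
correction to a proper rotation; degenerate (collinear or fewer than three
point) inputs are refused. Ensemble precision follows the reporting style of
NMR structure statistics: all models are superposed on the ensemble mean,
the mean is recomputed, and after two such rounds (which change the result
by far less than the quantities reported) the average RMSD-to-mean over the
selected atoms is returned. For isotropic Gaussian scatter of standard
deviation σ per coordinate over m models the expectation is
`σ·√3·√((m−1)/m)`, which the generator records and the tests verify. Whether
a published ensemble statistic used one or both chains is often ambiguous;
the default here selects both chains, and the selection argument makes
either choice explicit.

Secondary structure uses dihedral windows rather than a DSSP port: helix at
φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°] over ≥ 4 consecutive residues; strand at
φ ∈ [−180°, −40°], ψ ∈ [50°, 180°] (or below −170°, the periodic wrap) over
≥ 2 residues *supported by an inter-strand backbone hydrogen bond* (sequence
separation ≥ 3 or inter-chain). The H-bond requirement is what keeps an
isolated extended loop from being called a strand. For the two-helix /
one-strand topologies this package targets, the windowed scheme recovers
constructed boundaries exactly; on highly irregular folds a full DSSP would
be more faithful, and that is a stated limitation, not a goal.

Helix axes use the bisector construction: for consecutive Cα triplets the
vector `p(i) − 2p(i+1) + p(i+2)` points radially at the helix axis, so cross
products of successive bisectors are axial — exactly so on ideal geometry,
where a principal-component fit of the raw Cα cloud is biased by partial
turns (degree-scale errors on a 12-residue helix). Near-straight traces,
where the bisectors vanish, fall back to the principal component. Axes are
oriented N→C and the inter-helix angle is the arccos of their dot product,
so antiparallel pairs report near 180°; published inter-helix angles are
usually quoted unsigned, and comparisons should fold the angle accordingly.
Since published helix boundaries are rarely printed, angle computations here
take boundaries from this package's own assignment — a convention choice
that motivates the ±5° band used when comparing to reported angles.

## Chemical-shift perturbations

The weighted amide CSP is
`d = sqrt(0.5·(ΔδH² + (w·ΔδN)²))` with `w = 0.14`, the dimensionally
consistent convention in which the nitrogen weight scales the shift before
squaring. Published equations are sometimes typeset with the weight outside
the square (`0.5·(ΔδH² + w·ΔδN²)`); because the two readings can flip a
significance call (at ΔδN = 0.5 ppm they give 0.0495 vs 0.1323 ppm against
the 0.05 threshold), both are implemented, the conventional form is the
default, and the variant is a config switch rather than a silent choice.
Residues present in only one state — prolines, or bound-state peaks
broadened away in slow exchange — are reported as unmatched, never dropped:
a disappearing peak localizes binding as surely as a moving one.
Exchange-regime labels are input annotations; inferring them from spectra is
out of scope. Saturation of a titration is declared when the maximum
per-residue `d` between consecutive points drops below 0.01 ppm (default),
the quantitative form of "no further spectral change between ratios".

## Binding and denaturation fits

The FP isotherm is fit with protomer-denominated concentrations — the 2:1
peptide-per-dimer stoichiometry with independent sites collapses exactly to
a 1:1 per-protomer model. The default hyperbola ignores tracer depletion; at
10 nM tracer and micromolar Kd the exact quadratic-depletion model agrees to
well under 0.5%, and both are available. Kd is fitted as log Kd so the
optimizer cannot cross zero; standard errors are asymptotic (delta method
back to the linear scale) and `confint()` builds a t-based interval on the
log scale, which the Monte-Carlo tests show is calibrated (≥ 90% coverage at
95% nominal in the tested regime).

Denaturation uses the minimal two-state models with linear baselines:
thermal `f(T) = 1/(1+exp(ΔH/R·(1/T − 1/Tm)))` with T in Kelvin and ΔCp fixed
at zero (not estimable from a single melt), chemical
`ΔG(u) = ΔG0 − m·u`, `Cm = ΔG0/m` at 25 °C. Start values come from the
steepest slope of a lowess-smoothed trace and end-segment baseline fits. A
"no transition detected" error — rather than a number — is returned when the
optimizer fails, the midpoint leaves the data range, the fitted amplitude at
the midpoint is within 4 residual SDs of zero, or the fitted ΔH or m-value
is non-positive; this is the correct behaviour for the melt of an
already-unfolded variant, and the synthetic `folded = FALSE` traces exercise
it. Because the study's raw curves are not deposited, the reported Kd
(3.1 ± 0.3 µM), Tm (75 °C) and urea midpoint (~2.5 M) are covered by
parameter recovery at those generating values, not by refitting.

## Conservation

Column statistics count gaps in the denominator of residue and class
fractions, so heavily gapped columns cannot be called conserved; information
content is `log2(20) − H` of the gap-renormalized distribution (no
small-sample correction by default). Class sets are nonpolar
{A,V,L,I,M,F,W,P,G}, acidic {D,E}, basic {K,R}; His is excluded from the
basic set because consensus-plot colourings rarely list membership and His
charge is pH-dependent — the sets are arguments precisely so this choice can
be stress-tested. Flagging uses a strict `> 0.80` on a single class fraction
over the three coloured classes; whether a published "> 80% conserved" means
per-class or per-residue identity is ambiguous, so a per-residue mode is one
argument away. Consensus is majority-rule, alphabetical tie-break, lowercase
where the gap fraction exceeds one half. Sequences are unweighted: the
homolog sets this targets come from identity-clustered databases, and
Henikoff-style weighting is out of scope.

## What the synthetic data emulate — and what they do not

The toy dimer is an exact C2 homodimer: one 36-residue protomer (helices
3–14 and 17–28, strand 31–34, short loops) built from ideal internal
coordinates (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, helix φ/ψ −57°/−47°,
strand −120°/130°), positioned so the two strands pair across the two-fold
axis with inter-chain backbone hydrogen bonds. The contact distance (default
5.25 Å between strand centres, registry shift −2.6 Å) was chosen once, when
the generator was designed, as the clash-free placement producing that seam;
at 100 Å the protomers are isolated and every interface quantity goes to
zero. Residues are alanine (backbone + CB), so side-chain packing,
rotamers, and sequence-specific surface chemistry are *not* emulated —
passing interface tests demonstrate the correctness of the area bookkeeping
and symmetry, not PISA parity on real chemistry. Ensemble scatter is
i.i.d. Gaussian per atom with separate backbone/side-chain σ (defaults
0.45 / 0.75 Å, chosen so the expected spreads sit in the sub-angstrom range
typical of well-determined small-protein ensembles); real ensembles have
correlated, loop-concentrated disorder, so the closed-form recovery shows
the statistic is computed correctly, not that real ensembles behave this
way. Shift tables plant a 0.2 ppm (both dimensions) perturbation on native
45–54, mirroring a C-terminal-helix binding site; FP curves use 8 points,
0.25–50 µM, Gaussian noise at 2% of the dynamic range; melts span 25–95 °C
at 1 °C with ΔH = 300 kJ/mol; urea curves span 0–6 M at 0.25 M. Alignments
keep the reference residue with a per-column probability and draw
alternatives from outside the reference's class; at 200 sequences a
0.85-conserved column exceeds a strict 0.80 threshold with high but not
unit probability — binomial sampling at this depth leaves a few-percent
failure rate per column, which is why exact-recovery checks fix their seed
and the acceptance script reports the recovered fraction as a number.

All generators take an explicit seed, use a private RNG stream (the caller's
`.Random.seed` is restored), and emit a machine-readable ground-truth record
that downstream tests consume instead of hard-coded numbers.

## Problem sizes and runtime choices

Test and acceptance computations are sized to run comfortably on one CPU:
the 360-atom-per-chain toy dimer for surface work (with the brute-force
cross-check at `n_points = 10000` as the one deliberately heavy
computation), 20-model ensembles, 100-curve Monte-Carlo suites for Kd and
25-curve suites for Tm/Cm, and 200-sequence alignments. Analyses of the
deposited 20-model ensemble use the same code paths and run in seconds; the
corresponding checks activate only when a cached copy of the entry is
present (`fetch_pdb("8DSB")`), since its coordinates cannot be redistributed
inside the package.

## Known limitations

No ΔG of dissociation or interface p-values (beyond-scope PISA features); no
DSSP-faithful secondary structure on irregular folds; exchange-regime
classification is not inferred from spectra; ΔCp is fixed at zero in thermal
fits; sequence weighting and logo rendering are out of scope for
conservation; the report schema checker validates required blocks and types
with package code rather than a full JSON-Schema engine.
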