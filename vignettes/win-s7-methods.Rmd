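---
title: "Methods: quantifying the WIN-S7 rotamer switch and ITC binding thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the WIN-S7 rotamer switch and ITC binding thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wins7)
```

## The scientific problem

WDR5 is a WD40 beta-propeller scaffold whose central channel (the WIN
site) binds short "WIN motif" peptides through a conserved arginine at
motif position 0. Adjacent to the channel lies a cryptic hydrophobic
subsite — the S7 pocket, walled by Phe133, Phe149, Pro173 and Tyr191 —
that opens or closes depending on the rotamer adopted by the Tyr191 side
chain. The residue at motif position +4 (a serine in the kinesin-13
WIN motif studied here) hydrogen-bonds to the Tyr191 hydroxyl and the
Lys259 backbone carbonyl, rotating the ring and opening the pocket;
removing that contact (position +4 truncation, Ser-to-Gly substitution,
or a Tyr-to-Phe protein variant) closes it. Because dual-site WIN+S7
inhibitors gain orders of magnitude in affinity over WIN-only fragments,
the openness of S7 and the size of the Tyr191 rotation are the central
comparative observables across the family of deposited complexes.

This package turns those observables into reproducible computations:
a rigid-body frame (Kabsch superposition of propeller C-alphas), a
ring-rotation metric, a typed interaction fingerprint of the
peptide-protein interface including its ordered-water network, a
grid-based pocket openness classifier, and a single-site ITC model with
thermodynamic decomposition. A synthetic-fixture module generates every
input needed to exercise and validate the full surface without any
deposited coordinate file; deposited entries, when the user supplies
local copies, flow through exactly the same functions.

## The coordinate model

`read_structure()` consumes local PDB or mmCIF files (parsing is
delegated to bio3d) into a flat atom table grouped by model, chain and
author residue number. Author numbering is the canonical addressing
scheme because the literature on this system quotes author numbers
(propeller 24-334, peptide 114-122); waters are first-class residues —
the interface water census depends on them — and alternate locations are
retained on read, with `resolve_altlocs()` applying the
highest-occupancy policy (ties broken A before B) before geometry is
measured. All geometric criteria are defined on heavy atoms only: the
target crystal structures (1.6-1.9 Å) carry no hydrogens. Coordinates
are Ångström throughout; no unit conversion happens anywhere.

PDB writing preserves three decimals (the fixed-width format limit) and
refuses models beyond 99999 atoms rather than emitting corrupt serials;
mmCIF writing (a minimal `atom_site` loop, written by this package)
carries six decimals and has no size limit.

## The superposition frame

All rotamer comparisons are made in the *propeller frame*:
`superpose_ca()` pairs residues between two chains (by author number, or
by global sequence alignment with identity scoring and affine gaps when
numbering schemes differ), restricts to the author window 31-334, and
runs an unweighted Kabsch superposition (SVD of the covariance matrix
with the determinant sign correction, so the rotation is always proper).
No B-factor weighting is applied — no weighting scheme is defined for
the comparisons this package makes, and the pairs being compared are
near-identical propellers where weighting would change nothing
measurable.

When a crystal form contains two copies of the complex per asymmetric
unit, both copy pairings are legitimate analysis subjects; the
convention here is to report every pair and let headline numbers use the
pair with the smallest RMSD.

## The ring-rotation metric

The published rotation values for Tyr191 are printed without a stated
measurement convention, so the package defines one and uses it
uniformly: **the angle between the least-squares ring-plane normals of
the two side chains after mapping the second structure into the first's
propeller frame, folded into [0, 90]°.** This definition was chosen over
a pure chi-angle difference because

* it is well-defined for Tyr-vs-Phe comparisons (the Y191F variant has
  no hydroxyl; only the six ring carbons enter),
* it is invariant to the CD1/CD2-CE1/CE2 label ambiguity of a 2-fold
  symmetric ring, and
* it covers the full printed range of the family (9° to 88.2°) without
  wrap-around artefacts.

Chi-angle deltas (`delta_chi1` in (-180, 180], `delta_chi2` folded to
[0, 90] under ring symmetry) are reported alongside as secondary
metrics. On synthetic tyrosine pairs built with a known ring rotation
about the CB-CG axis (an in-ring-plane axis, so the construction angle
equals the normal-normal angle exactly), the metric recovers the
construction angle to numerical precision; the acceptance suite requires
0.5° at 5°-85°. For comparisons against printed values a tolerance of
±5° is appropriate: the original numbers are prefixed "approximately"
and their measurement convention is unknown.

## The interaction fingerprint

`fingerprint()` unions five typed detectors, all heavy-atom based, all
with criteria exposed in `interaction_criteria()`:

| kind | rule | default |
|------|------|---------|
| hydrogen bond | donor-acceptor distance; antecedent-donor-acceptor angle where the antecedent is modelled | ≤ 3.5 Å, ≥ 90° |
| salt bridge | Arg/Lys/His side-chain N to Asp/Glu carboxylate O (or OXT) | ≤ 4.0 Å |
| cation-pi | cation centre (Arg CZ, Lys NZ) to aromatic ring centroid, elevated above the plane | ≤ 6.0 Å, ≥ 45° |
| van der Waals | C/S pairs in a distance window, one record per residue pair (minimum distance kept) | 3.0-4.0 Å |
| water bridge | ordered water in the site sphere with ≥ 2 polar contacts, ≥ 1 to the interface | ≤ 3.5 Å contacts, 8.0 Å site radius |

The donor/acceptor chemistry table covers the twenty standard residues
(backbone N as donor except proline, backbone O/OXT as acceptors, the
usual side-chain assignments) and water oxygen as donor+acceptor with no
antecedent — the angle rule is skipped exactly where no antecedent
exists, which prunes impossible geometries without requiring hydrogen
placement.

Two design choices in the water census deserve emphasis. *Site
membership, not strict A-to-B bridging, qualifies a water*: the
interface water networks described for this system include waters that
knit the peptide to itself and waters that contact aromatic rings, so
requiring every water to touch both sides would systematically
undercount. The site sphere (default radius 8 Å around the midpoint of
the WIN and S7 centres) is the calibration knob and is reported with
every result. Second, a water oxygen within 3.6 Å of an aromatic ring
centroid gets a water-aromatic geometry note rather than a separate
interaction type.

Neighbour searches run through a cell-binned algorithm whose output is
property-tested against a brute-force all-pairs oracle.

## Pocket openness

The published evidence for S7 opening is rendered surfaces, not
numbers, so the package defines a deterministic volumetric proxy.
`pocket_volume()` lays a grid (default spacing 0.5 Å) over a site sphere
(S7 centre = centroid of the Phe133/Phe149 ring centroids, Pro173 CA and
residue-191 CB; default radius 8 Å on real propellers), marks a point
*free* when it lies at least one probe radius (default 1.4 Å, a
water-sized probe) from every retained protein heavy atom, and *buried*
when rays along at least 4 of the 6 axis directions pass within a probe
radius of an atom. Buried free points times the cell volume is the
pocket volume. Peptides, compounds and waters are always excluded before
scanning so that openness measures the protein pocket, not its
occupancy. The grid is anchored to the site, making the measure
invariant to rigid motion; halving the spacing moves the calibration
volumes by under 1%, far inside the 15% convergence requirement.

`classify_s7()` calls the pocket open when its volume exceeds the
midpoint of a closed/open calibration pair. The natural calibration pair
is an arginine-only (closed) and a WIN-motif-peptide-bound (open)
propeller supplied by the user as local files via `s7_calibration()`.
The *default* calibration shipped with the package is synthetic and
labelled as such: `make_pocket_gate()` builds an open-topped box cavity
whose mouth is gated by a tyrosine hinged on its CA-CB axis — ring
hanging into the cavity at 0° (closed, 227 Å³ under default
parameters), swung flat outside at 90° (open, 264 Å³) — and the
classifier thresholds at the midpoint. The gate fixture also supplies
the monotonicity property: swinging the ring out of the mouth strictly
increases the measured volume at 0/30/60/90°. A synthetic calibration
classifies synthetic structures; for verdicts on real deposited entries
the user-supplied calibration is the scientifically meaningful path, and
the report annotates which calibration produced each verdict.

The literal free-point rule (distance to atom *centres*, not
van-der-Waals surfaces) makes the hollow-shell oracle exact: a shell of
atoms at radius r + 1.4 Å has a probe-accessible interior of exactly
radius r, and the grid estimate must agree with 4/3 πr³ within 20%.

## The ITC model

The single-site forward model uses total concentrations after the
standard perfusion displacement correction for an overfilled cell
(cumulative injected volume v, cell volume V0):

* Mt = M0 (1 − v/2V0)/(1 + v/2V0), Lt = L0 (v/V0)/(1 + v/2V0)
* [ML] = ((N·Mt + Lt + K_D) − sqrt((N·Mt + Lt + K_D)² − 4·N·Mt·Lt))/2
* Q_i = ΔH · V0 · [ML]_i, and the measured injection heat
  q_i = Q_i − Q_{i−1} + (v_i/V0)(Q_i + Q_{i−1})/2.

Defaults mirror the documented experimental conditions: 0.05 mM
macromolecule in the cell, ~1 mM peptide in the syringe, an initial
1 µL priming shot (flagged for discard, as is standard) followed by
2 µL injections, 20 °C. The cell volume (200 µL) and injection count
(19 after the priming shot) are documented assumptions — typical for
the small-volume instrument class used for such titrations — since
neither is printed with the source data.

`fit_single_site()` minimises the sum of squared heat residuals over
(N, ln K_A, ΔH) by Levenberg-Marquardt, with ln K_A as the internal
parameter for conditioning. Initialisation ("midpoint" policy): N from
the molar ratio at the half-height of the cumulative heat, ΔH from the
early-injection normalised heat, and a small ladder of c-value starting
points (c = 1, 10, 100, 1000) for K_A with the best sum of squares
retained — multi-start costs microseconds here and removes any
dependence on a lucky guess. Parameter uncertainties come from the
covariance of the least-squares Jacobian. Non-convergence is flagged,
never silently returned; a converged fit is additionally flagged
unreliable when its c-value falls below 1 or its K_D exceeds the
titrated concentration range, the regimes where a single curve cannot
constrain the constant. Thermodynamic identities are applied exactly:
ΔG = RT ln K_D (R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹, standard state 1 M,
T = 293.15 K) and −TΔS = ΔG − ΔH, so ΔG = ΔH + (−TΔS) holds to
machine precision for every fit.

The published titration table ships with the package
(`wdr5_itc_table()`) as input data; `itc_consistency_check()` recomputes
−TΔS from each row's printed K_D and ΔH and reports the deviation (all
five detectable rows agree within 0.1 kcal/mol, maximum ≈ 0.04), plus
affinity fold changes of each variant against the wild type. The fold
changes printed alongside the source table do not equal the ratios of
its printed K_D values (e.g. 3.72/0.78 = 4.77, printed as "3.8-fold");
the package reports the computed ratios and leaves the discrepancy
visible rather than reconciling it.

## What the synthetic generators emulate — and what they do not

The fixture module generates: rigid (optionally noisy) copies of a
structure, the rmsd of which must follow σ√3 for isotropic per-
coordinate noise σ; tyrosine pairs with an exactly known ring rotation
on an identical scaffold; minimal interaction geometries (one per
detector, with controllable distance/angle); a hollow shell with an
analytically known interior volume; the gated-pocket cavity; and
single-site thermograms at any (N, K_D, ΔH, noise). All generators take
explicit seeds, never global RNG state, and are byte-reproducible.

These fixtures validate the *measurement machinery*, not crystallographic
reality: they have idealised bond geometry, no lattice contacts, no
anisotropy or correlated coordinate error, no partial-occupancy waters,
and cavities far simpler than a propeller surface. Green synthetic tests
therefore certify that the metrics recover known ground truth under
their own definitions; verdicts about real deposited structures
additionally depend on those structures being supplied and on the
documented criteria defaults, which are all exposed for sensitivity
checks.

## Problem sizes and numerical choices

The test and acceptance workloads use 291-atom C-alpha sets for
superposition (matching the size of a real propeller pair), 10-residue
scaffolds for rotation metrics, pocket grids of ~2000-17000 points
(radius-4 site at 0.5/0.25 Å spacing), and 50-replicate noise studies
for ITC recovery — sizes chosen so the full suite exercises every
code path in a few minutes on one core. Degenerate inputs are handled
explicitly: fewer than three or collinear superposition atoms are
errors; a negative binding-quadratic discriminant is clamped to zero
with a warning; an all-zero thermogram is a fit error; a site sphere in
bulk solvent returns zero volume with a warning. Ties in altloc
occupancy resolve alphabetically; the ring-plane normal's sign is never
used; angle folds use [0, 90] under ring symmetry.

## Limitations

* The rotation metric is defined for six-carbon aromatic rings (Tyr/Phe);
  His/Trp gates would need a different fold convention.
* The pocket proxy measures buried probe-accessible volume in a sphere;
  it is not a druggability score and does not segment subpockets (a
  large adjacent cavity and the subsite proper are measured together if
  both fall in the site sphere).
* Single-curve ITC fits only: duplicate-experiment averaging and
  competitive or multi-site models are out of scope.
* Accession fetching is deliberately out of band — the package consumes
  local files only, so all network variability stays outside the
  analysis.
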