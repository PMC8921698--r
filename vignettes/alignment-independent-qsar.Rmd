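---
title: "Alignment-independent 3D-QSAR of FLAP inhibitors: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-independent 3D-QSAR of FLAP inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flapqsar)
```

## The problem

Inhibitors of the 5-lipoxygenase-activating protein (FLAP) block leukotriene
biosynthesis at its first committed step. The chemotypes are structurally
diverse — indoles, biaryl bicycloheptanes, oxadiazoles, benzimidazoles — so
classical 3D-QSAR, which requires a common alignment, is fragile. This
package implements an *alignment-independent* workflow: docked-pose
selection by common-scaffold clustering, GRID-like molecular interaction
fields (MIFs), correlogram (GRIND-style) encoding in which variables are
products of field minima indexed only by their mutual distance, and PLS
regression with leave-one-out (LOO) validation. A parallel 2D track offers
activity curation (IC50 thresholds, lipophilic efficiency), descriptor
filtering, and recursive feature elimination with classification metrics.

Because the reference inputs (a curated ChEMBL compound set, commercial
descriptors, docking software, and proprietary field software) are not
reproducible at desk scale, every stage is validated against synthetic
worlds with planted, analytically known structure.

## Activity curation

* `pic50_from_ic50(x)` = −log10(x·1e−9), x in nM.
* `lipe(pic50, clogp)` = pIC50 − cLogP, **signed**. Values above ~5 indicate
  potency beyond what lipophilicity alone provides; the modeling filter
  keeps compounds with LipE > 1 *and* cLogP > 2 (both strict), the regime
  appropriate for a membrane-embedded target.
* Class labels: IC50 < 10 nM "active", > 70 nM "least", otherwise
  "intermediate" (dropped before classification).
* `stratified_split` uses a ceiling test size (503 compounds at 20 % gives
  exactly 101/402) with largest-remainder per-class apportionment.

## Classification metrics

Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, and Matthews
correlation coefficient with the standard product denominator. A zero
factor in the MCC denominator yields 0 with a warning — the common
convention that keeps fuzz tests total. (A printed variant of the
specificity formula with FN in the denominator is a typographical error:
that expression is not the true-negative rate.)

## Interaction fields

Four probes: DRY (hydrophobic), O (carbonyl oxygen; senses donors), N1
(amide nitrogen; senses acceptors), TIP (steric shape probe on the
solvent-accessible shell). The node energy is

E = Σ E_lj + Σ E_el + Σ E_hb

with 12-6 Lennard-Jones (Lorentz–Berthelot combination of probe and
per-element parameters; 8 Å truncation), Coulomb electrostatics with
distance-dependent dielectric ε(r) = 4r and constant 332.0 kcal·Å/(mol·e²),
and a 12-10 hydrogen-bond term (equilibrium 2.8 Å, 5 Å truncation) against
flag-complementary atoms only. Energies are clamped to [−100, +5] kcal/mol
for storage; nodes within 0.5 Å of an interacting atom cap at the ceiling.

Downstream node extraction uses the literature per-probe cutoffs −0.5
(DRY), −2.6 (O), −4.2 (N1), −0.74 (TIP) kcal/mol and the default 0.5 Å
lattice. The authentic GRID parameterization is proprietary; the
per-element table shipped here (`default_lj_table()`) is this package's
own, chosen so the fields are physically plausible and minima-bearing —
the encoding downstream needs nothing more. The hydrogen-bond well depth
is 2.5 kcal/mol, deliberately *above* the N1 cutoff of −4.2: a single
isolated acceptor does not produce a hotspot, while converging
contributions (two to three complementary atoms) do. TIP is a
surface-shell steric probe with water-like well depths; on convex toy
payloads its summed energy rarely passes −0.74, so TIP blocks are usually
empty in the synthetic world — a documented property, not a bug; TIP
masking and encoding mechanics are tested with custom parameters.

**Lattice phase.** `make_grid` snaps the lattice origin to an integer
multiple of the spacing in world coordinates. Translation of molecule and
grid by a lattice vector is then energy-preserving to double precision,
and two
molecules expressed in the same frame sample identical node positions —
the property that makes the synthetic correlogram ground truth analytic.

## Node extraction and encoding

`extract_nodes` keeps lattice nodes at or below the probe cutoff and
selects greedily by `(1−w)·|E|/max|E| + w·d_min/d_ref` (w = 0.5, d_ref =
grid diagonal), i.e. deepest-first with a spatial-coverage bonus,
deterministic with lowest-index tie-breaks. `encode` forms, for each of
the ten probe-pair blocks and each 0.4 Å distance bin, the *maximum
product* of node energies over qualifying pairs (MACC2-style), with the
argmax pair kept as provenance for hotspot back-mapping. Distances only —
the encoding is exactly invariant under rigid motion.

The proprietary CLACC encoding ("consistent" node selection across
compounds) is approximated by fixed binning + deterministic extraction,
plus `trim_correlogram`: variables nonzero in fewer than 10 % of compounds
— or varying by less than 5 % of their magnitude — are dropped before
modeling. A bin populated in one compound cannot express a trend, but
after autoscaling it acts as a per-compound dummy and destabilizes
cross-validation; the relative-range rule removes bins whose variation is
numerical jitter from distant atoms.

## Pose clustering

Scaffold RMSD is computed **without superposition**: docked poses share
the receptor frame, and superposition would erase exactly the binding-mode
differences of interest. Agglomerative clustering (complete linkage by
default; the source method is unstated, and complete linkage gives the
most conservative cluster diameters at the 3.5 Å cutoff) is cut at the
RMSD cutoff; the representative cluster is the one covering the most
distinct ligands (ties: more poses, then lowest label), and each covered
ligand contributes its best-scoring pose.

## PLS, validation, and variable selection

`fit_pls` is NIPALS with autoscaled X (zero-variance columns get exactly
zero coefficient) and centered y; at full rank it reproduces least squares
(tested against the normal-equations oracle). `loo_q2` re-centers and
re-scales inside every fold; q² = 1 − PRESS/TSS with TSS about the full
mean, SDEP = √(PRESS/n). Defaults: 5 latent variables, the customary
choice for drug-scale correlogram models; the synthetic suite uses 2
because the planted worlds are rank-2 by construction.

`ffd_select` implements one cycle of fractional-factorial variable
selection in the GOLPE convention: a two-level design over variable
inclusion plus 20 % dummy variables, fold-over (which cancels two-factor
aliasing on main effects), per-row SDEP by LOO (5-fold above n = 100), and
removal of variables whose effect exceeds mean + 2 SD of the dummy
effects. The design stacks 16 independently column-scrambled folded
Hadamard fractions (`runs_factor`): with the minimal fraction alone the
dummy-effect noise floor is comparable to the SDEP penalty of a single
pure-noise variable and the rule loses power; ~10+ runs per variable put
the floor well below it. This is a power consideration about the selection
design, fixed before the acceptance criteria were measured, and exposed in
the API.

`rm2_metrics` implements the regression-through-origin validation
statistics: rm² = r²(1 − √|r² − r0²|), computed in both axis orders,
averaged, with Δrm² their absolute difference.

`coefficient_correlogram` ranks variables by absolute **standardized**
coefficient (the coefficient acting on the autoscaled variable). Raw-scale
coefficients would spuriously promote small-variance bins; the
standardized scale is the one on which the model operates and on which
field-software correlograms are drawn.

## The synthetic world: what it emulates and what it does not

`gen_ligand_set` plants a pharmacophore: each feature is a payload of
atoms on a shell around its anchor at the probe's equilibrium distance
(six carbons for DRY, an acceptor triangle for N1, a donor triangle for
O), so the probe's field minimum falls *on the anchor*; anchors sit on
lattice-commensurate coordinates. Activity is a stated linear function of
which feature pairs are realized at their target distance, plus Gaussian
noise; unrealized pairs displace one feature 2–3 Å along the pair axis.
Realization bookkeeping is *re-measured from the emitted coordinates*, so
it matches the geometry exactly by construction.

Three structural choices make the correlogram ground truth analytic and
deserve emphasis:

1. **Group separation.** The two pair groups are based > 20 Å apart and
   re-placed per ligand by random lattice-multiple offsets (with a 10 Å
   clearance guard, deterministically resampled). Cross-group node
   distances therefore scatter over bins far above every planted and
   displaced-state distance; in a rigid world *without* this, every
   (static node, toggled node) bin would be an exact duplicate of the
   planted indicator and no regression could single one out.
2. **Scaffold invisibility.** The toy scaffold chain is fluorinated so it
   fails the hydrophobic flag rule and contributes no spurious DRY nodes;
   it is kept outside interaction range of every feature.
3. **Node budget.** The synthetic analysis configuration
   (`synthetic_grind_config`) caps extraction at 4 nodes per probe: the
   world contains at most four genuine minima per probe, and the
   drug-scale default of 100 would keep every lattice node of every basin
   and occupy nearly every bin for every compound.

A green end-to-end test therefore establishes: fields place minima where
the model says; the encoding maps planted geometry to the predicted bins;
FFD removes uninformative bins without harming predictivity; PLS-LOO
recovers the planted effects (q² ≥ 0.9 noiseless, ≥ 0.6 at noise 0.2) and
the top positive peak back-maps to the planted pair. It does **not**
establish realistic chemistry (no valence or strain), authentic GRID
energetics, docking quality, or behavior under conformational flexibility
— the toy ligands are rigid.

Two lattice caveats. First, extracted nodes are quantized to the 0.5 Å
lattice, so a planted node-pair distance can land up to about half a
spacing from the anchor distance; the peak-identification check allows one
bin width of slack around the planted distance and additionally verifies
the back-mapped provenance distance (in practice the top peak lands in the
exact planted bin). Second, rigid-motion stability of the *encoded row* is
exact only for lattice-symmetric motions: under a generic rotation the
broad hydrophobic basins stay within one bin and roughly a third in value
(each well is sampled up to half a spacing off center and the encoding
multiplies two wells), but a
sharply peaked hydrogen-bond well (passing region ~0.2 Å across) can fall
between lattice nodes and lose its hotspot altogether — an intrinsic
property of cutoff-thresholded fields sampled at 0.5 Å, which is why the
synthetic world pins anchors to lattice-commensurate coordinates.

## Numerical conventions

* Ties in greedy node selection and RFE break toward the lowest index;
  `hclust` merge order disambiguates clustering ties.
* MCC zero-denominator → 0 with warning; empty candidate sets are legal
  (empty node lists, all-zero correlograms).
* `derive_seed(seed, stream)` gives every generator and sub-stream its own
  deterministic seed below 2³¹; all generators are pure functions of
  (parameters, seed).
* Degenerate inputs: a single pose clusters with a warning; n_lv above the
  effective rank is reduced with a warning; FFD requires ≥ 8 variables.

## Limitations

* The LJ/electrostatic/hydrogen-bond parameterization is a stand-in, not
  GRID; absolute energies are not comparable with Pentacle's.
* The CLACC substitution (fixed binning + consistency trim) preserves the
  variable semantics but not the proprietary algorithm.
* The six named classifiers of the 2D track are represented by the
  estimator contract with base-R implementations; gradient boosting and
  kernel machines are out of scope.
* Statistics obtained on real FLAP compound sets depend on curated ChEMBL
  activities, commercial 2D descriptors, docking software, and proprietary
  field software; no such values are asserted here. The acceptance suite
  validates printed worked examples (LipE triples, split arithmetic) and
  planted-world properties instead.
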