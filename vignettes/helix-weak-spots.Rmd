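---
title: "Weak spots in transmembrane helices: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak spots in transmembrane helices: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixweak)
```

## The problem

Class A G protein-coupled receptors carry conserved sequence motifs in
six of their seven transmembrane helices whose common effect is not a
contact or a catalytic role but an *absence*: they weaken or remove a
backbone i to i-4 hydrogen bond, creating a local "weak spot" that gives
the helix the plasticity it needs during activation.  Different
receptors realise the same weak spot through different residues -- a
proline that simply has no amide proton, a glycine that tolerates
unusual backbone torsions, or a Ser/Thr/Asn/Asp/Cys side chain that
hydrogen-bonds to the local backbone and pulls a carbonyl out of its
ideal position.  The position of the weakened bond is more conserved
than the motif causing it.  Downstream of these local weaknesses sits a
concrete piece of machinery: the conserved sodium ion, whose escape to
the cytosol during activation is gated by the rotamer of Leu 2x46 in
the hydrophobic barrier 2x46/3x43/6x40.

`helixweak` implements this analysis as a reusable pipeline: hydrogen
bond energetics and classification, helix irregularity annotation,
mechanism attribution, GPCRdb-style generic numbering, grid-based
cavity/channel detection with the sodium escape test, rotamer and
pentamer-fragment analysis, and cross-structure conservation profiling.
A deterministic synthetic-structure generator supplies every class of
input with known ground truth, so the whole pipeline is testable
without any crystallographic downloads.

## Hydrogen-bond model

Backbone amide hydrogens are rebuilt uniformly (X-ray structures rarely
include them): H sits 1.0 A from N in the peptide plane, opposite the
bisector of the N-CA and N-C(i-1) bonds.  For an ideal trans peptide
this coincides with the classical anti-carbonyl placement; we prefer the
bisector form because it makes the donor geometry independent of the
acceptor's carbonyl orientation, so perturbing one carbonyl perturbs
exactly one bond -- an important property both for attribution and for
constructing single-bond synthetic distortions.

The bond energy is the Kabsch-Sander electrostatic model,

    E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol,

evaluated for each donor against the acceptors at offsets -3, -4 and -5
(the 3-10, alpha and pi registers).  The original structural analyses
used an in-house hydrogen-bond function whose exact form is not public;
the Kabsch-Sander model is standard, parameter-free and reproducible,
which is why it is the energy here.

Classification is a step function of the energy: `normal` at or below
`e_strong` (-1.2 kcal/mol), `weak` up to `e_weak` (-0.5 kcal/mol),
`missing` above that or when no donor proton exists.  The source
analyses define "very weak" bonds only pictorially, so these thresholds
are a calibration: ideal-helix bonds (about -2.2 kcal/mol here) must be
normal, and bonds over-stretched by roughly 0.4-0.8 A must become weak.
Both thresholds are arguments of every function that classifies.

```{r hbond}
h <- build_helix(strrep("A", 12))
map <- backbone_hbond_map(h, "A")
summary(map$energy[map$offset == -4])
table(map$class[map$offset == -4])
```

## Weak spots and mechanisms

A weak spot is an interior -4 bond of class weak or missing inside a
detected helix.  Helices are maximal runs of at least 6 residues with
phi in [-120, -20] and psi in [-80, +10] where at least 70% of donors
have a helical partner; single-residue breaks are bridged.  Irregularity
annotation marks pi-bulges (two or more consecutive donors preferring
-5), 3-10 constrictions (preferring -3) and kinks (local axes fitted to
7-residue windows either side of a position diverging by more than 20
degrees; the axis is fitted to 4-residue running means of the CA trace
so an incomplete final turn does not bias it).

Mechanism attribution is a fixed priority order:

1. `proline` -- PRO at the donor (no amide proton, unconditional);
2. `sidechain_clamp` -- a Ser/Thr/Asn/Asp/Cys side-chain polar atom
   within 3.5 A of the weakened bond's carbonyl O or amide N;
3. `glycine_flex` -- glycine within one residue of the donor;
4. `pushed_backbone` -- a heavy atom of another helix within 3.8 A of
   the donor-region backbone;
5. `unexplained` otherwise.

The source analyses never quantify how close a causal residue must be;
the donor +/- 1 window and the 3.5 A clamp distance are this package's
operationalisation and are deliberately plain distance rules (no angular
terms).  The TM3 motif (C, X23, DRY) is *not* special-cased anywhere:
TM3 stand-ins simply produce no weak spots because nothing weakens them.

## Generic numbering

Weak spots from different receptors are compared at GPCRdb-style
generic positions (helix x position, anchored at the most conserved
x50 residue of each helix).  Numbering here is linear from a
user-supplied anchor; the full structure-based bulge renumbering of
GPCRdb needs its alignment infrastructure and is out of scope.  Linear
numbering is exact for the x40-x60 positions this analysis uses, and
any residue separated from its anchor by a detected pi-bulge carries a
`bulge_flag` so the potential off-by-one is visible rather than silent.
Anchors are configuration (YAML, one entry per helix) rather than
inferred, keeping the module alignment-free.

## Cavity detection and the sodium escape test

A grid (default spacing 1 A) is laid over the structure and a voxel is
open when it lies more than the probe radius (default 1.4 A, a water)
from every atom.  The literal form of this rule measures from atom
*centers*; taken at face value it marks points inside van der Waals
envelopes as open, which is tolerable for visual contouring but not for
open/closed decisions, so the default mode measures from vdW *surfaces*
(C 1.70, N 1.55, O 1.52, S 1.80 A) and `mode = "literal"` preserves the
original rule.  Open voxels are grouped by 6-connectivity (a channel
must not leak diagonally through a one-voxel wall); a component is an
`enclosed_cavity` (no boundary contact), `channel` (two or more
disjoint boundary patches) or `open_cleft`.  Pore radii are bottleneck
clearances: the largest c such that the two ends stay connected using
only voxels with clearance at least c.

The escape test seeds the open space at the voxel nearest a point 2 A
toward the cytosol (-z by convention; orientation of real structures is
the user's responsibility) from the CB of the gate residue 2x46.  CB is
used as the reference rather than the side-chain centroid because CB is
rotamer-independent: the question is whether the passage below the gate
is open, not where the gate happens to point.  The verdict is `open`
when the seeded component reaches the cytosolic grid face with a
bottleneck clearance of at least the ion radius (Na+ 1.02 A); when no
open voxel lies within 5 A of the seed point -- the situation a closed
leucine plug creates -- the test reports `closed` with a seeding
diagnostic.  The 2 A offset and snap radius are parameters; "just
below" has no published numeric definition.

```{r gate}
ph <- build_gate_phantom("closed")
gate_assessment(ph$structure, ph$numbering, alt_chis = ph$open_chis)
```

## Rotamers and pentamer fragments

Chi angles use the IUPAC atom quadruples; rotamer labels bin each chi
to the nearest staggered well (m = -60, t = 180, p = +60).  "Open" and
"closed" gate rotamers are defined *functionally* by the channel verdict
rather than by fixed chi values, because the reference structures show
the two states without printing angles; canonical labels are reported
alongside.  Side-chain rebuilds use ideal internal coordinates at the
stated chi values with no refinement.  The pentamer search superposes
the 20 backbone atoms (N, CA, C, O of five residues) of every
same-middle-residue fragment onto the query with the Kabsch algorithm
and keeps matches within the RMSD threshold (default 0.5 A); the middle
side chains, transformed into the query frame, give the local rotamer
distribution.

## The synthetic generators and what they do (not) show

The generators define the study conditions:

* **Helices** are built NeRF-style from ideal bond geometry (N-CA
  1.458, CA-C 1.525, C-N 1.329 A) at requested torsions; alpha is
  (-57, -47), the planted 3-10 window uses (-49, -26) and the pi window
  (-57, -70), values chosen so the resulting bond registers actually
  shift to -3 / -5.  Full side chains exist for L, S, T, N, D, C, Y, W
  (the types the weakening mechanisms need); everything else is a CB
  stub.
* **Planted weak spots** come in two mechanisms.  A proline removes the
  donor proton.  A clamp places an asparagine whose side-chain amide is
  oriented at the i-4 carbonyl (chi = (-90, -90)) and rotates that
  carbonyl oxygen 40 degrees toward it -- the oxygen is a leaf atom, so
  exactly one bond is over-stretched (to about -0.7 kcal/mol, the
  middle of the weak band) while the side-chain hydrogen bond sits near
  2.7 A.  Asparagine is used because with ideal geometry a serine OG
  cannot come closer than about 4.2 A to the i-4 carbonyl even after
  carbonyl displacement, whereas Asn clamps are well attested at
  positions like 2x58.
* **Bundles** place seven 26-residue helices antiparallel on an 11.2 A
  circle (adjacent axes about 9.7 A apart), plant one weak spot per
  helix except TM3 at fixed generic positions (1x49, 2x58, 4x47, 5x43,
  6x47, 7x46), draw the mechanism per helix from the seed, and add
  0.02 A Gaussian coordinate jitter -- enough to break exact symmetry,
  small against the 0.3 kcal/mol classification margins.
* **Channel phantoms** surround an empty cylinder with a 0.5 A-spaced
  atom sheet; grid bounds are integer-aligned so the analytically
  expected open-voxel set equals the marked set exactly, not just
  approximately.  The hollow sphere uses smooth concentric shells so
  its cavity volume matches the closed form to well under 10%.
* The **gate phantom** is a blind 4 A bore (sealed top, open bottom)
  with a leucine whose closed rotamer plugs the bore below its own CB
  and whose open rotamer hugs the wall; both rotamers are found by a
  deterministic chi grid search, so the phantom's truth is constructed,
  not assumed.

Passing tests on these fixtures show that the detection machinery is
correct *given* idealised geometry.  They do not show robustness to
crystallographic reality: refinement errors much larger than 0.02 A,
missing side chains, alternate conformations beyond occupancy picking,
kinked and frayed helices, or genuinely ambiguous mechanisms.  On real
structures the classification thresholds are the sensitive knobs and
should be varied as a sensitivity analysis.

## Validation scale and numerical choices

The shipped validation uses helices of 6-30 residues, 100 random
50-atom clouds for the marking oracle, tube radii 2-4 A, 20 seeded
fragment databases of 103 fragments, and 50 seeded bundles for the
ensemble study -- sizes chosen so each property is exercised well past
its edge cases while the whole suite stays interactive.  Ties in
altloc resolution fall to label order; rotamer bins assign boundary
angles to the nearest well center; bottleneck searches compare
clearances with a 1e-9 slack so exact-equality levels are kept;
degenerate superposition inputs (fewer than 3 points, collinear sets)
are errors, and reflections are excluded by the determinant correction.

## Limitations

Beyond the synthetic-versus-real caveats above: bifurcated and
water-mediated hydrogen bonds are out of scope; the numbering module
does not reproduce GPCRdb bulge insertion codes; membrane orientation
is a convention the caller must establish (e.g. by superposition onto
an oriented reference); and mutation-effect tables from pharmacology
databases are annotations, not quantities this package recomputes.
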