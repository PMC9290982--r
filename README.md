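# helixweak

Detection and analysis of **weak spots** — weakened or missing backbone
i → i−4 hydrogen bonds — in the transmembrane helices of G
protein-coupled receptors (GPCRs) and other helical membrane proteins.

Class A GPCRs carry conserved sequence motifs in six of their seven
transmembrane helices whose shared functional role is to weaken the
helix locally: a proline contributes no amide proton, a glycine accepts
torsions other residues cannot, and small polar side chains
(Ser/Thr/Asn/Asp/Cys) hydrogen-bond to the local backbone and pull a
carbonyl out of place. The *position* of the weakened bond is more
conserved across receptors than the motif that causes it, and the
resulting plasticity feeds a concrete mechanism: the escape of the
conserved sodium ion to the cytosol, gated by the rotamer of Leu 2x46
in the hydrophobic barrier 2x46/3x43/6x40.

The package is aimed at structural bioinformaticians who want to run or
extend this analysis programmatically. It provides:

* **Hydrogen-bond energetics** — uniform amide-H placement and the
  Kabsch–Sander electrostatic energy
  `E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, evaluated
  per donor over the −3/−4/−5 helical registers and classified
  normal / weak / missing (configurable thresholds −1.2 / −0.5).
* **Weak-spot calling** with mechanism attribution (proline >
  side-chain clamp > glycine flexibility > inter-helix push), plus
  π-bulge / 3₁₀ / kink annotation.
* **Generic residue numbering** (GPCRdb-style `<helix>x<position>`,
  x50-anchored) so weak spots from different receptors are comparable.
* **Grid-based cavity and channel detection** (1 Å grid, 1.4 Å probe,
  vdW or literal marking) and the **sodium escape-channel test** below
  position 2x46, including the Leu 2x46 open/closed **rotamer gate
  assessment** with blocking-contact analysis (Asp 2x50 / Tyr 7x53).
* **Pentamer fragment searches** for local rotamer distributions,
  Kabsch superposition, sequence-logo information content, PGDNST
  profiling, and cross-structure **conservation profiles**.
* A deterministic **synthetic-structure generator** (ideal/distorted
  helices, 7-helix bundles with planted weak spots, channel/gate
  phantoms, fragment databases) so every stage is validated against
  constructed ground truth.

## Worked example

Build a synthetic 7-helix bundle with planted weak spots, detect
helices, assign generic numbers from the x50 anchors, and call weak
spots:

```r
library(helixweak)

b    <- build_bundle(seed = 42)
segs <- detect_helices(b$structure)
num  <- assign_generic_numbers(b$structure, segs, b$anchors)
ws   <- weakspot_table(b$structure, numbering = num, segments = segs)
ws[, c("chain", "donor_resno", "generic", "class", "mechanism")]
#>   chain donor_resno generic   class       mechanism
#> 1     A         112    1x49 missing         proline
#> 2     B         221    2x58 missing         proline
#> 3     D         410    4x47 missing         proline
#> 4     E         506    5x43    weak sidechain_clamp
#> 5     F         610    6x47    weak sidechain_clamp
#> 6     G         709    7x46    weak sidechain_clamp
```

Six helices carry exactly one weak spot each at the planted generic
position; chain C (the TM3 stand-in) has none, because nothing weakens
TM3. A `missing` bond has no donor proton (proline); a `weak` bond is
over-stretched by a clamping side chain but still partially formed.
The mechanism column matches the planted truth in `b$truth`.

The sodium-gate logic on a constructed gate phantom:

```r
ph <- build_gate_phantom("closed")
gate_assessment(ph$structure, ph$numbering, alt_chis = ph$open_chis)
#> <hw_gate> current rotamer pt -> closed ; alternative mm -> open
```

The leucine's built (closed) rotamer plugs the channel below 2x46 —
the escape test reports `closed`; rebuilt in the alternative rotamer
the channel opens for a sodium-sized probe (1.02 Å).

Real structures are read with `read_structure()` (PDB/mmCIF; altlocs
resolved by occupancy), anchors come from a YAML file via
`read_anchor_config()`, and `run_pipeline()` drives the whole analysis
over a set of structures, writing TSV/JSON tables and a manifest.

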