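---
title: "Screening FMO pair interaction energies with 3D-SPIEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening FMO pair interaction energies with 3D-SPIEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spies3d)
```

## The problem and the model

Protein–protein interfaces are flat and extended, and force-field methods
struggle to rank the interactions that actually hold them together. The
fragment molecular orbital (FMO) method makes a quantum-mechanical
treatment tractable by partitioning the complex into fragments — here one
fragment per residue, water, or ligand — and computing pair interaction
energies (PIEs) between all fragment pairs, decomposed by PIEDA into
electrostatic, exchange-repulsion, charge-transfer+mix, dispersion, and
optionally solvation terms:

$$\mathrm{PIE}\;(\Delta E^{int}_{ij}) = \Delta E^{es}_{ij} +
\Delta E^{ex}_{ij} + \Delta E^{ct+mix}_{ij} + \Delta E^{di}_{ij} +
\Delta G_{sol}$$

Two practical problems remain. First, raw PIEs between charged residues
are dominated by long-range electrostatics and can look enormous for pairs
that never touch. Second, with $N$ fragments there are $N(N-1)/2$ pairs,
far too many to inspect. The 3D-SPIEs screen answers both with two
criteria applied jointly:

* a **distance criterion**: the single-linkage distance between the two
  fragments — the minimum over all atom pairs of the Euclidean
  inter-atomic distance — must be within the cutoff (default 5.4 Å, the
  separation scale used for the electrostatic approximation in FMO);
* an **energy criterion**: the PIE must be attractively stronger than the
  significance threshold (default −3.0 kcal/mol).

Retained pairs carry their distance, decomposition and labels, and are the
dots of a 3D scatter (fragment i, fragment j, distance; energy as colour).
Classification against a chain→group map separates inter-protein (PPI)
pairs from intra-protein (non-PPI) pairs; pairs touching a water fragment
are water-mediated, and a water attractively bound on both sides of the
interface is a water bridge.

## Fragmentation scheme

Chains are cut at the Cα–C(carbonyl) sp³ bond following the hybrid orbital
projection (HOP) convention: the bond-detached atom is the Cα, the
bond-attached atom the carbonyl C, and consequently the carbonyl C and O
of residue $i$ are members of fragment $i+1$. A main-chain C=O hydrogen
bond is therefore attributed to the *next* residue's fragment — this is
the deliberate, documented bias of the scheme, not an accounting error.
The N-terminal residue additionally holds its ammonium hydrogens; the
C-terminal residue keeps its own carbonyl and OXT. Each water and each
ligand residue is one fragment; the two cysteines of a disulfide bridge
(SG–SG within 2.5 Å, greedy nearest-first pairing) can be merged into a
single two-residue fragment. Proline follows the same rule; its nitrogen
simply has no amide hydrogen. Multi-residue peptide ligands are fragmented
residue-wise like protein chains, because per-residue interactions of
peptide inhibitors are themselves of interest. Glycan residues attached to
Asn are treated as ligand fragments when declared, never silently guessed.

Formal charges are inferred from the hydrogens actually present rather
than from residue names, because protonation is fixed upstream at the
structure-preparation stage: a carboxylate without its acid hydrogen
contributes −1, Lys with three NZ hydrogens and Arg contribute +1, His
contributes +1 only when both ring nitrogens are protonated, a free
N-terminus with three N hydrogens +1, and a bare OXT −1. A residue with no
hydrogens at all triggers a warning and a name-based fallback.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `distance_cutoff` | 5.4 | Å | electrostatic-approximation distance scale of FMO |
| `attractive_threshold` | −3.0 | kcal/mol | conventional significance level for attractive PIEs |
| `sg_cutoff` | 2.5 | Å | S–S bond is ≈2.05 Å; 2.5 separates bonds from contacts |
| chain-break warning | 4.5 | Å | Cα–Cα above this cannot be a contiguous peptide |
| `gap_tolerance` | 2 | residues | reported hot-spot regions tolerate gaps of two in their residue runs |
| `waters_within` | user-set | Å | the radius for retaining crystallographic waters when trimming to a domain is a judgement call; it is exposed, not defaulted |

Both screen boundaries are implemented as *inclusive* (≤), so a pair at
exactly 5.4 Å with exactly −3.0 kcal/mol is retained; this makes the
documented defaults self-consistent. Distances use all atoms including
hydrogens, since structures are protonated before FMO; a heavy-atom-only
switch exists for unprotonated inputs. "Detected PPI" counts are retained
inter-group records, unique per fragment pair, with a merged disulfide
counting once. Antibody heavy and light chains are conventionally mapped
to a single group so that their mutual contacts are intra-group and only
antigen–antibody pairs count as PPI.

## Numerical choices and degenerate inputs

* Distance computation has two backends — a literal double loop and a
  cutoff-sized cell grid — kept result-identical and cross-checked in the
  tests; ties and degenerate geometry are handled by exact comparison on
  the squared-distance matrix with clamping at zero.
* Altloc groups resolve to one conformer: highest occupancy, ties broken
  by altloc letter; a `"first"` policy is available.
* Greedy disulfide pairing sorts candidate SG–SG pairs ascending and
  takes each cysteine at most once; ties break lexicographically on
  residue keys.
* The PIEDA parser splits on whitespace (column-width drift is harmless),
  skips malformed rows with a line-numbered warning, keeps the last of
  duplicated pair rows (restart files repeat blocks), and flags — never
  corrects — rows whose printed total deviates from the component sum by
  more than 0.01 kcal/mol. A missing solvation column leaves the total a
  four-term sum; whether quoted totals include solvation is a convention,
  so `total_pie()` simply treats an absent term as zero.
* The GAMESS deck is byte-deterministic; its hybrid-orbital block is a
  canned ideal-sp³ constant (overridable), since deriving SCF hybrid
  coefficients is not this package's job. Atom references in INDAT/FMOBND
  use sequential coordinate order, the numbering GAMESS applies.
* An empty selection, a residue missing Cα or C, an unmapped chain, or a
  fragment with no atoms are hard errors naming the offender; validation
  (`validate_for_fmo`) is advisory and never mutates.

## What the synthetic fixtures emulate

`make_toy_complex()` builds extended-conformation peptides with idealized
internal geometry: 4.28 Å per residue along the chain (so Cα–Cα stays
under the chain-break threshold and the peptide C–N bond is 1.33 Å),
Cα–C at 1.50 Å (under the 1.8 Å covalency check for detached bonds),
full protonation, chains stacked so the nearest-atom gap equals the
requested interface width (solved numerically), interface waters at
midpoints of the closest inter-chain Cα pairs, and disulfide SG pairs at
2.05 Å. Side chains beyond Cβ are methyl stubs except cysteine.
`make_synthetic_fmo_output()` wraps planted pairs (totals at or below
−3.0 kcal/mol by construction) and uniform background noise in
(−2.9, +3.0) kcal/mol — chosen so background never crosses the threshold —
into a GAMESS-style PIEDA block; values are rounded to the printed
precision first, so parsing recovers the ground truth exactly.

What passing tests on these fixtures do show: the bookkeeping of
fragmentation, the exactness of the distance/energy screen, and the
end-to-end recovery of planted interface signal (precision and recall 1
by construction). What they do not show: anything about real QM energy
magnitudes, PCM physics, conformational strain, or crystallographic noise
— real complexes enter only through externally computed PIE tables.

## Problem sizes

The test suite sweeps 50 seeded toy complexes (1–3 chains, 3–8 residues,
0–2 waters, occasional disulfides) for the fragmentation properties, 100
random point-cloud instances for the distance oracle, 30 randomized
record sets for the bridge enumeration, and three seeds of a 2×8-residue
complex for planted-truth recovery; these sizes exercise every branch
while keeping the whole suite fast enough to run on every change.

## Known limitations

* No mmCIF input; PDB only.
* No loop building, protonation prediction, or minimization — structures
  must arrive prepared; `validate_for_fmo()` only reports what is missing.
* The emitted deck is a faithful skeleton of an FMO2 input, but
  production runs should review job keywords (memory, PCM cavity
  settings) and supply a real hybrid-orbital block for the chosen basis.
* Merged disulfide fragments spanning two chains are attributed to the
  first cysteine's chain for grouping; interfaces stitched by inter-chain
  disulfides should be interpreted with that in mind.
* Water-to-water retained pairs are reported but excluded from bridges
  and maps by default.
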