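# spies3d

Quantum-chemical analysis of protein–protein and protein–ligand interfaces
at residue resolution, for structural bioinformaticians who run fragment
molecular orbital (FMO) calculations and need to turn the resulting
pair-energy tables into interpretable interface maps.

In a two-body FMO calculation with a one-fragment-per-residue scheme, every
residue, water and ligand of a complex is a fragment, and the program
reports a pair interaction energy (PIE) for every fragment pair, decomposed
(PIEDA) as

    PIE(ΔE_int_ij) = ΔE_es + ΔE_ex + ΔE_ct+mix + ΔE_di + ΔG_sol

(electrostatic, exchange-repulsion, charge-transfer+mix, dispersion, and
optional solvation, kcal/mol). Raw PIEs include unphysically large
long-range electrostatic terms, so significance is decided by the
**3D-SPIEs screen**: keep a pair only if its single-linkage distance — the
minimum over all atom pairs of the Euclidean distance between the two
fragments — is within 5.4 Å *and* its PIE is attractively stronger than
−3.0 kcal/mol (both thresholds inclusive and configurable). Retained pairs
are classified as inter-protein (PPI), intra-protein (non-PPI), or
water-mediated; waters attractively bound on both sides of an interface
are reported as water bridges; interface residues are grouped into
hot-spot regions; and per-residue hits can be aggregated across complexes
into an interaction map.

The package covers the full protocol around an external FMO run:

- **Structure model** — PDB reading/writing (via bio3d), altloc
  resolution, region selection with water retention by radius, disulfide
  detection, advisory validation (`read_pdb`, `select_region`,
  `detect_disulfides`, `validate_for_fmo`).
- **Fragmentation** — the hybrid-orbital-projection (HOP) scheme: chains
  split at the Cα–C(carbonyl) sp³ bond so each carbonyl belongs to the
  next residue's fragment; disulfide pairs optionally merged;
  hydrogen-count-based formal charges; GAMESS-style FMO deck output
  (`build_fragmentation`, `write_fmo_input`).
- **PIEDA parsing** — table-driven parser for PIEDA summary blocks, CSV
  interchange (`parse_fmo_output`, `write_pie_table`).
- **3D-SPIEs** — distances, screen, classification, bridges, hot spots,
  maps, scatter export (`all_pair_distances`, `spies_filter`,
  `classify_pairs`, `detect_water_bridges`, `hotspot_regions`,
  `build_interaction_map`, `export_scatter`).
- **Synthetic fixtures** — deterministic toy complexes and synthetic
  PIEDA output with planted ground truth (`make_toy_complex`,
  `make_synthetic_fmo_output`), so the whole pipeline is testable without
  quantum chemistry.
- **Pipeline & CLI** — `run_pipeline()` over a YAML/list config with an
  artifact manifest; `inst/cli/spies.R` is a thin Rscript front end.

The quantum chemistry itself (SCF/MP2/PCM) is out of scope: the package
emits the input deck and consumes the output.

## Worked example

```r
library(spies3d)

s <- make_toy_complex(toy_complex_spec(n_chains = 2, residues_per_chain = 6,
                                       n_waters = 2, seed = 42))
plan <- build_fragmentation(s, notation = list(prefix = c(B = "L")))
d <- all_pair_distances(plan, s, cutoff = 5.4)
gen <- make_synthetic_fmo_output(plan, synthetic_pie_spec(
  planted = rbind(planted_pair(3, 9, -12.4), planted_pair(4, 10, -6.1)),
  seed = 42))
rec <- classify_pairs(spies_filter(gen$table, d, plan, spies_params()),
                      c(A = "PD1", B = "PDL1"))
rec[, c("label_i", "label_j", "distance", "pie", "iclass")]
#>   label_i label_j distance   pie      iclass
#> 1      A3     LA3     4.84 -12.4 inter_group
#> 2      A4     LA4     4.84  -6.1 inter_group
hotspot_regions(rec, "PDL1")
#>   region start end n_residues residues support
#> 1      1     3   4          2      3,4       2
```

The two planted attractive pairs (−12.4 and −6.1 kcal/mol) sit 4.84 Å
apart across the chain A / chain B interface, pass the 5.4 Å / −3.0
kcal/mol screen, classify as inter-group (PPI) under the chain→group map,
and the two hit partner residues (3 and 4 on the "PDL1" side) form one
contiguous hot-spot region. Background pairs, drawn between −2.9 and
+3.0 kcal/mol, are all screened out.

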