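# septexo

Tools for two computational problems from fission-yeast cytokinesis:
deciding which septin and exocyst subunits can physically interact,
given predicted structures of all pairwise combinations, and
quantifying fluorescence at the division site (ROI intensities, line
scans, FRAP kinetics). It is aimed at cell biologists screening
predicted subunit-subunit complexes and at anyone who needs the
accompanying image/FRAP quantifications as tested, scriptable code.

## What it computes

**Interface screen.** For each subunit pair, predicted in both
sequence input orders with five models per order:

- interface residues: residue pairs of the two chains with minimum
  non-hydrogen atom distance <= 4 Å (inclusive), from the rank-1 model
  (models ranked by mean pLDDT, ties broken by id);
- confidence filter: contacts are kept only if both partner residues
  have pLDDT >= 50 (a score in the B-factor field, 0-100);
- consensus: a pair counts as interacting only when filtered contacts
  survive in *both* input orders; consensus pairs are ranked by
  min(order A:B, order B:A) of the interface-mean pLDDT.

**Steric feasibility.** Interface residues are mapped (by explicit
offsets, never alignment) onto an assembled complex model, and
classified by Shrake-Rupley solvent accessibility in complex context:
accessible ⇔ relative SASA = SASA / maxASA(residue type) >= 0.25. The
report is the percentage of mapped residues that remain accessible.

**Fluorescence quantification.** Sum/max z-projections; paired-ROI
background subtraction, `I₁ − A₁(I₂ − I₁)/(A₂ − A₁)`, with ROI2 ≈ 2×
the area of ROI1; axial colocalization profiles (column means over a
rectangle across the division plane); 3-pixel-wide line scans with
four alignment strategies; and a rim-spread index separating rim-ring
from centre-disk localization.

**FRAP.** Background/acquisition-bleaching correction against an
unbleached reference cell, normalization (pre-bleach → 100%, first
post-bleach → 0%), rolling average (window 3, post-bleach only), and
the exponential fit y = m1 + m2·exp(−m3·x) with t½ = ln2/m3. The model
is passed through the same smoothing operator as the data, so
smoothing introduces no parameter bias.

**β-galactosidase formulas.** The two printed ONPG quantifications:
activity = OD420·1.7/[0.0045·protein·volume·time] (nmol/min/mg) and
units = 1000·OD420/[T·V·OD595].

Every input class has a synthetic generator with planted ground truth
(`make_pair_model`, `make_screen_grid`, `make_complex_model`,
`make_division_stack`, `make_frap_trace`), so the full pipeline runs
and is tested without external data. Structures are read/written as
PDB or mmCIF (confidence in the B-factor field), PAE matrices as JSON
in the ColabFold and AF3-server dialects, image stacks as multi-page
TIFF with a JSON calibration sidecar, FRAP traces as CSV.

## Worked example

The numbered scripts under `analysis/` run the whole study on
synthetic data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # fixtures: PDB/mmCIF, PAE, TIFF, CSV
Rscript analysis/02_screen.R
Rscript analysis/03_feasibility.R
Rscript analysis/04_quant.R
Rscript analysis/05_frap.R
```

`02_screen.R` screens the 4 × 8 septin-exocyst grid (32 pairs, both
orders, 5 models each) in which 6 bidirectional interfaces were
planted among one-sided and low-confidence decoys:

```
screened 32 unordered pairs; 6 reached bidirectional consensus
planted:  Exo70:Spn1, Sec15:Spn3, Sec3:Spn1, Sec3:Spn2, Sec3:Spn4, Sec5:Spn3
found:    Exo70:Spn1, Sec15:Spn3, Sec3:Spn1, Sec3:Spn2, Sec3:Spn4, Sec5:Spn3
=> exact recovery of the planted interaction set
```

`03_feasibility.R` maps 40 labelled residues onto an assembled
synthetic complex (30% caged) and recovers the construction labels
exactly:

```
40 residues mapped (0 unmappable); 70.0% accessible at rSASA >= 0.25
planted exposed fraction: 70.0% => classification matches the construction labels exactly
```

`04_quant.R` and `05_frap.R` print the localization index and the
recovered kinetics (planted off-rate 0.05 /s under noise):

```
rim-spread index: ring 0.000, disk 0.778
two-channel peak separation: 0.40 um (planted 0.40 um)
fast design (dt 0.33 s): m3 = 0.0524 /s, t1/2 = 13.24 s (planted m3 = 0.05, t1/2 = 13.86 s)
slow design (dt 10.00 s): m3 = 0.0513 /s, t1/2 = 13.52 s (planted m3 = 0.05, t1/2 = 13.86 s)
```

A rim-spread index near 0 means the signal sits at the rim of the
division plane (an intact ring); values above ~0.6 mean it has spread
over the centre. The FRAP half-times are ln 2 / m3.

`run_pipeline(default_config(seed))` performs the same stages in one
call and writes TSV/JSON reports plus a resolved config and
provenance record; reruns with the same seed are byte-identical.

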