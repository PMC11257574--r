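Package: septexo
Title: Interface Screening of Predicted Septin-Exocyst Complexes and
    Division-Site Fluorescence Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for an all-vs-all screen of predicted
    septin-exocyst subunit complexes and the accompanying quantitative
    fluorescence analyses in fission yeast cytokinesis. Extracts
    inter-chain interface residues from predicted structure models at a
    heavy-atom distance cutoff, filters them by per-residue pLDDT
    confidence, applies a bidirectional input-order consensus over all
    subunit pairs, and scores steric feasibility of predicted binding
    sites on assembled complexes via Shrake-Rupley solvent-accessible
    surface area. Also implements division-site fluorescence
    quantification (sum/max projections, paired-ROI background
    subtraction, axial colocalization profiles, aligned line scans),
    FRAP recovery kinetics (acquisition-bleaching correction,
    normalization, rolling average, single-exponential fitting with
    t1/2 = ln2/m3), beta-galactosidase activity formulas, and synthetic
    generators for every input class with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
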