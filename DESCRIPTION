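Package: domasm
Title: Domain Assembly of Multi-Domain Protein Structures by
    Affine-Transform Interaction Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles rigid single-domain protein structures into
    full-length multi-domain (or multi-chain) models. Inter-domain
    residue-residue interactions are represented as six-dimensional
    affine transforms (Euler angles plus spherical translation) between
    per-residue backbone frames; predicted or structure-derived binned
    interaction distributions are converted into an atomic
    coordinate-deviation (ACD) energy, which a population-based
    evolutionary optimizer minimizes over linker phi/psi torsions and
    per-chain rigid placements. Includes a structure-derived interaction
    oracle, PDB backbone I/O, an ideal-geometry synthetic fixture
    generator, and evaluation metrics (Kabsch RMSD, TM-score,
    inter-domain distance error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
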