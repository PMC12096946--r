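Package: ccdimer
Title: Structural Analysis of Coiled-Coil Dimers and Their Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize two-chain coiled-coil dimer structures
    (multi-model NMR ensembles or molecular-dynamics-like frame sets) and to
    rank the structural impact of missense variants.  Provides heavy-atom
    contact-network enumeration and classification (hydrophobic, hydrogen
    bond, van der Waals, salt bridge), aromatic ring-pair geometry and
    pi-stacking classes, helix-axis fitting and crossing angles,
    Kabsch-Sander backbone hydrogen-bond energies and alpha-helicity,
    Shrake-Rupley solvent-accessible and buried surface area, axial charge
    profiles, Kabsch superposition with RMSD/RMSF, and wild-type-normalized
    replicate statistics with impact calls.  Includes a synthetic-structure
    builder (Crick-style coiled-coil backbones, perturbed ensembles, point
    mutants, progressive unfolding) so every analysis stage is testable
    against known ground truth, with ready-made constructors for the human
    PALB2 coiled-coil homodimer and a PALB2-BRCA1-like heterodimer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
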