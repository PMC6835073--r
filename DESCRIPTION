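Package: gamdtk
Title: Gaussian Accelerated Molecular Dynamics Toolkit for Toy Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale implementation of the Gaussian accelerated
    molecular dynamics (GaMD) enhanced-sampling workflow used to refine
    docked peptide poses: a BAOAB Langevin dynamics engine over analytic
    model potentials and a bead-chain molecular model, harmonic boost
    potentials tuned under the sigma-0 criterion (total, dihedral, or
    dual boost), exponential and cumulant-expansion energetic
    reweighting to potential-of-mean-force surfaces, PDB structure
    handling with Kabsch superposition and CAPRI-style ligand RMSD, and
    hierarchical-agglomerative and greedy pose clustering ranked by size
    or reweighted free energy. Every stage is verifiable against
    analytic Boltzmann statistics computed by quadrature.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
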