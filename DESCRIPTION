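Package: zernpatch
Title: 3D Zernike Descriptors of Protein Surface Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Superposition-free characterization of protein binding-site
    patches by 3D Zernike descriptors of molecular shape and sign-split
    surface electrostatic potential. Reads PDB and PQR structures, selects
    patches by residue ranges, samples the solvent-accessible surface,
    voxelizes shape and Coulomb potential into unit-ball grids, and computes
    rotation- and translation-invariant descriptor vectors (121 components
    at order 20 per channel). Provides Manhattan-distance similarity and
    complementarity scores, conformational-ensemble statistics (distance
    distributions, signed kernel-density overlap coefficients, PCA
    projections), deterministic synthetic fixtures, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
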