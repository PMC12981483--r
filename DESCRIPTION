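Package: phtitra
Title: Constant-pH Molecular Dynamics Titration and Hydrogen-Bond Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for lambda-dynamics constant-pH molecular
    dynamics simulations of peptides. Classifies per-frame protonation states
    from (lambda, chi) titration coordinates, computes deprotonated fractions
    and fits generalized Henderson-Hasselbalch (Hill) titration curves to
    estimate residue pKa values and their shifts from model-pentapeptide
    references. Builds geometric hydrogen-bond and water-bridge network graphs
    from coordinate ensembles with configurable distance/angle criteria and
    occupancy thresholds, quantifies backbone flexibility with a per-residue
    circular dispersion of phi/psi dihedrals, and assigns alpha-helical
    content from dihedral windows. Includes seeded synthetic generators for
    titration records and toy peptide/water ensembles with known ground truth,
    multi-model PDB and tab-separated titration record input/output, and a
    reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
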