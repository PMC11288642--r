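Package: glycantree
Title: Layer-by-Layer Modeling of N-Linked Glycan Trees on Protein Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, sample, and score branched N-linked glycans on protein
    scaffolds. Glycan trees are parsed from condensed-IUPAC strings, placed
    with idealized rigid-ring sugar templates, and optimized by a Monte Carlo
    sampler that draws glycosidic torsions from conformer libraries built with
    adaptive von Mises kernel density estimates. Trees are grown layer by
    layer from the reducing end outward, with a sampling budget linear in the
    number of sugar residues. Includes decoy analytics (fixed-frame and
    superimposed heavy-atom RMSD, pNear funnel quality, enrichment fractions),
    optional guidance by simulated electron density, N-glycosylation sequon
    scanning and design, and carbohydrate-aware PDB input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
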