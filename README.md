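# glycantree

Build, sample, and score N-linked glycan trees on protein scaffolds.

Branched glycans attached to Asn side chains are among the hardest parts of
a glycoprotein to determine or predict: each glycosidic linkage contributes
two or three rotatable torsions (phi, psi, and omega for 1→6 arms), and a
small change near the protein attachment moves the whole tree.  `glycantree`
is an R toolkit for structural modelers working on this problem.  It
implements:

* **Glycan tree topology** — a condensed-IUPAC parser/serializer
  (`b-D-GlcpNAc`, `-(1->4)-` linkages, bracketed branches, reducing end
  rightmost) and layer decomposition (graph distance to the root).
* **Rigid-ring kinematics** — idealized chair templates for the common
  N-glycan sugars (Glc, GlcNAc, Man, Gal, GalNAc, Fuc, Xyl), exact forward
  building from torsions, local torsion edits, randomization.
* **Conformer libraries** — adaptive von Mises kernel density estimates per
  linkage-type torsion.  With pilot concentration `kappa0` and sensitivity
  `alpha`, each observation gets `kappa_i = kappa0 / lambda_i^2` where
  `lambda_i = (f_pilot(mu_i)/g)^(-alpha)`; conformers are cross-products of
  per-torsion density modes with watershed-basin probability masses.  The
  statistical torsion energy is `E(theta) = -ln(f(theta)/f_max)`.
* **A Monte Carlo glycan sampler** — a weighted random sampler over
  conformer, single-torsion, local-refine, and hydroxyl moves with
  Metropolis acceptance, budgeted linearly in residue count.
* **A layer-by-layer tree modeler** — randomize, then build and optimize
  the tree root→foliage (optimizing all built layers after each new one),
  finish with a full-tree optimization, and report the lowest-energy decoy
  of an ensemble.  Optional guidance by (simulated) electron density via
  real-space correlation.
* **Decoy analytics** — fixed-frame and Kabsch-superimposed heavy-atom
  RMSD, the Boltzmann-weighted funnel metric
  `PNear = sum_i exp(-r_i^2/lambda^2) exp(-(E_i-E_min)/kT) / sum_i exp(-(E_i-E_min)/kT)`,
  and enrichment fractions below 1 / 2.5 / 5 Å.
* **Sequon design** — scan N-X(S/T) motifs (X ≠ P), design typical or
  enhanced sequons, attach whole glycans by IUPAC string, and rank candidate
  glycosylation sites by modeled energy.
* **Carbohydrate-aware PDB I/O** and seed-deterministic synthetic fixtures
  (torsion observation sets, toy scaffolds, reference complexes, density
  maps), so everything runs without downloads.

## Worked example

Model the Man3GlcNAc2 core on a toy helix and measure recovery against a
known native:

```r
library(glycantree)

lib      <- default_library()                 # synthetic conformer library
scaffold <- make_toy_scaffold("helix", 12, 6) # Asn at position 6
tree <- parse_iupac(
  "a-D-Manp-(1->3)-[a-D-Manp-(1->6)]-b-D-Manp-(1->4)-b-D-GlcpNAc-(1->4)-b-D-GlcpNAc",
  attachment = list(chain = "A", resno = 6, atom = "ND2"))
native <- make_reference_complex(tree, scaffold, lib)

cfg  <- modeler_config(n_decoys = 20, seed = 42)
recs <- generate_ensemble(scaffold, tree, cfg, lib, native = native$pose)
best <- select_best(recs)
round(unlist(best$metrics), 2)
#> rmsd_fixed rmsd_super  root_rmsd
#>       0.80       0.47       0.61

rmsds    <- vapply(recs, function(r) r$metrics$rmsd_fixed, numeric(1))
energies <- vapply(recs, function(r) r$energy$total, numeric(1))
round(pnear(rmsds, energies, lambda = 1), 2)
#> [1] 0.54
enrichment(rmsds)
#> <1.0A <2.5A <5.0A
#>  0.65  0.80  1.00
```

The best-scoring decoy reproduces the native's internal structure to about
half an Angstrom (superimposed RMSD) and its placement to about one
(fixed-frame RMSD); pNear near 0.5–0.9 at λ = 1 Å indicates a usable score
funnel on this fixture.  With a simulated 2 Å density map
(`simulate_density()` + `modeler_config(mode = "density")`) the best decoy
typically lands below 0.5 Å.  Exact numbers vary with the seed; the
acceptance script below reports them reproducibly.

A command-line wrapper ships in `inst/cli/glycantree.R` with subcommands
`build-library`, `model`, `benchmark`, `glycosylate`, and `design-sequons`
(`Rscript inst/cli/glycantree.R --help` after installation, or call
`run_cli()` directly).

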