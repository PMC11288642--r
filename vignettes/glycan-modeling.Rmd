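---
title: "Layer-by-layer glycan tree modeling: models, parameters and design choices"
author: "glycantree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-by-layer glycan tree modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycantree)
```

## The problem

N-linked glycans are branched sugar polymers attached to Asn side chains.
Their many rotatable glycosidic bonds make them hard to resolve
experimentally and hard to predict computationally: a single torsion near the
protein attachment can swing the whole tree by tens of Angstroms.  This
package models glycan trees on protein scaffolds by Monte Carlo sampling of
glycosidic torsions, guided by conformer statistics encoded as circular
kernel density estimates, growing each tree from its reducing-end "root"
outward to the "foliage" so that the attachment region — which dominates the
overall placement — is optimized first and re-optimized as every new layer
is added.

## The model

### Degrees of freedom and kinematics

Sugar rings are held rigid at their low-energy chair (4C1 for D-pyranoses,
1C4 for L-fucose, which is built as the mirror image of D-galactose with the
6-hydroxyl removed).  The sampled degrees of freedom are, per linkage,

* `phi` = O5(child)–C1(child)–Ox(parent)–Cx(parent),
* `psi` = C1(child)–Ox(parent)–Cx(parent)–C(x−1)(parent),
* `omega` = O6–C6–C5–O5 of the parent, only for 1→6 linkages,

and for the protein root `phi` = O5–C1–ND2–CG, `psi` = C1–ND2–CG–CB.  All
angles are degrees in [−180, 180).  Exocyclic hydroxyls (and the free
hydroxymethyl) are additional side-chain torsions.  The glycosidic bridge is
idealized: C1–Ox 1.40 Å with a 117° C–O–C angle (1.45 Å / 124° at ND2).
Because the templates and the bridge geometry are idealized rather than
force-field-relaxed, torsion values live in this package's own frame; they
are internally consistent (build → measure round-trips to 1e-6°) but not
numerically interchangeable with torsion statistics from other software.

Setting a torsion rotates exactly the distal subtree about the bond, so
edits are local, bond geometry is preserved to machine precision, and the
same pose can be rebuilt bitwise from its torsions.

### Conformer libraries from adaptive circular KDEs

Torsion observations for each chemically distinct linkage pair (e.g.
`a-D-Manp-(1->3)-b-D-Manp`) are smoothed with von Mises kernels.  The
estimate is adaptive in the Abramson sense: a pilot fixed-concentration
estimate $\tilde f$ at $\kappa_0$ is evaluated at each observation, the
local factor is $\lambda_i = (\tilde f(\mu_i)/g)^{-\alpha}$ with $g$ the
geometric mean of the pilot values, and the per-observation concentration is
$\kappa_i = \kappa_0 / \lambda_i^2$ — concentration playing the role of
inverse squared bandwidth.  Defaults: $\alpha = 0.5$; $\kappa_0 = 50$ for
$n \ge 100$ observations, else 20.  $\alpha = 0$ recovers the
fixed-bandwidth estimate exactly.  Densities are cached on a 1° grid (360
points) for the sampler; the exact kernel sum remains available and the two
agree to interpolation error (&lt; 1e-3 of the density scale).  For
$n > $ a few thousand the pilot is evaluated on the grid and interpolated at
the observations, keeping the fit $O(nP)$.

Conformers are built per torsion: the local maxima of each torsion's KDE on
the grid are its modes, the probability mass of a mode is the integrated
density over its watershed basin (every grid point assigned to the mode
reached by steepest ascent — robust to numerically flat tails), and the
basin's circular standard deviation records its width.  A linkage's
conformers are the cross-product of per-torsion modes with mass equal to the
product of basin masses, filtered at `min_mass` (default 0.01) and sorted by
mass.  A joint multi-dimensional KDE would capture phi/psi correlation that
this per-torsion treatment ignores; it is a known limitation, not
implemented.

The statistical torsion energy is $E(\theta) = -\ln(f(\theta)/f_{max})$,
zero exactly at the global mode and capped through a density floor of 1e-8
per radian, so it is finite everywhere.

### Score function

The total score is a weighted sum with defaults
`w_sugar_bb = 1.0, w_rep = 0.55, w_atr = 0.2, w_hbond = 1.0` (and
`w_density = 20` when a map is supplied):

* **sugar_bb** — the KDE torsion energy summed over unmasked residues;
* **sterics** — a capped Lennard-Jones-like pair term over heavy atoms
  (contact distance = sum of element radii, C 1.70 / N 1.55 / O 1.52 /
  S 1.80 Å; repulsion $(r_0/r)^{12}-1$ capped at 10 per pair; attraction
  $-(r_0/r)^6$ tapered to zero over 5–6 Å), excluding pairs within three
  covalent bonds.  The chemical bond list is carried on the pose, so a
  non-bonded clash at bonding distance is still scored as a clash;
* **hbond** — a geometric donor–acceptor term, −1 at ideal geometry
  (2.9 Å donor–acceptor, 180° at the hydrogen), cosine-smoothed windows on
  2.6–3.4 Å and above 120°;
* **density** — minus the real-space Pearson correlation between the map
  and a model-simulated map over voxels within 2.5 Å of the scored atoms.

This potential is deliberately simple — no solvation, no electrostatics, no
aromatic CH–π term — and is not an all-atom force field.  Its job is to
separate conformer basins from clashes during sampling, and the package's
recovery experiments measure exactly that.  Protein–protein pairs are never
scored (a constant during glycan sampling).

### The sampler and the build schedule

Each Monte Carlo cycle draws one move kind with configured probabilities
(defaults: conformer 0.30, single-torsion KDE draw 0.30, local grid refine
0.20, exocyclic chi 0.20), applies it to a uniformly chosen residue, and
accepts by the Metropolis criterion at `kT_mc = 1.0`.  The single-torsion
KDE draw is an independence proposal, so its acceptance carries the
Metropolis–Hastings correction for the proposal density; without it the
chain would converge to the squared density rather than the Boltzmann
target, which the stationary-distribution test would catch.  The conformer move
draws a conformer weighted by mass and jitters each torsion with a Gaussian
of the basin's sd (clipped at two sd); the local refine grid-searches each
torsion over ±15° in 3° steps and keeps the total-energy argmin — it is the
torsion-space stand-in for the gradient minimization a full force field
would provide.  Protein side-chain repacking is likewise out of scope (the
scaffold is fixed).  The sampling budget of every optimize event is
`rounds_per_residue × (number of residues in the event)`, so total effort
scales linearly with glycan size.

The modeler first places the full tree, randomizes every backbone torsion,
and masks all residues from scoring.  It then walks the layer schedule
(layers = graph distance from the root): build a block of `layer_window`
layers (unmask it), optimize the new block, optimize everything built so
far, and after the last layer run a final optimization of the whole tree.
The decoy is the lowest-energy pose encountered during that final full-tree
optimization — earlier stages score partial trees, so their energies are not
comparable.  Masking rather than deleting unbuilt residues keeps the
kinematic bookkeeping trivial; masked residues contribute to no energy term,
which the tests verify directly.  `layer_window = Inf` collapses the
schedule to a single sampler-only pass, the "GS-only" kinematic variant.
An ensemble runs decoy $i$ at seed `seed + i`; the reported model is the
lowest-energy decoy (ties go to the earlier decoy id).

### Decoy analytics

Heavy-atom RMSDs are computed fixed-frame (no fitting; both poses share the
protein frame) and superimposed (Kabsch SVD fit on the glycan selection, so
the value reflects internal structure only); the root RMSD covers the first
two residues from the root.  Funnel quality is summarized by
$P_{near} = \sum_i e^{-r_i^2/\lambda^2} w_i / \sum_i w_i$ with Boltzmann
weights $w_i = e^{-(E_i - E_{min})/kT}$; `kT_pnear` defaults to 0.62 (a
common packing-energy convention — the choice only rescales how sharply low
energies dominate) and $\lambda \in \{1, 2.5, 5\}$ Å.  Enrichment is the
fraction of decoys under an RMSD cutoff.  A residue-inclusion mask replaces
any density-based residue filtering: which residues enter the RMSD is the
caller's decision.

## The synthetic data generator

No experimental data ships with the package.  The generator provides:

* **torsion observations** — seeded von Mises mixtures per linkage type,
  with curated basin centers for the common N-glycan core linkages and a
  deterministic fallback for any other key.  Concentrations (κ 20–35,
  circular sd roughly 10–14°) mimic the scatter of well-ordered crystal
  structures; the 1→6 omega is bimodal (gg/gt at 0.65/0.35), so the
  Man3GlcNAc2 fixture genuinely exercises multi-conformer sampling.  Basin
  centers are expressed in the package's own torsion frame and were chosen
  once, by scanning the sterically allowed regions of the idealized
  geometry, to represent a realistic, extended, clash-free glycan;
* **a toy scaffold** — an ideal polyalanine helix (phi −57, psi −47) or
  strand with one Asn whose rotamer (chi1 150, chi2 −30) leaves the
  attachment cone open;
* **the reference complex** — the tree built at its top conformer-mode
  combination, asserted clash-free (steric repulsion below threshold, next
  combination tried otherwise);
* **simulated density** — per-heavy-atom isotropic Gaussians with
  σ = resolution/3 on a regular grid; a crude but deterministic stand-in
  for a 2 Å experimental map (no B-factors, no Fourier truncation, no
  noise).

What passing the recovery tests shows, therefore, is that the sampler and
score discriminate and reach the basins the library encodes on a clean,
idealized system.  It does not show performance on real crystallographic
data: real maps are noisier, real torsion statistics are broader and
correlated across phi/psi, real proteins offer competing interaction
surfaces, and the fixture's native was itself built from the library's
modes.  The scaled-down problem sizes (a 5-residue Man3GlcNAc2 core on a
12-residue helix, ensembles of 20 decoys, 10-batch seed batteries,
`rounds_per_residue = 15`) are the package's chosen study conditions; they
give stable recovery statistics in minutes on one core.

## Numerical choices and degenerate inputs

* Angles normalize to [−180, 180); −180 is the canonical image of +180.
* The KDE grid has 360 points; conformer modes are grid points, so "energy
  zero at the mode" is exact on the grid.
* Torsion rotations re-measure after applying the delta and retry with the
  opposite sign if needed, so a set is exact regardless of axis orientation
  conventions; omega is set before psi before phi, each leaving the earlier
  ones invariant.
* Ties: sibling branches order by ascending parent position; equal-mass
  conformers order by angle; equal-energy decoys by decoy id.
* Degenerate inputs raise early, named errors: empty observation sets,
  torsion maps missing a node, linkage keys absent from a library, density
  selections fully outside a map (warning + zero correlation), conformer
  tables with malformed lines (reported with their line number).
* Single-residue trees have a one-block schedule; `n = 0` draws return
  empty vectors; zero sampling rounds return the input pose unchanged.

## Known limitations

Ring pucker is never sampled; the score has no solvation or electrostatics;
per-torsion conformers ignore phi/psi coupling; PDB input trusts LINK
records (or a 1.6 Å distance rule) for connectivity and does not read
mmCIF; the sequon "enhanced" motif defaults to F at n−2 and is configurable
because conventions differ; protein side chains never move.  The
benchmarking utilities measure recovery of the package's own synthetic
natives, which is a calibration exercise, not a claim of accuracy on
experimental structures.

## A worked example

```{r example, eval = FALSE}
lib <- default_library()
scaffold <- make_toy_scaffold("helix", 12, 6)
tree <- parse_iupac(
  paste0("a-D-Manp-(1->3)-[a-D-Manp-(1->6)]-b-D-Manp-(1->4)-",
         "b-D-GlcpNAc-(1->4)-b-D-GlcpNAc"),
  attachment = list(chain = "A", resno = 6, atom = "ND2"))
native <- make_reference_complex(tree, scaffold, lib)

cfg <- modeler_config(n_decoys = 20, seed = 42)
recs <- generate_ensemble(scaffold, tree, cfg, lib, native = native$pose)
best <- select_best(recs)
best$metrics$rmsd_super   # internal accuracy of the best-scoring decoy
rmsds <- vapply(recs, function(r) r$metrics$rmsd_fixed, numeric(1))
energies <- vapply(recs, function(r) r$energy$total, numeric(1))
pnear(rmsds, energies, lambda = 1)
enrichment(rmsds)
```
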