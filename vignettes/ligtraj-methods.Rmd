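---
title: "ligtraj: models, conventions and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ligtraj: models, conventions and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`ligtraj` implements the trajectory- and pose-analysis layer of a
receptor–ligand binding-site study: given molecular-dynamics ensembles of a
seven-transmembrane receptor (the motivating system is the *C. elegans*
diacetyl receptor ODR-10, with butane-2,3-dione as the ligand), it measures
structural stability (RMSD, per-region RMSD share, RMSF), ligand conformer
populations (the O–O distance descriptor, PCA, k-means), docking-box
geometry and pose statistics, residue–ligand contact occupancies, and the
contact-loss metrics of a computational alanine scan. Force-field MD,
docking search/scoring and MM/PBSA evaluation are out of scope; the package
analyses their outputs.

## Units and numbering

All internal coordinates are nm and all times ns. Ångström appears in
exactly two places: PDB/pose file I/O (divided by 10 on read) and the
docking-box output, which follows the docking-engine convention. Residues
are numbered 1-based as in the source file, with no renumbering; a residue
is identified throughout by the key `"<chain>:<seq>"`.

## Superposition and the RMSD-share metric

Superposition is the SVD form of the Kabsch algorithm with the determinant
correction that excludes reflections. RMSD series fit and measure on the
same atom selection by default, mirroring standard MD-suite RMSD tools; the
two-selection signature (`fit_selection` / `measure_selection`) exposes the
alternative convention. "Backbone" means N, CA, C, O. RMSD is unweighted by
default with a per-atom weights hook, since the source analyses do not state
mass weighting.

The attribution metric for a region *R* is, per frame,

share(R) = 100 × (1 − RMSD(backbone ∖ R) / RMSD(backbone)),

with frames whose full-backbone RMSD falls below 1e-6 nm (in practice the
reference frame) skipped and counted. RMSF is computed after per-frame
fitting, as the RMS deviation of each atom from its time-average fitted
position, averaged unweighted over a residue's selected atoms.

## Conformer descriptors

The diketone's two carbonyl oxygens give a one-dimensional conformer
descriptor: a frame is **cis** iff the O–O distance is ≤ 0.32 nm
(inclusive — the boundary value classifies as cis), else **trans**; the
trans well sits near 0.35 nm. PCA runs on ligand heavy-atom coordinates
after Kabsch alignment of every frame to a reference frame (frame 1 by
default; hydrogens are excluded by default since the source protocol does
not state their treatment). Clustering is k-means with k-means++ seeding,
Lloyd iterations and best-of-50 restarts at a fixed default seed (1234);
k defaults to 3, the number of visible clusters in the motivating ensemble.
The "centroid conformation" of a cluster is the *medoid* — the real frame
nearest the centroid in the embedding, ties to the lower frame index — so
the reported conformation is always physically valid.

## Docking geometry and poses

The search box is built by the two-centroid protocol: the midpoint of the
Cα centroids of the transmembrane and extracellular residue sets, after
rotating the receptor so its principal axis lies on z (sign convention:
positive z toward the extracellular centroid). Box dimensions default to
15 × 15 × 25 Å read as **total edge lengths** (the docking-engine box
convention); a `half_extent` flag provides the doubled reading because the
prose protocol is ambiguous on this point.

Pose files are PDBQT-style multi-model files with a
`REMARK VINA RESULT: <affinity>` line per pose. Affinity filters are
strict: "better than −2 kcal/mol" keeps affinity < −2; the negative-control
group keeps affinity > 0. "Most representative pose" is not defined in the
motivating study; this package operationalizes it as the pose maximizing
the mean Jaccard similarity of its residue-contact set to all other poses'
sets, with ties broken by best (lowest) affinity and then file order. This
definition is a design choice of the package and is documented as such.

## Contact statistics

A residue is in contact with the ligand when any of its heavy atoms is
within 0.4 nm (4 Å) of a ligand heavy atom (all-atom mode by flag).
Interaction probability is the percentage of window frames with contact;
the default equilibrium window discards the first 25% of frames, and
absolute windows are expressible in config. Hydrophobic occurrence counts
frames with at least one C–C pair within 0.4 nm. Hydrogen bonds use the
standard geometric criterion of MD-suite H-bond tools — donor–acceptor
≤ 0.35 nm and H–donor–acceptor angle ≤ 30° — because the source names the
tool but not the numbers. Conserved-contact fraction is
100 × |frame ∩ reference| / |reference| with the reference taken from a
docking pose's initial contacts (or a different pose's, for the cross-pose
variant).

Distance scans are vectorized whole-array arithmetic rather than a
cell-list grid: at the package's target sizes (10²–10³ receptor atoms × a
small ligand × 10³–10⁴ frames) the constant-factor-fast vectorized scan is
the idiomatic R choice, and the brute-force double loop is retained in the
test suite as an independent oracle.

## Alanine scanning

Mutants are built by side-chain truncation: atoms beyond CB removed, CB
kept (or placed at ideal tetrahedral geometry from N/CA/C when absent, as
for glycine), residue renamed ALA, backbone coordinates bitwise untouched.
Contact loss at the mutated position is 100 × (wt − mut)/wt on occupancy
percentages; site-wide loss is the same ratio on *mean per-frame contact
counts* summed over the binding-site residues, so WT and mutant runs of
different lengths are comparable (the motivating study compares a 1 μs WT
run with 100 ns mutant runs). MM/PBSA energies are never computed — only
external per-frame tables are summarized into boxplot statistics.

## The synthetic world

The generator emulates exactly the statistics the pipeline measures, and
nothing else: no energies, membrane or solvent. Its defaults are the stated
conditions of the motivating study:

* ten pocket residues with contact occupancies 0.960, 0.918, 0.995, 0.989,
  0.995, 0.999, 0.949, 0.975, 0.987, 0.992 (the bound-complex occupancy
  table);
* bound-ligand cis probability 0.69 (solution-state ensembles use 0.035,
  docking-pose sets 0.40);
* a region layout with extracellular, transmembrane and H8 segments, the
  H8 analogue being the mobile region;
* positional noise σ = 0.01 nm per coordinate and mobile amplitude
  0.1 nm — a stable transmembrane core with a visibly mobile terminal
  helix;
* pose affinities drawn Normal(−2.5, 2.0) kcal/mol, giving roughly 78% of
  poses below 0 and 60% below −2 kcal/mol, the shape of the observed
  affinity distribution.

Contacts are realized geometrically with guaranteed margins: an in-contact
pocket residue has its Cα 0.2 nm from the ligand centroid (some ligand atom
is always within 0.4 nm of it, for any ligand orientation), an out-of-contact
residue sits 1.2 nm away, and generation errors by residue name if the
noise level makes either guarantee fail. Occupancy recovery is therefore
*exact* with respect to the realized Bernoulli draws — the only estimation
error is binomial. Frames are independent by default (binomial tolerances
are then exact); an optional Markov persistence parameter exists because
real MD contacts are autocorrelated, but tests use the independent mode.
Cis/trans templates have O–O distances 0.272 nm and 0.344 nm, safely on
either side of the 0.32 nm threshold at the default noise.

What a green test does **not** establish: the generator has no
conformational coupling between contacts, no ligand diffusion, no
autocorrelation (by default) and rigid internal ligand geometry, so
agreement on synthetic data validates the estimators, not the physics of
any particular system.

### A known red acceptance property

One stated acceptance property — mobile-region RMSD share above 95% when
the mobile amplitude is 10 × noise — is not attainable in this stated
world, and the corresponding test is left failing rather than recalibrated.
With i.i.d. jitter σ on every atom in both the frame and the reference,
the excluded-region RMSD has a floor of σ√6, while the full-backbone RMSD
is at most about √(2f(1−f))·A for mobile fraction f; at A = 10σ the share
is bounded near 67% even at the optimal f = 0.5, and measures 43% on the
default layout (f ≈ 0.13). Reaching 95% requires A ≈ 50σ. The share metric
itself is verified independently against a closed-form two-domain fixture
to 1e-9.

## Numerical choices

* Kabsch requires ≥ 3 non-collinear points; collinear clouds error.
* Zero-RMSD frames in the share series: skipped at tolerance 1e-6 nm,
  with a skipped-frame count attached to the result.
* k-means restarts re-seed empty clusters from a random point; the best
  inertia over restarts wins; everything is deterministic given the seed,
  and the caller's RNG stream is restored afterwards.
* Frame sampling (`sample_frames`) exposes both boundary conventions
  (`time >= discard` and `time > discard`) because sampling every 20 ns of
  a 1 μs run "disregarding the initial 200 ns" is boundary-sensitive:
  enumeration gives 41 structures at `>=`, 40 at `>`, and neither
  convention reproduces a printed count of 42; the operation leaves the
  choice to the caller.
* PCA on an ensemble of identical frames returns zero variances with a
  warning rather than erroring.

## Limitations

Native trajectory formats are multi-model PDB and a documented plain-text
frame format; compressed MD formats (XTC/TRR/DCD) must be converted by an
external adapter first, which keeps the package free of binary-format
dependencies. No PBC unwrapping is performed — inputs are assumed to be
whole molecules. Contact classes beyond generic/hydrophobic/H-bond
(π-stacking, salt bridges) are not detected, and no free energies are
computed anywhere.
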