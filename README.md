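# pmhctk

An R toolkit for the integrative solution-state characterization of
peptide/class-I major-histocompatibility (pMHC-I, peptide/HLA) complexes.
It reimplements, as tested reusable functions, the analysis layer that sits
downstream of the wet-lab and simulation engines in studies of neoepitope
presentation — for structural immunologists and biophysicists who have NMR
peak lists, restraint files, docking-decoy sets, HDX-MS centroid tables,
trajectory frame ensembles, or binding-predictor output, and want the
published bookkeeping reproduced exactly.

## What it computes

**Structure (`structio`)** — multi-model PDB/mmCIF coordinate handling;
SVD (Kabsch) least-squares superposition with reflection correction; RMSD
and ensemble RMSD summaries (to-reference and mean-pairwise conventions);
per-atom/per-residue RMSF; φ/ψ/χ1 dihedrals with IUPAC sign convention;
Ramachandran favored/allowed/outlier masks per residue class; 3.5 Å
peptide-groove contact lists; a simplified heavy-atom clash score
(clashes per 1000 atoms with a shipped van der Waals radius table).

**Restraints & decoys (`restraints`)** — the Rosetta `AtomPair ... BOUNDED`
restraint dialect with NMR pseudo-atom (methyl/aromatic) expansion;
ambiguous effective distances `d_eff = (Σ d⁻⁶)^(−1/6)`; flat-bottom
violation reports; decoy filtering (violators out, survivors sorted by
energy); energy-vs-RMSD funnel landscapes to the lowest-energy decoy;
greedy quality-threshold clustering (radius 2.3 Å, top 500, ≤5 clusters of
≤10 by default, ties broken by energy then tag).

**NMR observables (`nmr_obs`)** — methyl chemical-shift perturbations
`Δδ = sqrt((ΔδH² + ΔδC²/4)/2)`; mean±SD outlier/broadening flags with
excluded-probe bookkeeping; single-phase exponential association kinetics
(`t½ = ln2/k`); Boltzmann sigmoid melting curves (T_m); percent-empty
receptor from DSF fluorescence; the one-site two-ligand competition
equilibrium solved to machine precision and IC50 fitting of anisotropy
displacement series.

**HDX-MS (`hdx`)** — back-exchange-corrected percent deuterium uptake from
all-H/all-D reference centroids (both readings of the correction formula;
`span` default), uptake curves with replicate SD, residue-resolved uptake
maps from overlapping peptic fragments (uniform or length-weighted
averaging), and Welch + Brown–Forsythe heteroscedastic one-way ANOVA for
between-state comparisons.

**Trajectory statistics (`dynamics`)** — equally-spaced frame subsampling;
replicate-averaged RMSF; circular dihedral order parameters
`S² = ⟨cosθ⟩² + ⟨sinθ⟩²`; two-stage single-linkage clustering (backbone
0.5 Å, then heavy-atom 1.0 Å inside each backbone cluster, occupancies
relative to the grand frame total); water-occupancy voxel grids (1 Å
spacing, 1 Å atom radius, 5 Å inclusion) written as OpenDX maps.

**HLA repertoire (`repertoire`)** — BLOSUM62 pseudo-groove similarity
normalized to the reference self-score; strong/weak/non binder calls from
percentile ranks (0.5/2.0 defaults); Kullback–Leibler sequence-logo
matrices; population-frequency joins with stable missing-last sorting.

**Synthetic data (`synthgen`)** — seeded, byte-reproducible generators for
every input above (funnel decoy sets with exact violator counts, Markov
switching trajectories, per-residue-rate HDX tables, two-state peak lists,
decays, melts, competition series, water frames with exact voxel
occupancies), each returning a `GroundTruth` record of all latent
parameters.

## Worked example

Filter a synthetic 100-decoy docking set against its NOE restraints, plot
the energy funnel, and resolve an HDX protection pattern:

```r
library(pmhctk)

g <- gen_decoy_set(seed = 42, n = 100, violation_fraction = 0.37)
reports <- evaluate_violations(g$decoys, g$restraints, tolerance = 0.5)
names(reports) <- g$scores$tag
kept <- filter_decoys(g$scores, reports)
nrow(kept)
#> [1] 63

land <- energy_landscape(kept,
          ensemble(g$decoys$models[match(kept$tag, g$scores$tag)]),
          sel = atom_select(chain = "C", class = "backbone-no-O"))
head(land, 3)
#>          tag       rms    energy
#> 1 decoy_0017 0.0000000 -302.1849
#> 2 decoy_0014 0.3183938 -299.8913
#> 3 decoy_0054 0.2752973 -296.5411
```

37 programmed restraint violators are removed exactly; the surviving
landscape is anchored at the lowest-energy decoy (rms 0 by definition),
and the funnel slope (here 5 REU/Å by construction) is visible in the
rms/energy columns.

```r
gh <- gen_hdx_dataset(seed = 7, noise_sd = 0.02)   # protected span 11-20
curves <- build_uptake_curves(gh$fragments, gh$config)
map <- residue_resolve(curves, protein_length = 30, time_s = 600)
mean(map$uptake[11:20])                            # protected residues
#> [1] 26.8
mean(map$uptake[setdiff(which(map$covered), 11:20)])
#> [1] 71.2
```

The 100-fold protection factor programmed into residues 11–20 appears as
~27% resolved uptake at 600 s versus ~71% for exposed residues — the
residue-level readout used to paint uptake onto structures.

## Command line

A thin `pmhc` front end (installed under `inst/cli/pmhc.R`) exposes the
main pipelines:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/pmhc.R", package="pmhctk"))')" \
    decoys filter --cst contacts.cst --scores scores.sc --tol 0.5 decoys.pdb
```

Groups: `struct` (rmsd/rama/contacts/clash), `decoys`
(filter/landscape/cluster), `hdx` (curves/resolve), `hla`
(similarity/classify/logo), `sim` (seeded generators with ground-truth
JSON).

## Design notes

The methods vignette (`vignettes/pmhctk-methods.Rmd`) documents the models
and their assumptions, every tunable default with units, what the
synthetic generators emulate (and what they deliberately do not), and the
numerical choices — correction-formula variants, clustering tie-breaks,
order-parameter estimator, Ramachandran mask provenance.
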