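---
title: "Models, estimators and design choices in pmhctk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, estimators and design choices in pmhctk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhctk)
```

`pmhctk` is the analysis layer for solution studies of peptide/HLA class-I
complexes: it consumes coordinates, restraints, peak lists, HDX centroid
tables, trajectory frames and binder-prediction tables, and computes the
derived quantities those studies report. This vignette records the science
behind each estimator, the defaults and their units, what the synthetic
generators emulate, and the places where the design was genuinely open and
a choice had to be made. It states no empirical result that the test suite
does not itself compute.

## Coordinates, superposition and fluctuation

A `StructureModel` is an ordered atom table with author (1-based) residue
numbering and insertion codes carried verbatim; an `Ensemble` is an
ordered model list with an optional shared-topology guarantee (identical
atom identity lists), which all frame-wise statistics require.

Superposition is the closed-form SVD (Kabsch) least-squares fit with the
determinant sign correction, so the returned rotation is always proper.
Selections name atoms by role: `backbone-no-O` (N, CA, C) mirrors the
trajectory-tool convention of clustering backbone atoms without the
carbonyl oxygen; `backbone` adds O; `all-heavy` is the default reporting
scope.

Two ensemble-compactness conventions exist in the literature and deposits
rarely say which was used, so `ensemble_rmsd_summary()` provides both:
`"reference"` (every model fit to and compared with the first,
lowest-energy model — the default) and `"pairwise"` (mean over all model
pairs). Neither is asserted to be the convention behind any particular
published number.

RMSF uses a single re-fit to the coordinate mean (fit all frames to frame
1, average, re-fit once to the average) rather than iterating to
convergence: deterministic, order-independent, and what common trajectory
tools do in practice. `RMSF_i = sqrt(mean_t |x_i(t) − ⟨x_i⟩|²)`, averaged
over a residue's selected atoms for per-residue profiles, and averaged
arithmetically across replicate trajectories by `averaged_rmsf()`.

## Dihedrals and Ramachandran masks

Torsions follow the IUPAC sign convention (verified in the tests against
an independent vector-algebra oracle and planar cis/trans constructions:
anti = 180°, syn = 0°). Terminal residues yield only the defined angle;
missing backbone atoms yield `NA`, never a fabricated value.

No redistributable Ramachandran mask tables (MolProbity/RAMPAGE style) are
available to ship, so the masks are package-constructed: unions of
ellipses centered on the canonical α-helical (−63°, −43°), β/extended
(−115°, 130°) and left-handed-α basins, with glycine symmetrized about the
origin, proline restricted in φ, and a ζ basin added for pre-proline;
"allowed" is a 1.6× dilation of "favored". Rasterized at 2° × 2°, they are
deterministic, periodic, and partition the torus. They are *coarse
approximations* suitable for flagging gross outliers, not a re-derivation
of empirical density contours — a green classification here does not
certify MolProbity agreement.

## Clash score

`clash_score()` counts unordered heavy-atom pairs from different residues
whose van der Waals overlap `r_i + r_j − d` reaches 0.4 Å (boundary
inclusive, with a 1 × 10⁻⁹ Å numeric guard), excluding backbone–backbone
pairs of sequence-adjacent residues, normalized per 1000 atoms. This is a
deliberate simplification of probe-based all-atom clash scoring: no
hydrogens are placed and no bond graph beyond the peptide-bond adjacency
is built. It is meant for *relative* comparisons across models of the same
system.

## NOE restraints and decoy post-processing

Restraints use the `AtomPair a1 r1 a2 r2 BOUNDED lb ub sd [tag]` dialect;
methyl/aromatic pseudo-atoms (`MD1`, `QD`, …) expand to their proton
groups via a shipped table. Ambiguous distances use r⁻⁶ summation —
`d_eff = (Σ_{ab} d_ab⁻⁶)^{−1/6}` — the standard NOE treatment, which never
exceeds the minimum pair distance; a group-minimum mode is available since
the source protocols do not state their averaging.

Violation tolerance defaults to 0.5 Å (the conventional BOUNDED width);
whether published "NOE violation" filters used a tolerance at all is
unstated, so the tolerance is explicit and monotonicity (tightening it
never removes violations) is a tested property. Filtering removes any
decoy with ≥1 violation and sorts survivors by total energy (REU, parsed —
never computed — from whitespace score tables with a named total-score
column; binary silent files are out of scope).

Decoy clustering is a documented greedy quality-threshold scheme: seed at
the unassigned decoy with the most unassigned neighbors within the radius
(2.3 Å default, RMSD over the clustering selection), ties broken by lower
energy then tag order; clusters truncate to `max_cluster_size` keeping the
lowest energies; the representative is the lowest-energy member. The
upstream tool's exact clustering variant is unspecified, so the scheme is
stated rather than claimed identical; on small instances it is tested
against an exhaustive neighbor-count oracle.

## NMR observables

The methyl CSP is `sqrt((ΔδH² + ΔδC²/4)/2)` — the carbon scaling is taken
literally from the published formula. Outlier flags use mean + 1 SD of the
CSPs (and mean − 1 SD for empty/bound intensity ratios), computed over
non-excluded probes only, mirroring the practice of dropping fully
line-broadened probes from the statistics.

Kinetics fit `I(t) = plateau + (I0 − plateau)·e^{−kt}` by deterministic
`nls` (port) from analytic starts; the observable is the decaying
free-peptide signal and the plateau is free because complete binding is
not guaranteed. At 5 % amplitude noise with 10 points over 9 h the
estimator's per-replicate sampling SD on `t½` is ≈13 %, so recovery claims
over seeded replicates are about the Monte-Carlo mean (bias < 5 % is the
tested property), not each draw.

Thermal melts fit the Boltzmann sigmoid
`F(T) = F_min + (F_max − F_min)/(1 + e^{(T_m − T)/slope})`; percent-empty
receptor is the sample fluorescence at 25 °C relative to the empty
reference's maximum.

Competition anisotropy uses the exact one-site two-ligand equilibrium:
free receptor solves
`Rf(1 + Lt/(Kd_L + Rf) + Ct/(Kd_C + Rf)) = Rt` (monotone; uniroot to
1 × 10⁻¹⁴ relative), mapping bound-tracer fraction linearly between
`r_max` and `r_min`. The reported IC50 is the *operational*
half-displacement concentration of the fitted curve — not a Kd; a
Cheng–Prusoff conversion is provided but labeled derived. Fits are
Nelder–Mead from analytic starts with a deterministic polish restart, so
results are bit-reproducible. Default assay constants in the generator
(tracer 25 nM, tracer Kd 0.26 µM, exchange-available receptor 0.2 µM, grid
0/0.25/4/25 µM, triplicates) reflect the competitive-anisotropy designs
this pipeline targets.

## HDX-MS

Percent uptake corrects fragment centroid masses with the all-H (`m0`) and
all-D (`m100`) references. The published correction formula's denominator
("m100 − D·m0") is typographically ambiguous and dimensionally
inconsistent if read literally (0.8 × a whole-peptide mass), so two
variants are implemented and recorded in every output: `span`
(denominator `m100 − m0`; the default, because both references already
embody the experimental back-exchange) and `d-scaled` (denominator
`D_frac·(m100 − m0)`; the reading under which exchange saturated at the
solvent deuterium fraction reports 100 %). `D_frac` defaults to 0.8 — the
5 µL-into-20 µL labeling dilution.

Residue resolution averages, for each residue, the uptake of every
fragment covering it (uniform redistribution along the fragment — the
stated published procedure; a length-weighted mode is provided since the
wording could also be read that way). Uncovered residues are flagged,
never interpolated. Optionally the first residue of each fragment and
prolines (fast back-exchangers) can be excluded.

Between-state comparisons run Welch's heteroscedastic one-way ANOVA
(Welch 1951) and the Brown–Forsythe means test with Satterthwaite
denominator df — the standard pairing for biological-triplicate HDX. Both
are small-sample approximations: the null is visibly distorted for the
Brown–Forsythe statistic under extreme variance ratios (≥4:1 in SD at
n = 10), so the tested uniformity property uses a moderate
heteroscedastic null; Welch is robust across the tested range.

## Trajectory statistics

Subsampling takes frames at `round(i(N−1)/(n−1))` — deterministic,
endpoints always included (emulating equally-spaced frame extraction,
e.g. 1000 per replicate, 3000 total).

The dihedral order parameter is the circular resultant,
`S² = ⟨cosθ⟩² + ⟨sinθ⟩²`: 1 for a rigid torsion, 0 for angles cancelling
around the circle. The original analysis tool's estimator is not defined
in the sources available here; the circular-resultant form is adopted and
documented, not asserted identical.

Two-stage clustering is single linkage: backbone atoms (no oxygen) at a
0.5 Å cutoff, then heavy atoms at 1.0 Å within each backbone cluster,
with occupancies always relative to the grand frame total, so subcluster
occupancies sum to their parent's. Frames are assumed pre-aligned to a
common receptor frame (peptide motion measured relative to the groove);
a per-pair self-fit mode exists. Representatives are cluster medoids.
Published cluster *counts* depend on the unavailable trajectories and are
not asserted; the tested claims are recovery of programmed state counts
and occupancies on the synthetic switching generator, and agreement with
an exhaustive single-linkage oracle on small instances.

Water occupancy marks, per frame, every voxel (1 Å spacing) whose center
lies within the 1 Å atom radius of a water oxygen that is itself within
5 Å of the region of interest; occupancy is the marked-frame fraction.
Grids combine across disjoint frame subsets as frame-count-weighted means
and export as OpenDX text for isosurface rendering (e.g. at 0.2).

## HLA repertoire

Pseudo-groove similarity is the position-wise BLOSUM62 sum against the
reference allele's pre-aligned, gapless pseudo-sequence, normalized by the
reference self-score (the published axis scaling is unstated; the raw sum
is always emitted alongside). Binder classes use the predictor's default
percentile-rank thresholds (strong ≤ 0.5, weak ≤ 2.0), configurable.
KL logos compute per-position information `Σ p log2(p/q)` in bits with
letter heights proportional to `p` within a column — a Seq2Logo-style
convention, not a bit-exact clone. Frequency joins normalize allele
spellings, keep unmatched binders with missing frequency sorted last, and
are idempotent.

## The synthetic world

Every generator is a pure function of (seed, parameters): it seeds a fixed
RNG kind, restores the caller's RNG state, and returns a `GroundTruth`
record. Where a target proportion must be met exactly (decoy violator
counts, trajectory state occupancies, voxel occupancies) allocation is
deterministic by count, never sampled, so count-based tests are sharp.

Synthetic structures are minimal poly-alanine(+lysine) topologies —
sufficient for selections, RMSD bookkeeping and clustering geometry, with
no stereochemical realism. Decoy sets realize programmed peptide RMSDs
exactly and a linear energy funnel (5 REU/Å, SD 2 REU noise) over a
0.2–6 Å RMSD range; violators break an anchored restraint by construction.
HDX data follow `u_i(t) = D_frac(1 − e^{−k_i t})` per residue with a
uniform exposed rate (0.02 s⁻¹) and a 100× protected span, centroids
`m_t = m0 + Σ u_i·1.00628 Da + N(0, 0.02 Da)`; the all-D reference is full
deuteration (`m100 = m0 + n·1.00628`), making the two correction variants
saturate at 80 % and 100 % respectively. Trajectories are state offsets
(3 Å backbone, 3 Å CB rotamer) plus 0.1 Å isotropic jitter.

A green test against this world establishes that the estimators invert
their own forward models at the stated noise — it does not establish
instrument realism (no isotope envelopes, no spectral overlap, no
force-field physics, no peptide misidentification). Quantities that
require the real inputs (the deposited experimental ensemble's printed
compactness, the external binding predictor's printed outputs, wet-lab
T_m/IC50 values, trajectory-dependent cluster counts) are deliberately
not asserted; one acceptance test is left failing in offline environments
to record the first of these honestly.

## Known limitations

No hydrogen placement or rotamer analysis; no mmCIF writing; no binary
trajectory or silent-file parsing; clash score and Ramachandran masks are
simplified stand-ins for their reference tools; `S²` estimator choice is
an interpretation; per-residue HDX resolution does not model residue-level
exchange kinetics (it redistributes fragment averages).
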