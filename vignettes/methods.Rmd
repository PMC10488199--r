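---
title: "Models and methods behind pumplipid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pumplipid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumplipid)
```

pumplipid packages the computational path by which lipid regulation of a
plasma-membrane proton pump is quantified: fluorescence-trace kinetics,
solubilization curve fitting, coarse-grained trajectory contact and
density analysis, conservation mapping, and group statistics. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Proton-pumping kinetics

In the ACMA assay, vesicle acidification quenches probe fluorescence.
Traces are normalized to the fluorescence **directly after Mg²⁺
addition** — implemented as the first sample at or after `t_mg`, not an
interpolated value, because acquisition is discrete (0.1 s resolution) and
the first post-addition sample is what an analyst would anchor to. The
pumping rate is the negated ordinary-least-squares slope over the first
30 s after `t_mg`, using every sample in the window.

A trace is **inactive** when the mean signal just before CCCP addition is
less than 10% below the post-CCCP plateau. Two windows are needed that the
assay description leaves open; we use the 5 s ending at `t_cccp` for the
"before" signal, and the last 5 s of the trace — constrained to start at
least 10 s after `t_cccp` — for the plateau, skipping the fast
re-equilibration transient. Exactly 10% below counts as active (the strict
reading of "less than 10% below"). Inactive traces are flagged, never
silently dropped, and are excluded from rate aggregation.

Fold changes are ratios of *means* of active replicate rates; medians and
quartiles are also reported (`boxplot_summary()`) for the boxplot view,
since display conventions use medians. Whether published fold ratios are
ratios of means or medians is ambiguous; we chose means, matching the use
of mean ± SE in the statistical analysis.

### The synthetic quench model and its curvature

`gen_acma_trace()` uses
$F(t) = p + (1 - p)\,e^{-k (t - t_\mathrm{mg})}$, with the quench constant
tied to the nominal rate by $k = r/(1-p)$ so that $F'(t_\mathrm{mg}) = -r$
exactly; after `t_cccp` the trace relaxes toward the recovery level with a
fixed 5 s time constant (the probe responds fast compared with pumping),
and never *downward* — an unquenched trace stays flat. Gaussian noise is
added last; a given config and seed is bitwise reproducible.

Because the quench is exponential, the 30 s OLS slope is biased toward
zero by curvature: to first order the fitted slope is
$-r\,e^{-kT/2}$ for window length $T$. This is a property of the
initial-slope estimator itself, not an implementation artifact, and the
tests therefore check the estimator against the closed-form OLS oracle
and this analytic value rather than against $-r$. For fold-change studies
the generator conditions give every condition the **same quench constant**
($k_0 = 0.006\,\mathrm{s^{-1}}$ by default, plateau set per condition as
$p = 1 - r/k_0$): faster pumping quenches to a proportionally deeper
plateau, which is also what real traces show, and the common curvature
factor cancels exactly in rate ratios. Under these conditions configured
ratios of 5.3 / 2.4 / 2.2 / 3.2 are recovered within a few percent from
nine 0.5%-noise traces per condition.

## Solubilization curves

Detergent titrations of liposome scattering follow the decreasing sigmoid
$y = \mathrm{Bottom} + (\mathrm{Top} - \mathrm{Bottom})\,/\,(1 +
e^{(x - V_{50})/\mathrm{slope}})$, fitted with Levenberg–Marquardt
(`minpack.lm::nlsLM`). Start values are `Top = max(y)`,
`Bottom = min(y)`, `V50` at the point nearest midrange and
`slope = range(x)/10`; on failure the start is jittered (±30%) for up to
five restarts. By construction the fitted curve passes through
$(\mathrm{Top}+\mathrm{Bottom})/2$ at $V_{50}$, which the tests assert,
and with 2% noise on 25 points $V_{50}$ is recovered well within 5%.

## Contact analysis

The contact statistic follows the rule: a residue–lipid contact exists in
a frame when a protein bead of the residue and a lipid **headgroup** bead
are within 0.55 nm of one another *and no other lipid is closer to that
residue*. Decisions taken where the wording is open:

* The bead pair is read as **one** protein bead plus one headgroup bead.
  The stricter reading (at least two protein beads within the cutoff of
  the nearest lipid) is available via `min_beads = 2`; the default stays
  with the single-pair reading because the sentence enumerates the
  members of a pair.
* Exclusivity is **global across species**: a closer PC lipid blocks a PS
  contact. This is the literal reading of "no other lipid" and makes the
  per-residue contact a categorical "which lipid is annular here" label,
  so per-frame contacts per residue never exceed one — an invariant the
  tests assert on every trajectory.
* Distances are minimum-image in x and y only; z is non-periodic. The
  bilayer is periodic in-plane, and image copies along z would be
  artifactual.
* Ties at exactly equal distance go to the lowest lipid id, making the
  engine deterministic.
* Contacts are computed on **raw** frames, densities on **aligned**
  frames: rigid-body superposition changes the lab frame, and must not
  change contact geometry, so contacts never see the aligned coordinates.

Probabilities are contact counts divided by the frame count; replicas are
concatenated before normalization (pass a list of trajectories).
Display thresholds follow the conventions of published contact maps:
probabilities above 15% are labeled, at or above 5% highlighted.

The engine is validated against an exhaustive $O(\mathrm{residues}\times
\mathrm{lipids}\times\mathrm{beads}^2)$ re-implementation of the rule on
hundreds of random multi-bead frames (exact set equality), and is
invariant under global translation with periodic wrapping.

## Superposition

`align_frames()` removes overall protein translation and rotation by
least-squares (Kabsch/SVD) superposition of the protein beads of every
frame onto frame 1, applying each frame's transform to all beads. The
rotation uses the determinant-corrected SVD solution, so reflections are
never introduced. A frame that is an exact rigid motion of the reference
realigns to RMSD below 10⁻⁹ nm, and superposition never increases the
protein RMSD — tests check this against a brute-force rotation grid.
Fewer than three non-collinear protein beads is an error.

## Densities, enrichment, and sites

2D maps bin the headgroup-bead centroid of each selected lipid (species ×
leaflet) into half-open square cells anchored at the box corner, average
counts over frames, and divide by cell area; the default spacing is
0.02 nm. 3D grids bin individual beads (all beads of a species, or
headgroups only) into 0.1 nm voxels. Both satisfy exact conservation —
`sum(values) * cell_volume == mean per-frame selected count` — to 10⁻⁹
relative, asserted on all fixtures. Grids export as flat TSV plus a JSON
header, and OpenDX text with the conventional display isovalues (3 nm⁻³
for headgroup grids, 4 nm⁻³ for all-bead grids).

Leaflets are assigned per frame: the midplane is the mean z of all
headgroup beads, a lipid is "upper" iff the mean z of its headgroups
exceeds it, ties to lower. This is robust for planar bilayers and is
exactly right for the generator geometry; strongly curved membranes would
need a local midplane, which is out of scope.

Enrichment divides each cell by the uniform expectation
$N_\mathrm{species,leaflet}/(L_x L_y)$, so 1 means no preference. By
default the map's own mean per-frame count supplies $N$; an explicit
count (e.g. from known composition) can be passed instead.

`find_sites()` smooths the enrichment map with a periodic Gaussian (σ = 2
cells), finds strict local maxima above `min_enrichment = 2`, merges
maxima within `merge_radius = 1` nm (greedy, by descending value, with
minimum-image distances), and attaches contact residues with probability
≥ 5% whose mean in-plane position lies within `capture_radius = 1` nm of
the enrichment-weighted centroid. Sites are labeled A, B, … by descending
peak value. No objective criterion for delimiting sites is published for
this kind of map, so all thresholds are parameters; at desk-scale frame
counts the background of the map is shot-noise dominated, and maxima
barely above the threshold should be treated as noise unless they
localize planted or replicated structure.

## The bilayer generator

`gen_membrane_trajectory()` emulates the *geometry and bookkeeping* of a
coarse-grained membrane-protein simulation, not its physics:

* 524 lipids by default, split symmetrically into two leaflets of 262;
  per-leaflet species counts follow the molar composition (10:90 PS:PC
  by default; 10:45:45 PS:PE:PC is the other studied mixture) using
  largest-remainder rounding with ties to the majority species, so counts
  are exact.
* The protein is a static circle of vertical helices (10 helices × 12
  residues by default, circle radius 2 nm — a P-type-ATPase-sized
  transmembrane footprint) spanning the bilayer; headgroups sit at ±2 nm
  from the midplane with three tail beads evenly spaced toward it,
  matching coarse-grained bilayer dimensions. The box (13 × 13 × 9 nm)
  gives the bulk area per lipid of a coarse-grained bilayer
  (≈0.64 nm²).
* Lipids perform leaflet-confined 2D Brownian steps (σ = 0.3 nm per
  frame, the in-plane displacement of a lipid between typical analysis
  frames) with periodic wrapping.
* Planted affinity sites ("hotspots") bias lipids of one species by
  rejection: a displacement that increases the distance to the nearest
  hotspot locus, starting from within its radius, is rejected with
  probability `strength/(1 + strength)`. Strength 0 is exactly the free
  walk (the rejection variate is always drawn, so random streams align
  across strengths and dose–response comparisons share randomness). The
  bias applies only to lipids in the **same leaflet** as the hotspot
  residues: binding sites are leaflet-specific, and without this
  restriction the mirror-image residues of the opposite leaflet would
  show equally strong contacts.
* One root seed drives the whole generator; identical configs are
  byte-for-byte reproducible.

What this does **not** emulate: excluded volume (lipids can overlap the
protein footprint), lipid flip-flop, protein dynamics, realistic force
fields, or membrane curvature. Passing tests therefore demonstrate that
the *analysis* recovers planted structure and respects its invariants,
not that the generator reproduces membrane physics. With strength 10 and
radius 1 nm, planted residues carry >90% PS contact probability and are
exactly the top-ranked contact set, and site centroids localize to within
1 nm of the planted loci in ≥95% of seeded runs; the package's
acceptance checks measure precisely that.

Sampling note: successive frames are autocorrelated (a lipid takes
several frames to diffuse across the 0.55 nm contact shell), so binomial
standard errors on contact probabilities understate the truth by roughly
√(2τ+1) with τ ≈ 3 frames; uniformity tests use this deflation.

## Conservation

Columns are scored with the unweighted entropy measure of the AL2CO
family: $1 - H/\ln 21$ with Shannon entropy over the 20 amino acids plus
gap as a 21st symbol. Counting gaps penalizes gappy columns, which is the
desired behavior when asking "is this contact residue invariant"; a
column is reported `identical_in_all` only when gap-free and single-
valued. Which AL2CO variant (entropy/variance/sum-of-pairs, weighted or
not) published figures used is not documented; the unweighted entropy
variant is the simplest defensible choice and sequence weighting is out
of scope. Alignment columns are indexed 1-based, as is idiomatic in R.

No live sequence retrieval is performed. The packaged
`ptype_A1_block_synthetic.fasta` is a **synthetic** eight-sequence block
(plant and fungal H⁺-ATPases plus SERCA and Na,K-ATPase stand-ins, as the
file's ids suggest) constructed so that exactly one contact-residue
column — the arginine at reference position 842 — is invariant across all
sequences, emulating the structure of the published comparison for
testing. `site_report()` takes a `ref_offset` so windows of a longer
reference sequence can be analyzed without shipping full-length
sequences.

## Group statistics

One-way ANOVA uses the classical decomposition (`stats::aov`); Tukey HSD
uses `stats::TukeyHSD`, which applies the Tukey–Kramer standard error for
unequal replication — the realistic case, since reconstitutions are
measured unequal numbers of times. Each measured trace is one
observation; averaging replicate measurements per reconstitution first is
a pseudo-replication decision the data description leaves open, and can
be done upstream of these functions if desired. Tests verify the p values
against an independently hand-coded Tukey–Kramer oracle (means, pooled
MSE, studentized range) to 10⁻⁶ and the balanced two-group equivalence
q = t√2.

Compact letter displays assign one letter per clique of the
non-significance graph: maximal cliques are enumerated
(`igraph::max_cliques`) and the smallest subfamily covering every
non-significant pair and every group is selected (exhaustively for up to
16 cliques, greedily beyond). Two groups share a letter **iff** they are
not significantly different; tests verify both directions on random
significance patterns and letter-count minimality by enumeration for up
to five groups. Quartiles use linear interpolation between order
statistics (quantile type 7), whiskers are the extremes, and significance
tiers are reported at 0.05/0.01/0.001.

## Pipeline and problem sizes

`run_pipeline()` executes kinetics → membrane → conservation from one
validated YAML config, writing TSV/JSON/OpenDX outputs, a structured log
(timestamp, stage, level, message, with enough parameters to re-run any
stage), and a manifest with md5 checksums; identical config and seed
reproduce identical checksums for the deterministic stages. Validation
collects *all* violations before refusing to run. CLI flags live in the
thin wrapper `inst/cli/pumplipid.R`.

The shipped tests and the acceptance script run at desk scale: 2000-frame
null bilayers for uniformity checks, 400-frame hotspot runs, 9 traces per
condition, 25-point titrations, chosen so the whole suite completes in a
few minutes while leaving comfortable statistical margins. Production
analyses of multi-microsecond trajectories use the same code paths with
more frames; only wall time changes.

## Known limitations

* XTC trajectories are not read; use multi-frame GRO or multi-MODEL PDB.
* The generator's lipids ignore excluded volume; annular density around
  the protein is therefore flat under the null, whereas real proteins
  deplete their footprint.
* Entropy conservation is unweighted; highly redundant alignments will
  overstate conservation.
* Site calling at low frame counts is shot-noise limited (see above).
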