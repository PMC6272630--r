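---
title: "Evaluating docking protocols with benchpose: models, metrics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating docking protocols with benchpose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benchpose)
```

## The problem

Structure-based virtual screening stands or falls with the docking
protocol — the pairing of a search algorithm with a scoring function —
used to place and rank candidate ligands in a binding site. Before
committing a large library to one protocol, practitioners run a
*self-docking* (redocking) benchmark: each co-crystallized ligand is
docked back into its own protein structure, and every returned pose is
compared with the crystallographic binding mode. benchpose implements
the analysis side of such a benchmark: the geometry, the per-cell
quality metrics, the rank aggregation, the colour-map reports, a
simulator for license-constrained job dispatch, and the post-processing
utilities a subsequent screening campaign needs. The docking engines
themselves are out of scope — pose sets arrive as SDF files, from
whatever engine produced them, or from the package's own synthetic
generator.

## Geometry

Three quantities drive everything else.

**Centroid.** The binding-cavity centre is the mass-weighted centre of
the reference ligand's atoms,
$c_x = \sum_i x_i m_i / \sum_i m_i$ (and likewise for $y$, $z$).
All atoms are weighted, hydrogens included when the input has them;
since the centroid is only ever taken on the reference ligand, pose
files without hydrogens introduce no inconsistency. Masses come from an
embedded table of standard atomic weights (IUPAC 2021 values).

**Cavity cube side.** Engines that define the search region as a sphere
share a radius $r$ (default 20 Å). For engines that use a box, the cube
side is volume-matched to the sphere, $l = (4\pi/3)^{1/3}\, r$, so
protocols search comparable volumes; $l(20) \approx 32.24$ Å. The grid
spacing for grid-based engines defaults to 0.375 Å.

**RMSD.** Pose quality is the heavy-atom root-mean-square deviation

$$\mathrm{RMSD}(a,b) = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n}
  \lVert a_i - b_i \rVert^2}$$

with atoms paired *by position*: atom $i$ of the pose against atom $i$
of the reference. Two deliberate restrictions follow the benchmark's
definition of the metric and are worth stating prominently:

* **no superposition** — proteins are assumed pre-aligned, so a pose is
  compared in the crystal frame; refitting would hide placement errors;
* **no symmetry correction** — a pose of a symmetric ligand rotated into
  an equivalent atom labelling scores as if it were wrong. An
  automorphism-aware RMSD would silently change the metric, so it is
  intentionally not offered.

Because correspondence is positional, `rmsd()` refuses molecule pairs
whose heavy-atom element sequences differ; the engines this pipeline
targets preserve input atom order.

## Per-cell metrics and the Protocol Score

For each structure × protocol cell the pose RMSDs are reduced to
RMSDmin, RMSDmax and RMSDave (the arithmetic mean over *all* returned
poses — not unique poses; the 1.0 Å uniqueness threshold is an
engine-side setting that benchpose only carries in its configuration).
Two quality metrics follow:

* **N(RMSD \< R)** — the number of poses whose RMSD falls strictly below
  the structure's crystallographic resolution $R$. The resolution is the
  natural per-structure yardstick: deviations below it are within the
  experiment's own uncertainty. With the default 20-pose runs the best
  attainable value is 20.
* **Protocol Score** — an integer on a 0–3 scale, one point per
  criterion: RMSDmin \< R, RMSDave \< R, and
  N(RMSD \< R) ≥ ⌈n/2⌉. The three criteria grade complementary
  qualities: finding the binding mode at all, keeping the whole ensemble
  near it, and doing so for most poses. The original score this rubric
  follows is cited in the benchmark literature without a restated
  formula, so benchpose makes the rubric an explicit configurable object
  (`score_rubric()`): the fraction and the thresholds can be replaced,
  and the default reproduces the documented 0–3 range and qualitative
  behaviour (a protocol good on RMSDmin but poor on RMSDave loses
  points).

Failed cells — empty pose sets, missing files, correspondence errors —
are first-class: they stay in the grid, carry no statistics, and
contribute 0 to every rank sum. "Below" is strict everywhere, matching
the metric's name.

**Ranks.** Protocol ranks sum each protocol's scores over all
structures; protein ranks sum each structure's scores over all
protocols. Ties break alphabetically (the underlying studies never
define a tie rule; an alphabetical tie-break is deterministic and
neutral). Both views conserve the grand total, which the tests assert.

## The protocol registry

`dock_protocols()` ships the fixed 17-protocol registry (7 programs),
alphabetical by abbreviation, with each program's license status and
each scoring function's favourable direction (`lower_better` for
energy-like scores, `higher_better` for the GOLD fitness functions).
The registry is data, not behaviour: benchmark evaluation works with
any protocol label, but name parsing and the scheduler's license
classification consult the registry.

## Colour maps

`render_heatmap()` draws the four standard views — RMSDmin, RMSDave,
N(RMSD \< R), Protocol Score — with structures on x and protocols on y.
The colour scale is a continuous monotone map normalised per plot to
the grid's range and oriented so the **best value always sits at the
blue end** (low for RMSD metrics, high for the counts and scores);
failed cells are uncoloured and marked with an exclamation glyph.
Alongside the image the exact numeric grid, including the colour index
used, is exported as TSV, so any downstream check can work from numbers
rather than pixels. RMSD maps cap the colour index at a configurable
ceiling (default 10 Å) so one catastrophic pose cannot flatten the
contrast; the cap is presentation-only and never touches the exported
values.

## License-aware dispatch simulation

Docking campaigns mix freely redistributable engines with commercially
licensed ones. The dispatch model reserves one "traffic lane" per
licensed program, of width equal to its license count, and pools the
remaining cores into a single shared lane for all unlicensed jobs: with
8 cores and one license each for GLIDE, GOLD and MOE, one job of each
licensed program runs at a time and five cores serve everything else.
`simulate_schedule()` is a discrete-event simulation of that contract —
it dispatches no real processes. Two modelling choices were genuinely
open and are resolved as follows:

* **queue discipline**: FIFO within each lane, input order as arrival
  order — the simplest deterministic discipline;
* **no backfilling**: idle slots in a licensed lane are never lent to
  unlicensed jobs, because licensed lanes are reserved by construction.
  This makes the simulated makespan an upper bound relative to a
  backfilling dispatcher.

Utilisation is busy core-seconds over lane width × schedule makespan
(the schedule-wide makespan, so lanes that finish early show the idle
tail they actually had).

## Virtual-screening utilities

`split_library()` partitions an SDF library into order-preserving
chunks (default size ⌈n / (4 × slots)⌉ — about four waves per slot,
balancing lane load against file churn). `spike_benchmark_ligands()`
appends the benchmark ligands as tagged actives
(`BENCHMARK_LIGAND=yes`) for later enrichment analysis — the enrichment
statistics themselves are out of scope. `merge_and_rank()` keeps the
best pose per molecule id, then sorts in the scoring function's
favourable direction, ties broken by id; the result is provably
independent of the chunking, and records with missing or unparseable
score tags are warned about and ranked last rather than dropped.
Ranking operates within one protocol at a time: cross-protocol score
fusion has no defined semantics here and is excluded. The wall-clock
estimate is first-order, `n × t̄ / slots`, using the benchmark's
measured mean execution time per complex when available (absolute
timings are hardware-specific, so none are hard-coded); the tests show
it agrees with a full lane simulation to within one job duration for
uniform jobs.

## The synthetic pose generator

Every pipeline stage is testable without any docking engine because the
generator produces pose sets with *exactly prescribed* RMSDs: one
random displacement is drawn per heavy atom and the joint
3n-dimensional displacement vector is rescaled in closed form so the
achieved RMSD equals the target to within 1e−9 Å — no iteration, no
rejection sampling. Poses are coordinate perturbations of the
reference (no conformer regeneration), which suffices because every
in-scope metric is purely geometric. Planted-truth scenarios draw
per-cell pose RMSDs as |N(location, spread)| with one protocol's
location set below all others, so rank-recovery can be tested; the
scenario defaults mirror the benchmark study's conditions — 20 poses
per run, resolutions uniform in [1.0, 1.8] Å (the case-study selection
criterion was R \< 1.8 Å), the planted protocol centred at 0.8 Å and
the rest at 3.0 Å. All generators are bit-reproducible given a seed and
restore the caller's RNG state.

What the generator does *not* emulate: chemically valid topologies,
bond orders, energies, scoring noise correlated with pose quality, or
engine-specific failure modes. Green tests therefore demonstrate that
the analysis machinery is correct, not that any particular engine
performs well on real targets.

## File formats and fixtures

Reference ligands are Tripos mol2 (read and written via bio3d); pose
sets and libraries are SDF V2000, handled by a small codec of the
package's own because the pipeline's topology-free records (0 bonds,
down to a single atom) are outside what the available SDF containers
accept. V3000 is rejected with a clear error — benchmark ligands never
approach 999 atoms. PDB files are read for metadata only (resolution
from `REMARK 2`, ligand codes from `HET` records, waters excluded by
residue name HOH). Every generated file is named
`<ligand>-<PDB>-<protocol>` so provenance survives in the filename, and
a missing-output sweep flags failed jobs before evaluation.

When several affinity records exist for a co-crystallized ligand the
hierarchy Ki \> Kd \> IC50 picks the measure; within a measure the
strongest (lowest) value wins, making the selection independent of
record order.

## Numerical choices and problem sizes

Strict inequalities implement every "below"; cell invariants
(min ≤ ave ≤ max) are asserted with a 1e−12 slack for float round-off;
summary files print doubles to 17 significant digits so re-parsing
reconstructs the matrix exactly. The test suite runs its full-scale
check at the study's native size — 20 structures × 17 protocols × 20
poses (340 cells, 6800 poses) — and keeps property suites at 5–10
seeds each, sizes chosen so the whole suite completes in well under a
minute while still exercising the full combinatorics.

## Known limitations

* Positional correspondence means poses from engines that reorder atoms
  must be re-mapped upstream; benchpose aborts rather than guessing.
* No symmetry-corrected RMSD: scores for highly symmetric ligands are
  pessimistic.
* The Protocol Score rubric is a faithful but configurable
  reconstruction; a study using a different published rubric should set
  its own `score_rubric()`.
* The scheduler models capacities, not hosts: no NFS latency, no
  per-engine startup cost, no mid-flight restarts.
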