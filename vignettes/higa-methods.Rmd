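---
title: "History-guided genetic search for protein-ligand docking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{History-guided genetic search for protein-ligand docking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(higadock)
```

## The problem

Protein-ligand docking predicts the bound pose of a small molecule in a
receptor site by minimizing a scoring function over the pose space.  The
search variable is a fixed-length real vector — the *pose genome*:

* translation `(tx, ty, tz)` in Angstrom, an offset of the ligand's rigid
  root from its reference position;
* orientation, a unit quaternion `(qw, qx, qy, qz)`;
* one torsion angle in degrees per rotatable bond of the ligand's torsion
  tree, wrapped to `[-180, 180)`.

`decode_pose()` turns a genome into Cartesian coordinates: torsions are
applied branch-by-branch from the rigid root outward (each branch rotates
its distal moving set about the current position of its rotatable bond),
then the rigid rotation about the root-set centroid, then the translation.
This space is rugged and multimodal; exhaustive search is hopeless, so
docking engines use stochastic optimizers.

The package implements three optimizers over a shared, counted objective:

* **GA** — a plain generational genetic algorithm: rank-proportional
  selection, two-point crossover, per-gene Gaussian mutation.  No elite
  carry-through; only its best-so-far trace is monotone.
* **LGA** — the Lamarckian GA: the plain GA plus Solis-Wets local search on
  the best fraction of each generation, with the improved genome written
  back into the population (acquired traits are inherited).
* **HIGA** — the history-guided hybrid this package exists for.  It extends
  the LGA with three mechanisms that reuse the run's own history: CE
  crossover, ED mutation, and a non-revisiting BSP archive.

## The history-guided mechanisms

### CE crossover

The best `ceiling(elite_fraction * n)` individuals of a generation are
elites.  After ordinary two-point crossover on randomly mated pairs, each
elite is preserved into the next population *together with its recorded
parents* (`M_father`, `M_mother` — the genomes whose crossover produced
it), on the premise that parents of excellent individuals carry good genes
worth recombining again.  The default elite fraction is 10%.

Two bookkeeping choices were open and are resolved as follows:

* *Population size restoration.*  Appending `3k` preserved individuals
  would grow the population, and the pseudocode is silent on bookkeeping.
  We restore size `n` by dropping the children of the worst-fitness mated
  pairs — the only fitness information available before the children are
  evaluated — keeping the evaluation budget comparable across algorithms.
* *Parents of a never-crossed elite* (e.g., in the first generation) are
  recorded as two copies of the elite itself.

### ED mutation

ED mutation directs the mutation step using the two best solutions the run
has ever seen, the historic best `M_optimum` and the historic second-best
distinct solution `M_sub`.  Per gene, with a fresh uniform deviate
`theta`:

* if `theta < beta` the gene is resampled uniformly within its bounds
  (exploration);
* otherwise it moves by
  `theta * (M_optimum - M_sub) + delta * (M_optimum - m)` — a
  vector-addition step from the second-best towards the best solution,
  plus a pull from the current genome towards the best (exploitation).

`theta` and `delta` are independent uniform(0,1) deviates drawn per gene
(`ed_scope = "gene"`; a whole-genome variant is available).  `M_max`/
`M_min` of the exploration branch are interpreted as the per-gene search
bounds, making that branch a standard uniform reinitialization; an
alternate population-extremes reading would tie the exploration range to a
collapsing population, defeating its purpose.  `beta` defaults to 0.1.
Before the archive holds two distinct solutions the operator falls back to
the exploration branch.

Two embedding decisions deviate from the most literal reading, and both
were forced by measurement:

* *Mutation rate.*  The pseudocode loops over every individual each
  iteration.  Applied to every gene of every individual, the exploitation
  pull collapses the population onto the incumbent within a few
  generations and the search stalls in the first basin it finds, well
  behind even the plain GA on the 10-D rugged benchmark.  The run
  protocol states that all parameters other than the named ones keep the
  host GA's defaults, and a host GA applies mutation at a per-gene
  *rate*.  The engine therefore applies ED mutation per gene at
  `mutation_rate` (default 0.1).  Direct calls to `ed_mutation()` keep the
  full-genome contract (`rate = 1`).
* *Supplement, not replacement.*  With ED *replacing* Gaussian mutation
  outright, HIGA's only moves are full-range uniform resets and
  incumbent-directed pulls; it has no medium-scale move, cannot hop
  between basins, and still trails the plain GA — contradicting the
  method's entire premise.  In HIGA mode the engine therefore applies ED
  mutation *in addition to* the baseline Gaussian mutation, both at the
  host rate.  With this embedding HIGA dominates both baselines on the
  benchmark by roughly two orders of magnitude in median final energy —
  the comparison the acceptance suite and `scripts/acceptance.R` compute.

### The non-revisiting BSP archive

A binary space partition over *discretized* genome cells stores every
solution the operators produce.  The root represents the whole search
space; each split divides a leaf's box exactly into two disjoint child
boxes.  When a new candidate's cell is already visited (the revisit flag
fires), the candidate *mutates to the nearest unvisited neighbor
subspace*: a branch-and-bound search finds the unvisited cell minimizing
the bounds-normalized Euclidean distance to the query, and a uniform point
inside that cell is returned and itself archived.  The archive thus
guarantees that no cell is ever evaluated twice, maintaining diversity
precisely when the population would otherwise duplicate its incumbent.

Numerical choices:

* *Discretization.*  Exact equality on continuous vectors would never
  fire, so genes are quantized: translation 0.25 Angstrom, quaternion
  components 1/64, torsions 2 degrees, other (benchmark) genes 1/128 of
  their range by default; all configurable.
* *Split rule.*  A leaf holding two occupants splits on the dimension with
  the largest normalized gap between them, at the midpoint of that gap.
  One split always separates the occupants, which keeps the node count at
  exactly `2 * cells - 1` — the archive's memory bound.
* *Descent and distance.*  The descent comparison uses the distance from
  the query to each child's box (zero when inside); ties go left.
  Distances are computed on bounds-normalized coordinates so
  Angstrom-scale genes cannot dominate degree-scale genes.
* *Redirected genomes are not re-repaired.*  Renormalizing the quaternion
  block of a redirected genome could move it out of its assigned cell and
  break the non-revisiting guarantee; decoding normalizes the quaternion
  internally, so scoring is unaffected.
* *Local search probes* are not archived by default
  (`archive_local_search = FALSE`): Solis-Wets refines within a basin at
  resolutions finer than a cell.  The flag exists, and the non-revisiting
  acceptance audit runs with it on, so the guarantee then covers every
  evaluation of the run.

### Generation structure and budgets

One HIGA generation is: CE crossover, ED + Gaussian mutation, archive
gate, fitness evaluation, Solis-Wets on the best `ls_fraction` (default
6%) with Lamarckian writeback, rank-proportional selection.  LGA skips the
history mechanisms; GA also skips local search.  A run terminates at
`max_generations` (the protocol's "iterations") or `max_evaluations`,
whichever comes first; every Solis-Wets probe counts against the
evaluation budget.  The conventional docking protocol — population 50,
27,000 generations, 1.5e6 evaluations — is the config default; tests and
examples scale the budgets down (typically 500 generations or 1e4-1.2e4
evaluations) and state so where it matters.

Each run consumes a single RNG stream seeded from its config in a fixed
order, so identical configuration and seed give bit-identical results;
timing is excluded from serialization for that reason.

## Objectives

* `grid_objective()` — the AutoDock-style energy: per atom, trilinear
  interpolation into that atom type's affinity lattice plus partial charge
  times the electrostatic lattice, plus a torsional penalty
  `w_tors * torsdof` (default 0.2983 kcal/mol per torsion, the AutoDock 4
  convention).  Poses with any atom outside the box return a finite
  penalty `1e5 + (squared distance to the box)` rather than raising, so
  stochastic operators remain total.  The objective's vectorized lookup is
  tested to reproduce the reference `grid_score()` exactly.  The full
  semi-empirical free-energy force field (desolvation, directional
  hydrogen bonds) is out of scope; published absolute energies are not
  reproduced.
* `toy_pairwise_energy()` — a desk-scale stand-in force field: 12-6
  Lennard-Jones per receptor atom plus Coulomb with distance-dependent
  dielectric `eps(r) = 4r`, distances floored at 0.5 Angstrom so
  degenerate fixtures stay finite.
* `benchmark_landscape()` — `sphere`, `rastrigin-like` and
  `double-funnel` analytic surfaces operating directly on raw genome
  vectors, so operator and archive behaviour can be studied without any
  molecular fixture.  The double-funnel pairs a narrow deep global basin
  (depth 10, width 0.5) against a broad shallow decoy (depth 5, width 4).

## What the synthetic fixtures emulate — and what they do not

`make_toy_complex(n_torsions, seed)` builds a zig-zag chain ligand (bond
length 1.5 Angstrom, seeded jitter breaking symmetry) with one rotatable
bond per interior torsion, and a synthetic grid-map set in which each atom
has its own atom type whose lattice is a Gaussian well (depth 5 kcal/mol,
width 2 Angstrom) centered on that atom's position in a randomly drawn
target pose, plus a weak harmonic funnel (0.05 kcal/mol/A^2) that
provides gradient information everywhere in the box.  The joint minimum is
attained exactly when the decoded pose reproduces the target coordinates,
so the global-optimum genome, pose and energy are known by construction
and verified by direct scoring at construction time.  For
`n_torsions > 0` the wells act on decoded atom positions, so torsion genes
genuinely matter.

This gives exact ground truth for RMSD-success tests, which real
crystallographic complexes cannot give without the full force field.  The
cost is realism: real binding sites have many competing local minima, no
global funnel, receptor-dependent well shapes, and symmetric ligands.  A
green recovery test establishes that the search machinery finds a known
global optimum through a funneled landscape; it does not establish docking
accuracy on real receptors.

## Analytics

Repeated runs are summarized the way docking engines report them:

* `success_summary()` — a run succeeds when the RMSD between its best pose
  and the reference is strictly below 2.0 Angstrom (plain
  atom-order-matched RMSD in the receptor frame, no superposition, no
  symmetry correction; all fixture atoms are heavy atoms).  Reports the
  success count and mean RMSD over all runs and over successes only (`NA`,
  never 0, when there are no successes).
* `cluster_conformations()` — energy-ordered leader clustering: poses are
  processed by ascending energy (ties by index) and join the first cluster
  whose seed is within the RMSD tolerance (default 2.0 Angstrom), else
  seed a new cluster.  Clusters are ranked by their lowest member energy;
  the rank-1 cluster's size measures how often the lowest-energy structure
  was found.  For nonempty input the cluster count is `1..n`.
* `distribution_summary()` — five-number summary with quartiles by linear
  interpolation between order statistics and Tukey 1.5 x IQR outlier
  fences.
* `compare_energies()` — a one-sided Mann-Whitney rank-sum utility for
  pairwise algorithm comparison; an interpretation layer, since published
  pairwise test matrices of this kind rarely name their test.

## Known limitations

* The scoring stand-ins are deliberately simple; absolute energies are not
  comparable to published force-field values.
* The archive's non-revisiting guarantee is at cell resolution; two
  distinct genomes in one cell count as one visit, and two cells can decode
  to the same rotation (quaternion sign).
* In high dimension the nearest-unvisited redirect moves at cell scale, so
  the archive maintains diversity locally but cannot by itself drive
  basin-scale exploration; that is the Gaussian component's role.
* Flexible receptor side chains, ring conformer sampling and
  symmetry-corrected RMSD are out of scope.

## A worked example

```{r example, eval = FALSE}
tc <- make_toy_complex(n_torsions = 5, seed = 1)
cfg <- run_config("HIGA", pop_size = 50, max_generations = 150,
                  max_evaluations = 12000, ls_max_steps = 50, seed = 1)
res <- dock_run(cfg, toy_objective(tc), topo = tc$topo)
rmsd(res$pose, tc$optimum_pose)      # < 2 A on this fixture
```
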