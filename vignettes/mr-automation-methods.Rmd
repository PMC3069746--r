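---
title: "Methods: the decision layer of automated molecular replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the decision layer of automated molecular replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpilot)
```

## Scope and model of the problem

Molecular replacement (MR) solves the crystallographic phase problem by
placing a homologous model in the target's unit cell. When homologues
are plentiful, the hard part is not any single placement but the
*decisions around it*: which templates to try, how to edit them into
search models, in what order to submit them, when to stop, and how to
recognise a correct solution from refinement behaviour alone. mrpilot
implements exactly that decision layer. The MR and refinement engines
themselves are abstracted behind a two-function contract
(`place`/`refine`, see `mr_engine()`); everything the package computes
— library curation, homologue ranking, model editing, trace scoring,
orchestration — is engine-agnostic and exercised here against a seeded
simulated engine.

Two orchestration strategies are provided. The *staged* flow
(`run_balbes_flow()`) works database-first: multi-sequence assembly
models are tried before anything else, then per-sequence models
(ensembles before single chains), and finally the per-sequence best
solutions are combined by fixing one and placing the others in turn,
the result indexed by concatenating the constituent model indices with
underscores. The *exhaustive* flow (`run_mrbump_flow()`) prepares every
configured model type for every ranked template and submits them in
pre-MR rank order, stopping at the first *good* classification unless
`try_all` is set.

## Template-library curation

The library rules follow the classic MR-database recipe: chains must be
longer than 15 residues (`min_length = 16`) and refined against data to
3.5 Å or better; entries whose resolution is unknown fail the filter,
a deliberately conservative choice since the filter is resolution-based.
A pair of chains is redundant when sequence identity exceeds 0.80 *and*
the Cα RMSD after least-squares superposition over the aligned pairs is
below 1.0 Å; the member refined at higher resolution is kept.
High-identity pairs at RMSD ≥ 1 Å are conformational variants and both
survive. Reduction is greedy in resolution order with a lexicographic
tie-break on entry id, which makes the retained set independent of the
input order; the suite checks this against an exhaustive pairwise
oracle on planted sets.

Identity is defined as identical aligned pairs divided by aligned
(non-gap) columns, one definition used consistently across every
module; dividing by the shorter sequence length is available via
`align_params(identity_mode = "shorter")`.

Chains are organised hierarchically by average-linkage agglomeration on
`1 - identity`. How the original database "corrected" its sequence tree
with a domain alignment is not specified anywhere we could follow, so
the index simply records both trees independently (domains are
clustered by the identity of their subsequences).

Domain decomposition is a reproducible substitute for what is, in the
original databases, a manually assisted procedure. A chain is split by
recursive contiguous bipartition of its Cα contact map (8 Å cutoff,
sequence separation ≥ 3): every admissible cut point is scored by the
number of contacts it severs and the best cut is accepted while the
severed fraction stays below 5% of the segment's contacts, with a
minimum domain length of 40 residues. On a two-lobed chain this finds
the linker; on a compact globule no cut is cheap enough and the chain
stays whole.

## Search, ranking and copy number

Pairwise alignment is global (Needleman–Wunsch) with BLOSUM62 and
affine gaps (open 10, extend 1) — standard choices, configurable in
`align_params()`. The pre-MR ranking score is `identity × coverage`:
the two stated ingredients of the classic ranking (alignment quality
and completeness) combined as the simplest monotone product. It is
exposed as a pluggable `scorer` so other strategies can be swapped in.

The hierarchical search emits assembly hits for all target sequences
and every subset of two or more (larger subsets first, `2^k - k - 1`
subsets for `k` targets), then for each sequence up to five source
structures — selected by best chain prescore, the pipeline's intent
when more than five qualify — each contributing monomer, domain and
multimer models, then cross-structure domain hits. The default identity
floor for reporting a hit is 0.20, with a separate lower floor (0.10)
for domain hits because genuinely useful domain templates reach down to
about 12% identity.

Expected copies per asymmetric unit come from a Matthews-style
argument: for each candidate copy count the implied solvent fraction is
`1 - 1.345/Vm` with `Vm = V / (Z · n · MW)` in Å³/Da, anchoring 50%
solvent at the conventional `Vm = 2.69`; the count with solvent closest
to 50% wins among counts in the 25–75% window, and zero (with a
warning) signals infeasibility. Symmetry-operator counts per
Hermann–Mauguin symbol come from a curated table of the common
space groups, since no installed R library provides them.

## Search-model preparation

Mixed models prune nonconserved side chains under the target alignment:
conserved residues keep everything, substituted residues are truncated
to the longest common prefix of the two residues' canonical side-chain
atom lists (minimum Cβ, none for a glycine target) and relabelled to
the target type, and unaligned template residues are deleted. The
prefix rule is a fixed, testable table — e.g. a template Phe aligned to
a target Tyr keeps the ring through CZ; Ile against Leu truncates at
Cβ where the branches diverge.

Two mixed variants feed the same pruning engine from two alignment
sources: the plain pairwise alignment, and a multiple-alignment-informed
variant that masks the pairwise pair map down to target positions
supported by at least half of the top templates (a target-anchored
consensus). This mirrors the observation that multiple alignment firms
up pairings exactly where pairwise alignment is least reliable, without
depending on an external MSA program; external aligners remain optional
adapters.

Polyalanine models cut every residue to N, CA, C, O, Cβ. Ensembles
normalise member order (prescore descending, then id), trim to the
common aligned core — members aligning to the reference below 15%
identity are treated as unalignable — and superpose every member onto
the first over the core Cαs by the Kabsch SVD solution (proper
rotation enforced; degenerate/collinear point sets are rejected).
Trimming to the core is a deliberate choice: a real MR engine
down-weights divergent regions of an ensemble internally, and without
an engine the core representation makes that explicit
(`trim = FALSE` retains full length). Assemblies are expanded one
chain copy per stored operator, chain ids A, B, C, … in operator
order; operators are inputs, validated as proper rotations, never
derived from interface areas.

## Scoring refinement traces

The quality factor is computed from the weighted final R statistics,
`Rw = w·Rfree + (1-w)·R` with `w = 0.75`:

$$Q = \frac{1}{1 + R_w/q_0 + (R_w/R_r)^{\gamma}}, \qquad
q_0 = 1.58,\; R_r = 0.5,\; \gamma = 16.$$

This is an empirical calibration with two regimes: the rational term
sets the scale among well-refined solutions, and the steep high-power
term — numerically negligible (<10⁻³) for any plausible solution —
drives Q towards zero as `Rw` approaches the ~0.55 plateau of a random
model, so the "very unlikely" band is reachable for failed placements.
Q is strictly decreasing in both final statistics, and `Q > 0.75`
marks a definite solution, `Q < 0.25` a very unlikely one. The
solution probability is a logistic map centred mid-band,
`P = plogis((Q - 0.5)/0.05)`; reports display it to one decimal,
capped at 99.0% — presentation only, the internal value is never
capped. Every constant lives in `scoring_config()`.

The good/marginal/poor classification uses the final Rfree and its
change over the refinement: *good* means final Rfree ≤ 0.45 with a
drop of at least 0.05; *marginal* final Rfree ≤ 0.50 with a drop of at
least 0.02; everything else is *poor*, so a flat high trace can never
classify good. All boundaries are inclusive, compared with a 10⁻⁹
guard against floating-point representation of threshold differences.
It is a conservative rule — poor solutions can still merit manual
inspection — and the thresholds are config values, not literals in
code.

Solutions are ranked by final Rfree ascending, ties broken by Q
descending then model index, which makes the ranking a total order.
The staged flow reports its combined solution as the final answer even
if a constituent's refinement noise landed marginally lower in Rfree.

## The simulated engine and what it does not show

The simulated engine exists to exercise decision logic, not to model
crystallography. Its constants (all in `sim_config()`) were chosen once
so that every decision path is reachable: Rfree starts near 0.55 (the
random-model plateau), decays with cycle time constant 4 toward an
asymptote `0.55 - 0.35·sqrt(q*)` in the model quality
`q* = identity × coverage × exp(-rmsd)`, with Gaussian noise σ = 0.005;
R tracks Rfree minus a gap `0.02 + 0.08·(1 - q*)` that widens with
overfitting at low quality. Placements below `q* = 0.2` fail and
refine flat (σ = 0.002); each fixed model eases the floor by 15%,
reflecting that placing into a partial solution shrinks the search.
With these dynamics a perfect model ends below Rfree 0.30 almost
surely, a planted homologue at identity ≥ 0.8 and coordinate error
≤ 0.5 Å classifies good with Q above the definite band, and decoys
produce flat traces with Q below 0.25.

The synthetic generator builds compact self-avoiding Cα walks with
schematic full-atom backbones, mutates sequences to exact identity
targets, and perturbs coordinates with per-axis σ/√3 noise so the
realised Cα RMSD concentrates at the requested σ. What it does *not*
emulate: real fold space (decoys are random walks, so structural
similarity at low sequence identity — the regime where domain templates
shine in practice — cannot arise by accident), diffraction data,
twinning or pseudo-translation (for which the Q and P scores of real
pipelines are explicitly unreliable), anisotropy, or crystal packing.
Passing tests therefore demonstrate the correctness of the decision
layer, not MR success rates on real data.

Default problem sizes were picked as the smallest that leave the
planted/decoy separation unambiguous: 60–100 residue chains, ~10
decoys, 20-seed repetitions for stochastic properties, 30 refinement
cycles throughout.

## Numerical and serialisation choices

Coordinates are written at the PDB's 3-decimal precision and residue
numbering is never rewritten, because downstream engines expect source
numbering. The library index serialises to JSON column-wise with
coordinates rounded to 3 decimals and IEEE negative zeros collapsed,
which makes a save/load/save cycle byte-identical. Superposition
requires at least 3 non-collinear pairs; chains with fewer than 3
aligned pairs to any candidate are never declared redundant, since the
RMSD is undefined. mmCIF reading covers the `atom_site` loop and the
resolution items only — the subset this package consumes — because no
installed R package parses mmCIF.

## Known limitations

Domain decomposition only produces contiguous-range domains; discontinuous
domains enter the library only as externally supplied ranges. The
multimer data model stores homomeric operators per chain, so
heteromeric assemblies are represented at search level (subset matching)
rather than as mixed-chain coordinate sets. The external MOLREP/Phaser/
REFMAC adapters construct command lines behind the engine contract but
are not executed anywhere in the test suite. Cluster schedulers are out
of scope; `batch_runner()` reproduces the include-list batching locally.
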