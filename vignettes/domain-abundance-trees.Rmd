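---
title: "Building, rooting and auditing trees of life from domain abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building, rooting and auditing trees of life from domain abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domtol)
```

## The problem

A tree of life (ToL) relates whole proteomes, not genes, so the usual
outgroup trick for rooting is unavailable: there is nothing outside the
ingroup. One research program builds ToLs from a census of protein
structural domains — how many copies of each SCOP fold superfamily (FSF)
each proteome carries — treats the per-FSF abundance vector as a multistate
phylogenetic character, and roots the optimal unrooted trees *a
posteriori* with Weston's generality criterion (implemented by attaching a
hypothetical ancestor most parsimoniously, i.e. Lundberg optimization). A
competing program encodes direction into the model itself: an asymmetric
stepmatrix that taxes domain gains more than losses roots the tree during
Sankoff optimization, and tends to pull large proteomes toward the root.
`domtol` implements both model families and, more importantly, the
empirical audits that discriminate between them: ancestor sweeps,
reconstructed change-frequency spectra, frequency-derived stepmatrices
with a refinement round, and rooted tree distances.

## Characters and coding

Characters are coded on an ordered 32-symbol alphanumeric scale
(`0`–`9`, `A`–`V`). The default encoder maps a count $c$ of FSF $f$ in a
proteome to

$$\mathrm{state} = \left\lfloor (n-1)\,\frac{\ln(c+1)}{\ln(c_{\max}+1)} + \tfrac12 \right\rfloor,$$

with $n = 32$ and $c_{\max}$ the largest count of that FSF over the
proteomes. The log transform compresses the heavy upper tail (abundances
range from 0 to hundreds of copies), the per-character maximum preserves
each FSF's own abundance gradient as a series of serial homologies, and
the endpoints are pinned: absence is always state `0` and the maximal
proteome always state `V`. Whether the original studies normalized per FSF
or over the whole matrix is not documented, so both are provided
(`norm_scope = "per_character"` — the default — or `"global"`, and
`scale = "log"` or `"linear"`); the choice is recorded in the matrix's
`coding_params` for provenance. Rounding is deterministic half-up.
Characters that are all-zero carry no signal and are dropped with a
warning; characters that are constant after coding are retained, since
they enter the ensemble index sums. Binary occurrence coding
(`to_binary_occurrence`) records mere presence/absence and is the natural
companion of the two-state occurrence models.

## Transformation models

A stepmatrix assigns a cost to every directed state change.

* **Ordered / Wagner** (`ordered_stepmatrix`): cost $|i-j|$, the edge count
  on the linear character-state graph. Additive, symmetric, metric. On the
  5-state graph, states 0 and 2 are 2 steps apart; 0 and 4 are 4 steps.
* **Unordered / Fitch** (`unordered_stepmatrix`): every change costs 1.
  Among 32 states there are $32 \times 31 = 992$ possible directed
  transformations; the unordered model treats them all alike, which makes
  it maximally agnostic and minimally informative.
* **Asymmetric gain penalty** (`hk_stepmatrix`): for binary occurrence
  data, the gain `0→1` costs 2 and the loss 1; for 32-state abundance
  data the "first gain" cells cost 3 against a baseline of 1. The
  printed fraction of penalized transformations (~3%) pins down the
  ambiguity in "first gain": penalizing all 31 cells `0→j` gives
  31/992 = 3.1%, so that is the default; `first_gain_only = TRUE`
  restricts the penalty to `0→1`. Asymmetry forces polarization: these
  models only score rooted trees and root them intrinsically.
* **Frequency-derived / Wheeler** (`wheeler_stepmatrix`): given a matrix
  $f$ of reconstructed change counts,
  $\mathrm{cost}(i,j) = \min\!\big(\mathrm{cap},\, 1 + \mathrm{round}(-\ln \frac{f_{ij}+p}{f_{\max}+p})\big)$,
  implementing the inverse relation between cost and probability of
  change. The exact functional form of the original weight is not
  published; this log-relative-frequency form with a pseudocount
  ($p = 0.5$) and a cap (32) is the package's documented default, chosen
  because it is antitone in frequency, gives the most frequent change a
  cost of exactly 1 step, and stays integer-valued for Sankoff. All three
  constants are arguments.

`audit_triangle_inequality` checks all $32^3$ ordered triples exhaustively.
A matrix that violates the triangle inequality charges more for a direct
change than for a detour — an internally inconsistent notion of distance.
The ordered and unordered models are metric; notably, the 31-cell
first-gain penalty is *also* metric-consistent (a detour out of state 0
still pays the penalty: $3 \le 3 + 1$), so the audit is most useful
against published penalty variants and against frequency-derived
matrices, which are routinely non-metric.

## Scoring, search and fit

`sankoff_length` implements the standard bottom-up dynamic program
$c_v(i) = \sum_{w \in \mathrm{children}(v)} \min_j \big(S_{ij} + c_w(j)\big)$
for arbitrary cost matrices, vectorized across characters, with missing
leaves free at every state (the PAUP* convention) and the tree length the
minimum over root states. Fitch and Wagner lengths use the classical set
and Farris-interval up-passes; they are exact for binary trees with at
most a basal trifurcation — the only shapes the package produces — and
the equivalence to the generalized program is property-tested on random
instances, alongside a brute-force oracle that enumerates every internal
assignment on small trees.

`heuristic_search` uses random-addition starting trees and hill-climbing
branch swapping (NNI by default, optionally SPR; TBR is not offered — the
tested contract is equal-optimum recovery, not a particular swap
schedule). Ties are collected by a breadth-first walk over the
equal-length plateau, deduplicated by topology, and capped (`maxtrees`,
default 100). A seed is mandatory and the search is a pure function of it.
For asymmetric models the search space is effectively rooted trees: each
unrooted topology is scored at its best root edge via a re-rooting dynamic
program that computes all edge-rooted lengths in one pass, and the optima
are returned rooted. `exact_search` enumerates all $(2n-5)!!$ topologies
as the oracle.

Fit is summarized by the ensemble retention index
$RI = (\Sigma G - \Sigma S)/(\Sigma G - \Sigma M)$ and consistency index
$CI = \Sigma M / \Sigma S$, with per-character bounds $M$ (minimum
conceivable steps) and $G$ (star-tree maximum). $RI = 1$ means
homoplasy-free fit, $RI = 0$ the worst possible. RI is computed only for
ordered/unordered characters: the Farris bounds are ill-defined for
arbitrary stepmatrix costs, so refined (stepmatrix) trees are reported by
length alone.

## Rooting a posteriori

`lundberg_root` attaches a pendant hypothetical ancestor to every
internode of an unrooted optimum, scores each augmented tree, and roots at
the cheapest attachment. The `"standard"` ancestor is all-missing and adds
zero cost everywhere, so *every* edge ties; the tie set is reported, and
the pipeline resolves the standard scheme operationally as the all-`0`
rooting — on growth-dominated data the two are topologically isomorphic
and equally optimal, which the sweep makes visible. Tie-breaking elsewhere
is deterministic: first edge in the postorder edge ordering of the scoring
tree. Using a real taxon's state vector as the ancestor reproduces
outgroup rooting on that taxon (its pendant edge always ties at zero added
cost), which is the property-test anchoring the implementation.

`ancestor_sweep` scores the standard scheme plus all constant ancestors of
the alphabet and reports, per scheme, the rooted length, the ensemble RI
— computed with the ancestor included as a scored leaf, since otherwise
all rows would share one topology and one RI — and the basal-group call.
Two regressions (RI on length, RI on ancestor state index) summarize the
sweep; on gain-dominated data both slopes are negative and remarkably
regular, the signature of an ordered character system recording growth.

`classify_basal` calls the smaller side of the root split the basal group
(ties broken toward the first root child): pure and complete →
monophyletic; pure but continuing above the split → paraphyletic
(a grade); mixed → unresolved.

## Reconstruction, change frequencies and refinement

`reconstruct_states` returns, per node and character, the full MPR state
set (states achieved by at least one most-parsimonious reconstruction),
computed from the Sankoff vectors by a top-down pass that carries the cost
of the rest of the tree. `change_frequencies` counts a branch-character
pair as an unambiguous $i \to j$ change only when both endpoint sets are
singletons — then every MPR agrees on that change — and tallies everything
else as ambiguous. A transformation under an ordered model counts as one
event, not $|i-j|$ unit steps: the frequency matrix describes state
pairs. Counts are averaged (not pooled) over tied optimal trees so
datasets with different numbers of optima remain comparable, and the
pendant branch of the hypothetical ancestor is excluded by default
(it is an anchor, not a taxon). Directional counting needs an
orientation, so frequencies are always derived on a rooted tree; to
emulate "unrooted" spectra the pipeline roots by the standard scheme
first and says so in the report.

`dynamic_weighting_iterate` runs the refinement loop: search under an
initial model, root (intrinsically if asymmetric, Lundberg all-`0`
otherwise), reconstruct, count frequencies, derive a Wheeler stepmatrix,
re-search. One round is the audit used here: if the initial model matches
the data, the refined tree $T_1$ keeps the topology of $T_0$ (cluster
distance 0 → verdict "stable"); a large distance exposes data–model
mismatch. Seeding the loop with the gain-penalty model on gain-biased
data derives first-gain costs *below* the penalty it started from — the
model reverses a trend that is in the data.

## Tree distances

`cluster_distance` is the hardwired cluster distance: the size of the
symmetric difference of the two rooted trees' nontrivial cluster sets
(twice the rooted Robinson–Foulds count on binary trees; a halved variant
is an option). `hybridization_distance` is the hybridization number,
computed through maximum acyclic agreement forests: candidate forests are
enumerated as edge-cut sets of the first tree in increasing size — every
agreement forest arises this way — and each candidate is checked for
per-block topological agreement, vertex-disjoint embeddings in both trees,
and acyclicity of the component ancestry digraph, so the first feasible
size is exact. The problem is NP-hard; beyond `exact_leaf_limit` (default
16) or the enumeration budget the function returns certified bounds (lower
from the exhausted sizes, upper from a greedy agreement forest built by
peeling conflicting leaves) tagged `"heuristic"`. Exactness is
property-tested against an independent oracle that enumerates *all* leaf
partitions. `tanglegram_export` produces side-by-side leaf orderings via
barycenter passes that are only accepted when they do not increase the
crossing count, so crossings are non-increasing by construction.

## The synthetic generator

`simulate_proteomes` evolves FSF copy numbers along a known rooted tree as
a linear birth–death process per FSF (birth $\lambda n$, death $\mu n$)
with innovation as a Poisson process of rate $a n$ founding a brand-new
FSF at count 1 — growth of existing structures is common, new structures
are rare ($a \ll \lambda$). Events are sampled individually
(Gillespie-style) rather than through transition probabilities so that the
per-branch event log reconciles *exactly* with the leaf counts, which is
itself a tested invariant. Defaults encode the regime of interest at desk
scale: 16 taxa, 12 seed FSFs at root counts 1–3, tree height 5,
$\lambda = 0.6$, $\mu = 0.06$ (gain-biased, $\mu = 0.1\lambda$),
$a = 0.01$; these produce leaf abundances from 0 to the low hundreds with
heavy-tailed per-FSF distributions, comparable in range to real proteome
censuses, while keeping simulations fast enough to replicate. No published
values exist for $\lambda$ and $a$ in this setting; the defaults are the
package's own calibration and are fully exposed in `sim_config`. Rogue,
parasite-like proteomes are emulated by multiplying $\mu$ on designated
pendant branches; three superkingdom-like groups label the three
basal-most clades.

What the generator does *not* emulate: horizontal transfer, correlated
gain/loss across FSFs, genome-size-dependent rates, and annotation noise.
Passing tests therefore demonstrate internal correctness and the claimed
qualitative behaviors (gain bias, root recovery, penalty reversal) under a
clean birth–death regime — not performance on real, messier censuses.

One subtlety is deliberate. Under pure gain ($\mu = 0$) each FSF arises
exactly once and is never lost, so binary occurrence characters are
perfectly compatible with the true tree and the reconstructed
change-frequency matrix has an exactly empty lower triangle — a theorem,
and the form in which the package tests the "no losses under pure gain"
guarantee. The same is *not* true of graded multistate abundance coding:
parallel duplications in sister lineages create coded-state homoplasy,
which parsimony partly resolves as secondary loss even though no copy was
ever lost. The multistate tests therefore assert the (correct) weaker
property — gains dominate losses — rather than an exact zero.

## Problem sizes and numerics

The test and pipeline problem sizes — 8–12 taxa, 10–15 seed FSFs, 50
benchmark replicates, exhaustive search at 7 taxa, partition-oracle
distances at up to 8 leaves — are chosen so the full property suite
replicates many times over in minutes while every oracle remains
exhaustive. Costs are numbers, not integers (Wheeler matrices need not be
integral); equal-cost decisions use an absolute tolerance of $10^{-8}$;
argmin ties everywhere are broken by the first index in a deterministic
ordering. Seeds are mandatory at every stochastic entry point, and a local
RNG scope restores the caller's random state.

## Known limitations

* Heuristic search guarantees optimum recovery only statistically; the tie
  plateau is explored through the chosen swap neighborhood, so tied optima
  more than one plateau-step apart can be missed (`n_replicates` and
  `swap = "SPR"` mitigate).
* Hybridization numbers are exact only within the enumeration budget;
  beyond it the bounds are honest but can be loose.
* RI is undefined for arbitrary stepmatrices; refined trees are compared
  by length and topology distances only.
* The Nexus reader targets the dialect this package writes (DATA +
  ASSUMPTIONS with `USERTYPE`/`TYPESET`/`ANCSTATES`); it is not a general
  Nexus parser.
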