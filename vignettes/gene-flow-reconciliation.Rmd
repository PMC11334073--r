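---
title: "Methods: parsimony DTL reconciliation and gene-flow analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsimony DTL reconciliation and gene-flow analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter
choices, numerical conventions, and limitations. The worked code in the
README shows the outputs; here we explain why the machinery looks the
way it does.

## The reconciliation model

`dtlrecon` implements *undated* maximum-parsimony
duplication–transfer–loss (DTL) reconciliation of a rooted binary gene
tree against a rooted binary species tree. "Undated" means no node ages
are assumed: a transfer may connect any two branches neither of which is
an ancestor of the other ("incomparable" branches). This is the standard
parsimony machinery of tools such as Ranger-DTL, and the assumption set
matters:

* **Rooted, strictly binary trees.** Multifurcating gene trees are
  rejected at parse time rather than resolved silently — an unresolved
  polytomy makes the event assignment ill-posed. An optional rooting
  sweep is *not* provided; gene trees are consumed as rooted (callers
  with unrooted estimates should evaluate candidate rootings and keep
  the cheapest).
* **Event costs are exchange rates, not probabilities.** The defaults
  (duplication 3, transfer 3, loss 1) are dimensionless; only their
  ratios matter. The package centres its grid on D/T/L = 3:3:1 and ships
  `cost_grid_run()` so sensitivity of any conclusion to the ratios can
  be measured rather than asserted.
* **Origination is free.** The species mapping of the gene root is
  recorded as the family's origination; parsimony has no natural
  origination penalty, so a family's first appearance is wherever its
  root maps most cheaply.
* **Losses are first-class.** `in(g,s)` prices a mapping below `s` at
  one loss per skipped branch, and the traceback materializes each such
  loss as an explicit event on the branch where the lineage died, so
  per-branch loss counts come out of the same bookkeeping as gains.

Co-optimal reconciliations are typically numerous. Rather than
reporting one arbitrary optimum, `sample_reconciliation()` traces back
through the tables choosing uniformly among co-optimal alternatives at
*every decision point* (root placement, event kind, speciation side
assignment, loss-path endpoint, transfer recipient). This yields
per-decision uniformity, which is cheap and reproducible; it is not
exactly uniform over whole scenarios (a scenario reachable through more
decision sequences is not overweighted, but scenario counts per decision
subtree are not tracked). `reconcile_family_trials()` then aggregates
`n_trials = 100` samples per family as across-trial medians, and all
cross-family sums are taken on the raw (possibly fractional) medians
with integer rounding applied only after summation. Aggregating samples
of co-optimal scenarios is this package's stand-in for probabilistic
reconciliation samplers; amalgamation over bootstrap gene trees is out
of scope, though pooling trials across bootstrap trees of one family
approximates it, and externally produced event tables can be imported
via `read_event_table()`.

Numerical conventions: infeasible states carry `Inf` (a true IEEE
infinity, never a large sentinel float); cost ties are detected with a
relative tolerance of 1e-9; negative branch lengths are rejected while
zero-length branches are allowed everywhere except where a quantity
divides by them (see RED and rates below).

## Node identity

All tables reference species and gene nodes by the deterministic
numbering their Newick text induces (tips 1..n in order of appearance,
internal nodes from the root), alongside a persistent name map. Runs on
the same input are therefore diffable byte for byte. A strict post-order
index would serve equally; the parse-order numbering was chosen so every
structure stays a plain `ape::phylo` object and all of `ape`'s
machinery (I/O, distances, plotting) applies directly.

## RED and event rates

Relative evolutionary divergence interpolates each node between root
(0) and tips (1): for node *v* with parent *p*,
`red(v) = red(p) + (d/u)(1 - red(p))`, with *d* the branch above *v* and
*u* the mean distance from *p* to the leaves below *v*. On an
ultrametric tree this reduces to depth/height, which the tests verify to
1e-9 against trees the recursion never saw. Subtrees whose every branch
is zero make *u* vanish and are rejected by name. Event rates are
`ln(n + 1)/branch length` per node and event kind; the root (no branch)
is excluded structurally and zero-length branches carrying events are
excluded with a warning, since the ratio is undefined there. The recent
epoch defaults to RED ≥ 0.95; it is a plain config constant. Which
subtree RED is computed on is the caller's choice — the recursion is
applied to whatever species tree is supplied.

## The simulator: what it emulates and what it does not

`simulate_family()` evolves gene copies down the species tree by a
Gillespie scheme: per copy and per unit branch length, duplication
(rate δ), transfer (τ) and loss (λ) compete as exponential waiting
times; speciation copies every lineage into both children. Transfers
re-seed one copy at the top of a branch incomparable to the donor,
drawn with probability proportional to branch length by default
(matching a uniform-intensity landing; a switch gives the unweighted
choice). Branch lengths in substitutions/site serve directly as the
simulation clock — no separate time calibration is invented. The
default rates (δ = τ = λ = 0.1 per copy per unit length) produce, on a
16-leaf coalescent tree of height ~1–2, families with a handful of
events each: enough signal for every downstream statistic without
saturating parsimony, which is the regime the method assumes.

Origination is at the species root by default; the "random" mode draws
a single origination branch per family length-weighted. A literal
per-branch origination *probability* could seed several independent
copies of one family, which a single rooted gene tree cannot represent,
so it is deliberately not offered.

The ground-truth log records every origination, duplication, transfer
(with recipient), and loss, plus speciation/extant bookkeeping rows and
lineage identifiers, so the emitted gene tree can be *replayed* from the
log alone — the consistency invariant the tests assert. True copy
counts per species node come from the same pass.

What the simulator does **not** emulate: sequence evolution and hence
gene-tree estimation error (gene trees are emitted exactly),
inter-family rate variation, gene conversion, and transfer from outside
the analyzed taxa. Passing tests therefore demonstrate correctness of
the inference machinery under its own generative assumptions — not
robustness to tree error, which real orthogroup data always carries.

## Event accounting conventions

Per family and species branch the package books gains by mechanism
(origination, duplication, transfer-in), losses, copies (count at the
bottom of the branch) and *vertical passages*. A vertical passage is a
gene lineage crossing the speciation node at the bottom of an internal
branch into at least one child — the denominator partner of the
transfer-versus-vertical propensity. This definition is explicit
because the quantity is usually internal to reconciliation samplers:
with it, the exact bookkeeping identity

> Σ gains − Σ losses = Σ leaf copies − Σ vertical passages

holds family by family (each passage doubles a lineage at a speciation,
so passages — not root copies — balance the ledger), and per branch
`copies(child) = copies(parent) + gains − losses` replays exactly. Both
identities are asserted in the tests on simulator truth and on
reconciled output.

"Gene count at a node" defaults to summed copy numbers (extant-leaf
counts are then genome gene counts); a `presence` mode counts families
instead. Branch-to-clade attribution for breakdowns is strict: a branch
belongs to a clade iff all its descendant leaves do (stem branches
included), everything else lands in a `deep` bucket. The same rule
attributes branches to lineages for the vHGT matrix; the `deep` bucket
is assigned the total leaf count as its size, which makes its
frequencies conservative.

## Statistics

The Mann–Whitney U implementation enumerates all group assignments
exactly (midranks for ties) when both groups have ≤ 8 observations and
otherwise uses the tie-corrected normal approximation without continuity
correction; tests pin both paths to `wilcox.test` and to hand-counted
enumerations. Cliff's delta is computed by direct pair counting and
satisfies `delta = 2U/(n_x n_y) − 1` by construction. P-values are
two-sided by default. Kruskal–Wallis comparisons delegate to
`stats::kruskal.test`. Families count as "with detected vHGT" when
their across-trial *median* transfer count is positive — medians are the
aggregation unit, so detection should not hinge on a minority of
trials; propensities then use across-trial means as the `f` values.
Distance profiles average transfer counts over *all* admissible
(incomparable) branch pairs per bin, zeros included, so the profile is
an average per pair rather than per observed transfer. LOESS smoothing
of rate curves is a plotting nicety and deliberately outside any tested
contract.

## Curation heuristics

Viral-specific classification is a strict threshold rule (any member
hit against a cellular database at E < 1e-3 disqualifies the family),
monotone in the threshold by construction. Functional assignment takes
each member's maximum-bitscore GVOG below the threshold and the
family-level plurality, breaking ties lexicographically (and flagging
them) for reproducibility. Fragment merging selects the longest member
as reference (ties again lexicographic, logged), then chains
reference-hitting members of the same genome greedily left-to-right in
genomic order, joining neighbors with fewer than 4 intervening genes
and capping units at 4 genes; chains never cross genomes, ordinals are
treated linearly (no circular wraparound), and the operation is
idempotent. The greedy-chain reading resolves the ambiguity between
"fewer than 4 genes between them" (a pairwise rule) and a global cap:
the cap applies per chain as it is built.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data: species trees of 3–48 leaves, 25–500 families per dataset, 1–100
reconciliation trials per family, and 200 random instances for the
brute-force comparison (gene and species trees capped at 6 leaves each,
where exhaustive enumeration over all mappings is tractable). These
sizes were chosen so each statistical check retains power while a full
suite run stays in the minutes range; the algorithms themselves are
O(|gene| · |species|) per family after preprocessing and handle trees
of hundreds of leaves.

## Known limitations

* Parsimony underestimates events relative to the truth when rates are
  high, and ancestral counts are explicit lower bounds; the
  conservativeness test asserts the direction of the bias, not its
  size.
* Pure-loss histories can be re-explained as cheap transfers when the
  transfer cost is low relative to the losses saved; inference on
  loss-only data recovers zero gains only in the low-rate regime, which
  is what the corresponding test exercises.
* Per-decision-uniform scenario sampling is an approximation to uniform
  sampling over co-optima (exact on instances whose ties are
  independent, as in the tested two-scenario case).
* The host-overlap and propensity analyses inherit whatever lineage
  partition they are given; internal branches spanning several lineages
  are pooled into `deep` rather than split fractionally.
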