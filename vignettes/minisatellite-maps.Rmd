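---
title: "Minisatellite map alignment and its analyses: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minisatellite map alignment and its analyses: model, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatmap)
```

# The evolution model

A minisatellite map is a string of repeat-unit type symbols.  msatmap scores
its evolution with four events acting on single units:

* **unit mutation** — one type changes into another at cost `d_M(x, y)`,
  a symmetric, zero-diagonal, non-negative matrix supplied by the user (in
  practice proportional to the edit distance between the unit DNA
  sequences);
* **duplication** — a unit gains an adjacent tandem copy at cost `c_dup`;
* **insertion / deletion** — a unit appears or disappears at cost
  `c_ins` / `c_del`.

Costs conventionally satisfy `c_dup` < mutation ≤ indel, reflecting that
tandem turnover (slippage, unequal exchange) is by far the fastest process
at these loci.  All dynamic programs use the min-plus closure of `d_M`
(`close_mutation_costs()`), so one "effective mutation" per derivation node
prices an arbitrary chain of single-step mutations optimally, even for
non-metric user matrices.

## Duplication histories

`derivation_cost(s, c, costs)` returns the minimum cost of an ordered tree
of tandem duplications rooted in one unit of type `c` whose leaves spell
`s`, each node allowed one effective mutation.  The recurrence over
intervals is stated in the function documentation; its correctness is pinned
in the test suite against an independent uniform-cost search over explicit
event sequences (`oracle_derivation_cost()`), exhaustively for all strings
up to length 5 over two symbols under 25 random cost models, including
non-metric ones.

A useful collapse, proven by the same oracle: the cost of generating a run
`r` as offspring of a persistent flanking unit `x`
(`flank_generation_cost()`) equals `c_dup + D(r, x)` for non-empty `r` —
partitioning `r` into several direct-child blocks of the seed never beats
the single-block tree, because the block partition is itself one of the
interval splits available to the DP under an unmutated root.

## Map alignment

`align_pair()` minimizes, over monotone matchings of the two maps, the sum
of matched-pair closed mutation costs plus one explanation per maximal
unmatched run.  A run is split into a prefix generated from its left
flanking matched unit, an indel middle, and a suffix generated from its
right flanking matched unit; absent flanks (map ends) force their segment
empty, and the all-indel and no-match alignments remain available as
candidates.  This three-segment concretization is the package's definition
of the model; the brute-force matching oracle in the acceptance tests pins
the DP to it for all pairs up to length 4 over two symbols.

Direction restrictions (`mode = "lr"` / `"rl"`) drop the suffix or prefix
segment.  Because the restricted search space is a subset, restricted cost ≥
unrestricted cost always — the inequality the directional statistics count.

Complexity is O((nm)²) per pair with O(n³·σ) table building; the kernels are
C++ (Rcpp).  No compression tricks are attempted: cost-level fidelity, not
speed, is the contract here.

**Tie-breaks.**  Among equal-cost alignments the traceback maximizes the
number of matches, then prefers the earliest predecessor in scan order
(leftmost matches).  History reconstruction uses leftmost splits and the
lexicographically smallest intermediate symbol.  Strict cost comparisons use
a 1e-9 tolerance throughout.

# The analyses

## Pivot points (structural variation)

For one alignment the columns — matched pairs and run units, in map order,
a run's cost spread uniformly over its units, A-side run units emitted
before B-side units inside one gap — are scanned left to right; the pivot is
the mean of the two maps' normalized consumed-unit positions at the first
column where the cumulative cost reaches half the total.  Zero-cost pairs
are skipped.  `structural_variation_test()` compares the pivot histogram of
the real dataset against scramble replicates (units shuffled within each
map).

Two discretization facts, both visible in the tests: the "first column
reaching half" rule sits about half a column to the right of the continuous
crossing, and with tied optima the traceback may legitimately choose
non-mirrored alignments for mirrored inputs.  The mirror identity
`pivot(reversed) = 1 − pivot` therefore holds in aggregate up to the
half-column drift, not exactly per pair.  On maps of realistic length
(tens of units) the drift is below 0.03 and irrelevant next to the
polar-variability effects the test looks for.

## Directional bias (duplication dynamics)

`directional_bias_counts()` aligns every pair three times — unrestricted,
left-to-right only, right-to-left only — and counts pairs whose restricted
cost strictly exceeds the optimum (`E_l`, `E_r`), normalized to
`E_n = (E_l − E_r)/(E_l + E_r)` (0 when both counts are 0).
`directional_bias_test()` wraps this in a scramble test; by default all
datasets, real and shuffled alike, are first reduced to their modular
structure (`modular_structure()`, `aaabbc → abc`).  The reduction is the
standard speed approximation — type *transitions* carry the direction
signal — and the flag governs the real pass and the replicates uniformly so
the two histograms stay comparable.

## Phylogeny

`bionj_tree()` wraps the BIONJ variance-weighted neighbor joining of
**ape** on the pairwise cost matrix (raw costs by default; `normalize`
divides by summed map lengths).  Two labels yield the single split with the
distance halved.  Negative branch lengths are clamped to zero with the
deficit moved to the sibling branch(es); emitted lengths are always
non-negative.  `write_newick()` serializes with single-quoting of reserved
label characters.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `d_M` | 1 off-diagonal (`default_cost_model()`) | unit mutation costs; `gradient_cost_model()` gives `abs(i-j)` over an ordered alphabet |
| `c_dup` | 0.5 | duplication event cost; must stay below mutation/indel for duplication-aware behaviour |
| `c_ins`, `c_del` | 1.5 | indel event costs; with equal values alignment is orientation-symmetric |
| `iterations` | 2 (structvar), 25 (dupdyn) | scramble replicates |
| `bins` | 20 | histogram bins over [0,1] / [−1,1] |
| `use_modular` | TRUE | modular-structure reduction in the bias test |
| `tol` | 1e-9 | strictness tolerance for "restricted cost higher" |

With the uniform default matrix, generating one mutated copy from an
adjacent seed costs `c_dup + 1 = 1.5`, exactly the indel cost — a deliberate
tie: indels and single-copy explanations trade freely unless the data favor
duplication chains.  Analyses that hinge on *direction* should use a graded
matrix (below).

# The simulator

`simulate_dataset()` grows independent lineages from a shared root map.
Each of `n_events` steps is a duplication (`p_dup`), mutation (`p_mut`) or
indel (`p_indel`).  Duplications insert a copy adjacent to a template unit —
left of it with probability `beta` (right-to-left origin) — and model two
well-documented features of tandem-array turnover:

* **bursts** (`burst`, default 0.85): with this probability the next
  duplication's template is the copy made by the previous one, so tracts
  extend in a fixed direction from a hotspot (the direction is drawn once
  per burst);
* **copy errors** (`dup_mut`, default 0.1): the fresh copy immediately
  mutates — the duplication-followed-by-mutation motif.

Mutations step to a *neighbouring* symbol in alphabet order (unit types are
point-mutation derivatives of similar repeats), with position drawn
∝ `rank^(mut_end_bias − 1)` so `mut_end_bias = 1` is uniform and larger
values pile variation onto the 3' end.  Indels insert a uniform symbol at a
uniform slot or delete a uniform unit, never emptying the map.  Everything
is reproducible from one master seed via per-lineage sub-seeds.

## Why direction needs graded costs and burst growth

Two design facts drove the simulator, and they say something real about the
method:

1. **A uniform mutation matrix makes direction invisible.**  A single
   unmutated copy is the same string whichever side it lands on.  Worse, a
   diverged run that does not contain its seed's symbol costs the same from
   *any* seed when all mutations cost 1; and a run that does contain the
   seed symbol can usually be re-matched so the other copy is the inherited
   one, mirroring the explanation.  Direction becomes identifiable only
   when run content is *measurably closer* to one flank than to the other —
   i.e. with a graded `d_M`.  Real cost files grade mutation costs by unit
   similarity; `gradient_cost_model()` is the simulator's counterpart.

2. **The strict pair counts demand clean data.**  `E_l`/`E_r` count a pair
   as soon as *any* feature in it favors the forbidden direction.  A
   direction-neutral event (a standalone mutation at a block edge, a random
   insertion) taints a pair in one direction or the other with equal
   probability, so even a few percent of such events per lineage pushes
   both counts up and `|E_n|` toward 0.  A published Y-chromosome dataset
   showing `E_r = 0` over ~59000 pairs is therefore itself evidence of how
   duplication-dominated those loci are.  The parameter-recovery
   experiments accordingly run the simulator in its duplication-only regime
   (`p_dup = 1`, copy errors only), which is the regime the statistic is
   designed to interrogate.

## Study conditions used by the verification experiments

* **Direction recovery**: 20 maps, 30 events, 8-symbol ordered alphabet,
  24-unit root of six 4-unit blocks with well-separated symbols
  (`b g d h a f`), `p_dup = 1`, `burst = 0.85`, `dup_mut = 0.1`, graded
  costs with `c_ins = c_del = 2.5`; 25 scramble replicates.  `beta = 1`
  recovers `E_n ≥ 0.8`, `beta = 0` ≤ −0.8, replicate means stay within
  ±0.2 of 0.
* **Polarity recovery**: same root, 15 maps, 20 events, mutation-driven
  (`p_mut = 0.7`), uniform costs; `mut_end_bias = 5` pushes the real pivot
  mean above 0.55 while scramble replicates stay at 0.5 ± 0.05, and
  `mut_end_bias = 1` keeps the real mean at 0.5 ± 0.05.
* **Phylogeny**: BIONJ recovers 100 random additive 8–12 leaf matrices
  exactly (Robinson–Foulds 0) and separates two 5-map populations simulated
  from distant roots into two clades.

These sizes keep the full verification suite at a few minutes on one CPU
while using pair counts (190) large enough for the count statistics to be
stable.

## What the simulator does not emulate

Nucleotide-level unit sequences and typing noise; recombination between
lineages (maps are independent given the root); multi-unit duplication
blocks (only the optional double-copy *analysis* handles period-2 arrays);
population structure beyond a shared root.  Passing recovery tests
demonstrates that the statistics detect the modeled mechanisms — not that
real loci evolve by exactly these mechanisms.

# The double-copy extension

`transform_dataset()` locates maximal alternating arrays `xyxy...`
(left-to-right greedy, non-overlapping, at least two full periods; an odd
alternation contributes its even prefix) and rewrites them over composite
types `@x+y`.  Composite–original distances are derivation costs of `xy`
from the original type; composite–composite distances are two-unit
alignment costs; composites duplicate at `c_dup` (one double-copy event)
and indel at twice the unit indel cost (they span two physical units, via
the per-symbol `indel_weight` mechanism).  The feature is optional and off
by default; expanding composites restores the original content exactly.

# Degenerate inputs and numerical conventions

Empty maps and empty alphabets are rejected; a 1-symbol alphabet works
throughout (all mutation costs 0).  Intervals in outputs are 0-based
half-open; map positions in R data frames are 1-based.  Histogram bins are
half-open with a right-closed last bin and end-bin clamping.  PHYLIP
output truncates labels to 10 characters (refusing collisions) unless the
relaxed long-label dialect is requested.  All scramble machinery draws from
R's RNG under `withr::with_seed`, so equal seeds give bit-identical
results.

# Known limitations

* The three-segment run explanation cannot interleave indels *between* two
  generated blocks from the same flank; scenarios needing that are priced
  slightly conservatively.
* The pivot statistic inherits a half-column rightward discretization; on
  very short maps this is visible (it is accounted for in the tests).
* `E_l`/`E_r` are any-difference pair counts, not effect sizes: a single
  wrong-direction feature flips a pair, so the statistic is most meaningful
  on duplication-dominated, population-level data — which is exactly where
  it is used.
* BIONJ negative-branch clamping redistributes length to siblings; total
  tree length is preserved only approximately on non-additive matrices.
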