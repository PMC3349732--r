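---
title: "Finding phenotype-biased metabolic subsystems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding phenotype-biased metabolic subsystems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nibbsr)
```

## The problem and the model

Given dozens or hundreds of organisms, some expressing a phenotype of
interest (hydrogen production, acid tolerance, TCA expression, ...) and some
not, which metabolic subsystems are responsible for the phenotype?  A
subsystem that matters is under evolutionary pressure to be co-conserved in
the expressing organisms, so its *presence pattern* across organisms should
be biased toward the expressing group.

`nibbsr` works on a **reference metabolic map**: vertices are compounds,
each edge is a reaction labeled with the EC number of its catalyzing enzyme
class.  An organism-specific network is the restriction of the map to edges
whose EC label the organism possesses, so a subsystem (an edge set) *exists*
in an organism exactly when the organism has all of the set's distinct
labels.  Presence is therefore a conjunction of label bit-vectors — no
subgraph isomorphism is ever solved — and only *connected* edge sets are
candidate subsystems, because metabolic systems chain reactions through
shared metabolites.

## The bias metric

For `n` organisms of which `p` are positive, a subsystem present in `k`
organisms of which `k_p` are positive gets

$$\alpha \;=\; \sum_{i=k_p}^{\min(k,p)}
  \frac{\binom{p}{i}\binom{n-p}{k-i}}{\binom{n}{k}},$$

the upper-tail cumulative hypergeometric probability of drawing at least
`k_p` positives in `k` draws.  Small $\alpha$ means strongly
phenotype-biased.  Two monotonicity facts drive everything downstream: at
fixed `k_p`, dropping negatives (smaller `k`) never raises $\alpha$; at
fixed `k - k_p`, gaining positives never raises $\alpha$.  The upper-tail
form is the unique cumulative hypergeometric consistent with those two
properties and with "smaller is more biased"; the implementation sums in
log-space (`lchoose`) and is cross-checked in the tests against direct
`choose()` summation and `stats::phyper` to `1e-12` over the full grid
`n <= 25`.

```{r}
hypergeom_tail(n = 130, p = 65, k = 62, k_p = 62)
```

## Maximally-biased subgraphs and the exact enumerator

A **maximally-biased subgraph** (MBS) is a connected edge set with (1) no
connected subgraph of strictly smaller $\alpha$ and (2) no connected
supergraph of smaller-or-equal $\alpha$.  `mbs_enum()` enumerates the exact
set: by the metric's monotonicity, every MBS is a maximal frequent connected
subgraph of the positive networks at threshold equal to its own positive
support, so the candidate pool is the union of maximal frequent sets over
all thresholds `1..p` (plus whole connected components, which cover the
degenerate zero-positive-support case the threshold sweep cannot reach).
Candidates are then filtered by checking both criteria exhaustively —
connected subsets by direct enumeration, connected supersets by depth-first
growth with an anti-monotone cut: once a branch's positive support `k_p` is
low enough that even an all-positive-support superset
($\alpha(k_p, k_p)$, the best any further superset can do) cannot match the
candidate, the branch dies.

Both "subgraph" and "supergraph" are read as *connected* sets, consistent
with the network model; maximality among frequent sets likewise.  Exactness
is the contract, so map size is guarded (default 25 edges,
`override_guard = TRUE` to force).  `brute_force_mbs()` is a deliberately
independent oracle — `combn()` over all subsets, connectivity by plain
compound reachability, criteria by pairwise bitmask comparison — and the
suite requires set-equality between the two on batteries of random
instances.

## NIBBS-Search

Exhaustive enumeration is hopeless at genome scale, so the heuristic works
in two stages.

**Seed generation.**  Edges are sorted by single-edge $\alpha$ (ties by edge
id).  The least-$\alpha$ unmarked edge founds a seed set and is marked; the
seed greedily absorbs the candidate edge giving the largest $\alpha$
decrease (marking it too) until nothing strictly decreases $\alpha$ or the
seed has `k_max` edges; then the next unmarked least-$\alpha$ edge founds
the next seed.  Every edge ends up in exactly one seed set, so coverage is
total and seeds partition the map.  Candidates either must share a compound
with the seed (`seed_method = "connected"`) or may be any edge joined to the
seed by a path whose labels are present in every positive instance the
augmented seed would occupy (`"path_checked"`; the connecting path is
absorbed later, during expansion).

**Seed expansion.**  Seeds with $\alpha < \alpha_s$ are expanded: candidate
edges adjacent to the growing set qualify if the augmented set stays present
in at least $\lceil \delta \cdot s_0 \rceil$ of the seed's positive
instances ($s_0$ = the seed's positive support).  Among qualifiers the
cascade is (i) maximize the resulting positive-instance count, (ii) largest
$\alpha$ decrease, (iii) uniform random.  Expansion is support-driven, not
$\alpha$-driven: a ubiquitous neighbouring enzyme joins the subsystem
without changing $\alpha$ (that is how TCA-shared enzymes end up inside
rTCA-biased subsystems), and $\alpha$ may even rise transiently, so the
output carries `k`, `k_p` and the final $\alpha$ for downstream filtering.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `k_max` | 5 | maximum seed-set size; 1 makes every founding edge its own seed |
| `alpha_s` | 0.05 | only seeds with $\alpha$ *strictly below* this expand |
| `delta` | 1.0 | fraction of seed-supporting positives the expansion must retain |
| `seed_method` | `"connected"` | candidate rule during seed growth |
| `rng_seed` | 1 | drives the only randomness: the expansion tie-break |
| `restarts` | 1 | expansion attempts per seed, keeping the lowest $\alpha$ |

`delta = 1` is the strongest-signal setting and the default.  Tie-breaks the
procedure leaves open are fixed deterministically (lower edge id), except
the final expansion tie, which is drawn from a per-seed-set RNG substream
derived from `rng_seed` and the founding edge.  Because each seed's stream
is independent, changing `alpha_s` only adds or removes subsystems — it
cannot reshuffle the others — which makes the max-bias monotonicity trend
(`run_parameter_sweep()`) exact rather than merely expected.

## Pathway enrichment

To summarize a run against curated pathway annotations, all subsystem edges
are pooled (deduplicated) into a list `L`.  For each pathway, its edges in
the reference map form the population; population successes are the edges
whose label the target organism possesses; the sample is `L` restricted to
the pathway; sample successes are the sample's organism-present edges; the
p-value is the upper-tail hypergeometric.  Restricting the sample to the
pathway's own edges is a deliberate choice: a hypergeometric sample must be
drawn from its population, and the unrestricted pooled list can exceed the
population size.  No multiple-testing correction is applied by default (a
Benjamini–Hochberg column is available via `p_adjust = TRUE`).

## Synthetic validation data

`make_systematic_validation_dataset()` recreates the planted-bias
construction: 13 specialized pathways (6 uniquely-labeled edges each) are
planted in a background map; every organism receives background enzymes
independently at rate 0.5; the planted enzymes are then *removed from every
N-group organism* and kept in the 65 P-group organisms up to independent 5%
noise flips.  Planted labels are never reused by background edges, so the
artificial bias is fully attributable — a stronger guarantee than a
database-derived construction, where enzyme sharing between chosen pathways
and the rest of metabolism blurs attribution.

Each planted pathway also receives 12 pendant *periphery* edges labeled from
the background pool and tagged with the pathway id.  They play the role of
the reactions a reference pathway map contains beyond any organism-specific
restriction: the enrichment population (18 edges) is then genuinely larger
than the biased subsystem (6 edges), and the test tolerates several
false-positive background subsystems landing in a pathway before losing
significance.  For the enrichment target we use the planted enzyme
complement itself — an idealized phenotype-expressing reference organism.
A noisy positive organism would make pathway populations and successes
nearly coincide at this scale (population successes ≈ population), turning
each per-pathway p-value into a coin flip that measures the noise draw
rather than the recovery.

What the generator does *not* emulate: real metabolic map topology (degree
distributions, currency metabolites), enzyme sharing across pathways,
phylogenetic correlation between organisms (presence flips are independent),
and multi-copy enzymes.  Passing tests show the machinery recovers planted
bias under independent noise; they do not certify performance on real
phylogenetically structured data.

`generate_instance_battery()` drives the exactness and approximation
experiments: random dense maps of 10–12 edges over roughly half as many
compounds, 9–10 organisms split in half, and a planted biased core of 3–4
connected edges (labels in every positive, leaking into each negative with
probability 0.15; other labels present at 0.6).  Sizes sit at the upper end
of what the brute-force oracle enumerates comfortably, densities keep the
space of connected subgraphs — the permutation null — rich, and organism
counts keep the best achievable $\alpha$ ($1/\binom{n}{p}$) clearly below
the default seed cutoff (with 6 organisms split 3/3 it is exactly 0.05,
which the strict `alpha < alpha_s` filter would always exclude).

## Scoring the heuristic against the exact set

For each exact MBS $m_i$, $J_i$ is the best Jaccard index against any
heuristic subgraph; the approximation score is the RMS distance to the
all-ones optimum, $S = \sqrt{\sum_i (1-J_i)^2 / |M|}$, so $S \in [0,1]$ with
0 = every MBS matched exactly.  Significance is empirical: replicate sets of
`|G|` random connected subgraphs (frontier sampler — uniform start edge,
uniform frontier additions; fast, not uniform over all connected subgraphs,
and used on both sides of the comparison) are scored, with sizes drawn from
`G`'s size multiset (`p1`) or matched one-to-one (`p2`), and
$p = (1 + \#\{S(R) \le S\})/(N+1)$ — the add-one permutation estimator, so
p is never zero.  In the approximation experiments the heuristic runs with
`alpha_s = 1`: the exact enumerator has no bias cutoff, and with
`delta = 1` an expansion can never outgrow a maximally-biased seed
(qualifying candidates preserve `k_p` and can only shrink `k`, so one would
contradict the MBS supergraph criterion), making the cutoff-free run the
faithful counterpart.

## Baselines

Two per-enzyme association methods are included for comparison.
`ttest_per_enzyme()` runs a two-sided Welch t-test on copy numbers (absent
= 0) and flags labels significant with a higher positive-group mean; labels
absent everywhere are skipped, and zero-variance cases are handled
explicitly (equal means: t = 0, p = 1; unequal constant means: p = 0).
`mi_per_enzyme()` scores each label's mutual information with the phenotype
(bits, from the 2×2 table, zero cells contributing nothing) and flags labels
strictly above a permutation threshold: the maximum MI over shuffled
presence vectors — a single global maximum by default, per-label on request.
Each label's permutations come from a derived substream, so the shuffle set
for fewer permutations is a prefix of that for more, and the flagged set
shrinks exactly (not just in expectation) as shuffles are added.  Both
methods score enzymes one at a time and are conservative by construction
relative to the subgraph search, which can credit an enzyme for the company
it keeps.

## Numerical and degenerate-input choices

* The tail sum short-circuits to exactly 1 when `k_p` is at its feasible
  floor, avoiding `1 - 1e-16` artifacts.
* The empty edge set has all-ones presence (vacuous conjunction) and counts
  as connected; empty sets never reach the bias metric in the pipelines.
* A subsystem absent from every organism (`k = 0`) has $\alpha = 1$.
* Jaccard of two empty sets is 1; `approximation_score` of an empty `G`
  is 1; `empirical_pvalues` with empty `G` returns p = 1 for both variants.
* `ceiling(delta * s0)` integerizes the retention floor ("at least") and a
  seed with zero positive support makes the floor vacuous.
* Equal-$\alpha$ ties during sorting and seed growth break on the lower edge
  id; only the documented expansion tie uses randomness.

## Problem sizes used in the shipped experiments

The validation fixture is 300 edges (78 planted + 156 periphery + 66
background) over 130 organisms; a full NIBBS run takes well under a second.
The exactness experiments use 100 random instances and the approximation
experiments 20 instances with 1000 permutation replicates each; the whole
suite and the acceptance script each complete in a few minutes on one CPU.

## Known limitations

* `mbs_enum()` is exponential by nature; the guard is a convenience, not a
  performance promise, and dense maps near the guard can still be slow.
* The connected-subgraph sampler is not uniform over connected subgraphs of
  a given size; both the observed and null scores use the same sampler, but
  p-values inherit its bias.
* Organisms are treated as independent; phylogenetic relatedness can
  produce spuriously biased subsystems, and no diversity weighting is
  applied.
* Reaction reversibility and stoichiometry are out of scope: adjacency is
  undirected compound sharing.
* The enrichment test applies no multiple-testing correction by default,
  matching the headline protocol; switch on `p_adjust` when screening many
  pathways.
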