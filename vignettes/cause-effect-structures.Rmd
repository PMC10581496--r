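---
title: "Unfolding cause-effect structures of discrete causal networks"
author: "phistruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unfolding cause-effect structures of discrete causal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phistruct)
```

# The model

`phistruct` analyses a finite network of `n` interacting units, each with a
finite state alphabet, whose dynamics are completely described by an
*interventional* transition probability matrix (TPM)
$T_U \equiv p(\bar u \mid u)$: the probability of every next joint state
given every imposed current joint state. Two standing assumptions are made
about this object.

1. **Conditional independence.** Given the previous joint state, the units
   update independently: $p(\bar u \mid u) = \prod_i p(\bar u_i \mid u)$.
   `validateTpm()` reports the factorization error of any supplied TPM, and
   all internal computations operate on the per-unit factors, so the
   contract is maintained by construction everywhere noise is injected.
2. **Interventional semantics.** Rows of the TPM are read as
   $p(\bar u \mid do(u))$. Consequently every marginal used in the analysis
   is taken under a *uniform* interventional distribution over the
   marginalized units, never under an observed stationary distribution. This
   is what makes the quantities below properties of the network's causal
   powers rather than of its typical behaviour.

All state-indexed tables use one fixed ordering convention: joint states are
enumerated mixed-radix little-endian, with unit 1 varying fastest. Binary
units map label `-1` (OFF) to index 1 and `1` (ON) to index 2; compact
labels such as `"Abcdef"` follow the case convention (uppercase = ON). The
ordering is declared in all file formats and round-trips bit-exactly through
the JSON serializer.

The worked examples use networks of binary logistic units,
$p(U_i = 1 \mid u) = \left(1 + \exp(-k \sum_j w_{j,i} u_j)\right)^{-1}$
with $u_j \in \{-1, +1\}$: noisy linear threshold units whose determinism
grows with the slope $k$. The builder requires each unit's incoming weights
to sum to 1 — with one deliberate relaxation: a column summing to 0 denotes
a unit with no inputs, which the logistic maps to a constant 1/2
(an unconstrained noise source). This keeps simple open motifs (a single
directed edge, feed-forward layers with source units) expressible without
dummy self-loops.

# The pipeline

## Background conditioning

A candidate system $S \subseteq U$ is assessed over itself; the remaining
units $W = U \setminus S$ are *background conditions* and must not
contribute cause-effect power. On the effect side the background is clamped
at its current state: $p_e(\bar s \mid s) = p(\bar s \mid s, w)$. On the
cause side the prior state of the background is unknown, so each unit factor
is a mixture over prior background states $\bar w$, weighted by the
posterior probability of $\bar w$ given the current universe state under a
uniform prior over prior universe states; factors are then recombined by
product, which removes residual correlations routed through the background.
A current state that no prior state can produce makes this posterior
undefined; `conditionSystem()` raises an error rather than silently
renormalizing, because every cause-side quantity downstream would be
meaningless.

## Intrinsic information and the cause-effect state

Intrinsic information is a product of *selectivity* (the probability of the
selected state) and *informativeness* (the base-2 log-ratio of constrained
to unconstrained probability); its unit, the *ibit*, is a probability-
weighted pointwise information value and is deliberately not additive.
Non-maximal states may carry negative values; the maximum is provably
non-negative, and it is zero precisely when the constrained repertoire
equals chance (a property the test suite asserts in both directions). The
system's cause-effect state is the argmax pair. Two systematic behaviours
are worth knowing when interpreting results: *expansion* (a fully specified
added unit contributes exactly one ibit) and *dilution* (an unconstrained
added unit strictly decreases intrinsic information) — both are exercised as
tests.

## Partitions and system integrated information

Directional partitions split $S$ into $k \ge 2$ parts; each part's inputs,
outputs, or both are replaced by independent noise (uniform causal
marginalization of the severed inputs). Distinct direction labelings can
induce identical severed-input sets; since $\varphi$ depends only on those
sets, the search deduplicates by cut-set (9 labelings collapse to 3 cuts for
two units; 54 labelings exist for three). The minimum partition is the one
minimizing $\varphi_s(\theta)$ *relative to its maximal attainable value*
$\sum_i |S^{(i)}||X^{(i)}|$, which makes cuts across genuine fault lines
commensurable with cuts isolating single units. Ties on the normalized value
resolve to the largest unnormalized $\varphi_s$; residual exact ties (which
arise only from symmetries) resolve to the first partition in the canonical
enumeration order, so repeated runs are identical.

Two exact shortcuts are used, both validated against a naive full-labeling
search on small random systems: cut-set deduplication, and early termination
when some partition yields $\varphi_s(\theta) = 0$ — the normalized minimum
is then 0 and the reported value is 0 regardless of which zero-partition is
nominally selected. Because all binary marginalizations average over
power-of-two state counts, severed-but-ineffective connections reproduce the
intact probabilities bit-exactly, so feed-forward (not strongly connected)
systems return $\varphi_s = 0$ *exactly*, not approximately.

A single-unit candidate system has no $k \ge 2$ partition; it is evaluated
against the complete noising of its own input (normalization 1). This keeps
single units commensurable with multi-unit candidates during condensation,
matching the convention of the formalism this package follows, where
self-looping "monads" can be minimal complexes.

## Complexes

`condense()` evaluates $\varphi_s$ for every non-empty subset (all other
units as background), extracts the maximal candidate as a complex, removes
its units from candidacy — they continue to serve as background — and
repeats. Because a candidate's $\varphi_s$ depends only on the candidate and
the frozen state of everything else, the subset scan is computed once and
reused across rounds. Tie handling: tied candidates that are pairwise
disjoint are all extracted in the same round; tied overlapping candidates
fall through to the next $\varphi_s$ level that is unique or disjoint; if no
level resolves, the larger and then lexicographically smallest system is
chosen. Excluded tied systems do not re-enter later rounds. These rules go
beyond what the source formalism fixes; they were chosen once for
determinism and are stated here rather than buried in code.

## Mechanisms, purviews, distinctions

Within a conditioned system, a mechanism $M \subseteq S$ in its current
substate $m$ is evaluated over candidate purviews $Z \subseteq S$ using
*product* repertoires: per-unit probabilities with all non-mechanism (or
non-purview) units causally marginalized, multiplied across units. The
mechanism's intrinsic information selects a purview state; its integrated
information $\varphi$ is the selectivity-weighted positive log-loss over the
minimum *disintegrating* partition. Disintegrating partitions pair disjoint
(possibly empty) mechanism parts with disjoint (possibly empty) purview
parts, never pairing the whole mechanism with a non-empty purview part; for
a single-unit mechanism every such partition severs all mechanism-purview
connections. The normalizer for the minimization is the number of severed
mechanism-purview unit pairs, $|M||Z| - \sum_i |M^{(i)}||Z^{(i)}|$ — the
same pairwise-interaction counting used at the system level. (The source
formalism states this normalizer only as the number of affected pairwise
interactions; this is the one consistent reading and is flagged as a design
decision.)

Purview selection maximizes $\varphi$ over all non-empty $Z$; ties prefer
the larger purview, then the lexicographically smallest unit set, and
purview-state ties within a purview take the maximal-$\varphi$ state, then
the smallest state index. A distinction exists when
$\varphi_d = \min(\varphi_c, \varphi_e) > 0$ *and* both maximal purview
states are congruent — as (unit, state) tuples — with the system's maximal
cause-effect state. A mechanism state impossible under every purview state
is *causeless* ($\varphi_c = 0$), not an error.

Two implementation notes. First, all repertoire and partition probabilities
reduce to one primitive — the mean of a unit factor over the states of a
unit subset — which is memoized per system, so the full mechanism scan costs
little more than its combinatorics. Second, the minimum-partition search
enumerates coarse partitions first and terminates exactly on the first zero;
this ordering is what keeps the $2^{|S|}-1$ mechanism scan tractable for
sparsely connected systems, where almost every mechanism-purview pair is
reducible by an aligned two-block cut.

## Relations and the Phi-structure

Relations bind distinctions whose purviews overlap *congruently*: every
intersection operates on (unit, state) tuples, so a unit shared in
incongruent states never overlaps, and congruent cause/effect occurrences
of a unit count once. A face of a candidate relation selects cause, effect,
or both purviews from each distinction such that the common intersection is
non-empty (at least two purviews overall, which for a single distinction
leaves exactly the self-relation over its own cause and effect). A set of
$h$ distinctions has at most $3^h$ faces, with equality exactly when all
purviews share a congruent unit. The relation's integrated information is
the weakest distinction's per-purview-unit $\varphi_d$, scaled by the size
of the joint purview (the union of all face purviews):
$\varphi_r = \min_d \left[\varphi_d / |z^*_c(d) \cup z^*_e(d)|\right] \cdot
|\bigcup_f o^*_f|$, which never exceeds $\min_d \varphi_d$.

The enumeration over subsets of the distinction set is pruned by downward
closure: restricting a face of a superset to any subset keeps its purview
selections available and can only enlarge the intersection, so a subset
without faces rules out all its supersets. Subsets are grown from related
pairs; a configurable cap (default 20 distinctions) guards the worst-case
$2^{|D|}$ growth — beyond it the analysis should proceed by folds. Pruned
and unpruned enumerations are asserted equal on randomized small sets.
Closed-form relation counting for general distinction sets is *not*
implemented (the analytic results it would rest on are not reproduced
here); the schematic all-congruent counting cases are tested combinatorially
instead.

`unfold()` assembles the Phi-structure $C(D) = D \cup R(D)$ and
$\Phi = \sum_D \varphi_d + \sum_R \varphi_r$, an identity enforced by the
class validity and by the serialized phi ledger. `distinctionFold()` and
`compoundFold()` extract the sub-structures anchored on a distinction or a
unit subset (mechanisms *containing* any of the units, matching the reading
that a unit contributes a fold alone or in combination). A unit whose state
cannot be varied has no counterfactual states and cannot be a system member;
such "inactivated" units are modeled by leaving them in the background at
their fixed state.

# The fixture families

The generators reproduce the standard small-network families used to probe
the theory: `makeDirectedCycle()` (unidirectional ring, weight 1.0 — the
text-specified example, carrying the published values
$\varphi_s \approx 1.75$ and $\Phi \approx 7.65$ at $k = 4$, state
`Abcdef`), `makeBottleneck()` (hub with redundant inputs and outputs — high
degeneracy), `makeModularPairs()` (strongly coupled two-unit modules with
weak inter-module links — fault lines), `makeSpecializedLattice()`
(heterogeneous overlapping neighbourhoods, seeded), `makeFeedforwardCounter()` (three deterministic XOR units with only
feed-forward cross-connections from A, driven by a frozen input unit I),
and `makeExcitatoryInhibitory()` (a five-unit ring mixing excitatory and
inhibitory connections, column sums still 1).
Where the corresponding published architectures specify their exact weights
only in diagrams, the generators reproduce the topology *class* with
parameterized weights and make no claims about those diagrams' printed phi
values; only the text-specified cycle and feed-forward facts are asserted in
tests. The feed-forward counter deserves one caveat: a 3-unit binary system
whose only cross-edges leave A cannot realize a global 8-state cycle (the
B and C chains decouple into period-4 components), so the fixture honours
the described properties — determinism, feed-forward topology, exact
reducibility of the triad, condensation into single-unit complexes — rather
than any specific global sequence.

`makeRandomLogistic()` and `makeRandomFeedforward()` generate seeded,
column-normalized random networks (bit-identical given the seed) for
property tests: the first arbitrary recurrent topologies, the second
acyclic ones, which must and do come out exactly reducible.

What the synthetic families do *not* emulate: empirically estimated TPMs
(which would violate both completeness and interventional semantics),
non-binary alphabets at scale (the core supports them; the generators are
binary), and any macro/micro unit-grain structure — the analysis works at
the given grain only. Passing tests on these fixtures therefore validate
the formalism's bookkeeping and its exhaustive searches, not the adequacy
of any particular causal model of a real substrate.

# Numerical choices

- Probability and phi comparisons use an absolute tolerance of $10^{-10}$
  (option `phistruct.tolerance`); products of many factors accumulate
  rounding at the $10^{-15}$ scale, and no quantity of interest lives below
  $10^{-8}$ in the tested regimes.
- $0 \cdot \log 0 := 0$ throughout; the positive-part operator clamps
  partitioned probabilities that exceed the intact ones.
- Exhaustive subset/partition scans are capped at 8 units (option
  `phistruct.maxUnits`) with an explicit error beyond — the intended scale
  of this implementation; no approximate search is provided.
- Problem sizes in the shipped tests: full pipeline on the 6-unit cycle;
  oracle cross-checks on 3-unit systems (100 seeds); naive-versus-optimized
  MIP equality on 2-4-unit systems (100 seeds); reducibility over 50 random
  acyclic networks. These sizes make every brute-force oracle exact while
  keeping the default suite fast.
- Output files serialize numbers at 12 significant digits (networks at full
  precision); all comparisons in code are tolerance-based, never string
  equality.

# Known limitations

- Exhaustive only: nothing here scales beyond ~8 units; the combinatorics
  (subsets x partitions x purviews x relations) are intentionally exact.
- The cause side of intrinsic information uses Bayes' rule over product
  distributions; it is a product of selectivity and informativeness but not
  literally a difference measure between two distributions, and no
  alternative normalization is offered.
- Tie-breaking beyond the formalism's stated rules (purview size, part
  encodings, simultaneous extraction of disjoint tied complexes) is this
  package's own deterministic convention, documented above; other
  implementations may legitimately differ on exactly symmetric systems.
- Analytic relation counts and any approximate/sampled MIP search are out
  of scope.
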