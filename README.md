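# phistruct

Cause–effect structure analysis of discrete causal networks in R.

`phistruct` quantifies the intrinsic causal powers of a finite network of
interacting units whose dynamics are given by an interventional transition
probability matrix (TPM) `p(ū | u)` and a current state `u`. It is written
for researchers in integrated information theory and causal network
analysis who need a complete, exhaustively-searched reference
implementation for small systems (up to ~8 binary units), with every
quantity tested against brute-force enumeration oracles.

The pipeline implements, end to end:

- **Background conditioning.** A candidate system `S ⊆ U` is analysed from
  its intrinsic perspective: units outside `S` are causally marginalized
  conditional on the current universe state, giving an effect TPM
  `T_e = p_e(s̄ | s)` (background clamped) and a cause TPM
  `T_c = p_c(s | s̄)` (background mixed over its posterior prior-state
  distribution under a uniform interventional prior).
- **Intrinsic information** (in *ibits*), the product of selectivity and
  informativeness, e.g. on the effect side
  `ii_e(s, s̄) = p_e(s̄|s) · log₂( p_e(s̄|s) / p_e(s̄) )`,
  and the maximal cause–effect state `s′ = (s′_c, s′_e)` it selects.
- **System integrated information** `φ_s`: the loss of intrinsic
  information over the minimum directional partition (MIP). Partitions
  split `S` into k ≥ 2 parts whose inputs, outputs, or both are replaced by
  independent noise; the MIP minimizes `φ_s(θ)` relative to its maximal
  attainable value `Σᵢ |S⁽ⁱ⁾||X⁽ⁱ⁾|` (the number of severable pairwise
  interactions). Systems that are not strongly connected come out exactly
  reducible (`φ_s = 0`).
- **Complexes.** `condense()` recursively extracts maximal substrates:
  candidates with maximal `φ_s` against all overlapping competitors, until
  the universe is exhausted. The result is a disjoint set of complexes.
- **Unfolding.** `unfold()` computes the cause–effect structure of a
  complex: every mechanism `m ⊆ s` with its maximally irreducible,
  congruent cause and effect purviews (`φ_d = min(φ_c, φ_e)`), the causal
  relations binding congruently overlapping purviews (`φ_r`), and the
  structure integrated information `Φ = Σ φ_d + Σ φ_r`.

Networks can be supplied as explicit TPMs, as weighted-connection networks
of binary logistic units `p(Uᵢ = 1 | u) = 1/(1 + exp(−k Σⱼ wⱼᵢ uⱼ))`, or
read from JSON/YAML/TSV spec files. Generators for the standard example
families (directed cycles, modular pairs, bottlenecks, specialized
lattices, a feed-forward counter, seeded random networks) are included.

## Worked example: the 6-unit copy cycle

Six binary units connected in a directed ring (weight 1.0 to the next
unit, logistic slope k = 4), analysed in the state `Abcdef` (unit A ON,
rest OFF):

```r
library(phistruct)

net <- makeDirectedCycle(6, k = 4, state = "Abcdef")
systemPhi(net)
#> System phi: 1.74667 ibits (phi_c = 1.74667, phi_e = 1.74667)
#>   reducible: FALSE; partitions evaluated: 7896
#>   MIP: {1,2,3}<-> / {4,5}<- / {6}-> (normalization 20)

cx <- findFirstComplex(net)
cx
#> Complex 1: ABCDEF (state Abcdef), phi_s* = 1.74667 ibits

st <- unfold(cx)
st
#> Phi-structure: 6 distinction(s), 4 relation(s)
#>   Phi = 7.6504 ibits (sum phi_d = 5.7378, sum phi_r = 1.9126)
#>   candidate mechanisms evaluated: 63

distinctions(st)[[1]]
#> Distinction: mechanism {1} -> cause {6=2} / effect {2=2}, phi_d = 0.9563
```

The whole ring is one complex with `φ_s ≈ 1.75` ibits: the minimum
partition severs two ring connections, each costing
`log₂(σ/0.5) ≈ 0.97` ibits of informativeness at selectivity
`σ⁶ ≈ 0.90`, where `σ = 1/(1+e⁻⁴)` is the copy fidelity. But the
structure it unfolds into is sparse: all 63 candidate mechanisms reduce to
6 first-order distinctions (each unit specifying its predecessor's past
and its successor's future, `φ_d ≈ 0.96` each) bound by only 4
second-degree relations, so `Φ ≈ 7.65` ibits. Large but sparsely
structured substrates are exactly the regime where high system-level
irreducibility coexists with low structure integrated information.

The same analysis from the shell:

```sh
Rscript inst/scripts/phistruct unfold inst/extdata/cycle6.json --out structure.json
```

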