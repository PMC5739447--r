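---
title: "Logical dynamics of the central dogma: models, semantics and measures"
author: "cdlogic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical dynamics of the central dogma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdlogic)
```

# The models

`cdlogic` treats the central dogma as a dynamical system over binary
molecular species. Two generations of the model are bundled.

**The 1965 picture** has four nodes — Activator, DNA, mRNA, Protein — with
rules

| node | rule (activatory V1) | rule (inhibitory V2) |
|---|---|---|
| Activator | `Activator` | `Activator` |
| DNA | `DNA` | `DNA` |
| mRNA | `DNA & Protein` | `DNA &! Protein` |
| Protein | `(mRNA & Activator) | Protein` | same |

Long-half-life species (DNA, Protein, Activator) carry self-loops: once ON
they stay ON unless actively removed, which this era's model cannot do. The
two versions differ only in the sign of the Protein→mRNA feedback.

**The present-day picture** adds three species: miRNA (standing for all RNA
species that act against protein production), DegRNA (the RNA-degradation
machinery) and DegProtein (proteolytic turnover). Its seven nodes update as

```
Activator  <- Protein | Activator
DegProtein <- Protein &! DegProtein
DegRNA     <- miRNA & Protein &! DegProtein
DNA        <- (miRNA & Protein) | DNA
miRNA      <- (DNA & Protein | mRNA) &! DegRNA
mRNA       <- DNA & Protein &! DegRNA
Protein    <- (mRNA & Activator | Protein) &! DegProtein
```

Three of these interactions are signed: Protein's effect on mRNA
transcription, Protein's effect on miRNA transcription, and miRNA's effect
on DNA (gene silencing, `miRNA → !miRNA` in the DNA rule). Each sign can be
activatory or inhibitory, so `buildCDModel()` generates `2^3 = 8` versions,
catalogued as `CD-V1` (all activatory) through `CD-V8` (all inhibitory);
`cdModelIds()` lists them. The reconstruction is validated dynamically: the
packaged self-checks require, among others, that `CD-V2` closes the
synchronous 4-cycle `1001000 → 1001010 → 1001111 → 1111101` exactly, that
`CD-V1` has fixed points `{0000000, 1000000, 0001000, 1001000}` with basins
`{12.5, 21.88, 12.5, 53.12}` %, and that all eight versions are pairwise
distinct as truth tables.

`CD-PBN` is a probabilistic mixture of the activatory and inhibitory rule
variants: DNA chooses its silencing rule with probability 0.9 (vs 0.1),
miRNA and mRNA choose their activatory rules with probability 0.8 (vs 0.2),
all other nodes are deterministic. Per-node probabilities must sum to one
(validated to 1e-9).

## The rule grammar

Rules use `&` (AND), `|` (OR), `!` (NOT) over node identifiers, with
precedence NOT > AND > OR, left associativity and parentheses. The lexer
treats `!` as a prefix operator regardless of spacing, so the conventional
compact form `DNA &! Protein` parses as `DNA & (!Protein)`. Identifiers are
case-sensitive and must name declared nodes; anything else is rejected with
the offending identifier or position. `ruleToString()` emits the
minimal-parenthesis form, and serialize-then-parse is structurally exact
(property-tested over the whole catalog).

# State encoding

A state of an `n`-node network is a bit vector in declared node order. The
string form puts the first node leftmost — `"1001000"` for the present-day
models reads Activator/DegProtein/DegRNA/DNA/miRNA/mRNA/Protein — and the
integer form reads that string as a base-2 number (leftmost bit most
significant, `0`-based codes). This makes every state printed by the
package directly comparable with printed attractor tables, and makes
node iteration order (declaration order everywhere) reproducible
byte-for-byte.

# Update semantics and attractors

**Synchronous:** all nodes recompute from the same source state; the
dynamics is a function `F` on `2^n` states, and its state-transition graph
(STG) has out-degree exactly 1. Attractors are the cycles of `F` — fixed
points and limit cycles — and every state belongs to exactly one basin, so
basin counts sum to `2^n`. `findAttractorsSync()` finds cycle membership by
pointer doubling (composing `F` with itself `⌈log2 N⌉` times maps every
state onto its cycle), then walks each cycle and tallies basins. An
independent per-initial-state simulation oracle in the test suite confirms
attractors and basins on 100 seeded random networks.

**Asynchronous:** exactly one node updates per transition. The asynchronous
STG records the up-to-`n` distinct non-self successors per state;
self-transitions are not stored as edges, so a state fixed under every
single-node update is an isolated vertex (a *simple* attractor). *Complex
(loose) attractors* are terminal strongly connected components with at
least two states: closed (no single-node update leaves the set) and
strongly connected (every member reaches every other). They are computed
via strong components of the STG plus a condensation-terminality check, and
cross-checked against a reachability-closure oracle (`s` is an attractor
member iff everything reachable from `s` can reach `s` back). The edge
count reported for a complex attractor counts distinct directed non-self
internal transitions — the convention under which the present-day V2 loose
attractor has 32 states and 84 edges.

**Probabilistic:** each node independently selects one of its rules by its
probability, then all update synchronously. `pbnTransitionMatrix()`
enumerates the joint selections (8 for `CD-PBN`) and aggregates by target,
giving the exact row-stochastic transition law.

Limit cycles are canonicalized by rotating to their smallest integer state
and reporting forward-trajectory order; attractor sets are sorted by their
smallest member, so all reports are deterministic.

# Exact Markov iteration

`iterateDistribution()` applies the transition law to a distribution over
all `2^n` states, exactly. The default initial distribution is uniform:
under it, the long-run mass of a deterministic model's attractor equals its
basin fraction, which is how the absorption table's deterministic columns
tie out against the basin table (e.g. present-day V2's cycle mass
`0.047 + 0.047 + 0.203 + 0.234 = 0.531 = 68/128`). 1000 iterations is the
reporting default; deterministic networks iterate through the successor map
(`O(2^n)` per step, usable to the `n ≤ 24` guard) while PBNs use the dense
matrix (guarded at `n ≤ 16`). Mass conservation to 1e-9 over 1000 steps is
asserted in tests.

`reportAbsorption()` displays states above a probability cutoff. The cutoff
default is 0.001, chosen as the natural display threshold for 3-decimal
tables; display rounding is **half-up** (`0.0625 → 0.063`), the convention
of printed 3-decimal absorption tables, whereas R's own `round()` is half-even.
Comparisons in code always use the unrounded column.

# Graph statistics

**Centralities** (`stateCentralities()`): unweighted directed shortest-path
betweenness (endpoints excluded) and normalized closeness, via igraph. The
closeness direction is configurable; the default is the *outgoing*
convention (how quickly a state reaches the rest of the attractor), which
is the variant under which the all-ON state `1111111` is the closeness hub
of the present-day V2 loose attractor, with `1001111` the betweenness hub.
The incoming convention instead crowns `1001110`; both remain available via
`closenessMode`.

**Gini index** (`giniIndegree()`): inequality of the synchronous STG's
in-degree sequence, self-loop edges counted, with the small-sample
correction `n/(n-1)`. This estimator/self-loop combination is the recorded
matching variant: it reproduces the reference values 0.918 (present-day V1)
and 0.575 (1965) exactly, whereas the uncorrected population form gives
0.910/0.539 and no in-degree variant can distinguish the two 1965 versions
— their STGs have identical in-degree multisets, a fact the test suite
asserts. Both switches (`selfLoops`, `corrected`) are exposed.

# Robustness

`perturbationHamming()` draws a state uniformly, flips exactly one
uniformly chosen bit, advances both states one synchronous step (the
`steps` knob allows longer horizons) and records the normalized Hamming
distance between the images; the mean over `nCopies` trials is the
robustness observable. Closed forms anchor the implementation: the identity
network yields exactly `1/n` (the flip persists, nothing propagates), and a
network whose rules ignore all inputs yields exactly 0. The default
`nCopies = 100` matches the original protocol's sample size; the headline
ordering (every present-day version diverges less than either 1965 version)
is asserted at `nCopies = 1000`.

**Null model** (`randomizeLike()`): random networks with the same node
count and per-node in-degree, input sets drawn uniformly (self-inputs
allowed, as the catalog models themselves use self-loops) and truth tables
i.i.d. Bernoulli(0.5), rendered in disjunctive normal form so generated
networks flow through the same grammar and file formats as curated ones.
Matching in-degree isolates the effect of wiring *logic* from wiring
*density*. `significanceZ()` standardizes the observed statistic against
the null ensemble and reports a two-sided normal p-value; in a
`robustnessReport()` all randomness descends from one seed, making reports
bit-reproducible.

Under this null the present-day models' Hamming and Gini values are
significant at p < 0.05 while the 1965 models are not — the qualitative
split the analysis is designed to exhibit. The exact p-magnitudes depend on
the (otherwise unconstrained) choice of null ensemble and should be read as
pattern, not point estimates.

# What the synthetic generator does and does not emulate

`randomBooleanNetwork()` realizes the classical N-K random ensemble with a
truth-table bias knob. It emulates wiring-density-matched random logic —
the right null for "is this particular logic special given its density?" —
but not degree-distribution heterogeneity, canalyzing-function enrichment
or scale-free wiring, all of which real regulatory networks exhibit.
Passing the property tests on these ensembles therefore certifies the
*machinery* (attractor search, semantics, statistics) on arbitrary Boolean
networks; it does not certify biological realism of any particular random
ensemble.

Degenerate corners are defined, not excluded: `inDegree = 0` with bias 1
or 0 produces constant rules (rendered as tautology/contradiction in the
node's own literal, e.g. `x | !x`, keeping the grammar closed), and a DNF
whose truth table collapses to a constant mentions fewer inputs than
requested — realized in-degree is bounded by, not always equal to, the
requested one.

# Problem sizes and numerical choices

All shipped analyses are desk-scale and exhaustive: `2^4 = 16` and
`2^7 = 128` states, seconds on one CPU. Exhaustive enumeration is guarded
at `n ≤ 24` (dense PBN matrices at `n ≤ 16`); beyond that this package
deliberately declines rather than silently sampling. The test suite's
oracle comparisons use 100 random networks of 4–7 nodes, robustness
assertions use 20–30 seeds at 100–1000 perturbation copies, and the null
ensembles use 40–100 networks — sizes chosen so the full suite completes in
well under a minute while keeping Monte-Carlo assertions (3-standard-error
anchors, standard-error halving under sample quadrupling) statistically
meaningful.

Probability validity is enforced at 1e-9 throughout (per-node rule
probabilities, PBN row sums, distribution mass). Basin percentages are
exact rational counts out of `2^n`, rounded to 2 decimals only for display.
Ties in centrality argmaxes are possible on general graphs; the reference
attractor has unique maxima, and programmatic consumers should use the full
table rather than a single argmax.

# Known limitations

- The two 1965 model versions are indistinguishable by any in-degree Gini
  (identical multisets); reference values that differ between them cannot
  be reproduced from the in-degree sequence, and this package reports the
  common value 0.575.
- SBML-qual export covers deterministic networks only; PBNs have no qual
  encoding and round-trip through the BoolNet text dialect.
- No symbolic (BDD/SAT) attractor detection: state spaces beyond `2^24` are
  out of scope by design.
- Multi-valued logic, priority/delay update classes and continuous-time
  semantics are not modeled.
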