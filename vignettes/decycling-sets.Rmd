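---
title: "Exploring minimum decycling sets and their window guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring minimum decycling sets and their window guarantees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decyclr)
```

## The model

A context-free sketching scheme over an alphabet of size $\sigma$ selects
position $i$ of a sequence exactly when the $k$-mer starting there belongs
to a fixed set $M$. The scheme has a *window guarantee* — an upper bound
$w$ on runs of unselected positions — if and only if $M$ is a *decycling
set*: removing $M$ from the de Bruijn graph $D_k$ on all $\sigma^k$
$k$-mers leaves a DAG. Then $w$ equals the *remaining path length* (RPL)
of $M$, because a run of $p$ unselected positions is a $p$-vertex walk in
$D_k \setminus M$ and walks in a DAG are simple paths.

Every decycling set must intersect every cycle of $D_k$, in particular
every rotation orbit (*pure cycling register*, PCR). A *minimum decycling
set* (MDS) takes exactly one $k$-mer per PCR, so
$|M| = \frac{1}{k}\sum_{d \mid k} \varphi(d)\,\sigma^{k/d}$, the necklace
count. The package's subject is the space of all MDSs and the RPLs
(window guarantees) realized across it.

Two families of set-preserving edits structure this space. An *F-move* at
a $(k{-}1)$-mer word $f$ replaces the left companions
$lc(f) = \{af\}_{a \in \Sigma}$ — when all of them are in $M$ — by the
right companions $rc(f) = \{fa\}$; the *RF-move* is its inverse. F-moves
preserve the *hitting number* $\mathcal{H}_M(C) = |M \cap C|$ of every
cycle $C$, so the vector of all hitting numbers (the *cycle signature*)
is an invariant of each strongly connected component of the F-move graph
$G_{MDS}$. Components are $\sigma^{k-1}$-partite: each F-move edge
advances a layer index by one, cyclically, and the girth is
$\sigma^{k-1}$. An *I-move* $f|m$ swaps only the left companions flagged
by the bit-mask $m$ ($m_a = 1$ iff $af \in M$ before the move; the full
and zero masks are the F- and RF-moves and are excluded). I-moves also
map MDSs to MDSs but always change the signature, so they connect
different components; the component graph they induce is undirected (the
complement mask moves back).

## What the package computes

* `is_decycling()`, `remaining_path_length()` — Kahn peeling and
  longest-path dynamic programming over a topological order, implemented
  iteratively in C++ (no recursion-depth limits up to the $2^{26}$-node
  enumeration guard).
* `brute_force_mds()` — exhaustive scan of the Cartesian product of PCRs
  (the product of orbit sizes is 128 at $\sigma=2,k=4$ and 15 625 at
  $k=5$; the scan is refused above $10^7$ candidates).
* `enumerate_component()` — layered BFS keeping two resident layers plus
  a visited-key ledger; it checks the partite layer closure on every
  cross edge and fails loudly if it were ever violated.
* `component_i_moves()` — the component's full I-move list from a single
  member. A cycle hitting $M$ exactly once (*constrained cycle*) forbids
  $f|m$ throughout the component iff it uses an edge $af \to fb$ with
  $m_a = 1, m_b = 0$; the edges on constrained cycles are tagged with one
  forward and one backward $M$-avoiding search per member of $M$, so the
  cost is independent of component size.
* `enumerate_all_components()` — BFS over components, jumping along
  realized I-moves. Completeness rests on the connectivity of the
  component graph, which is an open conjecture in general; the test suite
  confirms it against brute force for $\sigma=2, k \le 5$, and the
  traversal reproduces the known totals at $k = 6, 7$ (273 components /
  68 288 MDSs and 4 / 18 432).
* `mykkeltveit_set()`, `syncmer_set()` — reference constructions;
  `anneal()` — simulated annealing for extremal RPL.

## Numerical and convention choices

**Vertices vs edges.** "Path length" is ambiguous by one. All internal
computation counts vertices; `rpl_calibration_offset()` fixes the
reported convention once by enumerating the 30 MDSs at $\sigma=2,k=4$ and
matching the known extrema 5 and 7 for that case. The measured
vertex-count range is exactly $[5,7]$, so the offset is 0: reported
lengths count vertices. The calibration is recomputed at run time, never
hard-coded, and would error on any third outcome.

**Mykkeltveit sector.** With the embedding
$W(u) = \sum_{j=0}^{k-1} u_{j+1}\,\omega^j$, $\omega = e^{2\pi i/k}$
(leftmost symbol at $j = 0$; a left rotation multiplies $W$ by
$\omega^{-1}$), the selected rotation of each nonzero-weight orbit is the
one whose *conjugate* weight argument lies in $[0, 2\pi/k)$ —
equivalently $\arg W \in (-2\pi/k, 0]$. We verified exhaustively for
$\sigma = 2, k = 3..8$ that sectors anchored on the positive or negative
real axis are the only ones that yield decycling sets under this $W$; the
frequently quoted sector $[0, 2\pi/k)$ belongs with the opposite
digit-indexing convention. Sector membership uses an absolute tolerance
of $10^{-9}$ (root-of-unity sums are well conditioned for $k \le 20$),
and exactly one rotation per orbit must qualify — asserted.

**Zero-weight orbits.** Orbits of period $< k$ (and occasional
full-period orbits) have $W = 0$ and no canonical rotation. Members are
tried in ascending code order with depth-first backtracking until the
completed set is decycling, and the result is verified (PCR set,
decycling, necklace-count size) before being returned. At $k = 5$ the
zero-weight orbits are exactly the two homopolymers, so the set is forced
and its RPL (11) equals the exhaustive minimum. Where zero-weight choices
are free the construction is a valid MDS but can differ from the classic
set — at $(2,6)$ it reaches RPL 13 (the global minimum) where the classic
choice gives 21 — so only the forced $k = 5$ value is treated as a
comparison point with published Mykkeltveit numbers.

**I-move masks.** The mask records the pre-move state ($m_a = 1$ iff
$af \in M$), so the full mask plays the role of the F-move and the zero
mask the RF-move; statements labeling the F-move as $f|0$ follow the
opposite convention and are treated as a labeling slip. For a homopolymer
word $f = a^{k-1}$ the shared $k$-mer $a^k$ counts as both companion
kinds: its bit is pinned to 1, it is never moved (sets are edited
remove-then-add, so $a^k$ survives F-moves too), and only
$2^{\sigma-1}-2$ masks remain admissible — none at $\sigma = 2$.

**Annealing schedule.** The search loop is: sample the current component
with $2k$ random F-moves tracking the local extremum of the RPL; compute
the component's I-moves; jump along a uniformly chosen one (realized from
a host member found in the layered enumeration); sample the new component
the same way; accept if its extremum improves, else with Metropolis
probability $e^{-|\Delta|/T}$; cool geometrically. Published accounts of
this procedure leave the schedule open, so the defaults — $T_0 = k$,
cooling 0.95 per iteration, restart by a $4k$-step random move walk when
a component has no I-move — are this package's choices, all exposed in
`anneal_config()`. With 200 iterations the exact extrema at $k = 4$ and
$k = 6$ are reached for (at least) a majority of seeds; runs are
reproducible from `(config, seed)`.

**Degenerate inputs.** The empty set is never decycling (homopolymer
self-loops remain); the full set is, with RPL 0 under both conventions.
Non-decycling inputs to `remaining_path_length()` raise a state error
("graph has a cycle") rather than returning a number. Operations that
materialize $\sigma^k$ objects refuse above `options(decyclr.max_nodes)`
(default $2^{26}$) with a resource error, and `enumerate_cycles()` — a
test instrument, not a production feature — is gated to 16 nodes by
default because simple-cycle counts explode.

## What the tests establish (and what they do not)

All experimental inputs are self-generated: de Bruijn graphs, PCR
partitions, MDSs and random sequences are built in code, so the "data"
under test is the stated combinatorial world itself, not an empirical
sample. Green tests establish: exact agreement with independent oracles
(igraph acyclicity, exhaustive-DFS longest paths) on small random sets;
the move-calculus invariants (move existence, MDS preservation,
signature invariance/changes, component symmetry, the constrained-cycle
characterization against a brute-force sweep at $k = 4$); the exhaustive
totals and RPL extrema for $\sigma = 2, k \le 7$; and the RPL bound
$|\Delta| \le 1$ for F/RF-moves and $\Delta \le +1$,
$\mathrm{new} \ge \lfloor \mathrm{old}/2 \rfloor - 1$ for I-moves over
random move sequences (a conservative reading of "decrease by half").
They do *not* establish anything about $k \ge 8$ (enumeration is
super-exponential; published values there are estimates and out of
scope), about alphabets beyond small $\sigma$, or about the classic
zero-weight tie-breaking of the original Mykkeltveit construction. The
window-guarantee checks use exhaustive sequence coverage only at small
lengths (all $2^{10}$ binary sequences of length 10 at $k = 4$) plus the
spelled witness path, which attains the bound by construction; longer
sequences are sampled.

## Known limitations

* Exhaustive traversal is practical to $\sigma = 2, k = 7$ on one CPU;
  beyond that only annealing estimates are available, and they are
  estimates of the same quantities, not replications.
* Completeness of `enumerate_all_components()` is conditional on
  component-graph connectivity (verified here up to $k = 7$).
* Reverse complements / canonical $k$-mers are not modeled; the graph is
  the plain directed de Bruijn graph.
* The Champarnaud construction and minimizer/minmer density analysis are
  out of scope.
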