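---
title: "Recovering rearranged chromosomes from karyotype graphs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering rearranged chromosomes from karyotype graphs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyocover)
```

## The model

Cancer genomes accumulate large-scale rearrangements — deletions,
duplications, inversions, translocations, whole-genome duplication — that
reorder and multiply pieces of the reference. Copy-number and
structural-variant callers can jointly be summarised as a *karyotype graph*
(weighted interval adjacency graph): reference segments contribute a tail and
a head vertex joined by a *segment edge*; observed transitions between
segment extremities contribute *adjacency edges* (reference adjacencies
follow the reference order, novel ones do not); every edge carries an integer
copy number $\mu(e)$. A linear chromosome is a segment/adjacency-alternating
walk that starts and ends with a segment edge; a circular chromosome (double
minute) is an alternating cycle.

The graph does not directly reveal the chromosomes. A candidate genome is an
*Eulerian decomposition* (ED): a multiset of alternating paths and cycles
using every edge exactly $\mu(e)$ times. Writing the *copy number excess* of
a vertex as

$$x(v) \;=\; \mu(e_S(v)) \;-\; \sum_{e \in E_A(v)} l(e)\,\mu(e),$$

with $l(e)=2$ for an adjacency loop and $1$ otherwise, a positive graph is
decomposable iff $x(v)\ge 0$ everywhere; vertices with $x(v)>0$ are
telomeres. Every ED has exactly $\tfrac12\sum_v x(v)$ paths, and the minimum
possible number of walks is that path count plus one cycle per fully
balanced connected component. `solve_edp()` builds an ED by balancing
telomeres with internal edges and matching segment to adjacency edge copies
at each vertex; `solve_min_edp()` then merges cycles into partners through
shared segment edges until the minimum is reached. Finding a *maximum*
cardinality ED is NP-hard (there is a reduction from triangle edge
partitioning, reproduced as `k3_reduction()`), so the package solves it only
by brute force on small instances.

## Consistent contigs

Minimal EDs are usually not unique, so instead of guessing one genome the
CCR algorithm (`run_ccr()`) reports *consistent contigs*: walks present in
every minimal ED. Formally it solves the consistent contig covering problem:
among coverings $T$ (segment edges used exactly $\mu$ times, adjacency edges
at most $\mu$ times) whose every walk occurs in every minimal ED, minimise
the *contiguity discordance*

$$\lVert G - T\rVert = \sum_{e \in E_A}\bigl(\mu(e) - \mu_T(e)\bigr),$$

the number of unused adjacency copies. The primitive covering (bare segment
copies) has discordance $\mu(E_A)$; any ED has discordance 0.

Per connected component CCR proceeds as follows.

1. **Balance transform.** A supplemental segment is attached to every
   telomere vertex ($\mu$ of the stub = $x(v)$, plus a head loop), making the
   component balanced so its minimal ED is a *single Eulerian cycle*.
2. **Forced-pair contraction.** Scan consecutive adjacency pairs $(e, y, f)$
   (both non-supplemental) in the current cycle. A pair is *forced* when
   every minimal ED routes $e$ and $f$ through a common copy of segment $y$.
   Forced pairs are contracted: one copy of $e$, $y$, $f$ is replaced by a
   chain edge joining the two outer endpoints, and the cycle is rewritten in
   place; the scan restarts until no unprocessed pair remains. Pairs judged
   not forced are never revisited.
3. **Terminal selection.** The leftover adjacency copies — and the optional
   outer attachments of every chain — are placed onto free segment copies,
   at most one attachment per copy (two adjacencies sharing a copy would
   form a walk already judged ambiguous). This is a maximum-cardinality
   b-matching: segments are nodes with capacity "free copies", ordinary
   adjacency copies are edges (loops demand two copies), chain ends are unit
   stubs. It is solved exactly by copy expansion to maximum matching with a
   blossom algorithm.

The emitted contigs are the chain interiors with whatever outer attachments
the matching retained, the selected two-segment contigs, and primitive
leftovers.

### The forced-pair decision

The original publication defers the forced-pair test to supplementary
material that is not part of this package's sources, so the package states
and implements its own exact criterion, validated against brute force. In
the balanced working graph every minimal ED is a single Eulerian cycle, and
a cycle corresponds to a choice, per segment, of a pairing between adjacency
ports at its two extremities. The pair $(e, y, f)$ is *avoidable* iff some
choice pairs no $e$-port with an $f$-port through $y$ **and** still yields
one connected cycle. The implementation starts from the current cycle,
reroutes all $(e,f)$ pairings at $y$ (count-feasible exactly when
$\lambda_e + \rho_f \le \mu(y)$, where $\lambda,\rho$ are the port counts),
then re-merges the resulting cycle fragments by transition swaps at shared
segment edges, refusing swaps at $y$ that would recreate $(e,f)$. If the
merge gets stuck the pair is forced: in a stuck state every remaining
fragment pair is separated only by $y$, one side carrying all remaining
$e$-ports and the other all $f$-ports, and a counting argument shows the
class-level pairing is then unique — no avoiding single cycle exists.
`is_pair_forced()` exposes this decision; the test suite checks it against
`forced_pairs_bruteforce()` on every enumerable instance.

### Chains commit their interior only

The published description adds both outer adjacencies of a forced pair to
the covering immediately, attaching them to any copies free at the relevant
extremities. There is a corner where that over-commits: several forced
chains can compete for the free copies of one flank segment, and the
brute-force optimum then drops exactly one contested outer adjacency (an
instance with three chains meeting a $\mu=2$ segment is constructed in
`test-ccr.R`). The package therefore lets each chain commit only its middle
segment copies and interior adjacencies; its two outer attachments enter the
terminal matching as optional unit demands. On every instance small enough
to enumerate, this reproduces the brute-force optimum exactly.

## Oracles

`enumerate_eds()` enumerates *all* EDs of a small graph: all ways of pairing
path endpoints at telomere vertices (symmetric count matrices over excess
vertices) times all per-segment port bijections, deduplicated up to walk
reversal, cycle rotation and multiset equality, per connected component.
`forced_pairs_bruteforce()`, `max_ed_bruteforce()` and
`optimal_covering_bruteforce()` derive from it. The default instance guard
is $\mu(E)\le 12$ (overridable); these functions are deliberately naive and
exist to define ground truth, never to stand in for the polynomial
algorithms.

With multiplicities, "present in every minimal ED" could mean at least one
occurrence or full multiplicity; the package fixes *at least once* (matching
one-copy-per-contraction semantics) and the oracle also reports the minimum
occurrence count per triple so the stricter reading is measurable.
Similarly, a closed contig counts as present only when it equals a cycle of
the decomposition up to rotation and reversal; open contigs are sub-walks
(wrapping across a cycle's rotation point is allowed).

## The simulator

`simulate_case()` draws a reference of `n_chrom` chromosomes (default 2, a
deliberately small karyotype so that oracle-sized graphs are common), each
`chrom_length` bp (default $10^8$, chromosome scale) split into
`segments_per_chrom` segments at uniform breakpoints (default 8; RCK-style
graphs are segmented at breakends, and this fixed pre-segmentation plays
that role — events act at existing boundaries). Default event counts are one
each of deletion, tandem duplication, inversion and reciprocal
translocation, spans of at most 3 segments: enough to create ambiguity
(duplications produce $\mu=2$ segments) while keeping truth recoverable.
Whole-genome duplication and circularization are off by default. Colliding
novel adjacencies merge with summed $\mu$. All randomness flows from the
single mandatory seed.

What a green test establishes: the algorithms are exact on graphs whose
ambiguity comes from these event classes at boundary-aligned breakpoints.
What it does not establish: behaviour on graphs with inference noise
(RCK-estimated copy numbers can be locally inconsistent), haplotype mixing,
or hotspot breakpoint clustering — real karyotype graphs are messier than
the generator in those specific ways.

## Numerical and degenerate-input choices

* Iteration order is canonical everywhere (sorted segment ids, edge keys),
  so all outputs are deterministic and invariant to input row order; no
  seeds are consumed outside the simulator.
* Adjacency edges are keyed by unordered extremity pair *plus kind*, so a
  reference and a novel adjacency between the same extremities are distinct
  parallel edges.
* A $\mu=0$ segment carrying a $\mu\ge 1$ adjacency is rejected at build
  time (fail fast on inconsistent input); `positive_restriction()` drops
  $\mu=0$ edges otherwise.
* The empty graph is decomposable with an empty decomposition of size 0.
* A fully forced balanced component ends as a single closed contig, emitted
  when the working cycle shrinks to one segment copy (at that point the
  remaining graph has a unique ED, so no further check is needed).
* Ties in the terminal matching are broken by the deterministic order of the
  expansion; the discordance (the objective) is tie-free.
* N50 returns the larger qualifying length on even splits (descending sort,
  cumulative $\ge$ half); closed contigs contribute their full length.

## Scaling

The solvers are quadratic in total multiplicity in the worst case. The CI
suite only asserts functional correctness on a $\mu(E)\approx 600$ instance;
`scripts/benchmark.R` runs the documented large benchmark
($\mu(E)\approx 5000$: 24 chromosomes of 50 segments, 200 events plus WGD)
and prints the timings and contiguity comparison against the naive baseline
— run it to reproduce the scaling claim on your machine; on one CPU it
finishes far inside the five-minute envelope the quadratic bound suggests.
Brute-force oracles are exponential and guarded at $\mu(E)\le 12$ by
default.

## Known limitations

* Single-clone, single-haplotype tables are the unit of input; per-clone RCK
  exports must be projected by the user (the algorithm itself does not
  distinguish haplotype-specific from haploid graphs).
* No sequence-level output: contigs are paths of oriented reference
  intervals (contig table or AGP), not FASTA.
* The forced-pair stuckness argument is proven at the pairing-class level;
  graphs combining adjacency loops at a contested segment with high
  multiplicities are exactly the regime the oracle-equivalence suite
  stresses, and no counterexample has surfaced on the randomised and
  simulated instances tested.
* max-EDP has no polynomial solver by design (NP-hard); only the guarded
  brute force handles it.
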