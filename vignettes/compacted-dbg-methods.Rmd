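---
title: "Methods: compacted de Bruijn graph construction in cdbg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compacted de Bruijn graph construction in cdbg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbg)
```

## The model

`cdbg` works on the *bidirected, edge-centric* de Bruijn graph
$G(\mathcal{R}, k)$ of a set $\mathcal{R}$ of DNA sequences. The edge set
$\mathcal{E}$ is the set of *canonical* $(k+1)$-mers — each window pooled
with its reverse complement, identified by their lexicographic minimum
(A < C < G < T) — that occur at least $f_0$ times in $\mathcal{R}$. The
vertex set $\mathcal{V}$ is induced: the canonical $k$-mers occurring as
prefix or suffix of an edge. Every vertex has two *sides*, front and back;
an edge attaches to the back of its prefix $k$-mer's vertex exactly when the
prefix is canonical (front otherwise) and to the front of its suffix
$k$-mer's vertex exactly when the suffix is canonical (back otherwise). $k$
must be odd so no $k$-mer is its own reverse complement.

A *maximal unitig* is a path that cannot be extended while all its internal
vertices keep exactly one incident edge per side; the compacted graph is the
set of these paths. A *maximal vertex-disjoint path cover* is a set of
non-overlapping paths covering every vertex, to which no remaining edge can
join two paths. Both are spectrum-preserving: their spellings contain
exactly the $k$-mers of $\mathcal{V}$.

## The algorithm

The pipeline never materializes the graph. It runs in five stages:

1. **Edge enumeration** (`enumerate_edges`). Sequences are split at
   non-ACGT symbols, and their $(k+1)$-mer windows are partitioned into
   bins by a *signature* — the smallest canonical `msig`-mer inside the
   window — so that a window and its reverse complement always share a
   bin. Maximal runs of windows with one signature (super-mers) are stored
   per bin; each bin is expanded, sorted on the 2-bit packing (whose
   word order equals lexicographic order), deduplicated by run-length, and
   filtered at $f_0$.
2. **Vertex extraction** (`extract_vertices`): the sorted distinct
   canonical end $k$-mers of the edges.
3. **Minimal perfect hashing** (`build_mphf`). A multi-level
   collision-free bit-marking scheme: each level hashes its surviving keys
   into $\lceil \gamma n_i \rceil$ bits; uniquely hit positions resolve
   their keys, colliding keys continue. The hash value is the rank of the
   key's bit in the concatenated arrays, so the image is exactly
   $[0, n)$. Stragglers after `max_levels` go to an exact sorted-array
   fallback.
4. **State computation** (`compute_states`). Each vertex is a 36-state
   automaton: per side one of *none*, *multi*, or *unique_c* for
   $c \in \{A,C,G,T\}$ (6 × 6 states, 6 bits). For every edge, each
   endpoint receives the input (side, symbol), where the symbol is the
   edge's terminal symbol in the form containing the endpoint's canonical
   $k$-mer. The resulting side state depends only on the *set* of distinct
   symbols fed, so edge order is irrelevant.
5. **Unitig extraction** (`extract_unitigs`). For each unvisited vertex,
   two walks leave through its two sides. A walk decodes the unique edge
   from the state, crosses to the neighbor's entrance side, and continues
   from the opposite side until it meets a *flanking* vertex: one whose own
   state class is not unique-front unique-back, or whose next meeting side
   carries more than one edge. The two subpaths are glued at the start
   vertex and emitted once, in canonical orientation.

Path covers reuse the same machinery: during state computation, edges are
examined in a seeded deterministic order and admitted only when both
endpoint sides are still empty, which keeps the admitted subgraph
branch-free; extraction then emits its maximal paths.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | — | odd k-mer length, 3–127 (vertices); edges are (k+1)-mers |
| `f0` | 1 | solidity threshold in occurrences; below it a (k+1)-mer is treated as a sequencing error |
| `gamma` | 2 | hash codomain expansion; size ≈ γe^{1/γ} bits/key against O(e^{1/γ}) expected probes |
| `msig`, `bins` | 9, 512 | signature length and bin count for counting; affect only partitioning, never output |
| `seed` | 1 | drives hash level seeds and path-cover admission order |
| `memory_budget` | 256 MB | counting buffer bytes before bins spill to temporary files |

At γ = 2 the hash arrays take an expected γe^{1/γ} ≈ 3.30 bits per key; the
rank index (one 64-bit cumulative count per 512-bit block, 12.5%) brings
the measured encoding to ≈ 3.7 bits/key, and the 6-bit state array brings
the whole associative structure to ≈ 9.7 bits per distinct k-mer. Those
two numbers are what `scripts/acceptance.R` measures.

## Numerical and design choices

* **Symbol coding.** A=0 < C=1 < G=2 < T=3, packed two bits per symbol,
  32 per 64-bit word, most significant first — integer comparison of packed
  words *is* lexicographic comparison, so canonicalization and bin sorting
  need no decoding.
* **Non-ACGT symbols** split sequences; no window spans them. Input is
  case-insensitive. Positions are 1-based.
* **Signatures** are plain smallest-canonical-substring minimizers without
  the exclusion heuristics counting tools use to balance bins: those only
  redistribute work, and the output is independent of the partition (the
  test suite checks equality with a naive dictionary counter). When
  `msig > k+1` the signature length is clamped.
* **Palindromic (k+1)-mers** (possible since k+1 is even) are stored once,
  with counts pooled over both orientations; their two endpoint incidences
  coincide, and the duplicate input is idempotent for the automaton.
* **Loops** (edges whose endpoints are one vertex) are fed to the single
  automaton twice, once per endpoint incidence. During walks, a decoded
  edge leading back to the current vertex flanks it — a loop can never be
  unitig-internal. In path-cover mode loops are never admitted: a loop
  cannot join two different paths.
* **Cycles.** A component may be an entirely branch-free cycle with no
  flanking vertex. The walk detects the return to its start, emits the
  component once as a cyclic record, and rotates the spelling so the
  lexicographically smallest canonical k-mer leads; output is therefore
  independent of iteration order. A cyclic record of n vertices spells
  n + k − 1 symbols; its n-th edge is the wrap-around window.
* **Path-cover admission is purely local.** Following the side-occupancy
  rule, an edge joining the two free ends of a *single* path cannot be
  distinguished from one joining two different paths using vertex states
  alone, so a branch-free cycle can occasionally be admitted (frequently
  at k = 3, where the graph is dense). Such components are emitted as
  cyclic records; they still cover their vertices exactly once and block
  both of their sides, so the cover remains vertex-disjoint, covering and
  maximal. The exhaustive tiny-graph enumeration used in the tests
  compares only cycle-free covers.
* **Visited marking** lives in a separate bit array rather than in
  reserved state codes: 36 marked variants would not fit 6 bits, and
  keeping states intact lets walks inspect the neighbors of already
  emitted unitigs.
* **Determinism.** Identical input and seed give byte-identical output:
  edges and vertices are sorted, records are emitted in canonical
  orientation and sorted, and the path-cover order is a seeded permutation
  of the sorted edge list. Execution is serial.
* **Degenerate inputs.** Empty input, sequences shorter than k+1, or
  all-N sequences yield an empty spectrum and an empty FASTA plus a zeroed
  report, without error.

## The synthetic data generator

`random_genome` draws i.i.d. uniform bases. `simulate_reads` samples
fixed-length reads uniformly from both strands with independent per-base
substitution errors; read starts may overhang the genome ends (clipped),
so terminal windows get the same expected coverage as interior ones —
otherwise the first and last (k+1)-mers would almost never reach the
solidity threshold at any realistic coverage. The error model is
substitution-only because the algorithm sees its input solely through the
(k+1)-mer spectrum.

What this emulates — and what it does not: uniform base composition, no
repeats beyond chance, uniform coverage, strand symmetry, no quality
structure, no indels, no chimeras. Passing the randomized equivalence
suite therefore demonstrates correctness of the graph algorithms on
arbitrary spectra of this kind, not robustness to the coverage biases and
error profiles of real instruments.

## Verification strategy and problem sizes

Every stage is checked against an independent brute-force implementation
kept deliberately naive (plain dictionaries, explicit adjacency lists, no
shared code with the packed/hashed path): dictionary counting, explicit
incidence-list unitigs, and exhaustive path-cover enumeration on tiny
graphs. The randomized equivalence suite runs a hundred-plus instances
over k ∈ {3, 15, 31, 63} and f0 ∈ {1, 2, 4}, genomes from 150 b to 50 kb
and simulated read sets, in both output modes; hash structure checks use
10^5 random 31-mers over five build seeds. These sizes exercise multi-word
packing (k ≥ 33), palindromes and loops (k = 3), threshold filtering, and
multi-level hashing, while keeping the whole suite runnable on a desk
machine in minutes.

## Known limitations

* Serial only; the concurrent lock-striped traversal of large-scale tools
  is out of scope.
* `k ≤ 127` (four 64-bit words per (k+1)-mer).
* The counting stage's spill mechanism bounds the in-memory buffer, not
  the per-bin sort; pathological inputs concentrated in one bin sort that
  bin in memory.
* No GFA topology output; the FASTA records carry only per-unitig length,
  vertex count and cyclicity tags.
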