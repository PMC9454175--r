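# cdbg — compacted de Bruijn graphs from reads and references

`cdbg` constructs the **compacted de Bruijn graph** — the set of maximal
unitigs — and **maximal vertex-disjoint path covers** of DNA sequence sets,
from FASTA/FASTQ reads or references (plain or gzipped). It is aimed at
people who need the canonical first data reduction of sequence analysis —
assembly front-ends, k-mer indexes, spectrum-preserving string sets — at
desk scale, with every stage verifiable against brute force.

## The method

For sequences \(\mathcal{R}\), an odd \(k\) and an abundance threshold
\(f_0\), the bidirected edge-centric graph \(G(\mathcal{R},k)\) has edge set
\(\mathcal{E}\) = the canonical \((k{+}1)\)-mers occurring \(\ge f_0\) times,
and vertex set \(\mathcal{V}\) = their canonical end \(k\)-mers. Each vertex
has a *front* and a *back* side; incidence sides are fixed by which
orientation of the end \(k\)-mer is canonical. The pipeline is:

1. enumerate \(\mathcal{E}\) by minimizer-partitioned sort-and-count;
2. extract \(\mathcal{V}\) from \(\mathcal{E}\);
3. build a minimal perfect hash \(h:\mathcal{V}\to[0,n)\)
   (multi-level collision-free bit marking, \(\gamma e^{1/\gamma}\) bits/key
   expected — ≈ 3.7 bits at \(\gamma=2\) with the rank index);
4. fold every edge into per-vertex DFA states (36 states = 6 side-states
   per side, 6 bits each, ≈ 9.7 bits/vertex for the whole table);
5. walk the unitigs out piecewise, decoding unique edges from the states,
   stopping at flanking vertices.

A maximal path cover is obtained by admitting, in a seeded order, only the
edges whose two endpoint sides are still free, then running the same
extraction. The graph itself is never materialized.

## A worked example

The set `{CTAAGAT, CGATGCA, TAAGAGG}` at `k = 3` gives a graph with 10
vertices and 10 edges (one of them the palindromic loop `TGCA`):

```r
library(cdbg)
res <- compact_dbg(c("CTAAGAT", "CGATGCA", "TAAGAGG"), k = 3, f0 = 1)
res$unitigs
#> <unitig_set> 4 records, k = 3 , mode = unitigs
#>   spelling vertex_count is_cycle
#> 1     CCTC            2    FALSE
#> 2      CGA            1    FALSE
#> 3   CTAAGA            4    FALSE
#> 4    GATGC            3    FALSE
```

Four maximal unitigs, spelled in canonical orientation, covering all 10
vertices exactly once (`sum(res$unitigs$vertex_count)` is 10). `CTAAGA` is
the chain CTA–TAA–AAG–AGA, which stops at `AGA` because its back side
carries two distinct edges. In path-cover mode:

```r
pc <- compact_dbg(c("CTAAGAT", "CGATGCA", "TAAGAGG"), k = 3,
                  mode = "path-cover", seed = 1)
sort(pc$unitigs$spelling)
#> [1] "CCTCTTAG" "CGATGC"
```

one of this graph's two maximal path covers (the other spells
`{CTAAGATGC, CGA, CCTC}`); `oracle_path_covers(build_explicit_graph(...))`
enumerates both. On files, and from the shell:

```sh
Rscript inst/cli/cdbg.R -s reads_1.fq.gz -s reads_2.fq.gz \
    -k 31 -c 2 -o unitigs.fa --seed 1
```

which writes FASTA records tagged `LN:i:` (length), `KC:i:` (vertex count)
and `CY:i:` (cyclic), plus a JSON run report at `unitigs.fa.json`.

## Package layout

* `R/`, `src/` — pipeline stages (`enumerate_edges`, `extract_vertices`,
  `build_mphf`, `compute_states`, `extract_unitigs`, `compact_dbg`) with
  the packed-mer and traversal cores in C++;
* `R/oracle.R`, `R/synth.R` — independent brute-force references and
  synthetic genome/read generators used as ground truth;
* `vignettes/compacted-dbg-methods.Rmd` — the model, the algorithm, every
  tunable parameter, and the package's design decisions;
* `inst/cli/cdbg.R` — the command-line wrapper.
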