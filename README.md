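# karyocover

Recovering the linear and circular chromosome structure of rearranged cancer
genomes from weighted karyotype graphs (interval adjacency graphs), in R.

Copy-number and structural-variant calls on a tumour sample can be reconciled
into a *karyotype graph*: one segment edge per reference segment, one
adjacency edge per observed transition between segment extremities, each with
an integer copy number μ(e). The graph constrains, but does not determine,
the underlying chromosomes: any multiset of segment/adjacency-alternating
paths and cycles using every edge exactly μ(e) times — an *Eulerian
decomposition* (ED) — is a candidate genome, and there are usually many.

`karyocover` implements:

* the weighted interval adjacency graph model, with the copy-number excess
  x(v) = μ(e_S(v)) − Σ l(e)·μ(e) and the decomposability criterion
  x(v) ≥ 0 everywhere;
* Eulerian decomposition (`solve_edp()`) and minimal-cardinality
  decomposition (`solve_min_edp()`), whose size is fixed at
  ½·Σ x(v) + #(balanced components);
* the NP-hard maximal decomposition only via a guarded brute force, plus the
  triangle-edge-partition reduction (`k3_reduction()`) behind the hardness;
* **CCR** (`run_ccr()`): the consistent contig covering — the longest walks
  present in *every* minimal ED, hence unambiguous no matter which genome
  the graph encodes, with minimum contiguity discordance
  ‖G − T‖ = Σ (μ(e) − μ_T(e)) over adjacency edges;
* a naive locally-unambiguous baseline (`naive_covering()`) and the
  primitive covering;
* exponential brute-force oracles (`enumerate_eds()`,
  `forced_pairs_bruteforce()`, `optimal_covering_bruteforce()`) defining
  ground truth on small instances;
* a structural-variant genome simulator with known truth
  (`simulate_case()`);
* contiguity metrics (N50, discordance, truth support) and readers/writers
  for segment/adjacency copy-number tables (RCK dialect), contig-path tables
  and AGP 2.1;
* a CLI (`inst/cli/karyocover`): `simulate`, `decompose`, `ccr`, `stats`,
  `verify`.

## Worked example

A tandem duplication of segment b in the chromosome a–b–c gives the graph
with μ(b) = 2 and adjacencies a:h–b:t, b:h–b:t, b:h–c:t:

```r
library(karyocover)
g <- example_iag("tandem")
copy_number_excess(g)
#> a:h a:t b:h b:t c:h c:t
#>   0   1   0   0   1   0
solve_min_edp(g)
#> kc_decomposition: 1 paths, 0 cycles
#> path:  a+ b+ b+ c+
cv <- run_ccr(g)
cv
#> kc_covering: 1 contigs, discordance 0
covering_stats(g, cv)
#>   n_contigs total_bp n50_bp n_closed discordance
#> 1         1     4000   4000        0           0
```

The two telomere vertices (x = 1 at a:t and c:h) force one linear
chromosome; its unique minimal decomposition is the single path
`a+ b+ b+ c+`, so CCR recovers the whole chromosome with discordance 0
(every adjacency copy used). On the `"ambiguous"` example two minimal
decompositions disagree about every pairing through b, and CCR instead
returns the unambiguous pieces:

```r
g2 <- example_iag("ambiguous")
run_ccr(g2)
#> kc_covering: 4 contigs, discordance 2
```

`discordance 2` means exactly two adjacency copies could not be placed in
any consistent contig — the brute-force optimum for this graph.

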