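Package: karyocover
Title: Eulerian Decomposition and Consistent Contig Covering of Cancer Karyotype Graphs
Version: 0.1.0
Authors@R:
    person("karyocover", "developers", email = "karyocover@example.org", role = c("aut", "cre"))
Description: Tools for recovering the linear and circular chromosome structure of
    rearranged cancer genomes from weighted interval adjacency (karyotype)
    graphs. Implements Eulerian decomposition of copy-number-weighted segment
    and adjacency edges, minimal-cardinality decomposition, the consistent
    contig covering algorithm (CCR) that extracts walks shared by every
    minimal decomposition, exponential brute-force oracles for validation on
    small instances, a structural-variant genome simulator with known truth,
    contiguity metrics (N50, discordance), and readers and writers for
    segment and adjacency copy-number tables, contig-path tables and AGP.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    optparse
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
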