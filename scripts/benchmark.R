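#!/usr/bin/env Rscript
# Scaling benchmark: CCR on a simulated graph with total edge multiplicity
# around 5000, one CPU.  Not part of the test suite; results are reported in
# the methods vignette.  Usage: Rscript scripts/benchmark.R [seed]

suppressPackageStartupMessages(library(karyocover))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 99L

cfg <- sim_config(n_chrom = 24L, chrom_length = 1e8, segments_per_chrom = 50L,
                  n_del = 40L, n_dup = 60L, n_inv = 60L, n_tra = 40L,
                  n_circ = 3L, wgd = TRUE, seed = seed)
cs <- simulate_case(cfg)
g <- cs$graph
cat(sprintf("graph: %d segments, %d adjacencies, mu(E) = %d\n",
            nrow(g$segments), nrow(g$adjacencies), mu_total(g)))

t0 <- proc.time()
dm <- solve_min_edp(g)
t1 <- proc.time()
cat(sprintf("min-EDP: %d walks in %.1f s\n", length(dm$walks), (t1 - t0)[3]))

t0 <- proc.time()
cv <- run_ccr(g)
t1 <- proc.time()
stopifnot(validate_covering(g, cv)$ok)
st <- covering_stats(g, cv)
cat(sprintf("CCR: %d contigs, discordance %d, N50 %.2f Mbp in %.1f s\n",
            st$n_contigs, st$discordance, st$n50_bp / 1e6, (t1 - t0)[3]))
stn <- covering_stats(g, naive_covering(g))
cat(sprintf("naive: %d contigs, discordance %d, N50 %.2f Mbp\n",
            stn$n_contigs, stn$discordance, stn$n50_bp / 1e6))
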