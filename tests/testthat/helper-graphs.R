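# Shared generators for the test suite.  All fixtures are built in code.

f1 <- function() example_iag("tandem")      # a b b c, unique min-ED
f2 <- function() example_iag("ambiguous")   # two min-EDs through b
f3 <- function() example_iag("circular")    # single circular chromosome

# Random positive decomposable graph with small total multiplicity,
# including loops and parallel kinds; NULL when the draw is unusable.
random_small_iag <- function(seed, max_mu = 12L) {
  set.seed(seed)
  ns <- sample(1:3, 1)
  ids <- letters[seq_len(ns)]
  mu <- sample(1:3, ns, replace = TRUE)
  verts <- c(paste0(ids, ":t"), paste0(ids, ":h"))
  adj <- NULL
  for (k in seq_len(sample(0:4, 1))) {
    adj <- rbind(adj, data.frame(v1 = sample(verts, 1), v2 = sample(verts, 1),
                                 kind = sample(c("reference", "novel"), 1),
                                 mu = sample(1:2, 1)))
  }
  g <- tryCatch(build_iag(stats::setNames(mu, ids), adj),
                error = function(e) NULL)
  if (is.null(g) || !is_decomposable(g)) return(NULL)
  if (mu_total(g) > max_mu || mu_total(g) == 0L) return(NULL)
  g
}

# a batch of usable random small graphs
small_graph_pool <- function(seeds) {
  Filter(Negate(is.null), lapply(seeds, random_small_iag))
}

random_sim_case <- function(seed) {
  cfg <- sim_config(n_chrom = 1L + seed %% 2L, chrom_length = 1e7,
                    segments_per_chrom = 2L + seed %% 4L,
                    n_del = seed %% 2L, n_dup = (seed %% 3L == 0L) * 1L,
                    n_inv = seed %% 2L, n_tra = (seed %% 5L == 0L) * 1L,
                    n_circ = (seed %% 7L == 0L) * 1L,
                    wgd = seed %% 11L == 0L, seed = seed)
  simulate_case(cfg)
}

# multiset equality of walks up to reversal/rotation
walksets_equal <- function(a, b) {
  ca <- sort(vapply(a, canonical_walk_string, character(1)))
  cb <- sort(vapply(b, canonical_walk_string, character(1)))
  identical(ca, cb)
}
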