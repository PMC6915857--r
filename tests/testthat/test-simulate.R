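# Genome simulator: determinism, event semantics, induced graphs.

test_that("configuration is validated and the seed is mandatory", {
  expect_error(sim_config(), "seed")
  cfg <- sim_config(seed = 1L)
  expect_s3_class(cfg, "kc_sim_config")
})

test_that("reference genomes are identity walks and zero events are a no-op", {
  cfg <- sim_config(n_chrom = 1L, segments_per_chrom = 3L, n_del = 0L,
                    n_dup = 0L, n_inv = 0L, n_tra = 0L, seed = 5L)
  cs <- simulate_case(cfg)
  expect_length(cs$genome$chromosomes, 1L)
  ch <- cs$genome$chromosomes[[1]]
  expect_equal(ch$orients, rep(1L, 3L))
  expect_equal(ch$segs, cs$reference$chromosomes[[1]]$segs)
  g <- cs$graph
  expect_true(all(g$adjacencies$kind == "reference"))
  expect_true(all(g$segments$mu == 1L))
})

test_that("identical seeds give identical cases; different seeds differ", {
  cfg <- sim_config(seed = 11L)
  a <- simulate_case(cfg)
  b <- simulate_case(cfg)
  expect_identical(a$graph, b$graph)
  expect_true(walksets_equal(a$truth, b$truth))
  c2 <- simulate_case(sim_config(seed = 12L))
  expect_false(identical(a$graph, c2$graph))
})

test_that("event primitives act at segment boundaries", {
  ref <- structure(list(
    segments = data.frame(id = c("a", "b", "c"), chrom = "chr1",
                          start = c(1L, 11L, 21L), end = c(10L, 20L, 30L)),
    chromosomes = list(list(segs = c("a", "b", "c"),
                            orients = c(1L, 1L, 1L), closed = FALSE)),
    ref_pairs = c("a:h b:t", "b:h c:t"), log = character(0)),
    class = "kc_genome")

  # tandem duplication of b reproduces the tandem fixture pattern
  dup <- ref
  dup$chromosomes[[1]]$segs <- c("a", "b", "b", "c")
  dup$chromosomes[[1]]$orients <- rep(1L, 4L)
  gi <- genome_to_iag(dup)
  expect_equal(seg_mu(gi$graph)[["b"]], 2L)
  expect_equal(sort(gi$graph$adjacencies$kind), c("novel", "reference", "reference"))
  expect_true(validate_decomposition(gi$graph, gi$truth)$ok)
  # and the induced graph matches the in-memory fixture up to naming
  expect_equal(unname(sort(copy_number_excess(gi$graph))),
               unname(sort(copy_number_excess(f1()))))

  # inversion flips orientation and creates two novel adjacencies
  inv <- ref
  inv$chromosomes[[1]]$orients <- c(1L, -1L, 1L)
  gi2 <- genome_to_iag(inv)
  expect_equal(sum(gi2$graph$adjacencies$kind == "novel"), 2L)

  # whole-genome duplication doubles every multiplicity
  wgd <- ref
  wgd$chromosomes <- c(wgd$chromosomes, wgd$chromosomes)
  gi3 <- genome_to_iag(wgd)
  expect_true(all(seg_mu(gi3$graph) == 2L))
  expect_true(all(adj_mu(gi3$graph) == 2L))
})

test_that("simulated graphs are always decomposable with the truth as witness", {
  for (s in 1:25) {
    cs <- random_sim_case(s)
    g <- cs$graph
    expect_true(is_decomposable(g))
    v <- validate_decomposition(g, cs$truth)
    expect_true(v$ok, info = paste("seed", s, paste(v$violations, collapse = ";")))
    expect_lte(min_decomposition_size(g), length(cs$truth))
  }
})

test_that("unit-copy cases recover the true chromosomes exactly", {
  for (s in c(3, 9, 21, 33)) {
    cfg <- sim_config(n_chrom = 2L, segments_per_chrom = 5L, n_del = 1L,
                      n_dup = 0L, n_inv = 1L, n_tra = 0L, wgd = FALSE,
                      seed = s)
    cs <- simulate_case(cfg)
    if (any(seg_mu(cs$graph) != 1L)) next
    cv <- run_ccr(cs$graph)
    expect_true(walksets_equal(cv$walks, cs$truth), info = paste("seed", s))
    expect_equal(contiguity_discordance(cs$graph, cv), 0L)
    for (w in cv$walks) expect_true(contig_supported(w, cs$truth))
  }
})
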