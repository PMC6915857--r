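# The CCR algorithm and its baselines.

test_that("primitive covering and discordance identities", {
  g <- f1()
  pr <- primitive_covering(g)
  expect_length(pr$walks, 4L)
  expect_equal(contiguity_discordance(g, pr), 3L)   # mu(E_A)
  expect_equal(contiguity_discordance(f2(), primitive_covering(f2())), 4L)
  gfree <- build_iag(c(a = 2L))
  expect_equal(contiguity_discordance(gfree, primitive_covering(gfree)), 0L)
  # any Eulerian decomposition has discordance 0
  expect_equal(contiguity_discordance(g, solve_min_edp(g)$walks), 0L)
})

test_that("validate_covering catches usage violations", {
  g <- f1()
  k <- g$adjacencies$key[1]
  over <- c(primitive_covering(g)$walks,
            list(walk(c("a", "b"), c(1L, 1L), g$adjacencies$key[grepl("a:h", g$adjacencies$key)])))
  v <- validate_covering(g, over)
  expect_false(v$ok)
  miss <- primitive_covering(g)$walks[-1]
  expect_false(validate_covering(g, miss)$ok)
  expect_true(validate_covering(g, primitive_covering(g))$ok)
})

test_that("balance_transform balances telomere vertices", {
  bt1 <- balance_transform(f1())
  g1 <- bt1$graph
  expect_true(all(copy_number_excess(g1) == 0L))
  supp <- g1$segments[g1$segments$id == bt1$supp_segment, ]
  expect_equal(supp$mu, 2L)
  expect_equal(sum(g1$adjacencies$kind == "supplemental"), 3L)  # 2 stubs + loop
  expect_equal(min_decomposition_size(g1), 1L)

  expect_identical(balance_transform(f3())$graph, f3())

  bt2 <- balance_transform(f2())
  g2 <- bt2$graph
  expect_equal(g2$segments$mu[g2$segments$id == bt2$supp_segment], 4L)
  expect_true(all(copy_number_excess(g2) == 0L))
})

test_that("is_pair_forced agrees with the oracle on fixture pairs", {
  # tandem fixture: both pairs through b are forced
  bt <- balance_transform(f1())
  wg <- bt$graph
  D <- solve_min_edp(wg)$walks
  k_ab <- grep("a:h\\|b:t", wg$adjacencies$key, value = TRUE)
  k_bb <- grep("novel\\|b:h\\|b:t", wg$adjacencies$key, value = TRUE)
  k_bc <- grep("b:h\\|c:t", wg$adjacencies$key, value = TRUE)
  expect_true(is_pair_forced(wg, D, "b", k_ab, k_bb, side_e = "t"))
  expect_true(is_pair_forced(wg, D, "b", k_bb, k_bc, side_e = "t"))

  # ambiguous fixture: nothing through b is forced
  bt2 <- balance_transform(f2())
  wg2 <- bt2$graph
  D2 <- solve_min_edp(wg2)$walks
  k1 <- grep("a:h\\|b:t", wg2$adjacencies$key, value = TRUE)
  k2 <- grep("b:h\\|d:t", wg2$adjacencies$key, value = TRUE)
  expect_false(is_pair_forced(wg2, D2, "b", k1, k2, side_e = "t"))
})

test_that("run_ccr recovers the fixtures optimally", {
  cv1 <- run_ccr(f1())
  expect_length(cv1$walks, 1L)
  expect_equal(format(cv1$walks[[1]]), "a+ b+ b+ c+")
  expect_equal(contiguity_discordance(f1(), cv1), 0L)

  cv2 <- run_ccr(f2())
  expect_equal(contiguity_discordance(f2(), cv2), 2L)
  expect_true(validate_covering(f2(), cv2)$ok)

  cv3 <- run_ccr(f3())
  expect_length(cv3$walks, 1L)
  expect_true(cv3$walks[[1]]$closed)
  expect_equal(contiguity_discordance(f3(), cv3), 0L)
})

test_that("contested chain flanks fall back to the terminal matching", {
  # Three forced chains all need an attachment copy of z, but mu(z) = 2:
  # the optimal covering must leave exactly one of the contested
  # adjacencies unused (discordance 1).
  g <- build_iag(
    c(u = 1L, p = 1L, v = 1L, q = 1L, x = 1L, y = 1L, z = 2L),
    data.frame(v1 = c("u:h", "p:h", "v:h", "q:h", "x:h", "y:h"),
               v2 = c("p:t", "z:t", "q:t", "z:t", "y:t", "z:h"),
               kind = "novel", mu = 1L))
  cv <- run_ccr(g)
  expect_true(validate_covering(g, cv)$ok)
  expect_equal(contiguity_discordance(g, cv), 1L)
  oc <- optimal_covering_bruteforce(g, cap = 14L)
  expect_equal(oc$discordance, 1L)
  fp <- forced_pairs_bruteforce(g, cap = 14L)
  expect_setequal(unique(attr(cv, "contracted_pairs")), fp$key)
  # every emitted contig is consistent with every minimal decomposition
  meds <- enumerate_min_eds(g, cap = 14L)
  for (w in cv$walks) {
    for (m in meds) {
      expect_true(karyocover:::walk_in_decomposition(w, m))
    }
  }
})

test_that("naive covering follows the local-uniqueness rule", {
  # unambiguous simple path: full chromosome recovered
  g <- build_iag(c(a = 1L, b = 1L, c = 1L),
                 data.frame(v1 = c("a:h", "b:h"), v2 = c("b:t", "c:t"),
                            kind = "reference", mu = 1L))
  nv <- naive_covering(g)
  expect_length(nv$walks, 1L)
  expect_equal(contiguity_discordance(g, nv), 0L)

  # tandem fixture: ambiguity at b fragments everything
  nv1 <- naive_covering(f1())
  expect_equal(contiguity_discordance(f1(), nv1), 3L)
  expect_gt(contiguity_discordance(f1(), nv1), contiguity_discordance(f1(), run_ccr(f1())))

  # every adjacency of the ambiguous fixture shares b: primitive-like result
  expect_equal(contiguity_discordance(f2(), naive_covering(f2())), 4L)
})

test_that("CCR is deterministic and order-insensitive", {
  g <- f2()
  cv1 <- run_ccr(g)
  cv2 <- run_ccr(g)
  expect_true(walksets_equal(cv1$walks, cv2$walks))
  # permute adjacency input rows: canonical ordering absorbs it
  adj <- g$adjacencies[c(3, 1, 4, 2), c("v1", "v2", "kind", "mu")]
  gp <- build_iag(g$segments, adj)
  expect_true(walksets_equal(run_ccr(gp)$walks, cv1$walks))
})

test_that("CCR matches the oracle across random small graphs", {
  pool <- small_graph_pool(200:340)
  expect_gt(length(pool), 15L)
  for (g in pool) {
    cv <- run_ccr(g)
    expect_true(validate_covering(g, cv)$ok)
    dc <- contiguity_discordance(g, cv)
    oc <- optimal_covering_bruteforce(g)
    expect_equal(dc, oc$discordance)
    fp <- forced_pairs_bruteforce(g)
    expect_setequal(unique(attr(cv, "contracted_pairs")), fp$key)
    expect_lte(dc, contiguity_discordance(g, naive_covering(g)))
    meds <- enumerate_min_eds(g)
    for (w in cv$walks) {
      for (m in meds) expect_true(karyocover:::walk_in_decomposition(w, m))
    }
  }
})
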