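# Brute-force reference implementations: frozen fixture values and internal
# consistency.  Expected counts below were computed by the enumeration itself
# on first construction and are kept as regression anchors; the structural
# assertions (sizes, path counts, containment) are the real oracle contract.

test_that("enumerate_eds on the fixtures", {
  e1 <- enumerate_eds(f1())
  expect_length(e1, 2L)     # the single path, and a 2-path fragmentation
  expect_equal(unname(sort(vapply(e1, length, integer(1)))), c(1L, 2L))

  m1 <- enumerate_min_eds(f1())
  expect_length(m1, 1L)
  expect_equal(format(m1[[1]][[1]]), "a+ b+ b+ c+")

  m2 <- enumerate_min_eds(f2())
  expect_length(m2, 2L)
  for (d in m2) expect_length(d, 2L)

  expect_length(enumerate_eds(f3()), 1L)
  expect_error(enumerate_eds(build_iag(c(a = 20L))), "too large")
})

test_that("forced pairs on the fixtures", {
  fp1 <- forced_pairs_bruteforce(f1())
  expect_equal(nrow(fp1), 2L)   # both consecutive pairs of the unique min-ED
  expect_true(all(fp1$min_count == 1L))
  expect_equal(nrow(forced_pairs_bruteforce(f2())), 0L)
  fp3 <- forced_pairs_bruteforce(f3())
  expect_equal(nrow(fp3), 1L)   # the loop-closure pair
})

test_that("max_ed_bruteforce and covering optimum on the fixtures", {
  expect_length(max_ed_bruteforce(build_iag(c(a = 2L)))$walks, 2L)
  expect_equal(optimal_covering_bruteforce(f1())$discordance, 0L)
  oc2 <- optimal_covering_bruteforce(f2())
  expect_equal(oc2$discordance, 2L)
  u2 <- usage_of(oc2$covering, f2())
  expect_equal(sum(u2$adj), 2L)
  expect_equal(optimal_covering_bruteforce(f3())$discordance, 0L)
})

test_that("a pair forced only through cycle-minimality is detected", {
  # square y - a - z - b - y: the unique minimal decomposition is the single
  # cycle; re-pairing would split it in two, so both pairs are forced even
  # though the counts alone would allow a re-pairing.
  g <- build_iag(c(y = 1L, z = 1L),
                 data.frame(v1 = c("y:h", "z:h"), v2 = c("z:t", "y:t"),
                            kind = "novel", mu = 1L))
  fp <- forced_pairs_bruteforce(g)
  expect_equal(nrow(fp), 2L)
  # and CCR agrees, recovering the full cycle
  cv <- run_ccr(g)
  expect_length(cv$walks, 1L)
  expect_true(cv$walks[[1]]$closed)
  expect_equal(contiguity_discordance(g, cv), 0L)
})
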