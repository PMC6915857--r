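# Eulerian decomposition solvers and the K3 reduction.

test_that("solve_edp handles the base fixtures", {
  d3 <- solve_edp(f3())
  expect_length(d3$walks, 1L)
  expect_true(d3$walks[[1]]$closed)

  d1 <- solve_edp(f1())
  expect_true(validate_decomposition(f1(), d1)$ok)

  g <- build_iag(c(z = 3L))
  dz <- solve_edp(g)
  expect_length(dz$walks, 3L)
  expect_true(all(vapply(dz$walks, walk_length, integer(1)) == 1L))
  expect_true(validate_decomposition(g, dz)$ok)

  gl <- build_iag(c(a = 1L),
                  data.frame(v1 = "a:h", v2 = "a:h", kind = "novel", mu = 1L))
  expect_error(solve_edp(gl), "negative copy number excess.*a:h")
})

test_that("solve_min_edp attains the minimal size identities", {
  d1 <- solve_min_edp(f1())
  expect_length(d1$walks, 1L)
  expect_equal(format(d1$walks[[1]]), "a+ b+ b+ c+")
  expect_equal(min_decomposition_size(f1()), 1L)
  expect_equal(expected_path_count(f1()), 1L)

  d2 <- solve_min_edp(f2())
  expect_length(d2$walks, 2L)
  expect_equal(expected_path_count(f2()), 2L)
  expect_true(validate_decomposition(f2(), d2)$ok)

  expect_equal(min_decomposition_size(f3()), 1L)
  expect_equal(expected_path_count(f3()), 0L)

  # two disjoint circular components -> two cycles
  g2c <- build_iag(c(a = 1L, b = 1L),
                   data.frame(v1 = c("a:h", "b:h"), v2 = c("a:t", "b:t"),
                              kind = "novel", mu = 1L))
  expect_length(solve_min_edp(g2c)$walks, 2L)
  expect_equal(min_decomposition_size(g2c), 2L)

  expect_equal(min_decomposition_size(build_iag(stats::setNames(integer(0), character(0)))), 0L)
})

test_that("validate_decomposition reports violations as data", {
  g <- f1()
  d <- solve_min_edp(g)
  broken <- list(walk(c("a", "b"), d$walks[[1]]$orients[1:2], d$walks[[1]]$adjs[1]))
  v <- validate_decomposition(g, broken)
  expect_false(v$ok)
  expect_true(any(grepl("segment", v$violations)))
  # a walk using a nonexistent adjacency is caught by walk_check
  v2 <- validate_decomposition(g, list(walk(c("a", "b"), c(1L, 1L),
                                            "bogus|a:h|b:t")))
  expect_false(v2$ok)
  # walks structurally cannot end on an adjacency edge
  expect_error(walk("a", 1L, "k|a:h|a:t"), "length")
})

test_that("decomposition identities hold on random small graphs vs oracle", {
  pool <- small_graph_pool(1:120)
  expect_gt(length(pool), 10L)
  for (g in pool) {
    d <- solve_edp(g)
    expect_true(validate_decomposition(g, d)$ok)
    dm <- solve_min_edp(g)
    expect_true(validate_decomposition(g, dm)$ok)
    np <- sum(!vapply(d$walks, `[[`, logical(1), "closed"))
    npm <- sum(!vapply(dm$walks, `[[`, logical(1), "closed"))
    expect_equal(np, expected_path_count(g))
    expect_equal(npm, expected_path_count(g))
    expect_equal(length(dm$walks), min_decomposition_size(g))
    expect_gte(length(d$walks), length(dm$walks))
    eds <- enumerate_eds(g)
    sizes <- vapply(eds, length, integer(1))
    expect_equal(min(sizes), length(dm$walks))
    expect_true(all(vapply(eds, function(w) {
      sum(!vapply(w, `[[`, logical(1), "closed"))
    }, integer(1)) == expected_path_count(g)))
  }
})

test_that("k3_reduction builds the balanced instance of the hardness proof", {
  tri <- data.frame(u = c("x", "y", "z"), v = c("y", "z", "x"))
  g <- k3_reduction(tri)
  expect_equal(sort(g$segments$mu), c(2L, 2L, 2L))
  expect_true(all(copy_number_excess(g) == 0L))
  # 3 head-head adjacencies mu 1 + 3 tail loops mu 1
  expect_equal(sum(g$adjacencies$mu), 6L)
  expect_error(k3_reduction(data.frame(u = "x", v = "y")), "odd-degree")
  expect_error(k3_reduction(data.frame(u = "x", v = "x")), "simple")
})
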