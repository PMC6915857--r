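# Graph model: construction, excess, decomposability, components.

test_that("build_iag constructs graphs and enforces referential integrity", {
  g <- build_iag(c(a = 1L))
  expect_equal(length(iag_vertices(g)), 2L)
  expect_equal(nrow(g$adjacencies), 0L)

  g2 <- build_iag(c(a = 1L, b = 1L),
                  data.frame(v1 = "a:h", v2 = "b:t", kind = "novel", mu = 1L))
  expect_equal(length(iag_vertices(g2)), 4L)
  expect_equal(nrow(g2$adjacencies), 1L)
  expect_equal(sum(g2$segments$mu) + sum(g2$adjacencies$mu), 3L)

  expect_error(
    build_iag(c(a = 1L),
              data.frame(v1 = "a:h", v2 = "c:t", kind = "novel", mu = 1L)),
    "unknown extremity")
  expect_error(build_iag(c(a = -1L)), "negative")
  # mu=0 segment carrying a live adjacency is inconsistent
  expect_error(
    build_iag(c(a = 1L, b = 0L),
              data.frame(v1 = "a:h", v2 = "b:t", kind = "novel", mu = 1L)),
    "copy number 0")
  # parallel reference and novel adjacencies stay distinct edges
  g3 <- build_iag(c(a = 2L, b = 2L),
                  data.frame(v1 = "a:h", v2 = "b:t",
                             kind = c("reference", "novel"), mu = 1L))
  expect_equal(nrow(g3$adjacencies), 2L)
  # same-kind duplicates merge with summed multiplicity
  g4 <- build_iag(c(a = 2L, b = 2L),
                  data.frame(v1 = c("a:h", "b:t"), v2 = c("b:t", "a:h"),
                             kind = "novel", mu = 1L))
  expect_equal(g4$adjacencies$mu, 2L)
})

test_that("positive_restriction drops zero-multiplicity edges and segments", {
  g <- build_iag(c(a = 1L, b = 1L, z = 0L),
                 data.frame(v1 = "a:h", v2 = "b:t", kind = "novel",
                            mu = c(1L)))
  gp <- positive_restriction(g)
  expect_false("z" %in% gp$segments$id)
  g2 <- build_iag(c(a = 1L, b = 1L),
                  data.frame(v1 = c("a:h", "a:t"), v2 = c("b:t", "b:h"),
                             kind = "novel", mu = c(1L, 0L)))
  gp2 <- positive_restriction(g2)
  expect_equal(nrow(gp2$adjacencies), 1L)
  # all-positive graph is unchanged
  expect_equal(positive_restriction(f1()), f1())
})

test_that("copy number excess matches hand evaluation", {
  g <- build_iag(c(a = 2L))
  expect_equal(copy_number_excess(g, "a:t"), c(`a:t` = 2L))

  gl <- build_iag(c(a = 1L),
                  data.frame(v1 = "a:h", v2 = "a:h", kind = "novel", mu = 1L))
  expect_equal(copy_number_excess(gl, "a:h"), c(`a:h` = -1L))

  x <- copy_number_excess(f1())
  expect_equal(x[c("a:t", "b:t", "b:h", "c:h")],
               c(`a:t` = 1L, `b:t` = 0L, `b:h` = 0L, `c:h` = 1L))
  expect_error(copy_number_excess(f1(), "zz:t"), "unknown vertex")
})

test_that("excess recomputed from raw incidence matches, and sums are even", {
  for (seed in 1:30) {
    g <- random_small_iag(seed)
    if (is.null(g)) next
    x <- copy_number_excess(g)
    for (v in iag_vertices(g)) {
      load <- 0L
      for (i in seq_len(nrow(g$adjacencies))) {
        l <- (g$adjacencies$v1[i] == v) + (g$adjacencies$v2[i] == v)
        load <- load + l * g$adjacencies$mu[i]
      }
      expect_identical(unname(x[v]), seg_mu(g)[[ext_seg(v)]] - load)
    }
    expect_equal(sum(x) %% 2L, 0L)
    for (comp in iag_components(g)) {
      expect_equal(sum(copy_number_excess(comp)) %% 2L, 0L)
    }
  }
})

test_that("decomposability and component classification", {
  expect_true(is_decomposable(f1()))
  expect_true(is_decomposable(build_iag(stats::setNames(integer(0), character(0)))))
  gl <- build_iag(c(a = 1L),
                  data.frame(v1 = "a:h", v2 = "a:h", kind = "novel", mu = 1L))
  expect_false(is_decomposable(gl))

  cc <- classify_components(f1())
  expect_length(cc$C_plus, 1L)
  expect_length(cc$C_zero, 0L)
  cc3 <- classify_components(f3())
  expect_length(cc3$C_zero, 1L)

  # union of tandem and circular fixtures: one component of each flavour
  gu <- build_iag(
    rbind(f1()$segments, transform(f3()$segments, id = "z")),
    rbind(f1()$adjacencies[, c("v1", "v2", "kind", "mu")],
          data.frame(v1 = "z:h", v2 = "z:t", kind = "novel", mu = 1L)))
  ccu <- classify_components(gu)
  expect_length(ccu$C_plus, 1L)
  expect_length(ccu$C_zero, 1L)
})
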