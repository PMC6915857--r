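# Maximum matching (blossom) and the degree-constrained b-matching.

# brute-force maximum matching size by recursion over edges
brute_matching <- function(edges, n) {
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nrow(edges) - i + 1L) <= best) return(invisible())
    if (i > nrow(edges)) {
      best <<- max(best, count)
      return(invisible())
    }
    u <- edges[i, 1]; v <- edges[i, 2]
    if (!used[u] && !used[v]) {
      used[u] <- used[v] <- TRUE
      recurse(i + 1L, used, count + 1L)
      used[u] <- used[v] <- FALSE
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, logical(n), 0L)
  best
}

blossom_size <- function(edges, n) {
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(edges))) {
    u <- edges[r, 1]; v <- edges[r, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  m <- karyocover:::blossom_matching(adj)
  sum(m != 0L) / 2L
}

test_that("blossom matching equals brute force on random graphs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(3:9, 1)
    ne <- sample(2:12, 1)
    edges <- unique(t(replicate(ne, sort(sample(n, 2)))))
    expect_equal(blossom_size(edges, n), brute_matching(edges, n),
                 info = paste("rep", rep))
  }
  # odd cycle (needs a blossom): C5 has maximum matching 2
  c5 <- cbind(1:5, c(2:5, 1))
  expect_equal(blossom_size(c5, 5), 2L)
  # petersen-like: two triangles joined by a path
  tt <- rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4), c(4, 5), c(5, 6), c(6, 4))
  expect_equal(blossom_size(tt, 6), brute_matching(tt, 6))
})

test_that("b-matching respects capacities, loops, and availability", {
  bm <- karyocover:::max_bmatching
  # one edge, plenty of capacity
  sel <- bm(c(a = 2L, b = 2L),
            data.frame(id = "e", n1 = "a", n2 = "b", avail = 5L))
  expect_equal(unname(sel["e"]), 2L)
  # loop needs two copies per selected unit
  sel2 <- bm(c(a = 3L), data.frame(id = "l", n1 = "a", n2 = "a", avail = 5L))
  expect_equal(unname(sel2["l"]), 1L)
  # competition: two edges sharing a capacity-1 node
  sel3 <- bm(c(a = 1L, b = 1L, c = 1L),
             data.frame(id = c("e1", "e2"), n1 = c("a", "a"),
                        n2 = c("b", "c"), avail = 1L))
  expect_equal(sum(sel3), 1L)
  # unusable edge (zero-capacity endpoint) reported as 0, not dropped
  sel4 <- bm(c(a = 1L, b = 0L),
             data.frame(id = "e", n1 = "a", n2 = "b", avail = 1L))
  expect_equal(unname(sel4["e"]), 0L)
})
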