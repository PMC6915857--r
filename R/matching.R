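# Maximum cardinality matching (blossom algorithm) and the degree-constrained
# edge selection (b-matching) built on it.
#
# The terminal step of CCR selects the largest multiset of adjacency-edge
# copies such that no two selected edges claim the same free segment copy.
# That is a maximum b-matching on the multigraph whose nodes are segments
# (capacity = free copies) and whose edges are adjacency copies (a loop
# demands two copies of its segment).  It reduces to maximum matching by copy
# expansion: one node per free segment copy, a two-node gadget per candidate
# edge copy.

# Maximum cardinality matching in a general undirected graph.
# `adj` is a list of integer neighbour vectors (1-based, symmetric).
# Returns the matching as an integer vector (0 = unmatched).
blossom_matching <- function(adj) {
  n <- length(adj)
  match <- integer(n)
  p <- integer(n)
  base <- seq_len(n)
  used <- logical(n)
  blossom <- logical(n)

  lca <- function(a, b) {
    used2 <- logical(n)
    a0 <- a
    repeat {
      a0 <- base[a0]
      used2[a0] <- TRUE
      if (match[a0] == 0L) break
      a0 <- p[match[a0]]
    }
    b0 <- b
    repeat {
      b0 <- base[b0]
      if (used2[b0]) return(b0)
      b0 <- p[match[b0]]
    }
  }

  mark_path <- function(v, b_, child) {
    while (base[v] != b_) {
      blossom[base[v]] <<- TRUE
      blossom[base[match[v]]] <<- TRUE
      p[v] <<- child
      child <- match[v]
      v <- p[match[v]]
    }
  }

  find_path <- function(root) {
    used <<- logical(n)
    p <<- integer(n)
    base <<- seq_len(n)
    used[root] <<- TRUE
    queue <- root
    qi <- 1L
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1L
      for (to in adj[[v]]) {
        if (base[v] == base[to] || match[v] == to) next
        if (to == root || (match[to] != 0L && p[match[to]] != 0L)) {
          curbase <- lca(v, to)
          blossom <<- logical(n)
          mark_path(v, curbase, to)
          mark_path(to, curbase, v)
          for (i in seq_len(n)) {
            if (blossom[base[i]]) {
              base[i] <<- curbase
              if (!used[i]) {
                used[i] <<- TRUE
                queue <- c(queue, i)
              }
            }
          }
        } else if (p[to] == 0L) {
          p[to] <<- v
          if (match[to] == 0L) {
            # augment
            v2 <- to
            while (v2 != 0L) {
              pv <- p[v2]
              ppv <- match[pv]
              match[v2] <<- pv
              match[pv] <<- v2
              v2 <- ppv
            }
            return(TRUE)
          }
          used[match[to]] <<- TRUE
          queue <- c(queue, match[to])
        }
      }
    }
    FALSE
  }

  # greedy initialisation
  for (v in seq_len(n)) {
    if (match[v] == 0L) {
      for (to in adj[[v]]) {
        if (match[to] == 0L) {
          match[v] <- to
          match[to] <- v
          break
        }
      }
    }
  }
  for (v in seq_len(n)) {
    if (match[v] == 0L) find_path(v)
  }
  match
}

# Maximum b-matching by copy expansion.
#
# nodes: character ids; b: named integer capacities; edges: data.frame with
# columns id, n1, n2 (node ids; n1 == n2 encodes a loop needing two distinct
# copies) and avail (available copies).  Returns a named integer vector of
# selected copies per edge id, of maximum total cardinality.
max_bmatching <- function(b, edges) {
  sel <- stats::setNames(integer(nrow(edges)), edges$id)
  b <- b[b > 0L]
  if (nrow(edges)) {
    keep <- edges$n1 %in% names(b) & edges$n2 %in% names(b)
    edges <- edges[keep, , drop = FALSE]
  }
  if (nrow(edges) == 0L || length(b) == 0L) return(sel)
  # cap units per edge at what capacities could ever admit
  unit_cap <- ifelse(edges$n1 == edges$n2,
                     b[edges$n1] %/% 2L,
                     pmin(b[edges$n1], b[edges$n2]))
  units_per_edge <- pmin(edges$avail, unit_cap)
  # expansion: copy nodes then gadget pairs
  copy_node_of <- lapply(names(b), function(s) integer(0))
  names(copy_node_of) <- names(b)
  nid <- 0L
  for (s in names(b)) {
    copy_node_of[[s]] <- nid + seq_len(b[[s]])
    nid <- nid + b[[s]]
  }
  gadget_e1 <- integer(0); gadget_e2 <- integer(0); gadget_edge <- integer(0)
  for (i in seq_len(nrow(edges))) {
    k <- units_per_edge[i]
    if (k <= 0L) next
    e1 <- nid + seq(1L, 2L * k, by = 2L)
    e2 <- e1 + 1L
    nid <- nid + 2L * k
    gadget_e1 <- c(gadget_e1, e1)
    gadget_e2 <- c(gadget_e2, e2)
    gadget_edge <- c(gadget_edge, rep(i, k))
  }
  adj <- vector("list", nid)
  for (t in seq_along(gadget_e1)) {
    i <- gadget_edge[t]
    c1 <- copy_node_of[[edges$n1[i]]]
    c2 <- copy_node_of[[edges$n2[i]]]
    e1 <- gadget_e1[t]; e2 <- gadget_e2[t]
    adj[[e1]] <- c(c1, e2)
    adj[[e2]] <- c(c2, e1)
    for (cn in c1) adj[[cn]] <- c(adj[[cn]], e1)
    for (cn in c2) adj[[cn]] <- c(adj[[cn]], e2)
  }
  for (v in seq_len(nid)) if (is.null(adj[[v]])) adj[[v]] <- integer(0)
  match <- blossom_matching(adj)
  for (t in seq_along(gadget_e1)) {
    e1 <- gadget_e1[t]; e2 <- gadget_e2[t]
    if (match[e1] != 0L && match[e1] != e2 &&
        match[e2] != 0L && match[e2] != e1) {
      # a selected unit has both gadget ends matched to copy nodes
      sel[edges$id[gadget_edge[t]]] <- sel[edges$id[gadget_edge[t]]] + 1L
    }
  }
  sel
}
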