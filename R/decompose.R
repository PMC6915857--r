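# Eulerian decomposition of weighted interval adjacency graphs.
#
# The solvers share one internal representation: every segment edge is
# expanded into mu copies and every adjacency edge into mu copies carrying one
# "port" at each endpoint (two for a loop).  In a balanced graph (all
# vertices with zero copy number excess) each vertex holds exactly mu(e_S(v))
# adjacency ports, and an Eulerian decomposition corresponds to a bijection,
# per vertex, between those ports and the segment copies.  Following the
# bijections yields the alternating cycles; unbalanced graphs are balanced
# first with internal ("suppbal") adjacency edges that are stripped from the
# result, turning cycles into paths.

BAL_KIND <- "supplemental"   # kind used for internal balancing edges
BAL_TAG <- "suppbal"         # uid tag marking them as strippable

is_balancing_key <- function(key) grepl("\\|suppbal", key)

# ---- port structure ---------------------------------------------------------

# Build the port tables for a positive, balanced graph.
pairing_struct <- function(g) {
  smu <- seg_mu(g)
  segs <- names(smu)
  adj <- g$adjacencies[g$adjacencies$mu > 0L, ]
  nport <- 2L * sum(adj$mu)
  key <- character(nport); acopy <- integer(nport); endn <- integer(nport)
  vert <- character(nport)
  offset <- stats::setNames(integer(nrow(adj)), adj$key)
  p <- 0L
  if (nrow(adj)) {
    for (i in seq_len(nrow(adj))) {
      m <- adj$mu[i]
      offset[adj$key[i]] <- p
      idx <- p + seq_len(2L * m)
      key[idx] <- adj$key[i]
      acopy[idx] <- rep(seq_len(m), each = 2L)
      endn[idx] <- rep(c(1L, 2L), m)
      vert[idx] <- rep(c(adj$v1[i], adj$v2[i]), m)
      p <- p + 2L * m
    }
  }
  partner <- ifelse(seq_len(nport) %% 2L == 1L,
                    seq_len(nport) + 1L, seq_len(nport) - 1L)
  vseg <- ext_seg(vert)
  vside <- ext_side(vert)
  # canonical per-vertex port order: by (key, copy, end)
  byv <- split(seq_len(nport), vert)
  byv <- lapply(byv, function(pp) pp[order(key[pp], acopy[pp], endn[pp])])
  # balance check
  for (v in names(byv)) {
    if (length(byv[[v]]) != smu[[ext_seg(v)]]) {
      stop("internal: graph not balanced at vertex ", v)
    }
  }
  # vertices with no adjacency port must have mu(seg)=0 which positive graphs
  # exclude, or the graph is unbalanced there; callers guarantee balance.
  for (v in setdiff(iag_vertices(g), names(byv))) {
    if (smu[[ext_seg(v)]] != 0L) stop("internal: graph not balanced at vertex ", v)
  }
  list(g = g, smu = smu, segs = segs,
       key = key, acopy = acopy, endn = endn, vert = vert,
       vseg = vseg, vside = vside, partner = partner, byv = byv,
       offset = offset)
}

# Canonical assignment: at every vertex, sorted ports get copies 1..m in order.
canonical_assign <- function(ps) {
  assign <- integer(length(ps$key))
  for (v in names(ps$byv)) {
    pp <- ps$byv[[v]]
    assign[pp] <- seq_along(pp)
  }
  assign
}

# inverse maps: per vertex, copy index -> port id
invert_assign <- function(ps, assign) {
  lapply(ps$byv, function(pp) {
    inv <- integer(length(pp))
    inv[assign[pp]] <- pp
    inv
  })
}

# Extract the alternating cycles determined by an assignment.  With
# `detail = TRUE` the result carries attributes "owner" (walk index per
# global segment copy) and "base" (per-segment copy index offsets).
extract_cycles <- function(ps, assign, detail = FALSE) {
  inv <- invert_assign(ps, assign)
  smu <- ps$smu
  segs <- ps$segs
  total <- sum(smu)
  if (total == 0L) return(list())
  base <- c(0L, cumsum(smu))[seq_along(segs)]
  names(base) <- segs
  used <- logical(total)
  owner <- integer(total)
  walks <- list()
  seg_buf <- character(total); ori_buf <- integer(total); adj_buf <- character(total)
  for (s0 in segs) {
    m0 <- smu[[s0]]
    for (j0 in seq_len(m0)) {
      if (used[base[[s0]] + j0]) next
      wid <- length(walks) + 1L
      cs <- s0; cj <- j0; cside <- "t"
      len <- 0L
      repeat {
        used[base[[cs]] + cj] <- TRUE
        owner[base[[cs]] + cj] <- wid
        len <- len + 1L
        seg_buf[len] <- cs
        ori_buf[len] <- if (cside == "t") 1L else -1L
        exit_v <- ext(cs, if (cside == "t") "h" else "t")
        pid <- inv[[exit_v]][cj]
        if (is.na(pid) || pid == 0L) stop("internal: dead end at ", exit_v)
        adj_buf[len] <- ps$key[pid]
        pid2 <- ps$partner[pid]
        cs <- ps$vseg[pid2]; cside <- ps$vside[pid2]
        cj <- assign[pid2]
        if (cs == s0 && cj == j0) {
          if (cside != "t") stop("internal: traversal re-entered start copy")
          break
        }
        if (used[base[[cs]] + cj]) stop("internal: traversal revisited a segment copy")
      }
      walks[[length(walks) + 1L]] <-
        walk(seg_buf[seq_len(len)], ori_buf[seq_len(len)],
             adj_buf[seq_len(len)], closed = TRUE)
    }
  }
  if (detail) {
    attr(walks, "owner") <- owner
    attr(walks, "base") <- base
  }
  walks
}

# Remove balancing adjacencies from cycles, splitting them into open paths.
strip_balancing <- function(cycles) {
  out <- list()
  for (w in cycles) {
    hit <- which(is_balancing_key(w$adjs))
    if (length(hit) == 0L) {
      out[[length(out) + 1L]] <- w
      next
    }
    n <- length(w$segs)
    k <- length(hit)
    for (t in seq_len(k)) {
      from <- hit[t] + 1L                 # step after the removed adjacency
      to <- if (t < k) hit[t + 1L] else hit[1L] + n
      if (to < from) stop("internal: empty strip piece")
      idx <- ((seq(from, to) - 1L) %% n) + 1L
      aidx <- if (to > from) ((seq(from, to - 1L) - 1L) %% n) + 1L else integer(0)
      out[[length(out) + 1L]] <-
        walk(w$segs[idx], w$orients[idx], w$adjs[aidx], closed = FALSE)
    }
  }
  out
}

# Add balancing loops and pairing edges (Theorem-1 style) so every vertex has
# zero excess.  `pair_plan` optionally overrides the endpoint pairing: a
# data.frame (v1, v2, mu) over excess units.  Returns the augmented graph.
balance_with_suppbal <- function(g, pair_plan = NULL) {
  x <- copy_number_excess(g)
  if (all(x == 0L)) return(g)
  extra <- data.frame(v1 = character(), v2 = character(), kind = character(),
                      mu = integer(), uid = character(), stringsAsFactors = FALSE)
  if (is.null(pair_plan)) {
    loops <- x %/% 2L
    lv <- names(loops)[loops > 0L]
    if (length(lv)) {
      extra <- rbind(extra, data.frame(v1 = lv, v2 = lv, kind = BAL_KIND,
                                       mu = as.integer(loops[lv]), uid = BAL_TAG))
    }
    odd <- names(x)[x %% 2L == 1L]
    if (length(odd)) {
      comp <- iag_component_ids(g)[odd]
      for (k in unique(sort(comp))) {
        vk <- sort(odd[comp == k])
        stopifnot(length(vk) %% 2L == 0L)
        i <- seq(1L, length(vk), by = 2L)
        extra <- rbind(extra, data.frame(v1 = vk[i], v2 = vk[i + 1L],
                                         kind = BAL_KIND, mu = 1L, uid = BAL_TAG))
      }
    }
  } else {
    extra <- rbind(extra, data.frame(v1 = pair_plan$v1, v2 = pair_plan$v2,
                                     kind = BAL_KIND, mu = as.integer(pair_plan$mu),
                                     uid = BAL_TAG))
  }
  adj <- g$adjacencies[, c("v1", "v2", "kind", "mu")]
  adj$uid <- sub("^[^|]*\\|[^|]*\\|[^|]*\\|?", "", g$adjacencies$key)
  adj$uid[adj$uid == ""] <- NA
  both <- rbind(adj, extra)
  build_iag(g$segments, both)
}

# ---- public solvers ---------------------------------------------------------

decomposability_report <- function(g) {
  x <- copy_number_excess(g)
  bad <- x[x < 0L]
  if (length(bad) == 0L) return(NULL)
  paste0("graph is not decomposable; vertices with negative copy number ",
         "excess: ", paste(sprintf("%s (x=%d)", names(bad), bad), collapse = ", "))
}

new_decomposition <- function(walks, g) {
  structure(list(walks = walks, graph = g), class = "kc_decomposition")
}

#' @export
print.kc_decomposition <- function(x, ...) {
  np <- sum(!vapply(x$walks, `[[`, logical(1), "closed"))
  nc <- length(x$walks) - np
  cat(sprintf("kc_decomposition: %d paths, %d cycles\n", np, nc))
  for (w in x$walks) print(w)
  invisible(x)
}

#' Solve the Eulerian decomposition problem
#'
#' Returns a collection of segment/adjacency edge-alternating paths and cycles
#' using every edge exactly its copy number of times.  Construction: telomere
#' vertices are balanced with internal loops and pairing edges, segment and
#' adjacency edge copies are matched at every vertex in canonical order, the
#' resulting cycles are read off, and the balancing edges are stripped so that
#' cycles split into paths.
#'
#' @param g a positive, decomposable `kc_iag`.
#' @return a `kc_decomposition`.
#' @export
solve_edp <- function(g) {
  rep_ <- decomposability_report(g)
  if (!is.null(rep_)) stop(rep_)
  if (nrow(g$segments) == 0L) return(new_decomposition(list(), g))
  gb <- balance_with_suppbal(g)
  ps <- pairing_struct(gb)
  cycles <- extract_cycles(ps, canonical_assign(ps))
  new_decomposition(strip_balancing(cycles), g)
}

#' Solve the minimal Eulerian decomposition problem
#'
#' Starts from [solve_edp()] and iteratively merges cycles with paths or other
#' cycles through shared segment edges until components with telomere vertices
#' contain no cycles and every balanced component is covered by a single
#' cycle.  The result attains the minimum possible cardinality,
#' `expected_path_count(g) + |C_zero(g)|`.
#'
#' @param g a positive, decomposable `kc_iag`.
#' @return a `kc_decomposition` of minimal size.
#' @export
solve_min_edp <- function(g) {
  d <- solve_edp(g)
  new_decomposition(merge_to_minimal(d$walks), g)
}

# Iteratively merge cycles into partners sharing a segment edge.
merge_to_minimal <- function(walks) {
  repeat {
    if (length(walks) <= 1L) return(walks)
    merged <- FALSE
    closed <- vapply(walks, `[[`, logical(1), "closed")
    for (ci in which(closed)) {
      cyc <- walks[[ci]]
      partner <- NULL
      for (qi in seq_along(walks)) {
        if (qi == ci) next
        if (any(walks[[qi]]$segs %in% cyc$segs)) { partner <- qi; break }
      }
      if (!is.null(partner)) {
        host <- walks[[partner]]
        neww <- splice_cycle(host, cyc)
        walks <- c(walks[-c(ci, partner)], list(neww))
        merged <- TRUE
        break
      }
    }
    if (!merged) return(walks)
  }
}

# Splice cycle `cyc` into `host` (path or cycle) at a shared segment edge.
splice_cycle <- function(host, cyc) {
  shared <- intersect(host$segs, cyc$segs)
  stopifnot(length(shared) > 0L)
  s <- sort(shared)[1L]
  i <- which(host$segs == s)[1L]
  if (!any(cyc$segs == s & cyc$orients == host$orients[i])) cyc <- walk_reverse(cyc)
  j <- which(cyc$segs == s & cyc$orients == host$orients[i])[1L]
  cycr <- walk_rotate(cyc, j)
  m <- length(cycr$segs)
  n <- length(host$segs)
  segs <- append(host$segs, c(cycr$segs[-1L], cycr$segs[1L]), after = i)
  oris <- append(host$orients, c(cycr$orients[-1L], cycr$orients[1L]), after = i)
  adjs <- append(host$adjs, cycr$adjs, after = i - 1L)
  walk(segs, oris, adjs, closed = host$closed)
}

#' Path count of any Eulerian decomposition
#'
#' Every Eulerian decomposition of a decomposable graph has the same number of
#' open paths: half the total copy number excess.
#'
#' @param g a decomposable `kc_iag`.
#' @return integer.
#' @export
expected_path_count <- function(g) {
  if (nrow(g$segments) == 0L) return(0L)
  as.integer(sum(copy_number_excess(g)) / 2L)
}

#' Minimal Eulerian decomposition size
#'
#' The minimum cardinality of any Eulerian decomposition: the fixed path count
#' plus one cycle per fully balanced connected component.
#'
#' @param g a decomposable `kc_iag`.
#' @return integer.
#' @export
min_decomposition_size <- function(g) {
  if (nrow(g$segments) == 0L) return(0L)
  expected_path_count(g) + length(classify_components(g)$C_zero)
}

#' Validate an Eulerian decomposition
#'
#' @param g a `kc_iag`.
#' @param d a `kc_decomposition` or list of `kc_walk`.
#' @return list with logical `ok` and character `violations`.
#' @export
validate_decomposition <- function(g, d) {
  walks <- if (inherits(d, "kc_decomposition")) d$walks else d
  viol <- character()
  for (w in walks) {
    chk <- walk_check(w, g)
    if (!isTRUE(chk)) viol <- c(viol, chk)
  }
  if (length(viol) == 0L) {
    u <- usage_of(walks, g)
    smu <- seg_mu(g); amu <- adj_mu(g)
    ds <- u$seg[names(smu)] - smu
    da <- u$adj[names(amu)] - amu
    if (any(ds != 0L)) {
      viol <- c(viol, sprintf("segment %s used %+d times relative to mu",
                              names(smu)[ds != 0L], ds[ds != 0L]))
    }
    if (length(da) && any(da != 0L)) {
      viol <- c(viol, sprintf("adjacency %s used %+d times relative to mu",
                              names(amu)[da != 0L], da[da != 0L]))
    }
  }
  list(ok = length(viol) == 0L, violations = viol)
}

#' Reduce a K3 edge-partition instance to a balanced IAG
#'
#' Encodes a simple undirected graph with all-even degrees as a balanced
#' interval adjacency graph: each vertex v becomes a segment with copy number
#' deg(v) plus an adjacency loop at its tail with copy number deg(v)/2, and
#' each edge \{u,v\} becomes a head-to-head adjacency with copy number 1.
#' Triangles of the input correspond to alternating cycles of the output, so
#' the input has a K3 edge partition exactly when a maximal Eulerian
#' decomposition of the output consists of |E|/3 cycles.
#'
#' @param edges a two-column data.frame or matrix of vertex names, one row per
#'   undirected edge of a simple graph.
#' @return a balanced `kc_iag`.
#' @export
k3_reduction <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(ncol(edges) >= 2L)
  u <- as.character(edges[[1]]); v <- as.character(edges[[2]])
  if (any(u == v)) stop("input graph must be simple (no loops)")
  if (anyDuplicated(paste(pmin(u, v), pmax(u, v)))) stop("input graph must be simple")
  deg <- table(c(u, v))
  if (any(deg %% 2L != 0L)) {
    stop("odd-degree vertex: ", paste(names(deg)[deg %% 2L != 0L], collapse = ", "))
  }
  segs <- data.frame(id = names(deg), mu = as.integer(deg))
  adj <- rbind(
    data.frame(v1 = ext(u, "h"), v2 = ext(v, "h"), kind = "novel", mu = 1L),
    data.frame(v1 = ext(names(deg), "t"), v2 = ext(names(deg), "t"),
               kind = "novel", mu = as.integer(deg) %/% 2L)
  )
  build_iag(segs, adj)
}
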