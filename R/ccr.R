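# CCR: consistent contig recovery.
#
# A contig covering uses every segment edge exactly its copy number of times
# and every adjacency edge at most its copy number of times.  CCR finds a
# covering of minimum contiguity discordance (unused adjacency multiplicity)
# among those whose every walk appears in every minimal Eulerian
# decomposition, i.e. the longest contigs that are unambiguous no matter
# which genome the graph truly encodes.
#
# Per connected component the algorithm (i) balances telomere vertices with a
# supplemental segment so the minimal decomposition becomes a single Eulerian
# cycle, (ii) repeatedly finds consecutive adjacency pairs in that cycle that
# occur in every minimal decomposition and contracts them into chain edges,
# and (iii) solves a degree-constrained matching on the terminal graph to
# place the remaining adjacency copies (and the optional outer attachments of
# the chains) onto free segment copies, no two on the same copy.

SUPP_SEG <- ".supp"

is_supp_key <- function(key) startsWith(key, "supplemental|")
is_ctr_key <- function(key) startsWith(key, "contracted|")

# ---- covering basics --------------------------------------------------------

new_covering <- function(walks, g) {
  structure(list(walks = walks, graph = g), class = "kc_covering")
}

#' @export
print.kc_covering <- function(x, ...) {
  cat(sprintf("kc_covering: %d contigs, discordance %d\n", length(x$walks),
              contiguity_discordance(x$graph, x)))
  invisible(x)
}

#' The primitive contig covering
#'
#' One single-segment open walk per segment copy; uses no adjacency at all,
#' so its contiguity discordance equals the total adjacency multiplicity.
#'
#' @param g a positive `kc_iag`.
#' @return a `kc_covering`.
#' @export
primitive_covering <- function(g) {
  smu <- seg_mu(g)
  walks <- list()
  for (s in names(smu)) {
    for (k in seq_len(smu[[s]])) {
      walks[[length(walks) + 1L]] <- walk(s, 1L)
    }
  }
  new_covering(walks, g)
}

#' Contiguity discordance of a covering
#'
#' The total unused adjacency multiplicity, `sum(mu(e) - mu_T(e))` over
#' adjacency edges.  Zero for any Eulerian decomposition; `mu(E_A)` for the
#' primitive covering.
#'
#' @param g a `kc_iag`.
#' @param t a `kc_covering` (or list of `kc_walk`).
#' @return integer.
#' @export
contiguity_discordance <- function(g, t) {
  walks <- if (inherits(t, "kc_covering")) t$walks else t
  chk <- validate_covering(g, walks)
  if (!chk$ok) stop("invalid covering: ", paste(chk$violations, collapse = "; "))
  u <- usage_of(walks, g)
  as.integer(sum(adj_mu(g) - u$adj[names(adj_mu(g))]))
}

#' Validate a contig covering
#'
#' Checks walk alternation, exact segment usage and bounded adjacency usage.
#'
#' @param g a `kc_iag`.
#' @param t a `kc_covering` or list of `kc_walk`.
#' @return list with logical `ok` and character `violations`.
#' @export
validate_covering <- function(g, t) {
  walks <- if (inherits(t, "kc_covering")) t$walks else t
  viol <- character()
  for (w in walks) {
    chk <- walk_check(w, g)
    if (!isTRUE(chk)) viol <- c(viol, chk)
  }
  if (length(viol) == 0L) {
    u <- usage_of(walks, g)
    smu <- seg_mu(g); amu <- adj_mu(g)
    ds <- u$seg[names(smu)] - smu
    if (any(ds != 0L)) {
      viol <- c(viol, sprintf("segment %s used %+d times relative to mu",
                              names(smu)[ds != 0L], ds[ds != 0L]))
    }
    over <- u$adj[names(amu)] > amu
    if (length(amu) && any(over)) {
      viol <- c(viol, sprintf("adjacency %s used more than mu times",
                              names(amu)[over]))
    }
  }
  list(ok = length(viol) == 0L, violations = viol)
}

# ---- balance transform ------------------------------------------------------

#' Balance a connected graph with a supplemental segment
#'
#' Adds one supplemental segment, a supplemental adjacency of multiplicity
#' x(v) from every positive-excess vertex v to the supplemental tail, and a
#' supplemental head loop, so that every vertex of the result has zero copy
#' number excess and (for a connected input) the minimal Eulerian
#' decomposition is a single cycle.  Already balanced graphs pass through
#' unchanged.
#'
#' @param g a positive, decomposable, connected `kc_iag`.
#' @return list with `graph` (the balanced `kc_iag`) and `supp_segment` (the
#'   supplemental segment id, or `NA` if the input was balanced).
#' @export
balance_transform <- function(g) {
  x <- copy_number_excess(g)
  pos <- x[x > 0L]
  if (length(pos) == 0L) return(list(graph = g, supp_segment = NA_character_))
  mu_i <- sum(pos)
  stopifnot(mu_i %% 2L == 0L)
  segs <- rbind(g$segments,
                data.frame(id = SUPP_SEG, chrom = NA, start = NA, end = NA,
                           mu = as.integer(mu_i)))
  adj <- g$adjacencies[, c("v1", "v2", "kind", "mu")]
  adj$uid <- sub("^[^|]*\\|[^|]*\\|[^|]*\\|?", "", g$adjacencies$key)
  extra <- data.frame(
    v1 = c(names(pos), ext(SUPP_SEG, "h")),
    v2 = c(rep(ext(SUPP_SEG, "t"), length(pos)), ext(SUPP_SEG, "h")),
    kind = "supplemental",
    mu = c(as.integer(pos), as.integer(mu_i %/% 2L)),
    uid = NA)
  list(graph = build_iag(segs, rbind(adj, extra)),
       supp_segment = SUPP_SEG)
}

# ---- forced-pair decision ---------------------------------------------------

# Map a set of closed walks covering a balanced graph onto a port assignment
# of its pairing structure (copies numbered in traversal order).
derive_assignment <- function(ps, walks) {
  assign <- integer(length(ps$key))
  seg_cnt <- stats::setNames(integer(length(ps$segs)), ps$segs)
  adj_cnt <- stats::setNames(integer(length(ps$offset)), names(ps$offset))
  for (w in walks) {
    stopifnot(w$closed)
    n <- length(w$segs)
    cops <- integer(n)
    for (i in seq_len(n)) {
      seg_cnt[w$segs[i]] <- seg_cnt[w$segs[i]] + 1L
      cops[i] <- seg_cnt[[w$segs[i]]]
    }
    for (i in seq_len(n)) {
      k <- w$adjs[i]
      adj_cnt[k] <- adj_cnt[k] + 1L
      cc <- adj_cnt[[k]]
      pid1 <- ps$offset[[k]] + (cc - 1L) * 2L + 1L
      pid2 <- pid1 + 1L
      inx <- if (i == n) 1L else i + 1L
      vex <- walk_exit_ext(w, i)
      ven <- walk_entry_ext(w, inx)
      if (ps$vert[pid1] == ps$vert[pid2]) {         # loop
        assign[pid1] <- cops[i]
        assign[pid2] <- cops[inx]
      } else if (ps$vert[pid1] == vex) {
        assign[pid1] <- cops[i]
        assign[pid2] <- cops[inx]
      } else {
        stopifnot(ps$vert[pid2] == vex, ps$vert[pid1] == ven)
        assign[pid2] <- cops[i]
        assign[pid1] <- cops[inx]
      }
    }
  }
  if (any(assign == 0L)) stop("internal: walks do not cover the graph")
  assign
}

#' Decide whether a consecutive adjacency pair is forced
#'
#' For a balanced connected working graph whose minimal Eulerian
#' decompositions are single cycles, a pair of adjacency edges `e` (at the
#' `side_e` extremity of segment `y`) and `f` (at the other extremity) is
#' *forced* when every minimal decomposition traverses e-y-f at least once.
#' The decision works on the current cycle: the pairing of e with f through
#' copies of y is first rerouted away wherever counts permit, then the
#' resulting cycle fragments are re-merged through shared segment edges by
#' transition swaps that never re-create the forbidden pairing.  The pair is
#' forced exactly when no complete re-merge exists.
#'
#' @param g the balanced working `kc_iag`.
#' @param walks a minimal Eulerian decomposition of `g` as a list of closed
#'   walks (typically one cycle).
#' @param y segment id carrying the pair.
#' @param e,f adjacency edge keys flanking one copy of `y`.
#' @param side_e side (`"t"` or `"h"`) of `y` where `e` attaches.
#' @return logical.
#' @export
is_pair_forced <- function(g, walks, y, e, f, side_e = "t") {
  ve <- ext(y, side_e)
  vf <- ext(y, if (side_e == "t") "h" else "t")
  m <- seg_mu(g)[[y]]
  arow <- function(k) which(g$adjacencies$key == k)
  ports_at <- function(k, v) {
    i <- arow(k)
    stopifnot(length(i) == 1L)
    ((g$adjacencies$v1[i] == v) + (g$adjacencies$v2[i] == v)) * g$adjacencies$mu[i]
  }
  lam <- ports_at(e, ve)
  rho <- ports_at(f, vf)
  stopifnot(lam >= 1L, rho >= 1L)
  if (lam + rho > m) return(TRUE)

  ps <- pairing_struct(g)
  assign <- derive_assignment(ps, walks)
  inv <- invert_assign(ps, assign)
  kt <- ps$key[inv[[ve]]]     # class at the e side, per copy of y
  kh <- ps$key[inv[[vf]]]     # class at the f side
  # eliminate all forbidden (e, f) co-assignments by rerouting at the f side
  repeat {
    bad <- which(kt == e & kh == f)
    if (length(bad) == 0L) break
    part <- which(kt != e & kh != f)
    stopifnot(length(part) >= 1L)   # guaranteed by the count condition
    pa <- inv[[vf]][bad[1L]]
    pb <- inv[[vf]][part[1L]]
    tmp <- assign[pa]; assign[pa] <- assign[pb]; assign[pb] <- tmp
    inv <- invert_assign(ps, assign)
    kt <- ps$key[inv[[ve]]]
    kh <- ps$key[inv[[vf]]]
  }
  # merge the cycle fragments back together without recreating (e, f)
  repeat {
    cyc <- extract_cycles(ps, assign, detail = TRUE)
    if (length(cyc) <= 1L) return(FALSE)
    owner <- attr(cyc, "owner")
    base <- attr(cyc, "base")
    inv <- invert_assign(ps, assign)
    swapped <- FALSE
    for (s in ps$segs) {
      ms <- ps$smu[[s]]
      if (ms < 2L) next
      own <- owner[base[[s]] + seq_len(ms)]
      if (length(unique(own)) < 2L) next
      hv <- ext(s, "h")
      if (s != y) {
        j1 <- 1L
        j2 <- which(own != own[1L])[1L]
        pa <- inv[[hv]][j1]; pb <- inv[[hv]][j2]
        tmp <- assign[pa]; assign[pa] <- assign[pb]; assign[pb] <- tmp
        swapped <- TRUE
        break
      }
      # swaps at y must not recreate the forbidden pairing
      kt <- ps$key[inv[[ve]]]
      kh <- ps$key[inv[[vf]]]
      found <- FALSE
      for (j1 in seq_len(ms)) {
        for (j2 in seq_len(ms)) {
          if (own[j1] == own[j2]) next
          if ((kt[j1] == e && kh[j2] == f) || (kt[j2] == e && kh[j1] == f)) next
          pa <- inv[[vf]][j1]; pb <- inv[[vf]][j2]
          tmp <- assign[pa]; assign[pa] <- assign[pb]; assign[pb] <- tmp
          swapped <- TRUE; found <- TRUE
          break
        }
        if (found) break
      }
      if (swapped) break
    }
    if (!swapped) return(TRUE)   # stuck: every re-merge recreates (e, f)
  }
}

# ---- the CCR driver ---------------------------------------------------------

#' Recover consistent contigs from a karyotype graph
#'
#' Runs the CCR algorithm per connected component and returns a contig
#' covering in which every walk is present in every minimal Eulerian
#' decomposition of `g` and the contiguity discordance is minimized.
#'
#' @param g a positive, decomposable `kc_iag`.
#' @return a `kc_covering`; attribute `"contracted_pairs"` carries the keys of
#'   the forced adjacency pairs that were contracted (expanded to original
#'   edges), for comparison with [forced_pairs_bruteforce()].
#' @export
run_ccr <- function(g) {
  rep_ <- decomposability_report(g)
  if (!is.null(rep_)) stop(rep_)
  walks <- list()
  contracted <- character(0)
  for (comp in iag_components(g)) {
    res <- ccr_component(comp)
    walks <- c(walks, res$walks)
    contracted <- c(contracted, res$contracted)
  }
  out <- new_covering(walks, g)
  attr(out, "contracted_pairs") <- contracted
  out
}

# reverse a chain record (oriented alternating fragment between the two
# endpoints of a contracted edge)
chain_reverse <- function(ch) {
  list(adjs = rev(ch$adjs), segs = rev(ch$segs), oris = -rev(ch$oris),
       p = ch$q, q = ch$p)
}

ccr_component <- function(cg) {
  bt <- balance_transform(cg)
  wg <- bt$graph
  d0 <- solve_min_edp(wg)
  stopifnot(length(d0$walks) == 1L, d0$walks[[1L]]$closed)
  st <- new.env(parent = emptyenv())
  st$wg <- wg
  st$D <- d0$walks[[1L]]
  st$chains <- list()          # contracted key -> chain record
  st$processed <- new.env(parent = emptyenv())
  st$contracted <- character(0)
  st$middles <- stats::setNames(integer(nrow(cg$segments)), cg$segments$id)
  st$emitted <- list()
  st$ctr <- 0L
  st$cache_ok <- FALSE

  repeat {
    n <- walk_length(st$D)
    if (n == 0L) break
    if (n == 1L && st$D$closed) {
      ccr_emit_degenerate(st)
      break
    }
    acted <- FALSE
    for (i in seq_len(n)) {
      y <- st$D$segs[i]
      if (y == SUPP_SEG) next
      ip <- if (i == 1L) n else i - 1L
      e <- st$D$adjs[ip]
      f <- st$D$adjs[i]
      if (is_supp_key(e) || is_supp_key(f)) next
      side_e <- if (st$D$orients[i] > 0L) "t" else "h"
      side_f <- if (side_e == "t") "h" else "t"
      pk <- triple_key(y, e, side_e, f, side_f)
      if (!is.null(st$processed[[pk]])) next
      if (is_pair_forced(st$wg, list(st$D), y, e, f, side_e)) {
        ccr_contract(st, i)
        acted <- TRUE
        break
      } else {
        st$processed[[pk]] <- TRUE
      }
    }
    if (!acted) break
  }

  sel <- ccr_terminal(st, cg)
  list(walks = c(st$emitted, sel$walks), contracted = st$contracted)
}

# Contract the forced pair flanking step i of the current cycle.
ccr_contract <- function(st, i) {
  D <- st$D
  n <- walk_length(D)
  y <- D$segs[i]
  o <- D$orients[i]
  ve <- walk_entry_ext(D, i)
  vf <- walk_exit_ext(D, i)
  ip <- if (i == 1L) n else i - 1L
  inx <- if (i == n) 1L else i + 1L
  e <- D$adjs[ip]
  f <- D$adjs[i]
  outer_e <- walk_exit_ext(D, ip)
  outer_f <- walk_entry_ext(D, inx)

  orient_chain <- function(key, junction, at) {
    ch <- st$chains[[key]]
    if (ch[[at]] == junction) ch
    else if (ch[[if (at == "q") "p" else "q"]] == junction) chain_reverse(ch)
    else stop("internal: chain endpoint mismatch")
  }
  partE <- if (is_ctr_key(e)) orient_chain(e, ve, "q") else
    list(adjs = e, segs = character(0), oris = integer(0), p = outer_e, q = ve)
  partF <- if (is_ctr_key(f)) orient_chain(f, vf, "p") else
    list(adjs = f, segs = character(0), oris = integer(0), p = vf, q = outer_f)
  newch <- list(adjs = c(partE$adjs, partF$adjs),
                segs = c(partE$segs, y, partF$segs),
                oris = c(partE$oris, o, partF$oris),
                p = partE$p, q = partF$q)
  stopifnot(newch$p == outer_e, newch$q == outer_f)

  # ledger: the junction pair expanded to original adjacency edges
  e_orig <- partE$adjs[length(partE$adjs)]
  f_orig <- partF$adjs[1L]
  st$contracted <- c(st$contracted,
                     triple_key(y, e_orig, ext_side(ve), f_orig, ext_side(vf)))
  st$middles[y] <- st$middles[y] + 1L

  # graph surgery: one copy each of e, y, f out; contracted edge j in
  st$ctr <- st$ctr + 1L
  jkey_uid <- sprintf("c%d", st$ctr)
  adj <- st$wg$adjacencies
  dec <- function(adj, key, by) {
    r <- which(adj$key == key)
    stopifnot(length(r) == 1L, adj$mu[r] >= by)
    adj$mu[r] <- adj$mu[r] - by
    adj
  }
  adj <- if (e == f) dec(adj, e, 2L) else dec(dec(adj, e, 1L), f, 1L)
  segs <- st$wg$segments
  segs$mu[segs$id == y] <- segs$mu[segs$id == y] - 1L
  adj2 <- adj[adj$mu > 0L, c("v1", "v2", "kind", "mu")]
  adj2$uid <- sub("^[^|]*\\|[^|]*\\|[^|]*\\|?", "", adj$key[adj$mu > 0L])
  adj2 <- rbind(adj2, data.frame(v1 = outer_e, v2 = outer_f,
                                 kind = "contracted", mu = 1L, uid = jkey_uid))
  segs <- segs[segs$mu > 0L, , drop = FALSE]
  st$wg <- build_iag(segs, adj2)
  jkey <- adj_edge_key(pmin(outer_e, outer_f), pmax(outer_e, outer_f),
                       "contracted", jkey_uid)
  stopifnot(jkey %in% st$wg$adjacencies$key)

  # chain registry
  st$chains[[e]] <- NULL
  st$chains[[f]] <- NULL
  st$chains[[jkey]] <- newch

  # rewrite the cycle: rotate the predecessor step to the front, drop step 2
  rot <- walk_rotate(D, ip)
  stopifnot(rot$segs[2L] == y, rot$adjs[1L] == e, rot$adjs[2L] == f)
  st$D <- walk(rot$segs[-2L], rot$orients[-2L],
               c(jkey, rot$adjs[-c(1L, 2L)]), closed = TRUE)
}

# Emit the final fully forced cycle: the working graph is down to one segment
# copy and one adjacency copy.
ccr_emit_degenerate <- function(st) {
  D <- st$D
  s <- D$segs[1L]
  a <- D$adjs[1L]
  stopifnot(!is_supp_key(a), s != SUPP_SEG)
  side_out <- ext_side(walk_exit_ext(D, 1L))
  side_in <- ext_side(walk_entry_ext(D, 1L))
  if (is_ctr_key(a)) {
    ch <- st$chains[[a]]
    if (ch$p != walk_exit_ext(D, 1L)) ch <- chain_reverse(ch)
    stopifnot(ch$p == walk_exit_ext(D, 1L), ch$q == walk_entry_ext(D, 1L))
    st$emitted[[length(st$emitted) + 1L]] <-
      walk(c(s, ch$segs), c(D$orients[1L], ch$oris), ch$adjs, closed = TRUE)
    k <- length(ch$adjs)
    st$contracted <- c(st$contracted,
                       triple_key(s, ch$adjs[k], side_in, ch$adjs[1L], side_out))
    st$chains[[a]] <- NULL
  } else {
    st$emitted[[length(st$emitted) + 1L]] <-
      walk(s, D$orients[1L], a, closed = TRUE)
    st$contracted <- c(st$contracted, triple_key(s, a, side_in, a, side_out))
  }
  st$middles[s] <- st$middles[s] + 1L
  st$wg <- build_iag(st$wg$segments[0L, , drop = FALSE], NULL)
  st$D <- NULL
}

# Terminal selection: place remaining ordinary adjacency copies and the
# optional outer flanks of chains onto free segment copies, no two demands on
# one copy, maximizing the number of retained adjacency copies.
ccr_terminal <- function(st, cg) {
  smu <- seg_mu(cg)
  budget <- smu - st$middles[names(smu)]
  stopifnot(all(budget >= 0L))
  adj <- st$wg$adjacencies
  ord <- adj[!is_supp_key(adj$key) & !is_ctr_key(adj$key) & adj$mu > 0L, ,
             drop = FALSE]
  edges <- data.frame(id = character(0), n1 = character(0), n2 = character(0),
                      avail = integer(0), stringsAsFactors = FALSE)
  if (nrow(ord)) {
    edges <- rbind(edges, data.frame(
      id = paste0("A:", ord$key),
      n1 = ext_seg(ord$v1), n2 = ext_seg(ord$v2),
      avail = ord$mu, stringsAsFactors = FALSE))
  }
  chains <- st$chains
  ckeys <- names(chains)
  stubs <- data.frame(id = character(0), n1 = character(0), n2 = character(0),
                      avail = integer(0), stringsAsFactors = FALSE)
  for (k in ckeys) {
    ch <- chains[[k]]
    stubs <- rbind(stubs, data.frame(
      id = c(paste0("P:", k), paste0("Q:", k)),
      n1 = c(ext_seg(ch$p), ext_seg(ch$q)),
      n2 = ".dummy", avail = 1L, stringsAsFactors = FALSE))
  }
  b <- c(budget, .dummy = nrow(stubs))
  sel <- max_bmatching(b, rbind(edges, stubs))

  walks <- list()
  used <- stats::setNames(integer(length(smu)), names(smu))
  used <- used + st$middles[names(used)]
  step_exiting <- function(v) {
    walk(ext_seg(v), if (ext_side(v) == "h") 1L else -1L)
  }
  step_entering <- function(v) {
    walk(ext_seg(v), if (ext_side(v) == "t") 1L else -1L)
  }
  for (k in ckeys) {
    ch <- chains[[k]]
    kp <- sel[paste0("P:", k)]
    kq <- sel[paste0("Q:", k)]
    keep_p <- !is.na(kp) && kp >= 1L
    keep_q <- !is.na(kq) && kq >= 1L
    segs <- ch$segs; oris <- ch$oris
    adjs <- ch$adjs
    if (!keep_q) adjs <- adjs[-length(adjs)]
    if (!keep_p) adjs <- adjs[-1L]
    if (keep_p) {
      sp <- step_exiting(ch$p)
      segs <- c(sp$segs, segs); oris <- c(sp$orients, oris)
      used[sp$segs] <- used[sp$segs] + 1L
    }
    if (keep_q) {
      sq <- step_entering(ch$q)
      segs <- c(segs, sq$segs); oris <- c(oris, sq$orients)
      used[sq$segs] <- used[sq$segs] + 1L
    }
    stopifnot(length(adjs) == length(segs) - 1L)
    walks[[length(walks) + 1L]] <- walk(segs, oris, adjs, closed = FALSE)
  }
  if (nrow(ord)) {
    for (r in seq_len(nrow(ord))) {
      k <- ord$key[r]
      cnt <- sel[paste0("A:", k)]
      if (is.na(cnt) || cnt < 1L) next
      for (j in seq_len(cnt)) {
        s1 <- step_exiting(ord$v1[r])
        s2 <- step_entering(ord$v2[r])
        walks[[length(walks) + 1L]] <-
          walk(c(s1$segs, s2$segs), c(s1$orients, s2$orients), k)
        used[s1$segs] <- used[s1$segs] + 1L
        used[s2$segs] <- used[s2$segs] + 1L
      }
    }
  }
  free <- smu - used
  stopifnot(all(free >= 0L))
  for (s in names(free)) {
    for (j in seq_len(free[[s]])) {
      walks[[length(walks) + 1L]] <- walk(s, 1L)
    }
  }
  list(walks = walks)
}

# ---- naive baseline ---------------------------------------------------------

#' Naive baseline contig covering
#'
#' Chains segment copies only through adjacency edges that are completely
#' unambiguous locally: the edge is the only adjacency at both of its
#' endpoint vertices and its (loop-weighted) copy number matches the incident
#' segment copy number exactly.  All other adjacencies are left unused, so
#' ambiguous regions fragment into primitive pieces.
#'
#' @param g a positive, decomposable `kc_iag`.
#' @return a `kc_covering`.
#' @export
naive_covering <- function(g) {
  adj <- g$adjacencies[g$adjacencies$mu > 0L, , drop = FALSE]
  smu <- seg_mu(g)
  clean_at <- function(key, v) {
    inc <- adj$v1 == v | adj$v2 == v
    if (sum(inc) != 1L || adj$key[inc] != key) return(FALSE)
    i <- which(adj$key == key)
    l <- 1L + (adj$v1[i] == adj$v2[i])
    l * adj$mu[i] == smu[[ext_seg(v)]]
  }
  keep <- logical(nrow(adj))
  for (i in seq_len(nrow(adj))) {
    keep[i] <- clean_at(adj$key[i], adj$v1[i]) && clean_at(adj$key[i], adj$v2[i])
  }
  gu <- build_iag(g$segments, adj[keep, c("v1", "v2", "kind", "mu")])
  ports <- pairing_struct_partial(gu)
  copy_seg <- rep(names(smu), smu)
  base <- c(0L, cumsum(smu))[seq_along(smu)]
  names(base) <- names(smu)
  ncopy <- length(copy_seg)
  tlink <- rep(NA_integer_, ncopy)
  hlink <- rep(NA_integer_, ncopy)
  for (v in names(ports$byv)) {
    pp <- ports$byv[[v]]
    target <- base[[ext_seg(v)]] + seq_along(pp)
    if (ext_side(v) == "t") tlink[target] <- pp else hlink[target] <- pp
  }
  # the original adjacency keys survive the rebuild because kind and
  # endpoints are unchanged
  new_covering(partial_walks(g, ports, tlink, hlink, copy_seg), g)
}
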