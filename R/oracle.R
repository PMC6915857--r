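# Exponential brute-force reference implementations.
#
# These enumerate every Eulerian decomposition of a small graph by walking
# over (i) all ways of pairing up path endpoints at telomere vertices and
# (ii) all per-segment bijections between adjacency ports at the two segment
# extremities.  They define ground truth for the polynomial algorithms and
# are used in tests and --verify modes only; they are deliberately naive.

ORACLE_CAP <- 12L

oracle_guard <- function(g, cap) {
  if (mu_total(g) > cap) {
    stop(sprintf("instance too large for brute force: mu(E)=%d > cap=%d",
                 mu_total(g), cap))
  }
}

# All distinct ways of pairing up the excess units, as pair plans
# (data.frames v1, v2, mu).  Only the per-vertex-pair counts matter, so the
# enumeration walks over symmetric count matrices with prescribed degrees
# (diagonal entries are balancing loops, consuming two units each).
endpoint_pairings <- function(g) {
  x <- copy_number_excess(g)
  x <- x[x > 0L]
  if (length(x) == 0L) return(list(NULL))
  vs <- names(x)
  k <- length(vs)
  cells <- list()
  for (i in seq_len(k)) for (j in i:k) cells[[length(cells) + 1L]] <- c(i, j)
  plans <- list()
  recurse <- function(ci, rem, take) {
    if (ci > length(cells)) {
      if (all(rem == 0L)) {
        cnt <- take[take[, 3L] > 0L, , drop = FALSE]
        plans[[length(plans) + 1L]] <<-
          data.frame(v1 = vs[cnt[, 1L]], v2 = vs[cnt[, 2L]],
                     mu = cnt[, 3L], stringsAsFactors = FALSE)
      }
      return(invisible())
    }
    ij <- cells[[ci]]
    i <- ij[1L]; j <- ij[2L]
    maxc <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (cval in 0:maxc) {
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * cval
      else {
        rem2[i] <- rem2[i] - cval
        rem2[j] <- rem2[j] - cval
      }
      recurse(ci + 1L, rem2, rbind(take, c(i, j, cval)))
    }
  }
  recurse(1L, unname(x), matrix(integer(0), ncol = 3L))
  plans
}

# iterate over all permutations of 1..n (n small)
perms_of <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

#' Enumerate all Eulerian decompositions of a small graph
#'
#' Exhaustive backtracking over vertex-local pairings of segment-edge copies
#' with adjacency-edge copies; results are deduplicated up to walk reversal,
#' cycle rotation, and multiset equality.
#'
#' @param g a positive, decomposable `kc_iag`.
#' @param cap refuse instances with total multiplicity mu(E) above this.
#' @param max_structures guard on the number of enumerated pairing structures.
#' @return named list of decompositions (each a list of `kc_walk`); names are
#'   canonical multiset strings.
#' @export
enumerate_eds <- function(g, cap = ORACLE_CAP, max_structures = 3e5) {
  oracle_guard(g, cap)
  rep_ <- decomposability_report(g)
  if (!is.null(rep_)) stop(rep_)
  if (nrow(g$segments) == 0L) return(stats::setNames(list(list()), ""))
  comps <- iag_components(g)
  if (length(comps) > 1L) {
    percomp <- lapply(comps, enumerate_eds_component,
                      max_structures = max_structures)
    combos <- list(list())
    for (pc in percomp) {
      combos <- unlist(lapply(combos, function(acc) {
        lapply(pc, function(d) c(acc, d))
      }), recursive = FALSE)
      if (length(combos) > max_structures) stop("instance too large: ED cross product")
    }
    sigs <- vapply(combos, canonical_walkset_string, character(1))
    names(combos) <- sigs
    return(combos[sort(unique(sigs))])
  }
  enumerate_eds_component(g, max_structures)
}

enumerate_eds_component <- function(g, max_structures = 3e5) {
  plans <- endpoint_pairings(g)
  smu <- seg_mu(g)
  nstruct_per_plan <- prod(factorial(smu))
  if (length(plans) * nstruct_per_plan > max_structures) {
    stop("instance too large: ", length(plans) * nstruct_per_plan,
         " pairing structures to enumerate")
  }
  found <- new.env(parent = emptyenv())
  for (plan in plans) {
    gb <- if (is.null(plan)) g else balance_with_suppbal(g, plan)
    ps <- pairing_struct(gb)
    hverts <- ext(names(smu), "h")
    permsets <- lapply(names(smu), function(s) perms_of(smu[[s]]))
    counter <- rep(1L, length(hverts))
    sizes <- vapply(permsets, length, integer(1))
    base_assign <- canonical_assign(ps)
    repeat {
      assign <- base_assign
      for (i in seq_along(hverts)) {
        pp <- ps$byv[[hverts[i]]]
        assign[pp] <- permsets[[i]][[counter[i]]]
      }
      walks <- strip_balancing(extract_cycles(ps, assign))
      sig <- canonical_walkset_string(walks)
      if (is.null(found[[sig]])) found[[sig]] <- walks
      # odometer increment
      i <- 1L
      while (i <= length(counter)) {
        counter[i] <- counter[i] + 1L
        if (counter[i] <= sizes[i]) break
        counter[i] <- 1L
        i <- i + 1L
      }
      if (i > length(counter)) break
    }
  }
  sigs <- sort(ls(found))
  stats::setNames(lapply(sigs, function(s) found[[s]]), sigs)
}

#' Enumerate all minimal Eulerian decompositions of a small graph
#' @inheritParams enumerate_eds
#' @return named list of decompositions of minimal cardinality.
#' @export
enumerate_min_eds <- function(g, cap = ORACLE_CAP, max_structures = 3e5) {
  eds <- enumerate_eds(g, cap, max_structures)
  k <- min_decomposition_size(g)
  eds[vapply(eds, length, integer(1)) == k]
}

#' Brute-force maximal Eulerian decomposition
#' @inheritParams enumerate_eds
#' @return a `kc_decomposition` of maximum cardinality (ties broken by
#'   canonical order).
#' @export
max_ed_bruteforce <- function(g, cap = ORACLE_CAP, max_structures = 3e5) {
  eds <- enumerate_eds(g, cap, max_structures)
  sizes <- vapply(eds, length, integer(1))
  new_decomposition(eds[[which.max(sizes)]], g)
}

# canonical key for the unordered triple (adjacency e at side_e of segment y,
# adjacency f at side_f)
triple_key <- function(y, e, side_e, f, side_f) {
  halves <- sort(c(paste0(e, "@", side_e), paste0(f, "@", side_f)))
  paste(y, halves[1L], halves[2L], sep = " & ")
}

# all consecutive adjacency-pair triples of a walk, as keys
walk_triples <- function(w) {
  n <- length(w$segs)
  out <- character(0)
  if (w$closed) {
    if (n == 0L) return(out)
    for (i in seq_len(n)) {
      eprev <- if (i == 1L) w$adjs[n] else w$adjs[i - 1L]
      enext <- w$adjs[i]
      side_in <- if (w$orients[i] > 0L) "t" else "h"
      out <- c(out, triple_key(w$segs[i], eprev, side_in, enext,
                               if (side_in == "t") "h" else "t"))
    }
  } else if (n >= 3L) {
    for (i in 2L:(n - 1L)) {
      side_in <- if (w$orients[i] > 0L) "t" else "h"
      out <- c(out, triple_key(w$segs[i], w$adjs[i - 1L], side_in, w$adjs[i],
                               if (side_in == "t") "h" else "t"))
    }
  }
  out
}

#' Brute-force forced adjacency pairs
#'
#' A triple (e, y, f) of an adjacency edge e, a segment edge y and an
#' adjacency edge f is *forced* when every minimal Eulerian decomposition
#' contains the sub-walk e-y-f at least once: the pair is then unambiguous
#' and belongs in every consistent contig.
#'
#' @inheritParams enumerate_eds
#' @return data.frame with the triple `key` and `min_count`, the smallest
#'   number of occurrences across minimal decompositions (>= 1 for all rows;
#'   use `min_count` for full-multiplicity forcing semantics).
#' @export
forced_pairs_bruteforce <- function(g, cap = ORACLE_CAP, max_structures = 3e5) {
  meds <- enumerate_min_eds(g, cap, max_structures)
  stopifnot(length(meds) >= 1L)
  tabs <- lapply(meds, function(walks) {
    tr <- unlist(lapply(walks, walk_triples))
    if (length(tr) == 0L) return(integer(0))
    table(tr)
  })
  keys <- Reduce(intersect, lapply(tabs, names))
  if (length(keys) == 0L || is.null(keys)) {
    return(data.frame(key = character(), min_count = integer()))
  }
  mc <- vapply(keys, function(k) {
    min(vapply(tabs, function(tb) as.integer(tb[[k]]), integer(1)))
  }, integer(1))
  data.frame(key = keys, min_count = mc, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Is walk w present in the decomposition (sub-walk for open, identity up to
# rotation/reversal for closed)?
walk_in_decomposition <- function(w, walks) {
  for (h in walks) if (is_subwalk(w, h)) return(TRUE)
  FALSE
}

# enumerate all injections of 1..k into 1..m (ordered selections)
injections_of <- function(k, m) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  recurse <- function(chosen) {
    if (length(chosen) == k) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    for (j in setdiff(seq_len(m), chosen)) recurse(c(chosen, j))
  }
  recurse(integer(0))
  out
}

# Build the walks determined by a partial port assignment: tlink/hlink give,
# per segment copy, the global port id attached at its tail/head (NA = free).
partial_walks <- function(g, ports, tlink, hlink, copy_seg) {
  nport <- length(ports$key)
  # port -> copy it is assigned to
  port_copy <- rep(NA_integer_, nport)
  port_copy[tlink[!is.na(tlink)]] <- which(!is.na(tlink))
  port_copy[hlink[!is.na(hlink)]] <- which(!is.na(hlink))
  ncopy <- length(copy_seg)
  seen <- logical(ncopy)
  walks <- list()
  link_at <- function(j, side) if (side == "t") tlink[j] else hlink[j]
  step_from <- function(j, enter_side) {
    # returns c(next_copy, next_enter_side, adj_key) or NULL
    exit_side <- if (enter_side == "t") "h" else "t"
    pid <- link_at(j, exit_side)
    if (is.na(pid)) return(NULL)
    pid2 <- ports$partner[pid]
    j2 <- port_copy[pid2]
    stopifnot(!is.na(j2))
    list(j2, ext_side(ports$vert[pid2]), ports$key[pid])
  }
  for (j0 in seq_len(ncopy)) {
    if (seen[j0]) next
    # walk back to the start of the chain (or detect a cycle)
    j <- j0; enter <- "t"; guard <- 0L
    repeat {
      back_pid <- link_at(j, enter)
      if (is.na(back_pid)) break
      pid2 <- ports$partner[back_pid]
      jprev <- port_copy[pid2]
      prev_exit <- ext_side(ports$vert[pid2])
      j <- jprev; enter <- if (prev_exit == "t") "h" else "t"
      guard <- guard + 1L
      if (j == j0 && enter == "t") break  # cycle
      if (guard > ncopy + 1L) stop("internal: backtrack loop")
    }
    is_cycle <- !is.na(link_at(j, enter))
    segs <- character(0); oris <- integer(0); adjs <- character(0)
    cj <- j; cent <- enter
    repeat {
      seen[cj] <- TRUE
      segs <- c(segs, copy_seg[cj])
      oris <- c(oris, if (cent == "t") 1L else -1L)
      nx <- step_from(cj, cent)
      if (is.null(nx)) break
      adjs <- c(adjs, nx[[3]])
      cj <- nx[[1]]; cent <- nx[[2]]
      if (is_cycle && cj == j && cent == enter) break
    }
    walks[[length(walks) + 1L]] <- walk(segs, oris, adjs, closed = is_cycle)
  }
  walks
}

#' Brute-force optimal consistent contig covering
#'
#' Exhaustively searches contig coverings assembled from assignments of
#' adjacency-edge copies to segment-edge copies.  A covering qualifies when
#' each of its walks is present in every minimal Eulerian decomposition; the
#' minimum contiguity discordance over qualifying coverings is returned with
#' one witness.
#'
#' @inheritParams enumerate_eds
#' @return list with `discordance` (integer), `covering` (list of `kc_walk`)
#'   and `n_min_eds`.
#' @export
optimal_covering_bruteforce <- function(g, cap = ORACLE_CAP, max_structures = 3e5) {
  oracle_guard(g, cap)
  meds <- enumerate_min_eds(g, cap, max_structures)
  smu <- seg_mu(g)
  adj <- g$adjacencies[g$adjacencies$mu > 0L, ]
  mu_ea <- sum(adj$mu)
  copy_seg <- rep(names(smu), smu)
  na <- nrow(adj)
  # usage vectors, largest total first
  grid <- if (na) expand.grid(lapply(adj$mu, function(m) 0:m)) else
    data.frame(row.names = 1)
  totals <- if (na) rowSums(grid) else 0L
  ord <- order(totals, decreasing = TRUE)
  best <- NULL
  for (ridx in ord) {
    u <- if (na) as.integer(grid[ridx, ]) else integer(0)
    # vertex load feasibility
    if (na) {
      load <- stats::setNames(numeric(0), character(0))
      addl <- function(v, k) {
        load[v] <<- if (v %in% names(load)) load[[v]] + k else k
      }
      for (i in seq_len(na)) {
        if (u[i] == 0L) next
        addl(adj$v1[i], u[i]); addl(adj$v2[i], u[i])
      }
      if (length(load) &&
          any(load > smu[ext_seg(names(load))])) next
    }
    # build used-port table
    used <- adj
    used$mu <- u
    used <- used[used$mu > 0L, ]
    gu <- build_iag(g$segments, used[, c("v1", "v2", "kind", "mu")])
    ports <- pairing_struct_partial(gu)
    ok_walks <- covering_assignments_qualify(g, ports, copy_seg, smu, meds)
    if (!is.null(ok_walks)) {
      best <- list(discordance = as.integer(mu_ea - sum(u)),
                   covering = ok_walks, n_min_eds = length(meds))
      break
    }
  }
  if (is.null(best)) stop("internal: no qualifying covering (primitive always qualifies)")
  best
}

# like pairing_struct but without the balance requirement
pairing_struct_partial <- function(g) {
  adj <- g$adjacencies[g$adjacencies$mu > 0L, ]
  nport <- 2L * sum(adj$mu)
  key <- character(nport); acopy <- integer(nport); endn <- integer(nport)
  vert <- character(nport)
  p <- 0L
  if (nrow(adj)) {
    for (i in seq_len(nrow(adj))) {
      m <- adj$mu[i]
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
  byv <- split(seq_len(nport), vert)
  byv <- lapply(byv, function(pp) pp[order(key[pp], acopy[pp], endn[pp])])
  list(key = key, vert = vert, partner = partner, byv = byv)
}

# Try all injective assignments of used ports to segment copies; return the
# first assignment whose walks are all present in every minimal ED, else NULL.
covering_assignments_qualify <- function(g, ports, copy_seg, smu, meds) {
  segs <- names(smu)
  base <- c(0L, cumsum(smu))[seq_along(segs)]
  names(base) <- segs
  verts <- names(ports$byv)
  inj_sets <- lapply(verts, function(v) {
    k <- length(ports$byv[[v]])
    m <- smu[[ext_seg(v)]]
    if (ext_side(v) == "t") list(seq_len(k)) else injections_of(k, m)
  })
  sizes <- vapply(inj_sets, length, integer(1))
  if (prod(sizes) > 2e4) stop("instance too large: covering assignment explosion")
  counter <- rep(1L, length(verts))
  ncopy <- length(copy_seg)
  repeat {
    tlink <- rep(NA_integer_, ncopy)
    hlink <- rep(NA_integer_, ncopy)
    ok <- TRUE
    for (i in seq_along(verts)) {
      v <- verts[i]
      pp <- ports$byv[[v]]
      target <- base[[ext_seg(v)]] + inj_sets[[i]][[counter[i]]]
      if (ext_side(v) == "t") tlink[target] <- pp else hlink[target] <- pp
    }
    walks <- partial_walks(g, ports, tlink, hlink, copy_seg)
    qual <- TRUE
    for (w in walks) {
      if (length(w$segs) == 1L && !w$closed) next
      for (med in meds) {
        if (!walk_in_decomposition(w, med)) { qual <- FALSE; break }
      }
      if (!qual) break
    }
    if (qual) return(walks)
    i <- 1L
    while (i <= length(counter)) {
      counter[i] <- counter[i] + 1L
      if (counter[i] <= sizes[i]) break
      counter[i] <- 1L
      i <- i + 1L
    }
    if (i > length(counter) || length(counter) == 0L) break
  }
  NULL
}
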