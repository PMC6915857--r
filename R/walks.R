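# Walks: segment/adjacency edge-alternating paths and cycles.
#
# A walk records an ordered sequence of oriented segment occurrences plus the
# adjacency edge used between each consecutive pair (and, for a cycle, the
# adjacency closing it).  Traversing a segment tail-to-head is "forward" (+1).

#' Construct a walk
#'
#' @param segs character vector of segment ids, in traversal order.
#' @param orients integer vector of +1 (tail to head) / -1 per step.
#' @param adjs character vector of adjacency edge keys joining consecutive
#'   steps; length `length(segs) - 1` for an open walk, `length(segs)` for a
#'   closed one (the last entry closes the cycle).
#' @param closed logical; is this a cycle?
#' @return an object of class `kc_walk`.
#' @export
walk <- function(segs, orients, adjs = character(), closed = FALSE) {
  n <- length(segs)
  stopifnot(n >= 1L, length(orients) == n,
            length(adjs) == if (closed) n else n - 1L,
            all(orients %in% c(-1L, 1L)))
  structure(list(segs = as.character(segs), orients = as.integer(orients),
                 adjs = as.character(adjs), closed = isTRUE(closed)),
            class = "kc_walk")
}

#' @export
print.kc_walk <- function(x, ...) {
  cat(if (x$closed) "cycle: " else "path:  ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.kc_walk <- function(x, ...) {
  paste0(x$segs, ifelse(x$orients > 0L, "+", "-"), collapse = " ")
}

#' Number of segment occurrences in a walk
#' @param w a `kc_walk`.
#' @return integer.
#' @export
walk_length <- function(w) length(w$segs)

# Extremity where step i is entered / exited.
walk_entry_ext <- function(w, i = seq_along(w$segs)) {
  ext(w$segs[i], ifelse(w$orients[i] > 0L, "t", "h"))
}
walk_exit_ext <- function(w, i = seq_along(w$segs)) {
  ext(w$segs[i], ifelse(w$orients[i] > 0L, "h", "t"))
}

#' Reverse a walk
#' @param w a `kc_walk`.
#' @return the same walk traversed in the opposite direction.
#' @export
walk_reverse <- function(w) {
  n <- length(w$segs)
  adjs <- if (w$closed) {
    if (n == 1L) w$adjs else c(rev(w$adjs[seq_len(n - 1L)]), w$adjs[n])
  } else rev(w$adjs)
  walk(rev(w$segs), -rev(w$orients), adjs, w$closed)
}

# Rotate a closed walk so that step k becomes step 1.
walk_rotate <- function(w, k) {
  stopifnot(w$closed)
  n <- length(w$segs)
  if (k == 1L || n == 1L) return(w)
  idx <- c(k:n, seq_len(k - 1L))
  walk(w$segs[idx], w$orients[idx], w$adjs[idx], TRUE)
}

# Interleaved token vector: step, adj, step, adj, ...
walk_tokens <- function(w) {
  steps <- paste0(w$segs, ifelse(w$orients > 0L, "+", "-"))
  n <- length(steps)
  if (length(w$adjs) == 0L) return(steps)
  if (w$closed) {
    as.vector(rbind(steps, w$adjs))
  } else {
    c(as.vector(rbind(steps[-n], w$adjs)), steps[n])
  }
}

walk_string <- function(w) paste(walk_tokens(w), collapse = "\x1f")

#' Canonical form of a walk
#'
#' Open walks are rendered in the lexicographically smaller of their two
#' traversal directions; closed walks additionally minimise over all
#' rotations.  Two walks are equal exactly when their canonical strings (and
#' closed flags) agree.
#'
#' @param w a `kc_walk`.
#' @return a character scalar.
#' @export
canonical_walk_string <- function(w) {
  if (!w$closed) {
    return(min(walk_string(w), walk_string(walk_reverse(w))))
  }
  n <- length(w$segs)
  cands <- character(0)
  for (base in list(w, walk_reverse(w))) {
    for (k in seq_len(n)) cands <- c(cands, walk_string(walk_rotate(base, k)))
  }
  paste0("O", min(cands))
}

#' Walk equality up to reversal (and rotation for cycles)
#'
#' @param w1,w2 `kc_walk` objects.
#' @return logical.
#' @export
walks_equal <- function(w1, w2) {
  if (w1$closed != w2$closed) return(FALSE)
  canonical_walk_string(w1) == canonical_walk_string(w2)
}

# endpoints (v1, v2) of an adjacency key
adj_key_ends <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  t(vapply(parts, function(p) p[2:3], character(2)))
}

#' Check structural validity of a walk against a graph
#'
#' Verifies that every referenced segment and adjacency edge exists with
#' positive multiplicity and that each adjacency joins the facing extremities
#' implied by the flanking steps.
#'
#' @param w a `kc_walk`.
#' @param g a `kc_iag`.
#' @return `TRUE`, or a character vector of violation messages.
#' @export
walk_check <- function(w, g) {
  bad <- character()
  smu <- seg_mu(g)
  miss <- setdiff(w$segs, names(smu)[smu > 0L])
  if (length(miss)) bad <- c(bad, paste("unknown or zero-copy segment:", miss))
  amu <- adj_mu(g)
  missa <- setdiff(w$adjs, names(amu)[amu > 0L])
  if (length(missa)) bad <- c(bad, paste("unknown or zero-copy adjacency:", missa))
  n <- length(w$segs)
  if (length(w$adjs)) {
    ends <- adj_key_ends(w$adjs)
    from <- walk_exit_ext(w)
    to <- walk_entry_ext(w)
    i <- seq_along(w$adjs)
    nxt <- if (w$closed) c(seq_len(n)[-1L], 1L) else i + 1L
    ok <- (ends[, 1] == from[i] & ends[, 2] == to[nxt]) |
          (ends[, 2] == from[i] & ends[, 1] == to[nxt])
    if (any(!ok)) {
      bad <- c(bad, paste0("adjacency ", w$adjs[!ok],
                           " does not join the facing extremities"))
    }
  }
  if (length(bad)) bad else TRUE
}

#' Edge usage counts of a walk multiset
#'
#' Tallies how many times each segment and adjacency edge is traversed across
#' a collection of walks (direction-insensitive; each loop traversal counts
#' once toward its edge).
#'
#' @param walks a list of `kc_walk`.
#' @param g optional `kc_iag`; when supplied, each walk is validated with
#'   [walk_check()] and usage vectors cover all edges of `g` (zeros included).
#' @return list with named integer vectors `seg` and `adj`.
#' @export
usage_of <- function(walks, g = NULL) {
  if (!is.null(g)) {
    for (w in walks) {
      chk <- walk_check(w, g)
      if (!isTRUE(chk)) stop("invalid walk: ", paste(chk, collapse = "; "))
    }
  }
  segs <- unlist(lapply(walks, `[[`, "segs"))
  adjs <- unlist(lapply(walks, `[[`, "adjs"))
  su <- if (length(segs)) table(segs) else integer()
  au <- if (length(adjs)) table(adjs) else integer()
  seg_out <- stats::setNames(as.integer(su), names(su))
  adj_out <- stats::setNames(as.integer(au), names(au))
  if (!is.null(g)) {
    full_s <- stats::setNames(integer(nrow(g$segments)), g$segments$id)
    full_s[names(seg_out)] <- seg_out
    full_a <- stats::setNames(integer(nrow(g$adjacencies)), g$adjacencies$key)
    full_a[names(adj_out)] <- adj_out
    seg_out <- full_s
    adj_out <- full_a
  }
  list(seg = seg_out, adj = adj_out)
}

#' Is an open walk a sub-walk of another walk?
#'
#' Token-level containment up to reversal; in a closed host the match may wrap
#' around the rotation point.  A closed `sub` is instead required to equal the
#' host as a cycle (see [walks_equal()]).
#'
#' @param sub,host `kc_walk` objects.
#' @return logical.
#' @export
is_subwalk <- function(sub, host) {
  if (sub$closed) {
    return(host$closed && walks_equal(sub, host))
  }
  pat_f <- walk_tokens(sub)
  pat_r <- walk_tokens(walk_reverse(sub))
  htok <- walk_tokens(host)
  if (host$closed && length(htok) > 1L) htok <- c(htok, htok[seq_len(length(htok) - 1L)])
  match_at <- function(pat) {
    np <- length(pat); nh <- length(htok)
    if (np > nh) return(FALSE)
    # steps sit at odd token positions
    for (st in seq(1L, nh - np + 1L, by = 2L)) {
      if (all(htok[st:(st + np - 1L)] == pat)) return(TRUE)
    }
    FALSE
  }
  match_at(pat_f) || match_at(pat_r)
}

# canonical id string for a multiset of walks (used to dedupe decompositions)
canonical_walkset_string <- function(walks) {
  paste(sort(vapply(walks, canonical_walk_string, character(1))),
        collapse = " %% ")
}
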