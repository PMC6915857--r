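# The weighted interval adjacency graph (karyotype graph) data model.

SUPP_SEG_PREFIX <- ".supp"

#' Construct a weighted interval adjacency graph
#'
#' An interval adjacency graph (IAG, or karyotype graph) has one vertex per
#' segment extremity, one segment edge per segment, and one adjacency edge per
#' adjacency, each carrying a non-negative integer copy number (multiplicity).
#'
#' @param segments either a named integer vector of segment copy numbers
#'   (names are segment ids), or a data.frame with columns `id`, `mu` and
#'   optionally `chrom`, `start`, `end` (1-based inclusive coordinates).
#' @param adjacencies `NULL` for an adjacency-free graph, or a data.frame with
#'   columns `v1`, `v2` (extremity ids, see [ext()]), `kind` (one of
#'   `"reference"`, `"novel"`, `"supplemental"`, `"contracted"`) and `mu`.
#'   Duplicate rows with the same unordered extremity pair and kind are merged
#'   by summing their copy numbers.
#' @return an object of class `kc_iag`.
#' @details A segment with copy number 0 that still carries an adjacency with
#'   positive copy number is rejected: no decomposition could ever traverse
#'   such an adjacency, so the input is inconsistent.
#' @examples
#' g <- build_iag(c(a = 1, b = 2, c = 1),
#'                data.frame(v1 = c("a:h", "b:h", "b:h"),
#'                           v2 = c("b:t", "b:t", "c:t"),
#'                           kind = "novel", mu = 1))
#' copy_number_excess(g)
#' @export
build_iag <- function(segments, adjacencies = NULL) {
  if (is.numeric(segments)) {
    stopifnot(!is.null(names(segments)))
    segments <- data.frame(id = names(segments), mu = as.integer(segments),
                           stringsAsFactors = FALSE)
  }
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "mu") %in% names(segments)))
  if (anyDuplicated(segments$id)) stop("duplicate segment ids")
  if (any(segments$mu < 0)) stop("negative segment multiplicity")
  segments$mu <- as.integer(segments$mu)
  for (col in c("chrom", "start", "end")) {
    if (is.null(segments[[col]])) segments[[col]] <- rep(NA, nrow(segments))
  }
  if (any(!is.na(segments$start) & !is.na(segments$end) &
          segments$start > segments$end)) {
    stop("segment with start > end")
  }
  segments <- segments[order(segments$id), c("id", "chrom", "start", "end", "mu")]
  rownames(segments) <- NULL

  if (is.null(adjacencies) || nrow(as.data.frame(adjacencies)) == 0L) {
    adjacencies <- data.frame(key = character(), v1 = character(),
                              v2 = character(), kind = character(),
                              mu = integer(), stringsAsFactors = FALSE)
  } else {
    adjacencies <- as.data.frame(adjacencies, stringsAsFactors = FALSE)
    stopifnot(all(c("v1", "v2", "mu") %in% names(adjacencies)))
    if (is.null(adjacencies$kind)) adjacencies$kind <- "novel"
    if (any(adjacencies$mu < 0)) stop("negative adjacency multiplicity")
    bad <- !adjacencies$kind %in% c("reference", "novel", "supplemental", "contracted")
    if (any(bad)) stop("unknown adjacency kind: ", adjacencies$kind[bad][1])
    verts <- c(ext(segments$id, "t"), ext(segments$id, "h"))
    miss <- setdiff(c(adjacencies$v1, adjacencies$v2), verts)
    if (length(miss)) {
      stop("adjacency references unknown extremity: ", paste(miss, collapse = ", "))
    }
    lo <- pmin(adjacencies$v1, adjacencies$v2)
    hi <- pmax(adjacencies$v1, adjacencies$v2)
    key <- adj_edge_key(lo, hi, adjacencies$kind)
    if (!is.null(adjacencies$uid)) {
      has_uid <- !is.na(adjacencies$uid) & adjacencies$uid != ""
      key[has_uid] <- adj_edge_key(lo[has_uid], hi[has_uid],
                                   adjacencies$kind[has_uid],
                                   adjacencies$uid[has_uid])
    }
    adjacencies <- data.frame(key = key, v1 = lo, v2 = hi,
                              kind = adjacencies$kind,
                              mu = as.integer(adjacencies$mu),
                              stringsAsFactors = FALSE)
    # merge duplicate edges (e.g. two events creating the same breakend pair)
    if (anyDuplicated(adjacencies$key)) {
      mu <- tapply(adjacencies$mu, adjacencies$key, sum)
      adjacencies <- adjacencies[!duplicated(adjacencies$key), ]
      adjacencies$mu <- as.integer(mu[adjacencies$key])
    }
    adjacencies <- adjacencies[order(adjacencies$key), ]
    rownames(adjacencies) <- NULL
  }

  g <- structure(list(segments = segments, adjacencies = adjacencies),
                 class = "kc_iag")
  smu <- seg_mu(g)
  dead <- names(smu)[smu == 0L]
  if (length(dead)) {
    dead_ext <- c(ext(dead, "t"), ext(dead, "h"))
    live_adj <- g$adjacencies$mu > 0L
    touch <- (g$adjacencies$v1 %in% dead_ext | g$adjacencies$v2 %in% dead_ext) & live_adj
    if (any(touch)) {
      stop("segment with copy number 0 carries an adjacency with positive ",
           "copy number: ", g$adjacencies$key[touch][1])
    }
  }
  g
}

#' @export
print.kc_iag <- function(x, ...) {
  cat(sprintf("kc_iag: %d segments (mu(E_S)=%d), %d adjacencies (mu(E_A)=%d)\n",
              nrow(x$segments), sum(x$segments$mu),
              nrow(x$adjacencies), sum(x$adjacencies$mu)))
  invisible(x)
}

#' Segment copy numbers as a named vector
#' @param g a `kc_iag`.
#' @return named integer vector, names are segment ids.
#' @export
seg_mu <- function(g) stats::setNames(g$segments$mu, g$segments$id)

#' Adjacency copy numbers as a named vector
#' @param g a `kc_iag`.
#' @return named integer vector, names are adjacency edge keys.
#' @export
adj_mu <- function(g) stats::setNames(g$adjacencies$mu, g$adjacencies$key)

#' Vertex set (all segment extremities)
#' @param g a `kc_iag`.
#' @return sorted character vector of extremity ids.
#' @export
iag_vertices <- function(g) sort(c(ext(g$segments$id, "t"), ext(g$segments$id, "h")))

#' Total edge multiplicity mu(E)
#' @param g a `kc_iag`.
#' @return integer, the sum of all segment and adjacency copy numbers.
#' @export
mu_total <- function(g) sum(g$segments$mu) + sum(g$adjacencies$mu)

#' Restrict a weighted IAG to its positive part
#'
#' Drops all edges with copy number 0; segments with copy number 0 are removed
#' together with their two extremities.
#'
#' @param g a `kc_iag`.
#' @return a positive `kc_iag` (all retained edges have mu >= 1).
#' @export
positive_restriction <- function(g) {
  build_iag(g$segments[g$segments$mu > 0L, , drop = FALSE],
            g$adjacencies[g$adjacencies$mu > 0L, c("v1", "v2", "kind", "mu")])
}

#' Copy number excess of vertices
#'
#' The excess of a vertex is the copy number of its segment edge minus the
#' loop-weighted sum of copy numbers of its incident adjacency edges (a loop
#' counts twice).  Positive excess marks telomere vertices; a graph admits an
#' Eulerian decomposition if and only if no vertex has negative excess.
#'
#' @param g a `kc_iag`.
#' @param v extremity ids (default: all vertices of `g`).
#' @return named integer vector of excesses.
#' @export
copy_number_excess <- function(g, v = NULL) {
  verts <- iag_vertices(g)
  if (is.null(v)) v <- verts
  if (!all(v %in% verts)) {
    stop("unknown vertex: ", paste(setdiff(v, verts), collapse = ", "))
  }
  x <- stats::setNames(seg_mu(g)[ext_seg(verts)], verts)
  # counting both endpoints of every adjacency naturally gives loops weight 2
  load <- c(tapply(c(g$adjacencies$mu, g$adjacencies$mu),
                   c(g$adjacencies$v1, g$adjacencies$v2), sum))
  hit <- intersect(names(load), verts)
  x[hit] <- x[hit] - load[hit]
  x[v]
}

#' Is the graph Eulerian-decomposable?
#'
#' @param g a positive `kc_iag`.
#' @return `TRUE` iff every vertex has non-negative copy number excess.
#' @export
is_decomposable <- function(g) {
  nrow(g$segments) == 0L || all(copy_number_excess(g) >= 0L)
}

# Connected component id per vertex (union-find over segment + adjacency edges
# with positive multiplicity).  Returns a named integer vector.
iag_component_ids <- function(g) {
  verts <- iag_vertices(g)
  n <- length(verts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  idx <- stats::setNames(seq_len(n), verts)
  live <- g$segments$id[g$segments$mu > 0L]
  for (s in live) unite(idx[ext(s, "t")], idx[ext(s, "h")])
  adj <- g$adjacencies[g$adjacencies$mu > 0L, ]
  if (nrow(adj)) {
    for (i in seq_len(nrow(adj))) unite(idx[adj$v1[i]], idx[adj$v2[i]])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, sort(unique(roots)))
  stats::setNames(comp, verts)
}

#' Split a graph into its connected components
#' @param g a `kc_iag`.
#' @return list of `kc_iag`, one per connected component, in canonical vertex
#'   order.
#' @export
iag_components <- function(g) {
  if (nrow(g$segments) == 0L) return(list())
  comp <- iag_component_ids(g)
  lapply(sort(unique(comp)), function(k) {
    vk <- names(comp)[comp == k]
    segs <- unique(ext_seg(vk))
    build_iag(g$segments[g$segments$id %in% segs, , drop = FALSE],
              g$adjacencies[g$adjacencies$v1 %in% vk |
                            g$adjacencies$v2 %in% vk,
                            c("v1", "v2", "kind", "mu")])
  })
}

#' Partition connected components by copy number excess
#'
#' Components containing at least one vertex with positive excess (`C_plus`,
#' ending in telomeres) are decomposable into paths; fully balanced components
#' (`C_zero`) are covered by cycles.
#'
#' @param g a positive, decomposable `kc_iag`.
#' @return list with elements `C_plus` and `C_zero`, each a list of `kc_iag`.
#' @export
classify_components <- function(g) {
  comps <- iag_components(g)
  pos <- vapply(comps, function(cg) any(copy_number_excess(cg) > 0L), logical(1))
  list(C_plus = comps[pos], C_zero = comps[!pos])
}
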