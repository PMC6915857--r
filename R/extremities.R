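# Extremity and edge-key helpers.
#
# Vertices of an interval adjacency graph are segment extremities, encoded as
# "<segment_id>:t" (tail) and "<segment_id>:h" (head).  Adjacency edges are
# keyed by their unordered extremity pair plus their kind, so that parallel
# reference and novel adjacencies between the same two extremities remain
# distinct edges.

#' Build extremity identifiers
#'
#' @param seg character vector of segment identifiers.
#' @param side "t" (tail) or "h" (head), recycled against `seg`.
#' @return character vector of extremity ids of the form `"seg:side"`.
#' @examples
#' ext("a", "h")
#' @export
ext <- function(seg, side) {
  stopifnot(all(side %in% c("t", "h")))
  paste0(seg, ":", side)
}

#' Segment id of an extremity
#' @param v extremity id vector.
#' @return character vector of segment ids.
#' @export
ext_seg <- function(v) sub(":[th]$", "", v)

#' Side of an extremity
#' @param v extremity id vector.
#' @return "t" or "h" per element.
#' @export
ext_side <- function(v) substring(v, nchar(v), nchar(v))

#' Opposite extremity of the same segment
#' @param v extremity id vector.
#' @return the other extremity of each segment.
#' @export
ext_other <- function(v) {
  ext(ext_seg(v), ifelse(ext_side(v) == "t", "h", "t"))
}

# Canonical adjacency edge key: unordered pair + kind.  `uid` is used for
# contracted edges, which must stay distinct even with equal endpoints.
adj_edge_key <- function(v1, v2, kind, uid = NULL) {
  lo <- pmin(v1, v2)
  hi <- pmax(v1, v2)
  k <- paste(kind, lo, hi, sep = "|")
  if (!is.null(uid)) k <- paste(k, uid, sep = "|")
  k
}
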