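# Contiguity statistics for coverings.

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length at least L together cover
#' at least half the total length.  With even splits the larger qualifying
#' length is returned (lengths sorted descending, cumulative sum >= half).
#'
#' @param lengths numeric vector of contig lengths (bp), non-empty.
#' @return numeric scalar.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length collection")
  stopifnot(all(lengths >= 0))
  srt <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(srt)
  srt[which(cum >= sum(srt) / 2)[1L]]
}

seg_lengths <- function(g) {
  len <- g$segments$end - g$segments$start + 1L
  stats::setNames(as.numeric(len), g$segments$id)
}

walk_bp <- function(w, lens) sum(lens[w$segs])

#' Contiguity statistics of a covering
#'
#' @param g a `kc_iag` with segment coordinates.
#' @param t a `kc_covering` (or list of `kc_walk`).
#' @return data.frame with one row: `n_contigs`, `total_bp` (multiplicities
#'   included), `n50_bp`, `n_closed`, `discordance`.
#' @export
covering_stats <- function(g, t) {
  walks <- if (inherits(t, "kc_covering")) t$walks else t
  disc <- contiguity_discordance(g, walks)
  lens <- seg_lengths(g)
  if (any(is.na(lens))) stop("covering_stats requires segment coordinates")
  wl <- vapply(walks, walk_bp, numeric(1), lens = lens)
  data.frame(n_contigs = length(walks),
             total_bp = sum(wl),
             n50_bp = n50(wl),
             n_closed = sum(vapply(walks, `[[`, logical(1), "closed")),
             discordance = disc)
}

#' Is a contig supported by the true genome?
#'
#' True when the contig is a sub-walk (up to reversal; identity up to
#' rotation for cycles) of some true chromosome.
#'
#' @param contig a `kc_walk`.
#' @param truth list of true chromosome `kc_walk`s (e.g. from
#'   [genome_to_iag()]).
#' @return logical.
#' @export
contig_supported <- function(contig, truth) {
  walk_in_decomposition(contig, truth)
}
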