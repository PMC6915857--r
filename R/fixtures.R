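# Small worked-example graphs used throughout the documentation and tests.

#' Example karyotype graphs
#'
#' Three tiny graphs that exercise the main structural situations:
#' \describe{
#'   \item{`"tandem"`}{a single chromosome `a b b c` after a tandem
#'     duplication of `b`: segments a, b, c with mu(b) = 2 and adjacencies
#'     a:h-b:t, b:h-b:t, b:h-c:t.  Its minimal Eulerian decomposition is the
#'     unique path `a+ b+ b+ c+`.}
#'   \item{`"ambiguous"`}{segments a..e with mu(b) = 2 and adjacencies
#'     a:h-b:t, c:h-b:t, b:h-d:t, b:h-e:t.  Two distinct minimal
#'     decompositions exist (`{a b d, c b e}` and `{a b e, c b d}`), so no
#'     adjacency pair through b is consistent.}
#'   \item{`"circular"`}{one segment `a` with the adjacency a:h-a:t: a
#'     circular chromosome (double minute).}
#' }
#'
#' Coordinates are synthetic (1 kb segments on one chromosome) so that length
#' metrics are well defined.
#'
#' @param which one of `"tandem"`, `"ambiguous"`, `"circular"`.
#' @return a `kc_iag`.
#' @examples
#' g <- example_iag("tandem")
#' solve_min_edp(g)
#' @export
example_iag <- function(which = c("tandem", "ambiguous", "circular")) {
  which <- match.arg(which)
  seg_tab <- function(ids) {
    n <- length(ids)
    data.frame(id = ids, chrom = "chr1",
               start = seq(1L, by = 1000L, length.out = n),
               end = seq(1000L, by = 1000L, length.out = n),
               mu = 1L, stringsAsFactors = FALSE)
  }
  switch(which,
    tandem = {
      segs <- seg_tab(c("a", "b", "c"))
      segs$mu[segs$id == "b"] <- 2L
      build_iag(segs, data.frame(
        v1 = c("a:h", "b:h", "b:h"), v2 = c("b:t", "b:t", "c:t"),
        kind = c("reference", "novel", "reference"), mu = 1L))
    },
    ambiguous = {
      segs <- seg_tab(c("a", "b", "c", "d", "e"))
      segs$mu[segs$id == "b"] <- 2L
      build_iag(segs, data.frame(
        v1 = c("a:h", "c:h", "b:h", "b:h"), v2 = c("b:t", "b:t", "d:t", "e:t"),
        kind = c("reference", "novel", "reference", "novel"), mu = 1L))
    },
    circular = {
      build_iag(seg_tab("a"),
                data.frame(v1 = "a:h", v2 = "a:t", kind = "novel", mu = 1L))
    })
}
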