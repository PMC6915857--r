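# Readers and writers: RCK-dialect segment/adjacency tables, contig-path
# tables, and AGP 2.1.
#
# All coordinates in files are 1-based inclusive.  Algorithms never see
# coordinates, only extremity identities, so no off-by-one can leak into the
# math.  Files are tab-separated with a mandatory header; extra columns are
# ignored (and preserved only in the sense that the reader does not reject
# them).

seg_id_from_coords <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, start, end)
}

#' Read a weighted IAG from segment and adjacency tables
#'
#' The segments table needs columns `chrom`, `start`, `end`, `cn`; the
#' adjacency table needs `aid`, `chrom1`, `coord1`, `strand1`, `chrom2`,
#' `coord2`, `strand2`, `kind` (`R` or `N`), `cn`.  A `+`-strand breakend at
#' a coordinate maps to the head of the segment ending there, a `-`-strand
#' breakend to the tail of the segment starting there.
#'
#' @param segments_path,adjacencies_path file paths.
#' @return a `kc_iag` (positive restriction of the tables).
#' @export
read_iag <- function(segments_path, adjacencies_path) {
  st <- utils::read.delim(segments_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("chrom", "start", "end", "cn")
  if (!all(need %in% names(st))) {
    stop("segments table must have columns: ", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(st))) {
    if (is.na(st$start[i]) || is.na(st$end[i]) || st$start[i] > st$end[i] ||
        is.na(st$cn[i]) || st$cn[i] < 0) {
      stop("malformed segment row at line ", i + 1L)
    }
  }
  segs <- data.frame(id = seg_id_from_coords(st$chrom, st$start, st$end),
                     chrom = st$chrom, start = st$start, end = st$end,
                     mu = as.integer(st$cn), stringsAsFactors = FALSE)

  resolve_breakend <- function(chrom, pos, strand, line) {
    if (strand == "+") {
      hit <- which(segs$chrom == chrom & segs$end == pos)
      side <- "h"
    } else if (strand == "-") {
      hit <- which(segs$chrom == chrom & segs$start == pos)
      side <- "t"
    } else {
      stop("bad strand at line ", line)
    }
    if (length(hit) != 1L) {
      stop("breakend ", chrom, ":", pos, strand,
           " does not match a segment boundary (line ", line, ")")
    }
    ext(segs$id[hit], side)
  }

  at <- utils::read.delim(adjacencies_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  adj <- NULL
  if (nrow(at)) {
    need <- c("aid", "chrom1", "coord1", "strand1", "chrom2", "coord2",
              "strand2", "kind", "cn")
    if (!all(need %in% names(at))) {
      stop("adjacency table must have columns: ", paste(need, collapse = ", "))
    }
    v1 <- character(nrow(at)); v2 <- character(nrow(at))
    for (i in seq_len(nrow(at))) {
      if (is.na(at$cn[i]) || at$cn[i] < 0 ||
          !at$kind[i] %in% c("R", "N")) {
        stop("malformed adjacency row at line ", i + 1L)
      }
      v1[i] <- resolve_breakend(at$chrom1[i], at$coord1[i], at$strand1[i], i + 1L)
      v2[i] <- resolve_breakend(at$chrom2[i], at$coord2[i], at$strand2[i], i + 1L)
    }
    adj <- data.frame(v1 = v1, v2 = v2,
                      kind = ifelse(at$kind == "R", "reference", "novel"),
                      mu = as.integer(at$cn), stringsAsFactors = FALSE)
  }
  positive_restriction(build_iag(segs, adj))
}

#' Write a weighted IAG as segment and adjacency tables
#'
#' Inverse of [read_iag()]; requires segment coordinates.
#'
#' @param g a `kc_iag`.
#' @param segments_path,adjacencies_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_iag <- function(g, segments_path, adjacencies_path) {
  st <- data.frame(chrom = g$segments$chrom, start = g$segments$start,
                   end = g$segments$end, cn = g$segments$mu)
  if (any(is.na(st$chrom))) stop("write_iag requires segment coordinates")
  utils::write.table(st, segments_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  adj <- g$adjacencies
  brk <- function(v) {
    seg <- match(ext_seg(v), g$segments$id)
    side <- ext_side(v)
    list(chrom = g$segments$chrom[seg],
         coord = ifelse(side == "h", g$segments$end[seg], g$segments$start[seg]),
         strand = ifelse(side == "h", "+", "-"))
  }
  if (nrow(adj)) {
    b1 <- brk(adj$v1); b2 <- brk(adj$v2)
    at <- data.frame(aid = sprintf("a%d", seq_len(nrow(adj))),
                     chrom1 = b1$chrom, coord1 = b1$coord, strand1 = b1$strand,
                     chrom2 = b2$chrom, coord2 = b2$coord, strand2 = b2$strand,
                     kind = ifelse(adj$kind == "reference", "R", "N"),
                     cn = adj$mu)
  } else {
    at <- data.frame(aid = character(), chrom1 = character(),
                     coord1 = integer(), strand1 = character(),
                     chrom2 = character(), coord2 = integer(),
                     strand2 = character(), kind = character(), cn = integer())
  }
  utils::write.table(at, adjacencies_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(segments_path, adjacencies_path))
}

#' Write a covering (or decomposition) as a contig-path table
#'
#' One row per walk: `contig_id`, `closed`, `path` (semicolon-joined oriented
#' reference intervals `chrom:start-end:+`), `adjacencies` (semicolon-joined
#' adjacency edge keys, enabling exact round trips), `length_bp`.
#'
#' @param t a `kc_covering`, `kc_decomposition` or list of `kc_walk`.
#' @param g the underlying `kc_iag` (for coordinates).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_covering <- function(t, g, path) {
  walks <- if (inherits(t, "kc_covering") || inherits(t, "kc_decomposition"))
    t$walks else t
  lens <- seg_lengths(g)
  ivl <- stats::setNames(
    sprintf("%s:%d-%d", g$segments$chrom, g$segments$start, g$segments$end),
    g$segments$id)
  # adjacency keys are rewritten in coordinate terms so that tables survive
  # a round trip through read_iag (which renames segments by coordinates)
  portable_adj <- function(keys) {
    if (length(keys) == 0L) return("")
    parts <- strsplit(keys, "|", fixed = TRUE)
    vapply(parts, function(p) {
      paste(p[1L],
            paste0(ivl[ext_seg(p[2L])], ":", ext_side(p[2L])),
            paste0(ivl[ext_seg(p[3L])], ":", ext_side(p[3L])),
            sep = "|")
    }, character(1))
  }
  rows <- lapply(seq_along(walks), function(i) {
    w <- walks[[i]]
    data.frame(contig_id = sprintf("ctg%03d", i),
               closed = w$closed,
               path = paste0(ivl[w$segs],
                             ifelse(w$orients > 0L, ":+", ":-"),
                             collapse = ";"),
               adjacencies = paste(portable_adj(w$adjs), collapse = ";"),
               length_bp = walk_bp(w, lens))
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(), closed = logical(), path = character(),
               adjacencies = character(), length_bp = numeric())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contig-path table back into walks
#'
#' @param path a file written by [write_covering()].
#' @param g the `kc_iag` the covering refers to.
#' @return a `kc_covering`.
#' @export
read_covering <- function(path, g) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  id_of <- stats::setNames(
    g$segments$id,
    sprintf("%s:%d-%d", g$segments$chrom, g$segments$start, g$segments$end))
  unportable_adj <- function(entries) {
    vapply(entries, function(e) {
      p <- strsplit(e, "|", fixed = TRUE)[[1]]
      stopifnot(length(p) == 3L)
      to_ext <- function(x) {
        side <- sub("^.*:", "", x)
        ivl <- sub(":[th]$", "", x)
        ext(id_of[[ivl]], side)
      }
      v1 <- to_ext(p[2L]); v2 <- to_ext(p[3L])
      adj_edge_key(min(v1, v2), max(v1, v2), p[1L])
    }, character(1), USE.NAMES = FALSE)
  }
  walks <- lapply(seq_len(nrow(tab)), function(i) {
    steps <- strsplit(tab$path[i], ";", fixed = TRUE)[[1]]
    m <- regmatches(steps, regexec("^(.*):([+-])$", steps))
    segs <- id_of[vapply(m, `[`, "", 2L)]
    oris <- ifelse(vapply(m, `[`, "", 3L) == "+", 1L, -1L)
    adjs <- if (is.na(tab$adjacencies[i]) || tab$adjacencies[i] == "")
      character(0) else
      unportable_adj(strsplit(tab$adjacencies[i], ";", fixed = TRUE)[[1]])
    walk(unname(segs), oris, adjs, closed = tab$closed[i])
  })
  new_covering(walks, g)
}

#' Write open contigs as an AGP 2.1 file
#'
#' Every open walk becomes one AGP object whose components are the oriented
#' reference intervals of its steps (W lines, 1-based, no gap lines).
#' Closed walks cannot be represented in AGP and raise an error.
#'
#' @param t a `kc_covering` or list of `kc_walk`.
#' @param g the underlying `kc_iag`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_agp <- function(t, g, path) {
  walks <- if (inherits(t, "kc_covering") || inherits(t, "kc_decomposition"))
    t$walks else t
  if (any(vapply(walks, `[[`, logical(1), "closed"))) {
    stop("AGP describes linear objects only; write closed walks with ",
         "write_covering() instead")
  }
  lens <- seg_lengths(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (i in seq_along(walks)) {
    w <- walks[[i]]
    obj <- sprintf("ctg%03d", i)
    pos <- 1L
    for (k in seq_along(w$segs)) {
      s <- match(w$segs[k], g$segments$id)
      L <- lens[[w$segs[k]]]
      writeLines(paste(obj, pos, pos + L - 1L, k, "W",
                       g$segments$chrom[s], g$segments$start[s],
                       g$segments$end[s],
                       if (w$orients[k] > 0L) "+" else "-",
                       sep = "\t"), con)
      pos <- pos + L
    }
  }
  invisible(path)
}
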