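# Simulation of rearranged genomes with known chromosome structure.
#
# A reference genome is built as a set of linear chromosomes partitioned into
# segments; large-scale events (deletion, tandem duplication, inversion,
# reciprocal translocation, circularization, whole-genome duplication) are
# applied at segment boundaries; the derived genome then induces a weighted
# interval adjacency graph whose ground truth decomposition is known.
#
# All randomness flows from the single seed in the configuration, applied
# once by simulate_case(); the individual steps are deterministic given the
# RNG state.

#' Simulation configuration
#'
#' @param n_chrom number of reference chromosomes.
#' @param chrom_length length of each reference chromosome in bp (recycled).
#' @param segments_per_chrom number of segments each chromosome is split
#'   into; event breakpoints are drawn from these boundaries.
#' @param n_del,n_dup,n_inv,n_tra,n_circ event counts (deletion, tandem
#'   duplication, inversion, reciprocal translocation, circularization).
#' @param wgd logical; append a whole-genome duplication?
#' @param seed mandatory integer seed.
#' @return a `kc_sim_config`.
#' @export
sim_config <- function(n_chrom = 2L, chrom_length = 1e8, segments_per_chrom = 8L,
                       n_del = 1L, n_dup = 1L, n_inv = 1L, n_tra = 1L,
                       n_circ = 0L, wgd = FALSE, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_chrom = as.integer(n_chrom),
              chrom_length = rep_len(chrom_length, n_chrom),
              segments_per_chrom = as.integer(segments_per_chrom),
              n_del = as.integer(n_del), n_dup = as.integer(n_dup),
              n_inv = as.integer(n_inv), n_tra = as.integer(n_tra),
              n_circ = as.integer(n_circ), wgd = isTRUE(wgd),
              seed = as.integer(seed))
  stopifnot(cfg$n_chrom >= 1L, cfg$segments_per_chrom >= 1L,
            all(unlist(cfg[4:8]) >= 0L))
  structure(cfg, class = "kc_sim_config")
}

#' Build the reference genome of a simulation
#'
#' Chromosomes are identity walks over consecutive segments with random
#' segment lengths (uniform breakpoints).
#'
#' @param cfg a `kc_sim_config`.
#' @return a `kc_genome`: segments table, chromosome walks, and the set of
#'   reference-consecutive extremity pairs.
#' @export
simulate_reference <- function(cfg) {
  segs <- NULL
  chroms <- list()
  for (ci in seq_len(cfg$n_chrom)) {
    chrom <- paste0("chr", ci)
    L <- cfg$chrom_length[ci]
    k <- cfg$segments_per_chrom
    cuts <- if (k > 1L) sort(sample.int(L - 1L, k - 1L)) else integer(0)
    start <- c(1L, cuts + 1L)
    end <- c(cuts, L)
    ids <- sprintf("%s.%02d", chrom, seq_len(k))
    segs <- rbind(segs, data.frame(id = ids, chrom = chrom, start = start,
                                   end = end, stringsAsFactors = FALSE))
    chroms[[ci]] <- list(segs = ids, orients = rep(1L, k), closed = FALSE)
  }
  ref_pairs <- character(0)
  for (ch in chroms) {
    n <- length(ch$segs)
    if (n > 1L) {
      ref_pairs <- c(ref_pairs, paste(ext(ch$segs[-n], "h"),
                                      ext(ch$segs[-1L], "t")))
    }
  }
  structure(list(segments = segs, chromosomes = chroms,
                 ref_pairs = ref_pairs, log = character(0)),
            class = "kc_genome")
}

# pick a span of up to `maxlen` consecutive steps inside chromosome `ch`
pick_span <- function(n, maxlen = 3L) {
  len <- sample.int(min(maxlen, n), 1L)
  i <- sample.int(n - len + 1L, 1L)
  c(i, i + len - 1L)
}

#' Apply rearrangement events to a genome
#'
#' Events are applied in random order at segment boundaries.  Inapplicable
#' draws (e.g. a deletion that would erase a whole chromosome) are resampled
#' and logged in the genome's `log` field.
#'
#' @param genome a `kc_genome`.
#' @param cfg a `kc_sim_config`.
#' @return the rearranged `kc_genome`.
#' @export
apply_events <- function(genome, cfg) {
  events <- c(rep("del", cfg$n_del), rep("dup", cfg$n_dup),
              rep("inv", cfg$n_inv), rep("tra", cfg$n_tra),
              rep("circ", cfg$n_circ))
  if (length(events) > 1L) events <- sample(events)
  if (cfg$wgd) events <- c(events, "wgd")
  for (ev in events) {
    done <- FALSE
    for (try in 1:50) {
      ci <- sample.int(length(genome$chromosomes), 1L)
      ch <- genome$chromosomes[[ci]]
      n <- length(ch$segs)
      if (ev == "del") {
        if (n < 2L) next
        sp <- pick_span(n, maxlen = min(3L, n - 1L))
        idx <- sp[1]:sp[2]
        if (length(idx) >= n) next
        if (ch$closed && length(idx) >= n) next
        ch$segs <- ch$segs[-idx]; ch$orients <- ch$orients[-idx]
        genome$chromosomes[[ci]] <- ch
      } else if (ev == "dup") {
        sp <- pick_span(n)
        idx <- sp[1]:sp[2]
        ch$segs <- append(ch$segs, ch$segs[idx], after = sp[2])
        ch$orients <- append(ch$orients, ch$orients[idx], after = sp[2])
        genome$chromosomes[[ci]] <- ch
      } else if (ev == "inv") {
        sp <- pick_span(n)
        idx <- sp[1]:sp[2]
        ch$segs[idx] <- rev(ch$segs[idx])
        ch$orients[idx] <- -rev(ch$orients[idx])
        genome$chromosomes[[ci]] <- ch
      } else if (ev == "tra") {
        lin <- which(!vapply(genome$chromosomes, `[[`, logical(1), "closed"))
        lin <- setdiff(lin, ci)
        if (ch$closed || length(lin) == 0L) next
        cj <- if (length(lin) == 1L) lin else sample(lin, 1L)
        ch2 <- genome$chromosomes[[cj]]
        n2 <- length(ch2$segs)
        if (n < 2L || n2 < 2L) next
        cut1 <- sample.int(n - 1L, 1L)
        cut2 <- sample.int(n2 - 1L, 1L)
        newA <- list(segs = c(ch$segs[1:cut1], ch2$segs[(cut2 + 1L):n2]),
                     orients = c(ch$orients[1:cut1], ch2$orients[(cut2 + 1L):n2]),
                     closed = FALSE)
        newB <- list(segs = c(ch2$segs[1:cut2], ch$segs[(cut1 + 1L):n]),
                     orients = c(ch2$orients[1:cut2], ch$orients[(cut1 + 1L):n]),
                     closed = FALSE)
        genome$chromosomes[[ci]] <- newA
        genome$chromosomes[[cj]] <- newB
      } else if (ev == "circ") {
        if (ch$closed) next
        ch$closed <- TRUE
        genome$chromosomes[[ci]] <- ch
      } else if (ev == "wgd") {
        genome$chromosomes <- c(genome$chromosomes, genome$chromosomes)
      }
      done <- TRUE
      break
    }
    if (!done) genome$log <- c(genome$log, paste("event skipped:", ev))
  }
  genome
}

#' Induce the weighted IAG of a genome
#'
#' Edge multiplicities are the traversal counts of the chromosome walks;
#' adjacencies present in the reference order are labelled `reference`,
#' all others `novel`.  Segments never used by the genome are dropped.
#'
#' @param genome a `kc_genome`.
#' @return list with `graph` (a positive `kc_iag`) and `truth` (the
#'   chromosomes as `kc_walk`s over that graph, a valid Eulerian
#'   decomposition by construction).
#' @export
genome_to_iag <- function(genome) {
  chroms <- genome$chromosomes
  segs_used <- table(unlist(lapply(chroms, `[[`, "segs")))
  seg_tab <- genome$segments[genome$segments$id %in% names(segs_used), ]
  seg_tab$mu <- as.integer(segs_used[seg_tab$id])
  adj <- NULL
  for (ch in chroms) {
    n <- length(ch$segs)
    w0 <- walk(ch$segs, ch$orients,
               adjs = rep("x", if (ch$closed) n else max(n - 1L, 0L)),
               closed = ch$closed)
    k <- length(w0$adjs)
    if (k == 0L) next
    i <- seq_len(k)
    nxt <- if (ch$closed) c(seq_len(n)[-1L], 1L) else i + 1L
    from <- walk_exit_ext(w0, i)
    to <- walk_entry_ext(w0, nxt)
    kind <- ifelse(paste(from, to) %in% genome$ref_pairs |
                   paste(to, from) %in% genome$ref_pairs, "reference", "novel")
    adj <- rbind(adj, data.frame(v1 = from, v2 = to, kind = kind, mu = 1L,
                                 stringsAsFactors = FALSE))
  }
  g <- build_iag(seg_tab, adj)
  truth <- lapply(chroms, function(ch) {
    n <- length(ch$segs)
    k <- if (ch$closed) n else n - 1L
    if (k > 0L) {
      w0 <- walk(ch$segs, ch$orients, rep("x", k), ch$closed)
      i <- seq_len(k)
      nxt <- if (ch$closed) c(seq_len(n)[-1L], 1L) else i + 1L
      from <- walk_exit_ext(w0, i)
      to <- walk_entry_ext(w0, nxt)
      kind <- ifelse(paste(from, to) %in% genome$ref_pairs |
                     paste(to, from) %in% genome$ref_pairs, "reference", "novel")
      adjs <- adj_edge_key(pmin(from, to), pmax(from, to), kind)
      walk(ch$segs, ch$orients, adjs, ch$closed)
    } else {
      walk(ch$segs, ch$orients, character(0), ch$closed)
    }
  })
  list(graph = g, truth = truth)
}

#' Simulate a complete case: reference, rearranged genome, induced graph
#'
#' Seeds the RNG from the configuration, so identical configurations give
#' identical cases.
#'
#' @param cfg a `kc_sim_config`.
#' @return list with `reference`, `genome`, `graph`, `truth`.
#' @export
simulate_case <- function(cfg) {
  stopifnot(inherits(cfg, "kc_sim_config"))
  withr_seed <- cfg$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(withr_seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  ref <- simulate_reference(cfg)
  gen <- apply_events(ref, cfg)
  gi <- genome_to_iag(gen)
  list(reference = ref, genome = gen, graph = gi$graph, truth = gi$truth)
}
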