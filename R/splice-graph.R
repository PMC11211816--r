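## Splice graph: weighted DAG over (partial) exons for one gene locus.
## Vertices are numbered 1..n left to right; 0 is the source s and n+1 the
## sink t. Edge kinds: "junction" (spliced intron), "adjacent" (two
## vertices abutting in the genome with continuous coverage), "source",
## "sink". Vertex weight is mean per-base coverage; junction edge weight
## is the number of reads spanning that junction.

SOURCE_V <- 0L

sink_id <- function(g) nrow(g$vs) + 1L

#' Build a splice graph from the fragments of one locus and sample
#'
#' Junctions extracted from spliced alignments become edges; junction
#' donor/acceptor positions partition the covered genome into (partial)
#' exons, which become vertices. Vertex weight is the average per-base
#' coverage of the exon; junction edge weight is the count of reads
#' spanning the junction; adjacent edges connect coordinate-adjacent
#' vertices with continuous coverage, weighted by the reads overlapping
#' the shared boundary.
#'
#' @param frags list of fragments (see [pair_fragments()]); pooled
#'   fragments of several samples yield the cluster's combined graph.
#' @param chrom,strand locus coordinates (taken from the first fragment
#'   when omitted).
#' @param sample_id integer sample index, or `NA` for a combined graph.
#' @param min_junction_support drop junctions seen in fewer reads
#'   (default 1, i.e. keep all; the downstream scorer handles noise).
#' @param merge_gap internal zero-coverage gaps at least this wide split
#'   a vertex; narrower holes are bridged (default 50 bp).
#' @param extra_reads optional list of pseudo-reads (as produced during
#'   graph refinement) added to the fragment evidence.
#' @return a `splice_graph` object (unaugmented).
#' @export
build_graph <- function(frags, chrom = NULL, strand = NULL, sample_id = NA_integer_,
                        min_junction_support = 1L, merge_gap = 50L,
                        extra_reads = list()) {
  reads <- list()
  for (f in frags) {
    reads[[length(reads) + 1L]] <- f$r1
    if (!is.null(f$r2)) reads[[length(reads) + 1L]] <- f$r2
  }
  reads <- c(reads, extra_reads)
  if (is.null(chrom)) chrom <- if (length(frags)) frags[[1L]]$chrom else "."
  if (is.null(strand)) strand <- if (length(frags)) frags[[1L]]$strand else "."
  g <- structure(list(chrom = chrom, strand = strand, sample_id = sample_id,
                      vs = data.frame(start = integer(0), end = integer(0),
                                      weight = numeric(0)),
                      edges = empty_edges(), augmented = FALSE,
                      n_frags = length(frags)),
                 class = "splice_graph")
  if (length(reads) == 0L) return(g)

  ## flatten blocks of every read
  bs <- integer(0); be <- integer(0)
  jk <- character(0)
  for (r in reads) {
    j <- r$juncs
    if (nrow(j)) {
      bs <- c(bs, r$start, j[, 2L])
      be <- c(be, j[, 1L], r$end)
      jk <- c(jk, paste(j[, 1L], j[, 2L]))
    } else {
      bs <- c(bs, r$start); be <- c(be, r$end)
    }
  }
  jtab <- table(jk)
  jmat <- if (length(jtab)) {
    xy <- do.call(rbind, lapply(strsplit(names(jtab), " "), as.integer))
    keep <- as.integer(jtab) >= min_junction_support
    cbind(donor = xy[keep, 1L], acceptor = xy[keep, 2L],
          weight = as.integer(jtab)[keep])
  } else matrix(integer(0), ncol = 3L,
                dimnames = list(NULL, c("donor", "acceptor", "weight")))

  blocks_ir <- IRanges::IRanges(start = bs + 1L, end = be)  # to 1-based
  regions <- IRanges::reduce(blocks_ir, min.gapwidth = merge_gap)
  cov <- IRanges::coverage(blocks_ir)
  splice_pos <- sort(unique(c(jmat[, "donor"], jmat[, "acceptor"])))

  vs_start <- integer(0); vs_end <- integer(0)
  for (k in seq_along(regions)) {
    l <- IRanges::start(regions)[k] - 1L
    r <- IRanges::end(regions)[k]
    cuts <- splice_pos[splice_pos > l & splice_pos < r]
    b <- c(l, cuts, r)
    vs_start <- c(vs_start, b[-length(b)])
    vs_end <- c(vs_end, b[-1L])
  }
  ord <- order(vs_start)
  vs_start <- vs_start[ord]; vs_end <- vs_end[ord]
  covn <- as.numeric(cov)
  wts <- vapply(seq_along(vs_start), function(i) {
    a <- vs_start[i] + 1L; b <- vs_end[i]
    if (b > length(covn)) b <- length(covn)
    if (a > b) return(0)
    mean(covn[a:b])
  }, numeric(1))
  g$vs <- data.frame(start = vs_start, end = vs_end, weight = wts)

  from <- integer(0); to <- integer(0); kind <- character(0); wt <- numeric(0)
  if (nrow(jmat)) {
    u <- match(jmat[, "donor"], vs_end)
    v <- match(jmat[, "acceptor"], vs_start)
    ok <- !is.na(u) & !is.na(v)
    from <- c(from, u[ok]); to <- c(to, v[ok])
    kind <- c(kind, rep("junction", sum(ok)))
    wt <- c(wt, as.numeric(jmat[ok, "weight"]))
  }
  n <- nrow(g$vs)
  if (n > 1L) {
    adj <- which(vs_end[-n] == vs_start[-1L])
    if (length(adj)) {
      b <- vs_end[adj]  # shared boundaries
      spanning <- IRanges::countOverlaps(IRanges::IRanges(b, b + 1L),
                                         blocks_ir, type = "within")
      from <- c(from, adj); to <- c(to, adj + 1L)
      kind <- c(kind, rep("adjacent", length(adj)))
      wt <- c(wt, as.numeric(spanning))
    }
  }
  ord <- order(from, to)
  g$edges <- data.frame(from = from[ord], to = to[ord], kind = kind[ord],
                        weight = wt[ord], stringsAsFactors = FALSE)
  g
}

empty_edges <- function() {
  data.frame(from = integer(0), to = integer(0), kind = character(0),
             weight = numeric(0), stringsAsFactors = FALSE)
}

#' Add source and sink to a splice graph
#'
#' Every vertex with in-degree 0 receives an edge from the source `s`
#' weighted by the sum of its out-edge weights, and every vertex with
#' out-degree 0 an edge to the sink `t` weighted by the sum of its
#' in-edge weights, so that transcripts correspond exactly to s-t paths.
#' An isolated vertex (no junctions or adjacencies at all) would get
#' weight 0 under that rule; it is assigned its own coverage instead so
#' single-exon loci keep a usable abundance.
#'
#' @param g a `splice_graph`.
#' @return the augmented graph (idempotent).
#' @export
augment_source_sink <- function(g) {
  if (isTRUE(g$augmented)) return(g)
  n <- nrow(g$vs)
  if (n == 0L) { g$augmented <- TRUE; return(g) }
  e <- g$edges
  indeg <- tabulate(e$to, n)
  outdeg <- tabulate(e$from, n)
  outw <- vapply(seq_len(n), function(v) sum(e$weight[e$from == v]), numeric(1))
  inw <- vapply(seq_len(n), function(v) sum(e$weight[e$to == v]), numeric(1))
  starting <- which(indeg == 0L)
  ending <- which(outdeg == 0L)
  src_w <- ifelse(outdeg[starting] > 0L, outw[starting], g$vs$weight[starting])
  snk_w <- ifelse(indeg[ending] > 0L, inw[ending], g$vs$weight[ending])
  g$edges <- rbind(
    data.frame(from = SOURCE_V, to = starting, kind = "source",
               weight = src_w, stringsAsFactors = FALSE),
    e,
    data.frame(from = ending, to = n + 1L, kind = "sink",
               weight = snk_w, stringsAsFactors = FALSE))
  rownames(g$edges) <- NULL
  g$augmented <- TRUE
  g
}

#' Splice positions of a graph
#'
#' The union of donor and acceptor coordinates over all junction edges;
#' the basis of the cross-sample graph similarity.
#'
#' @param g a `splice_graph`.
#' @return sorted integer vector (possibly empty).
#' @export
splice_positions <- function(g) {
  e <- g$edges[g$edges$kind == "junction", , drop = FALSE]
  if (nrow(e) == 0L) return(integer(0))
  sort(unique(c(g$vs$end[e$from], g$vs$start[e$to])))
}

#' Junction edges of a graph as a coordinate matrix
#'
#' @param g a `splice_graph`.
#' @return numeric matrix with columns `donor`, `acceptor`, `weight`.
#' @export
graph_junctions <- function(g) {
  e <- g$edges[g$edges$kind == "junction", , drop = FALSE]
  cbind(donor = g$vs$end[e$from], acceptor = g$vs$start[e$to],
        weight = e$weight)
}

## Left/right genomic position of edge row i: L(e) = R(u), R(e) = L(v).
edge_coords <- function(g, i) {
  u <- g$edges$from[i]; v <- g$edges$to[i]
  c(L = if (u == SOURCE_V) NA_integer_ else g$vs$end[u],
    R = if (v > nrow(g$vs)) NA_integer_ else g$vs$start[v])
}

#' @export
format.splice_graph <- function(x, ...) {
  hdr <- sprintf("graph %s:%s sample=%s vertices=%d edges=%d%s",
                 x$chrom, x$strand,
                 if (is.na(x$sample_id)) "combined" else x$sample_id,
                 nrow(x$vs), nrow(x$edges),
                 if (isTRUE(x$augmented)) " augmented" else "")
  vl <- sprintf("vertex %d [%d,%d) w=%.4g", seq_len(nrow(x$vs)),
                x$vs$start, x$vs$end, x$vs$weight)
  el <- sprintf("edge %s %d->%d w=%.4g", x$edges$kind, x$edges$from,
                x$edges$to, x$edges$weight)
  c(hdr, vl, el)
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Write a splice graph in a plain-text debug format
#'
#' One line per vertex and edge; used by fixtures and for inspection.
#'
#' @param g a `splice_graph`.
#' @param path output file.
#' @export
write_graph_debug <- function(g, path) {
  writeLines(format(g), path)
  invisible(path)
}
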