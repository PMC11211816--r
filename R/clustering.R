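## Cross-sample clustering of individual splice graphs. Graphs from
## different samples that describe the same gene locus share splice
## positions; single-linkage agglomeration on the Jaccard similarity of
## splice-position sets groups them, capped at a maximum cluster size.

#' Similarity between two splice graphs
#'
#' Jaccard index of the two graphs' splice-position sets. Two graphs
#' without any junctions have an undefined (0/0) index; it is defined as
#' 0 here, so junction-free graphs group only through genomic bundling.
#'
#' @param gi,gj `splice_graph` objects.
#' @return a number in \[0, 1\].
#' @export
graph_similarity <- function(gi, gj) {
  si <- splice_positions(gi)
  sj <- splice_positions(gj)
  u <- length(union(si, sj))
  if (u == 0L) return(0)
  length(intersect(si, sj)) / u
}

#' Single-linkage clustering of individual splice graphs
#'
#' Pairs are merged in decreasing similarity order; a merge that would
#' push a cluster past `size_cap` is skipped, and merging stops below
#' `min_similarity`. Ties in similarity are broken by the smaller
#' (sample, sample) index pair so the partition is deterministic.
#'
#' @param graphs list of `splice_graph` objects (one per sample, all
#'   overlapping one genomic bundle).
#' @param size_cap maximum members per cluster; conventionally the
#'   number of samples.
#' @param min_similarity merging stops below this similarity
#'   (default 0.1), preventing unrelated loci that share one splice site
#'   from fusing.
#' @return list of integer vectors, each the indices (into `graphs`) of
#'   one cluster's members, ordered by smallest member.
#' @export
cluster_graphs <- function(graphs, size_cap = length(graphs),
                           min_similarity = 0.1) {
  m <- length(graphs)
  if (m == 0L) return(list())
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1L) {
    pairs <- utils::combn(m, 2L)
    sims <- apply(pairs, 2L, function(p)
      graph_similarity(graphs[[p[1L]]], graphs[[p[2L]]]))
    ord <- order(-sims, pairs[1L, ], pairs[2L, ])
    sizes <- rep(1L, m)
    for (k in ord) {
      if (sims[k] < min_similarity) break
      a <- find(pairs[1L, k]); b <- find(pairs[2L, k])
      if (a == b) next
      if (sizes[a] + sizes[b] > size_cap) next
      parent[b] <- a
      sizes[a] <- sizes[a] + sizes[b]
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  out <- split(seq_len(m), roots)
  names(out) <- NULL
  out[order(vapply(out, min, integer(1)))]
}

#' Build the combined splice graph of a cluster
#'
#' The combined graph pools every fragment that contributed to any
#' member graph and rebuilds a single graph from them, so it contains
#' every member junction (with at least the member's weight) plus any
#' junction seen only in other members.
#'
#' @param frags_by_member list of fragment lists, one per cluster member.
#' @param chrom,strand locus coordinates.
#' @param min_junction_support,merge_gap as in [build_graph()].
#' @return an augmented `splice_graph` with `sample_id = NA` (combined).
#' @export
build_combined <- function(frags_by_member, chrom = NULL, strand = NULL,
                           min_junction_support = 1L, merge_gap = 50L) {
  pooled <- do.call(c, frags_by_member)
  g <- build_graph(pooled, chrom = chrom, strand = strand,
                   sample_id = NA_integer_,
                   min_junction_support = min_junction_support,
                   merge_gap = merge_gap)
  augment_source_sink(g)
}
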