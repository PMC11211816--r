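## Edge supports: for every edge of every graph in a cluster, a length-N
## vector quantifying how strongly each member sample's graph
## corroborates that edge. Junction edges are supported by an identical
## junction; adjacent edges by an identical adjacency or by a vertex
## spanning the boundary; starting/ending edges by a nearby boundary
## edge, allowing a bounded extension (200 bp by default) across one
## adjacent hop.

## Per-member lookup tables used when computing supports repeatedly.
support_index <- function(gj) {
  e <- gj$edges
  jr <- which(e$kind == "junction")
  jw <- stats::setNames(e$weight[jr],
                        paste(gj$vs$end[e$from[jr]], gj$vs$start[e$to[jr]]))
  ar <- which(e$kind == "adjacent")
  aw <- stats::setNames(e$weight[ar], gj$vs$end[e$from[ar]])
  n <- nrow(gj$vs)
  start_w <- rep(NA_real_, n); end_w <- rep(NA_real_, n)
  sr <- which(e$kind == "source")
  start_w[e$to[sr]] <- e$weight[sr]
  kr <- which(e$kind == "sink")
  end_w[e$from[kr]] <- e$weight[kr]
  has_in_adj <- rep(FALSE, n); has_out_adj <- rep(FALSE, n)
  has_in_adj[e$to[ar]] <- TRUE
  has_out_adj[e$from[ar]] <- TRUE
  list(vs = gj$vs, jw = jw, aw = aw, start_w = start_w, end_w = end_w,
       has_in_adj = has_in_adj, has_out_adj = has_out_adj)
}

## Vertex of idx strictly containing boundary position b, else NA.
vertex_spanning <- function(idx, b) {
  v <- findInterval(b - 0.5, idx$vs$start)
  if (v >= 1L && idx$vs$start[v] < b && idx$vs$end[v] > b) v else NA_integer_
}

#' Support of a junction edge by a member graph
#'
#' A member supports a junction exactly when it has a junction edge with
#' identical donor and acceptor coordinates; the support is that edge's
#' weight, else 0.
#'
#' @param gj a member `splice_graph`.
#' @param donor,acceptor junction coordinates (0-based half-open).
#' @return a non-negative number.
#' @export
support_junction <- function(gj, donor, acceptor) {
  w <- support_index(gj)$jw[paste(donor, acceptor)]
  if (is.na(w)) 0 else unname(w)
}

#' Support of an adjacent edge by a member graph
#'
#' An identical adjacent edge supports with its weight; failing that, a
#' vertex of the member that strictly spans the boundary (covers the
#' bases on both sides) supports with its coverage. When both exist the
#' adjacent edge takes precedence.
#'
#' @param gj a member `splice_graph`.
#' @param boundary the shared coordinate of the two adjacent vertices.
#' @return a non-negative number.
#' @export
support_adjacent <- function(gj, boundary) {
  support_adjacent_idx(support_index(gj), boundary)
}

support_adjacent_idx <- function(idx, b) {
  w <- idx$aw[as.character(b)]
  if (!is.na(w)) return(unname(w))
  v <- vertex_spanning(idx, b)
  if (!is.na(v)) idx$vs$weight[v] else 0
}

#' Support of a starting or ending edge by a member graph
#'
#' For a starting edge into vertex `v`, the right coordinate of `v` is
#' located in the member graph; a starting edge into the vertex
#' containing it supports directly, otherwise one incoming adjacent hop
#' to the left is examined, provided the extension does not exceed
#' `max_ext` base pairs (strict threshold). Ending edges mirror this to
#' the right.
#'
#' @param gj a member `splice_graph` (augmented, so its own boundary
#'   edges exist).
#' @param pos the located coordinate: R(v) of the starting vertex, or
#'   L(u) of the ending vertex (0-based).
#' @param side `"start"` or `"end"`.
#' @param max_ext maximum extension in bp (default 200).
#' @return a non-negative number.
#' @export
support_boundary <- function(gj, pos, side = c("start", "end"),
                             max_ext = 200L) {
  support_boundary_idx(support_index(gj), pos, match.arg(side), max_ext)
}

support_boundary_idx <- function(idx, pos, side, max_ext = 200L) {
  n <- nrow(idx$vs)
  if (n == 0L) return(0)
  if (side == "start") {
    v <- findInterval(pos - 0.5, idx$vs$start)   # last vertex with start < pos
    if (v < 1L || idx$vs$end[v] < pos) return(0)
    if (!is.na(idx$start_w[v])) return(idx$start_w[v])
    if (v > 1L && idx$has_in_adj[v] && !is.na(idx$start_w[v - 1L]) &&
        pos - idx$vs$start[v] <= max_ext)
      return(idx$start_w[v - 1L])
    return(0)
  }
  v <- findInterval(pos, idx$vs$start)           # last vertex with start <= pos
  if (v < 1L || idx$vs$end[v] <= pos) return(0)
  if (!is.na(idx$end_w[v])) return(idx$end_w[v])
  if (v < n && idx$has_out_adj[v] && !is.na(idx$end_w[v + 1L]) &&
      idx$vs$end[v] - pos <= max_ext)
    return(idx$end_w[v + 1L])
  0
}

#' Compose two support vectors
#'
#' The support of a path through two consecutive edges is the
#' elementwise minimum of the two edges' supports: a sample corroborates
#' the composite only as much as its weakest constituent.
#'
#' @param mi,mo equal-length numeric support vectors.
#' @return numeric vector of the same length.
#' @export
compose_support <- function(mi, mo) {
  if (length(mi) != length(mo))
    stop("support vectors have different lengths: ",
         length(mi), " vs ", length(mo))
  pmin(mi, mo)
}

#' Compute support vectors for every edge of a set of graphs
#'
#' For each edge of each graph in `graphs` (typically the refined member
#' graphs plus the combined graph), the length-N support vector over the
#' `members` graphs is computed by the type-appropriate rule. A member
#' supports its own edges too (the self-entry equals the edge weight for
#' junction and adjacent edges).
#'
#' @param graphs list of augmented `splice_graph`s needing supports.
#' @param members list of the N member `splice_graph`s (augmented).
#' @param max_ext boundary extension threshold in bp (default 200).
#' @return list parallel to `graphs`; element k is a numeric matrix
#'   with one row per edge of `graphs[[k]]` and N columns.
#' @export
compute_supports <- function(graphs, members, max_ext = 200L) {
  idxs <- lapply(members, support_index)
  n_samp <- length(members)
  lapply(graphs, function(g) {
    ne <- nrow(g$edges)
    m <- matrix(0, nrow = ne, ncol = n_samp)
    if (ne == 0L) return(m)
    sink <- nrow(g$vs) + 1L
    for (i in seq_len(ne)) {
      kind <- g$edges$kind[i]
      u <- g$edges$from[i]; v <- g$edges$to[i]
      for (j in seq_len(n_samp)) {
        idx <- idxs[[j]]
        m[i, j] <- switch(
          kind,
          junction = {
            w <- idx$jw[paste(g$vs$end[u], g$vs$start[v])]
            if (is.na(w)) 0 else unname(w)
          },
          adjacent = support_adjacent_idx(idx, g$vs$end[u]),
          source = support_boundary_idx(idx, g$vs$end[v], "start", max_ext),
          sink = support_boundary_idx(idx, g$vs$start[u], "end", max_ext),
          0)
      }
    }
    m
  })
}
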