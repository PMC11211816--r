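## Phase-preserving graph decomposition. Vertices are removed one at a
## time; each removal replaces the vertex's in/out edges by merged
## in-out pairs. Pairs are dictated by the phasing paths threading the
## vertex; in/out edges not touched by any phasing path are paired with
## the counterpart maximizing the summed composed support across
## samples. Because every phasing-path pair becomes a merged edge and
## every edge keeps at least one partner, each phasing path survives
## contiguously in at least one final s-t path, and every input junction
## is covered by at least one transcript. Weights are reallocated
## proportionally on the in-side, so the total source outflow -- and
## hence the summed transcript abundance -- is conserved exactly.

#' Resolve isolated vertices of a bipartite decomposition graph
#'
#' Given the phasing links of a vertex being decomposed, every in-edge
#' or out-edge not covered by a link is connected to the opposite-side
#' edge with the largest summed composed support
#' (`sum_j min(M_in[j], M_out[j])`). Left side (in-edges) is resolved
#' first, then the right side, each in edge order; ties pick the first
#' candidate in edge order.
#'
#' @param links two-column integer matrix of (in-edge id, out-edge id)
#'   phasing links (possibly 0 rows).
#' @param ins,outs integer ids of the in-edges and out-edges, in order.
#' @param sup named list (or environment) mapping edge id to its support
#'   vector.
#' @return the completed two-column link matrix.
#' @export
resolve_isolated <- function(links, ins, outs, sup) {
  getsup <- function(id) sup[[as.character(id)]]
  score <- function(a, b) sum(pmin(getsup(a), getsup(b)))
  for (side in 1:2) {
    mine <- if (side == 1L) ins else outs
    other <- if (side == 1L) outs else ins
    for (e in mine) {
      linked <- if (side == 1L) links[, 1L] else links[, 2L]
      if (e %in% linked) next
      if (length(other) == 0L) next
      sc <- vapply(other, function(o) score(e, o), numeric(1))
      best <- other[which.max(sc)]   # which.max: first index on ties
      links <- rbind(links, if (side == 1L) c(e, best) else c(best, e))
    }
  }
  links
}

## Mutable decomposition state built from an augmented graph.
decomp_state <- function(g, supports = NULL, paths = list()) {
  stopifnot(isTRUE(g$augmented))
  n <- nrow(g$vs)
  ne <- nrow(g$edges)
  if (is.null(supports)) supports <- matrix(g$edges$weight, ncol = 1L)
  st <- new.env(parent = emptyenv())
  st$g <- g
  st$n <- n
  st$from <- g$edges$from
  st$to <- g$edges$to
  st$weight <- g$edges$weight
  real <- g$edges$kind %in% c("junction", "adjacent")
  st$minw <- ifelse(real, g$edges$weight, Inf)
  st$sup <- lapply(seq_len(ne), function(i) supports[i, ])
  st$bsup <- st$sup
  st$chain <- lapply(seq_len(ne), function(i) c(g$edges$from[i], g$edges$to[i]))
  st$alive <- rep(TRUE, ne)
  st$ins <- lapply(seq_len(n), function(v) which(g$edges$to == v))
  st$outs <- lapply(seq_len(n), function(v) which(g$edges$from == v))
  st$vertex_alive <- rep(TRUE, n)
  ekey <- stats::setNames(seq_len(ne), paste(st$from, st$to))
  st$paths <- list(); st$path_count <- integer(0)
  st$dropped <- 0L
  for (p in paths) {
    if (length(p$vseq) < 2L) next
    ids <- unname(ekey[paste(p$vseq[-length(p$vseq)], p$vseq[-1L])])
    if (anyNA(ids)) { st$dropped <- st$dropped + p$count; next }
    st$paths[[length(st$paths) + 1L]] <- ids
    st$path_count <- c(st$path_count, p$count)
  }
  st
}

## Decompose one vertex of the state (trivial or non-trivial).
decompose_vertex <- function(st, v) {
  ins <- sort(st$ins[[v]]); outs <- sort(st$outs[[v]])
  links <- matrix(integer(0), ncol = 2L)
  for (p in st$paths) {
    if (length(p) < 2L) next
    at <- which(st$to[p[-length(p)]] == v)
    for (k in at) links <- rbind(links, c(p[k], p[k + 1L]))
  }
  if (nrow(links)) links <- unique(links)
  if (length(ins) == 1L || length(outs) == 1L) {
    links <- as.matrix(expand.grid(ins, outs, KEEP.OUT.ATTRS = FALSE))
  } else {
    supmap <- stats::setNames(st$sup[c(ins, outs)], c(ins, outs))
    links <- resolve_isolated(links, ins, outs, supmap)
  }
  ## proportional in-side weight allocation
  new_ids <- integer(0)
  pair_new <- character(0)
  first_in <- list(); first_out <- list()
  for (ei in ins) {
    eos <- links[links[, 1L] == ei, 2L]
    denom <- sum(st$weight[eos])
    for (eo in eos) {
      w <- if (denom > 0) st$weight[ei] * st$weight[eo] / denom
           else st$weight[ei] / length(eos)
      id <- length(st$alive) + 1L
      st$from[id] <- st$from[ei]
      st$to[id] <- st$to[eo]
      st$weight[id] <- w
      st$sup[[id]] <- pmin(st$sup[[ei]], st$sup[[eo]])
      if (st$minw[ei] <= st$minw[eo]) {
        st$minw[id] <- st$minw[ei]; st$bsup[[id]] <- st$bsup[[ei]]
      } else {
        st$minw[id] <- st$minw[eo]; st$bsup[[id]] <- st$bsup[[eo]]
      }
      st$chain[[id]] <- c(st$chain[[ei]], st$chain[[eo]][-1L])
      st$alive[id] <- TRUE
      if (st$from[id] >= 1L && st$from[id] <= st$n)
        st$outs[[st$from[id]]] <- c(st$outs[[st$from[id]]], id)
      if (st$to[id] >= 1L && st$to[id] <= st$n)
        st$ins[[st$to[id]]] <- c(st$ins[[st$to[id]]], id)
      pair_new[paste(ei, eo)] <- id
      if (is.null(first_in[[as.character(ei)]]))
        first_in[[as.character(ei)]] <- id
      if (is.null(first_out[[as.character(eo)]]))
        first_out[[as.character(eo)]] <- id
      new_ids <- c(new_ids, id)
    }
  }
  ## retire old edges
  for (ei in ins) {
    st$alive[ei] <- FALSE
    u <- st$from[ei]
    if (u >= 1L && u <= st$n) st$outs[[u]] <- setdiff(st$outs[[u]], ei)
  }
  for (eo in outs) {
    st$alive[eo] <- FALSE
    w <- st$to[eo]
    if (w >= 1L && w <= st$n) st$ins[[w]] <- setdiff(st$ins[[w]], eo)
  }
  st$ins[[v]] <- integer(0); st$outs[[v]] <- integer(0)
  st$vertex_alive[v] <- FALSE
  ## rewrite phasing paths over the new edges
  touched <- c(ins, outs)
  keep <- rep(TRUE, length(st$paths))
  for (pi in seq_along(st$paths)) {
    p <- st$paths[[pi]]
    if (!any(p %in% touched)) next
    q <- integer(0); k <- 1L; ok <- TRUE
    while (k <= length(p)) {
      e <- p[k]
      if (e %in% ins && k < length(p) && p[k + 1L] %in% outs) {
        id <- pair_new[paste(e, p[k + 1L])]
        if (is.na(id)) { ok <- FALSE; break }
        q <- c(q, as.integer(id)); k <- k + 2L
      } else if (e %in% ins) {
        id <- first_in[[as.character(e)]]
        if (is.null(id)) { ok <- FALSE; break }
        q <- c(q, id); k <- k + 1L
      } else if (e %in% outs) {
        id <- first_out[[as.character(e)]]
        if (is.null(id)) { ok <- FALSE; break }
        q <- c(q, id); k <- k + 1L
      } else {
        q <- c(q, e); k <- k + 1L
      }
    }
    if (ok) st$paths[[pi]] <- q
    else {
      keep[pi] <- FALSE
      st$dropped <- st$dropped + st$path_count[pi]
    }
  }
  st$paths <- st$paths[keep]
  st$path_count <- st$path_count[keep]
  invisible(st)
}

## Pick the next vertex: any trivial vertex (leftmost), else the
## non-trivial vertex with the smallest in*out degree (leftmost on ties).
next_vertex <- function(st) {
  alive <- which(st$vertex_alive)
  if (length(alive) == 0L) return(NA_integer_)
  indeg <- lengths(st$ins[alive])
  outdeg <- lengths(st$outs[alive])
  triv <- alive[indeg == 1L | outdeg == 1L]
  if (length(triv)) return(triv[1L])
  alive[which.min(indeg * outdeg)]
}

#' Decompose a splice graph into candidate transcripts
#'
#' Iteratively removes vertices until only parallel s-t edges remain;
#' each final edge is expanded into a candidate transcript carrying its
#' inferred abundance (the final edge weight), its support vector, and
#' the bottleneck (minimum-weight) edge information along its path.
#'
#' @param g an augmented `splice_graph`.
#' @param supports numeric matrix of per-edge support vectors (rows
#'   aligned with `g$edges`), e.g. one element of [compute_supports()];
#'   `NULL` uses the edge weights themselves as a single-sample support.
#' @param paths list of phasing paths (`vseq`, `count`) in `g`'s vertex
#'   numbering, e.g. from [bridge_all()].
#' @return list of `candidate` transcripts; attribute `dropped_paths`
#'   counts phasing paths that could not be preserved.
#' @export
decompose_graph <- function(g, supports = NULL, paths = list()) {
  if (nrow(g$vs) == 0L) return(structure(list(), dropped_paths = 0L))
  st <- decomp_state(g, supports, paths)
  repeat {
    v <- next_vertex(st)
    if (is.na(v)) break
    decompose_vertex(st, v)
  }
  ids <- which(st$alive)
  out <- lapply(ids, function(id) {
    vseq <- st$chain[[id]]
    vseq <- vseq[vseq >= 1L & vseq <= st$n]
    starts <- g$vs$start[vseq]; ends <- g$vs$end[vseq]
    k <- length(vseq)
    brk <- if (k > 1L) which(starts[-1L] > ends[-k]) else integer(0)
    exon_from <- c(1L, brk + 1L); exon_to <- c(brk, k)
    exons <- cbind(start = starts[exon_from], end = ends[exon_to])
    introns <- if (length(brk))
      cbind(donor = ends[brk], acceptor = starts[brk + 1L])
    else empty_juncs()
    minw <- st$minw[id]; bsup <- st$bsup[[id]]
    if (!is.finite(minw)) { minw <- st$weight[id]; bsup <- st$sup[[id]] }
    structure(list(chrom = g$chrom, strand = g$strand,
                   exons = exons, introns = introns, vseq = vseq,
                   abundance = st$weight[id], support = st$sup[[id]],
                   bottleneck_weight = minw, bottleneck_support = bsup,
                   origin = g$sample_id),
              class = "candidate")
  })
  ord <- order(vapply(out, function(t) t$exons[1L, 1L], numeric(1)),
               vapply(out, function(t) t$exons[nrow(t$exons), 2L], numeric(1)))
  structure(out[ord], dropped_paths = st$dropped)
}

#' @export
print.candidate <- function(x, ...) {
  cat(sprintf("<candidate %s:%d-%d(%s) %d exons, abundance %.3g>\n",
              x$chrom, x$exons[1L, 1L], x$exons[nrow(x$exons), 2L],
              x$strand, nrow(x$exons), x$abundance))
  invisible(x)
}

## Intron-chain identity key; single-exon candidates get a span key that
## never matches a multi-exon chain.
chain_key <- function(chrom, strand, introns) {
  if (nrow(introns) == 0L) return(NA_character_)
  paste0(chrom, strand, ":", paste(introns[, 1L], introns[, 2L],
                                   sep = "-", collapse = ","))
}

candidate_key <- function(t) chain_key(t$chrom, t$strand, t$introns)
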