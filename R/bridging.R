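## Bridging: infer the unsequenced middle of a paired-end fragment as a
## path in a splice graph. Stage 1 bridges each fragment against its own
## sample's graph; only fragments that fail there are retried against the
## cluster's combined graph, whose richer junction set can restore
## junctions missed in one sample. Successfully rescued fragments are
## then used to refine the individual graph.

## Lookup structures for one graph, built once per bridging session.
graph_index <- function(g) {
  e <- g$edges
  real <- which(e$kind %in% c("junction", "adjacent"))
  key <- paste(e$from[real], e$to[real])
  ins <- split(real, e$to[real])
  list(edge_row = stats::setNames(real, key),
       in_edges = ins,
       width = g$vs$end - g$vs$start)
}

## Vertex containing 0-based position p, or NA.
vertex_at <- function(g, p) {
  i <- findInterval(p, g$vs$start)
  if (i == 0L || p >= g$vs$end[i]) return(NA_integer_)
  i
}

## Map one mate onto the graph: the ordered vertices its blocks cover.
## NULL when a block edge or junction of the read is absent from g.
read_chain <- function(r, g, gi = graph_index(g)) {
  j <- r$juncs
  k <- nrow(j)
  b_start <- c(r$start, if (k) j[, 2L])
  b_end <- c(if (k) j[, 1L], r$end)
  chain <- integer(0)
  for (bi in seq_along(b_start)) {
    v1 <- vertex_at(g, b_start[bi])
    v2 <- vertex_at(g, b_end[bi] - 1L)
    if (is.na(v1) || is.na(v2) || v1 > v2) return(NULL)
    if (v2 > v1) {
      seg <- v1:v2
      for (x in seg[-length(seg)]) {
        row <- gi$edge_row[paste(x, x + 1L)]
        if (is.na(row) || g$edges$kind[row] != "adjacent") return(NULL)
      }
    }
    if (bi > 1L) {
      u <- chain[length(chain)]
      if (g$vs$end[u] != j[bi - 1L, 1L] || g$vs$start[v1] != j[bi - 1L, 2L])
        return(NULL)
      row <- gi$edge_row[paste(u, v1)]
      if (is.na(row) || g$edges$kind[row] != "junction") return(NULL)
    }
    chain <- c(chain, v1:v2)
  }
  chain
}

## Bottleneck-optimal u -> v path over junction/adjacent edges:
## maximize the minimum edge weight, tie-break by fewer junctions, then
## by smaller summed vertex width. Dynamic programming in coordinate
## (= topological) order. Returns the vertex sequence or NULL.
bridge_path <- function(g, gi, u, v) {
  if (u == v) return(u)
  if (u > v) return(NULL)
  bott <- rep(-Inf, v); njunc <- rep(Inf, v); len <- rep(Inf, v)
  pred <- rep(NA_integer_, v)
  bott[u] <- Inf; njunc[u] <- 0; len[u] <- 0
  for (x in (u + 1L):v) {
    for (row in gi$in_edges[[as.character(x)]]) {
      y <- g$edges$from[row]
      if (y < u || bott[y] == -Inf) next
      cb <- min(bott[y], g$edges$weight[row])
      cj <- njunc[y] + (g$edges$kind[row] == "junction")
      cl <- len[y] + if (x == v) 0 else gi$width[x]
      if (cb > bott[x] ||
          (cb == bott[x] && (cj < njunc[x] ||
                             (cj == njunc[x] && cl < len[x])))) {
        bott[x] <- cb; njunc[x] <- cj; len[x] <- cl; pred[x] <- y
      }
    }
  }
  if (bott[v] == -Inf) return(NULL)
  path <- v
  while (path[1L] != u) path <- c(pred[path[1L]], path)
  path
}

## Merge two vertex chains that overlap (mates overlapping in the
## genome). NULL when they disagree on the shared stretch.
merge_chains <- function(c1, c2) {
  k <- match(c2[1L], c1)
  if (is.na(k)) return(NULL)
  m <- min(length(c1) - k + 1L, length(c2))
  if (!all(c1[k:(k + m - 1L)] == c2[seq_len(m)])) return(NULL)
  if (length(c2) > m) c(c1, c2[(m + 1L):length(c2)]) else c1
}

#' Bridge one fragment in a splice graph
#'
#' Maps both mates onto the graph and connects the last vertex touched
#' by the left mate to the first vertex touched by the right mate with a
#' bottleneck-optimal path (maximum minimum edge weight, then fewest
#' junctions, then least exonic length). Returns `NULL` (failure) when a
#' mate's junction chain is absent from the graph or no connecting path
#' exists — failure is an expected outcome, not an error.
#'
#' @param f a fragment (see [pair_fragments()]).
#' @param g an (augmented or not) `splice_graph`.
#' @param gi optional precomputed index from `graph_index(g)`.
#' @param max_span fragments spanning more than this many bases fail
#'   immediately (default 500 kb).
#' @return list with `vseq` (ordered vertex indices) and `paired`
#'   (logical: were both mates present), or `NULL` on failure.
#' @export
bridge_fragment <- function(f, g, gi = graph_index(g), max_span = 500000L) {
  c1 <- read_chain(f$r1, g, gi)
  if (is.null(c1)) return(NULL)
  if (is.null(f$r2)) return(list(vseq = c1, paired = FALSE))
  sp <- frag_span(f)
  if (sp[2L] - sp[1L] > max_span) return(NULL)
  c2 <- read_chain(f$r2, g, gi)
  if (is.null(c2)) return(NULL)
  u <- c1[length(c1)]; v <- c2[1L]
  if (f$r2$start < f$r1$end || v <= u) {
    vseq <- merge_chains(c1, c2)
    if (is.null(vseq)) return(NULL)
  } else {
    mid <- bridge_path(g, gi, u, v)
    if (is.null(mid)) return(NULL)
    vseq <- c(c1, mid[-c(1L, length(mid))], c2)
  }
  list(vseq = vseq, paired = TRUE)
}

## Compress a list of vertex sequences into distinct phasing paths with
## multiplicities.
compress_paths <- function(vseqs) {
  if (length(vseqs) == 0L) return(list())
  keys <- vapply(vseqs, paste, character(1), collapse = ",")
  tab <- table(keys)
  idx <- match(names(tab), keys)
  out <- lapply(seq_along(idx), function(i)
    list(vseq = vseqs[[idx[i]]], count = as.integer(tab[i])))
  out[order(vapply(out, function(p) p$vseq[1L], integer(1)),
            vapply(out, function(p) length(p$vseq), integer(1)))]
}

## Re-express a path of graph g as a read (span + junction chain), so it
## can be mapped into another graph covering the same locus.
path_to_read <- function(g, vseq) {
  juncs <- empty_juncs()
  if (length(vseq) > 1L) {
    d <- g$vs$end[vseq[-length(vseq)]]
    a <- g$vs$start[vseq[-1L]]
    spliced <- a > d
    if (any(spliced))
      juncs <- cbind(donor = d[spliced], acceptor = a[spliced])
  }
  new_read(g$vs$start[vseq[1L]], g$vs$end[vseq[length(vseq)]], juncs)
}

#' Two-stage bridging of a cluster's fragments
#'
#' Stage 1 bridges every fragment against its own member graph. Only
#' stage-1 failures proceed to stage 2 against the combined graph `gm`;
#' fragments bridged there are "rescued" and later drive graph
#' refinement. Fragments failing both stages contribute each mapped mate
#' chain as a short phasing path. The combined graph's phasing set
#' collects the stage-2 paths plus a coordinate translation of every
#' stage-1 path — translation is a fixed re-mapping of an already
#' bridged path, so a fragment bridged in its own sample is never
#' re-bridged against the combined graph.
#'
#' @param members list of member `splice_graph`s.
#' @param frags_by_member list of fragment lists aligned with `members`.
#' @param gm the combined `splice_graph` of the cluster.
#' @param max_span see [bridge_fragment()].
#' @return list with `paths` (per-member compressed phasing paths),
#'   `gm_paths`, `rescued` (per member: list of `frag` + `gm_vseq`),
#'   and `counters` (stage1/stage2/unbridged fragment counts).
#' @export
bridge_all <- function(members, frags_by_member, gm, max_span = 500000L) {
  gmi <- graph_index(gm)
  paths <- vector("list", length(members))
  rescued <- vector("list", length(members))
  gm_vseqs <- list()
  add_gm <- function(g, vseq) {
    ch <- read_chain(path_to_read(g, vseq), gm, gmi)
    if (!is.null(ch)) gm_vseqs[[length(gm_vseqs) + 1L]] <<- ch
  }
  n1 <- 0L; n2 <- 0L; nf <- 0L
  for (j in seq_along(members)) {
    g <- members[[j]]
    gi <- graph_index(g)
    vs <- list(); resc <- list()
    for (f in frags_by_member[[j]]) {
      b <- bridge_fragment(f, g, gi, max_span)
      if (!is.null(b)) {
        n1 <- n1 + 1L
        vs[[length(vs) + 1L]] <- b$vseq
        add_gm(g, b$vseq)
        next
      }
      bm <- bridge_fragment(f, gm, gmi, max_span)
      if (!is.null(bm) && bm$paired) {
        n2 <- n2 + 1L
        resc[[length(resc) + 1L]] <- list(frag = f, gm_vseq = bm$vseq)
        gm_vseqs[[length(gm_vseqs) + 1L]] <- bm$vseq
      } else {
        nf <- nf + 1L
        for (r in list(f$r1, f$r2)) {
          if (is.null(r)) next
          ch <- read_chain(r, g, gi)
          if (!is.null(ch)) {
            vs[[length(vs) + 1L]] <- ch
            add_gm(g, ch)
          }
        }
      }
    }
    paths[[j]] <- compress_paths(vs)
    rescued[[j]] <- resc
  }
  list(paths = paths, gm_paths = compress_paths(gm_vseqs),
       rescued = rescued,
       counters = c(stage1 = n1, stage2 = n2, unbridged = nf))
}

#' Refine an individual splice graph with rescued fragments
#'
#' Each fragment rescued on the combined graph contributes a pseudo-read
#' covering its previously unsequenced middle, following the junctions
#' of its combined-graph path. Rebuilding the graph from the original
#' fragments plus these pseudo-reads restores missed junctions
#' (weighted by the rescued fragment count), splits vertices at the new
#' splice positions, and corrects vertex coverages.
#'
#' @param g the member `splice_graph` to refine.
#' @param frags the member's original fragments.
#' @param rescued list of `list(frag, gm_vseq)` entries from
#'   [bridge_all()].
#' @param gm the combined graph the rescue paths live in.
#' @param min_junction_support,merge_gap as in [build_graph()].
#' @return the refined, augmented `splice_graph`.
#' @export
refine_graph <- function(g, frags, rescued, gm,
                         min_junction_support = 1L, merge_gap = 50L) {
  extra <- list()
  for (r in rescued) {
    f <- r$frag
    lo <- f$r1$end; hi <- f$r2$start
    if (hi <= lo) next
    vseq <- r$gm_vseq
    juncs <- empty_juncs()
    for (k in seq_len(length(vseq) - 1L)) {
      d <- gm$vs$end[vseq[k]]; a <- gm$vs$start[vseq[k + 1L]]
      if (a > d && d >= lo && a <= hi)   # junction inside the middle
        juncs <- rbind(juncs, c(d, a))
    }
    extra[[length(extra) + 1L]] <- new_read(lo, hi, juncs)
  }
  if (length(extra) == 0L && isTRUE(g$augmented)) return(g)
  refined <- build_graph(frags, chrom = g$chrom, strand = g$strand,
                         sample_id = g$sample_id,
                         min_junction_support = min_junction_support,
                         merge_gap = merge_gap, extra_reads = extra)
  augment_source_sink(refined)
}
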