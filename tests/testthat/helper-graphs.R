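# Constructors for toy reads, fragments and splice graphs, a seeded
# random graph/cluster generator, and small numeric utilities shared by
# the tests.

mk_juncs <- function(...) {
  v <- c(...)
  if (length(v) == 0L) return(metassembler:::empty_juncs())
  matrix(as.integer(v), ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("donor", "acceptor")))
}

mk_read <- function(start, end, juncs = mk_juncs()) {
  metassembler:::new_read(start, end, juncs)
}

mk_frag <- function(r1, r2 = NULL, qname = "q", sample_id = 1L,
                    chrom = "chr1", strand = "+") {
  list(qname = qname, sample_id = sample_id, chrom = chrom,
       strand = strand, r1 = r1, r2 = r2)
}

## One single-end fragment per read.
se_frags <- function(reads, sample_id = 1L, chrom = "chr1", strand = "+") {
  lapply(seq_along(reads), function(i)
    mk_frag(reads[[i]], qname = paste0("q", i), sample_id = sample_id,
            chrom = chrom, strand = strand))
}

graph_of <- function(reads, augment = TRUE, ...) {
  g <- build_graph(se_frags(reads), ...)
  if (augment) augment_source_sink(g) else g
}

## Build a splice graph object directly from explicit vertices/edges
## (for tests that need exact weights/topologies).
direct_graph <- function(vs, edges, chrom = "chr1", strand = "+",
                         sample_id = 1L, augment = TRUE) {
  g <- structure(list(chrom = chrom, strand = strand, sample_id = sample_id,
                      vs = vs, edges = edges, augmented = FALSE,
                      n_frags = 0L),
                 class = "splice_graph")
  if (augment) augment_source_sink(g) else g
}

## Random scaffold of disjoint, coordinate-sorted exon intervals; some
## pairs touch so adjacent edges can exist.
random_scaffold <- function(n_v = sample(4:15, 1L)) {
  cursor <- 1000L
  start <- integer(n_v); end <- integer(n_v)
  for (i in seq_len(n_v)) {
    w <- sample(50:300, 1L)
    start[i] <- cursor; end[i] <- cursor + w
    gap <- if (stats::runif(1) < 0.4) 0L else sample(100:1000, 1L)
    cursor <- end[i] + gap
  }
  cbind(start = start, end = end)
}

## A random splice graph over (a subset of) a scaffold. Touching
## vertices get adjacent edges with high probability; junction edges
## connect random non-touching forward pairs.
sample_graph <- function(scaffold, keep_p = 1, sample_id = 1L) {
  keep <- stats::runif(nrow(scaffold)) < keep_p
  if (!any(keep)) keep[sample(nrow(scaffold), 1L)] <- TRUE
  sc <- scaffold[keep, , drop = FALSE]
  n <- nrow(sc)
  vs <- data.frame(start = sc[, "start"], end = sc[, "end"],
                   weight = sample(1:20, n, replace = TRUE))
  from <- integer(0); to <- integer(0); kind <- character(0)
  for (i in seq_len(n - 1L)) {
    if (vs$end[i] == vs$start[i + 1L] && stats::runif(1) < 0.9) {
      from <- c(from, i); to <- c(to, i + 1L); kind <- c(kind, "adjacent")
    }
    for (j in (i + 1L):n) {
      if (vs$end[i] < vs$start[j] && stats::runif(1) < 2 / (j - i + 1)) {
        from <- c(from, i); to <- c(to, j); kind <- c(kind, "junction")
      }
    }
  }
  edges <- data.frame(from = from, to = to, kind = kind,
                      weight = as.numeric(sample(1:20, length(from),
                                                 replace = TRUE)),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  direct_graph(vs, edges, sample_id = sample_id)
}

random_splice_graph <- function(n_v = sample(4:15, 1L)) {
  sample_graph(random_scaffold(n_v))
}

## Random phasing paths: forward walks over the graph's real edges,
## consistent with the graph by construction.
random_phasing <- function(g, n_paths = sample(0:6, 1L)) {
  e <- g$edges[g$edges$kind %in% c("junction", "adjacent"), , drop = FALSE]
  if (nrow(e) == 0L || n_paths == 0L) return(list())
  outs <- split(e$to, e$from)
  paths <- list()
  for (k in seq_len(n_paths)) {
    v <- sample(nrow(g$vs), 1L)
    vseq <- v
    for (step in 1:4) {
      nxt <- outs[[as.character(vseq[length(vseq)])]]
      if (is.null(nxt)) break
      vseq <- c(vseq, nxt[sample.int(length(nxt), 1L)])
    }
    if (length(vseq) > 1L)
      paths[[length(paths) + 1L]] <- list(vseq = vseq,
                                          count = sample(1:5, 1L))
  }
  paths
}

## Is `sub` a contiguous subsequence of `seq`?
contains_contig <- function(seq, sub) {
  k <- length(sub); n <- length(seq)
  if (k > n) return(FALSE)
  for (i in seq_len(n - k + 1L))
    if (all(seq[i:(i + k - 1L)] == sub)) return(TRUE)
  FALSE
}

## The two-sample rescue scenario: sample 1 misses the junction between
## exons B and C (no read of sample 1 spans it), but has fragments whose
## mates flank it; sample 2 covers the junction. Stage 2 bridges the
## fragment on the combined graph and refinement restores the junction.
rescue_fixture <- function(n_straddle = 2L) {
  exA <- c(0L, 200L); exB <- c(1000L, 1200L); exC <- c(2000L, 2200L)
  jAB <- mk_juncs(exA[2], exB[1]); jBC <- mk_juncs(exB[2], exC[1])
  s1 <- c(rep(list(mk_read(100L, 1100L, jAB)), 3L),
          list(mk_read(2000L, 2200L)))
  frags1 <- se_frags(s1, sample_id = 1L)
  for (k in seq_len(n_straddle))
    frags1[[length(frags1) + 1L]] <-
      mk_frag(mk_read(1050L, 1150L), mk_read(2050L, 2150L),
              qname = sprintf("straddle%d", k), sample_id = 1L)
  s2 <- c(rep(list(mk_read(100L, 1100L, jAB)), 2L),
          rep(list(mk_read(1100L, 2100L, jBC)), 3L))
  frags2 <- se_frags(s2, sample_id = 2L)
  list(frags1 = frags1, frags2 = frags2)
}

## Synthetic feature rows: label-1 rows are shifted on a handful of
## abundance/support features.
make_rows <- function(n, seed = 1L, separation = 3) {
  set.seed(seed)
  sch <- feature_schema()$name
  x <- as.data.frame(matrix(stats::rnorm(n * length(sch)), n, length(sch)))
  names(x) <- sch
  label <- rep(0:1, length.out = n)
  for (cc in sch[c(1, 3, 5, 8, 11)]) x[[cc]] <- x[[cc]] + separation * label
  x$label <- label
  x
}

## Rank-based AUC (Mann-Whitney), independent of any modeling package.
auc_rank <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
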