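# Splice graph construction: exon partition by splice positions,
# coverage weights, junction/adjacent edges, source/sink augmentation.

test_that("reads over one junction give two exons and a weighted junction edge", {
  reads <- rep(list(mk_read(100L, 1200L, mk_juncs(150L, 1150L))), 3L)
  g <- graph_of(reads, augment = FALSE)
  expect_equal(g$vs$start, c(100L, 1150L))
  expect_equal(g$vs$end, c(150L, 1200L))
  expect_equal(g$vs$weight, c(3, 3))
  expect_equal(g$edges$kind, "junction")
  expect_equal(g$edges$weight, 3)
  expect_equal(splice_positions(g), c(150L, 1150L))
})

test_that("junction-free coverage gives a single vertex and no junction edges", {
  g <- graph_of(list(mk_read(0L, 120L), mk_read(80L, 200L)), augment = FALSE)
  expect_equal(nrow(g$vs), 1L)
  expect_equal(c(g$vs$start, g$vs$end), c(0L, 200L))
  expect_equal(nrow(g$edges), 0L)
  expect_equal(splice_positions(g), integer(0))
})

test_that("two junctions sharing a donor partition the genome at all splice positions", {
  reads <- c(rep(list(mk_read(100L, 1200L, mk_juncs(150L, 1150L))), 2L),
             rep(list(mk_read(100L, 2200L, mk_juncs(150L, 2150L))), 3L))
  g <- graph_of(reads, augment = FALSE)
  expect_equal(nrow(g$vs), 3L)
  expect_equal(g$vs$start, c(100L, 1150L, 2150L))
  expect_equal(sum(g$edges$kind == "junction"), 2L)
  expect_equal(splice_positions(g), c(150L, 1150L, 2150L))
  ## weights follow the spanning-read counts
  jw <- graph_junctions(g)
  expect_equal(jw[jw[, "acceptor"] == 1150L, "weight"][[1]], 2)
  expect_equal(jw[jw[, "acceptor"] == 2150L, "weight"][[1]], 3)
})

test_that("splice positions inside covered regions split vertices with adjacent edges", {
  ## junction (150, 300) lands inside the [100, 400) coverage of other reads
  reads <- c(rep(list(mk_read(100L, 400L)), 4L),
             list(mk_read(120L, 330L, mk_juncs(150L, 300L))))
  g <- graph_of(reads, augment = FALSE)
  expect_equal(g$vs$start, c(100L, 150L, 300L))
  expect_equal(g$vs$end, c(150L, 300L, 400L))
  adj <- g$edges[g$edges$kind == "adjacent", ]
  expect_equal(nrow(adj), 2L)
  expect_equal(adj$weight, c(4, 4))   # reads spanning each boundary
})

test_that("source/sink weights equal the summed boundary-vertex edge weights", {
  ## chain: a --(junction w=4)--> b
  reads <- rep(list(mk_read(0L, 300L, mk_juncs(100L, 200L))), 4L)
  g <- graph_of(reads)
  e <- g$edges
  expect_equal(e$weight[e$kind == "source"], 4)
  expect_equal(e$weight[e$kind == "sink"], 4)
  ## starting vertex with out-edges 2 and 3 gets w(s,u) = 5
  reads <- c(rep(list(mk_read(50L, 250L, mk_juncs(100L, 200L))), 2L),
             rep(list(mk_read(50L, 450L, mk_juncs(100L, 400L))), 3L))
  g <- graph_of(reads)
  src <- g$edges[g$edges$kind == "source", ]
  expect_equal(src$weight[src$to == 1L], 5)
  ## isolated single vertex: boundary edges take the vertex coverage
  g <- graph_of(list(mk_read(0L, 100L), mk_read(0L, 100L)))
  expect_equal(g$edges$weight, c(2, 2))
  expect_equal(g$edges$kind, c("source", "sink"))
})

test_that("graph construction is deterministic under fragment reordering", {
  set.seed(3)
  reads <- c(rep(list(mk_read(100L, 1200L, mk_juncs(150L, 1150L))), 3L),
             rep(list(mk_read(50L, 160L)), 2L),
             list(mk_read(1100L, 1300L)))
  g1 <- graph_of(reads)
  g2 <- graph_of(reads[sample(length(reads))])
  expect_equal(g1$vs, g2$vs)
  expect_equal(g1$edges, g2$edges)
})

test_that("internal coverage gaps split vertices only at the merge gap", {
  reads <- list(mk_read(0L, 100L), mk_read(120L, 220L))   # 20 bp hole
  g <- graph_of(reads, augment = FALSE, merge_gap = 50L)
  expect_equal(nrow(g$vs), 1L)                             # hole bridged
  g <- graph_of(reads, augment = FALSE, merge_gap = 10L)
  expect_equal(nrow(g$vs), 2L)                             # hole splits
  expect_equal(sum(g$edges$kind == "adjacent"), 0L)
})

test_that("combined graph contains every member junction with pooled weight", {
  fr1 <- se_frags(rep(list(mk_read(0L, 300L, mk_juncs(100L, 200L))), 2L),
                  sample_id = 1L)
  fr2 <- se_frags(c(rep(list(mk_read(0L, 300L, mk_juncs(100L, 200L))), 3L),
                    list(mk_read(250L, 550L, mk_juncs(300L, 500L)))),
                  sample_id = 2L)
  g1 <- augment_source_sink(build_graph(fr1, sample_id = 1L))
  g2 <- augment_source_sink(build_graph(fr2, sample_id = 2L))
  gm <- build_combined(list(fr1, fr2))
  jm <- graph_junctions(gm)
  for (g in list(g1, g2)) {
    jg <- graph_junctions(g)
    for (k in seq_len(nrow(jg))) {
      hit <- which(jm[, "donor"] == jg[k, "donor"] &
                   jm[, "acceptor"] == jg[k, "acceptor"])
      expect_length(hit, 1L)
      expect_gte(jm[hit, "weight"], jg[k, "weight"])
    }
  }
  expect_equal(jm[jm[, "donor"] == 100L, "weight"][[1]], 5)  # 2 + 3 pooled
})
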