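# Bridging paired-end fragments through splice graphs, two-stage
# rescue on the combined graph, and graph refinement.

test_that("a unique connecting path bridges the mates", {
  ## chain v1 -j- v2 -j- v3
  reads <- rep(list(mk_read(0L, 900L, mk_juncs(100L, 400L, 500L, 800L))), 2L)
  g <- graph_of(reads)
  f <- mk_frag(mk_read(0L, 80L), mk_read(820L, 900L))
  b <- bridge_fragment(f, g)
  expect_equal(b$vseq, 1:3)
  expect_true(b$paired)
})

test_that("bridging fails without a connecting path or a matching junction chain", {
  ## two disconnected exons
  g <- graph_of(list(mk_read(0L, 100L), mk_read(500L, 600L)))
  f <- mk_frag(mk_read(0L, 50L), mk_read(550L, 600L))
  expect_null(bridge_fragment(f, g))
  ## mate carries a junction the graph lacks
  g2 <- graph_of(rep(list(mk_read(0L, 900L, mk_juncs(100L, 400L))), 2L))
  f2 <- mk_frag(mk_read(0L, 450L, mk_juncs(100L, 420L)), mk_read(800L, 900L))
  expect_null(bridge_fragment(f2, g2))
})

test_that("the bottleneck objective picks the heavier branch of a diamond", {
  vs <- data.frame(start = c(0L, 200L, 200L, 600L),
                   end = c(100L, 300L, 300L, 700L), weight = c(10, 9, 1, 10))
  vs$start[3] <- 400L; vs$end[3] <- 500L
  edges <- data.frame(from = c(1L, 1L, 2L, 3L), to = c(2L, 3L, 4L, 4L),
                      kind = rep("junction", 4L), weight = c(9, 1, 5, 5),
                      stringsAsFactors = FALSE)
  g <- direct_graph(vs, edges)
  f <- mk_frag(mk_read(0L, 100L), mk_read(600L, 700L))
  expect_equal(bridge_fragment(f, g)$vseq, c(1L, 2L, 4L))
  ## flip the weights: the other branch wins
  edges2 <- edges; edges2$weight <- c(1, 9, 5, 5)
  g2 <- direct_graph(vs, edges2)
  expect_equal(bridge_fragment(f, g2)$vseq, c(1L, 3L, 4L))
})

test_that("overlapping mates merge consistently and conflicts fail", {
  reads <- rep(list(mk_read(0L, 600L, mk_juncs(200L, 400L))), 2L)
  g <- graph_of(reads)
  f <- mk_frag(mk_read(0L, 450L, mk_juncs(200L, 400L)),
               mk_read(150L, 600L, mk_juncs(200L, 400L)))
  expect_equal(bridge_fragment(f, g)$vseq, 1:2)
})

test_that("fragments wider than the bridging span fail fast", {
  g <- graph_of(rep(list(mk_read(0L, 900L, mk_juncs(100L, 800L))), 2L))
  f <- mk_frag(mk_read(0L, 80L), mk_read(820L, 900L))
  expect_null(bridge_fragment(f, g, max_span = 500L))
  expect_false(is.null(bridge_fragment(f, g)))
})

test_that("stage-2 bridging on the combined graph rescues and refinement restores the junction", {
  fx <- rescue_fixture(n_straddle = 2L)
  g1 <- augment_source_sink(build_graph(fx$frags1, sample_id = 1L))
  g2 <- augment_source_sink(build_graph(fx$frags2, sample_id = 2L))
  gm <- build_combined(list(fx$frags1, fx$frags2))
  ## the junction is absent from sample 1 but present in the combined graph
  expect_false(1200L %in% graph_junctions(g1)[, "donor"])
  expect_true(1200L %in% graph_junctions(gm)[, "donor"])
  br <- bridge_all(list(g1, g2), list(fx$frags1, fx$frags2), gm)
  expect_equal(unname(br$counters["stage2"]), 2L)
  expect_length(br$rescued[[1]], 2L)
  refined <- refine_graph(g1, fx$frags1, br$rescued[[1]], gm)
  jr <- graph_junctions(refined)
  hit <- jr[, "donor"] == 1200L & jr[, "acceptor"] == 2000L
  expect_true(any(hit))
  expect_equal(jr[hit, "weight"][[1]], 2)   # one per rescued fragment
  ## the transcript crossing the junction is assembled for sample 1
  br2 <- bridge_all(list(refined, g2), list(fx$frags1, fx$frags2), gm)
  cands <- decompose_graph(refined, paths = br2$paths[[1]])
  keys <- vapply(cands, metassembler:::candidate_key, character(1))
  expect_true(metassembler:::chain_key("chr1", "+",
                                       rbind(c(200L, 1000L), c(1200L, 2000L)))
              %in% keys)
})

test_that("no fragment bridged at stage 1 is retried on the combined graph", {
  fx <- rescue_fixture()
  g1 <- augment_source_sink(build_graph(fx$frags1, sample_id = 1L))
  g2 <- augment_source_sink(build_graph(fx$frags2, sample_id = 2L))
  gm <- build_combined(list(fx$frags1, fx$frags2))
  br <- bridge_all(list(g1, g2), list(fx$frags1, fx$frags2), gm)
  n_frag <- length(fx$frags1) + length(fx$frags2)
  expect_equal(unname(sum(br$counters)), n_frag)
  ## every stage-1 bridged fragment is accounted for in member paths
  expect_equal(sum(vapply(br$paths[[1]], `[[`, 1L, "count")) +
               sum(vapply(br$paths[[2]], `[[`, 1L, "count")),
               unname(br$counters["stage1"]))
})

test_that("returned phasing paths are connected and junction-consistent", {
  set.seed(11)
  for (rep in 1:20) {
    g <- random_splice_graph()
    gi <- metassembler:::graph_index(g)
    n <- nrow(g$vs)
    v1 <- sample(n, 1L)
    v2 <- sample(n, 1L)
    if (v1 > v2) { tmp <- v1; v1 <- v2; v2 <- tmp }
    f <- mk_frag(mk_read(g$vs$start[v1], g$vs$end[v1]),
                 if (v2 > v1) mk_read(g$vs$start[v2], g$vs$end[v2]))
    b <- bridge_fragment(f, g, gi)
    if (is.null(b)) next
    vs <- b$vseq
    for (k in seq_len(length(vs) - 1L))
      expect_true(paste(vs[k], vs[k + 1L]) %in% names(gi$edge_row))
    expect_equal(vs[1L], v1)
    if (!is.null(f$r2)) expect_equal(vs[length(vs)], v2)
  }
})
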