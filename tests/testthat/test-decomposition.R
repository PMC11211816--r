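# Phase-preserving decomposition: trivial and non-trivial vertices,
# isolated-edge resolution by supports, weight conservation.

test_that("a chain graph decomposes into its single transcript", {
  g <- graph_of(rep(list(mk_read(0L, 900L, mk_juncs(100L, 400L, 500L, 800L))), 3L))
  cands <- decompose_graph(g)
  expect_length(cands, 1L)
  expect_equal(unname(cands[[1]]$introns),
               rbind(c(100L, 400L), c(500L, 800L)))
  expect_equal(cands[[1]]$abundance, 3)
})

test_that("trivial decomposition allocates the in-weight proportionally to out-weights", {
  ## u -> v (w=5), v -> a (w=2), v -> b (w=3)
  vs <- data.frame(start = c(0L, 200L, 400L, 600L),
                   end = c(100L, 300L, 500L, 700L), weight = c(5, 5, 2, 3))
  ed <- data.frame(from = c(1L, 2L, 2L), to = c(2L, 3L, 4L),
                   kind = "junction", weight = c(5, 2, 3),
                   stringsAsFactors = FALSE)
  g <- direct_graph(vs, ed)
  cands <- decompose_graph(g)
  expect_length(cands, 2L)
  ab <- sort(vapply(cands, function(t) t$abundance, numeric(1)))
  expect_equal(ab, c(2, 3))
})

test_that("phased 2x2 vertices split into exactly the phased pairings", {
  ## diamond through a shared middle exon: in-edges e1,e2; out e3,e4
  vs <- data.frame(start = c(0L, 200L, 400L, 600L, 800L),
                   end = c(100L, 300L, 500L, 700L, 900L),
                   weight = c(3, 2, 5, 3, 2))
  ed <- data.frame(from = c(1L, 2L, 3L, 3L), to = c(3L, 3L, 4L, 5L),
                   kind = "junction", weight = c(3, 2, 3, 2),
                   stringsAsFactors = FALSE)
  g <- direct_graph(vs, ed)
  paths <- list(list(vseq = c(1L, 3L, 4L), count = 3L),
                list(vseq = c(2L, 3L, 5L), count = 2L))
  cands <- decompose_graph(g, paths = paths)
  expect_length(cands, 2L)
  seqs <- lapply(cands, `[[`, "vseq")
  expect_true(any(vapply(seqs, identical, TRUE, c(1L, 3L, 4L))))
  expect_true(any(vapply(seqs, identical, TRUE, c(2L, 3L, 5L))))
  ab <- vapply(cands, function(t) t$abundance, numeric(1))
  expect_equal(sort(ab), c(2, 3))
})

test_that("isolated edges link to the argmax-support counterpart", {
  sup <- list(`1` = c(1, 0, 0), `4` = c(1, 0, 0), `5` = c(0, 6, 0),
              `6` = c(1, 0, 0))
  links <- matrix(integer(0), ncol = 2L)
  ## in-edge 1 is isolated; outs 4,5,6 have summed composed supports 1,0,1
  out <- resolve_isolated(links, ins = 1L, outs = c(4L, 5L, 6L), sup = sup)
  expect_equal(out[1, ], c(1L, 4L))   # ties (4,6) -> first in edge order
  sup$`1` <- c(1, 6, 0)               # now 5 (summed min 6) dominates
  out <- resolve_isolated(links, ins = 1L, outs = c(4L, 5L, 6L), sup = sup)
  expect_equal(out[1, ], c(1L, 5L))
  ## single candidate on the opposite side
  out <- resolve_isolated(links, ins = 1L, outs = 4L, sup = sup)
  expect_equal(out[1, ], c(1L, 4L))
  ## all-zero supports: first candidate by edge order
  sup0 <- list(`1` = c(0, 0), `4` = c(0, 0), `5` = c(0, 0))
  out <- resolve_isolated(links, ins = 1L, outs = c(4L, 5L), sup = sup0)
  expect_equal(out[1, ], c(1L, 4L))
})

test_that("unphased branches follow the cross-sample supports", {
  ## 2-in/2-out vertex, no phasing; supports pair e1-e3 and e2-e4
  vs <- data.frame(start = c(0L, 200L, 400L, 600L, 800L),
                   end = c(100L, 300L, 500L, 700L, 900L),
                   weight = c(3, 2, 5, 3, 2))
  ed <- data.frame(from = c(1L, 2L, 3L, 3L), to = c(3L, 3L, 4L, 5L),
                   kind = "junction", weight = c(3, 2, 3, 2),
                   stringsAsFactors = FALSE)
  g <- direct_graph(vs, ed)
  ## rows follow g$edges (after augmentation: sources first); boundary
  ## edges get uniform high support so composition keeps junction values
  sup <- matrix(9, nrow = nrow(g$edges), ncol = 3L)
  real <- which(g$edges$kind == "junction")
  sup[real[1], ] <- c(9, 0, 1)   # e1 = (1,3)
  sup[real[2], ] <- c(0, 7, 0)   # e2 = (2,3)
  sup[real[3], ] <- c(8, 0, 0)   # e3 = (3,4): pairs with e1
  sup[real[4], ] <- c(0, 5, 2)   # e4 = (3,5): pairs with e2
  cands <- decompose_graph(g, supports = sup)
  seqs <- lapply(cands, `[[`, "vseq")
  expect_true(any(vapply(seqs, identical, TRUE, c(1L, 3L, 4L))))
  expect_true(any(vapply(seqs, identical, TRUE, c(2L, 3L, 5L))))
  expect_false(any(vapply(seqs, identical, TRUE, c(1L, 3L, 5L))))
})

test_that("random graphs: phase preservation, junction coverage, conservation", {
  set.seed(202)
  for (rep in 1:60) {
    g <- random_splice_graph()
    paths <- random_phasing(g)
    cands <- decompose_graph(g, paths = paths)
    seqs <- lapply(cands, `[[`, "vseq")
    ## every phasing path survives contiguously in some transcript
    for (p in paths)
      expect_true(any(vapply(seqs, contains_contig, TRUE, sub = p$vseq)),
                  label = sprintf("phasing path preserved (rep %d)", rep))
    ## every junction edge is covered by at least one transcript
    ej <- g$edges[g$edges$kind == "junction", , drop = FALSE]
    for (k in seq_len(nrow(ej)))
      expect_true(any(vapply(seqs, contains_contig, TRUE,
                             sub = c(ej$from[k], ej$to[k]))))
    ## total abundance equals total source outflow
    total_src <- sum(g$edges$weight[g$edges$kind == "source"])
    total_ab <- sum(vapply(cands, function(t) t$abundance, numeric(1)))
    expect_equal(total_ab, total_src, tolerance = 1e-6)
  }
})

test_that("transcript supports never exceed any constituent edge's support", {
  set.seed(303)
  for (rep in 1:20) {
    scaffold <- random_scaffold(sample(6:12, 1L))
    members <- lapply(1:3, function(j) sample_graph(scaffold, 0.8, j))
    g <- members[[1L]]
    sup <- compute_supports(list(g), members)[[1L]]
    ekey <- stats::setNames(seq_len(nrow(g$edges)),
                            paste(g$edges$from, g$edges$to))
    cands <- decompose_graph(g, supports = sup, paths = random_phasing(g))
    for (t in cands) {
      vs <- c(0L, t$vseq, nrow(g$vs) + 1L)
      for (k in seq_len(length(vs) - 1L)) {
        row <- ekey[paste(vs[k], vs[k + 1L])]
        if (is.na(row)) next
        expect_true(all(t$support <= sup[row, ] + 1e-9))
      }
    }
  }
})
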