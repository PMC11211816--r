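# The 50-feature characterization: a fully hand-computed golden vector,
# scaling behavior under read duplication, and label assignment.

## Two-sample cluster, one spliced transcript: sample 1 sees the
## junction 3 times, sample 2 twice; the combined graph pools both.
golden_cluster <- function(mult = 1L) {
  r <- mk_read(50L, 250L, mk_juncs(100L, 200L))
  fr1 <- se_frags(rep(list(r), 3L * mult), sample_id = 1L)
  fr2 <- se_frags(rep(list(r), 2L * mult), sample_id = 2L)
  g1 <- augment_source_sink(build_graph(fr1, sample_id = 1L))
  g2 <- augment_source_sink(build_graph(fr2, sample_id = 2L))
  gm <- build_combined(list(fr1, fr2))
  sup <- compute_supports(list(g1, g2, gm), list(g1, g2))
  list(g1 = g1, g2 = g2, gm = gm, sup = sup,
       fr1 = fr1, fr2 = fr2)
}

test_that("the golden two-sample locus matches the hand-computed 50-vector", {
  cl <- golden_cluster()
  cands <- decompose_graph(cl$g1, cl$sup[[1]])
  expect_length(cands, 1L)
  t <- cands[[1]]
  fv <- compute_features(t, cl$g1, cl$gm, cl$sup[[1]], n_samples = 2L,
                         locus_reads = 3L, other_abundance = 5,
                         in_both = TRUE)
  ## hand computation: g1 chain [50,100) -(w3)-> [200,250); supports
  ## from (g1, g2) are (3, 2) for the junction and both boundaries;
  ## the combined graph carries the pooled weight 5
  expected <- c(
    abundance = 3, log_abundance = log1p(3),
    support_samples = 2, support_frac = 1, support_total = 5,
    support_mean = 2.5, support_max = 3,
    bottleneck_weight = 3, bottleneck_support_samples = 2,
    bottleneck_support_total = 5, rel_abundance = 1,
    locus_reads_log = log1p(3), path_cov_mean = 3, path_cov_min = 3,
    n_vertices_graph = 2, n_junctions_graph = 1,
    n_vertices_combined = 2, n_junctions_combined = 1,
    n_samples = 2, n_exons = 2, n_introns = 1,
    transcript_length = 100, genomic_span_log = log1p(200),
    from_combined = 0, in_both_graphs = 1, other_side_abundance = 5,
    start_edge_weight = 3, end_edge_weight = 3,
    start_support_samples = 2, start_support_total = 5,
    end_support_samples = 2, end_support_total = 5,
    start_rel = 1, end_rel = 1,
    first_exon_length = 50, last_exon_length = 50,
    start_vertex_cov = 3, end_vertex_cov = 3,
    n_starting_edges = 1, n_ending_edges = 1,
    n_retained_introns = 0, retained_frac = 0,
    retention_comp_max = 0, retention_comp_mean = 0,
    junction_weight_min = 3, junction_weight_mean = 3,
    junction_support_min_samples = 2, junction_support_mean_total = 5,
    intron_length_max = 100, intron_length_min = 100)
  expect_equal(fv, expected)
})

test_that("retained introns are detected with their coverage competitiveness", {
  ## 5 reads of continuous coverage, 2 spliced reads: the unspliced
  ## transcript retains the intron (100, 200)
  reads <- c(rep(list(mk_read(0L, 300L)), 5L),
             rep(list(mk_read(0L, 300L, mk_juncs(100L, 200L))), 2L))
  g <- graph_of(reads)
  paths <- list(list(vseq = c(1L, 2L, 3L), count = 5L),
                list(vseq = c(1L, 3L), count = 2L))
  cands <- decompose_graph(g, paths = paths)
  seqs <- lapply(cands, `[[`, "vseq")
  retained <- cands[[which(vapply(seqs, identical, TRUE, c(1L, 2L, 3L)))]]
  fv <- compute_features(retained, g, g)
  expect_equal(unname(fv["n_exons"]), 1)
  expect_equal(unname(fv["n_retained_introns"]), 1)
  expect_equal(unname(fv["retained_frac"]), 1)
  ## intronic vertex coverage 5 vs junction weight 2
  expect_equal(unname(fv["retention_comp_max"]), 5 / 2)
  spliced <- cands[[which(vapply(seqs, identical, TRUE, c(1L, 3L)))]]
  fv2 <- compute_features(spliced, g, g)
  expect_equal(unname(fv2["n_retained_introns"]), 0)
})

test_that("duplicating every read doubles scale features and fixes invariant ones", {
  run <- function(mult) {
    cl <- golden_cluster(mult)
    ## a second isoform in sample 1 adds branching so the test is not
    ## entirely trivial
    t <- decompose_graph(cl$g1, cl$sup[[1]])[[1]]
    compute_features(t, cl$g1, cl$gm, cl$sup[[1]], n_samples = 2L,
                     locus_reads = 3L * mult, other_abundance = 5 * mult,
                     in_both = TRUE)
  }
  f1 <- run(1L); f2 <- run(2L)
  sch <- feature_schema()
  for (k in seq_len(nrow(sch))) {
    nm <- sch$name[k]
    if (sch$behavior[k] == "scale")
      expect_equal(unname(f2[nm]), 2 * unname(f1[nm]), label = nm)
    else if (sch$behavior[k] == "invariant")
      expect_equal(unname(f2[nm]), unname(f1[nm]), label = nm)
  }
})

test_that("labels are exact intron-chain matches, single-exon rows excluded", {
  feats <- data.frame(
    chain_key = c("chr1+:100-200", "chr1+:100-201", NA),
    stringsAsFactors = FALSE)
  out <- label_candidates(feats, c("chr1+:100-200", "chr2-:5-9"))
  expect_equal(nrow(out), 2L)
  expect_equal(out$label, c(1L, 0L))
})
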