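# Random-forest scoring, meta-transcript aggregation and GTF emission.

test_that("separable rows score with high held-out AUC; permuted labels do not", {
  rows <- make_rows(800, seed = 2L)
  train <- rows[1:400, ]; test <- rows[401:800, ]
  model <- train_model(train, seed = 7L)
  auc <- auc_rank(score_candidates(test, model), test$label)
  expect_gt(auc, 0.95)
  null_rows <- rows
  set.seed(3); null_rows$label <- sample(null_rows$label)
  null_model <- train_model(null_rows[1:400, ], seed = 7L)
  null_auc <- auc_rank(score_candidates(null_rows[401:800, ], null_model),
                       null_rows$label[401:800])
  expect_gt(null_auc, 0.35)
  expect_lt(null_auc, 0.65)
})

test_that("the forest is configured as 100 trees of depth at most 20", {
  model <- train_model(make_rows(120), seed = 5L)
  expect_equal(model$forest$num.trees, 100L)
  expect_equal(model$num_trees, 100L)
  expect_equal(model$max_depth, 20L)
  expect_s3_class(model, "scoring_model")
})

test_that("training and scoring are deterministic for a fixed seed", {
  rows <- make_rows(150, seed = 4L)
  m1 <- train_model(rows, seed = 11L)
  m2 <- train_model(rows, seed = 11L)
  expect_identical(m1$train_digest, m2$train_digest)
  expect_identical(score_candidates(rows, m1), score_candidates(rows, m2))
  p <- score_candidates(rows, m1)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(score_candidates(rows[0, ], m1), numeric(0))
})

test_that("degenerate training sets are rejected with clear errors", {
  rows <- make_rows(50)
  rows$label <- 1L
  expect_error(train_model(rows), "single class")
  rows2 <- make_rows(50)
  rows2$abundance[1] <- NaN
  expect_error(train_model(rows2), "non-finite")
  rows3 <- make_rows(50)[, -1]
  expect_error(train_model(rows3), "missing feature")
})

test_that("models persist with a schema sidecar and refuse mismatched schemas", {
  model <- train_model(make_rows(80), seed = 1L)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  rows <- make_rows(30, seed = 9L)
  expect_identical(score_candidates(rows, model), score_candidates(rows, m2))
  m2$schema_hash <- "tampered"
  expect_error(score_candidates(rows, m2), "schema")
})

mk_cand <- function(introns, exons, abundance, origin = 1L,
                    chrom = "chr1", strand = "+") {
  structure(list(chrom = chrom, strand = strand, exons = exons,
                 introns = introns, vseq = integer(0),
                 abundance = abundance, support = abundance,
                 bottleneck_weight = abundance,
                 bottleneck_support = abundance, origin = origin),
            class = "candidate")
}

test_that("identical intron chains aggregate with averaged scores", {
  introns <- rbind(c(100L, 200L))
  c1 <- mk_cand(introns, rbind(c(0L, 100L), c(200L, 300L)), 4, origin = 3L)
  c2 <- mk_cand(introns, rbind(c(10L, 100L), c(200L, 280L)), 9,
                origin = NA_integer_)           # from the combined graph
  c3 <- mk_cand(rbind(c(500L, 600L)), rbind(c(400L, 500L), c(600L, 700L)), 1)
  metas <- aggregate_meta(list(c1, c2, c3), c(0.4, 0.6, 0.8))
  expect_length(metas, 2L)
  m <- metas[[1L]]
  expect_equal(m$score, 0.5)
  expect_equal(m$members, 2L)
  expect_equal(m$exons[1L, 1L], 10L)   # representative: higher abundance
  expect_setequal(m$member_origins, c("3", "combined"))
  expect_equal(metas[[2L]]$score, 0.8)
  ## aggregating an aggregated set is the identity on chains and scores
  again <- aggregate_meta(metas, vapply(metas, `[[`, 0, "score"))
  expect_equal(vapply(again, `[[`, 0, "score"),
               vapply(metas, `[[`, 0, "score"))
  expect_length(again, 2L)
})

test_that("the score filter is inclusive at the threshold and monotone", {
  introns <- lapply(1:3, function(i) rbind(c(i * 100L, i * 100L + 50L)))
  cands <- lapply(1:3, function(i)
    mk_cand(introns[[i]], rbind(c(i * 100L - 50L, i * 100L),
                                c(i * 100L + 50L, i * 100L + 99L)), i))
  metas <- aggregate_meta(cands, c(0.49, 0.5, 0.9))
  expect_length(filter_and_emit(metas, 0.5), 2L)
  expect_length(filter_and_emit(metas, 0), 3L)
  counts <- vapply(seq(0, 1, by = 0.1), function(th)
    length(filter_and_emit(metas, th)), integer(1))
  expect_true(all(diff(counts) <= 0L))
  ## GTF emission carries score and samples attributes, 1-based coords
  gtf <- tempfile(fileext = ".gtf")
  filter_and_emit(metas, 0.5, path = gtf)
  lines <- readLines(gtf)
  expect_equal(sum(grepl("\ttranscript\t", lines)), 2L)
  expect_true(all(grepl('score "0\\.', lines)))
  expect_true(any(grepl('samples "1"', lines)))
  first_exon <- strsplit(lines[grepl("\texon\t", lines)][1], "\t")[[1]]
  expect_equal(as.integer(first_exon[4]), 151L)  # 0-based 150 -> 1-based 151
})
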