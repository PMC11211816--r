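## Random-forest scoring of candidate transcripts and aggregation of
## identical intron chains into meta-transcripts.

#' Train the transcript scoring model
#'
#' Fits a probability random forest (100 trees, maximum depth 20) on
#' labeled feature rows. The model records the feature schema hash, the
#' seed and a digest of the training data, so scoring is reproducible
#' and schema mismatches are caught at prediction time.
#'
#' @param rows data.frame containing the 50 feature columns (see
#'   [feature_schema()]) and a `label` column with both classes present.
#' @param seed integer seed for the forest.
#' @param num_trees,max_depth forest configuration (defaults 100 and 20).
#' @return a `scoring_model` object.
#' @export
train_model <- function(rows, seed = 1L, num_trees = 100L, max_depth = 20L) {
  sch <- feature_schema()$name
  missing <- setdiff(sch, names(rows))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  if (!"label" %in% names(rows)) stop("rows must have a `label` column")
  y <- factor(rows$label, levels = c(0L, 1L))
  if (length(unique(rows$label)) < 2L)
    stop("training set contains a single class (all labels ",
         rows$label[1L], "); cannot train a classifier")
  x <- rows[, sch, drop = FALSE]
  if (any(!vapply(x, function(col) all(is.finite(col)), logical(1))))
    stop("non-finite feature values in training rows")
  dat <- cbind(x, .label = y)
  forest <- ranger::ranger(
    dependent.variable.name = ".label", data = dat,
    num.trees = num_trees, max.depth = max_depth,
    probability = TRUE, seed = seed,
    respect.unordered.factors = "order", verbose = FALSE)
  structure(list(forest = forest,
                 num_trees = num_trees, max_depth = max_depth,
                 seed = seed,
                 schema_hash = feature_schema_hash(),
                 train_digest = digest::digest(list(x, y), algo = "md5"),
                 n_train = nrow(rows)),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat(sprintf("<scoring_model: %d trees, depth <= %d, %d training rows, seed %d>\n",
              x$num_trees, x$max_depth, x$n_train, x$seed))
  invisible(x)
}

#' Score candidate feature rows
#'
#' @param rows data.frame with the 50 feature columns.
#' @param model a `scoring_model` from [train_model()]; its schema hash
#'   must match the current feature schema.
#' @return numeric vector of probabilities in \[0, 1\], one per row.
#' @export
score_candidates <- function(rows, model) {
  stopifnot(inherits(model, "scoring_model"))
  if (!identical(model$schema_hash, feature_schema_hash()))
    stop("model feature schema does not match this feature extractor")
  if (nrow(rows) == 0L) return(numeric(0))
  x <- rows[, feature_schema()$name, drop = FALSE]
  p <- predict(model$forest, data = x, verbose = FALSE)$predictions
  unname(p[, "1"])
}

#' Save / load a scoring model
#'
#' The model is serialized alongside a JSON sidecar recording the
#' schema hash, seed and training digest.
#'
#' @param model a `scoring_model`.
#' @param path destination file (`.rds`); the sidecar is `path` +
#'   `.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "scoring_model"))
  saveRDS(model, path)
  meta <- model[c("num_trees", "max_depth", "seed", "schema_hash",
                  "train_digest", "n_train")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "scoring_model"))
  model
}

#' Aggregate scored candidates into meta-transcripts
#'
#' Candidates sharing a chromosome, strand and intron chain are
#' identical by definition and collapse into one meta-transcript whose
#' score is the arithmetic mean of the member scores. The representative
#' exon chain is taken from the most abundant member (terminal exon ends
#' differ between identical chains). Single-exon candidates group by
#' their exact span instead.
#'
#' @param cands list of `candidate` objects.
#' @param scores numeric vector parallel to `cands`.
#' @return list of `meta_transcript` objects, coordinate-sorted.
#' @export
aggregate_meta <- function(cands, scores) {
  stopifnot(length(cands) == length(scores))
  if (length(cands) == 0L) return(list())
  keys <- vapply(cands, function(t) {
    k <- candidate_key(t)
    if (is.na(k))
      k <- paste0("SE:", t$chrom, t$strand, ":", t$exons[1L, 1L], "-",
                  t$exons[1L, 2L])
    k
  }, character(1))
  groups <- split(seq_along(cands), keys)
  metas <- lapply(groups, function(idx) {
    ab <- vapply(cands[idx], function(t) t$abundance, numeric(1))
    rep_t <- cands[[idx[which.max(ab)]]]
    structure(list(chrom = rep_t$chrom, strand = rep_t$strand,
                   exons = rep_t$exons, introns = rep_t$introns,
                   score = mean(scores[idx]),
                   abundance = sum(ab),
                   members = length(idx),
                   member_origins = vapply(cands[idx], function(t) {
                     if (!is.null(t$member_origins))
                       paste(t$member_origins, collapse = ";")
                     else if (is.na(t$origin)) "combined"
                     else as.character(t$origin)
                   }, character(1))),
              class = "meta_transcript")
  })
  names(metas) <- NULL
  ord <- order(vapply(metas, function(m) m$chrom, character(1)),
               vapply(metas, function(m) m$exons[1L, 1L], numeric(1)),
               vapply(metas, function(m) m$exons[nrow(m$exons), 2L], numeric(1)))
  metas[ord]
}

#' Filter meta-transcripts and emit them as GTF
#'
#' Keeps meta-transcripts with score at or above `threshold` (0.5 by
#' default, balancing recall and precision; 0.2 is the recommended hard
#' floor below which meta-transcripts should be discarded) and writes
#' them as GTF transcript/exon records with `score` and `samples`
#' attributes.
#'
#' @param metas list of `meta_transcript` objects.
#' @param threshold minimum score, inclusive, in \[0, 1\].
#' @param path optional GTF output file.
#' @return the retained meta-transcripts, invisibly when writing.
#' @export
filter_and_emit <- function(metas, threshold = 0.5, path = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  keep <- metas[vapply(metas, function(m) m$score >= threshold, logical(1))]
  if (!is.null(path)) {
    write_gtf(keep, path)
    return(invisible(keep))
  }
  keep
}

#' Write transcripts to a GTF file
#'
#' Internal coordinates are 0-based half-open; GTF is written 1-based
#' inclusive. Accepts `meta_transcript` objects or any list of objects
#' with `chrom`, `strand`, `exons` and optional `score`/`members`.
#'
#' @param txs list of transcripts.
#' @param path output file.
#' @param source_name the GTF source column.
#' @export
write_gtf <- function(txs, path, source_name = "metassembler") {
  lines <- character(0)
  for (i in seq_along(txs)) {
    t <- txs[[i]]
    tid <- if (!is.null(t$tid)) t$tid else sprintf("MT.%d", i)
    gid <- if (!is.null(t$gene)) t$gene else tid
    score <- if (!is.null(t$score)) sprintf(' score "%.4f";', t$score) else ""
    samples <- if (!is.null(t$members))
      sprintf(' samples "%d";', t$members) else ""
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";%s%s',
                     gid, tid, score, samples)
    st <- if (t$strand %in% c("+", "-")) t$strand else "."
    lines <- c(lines, sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              t$chrom, source_name,
                              t$exons[1L, 1L] + 1L,
                              t$exons[nrow(t$exons), 2L], st, attrs))
    for (k in seq_len(nrow(t$exons)))
      lines <- c(lines, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                                t$chrom, source_name,
                                t$exons[k, 1L] + 1L, t$exons[k, 2L],
                                st, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
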