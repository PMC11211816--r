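## Evaluation harness: intron-chain matching against a reference
## annotation, precision/recall, precision-recall curves over a score
## sweep, and partial area under the curve (pAUC) restricted to a
## shared precision or recall range. Only multi-exon transcripts take
## part; duplicate predicted chains count once (set semantics).

#' Read transcripts from a GTF annotation
#'
#' @param path a GTF file with exon records carrying `transcript_id`.
#' @return data.frame with one row per transcript: `tid`, `chrom`,
#'   `strand`, `n_exons`, `start`, `end` (0-based half-open) and
#'   `chain_key` (NA for single-exon transcripts). Exon matrices are in
#'   the `exons` list column.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("annotation has no exon records: ", path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   tid = gr$transcript_id, stringsAsFactors = FALSE)
  by_tid <- split(df, df$tid)
  rows <- lapply(by_tid, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    exons <- cbind(start = d$start, end = d$end)
    introns <- if (nrow(d) > 1L)
      cbind(donor = d$end[-nrow(d)], acceptor = d$start[-1L])
    else empty_juncs()
    strand <- if (d$strand[1L] == "*") "." else d$strand[1L]
    list(tid = d$tid[1L], chrom = d$chrom[1L], strand = strand,
         n_exons = nrow(d), start = d$start[1L], end = d$end[nrow(d)],
         chain_key = chain_key(d$chrom[1L], strand, introns),
         exons = exons)
  })
  out <- data.frame(
    tid = vapply(rows, `[[`, character(1), "tid"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    n_exons = vapply(rows, `[[`, integer(1), "n_exons"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    chain_key = vapply(rows, `[[`, character(1), "chain_key"),
    stringsAsFactors = FALSE)
  out$exons <- lapply(rows, `[[`, "exons")
  rownames(out) <- NULL
  out
}

#' Count intron-chain matches
#'
#' Number of distinct predicted intron chains that exactly match a
#' chain in the truth set (chromosome- and strand-aware). Duplicate
#' predicted chains count once.
#'
#' @param predicted,truth character vectors of chain keys (NA entries,
#'   i.e. single-exon transcripts, are ignored).
#' @return integer match count.
#' @export
match_count <- function(predicted, truth) {
  p <- unique(predicted[!is.na(predicted)])
  t <- unique(truth[!is.na(truth)])
  length(intersect(p, t))
}

#' Precision and recall of a predicted transcript set
#'
#' Precision is matched / distinct predicted chains, recall is
#' matched / distinct truth chains; both over multi-exon transcripts
#' only. An empty prediction has precision 0 by convention; an empty
#' truth set is an error because the evaluation is meaningless.
#'
#' @param predicted,truth character vectors of chain keys.
#' @return named numeric vector `c(precision, recall, matched,
#'   n_predicted, n_truth)`.
#' @export
precision_recall <- function(predicted, truth) {
  t <- unique(truth[!is.na(truth)])
  if (length(t) == 0L) stop("empty truth set: evaluation is undefined")
  p <- unique(predicted[!is.na(predicted)])
  m <- length(intersect(p, t))
  c(precision = if (length(p)) m / length(p) else 0,
    recall = m / length(t),
    matched = m, n_predicted = length(p), n_truth = length(t))
}

#' Precision-recall curve over a score sweep
#'
#' Sweeps a threshold over the distinct prediction scores (or a given
#' grid); at each threshold the predictions scoring at or above it are
#' evaluated with [precision_recall()].
#'
#' @param keys chain keys of the predictions (NA = single-exon,
#'   excluded).
#' @param scores numeric vector parallel to `keys` (confidence score,
#'   or abundance for a baseline ranking).
#' @param truth truth chain keys.
#' @param grid optional increasing threshold grid; defaults to the
#'   distinct scores.
#' @return data.frame with columns `threshold`, `precision`, `recall`,
#'   `matched`, `n_predicted`; thresholds strictly increasing.
#' @export
prc_sweep <- function(keys, scores, truth, grid = NULL) {
  ok <- !is.na(keys)
  keys <- keys[ok]; scores <- scores[ok]
  if (is.null(grid)) grid <- sort(unique(scores))
  grid <- sort(unique(grid))
  ## thresholds above every score give an empty prediction set, whose
  ## precision is undefined; they are not part of the curve
  if (length(scores)) grid <- grid[grid <= max(scores)]
  rows <- lapply(grid, function(thr) {
    pr <- precision_recall(keys[scores >= thr], truth)
    data.frame(threshold = thr, precision = pr[["precision"]],
               recall = pr[["recall"]], matched = pr[["matched"]],
               n_predicted = pr[["n_predicted"]])
  })
  do.call(rbind, rows)
}

#' Partial area under a curve
#'
#' Trapezoidal area under the piecewise-linear curve through the given
#' points, restricted to `range` on the x axis. Duplicate x values keep
#' the largest y. The restriction interval must intersect the curve's
#' x span in more than a point.
#'
#' @param x,y curve coordinates (e.g. recall and precision).
#' @param range length-2 numeric interval on x.
#' @return the restricted area (a number).
#' @export
pauc <- function(x, y, range = c(min(x), max(x))) {
  stopifnot(length(x) == length(y), length(range) == 2L)
  range <- sort(range)
  o <- order(x, -y)
  x <- x[o]; y <- y[o]
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  lo <- max(range[1L], min(x)); hi <- min(range[2L], max(x))
  if (length(x) < 2L || !(hi > lo))
    stop("restriction interval is empty over the curve span")
  yat <- function(v) stats::approx(x, y, xout = v, ties = "ordered")$y
  xs <- c(lo, x[x > lo & x < hi], hi)
  ys <- yat(xs)
  sum(diff(xs) * (utils::head(ys, -1L) + utils::tail(ys, -1L)) / 2)
}

#' Precision-recall curve and pAUC for a scored prediction set
#'
#' Builds the PRC by sweeping the score, then computes the partial area
#' under the curve constrained either by recall (area of precision over
#' a recall interval) or by precision (area of recall over a precision
#' interval). When two methods are compared, the shared range is the
#' intersection of their spans on the constraining axis.
#'
#' @param keys,scores,truth,grid as in [prc_sweep()].
#' @param constraint `"recall"` or `"precision"`.
#' @param range optional length-2 interval on the constraining axis;
#'   defaults to the curve's own span.
#' @return list with `curve` (the sweep data.frame) and `pauc`.
#' @export
prc_pauc <- function(keys, scores, truth, constraint = c("recall", "precision"),
                     range = NULL, grid = NULL) {
  constraint <- match.arg(constraint)
  curve <- prc_sweep(keys, scores, truth, grid)
  x <- curve[[constraint]]
  y <- curve[[setdiff(c("recall", "precision"), constraint)]]
  if (is.null(range)) range <- c(min(x), max(x))
  list(curve = curve, pauc = pauc(x, y, range))
}
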