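## Ground-truthed multi-sample simulator. Generates random multi-exon
## gene models, per-sample truth sets in which each sample expresses a
## fraction p of the transcript set, and perfect spliced paired-end
## alignments written as coordinate-sorted SAM. Optional junction
## dropout removes, in a chosen sample, every read whose alignment
## spans a designated junction -- manufacturing exactly the situation
## in which a fragment straddling the junction can only be bridged via
## the combined graph and the junction restored by refinement.

#' Simulation configuration
#'
#' @param n_loci number of gene loci.
#' @param transcripts_per_locus transcripts per locus (alternative
#'   exon-skipping isoforms of a shared exon scaffold).
#' @param n_samples number of samples N.
#' @param sharing fraction p of the transcript set expressed by each
#'   sample (each sample draws its own p-fraction subset).
#' @param read_length,frag_mean,frag_sd paired-end geometry in bp
#'   (fragment length is Normal, truncated at the read length).
#' @param depth target mean per-base coverage of an expressed
#'   transcript at the average expression level.
#' @param expr_meanlog,expr_sdlog log-normal expression distribution
#'   (meanlog 1, sdlog 1: roughly 30-fold dynamic range).
#' @param dropout_rate probability that an expressed junction is
#'   designated for dropout in a given sample (0 disables).
#' @param dropout optional explicit data.frame (`sample`, `donor`,
#'   `acceptor`) of designated junctions.
#' @param chrom chromosome name of the simulated genome.
#' @param seed RNG seed; the seed fully determines the output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci = 30L, transcripts_per_locus = 3L,
                       n_samples = 5L, sharing = 0.9,
                       read_length = 100L, frag_mean = 300L, frag_sd = 50L,
                       depth = 20, expr_meanlog = 1, expr_sdlog = 1,
                       dropout_rate = 0, dropout = NULL,
                       chrom = "chrS", seed = 1L) {
  stopifnot(sharing > 0, sharing <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            n_loci >= 1, n_samples >= 1, depth > 0,
            frag_mean >= read_length)
  structure(list(n_loci = as.integer(n_loci),
                 transcripts_per_locus = as.integer(transcripts_per_locus),
                 n_samples = as.integer(n_samples), sharing = sharing,
                 read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd, depth = depth,
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 dropout_rate = dropout_rate, dropout = dropout,
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a ground-truth transcriptome and per-sample truth sets
#'
#' Each locus gets a scaffold of 3-12 exons (80-600 bp, introns
#' 200-5000 bp); isoforms keep the terminal exons and skip interior
#' exons at random, deduplicated by intron chain. Every sample's truth
#' is an independent `sharing`-fraction subset of the transcript set,
#' and per-(transcript, sample) expression is log-normal.
#'
#' @param cfg a [sim_config()].
#' @return list with `transcripts` (data.frame: tid, gene, chrom,
#'   strand, start, end, length, n_exons, chain_key, plus `exons` list
#'   column), `truth` (per-sample tid vectors), `expr` (transcripts x
#'   samples matrix), and `cfg`.
#' @export
simulate_transcriptome <- function(cfg) {
  set.seed(cfg$seed)
  cursor <- 10000L
  rows <- list()
  for (li in seq_len(cfg$n_loci)) {
    n_ex <- sample(3:12, 1L)
    widths <- sample(80:600, n_ex, replace = TRUE)
    introns <- sample(200:5000, max(n_ex - 1L, 1L), replace = TRUE)
    starts <- cursor + c(0L, cumsum(widths[-n_ex] + introns[seq_len(n_ex - 1L)]))
    ends <- starts + widths
    strand <- sample(c("+", "-"), 1L)
    scaffold <- cbind(start = starts, end = ends)
    chains <- character(0)
    for (ti in seq_len(cfg$transcripts_per_locus)) {
      key <- NULL; ex <- NULL
      for (try in 1:10) {
        ## isoforms skip 1-2 interior exons of the scaffold (typical
        ## exon-skipping events); terminal exons are shared
        keep <- rep(TRUE, n_ex)
        if (ti > 1L && n_ex > 2L) {
          n_skip <- min(sample(1:2, 1L), n_ex - 2L)
          keep[sample(2:(n_ex - 1L), n_skip)] <- FALSE
        }
        cand <- scaffold[keep, , drop = FALSE]
        if (nrow(cand) < 2L) next
        k <- chain_key(cfg$chrom, strand,
                       cbind(cand[-nrow(cand), 2L], cand[-1L, 1L]))
        if (!(k %in% chains)) { chains <- c(chains, k); key <- k; ex <- cand; break }
      }
      if (is.null(key)) next
      rows[[length(rows) + 1L]] <- list(
        tid = sprintf("G%04d.T%d", li, ti), gene = sprintf("G%04d", li),
        chrom = cfg$chrom, strand = strand, exons = ex,
        start = ex[1L, 1L], end = ex[nrow(ex), 2L],
        length = sum(ex[, 2L] - ex[, 1L]), n_exons = nrow(ex),
        chain_key = key)
    }
    cursor <- ends[n_ex] + 20000L
  }
  tx <- data.frame(
    tid = vapply(rows, `[[`, character(1), "tid"),
    gene = vapply(rows, `[[`, character(1), "gene"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    length = vapply(rows, `[[`, numeric(1), "length"),
    n_exons = vapply(rows, `[[`, numeric(1), "n_exons"),
    chain_key = vapply(rows, `[[`, character(1), "chain_key"),
    stringsAsFactors = FALSE)
  tx$exons <- lapply(rows, `[[`, "exons")
  ntx <- nrow(tx)
  truth <- lapply(seq_len(cfg$n_samples), function(s) {
    k <- max(1L, round(cfg$sharing * ntx))
    sort(sample(tx$tid, k))
  })
  expr <- matrix(stats::rlnorm(ntx * cfg$n_samples,
                               cfg$expr_meanlog, cfg$expr_sdlog),
                 nrow = ntx,
                 dimnames = list(tx$tid, paste0("s", seq_len(cfg$n_samples))))
  for (s in seq_len(cfg$n_samples))
    expr[!(tx$tid %in% truth[[s]]), s] <- 0
  list(transcripts = tx, truth = truth, expr = expr, cfg = cfg)
}

## Map a transcript-coordinate interval [a, b) onto genomic blocks.
tx_interval_to_read <- function(exons, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  widths <- as.integer(exons[, 2L] - exons[, 1L])
  offs <- c(0L, cumsum(widths))
  bs <- integer(0); be <- integer(0)
  for (k in seq_len(nrow(exons))) {
    lo <- max(a, offs[k]); hi <- min(b, offs[k + 1L])
    if (hi > lo) {
      bs <- c(bs, as.integer(exons[k, 1L] + (lo - offs[k])))
      be <- c(be, as.integer(exons[k, 1L] + (hi - offs[k])))
    }
  }
  juncs <- if (length(bs) > 1L)
    cbind(donor = be[-length(be)], acceptor = bs[-1L])
  else empty_juncs()
  list(start = bs[1L], end = be[length(be)], juncs = juncs,
       blocks = cbind(bs, be))
}

#' Simulate perfect spliced paired-end alignments for one sample
#'
#' Fragment counts per transcript are Poisson around
#' `depth * expr / E[expr] * length / (2 * read_length)`; fragment
#' lengths are Normal, truncated into `[read_length, transcript
#' length]`. Reads are exact coordinate alignments (the simulator
#' emulates the aligner's output, not the sequencer). When junctions
#' are designated for dropout, any fragment with a mate spanning one of
#' them is removed entirely.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param sample_id which sample to generate.
#' @param dropout_juncs optional matrix/data.frame with `donor`,
#'   `acceptor` columns: designated junctions for this sample.
#' @return list of fragment records (qname, strand, r1, r2) ready for
#'   [write_sam()].
#' @export
simulate_reads <- function(sim, sample_id, dropout_juncs = NULL) {
  cfg <- sim$cfg
  set.seed(cfg$seed * 1000L + sample_id)
  rl <- cfg$read_length
  escale <- exp(cfg$expr_meanlog + cfg$expr_sdlog^2 / 2)
  drop_keys <- if (!is.null(dropout_juncs) && nrow(dropout_juncs))
    paste(dropout_juncs[, "donor"], dropout_juncs[, "acceptor"]) else character(0)
  recs <- list()
  counter <- 0L
  for (i in seq_len(nrow(sim$transcripts))) {
    e <- sim$expr[i, sample_id]
    if (e == 0) next
    tx <- sim$transcripts[i, ]
    L <- tx$length
    exons <- sim$transcripts$exons[[i]]
    nfrag <- stats::rpois(1L, cfg$depth * (e / escale) * L / (2 * rl))
    if (nfrag == 0L) next
    flen <- round(stats::rnorm(nfrag, cfg$frag_mean, cfg$frag_sd))
    flen <- pmin(pmax(flen, rl), L)
    fstart <- floor(stats::runif(nfrag, 0, L - flen + 1))
    for (k in seq_len(nfrag)) {
      r1 <- tx_interval_to_read(exons, fstart[k], fstart[k] + rl)
      r2 <- tx_interval_to_read(exons, fstart[k] + flen[k] - rl,
                                fstart[k] + flen[k])
      if (length(drop_keys)) {
        mk <- c(if (nrow(r1$juncs)) paste(r1$juncs[, 1L], r1$juncs[, 2L]),
                if (nrow(r2$juncs)) paste(r2$juncs[, 1L], r2$juncs[, 2L]))
        if (any(mk %in% drop_keys)) next
      }
      counter <- counter + 1L
      recs[[length(recs) + 1L]] <- list(
        qname = sprintf("s%d.f%06d", sample_id, counter),
        chrom = tx$chrom, strand = tx$strand, r1 = r1, r2 = r2)
    }
  }
  recs
}

cigar_of <- function(blocks) {
  w <- blocks[, 2L] - blocks[, 1L]
  if (nrow(blocks) == 1L) return(sprintf("%dM", w))
  gaps <- blocks[-1L, 1L] - blocks[-nrow(blocks), 2L]
  paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
         w[length(w)], "M")
}

#' Write simulated fragments as a coordinate-sorted SAM file
#'
#' @param recs fragment records from [simulate_reads()].
#' @param path output SAM path.
#' @param chrom,chrom_len reference name and length for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(recs, path, chrom, chrom_len) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  if (length(recs) == 0L) { writeLines(hdr, path); return(invisible(path)) }
  lines <- character(0)
  pos1 <- integer(0)
  for (r in recs) {
    seq1 <- strrep("A", sum(r$r1$blocks[, 2L] - r$r1$blocks[, 1L]))
    seq2 <- strrep("A", sum(r$r2$blocks[, 2L] - r$r2$blocks[, 1L]))
    xs <- if (r$strand %in% c("+", "-")) sprintf("\tXS:A:%s", r$strand) else ""
    tlen <- r$r2$end - r$r1$start
    l1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*%s",
                  r$qname, r$chrom, r$r1$start + 1L, cigar_of(r$r1$blocks),
                  r$r2$start + 1L, tlen, seq1, xs)
    l2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*%s",
                  r$qname, r$chrom, r$r2$start + 1L, cigar_of(r$r2$blocks),
                  r$r1$start + 1L, -tlen, seq2, xs)
    lines <- c(lines, l1, l2)
    pos1 <- c(pos1, r$r1$start, r$r2$start)
  }
  writeLines(c(hdr, lines[order(pos1)]), path)
  invisible(path)
}

#' Generate a complete multi-sample fixture bundle
#'
#' Writes one SAM per sample, the truth annotation GTF, a manifest, the
#' designated-dropout table (`expected_rescues.tsv`) and the effective
#' configuration JSON into `dir`. Junction dropout designates, per
#' sample, each junction of an expressed transcript with probability
#' `dropout_rate` (explicit `cfg$dropout` entries are added as given).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `dir`, `manifest`, `truth_gtf`, `sim`, and
#'   `expected_rescues` (data.frame: sample, donor, acceptor).
#' @export
end_to_end_fixture <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_transcriptome(cfg)
  tx <- sim$transcripts
  ## designate dropout junctions
  set.seed(cfg$seed + 7L)
  drops <- list()
  if (cfg$dropout_rate > 0) {
    for (s in seq_len(cfg$n_samples)) {
      juncs <- unique(do.call(rbind, lapply(
        which(tx$tid %in% sim$truth[[s]] & tx$n_exons > 1), function(i) {
          ex <- tx$exons[[i]]
          cbind(donor = ex[-nrow(ex), 2L], acceptor = ex[-1L, 1L])
        })))
      sel <- stats::runif(nrow(juncs)) < cfg$dropout_rate
      if (any(sel))
        drops[[length(drops) + 1L]] <-
          data.frame(sample = s, donor = juncs[sel, "donor"],
                     acceptor = juncs[sel, "acceptor"])
    }
  }
  if (!is.null(cfg$dropout)) drops[[length(drops) + 1L]] <- cfg$dropout
  rescues <- if (length(drops)) do.call(rbind, drops)
             else data.frame(sample = integer(0), donor = integer(0),
                             acceptor = integer(0))
  chrom_len <- max(tx$end) + 10000L
  sam_paths <- character(cfg$n_samples)
  for (s in seq_len(cfg$n_samples)) {
    dj <- rescues[rescues$sample == s, c("donor", "acceptor"), drop = FALSE]
    recs <- simulate_reads(sim, s, if (nrow(dj)) dj else NULL)
    sam_paths[s] <- file.path(dir, sprintf("sample%d.sam", s))
    write_sam(recs, sam_paths[s], cfg$chrom, chrom_len)
  }
  truth_gtf <- file.path(dir, "truth.gtf")
  txs <- lapply(seq_len(nrow(tx)), function(i)
    list(chrom = tx$chrom[i], strand = tx$strand[i],
         exons = tx$exons[[i]], tid = tx$tid[i], gene = tx$gene[i]))
  write_gtf(txs, truth_gtf, source_name = "sim")
  manifest <- file.path(dir, "manifest.txt")
  writeLines(sprintf("%s\tsample%d", basename(sam_paths),
                     seq_len(cfg$n_samples)), manifest)
  utils::write.table(rescues, file.path(dir, "expected_rescues.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  list(dir = dir, manifest = manifest, truth_gtf = truth_gtf,
       sim = sim, expected_rescues = rescues)
}
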