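## Coordinate convention: every interval in this package is 0-based,
## half-open [start, end).  A junction is the pair (donor, acceptor) where
## `donor` is the half-open end of the exonic block left of the intron and
## `acceptor` is the start of the block right of it; donor < acceptor.
## GTF import/export is the single place where 1-based inclusive
## coordinates are converted.

#' Read a sample manifest
#'
#' A manifest is a plain-text file with one alignment file per line and an
#' optional tab-separated sample label. Relative paths are resolved
#' against the manifest's directory.
#'
#' @param path path to the manifest file.
#' @return data.frame with columns `path`, `label` and `sample_id`
#'   (1-based integer index).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("manifest is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  paths <- vapply(parts, `[[`, character(1), 1L)
  labels <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else basename(p[[1L]]),
                   character(1))
  rel <- !grepl("^/", paths)
  paths[rel] <- file.path(dirname(path), paths[rel])
  data.frame(path = paths, label = labels,
             sample_id = seq_along(paths), stringsAsFactors = FALSE)
}

#' Parse paired-end alignments from a SAM or BAM file
#'
#' Loads primary alignments, derives aligned blocks and splice junctions
#' from the CIGAR string (`N` operations), and records the spliced-read
#' strand from the `XS` tag when present. Secondary, supplementary and
#' unmapped records are skipped; records with unparsable CIGARs are
#' dropped and counted in the `skipped` attribute.
#'
#' @param path a SAM or BAM file (SAM files are converted on the fly).
#' @param sample_id integer index of the sample this file belongs to.
#' @param min_mapq minimum mapping quality; default 0 accepts every
#'   primary alignment, which keeps sensitivity on low-coverage
#'   (e.g. single-cell) samples.
#' @return data.frame with one row per alignment: `qname`, `chrom`,
#'   `strand` (from XS; "." when absent), `start`, `end` (0-based
#'   half-open), `mate1` (logical), `sample_id`, and a list column
#'   `juncs` of two-column matrices (donor, acceptor).
#' @export
parse_alignments <- function(path, sample_id = 1L, min_mapq = 0L) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "XS")
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(res$qname)
  if (n == 0L) {
    out <- data.frame(qname = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), mate1 = logical(0),
                      sample_id = integer(0))
    out$juncs <- list()
    attr(out, "skipped") <- 0L
    return(out)
  }
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 255L
  keep <- !is.na(res$cigar) & !is.na(res$pos) & mapq >= min_mapq
  skipped <- sum(!keep)
  qname <- res$qname[keep]
  flag <- res$flag[keep]
  chrom <- as.character(res$rname)[keep]
  pos <- res$pos[keep]
  cigar <- res$cigar[keep]
  xs <- res$tag$XS
  strand <- if (is.null(xs)) rep(".", length(qname)) else {
    s <- as.character(xs)[keep]
    s[is.na(s) | !(s %in% c("+", "-"))] <- "."
    s
  }
  ## blocks on the reference, split at N operations (0-based half-open)
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(cigar, pos = pos)
  bl_start <- unlist(IRanges::start(blocks), use.names = FALSE) - 1L
  bl_end <- unlist(IRanges::end(blocks), use.names = FALSE)
  nb <- lengths(blocks)
  row_of <- rep.int(seq_along(nb), nb)
  start0 <- vapply(split(bl_start, row_of), min, integer(1))
  end0 <- vapply(split(bl_end, row_of), max, integer(1))
  juncs <- junctions_from_blocks(bl_start, bl_end, row_of, length(nb))
  mate1 <- bitwAnd(flag, 0x80L) == 0L   # second-mate bit unset -> mate 1
  out <- data.frame(qname = qname, chrom = chrom, strand = strand,
                    start = unname(start0), end = unname(end0),
                    mate1 = mate1, sample_id = sample_id,
                    stringsAsFactors = FALSE)
  out$juncs <- juncs
  attr(out, "skipped") <- skipped
  out
}

## Build per-read junction matrices from flattened block coordinates.
junctions_from_blocks <- function(bl_start, bl_end, row_of, n) {
  juncs <- rep(list(empty_juncs()), n)
  multi <- which(tabulate(row_of, n) > 1L)
  if (length(multi)) {
    by_row <- split(seq_along(row_of), row_of)
    for (i in multi) {
      idx <- by_row[[as.character(i)]]
      k <- length(idx)
      juncs[[i]] <- cbind(donor = bl_end[idx[-k]], acceptor = bl_start[idx[-1L]])
    }
  }
  juncs
}

empty_juncs <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("donor", "acceptor")))
}

## A mate as carried through the pipeline: span plus junction chain.
new_read <- function(start, end, juncs = empty_juncs()) {
  list(start = as.integer(start), end = as.integer(end), juncs = juncs)
}

#' Pair mates into fragments
#'
#' Mates are matched by query name. Reads without a partner become
#' single-read fragments. If more than two primary records share a name,
#' the leftmost first/second mate pair is kept and the rest dropped with
#' a warning.
#'
#' @param reads data.frame from [parse_alignments()] (one sample, any
#'   number of chromosomes).
#' @return list of fragments; each fragment is a list with `qname`,
#'   `sample_id`, `chrom`, `strand`, `r1`, `r2` (NULL when unpaired),
#'   where `r1` is the leftmost mate.
#' @export
pair_fragments <- function(reads) {
  if (nrow(reads) == 0L) return(list())
  key <- paste(reads$qname, reads$chrom, sep = "\r")
  idx_by_key <- split(seq_len(nrow(reads)), key)
  dup <- 0L
  frags <- lapply(idx_by_key, function(idx) {
    if (length(idx) > 2L) {
      dup <<- dup + 1L
      i1 <- idx[reads$mate1[idx]]
      i2 <- idx[!reads$mate1[idx]]
      idx <- c(if (length(i1)) i1[which.min(reads$start[i1])],
               if (length(i2)) i2[which.min(reads$start[i2])])
    }
    idx <- idx[order(reads$start[idx], reads$end[idx])]
    strands <- setdiff(unique(reads$strand[idx]), ".")
    strand <- if (length(strands) == 1L) strands else "."
    r1 <- new_read(reads$start[idx[1L]], reads$end[idx[1L]], reads$juncs[[idx[1L]]])
    r2 <- if (length(idx) == 2L)
      new_read(reads$start[idx[2L]], reads$end[idx[2L]], reads$juncs[[idx[2L]]])
    list(qname = reads$qname[idx[1L]], sample_id = reads$sample_id[idx[1L]],
         chrom = reads$chrom[idx[1L]], strand = strand, r1 = r1, r2 = r2)
  })
  if (dup > 0L)
    warning(dup, " query names had >2 primary records; kept leftmost pairs")
  names(frags) <- NULL
  frags[order(vapply(frags, function(f) f$r1$start, integer(1)))]
}

frag_span <- function(f) {
  c(f$r1$start, if (is.null(f$r2)) f$r1$end else max(f$r1$end, f$r2$end))
}

#' Bundle fragments into gene loci
#'
#' Fragments (possibly pooled across samples) are swept along each
#' chromosome; a new locus starts whenever the next fragment leaves at
#' least `gap` uncovered bases after the previous footprint. Loci are
#' formed per (chromosome, strand); fragments without strand information
#' are assigned to the stranded locus they overlap most, and form
#' unstranded loci only when they overlap none.
#'
#' @param fragments list of fragments from [pair_fragments()], any
#'   samples mixed.
#' @param gap minimum run of uncovered bases separating two loci
#'   (default 50).
#' @param n_samples total number of samples (defaults to the largest
#'   `sample_id` seen).
#' @return list of `locus` objects: `chrom`, `strand`, `start`, `end`,
#'   and `frags`, a list of per-sample fragment lists of length
#'   `n_samples`.
#' @export
bundle_loci <- function(fragments, gap = 50L, n_samples = NULL) {
  if (length(fragments) == 0L) return(list())
  if (is.null(n_samples))
    n_samples <- max(vapply(fragments, function(f) f$sample_id, integer(1)))
  chrom <- vapply(fragments, function(f) f$chrom, character(1))
  strand <- vapply(fragments, function(f) f$strand, character(1))
  spans <- t(vapply(fragments, frag_span, integer(2)))
  loci <- list()
  for (ch in sort(unique(chrom))) {
    stranded <- list()
    for (st in c("+", "-")) {
      sel <- which(chrom == ch & strand == st)
      stranded[[st]] <- sweep_bundles(sel, spans, gap)
    }
    ## assign unstranded fragments to the most-overlapping stranded locus
    uns <- which(chrom == ch & strand == ".")
    leftover <- integer(0)
    assign_extra <- list()
    for (i in uns) {
      best <- 0L; best_ov <- 0L; k <- 0L
      for (st in c("+", "-")) for (b in seq_along(stranded[[st]])) {
        k <- k + 1L
        bb <- stranded[[st]][[b]]
        ov <- min(spans[i, 2L], bb$end) - max(spans[i, 1L], bb$start)
        if (ov > best_ov) { best_ov <- ov; best <- k; best_ref <- c(st, b) }
      }
      if (best > 0L) {
        key <- paste(best_ref, collapse = "\r")
        assign_extra[[key]] <- c(assign_extra[[key]], i)
      } else leftover <- c(leftover, i)
    }
    for (key in names(assign_extra)) {
      ref <- strsplit(key, "\r")[[1L]]
      b <- as.integer(ref[2L])
      stranded[[ref[1L]]][[b]]$idx <- c(stranded[[ref[1L]]][[b]]$idx,
                                        assign_extra[[key]])
    }
    for (st in c("+", "-")) for (bb in stranded[[st]])
      loci[[length(loci) + 1L]] <- make_locus(ch, st, bb$idx, fragments,
                                              spans, n_samples)
    for (bb in sweep_bundles(leftover, spans, gap))
      loci[[length(loci) + 1L]] <- make_locus(ch, ".", bb$idx, fragments,
                                              spans, n_samples)
  }
  ord <- order(vapply(loci, function(l) l$chrom, character(1)),
               vapply(loci, function(l) l$start, integer(1)),
               vapply(loci, function(l) l$strand, character(1)))
  loci[ord]
}

sweep_bundles <- function(sel, spans, gap) {
  if (length(sel) == 0L) return(list())
  sel <- sel[order(spans[sel, 1L], spans[sel, 2L])]
  out <- list()
  cur <- sel[1L]
  cur_end <- spans[sel[1L], 2L]
  cur_start <- spans[sel[1L], 1L]
  for (i in sel[-1L]) {
    if (spans[i, 1L] - cur_end >= gap) {
      out[[length(out) + 1L]] <- list(idx = cur, start = cur_start, end = cur_end)
      cur <- i; cur_start <- spans[i, 1L]; cur_end <- spans[i, 2L]
    } else {
      cur <- c(cur, i)
      cur_end <- max(cur_end, spans[i, 2L])
    }
  }
  out[[length(out) + 1L]] <- list(idx = cur, start = cur_start, end = cur_end)
  out
}

make_locus <- function(chrom, strand, idx, fragments, spans, n_samples) {
  frags <- rep(list(list()), n_samples)
  for (i in idx) {
    s <- fragments[[i]]$sample_id
    frags[[s]][[length(frags[[s]]) + 1L]] <- fragments[[i]]
  }
  structure(list(chrom = chrom, strand = strand,
                 start = min(spans[idx, 1L]), end = max(spans[idx, 2L]),
                 frags = frags),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  n <- sum(lengths(x$frags) > 0L)
  cat(sprintf("<locus %s:%d-%d(%s) %d fragments in %d samples>\n",
              x$chrom, x$start, x$end, x$strand,
              sum(lengths(x$frags)), n))
  invisible(x)
}
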