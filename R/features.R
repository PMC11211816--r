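## 50-feature characterization of a candidate transcript, grouped as
## abundance (14), graph-structural (12), boundary (14) and intron (10)
## features. Features declared "scale" grow linearly when every read in
## every sample is duplicated; "invariant" features do not change; "log"
## features are log-transformed counts.

#' Feature schema
#'
#' The fixed, ordered list of the 50 features with their group and
#' scaling behavior. The schema (names in order) is hashed into trained
#' models so a scorer is never applied to features it was not trained
#' on.
#'
#' @return data.frame with columns `name`, `group`, `behavior`.
#' @export
feature_schema <- function() {
  tab <- rbind(
    ## abundance
    c("abundance", "abundance", "scale"),
    c("log_abundance", "abundance", "log"),
    c("support_samples", "abundance", "invariant"),
    c("support_frac", "abundance", "invariant"),
    c("support_total", "abundance", "scale"),
    c("support_mean", "abundance", "scale"),
    c("support_max", "abundance", "scale"),
    c("bottleneck_weight", "abundance", "scale"),
    c("bottleneck_support_samples", "abundance", "invariant"),
    c("bottleneck_support_total", "abundance", "scale"),
    c("rel_abundance", "abundance", "invariant"),
    c("locus_reads_log", "abundance", "log"),
    c("path_cov_mean", "abundance", "scale"),
    c("path_cov_min", "abundance", "scale"),
    ## graph structure
    c("n_vertices_graph", "structure", "invariant"),
    c("n_junctions_graph", "structure", "invariant"),
    c("n_vertices_combined", "structure", "invariant"),
    c("n_junctions_combined", "structure", "invariant"),
    c("n_samples", "structure", "invariant"),
    c("n_exons", "structure", "invariant"),
    c("n_introns", "structure", "invariant"),
    c("transcript_length", "structure", "invariant"),
    c("genomic_span_log", "structure", "log"),
    c("from_combined", "structure", "invariant"),
    c("in_both_graphs", "structure", "invariant"),
    c("other_side_abundance", "structure", "scale"),
    ## boundaries
    c("start_edge_weight", "boundary", "scale"),
    c("end_edge_weight", "boundary", "scale"),
    c("start_support_samples", "boundary", "invariant"),
    c("start_support_total", "boundary", "scale"),
    c("end_support_samples", "boundary", "invariant"),
    c("end_support_total", "boundary", "scale"),
    c("start_rel", "boundary", "invariant"),
    c("end_rel", "boundary", "invariant"),
    c("first_exon_length", "boundary", "invariant"),
    c("last_exon_length", "boundary", "invariant"),
    c("start_vertex_cov", "boundary", "scale"),
    c("end_vertex_cov", "boundary", "scale"),
    c("n_starting_edges", "boundary", "invariant"),
    c("n_ending_edges", "boundary", "invariant"),
    ## introns
    c("n_retained_introns", "intron", "invariant"),
    c("retained_frac", "intron", "invariant"),
    c("retention_comp_max", "intron", "invariant"),
    c("retention_comp_mean", "intron", "invariant"),
    c("junction_weight_min", "intron", "scale"),
    c("junction_weight_mean", "intron", "scale"),
    c("junction_support_min_samples", "intron", "invariant"),
    c("junction_support_mean_total", "intron", "scale"),
    c("intron_length_max", "intron", "invariant"),
    c("intron_length_min", "intron", "invariant"))
  data.frame(name = tab[, 1L], group = tab[, 2L], behavior = tab[, 3L],
             stringsAsFactors = FALSE)
}

feature_schema_hash <- function() {
  digest::digest(feature_schema()$name, algo = "md5")
}

#' Compute the 50-feature vector of one candidate transcript
#'
#' @param t a `candidate` from [decompose_graph()].
#' @param g the (augmented) graph the candidate was decomposed from.
#' @param gm the cluster's combined graph (pass `g` again when the
#'   candidate originates from the combined graph).
#' @param supports support matrix of `g`'s edges (rows aligned with
#'   `g$edges`), or `NULL` for a single-sample self-support.
#' @param n_samples the cluster size N.
#' @param locus_reads number of fragments behind `g` at this locus.
#' @param other_abundance abundance of the identical intron chain
#'   assembled on the other side (combined vs individual), 0 if absent.
#' @param in_both logical: was the identical chain assembled both from
#'   an individual graph and from the combined graph.
#' @return named numeric vector of length 50, ordered as
#'   [feature_schema()].
#' @export
compute_features <- function(t, g, gm, supports = NULL, n_samples = 1L,
                             locus_reads = 0L, other_abundance = 0,
                             in_both = FALSE) {
  if (is.null(supports)) supports <- matrix(g$edges$weight, ncol = 1L)
  N <- n_samples
  sup <- t$support
  bsup <- t$bottleneck_support
  src_rows <- which(g$edges$kind == "source")
  total_flow <- sum(g$edges$weight[src_rows])
  vw <- g$vs$weight[t$vseq]
  n_exons <- nrow(t$exons)
  n_introns <- nrow(t$introns)
  exon_len <- unname(t$exons[, 2L] - t$exons[, 1L])
  span <- unname(t$exons[n_exons, 2L] - t$exons[1L, 1L])

  ## boundary edges of the original graph
  first_v <- t$vseq[1L]; last_v <- t$vseq[length(t$vseq)]
  srow <- which(g$edges$kind == "source" & g$edges$to == first_v)
  erow <- which(g$edges$kind == "sink" & g$edges$from == last_v)
  start_w <- if (length(srow)) g$edges$weight[srow[1L]] else 0
  end_w <- if (length(erow)) g$edges$weight[erow[1L]] else 0
  ssup <- if (length(srow)) supports[srow[1L], ] else numeric(N)
  esup <- if (length(erow)) supports[erow[1L], ] else numeric(N)

  ## junction edges traversed by the transcript
  jrows <- integer(0)
  if (n_introns > 0L) {
    jall <- which(g$edges$kind == "junction")
    jd <- g$vs$end[g$edges$from[jall]]
    ja <- g$vs$start[g$edges$to[jall]]
    jrows <- jall[match(paste(t$introns[, 1L], t$introns[, 2L]),
                        paste(jd, ja))]
    jrows <- jrows[!is.na(jrows)]
  }
  jw <- g$edges$weight[jrows]
  jsup <- if (length(jrows)) supports[jrows, , drop = FALSE]
          else matrix(0, 0L, N)

  ## retained-intron competitiveness: graph junctions fully inside one
  ## exon of t, compared with the coverage of the intronic vertices
  comp <- numeric(0)
  gj <- graph_junctions(g)
  if (nrow(gj) && n_exons > 0L) {
    for (k in seq_len(nrow(gj))) {
      d <- gj[k, "donor"]; a <- gj[k, "acceptor"]
      inside <- which(t$exons[, 1L] < d & a < t$exons[, 2L])
      if (length(inside)) {
        iv <- t$vseq[g$vs$start[t$vseq] >= d & g$vs$end[t$vseq] <= a]
        icov <- if (length(iv)) mean(g$vs$weight[iv]) else 0
        comp <- c(comp, icov / gj[k, "weight"])
      }
    }
  }

  vals <- c(
    abundance = t$abundance,
    log_abundance = log1p(t$abundance),
    support_samples = sum(sup > 0),
    support_frac = sum(sup > 0) / N,
    support_total = sum(sup),
    support_mean = sum(sup) / N,
    support_max = max(sup, 0),
    bottleneck_weight = t$bottleneck_weight,
    bottleneck_support_samples = sum(bsup > 0),
    bottleneck_support_total = sum(bsup),
    rel_abundance = if (total_flow > 0) t$abundance / total_flow else 0,
    locus_reads_log = log1p(locus_reads),
    path_cov_mean = mean(vw),
    path_cov_min = min(vw),
    n_vertices_graph = nrow(g$vs),
    n_junctions_graph = sum(g$edges$kind == "junction"),
    n_vertices_combined = nrow(gm$vs),
    n_junctions_combined = sum(gm$edges$kind == "junction"),
    n_samples = N,
    n_exons = n_exons,
    n_introns = n_introns,
    transcript_length = sum(exon_len),
    genomic_span_log = log1p(span),
    from_combined = as.numeric(is.na(t$origin)),
    in_both_graphs = as.numeric(in_both),
    other_side_abundance = other_abundance,
    start_edge_weight = start_w,
    end_edge_weight = end_w,
    start_support_samples = sum(ssup > 0),
    start_support_total = sum(ssup),
    end_support_samples = sum(esup > 0),
    end_support_total = sum(esup),
    start_rel = if (t$abundance > 0) start_w / t$abundance else 0,
    end_rel = if (t$abundance > 0) end_w / t$abundance else 0,
    first_exon_length = exon_len[1L],
    last_exon_length = exon_len[n_exons],
    start_vertex_cov = g$vs$weight[first_v],
    end_vertex_cov = g$vs$weight[last_v],
    n_starting_edges = length(src_rows),
    n_ending_edges = sum(g$edges$kind == "sink"),
    n_retained_introns = length(comp),
    retained_frac = if (n_exons > 0) length(comp) / n_exons else 0,
    retention_comp_max = if (length(comp)) max(comp) else 0,
    retention_comp_mean = if (length(comp)) mean(comp) else 0,
    junction_weight_min = if (length(jw)) min(jw) else 0,
    junction_weight_mean = if (length(jw)) mean(jw) else 0,
    junction_support_min_samples = if (length(jrows))
      min(rowSums(jsup > 0)) else 0,
    junction_support_mean_total = if (length(jrows))
      mean(rowSums(jsup)) else 0,
    intron_length_max = if (n_introns)
      max(t$introns[, 2L] - t$introns[, 1L]) else 0,
    intron_length_min = if (n_introns)
      min(t$introns[, 2L] - t$introns[, 1L]) else 0)
  stopifnot(length(vals) == nrow(feature_schema()))
  names(vals) <- feature_schema()$name
  vals
}

#' Label candidate feature rows against an annotation
#'
#' A multi-exon candidate is labeled 1 when its intron chain exactly
#' matches an annotated transcript on the same chromosome and strand,
#' else 0. Single-exon candidates carry no intron chain and are excluded
#' from training rows.
#'
#' @param features data.frame of feature rows with a `chain_key` column
#'   (see [feature_table()]).
#' @param annotation annotated transcripts from [read_annotation()], or
#'   a character vector of chain keys.
#' @return `features` restricted to multi-exon rows, with a `label`
#'   column appended.
#' @export
label_candidates <- function(features, annotation) {
  truth <- if (is.character(annotation)) annotation else annotation$chain_key
  out <- features[!is.na(features$chain_key), , drop = FALSE]
  out$label <- as.integer(out$chain_key %in% truth)
  rownames(out) <- NULL
  out
}
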