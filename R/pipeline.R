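## End-to-end orchestration: alignments -> loci -> per-sample graphs ->
## cross-sample clusters -> two-stage bridging and refinement -> edge
## supports -> decomposition of every member graph and the combined
## graph -> features -> (optional) scoring -> meta-transcripts.

default_params <- function() {
  list(min_mapq = 0L, bundle_gap = 50L, min_junction_support = 1L,
       min_similarity = 0.1, size_cap = NULL, max_boundary_ext = 200L,
       max_bridge_span = 500000L, score_threshold = 0.5)
}

## Process one locus: returns list(cands = list, features = data.frame,
## counters, restored_junctions = data.frame).
process_locus <- function(locus, n_samples, p) {
  present <- which(lengths(locus$frags) > 0L)
  if (length(present) == 0L) return(NULL)
  graphs <- lapply(present, function(j)
    augment_source_sink(build_graph(
      locus$frags[[j]], chrom = locus$chrom, strand = locus$strand,
      sample_id = j, min_junction_support = p$min_junction_support,
      merge_gap = p$bundle_gap)))
  nonempty <- vapply(graphs, function(g) nrow(g$vs) > 0L, logical(1))
  present <- present[nonempty]; graphs <- graphs[nonempty]
  if (length(present) == 0L) return(NULL)
  size_cap <- if (is.null(p$size_cap)) n_samples else p$size_cap
  clusters <- cluster_graphs(graphs, size_cap = size_cap,
                             min_similarity = p$min_similarity)
  all_cands <- list(); all_feats <- list()
  counters <- c(stage1 = 0L, stage2 = 0L, unbridged = 0L,
                restored = 0L, dropped_paths = 0L)
  restored <- list()
  for (cl in clusters) {
    members_raw <- graphs[cl]
    frags_by_member <- lapply(present[cl], function(j) locus$frags[[j]])
    nm <- length(members_raw)
    gm <- build_combined(frags_by_member, chrom = locus$chrom,
                         strand = locus$strand,
                         min_junction_support = p$min_junction_support,
                         merge_gap = p$bundle_gap)
    ## stage-1 failures rescued on the combined graph
    gmi <- graph_index(gm)
    rescued <- vector("list", nm)
    for (j in seq_len(nm)) {
      gi <- graph_index(members_raw[[j]])
      resc <- list()
      for (f in frags_by_member[[j]]) {
        b <- bridge_fragment(f, members_raw[[j]], gi, p$max_bridge_span)
        if (!is.null(b)) { counters["stage1"] <- counters["stage1"] + 1L; next }
        bm <- bridge_fragment(f, gm, gmi, p$max_bridge_span)
        if (!is.null(bm) && bm$paired) {
          counters["stage2"] <- counters["stage2"] + 1L
          resc[[length(resc) + 1L]] <- list(frag = f, gm_vseq = bm$vseq)
        } else counters["unbridged"] <- counters["unbridged"] + 1L
      }
      rescued[[j]] <- resc
    }
    members <- lapply(seq_len(nm), function(j) {
      if (length(rescued[[j]]) == 0L) return(members_raw[[j]])
      refined <- refine_graph(members_raw[[j]], frags_by_member[[j]],
                              rescued[[j]], gm,
                              min_junction_support = p$min_junction_support,
                              merge_gap = p$bundle_gap)
      new_j <- setdiff(apply(graph_junctions(refined)[, 1:2, drop = FALSE],
                             1L, paste, collapse = "-"),
                       apply(graph_junctions(members_raw[[j]])[, 1:2, drop = FALSE],
                             1L, paste, collapse = "-"))
      if (length(new_j))
        restored[[length(restored) + 1L]] <<-
          data.frame(sample = members_raw[[j]]$sample_id, junction = new_j)
      refined
    })
    br <- bridge_all(members, frags_by_member, gm, p$max_bridge_span)
    sup <- compute_supports(c(members, list(gm)), members,
                            max_ext = p$max_boundary_ext)
    decomp <- lapply(seq_len(nm), function(j)
      decompose_graph(members[[j]], sup[[j]], br$paths[[j]]))
    gm_cands <- decompose_graph(gm, sup[[nm + 1L]], br$gm_paths)
    counters["dropped_paths"] <- counters["dropped_paths"] +
      sum(vapply(decomp, function(d) attr(d, "dropped_paths"), numeric(1))) +
      attr(gm_cands, "dropped_paths")
    ## cross-side lookup: was the same chain assembled on the other side?
    gm_keys <- vapply(gm_cands, candidate_key, character(1))
    gm_ab <- vapply(gm_cands, function(t) t$abundance, numeric(1))
    ind_keys <- unlist(lapply(decomp, function(d)
      vapply(d, candidate_key, character(1))), use.names = FALSE)
    ind_ab <- unlist(lapply(decomp, function(d)
      vapply(d, function(t) t$abundance, numeric(1))), use.names = FALSE)
    locus_total_frags <- sum(lengths(frags_by_member))
    emit <- function(t, g, supports_g, locus_reads, other_keys, other_ab) {
      k <- candidate_key(t)
      hit <- !is.na(k) & other_keys == k
      other_abundance <- if (any(hit, na.rm = TRUE))
        max(other_ab[which(hit)]) else 0
      fv <- compute_features(t, g, gm, supports_g,
                             n_samples = nm, locus_reads = locus_reads,
                             other_abundance = other_abundance,
                             in_both = any(hit, na.rm = TRUE))
      all_cands[[length(all_cands) + 1L]] <<- t
      all_feats[[length(all_feats) + 1L]] <<- c(
        list(chain_key = if (is.na(k)) NA_character_ else k,
             chrom = t$chrom, strand = t$strand,
             start = t$exons[1L, 1L], end = t$exons[nrow(t$exons), 2L],
             n_exons = nrow(t$exons),
             origin = if (is.na(t$origin)) "combined"
                      else as.character(t$origin),
             abundance = t$abundance),
        as.list(fv))
    }
    for (j in seq_len(nm)) {
      for (t in decomp[[j]])
        emit(t, members[[j]], sup[[j]],
             length(frags_by_member[[j]]), gm_keys, gm_ab)
    }
    for (t in gm_cands)
      emit(t, gm, sup[[nm + 1L]], locus_total_frags, ind_keys, ind_ab)
  }
  counters["restored"] <- if (length(restored))
    sum(vapply(restored, nrow, integer(1))) else 0L
  feats <- if (length(all_feats))
    do.call(rbind, lapply(all_feats, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  else NULL
  list(cands = all_cands, features = feats, counters = counters,
       restored = if (length(restored)) do.call(rbind, restored) else NULL)
}

#' Assemble candidate transcripts from multi-sample alignments
#'
#' Runs the full pipeline up to (but excluding) scoring: every cluster
#' member graph and every combined graph is decomposed, and each
#' candidate transcript is characterized by its 50-feature vector.
#'
#' @param paths character vector of SAM/BAM files, one per sample, or a
#'   manifest file (see [read_manifest()]).
#' @param params list overriding pipeline defaults: `min_mapq`,
#'   `bundle_gap` (50), `min_junction_support` (1), `min_similarity`
#'   (0.1), `size_cap` (number of samples), `max_boundary_ext` (200),
#'   `max_bridge_span` (500000).
#' @param verbose log per-stage counters.
#' @return list with `cands` (candidate objects), `features`
#'   (data.frame: meta columns + 50 features), `counters`, `restored`
#'   (junctions restored by refinement), `n_samples`.
#' @export
assemble_candidates <- function(paths, params = list(), verbose = FALSE) {
  p <- utils::modifyList(default_params(), params)
  if (length(paths) == 1L && !grepl("\\.(sam|bam)$", paths, ignore.case = TRUE))
    paths <- read_manifest(paths)$path
  n_samples <- length(paths)
  frags <- list()
  for (s in seq_len(n_samples)) {
    reads <- parse_alignments(paths[s], sample_id = s, min_mapq = p$min_mapq)
    frags <- c(frags, pair_fragments(reads))
  }
  loci <- bundle_loci(frags, gap = p$bundle_gap, n_samples = n_samples)
  if (verbose)
    message(sprintf("%d samples, %d fragments, %d loci",
                    n_samples, length(frags), length(loci)))
  cands <- list(); feats <- list(); restored <- list()
  counters <- c(stage1 = 0L, stage2 = 0L, unbridged = 0L,
                restored = 0L, dropped_paths = 0L)
  for (lc in loci) {
    res <- process_locus(lc, n_samples, p)
    if (is.null(res)) next
    cands <- c(cands, res$cands)
    if (!is.null(res$features)) feats[[length(feats) + 1L]] <- res$features
    counters <- counters + res$counters
    if (!is.null(res$restored)) restored[[length(restored) + 1L]] <- res$restored
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  if (verbose)
    message(sprintf(
      "bridged stage1=%d stage2=%d unbridged=%d restored=%d candidates=%d",
      counters["stage1"], counters["stage2"], counters["unbridged"],
      counters["restored"], length(cands)))
  list(cands = cands, features = features, counters = counters,
       restored = if (length(restored)) do.call(rbind, restored) else NULL,
       n_samples = n_samples)
}

#' Assemble, score and emit meta-transcripts
#'
#' @param paths alignment files or a manifest (see
#'   [assemble_candidates()]).
#' @param model a `scoring_model`; when `NULL`, candidates are
#'   aggregated unscored (score 1 for every meta-transcript) so the
#'   output can still be inspected or ranked by abundance.
#' @param score_threshold minimum meta-transcript score to emit
#'   (default 0.5; 0.2 is the recommended floor).
#' @param out_gtf optional output GTF path.
#' @param params,verbose see [assemble_candidates()].
#' @return list with `metas` (all meta-transcripts), `emitted` (those
#'   passing the threshold), `asm` (the [assemble_candidates()] result)
#'   and `scores`.
#' @export
assemble <- function(paths, model = NULL, score_threshold = 0.5,
                     out_gtf = NULL, params = list(), verbose = FALSE) {
  asm <- assemble_candidates(paths, params = params, verbose = verbose)
  scores <- if (!is.null(model) && !is.null(asm$features))
    score_candidates(asm$features, model)
  else rep(1, length(asm$cands))
  metas <- aggregate_meta(asm$cands, scores)
  emitted <- filter_and_emit(metas,
                             threshold = if (is.null(model)) 0 else score_threshold,
                             path = out_gtf)
  if (verbose)
    message(sprintf("%d meta-transcripts, %d emitted at threshold %.2f",
                    length(metas), length(emitted), score_threshold))
  list(metas = metas, emitted = emitted, asm = asm, scores = scores)
}

#' Train a scoring model from alignments and an annotation
#'
#' Assembles candidates, labels them by exact intron-chain match
#' against the annotation, and fits the random forest.
#'
#' @param paths alignment files or a manifest.
#' @param annotation_gtf reference annotation used for labels.
#' @param seed forest seed.
#' @param params,verbose see [assemble_candidates()].
#' @param out_model optional path; when given the model is saved there
#'   with its JSON sidecar.
#' @return a `scoring_model`.
#' @export
train_assembler <- function(paths, annotation_gtf, seed = 1L,
                            params = list(), out_model = NULL,
                            verbose = FALSE) {
  asm <- assemble_candidates(paths, params = params, verbose = verbose)
  if (is.null(asm$features) || nrow(asm$features) == 0L)
    stop("no candidate transcripts assembled; cannot train")
  ann <- read_annotation(annotation_gtf)
  rows <- label_candidates(asm$features, ann)
  model <- train_model(rows, seed = seed)
  if (!is.null(out_model)) save_model(model, out_model)
  model
}

## Meta-transcripts as a data.frame (for evaluation and reporting).
meta_table <- function(metas) {
  if (length(metas) == 0L)
    return(data.frame(chain_key = character(0), chrom = character(0),
                      strand = character(0), score = numeric(0),
                      abundance = numeric(0), members = integer(0),
                      n_exons = integer(0)))
  data.frame(
    chain_key = vapply(metas, function(m)
      chain_key(m$chrom, m$strand, m$introns), character(1)),
    chrom = vapply(metas, function(m) m$chrom, character(1)),
    strand = vapply(metas, function(m) m$strand, character(1)),
    score = vapply(metas, function(m) m$score, numeric(1)),
    abundance = vapply(metas, function(m) m$abundance, numeric(1)),
    members = vapply(metas, function(m) m$members, integer(1)),
    n_exons = vapply(metas, function(m) nrow(m$exons), integer(1)),
    stringsAsFactors = FALSE)
}

#' Evaluate emitted meta-transcripts against a truth annotation
#'
#' @param metas list of meta-transcripts (from [assemble()]).
#' @param truth_gtf truth annotation path, or a data.frame from
#'   [read_annotation()].
#' @return list with `pr` (precision/recall at the given set),
#'   `table` (per-meta data.frame), `truth_keys`.
#' @export
evaluate_assembly <- function(metas, truth_gtf) {
  truth <- if (is.character(truth_gtf)) read_annotation(truth_gtf)
           else truth_gtf
  tab <- meta_table(metas)
  list(pr = precision_recall(tab$chain_key, truth$chain_key),
       table = tab, truth_keys = truth$chain_key)
}
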