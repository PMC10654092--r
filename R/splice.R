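# Contig-end prophage splicing: prophages interrupted by assembly breaks leave
# phage-like fragments at contig ends; these are located against a reference
# phage database, ordered along their best reference, and concatenated back
# into a single prophage sequence that inherits the reference's cluster.

#' Assemble a phage reference database
#'
#' @param sequences Named character vector or `DNAStringSet` of phage genomes.
#' @param clusters Tibble (`phage_id`, `cluster`) of cluster labels.
#' @param genes Optional gene table for the reference genomes (contig_id =
#'   phage_id), used by validators.
#' @return An object of class `phage_db`.
#' @export
phage_db <- function(sequences, clusters, genes = NULL) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (!length(sequences)) {
    abort("Phage database must contain at least one genome.",
          class = "prophagr_configuration_error")
  }
  clusters <- as_tibble(clusters)
  structure(list(sequences = toupper(sequences), clusters = clusters,
                 genes = genes),
            class = "phage_db")
}

#' @export
print.phage_db <- function(x, ...) {
  cat(sprintf("<phage_db> %d genome(s), %d cluster label(s)\n",
              length(x$sequences), length(unique(x$clusters$cluster))))
  invisible(x)
}

db_cluster_of <- function(db, phage_id) {
  row <- filter(db$clusters, .data$phage_id == .env$phage_id)
  if (!nrow(row) || is.na(row$cluster[1]) || !nzchar(row$cluster[1])) {
    abort(sprintf("Reference '%s' carries no cluster label.", phage_id),
          class = "prophagr_annotation_error")
  }
  row$cluster[1]
}

#' Find phage-like fragments at contig ends
#'
#' Aligns every contig against the phage database and keeps alignments that
#' (a) are at least `config$min_fragment_len_bp` long at
#' `config$min_alignment_identity`, and (b) lie within `config$end_margin_bp`
#' of a contig end. Alignments interior to long contigs are excluded (those
#' are ordinary whole-prophage calls, not assembly breaks). Overlapping
#' candidate alignments on a contig are grouped and each group keeps only its
#' best-scoring reference (identity x length).
#'
#' @param assembly A `genome_assembly`.
#' @param db A [phage_db()].
#' @param config A [pipeline_config()].
#' @return Tibble of fragments: `contig_id`, `frag_start`, `frag_end`,
#'   `reference_id`, `ref_start`, `ref_end`, `orientation`, `identity`,
#'   `end_distance`.
#' @export
find_end_fragments <- function(assembly, db, config = pipeline_config()) {
  if (!inherits(db, "phage_db")) {
    abort("`db` must be a phage_db.", class = "prophagr_configuration_error")
  }
  rows <- list()
  for (cid in names(assembly$contigs)) {
    cseq <- as.character(assembly$contigs[[cid]])
    clen <- nchar(cseq)
    aln <- find_local_alignments(cseq, db$sequences,
                                 min_len = config$min_fragment_len_bp,
                                 min_identity = config$min_alignment_identity,
                                 k = config$seed_k,
                                 max_seed_gap = config$max_seed_gap_bp,
                                 xdrop = config$xdrop, query_id = cid)
    if (!nrow(aln)) next
    aln <- aln %>%
      mutate(end_distance = pmin(.data$q_start - 1L, clen - .data$q_end)) %>%
      filter(.data$end_distance <= config$end_margin_bp)
    if (!nrow(aln)) next
    # group overlapping alignments on the contig; keep best reference per group
    aln <- arrange(aln, .data$q_start)
    grp <- cumsum(c(TRUE, aln$q_start[-1] > cummax(aln$q_end)[-nrow(aln)]))
    aln$grp <- grp
    best <- aln %>%
      group_by(.data$grp) %>%
      slice(which.max(.data$identity * .data$aln_length)) %>%
      ungroup()
    rows[[length(rows) + 1]] <- best %>%
      transmute(contig_id = cid,
                frag_start = .data$q_start, frag_end = .data$q_end,
                reference_id = .data$subject_id,
                ref_start = .data$s_start, ref_end = .data$s_end,
                orientation = .data$strand,
                identity = .data$identity,
                end_distance = .data$end_distance)
  }
  if (!length(rows)) {
    return(tibble(contig_id = character(), frag_start = integer(),
                  frag_end = integer(), reference_id = character(),
                  ref_start = integer(), ref_end = integer(),
                  orientation = character(), identity = numeric(),
                  end_distance = integer()))
  }
  bind_rows(rows)
}

#' Splice contig-end fragments into one prophage sequence
#'
#' Fragments sharing one reference are ordered by reference start,
#' reverse-orientation fragments are reverse-complemented, overlapping
#' reference coverage is trimmed from the later fragment (the earlier copy is
#' kept), and the pieces are concatenated without padding; gap extents are
#' recorded. Completeness is `complete_on_reference` when the union of
#' reference intervals covers at least 95% of the reference.
#'
#' @param fragments Fragment tibble (one reference) from
#'   [find_end_fragments()].
#' @param assembly The `genome_assembly` the fragments live on.
#' @param db The [phage_db()] providing reference lengths.
#' @param config A [pipeline_config()].
#' @return An object of class `spliced_prophage`: fragments (ordered),
#'   `sequence`, `reference_id`, `completeness`, `gaps_bp`, and slots for
#'   `cluster_label` / `validated`.
#' @export
splice_fragments <- function(fragments, assembly, db, config = pipeline_config()) {
  if (!nrow(fragments)) {
    abort("Need at least one fragment.", class = "prophagr_validation_error")
  }
  if (length(unique(fragments$reference_id)) != 1) {
    abort("Fragments map to different references; group per reference first.",
          class = "prophagr_grouping_error")
  }
  ref_id <- fragments$reference_id[1]
  ref_len <- nchar(db$sequences[[ref_id]])
  frs <- arrange(fragments, .data$ref_start, .data$ref_end)
  pieces <- character(nrow(frs))
  cov_end <- 0L; gaps <- integer(0)
  for (i in seq_len(nrow(frs))) {
    seq_i <- extract_subsequence(assembly, frs$contig_id[i],
                                 frs$frag_start[i], frs$frag_end[i],
                                 strand = frs$orientation[i])
    rs <- frs$ref_start[i]; re <- frs$ref_end[i]
    if (i > 1) {
      if (re <= cov_end) {
        # fully contained in earlier coverage: contributes nothing
        pieces[i] <- ""
        next
      }
      overlap <- cov_end - rs + 1L
      if (overlap > 0) {
        seq_i <- substr(seq_i, overlap + 1L, nchar(seq_i))
        rs <- rs + overlap
      } else if (overlap < 0) {
        gaps <- c(gaps, -overlap - 1L)
      }
    }
    pieces[i] <- seq_i
    cov_end <- max(cov_end, re)
  }
  # union coverage of the reference by fragment intervals
  iv <- frs[, c("ref_start", "ref_end")]
  iv <- arrange(iv, .data$ref_start)
  hi <- cummax(iv$ref_end)
  new_blk <- c(TRUE, iv$ref_start[-1] > hi[-nrow(iv)] + 1L)
  blk <- cumsum(new_blk)
  covered <- sum(tapply(iv$ref_end, blk, max) - tapply(iv$ref_start, blk, min) + 1L)
  completeness <- if (covered >= 0.95 * ref_len) "complete_on_reference" else "partial"
  structure(list(fragments = frs,
                 sequence = paste(pieces, collapse = ""),
                 reference_id = ref_id,
                 completeness = completeness,
                 gaps_bp = gaps,
                 cluster_label = NA_character_,
                 validated = NA),
            class = "spliced_prophage")
}

#' @export
print.spliced_prophage <- function(x, ...) {
  cat(sprintf("<spliced_prophage> %s: %d fragment(s), %s bp, %s\n",
              x$reference_id, nrow(x$fragments),
              format(nchar(x$sequence), big.mark = ","), x$completeness))
  invisible(x)
}

#' Assign a cluster to a spliced prophage from its reference
#'
#' Spliced prophages inherit the cluster label of the reference genome they
#' were ordered against, verbatim.
#'
#' @param spliced A `spliced_prophage`.
#' @param db A [phage_db()].
#' @return The input with `cluster_label` filled in.
#' @export
assign_cluster_from_reference <- function(spliced, db) {
  spliced$cluster_label <- db_cluster_of(db, spliced$reference_id)
  spliced
}

#' Validate a spliced prophage
#'
#' Any contract mapping (sequence, gene table) to accept/reject can stand in
#' for a full prophage caller here; see [profile_validator()] for the built-in
#' heuristic.
#'
#' @param spliced A `spliced_prophage`.
#' @param validator Function `(sequence, genes) -> logical(1)`.
#' @param genes Gene table for the spliced sequence (e.g. the reference's
#'   genes when the splice is complete).
#' @return The input with `validated` set.
#' @export
validate_spliced <- function(spliced, validator, genes) {
  verdict <- tryCatch(
    isTRUE(validator(spliced$sequence, genes)),
    error = function(e) {
      abort(sprintf("Validator failed on reference %s: %s",
                    spliced$reference_id, conditionMessage(e)),
            class = "prophagr_validator_error")
    })
  spliced$validated <- verdict
  spliced
}

#' Built-in heuristic prophage validator
#'
#' Accepts a sequence iff at least `min_fraction` of its annotated genes carry
#' a significant phage-archetype profile hit.
#'
#' @param profile_db List of `protein_profile`s.
#' @param config A [pipeline_config()].
#' @param min_fraction Acceptance fraction (default 0.5).
#' @return A validator function for [validate_spliced()].
#' @export
profile_validator <- function(profile_db, config = pipeline_config(),
                              min_fraction = 0.5) {
  arch <- Filter(function(p) p$category == "phage_archetype", profile_db)
  function(sequence, genes) {
    if (is.null(genes) || !nrow(genes)) return(FALSE)
    hits <- scan_profile_hits(genes, arch, threshold = config$profile_score_threshold)
    frac <- length(unique(hits$gene_id)) / nrow(genes)
    frac >= min_fraction
  }
}
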