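# Attachment-site machinery. Integrase-mediated recombination of attB (host)
# with attP (phage) duplicates a common core sequence as direct repeats (attL,
# attR) flanking the prophage. The core is recovered as the longest exact
# direct repeat spanning the prophage boundaries, occurrences from many
# strains are mapped onto one reference chromosome, overlapping occurrences
# are reduced to consensus attB sites, and attP is rebuilt by circularizing
# the prophage at the core.

lcs_positions <- function(left, right, len) {
  # leftmost occurrence pair of a shared substring of exactly `len`
  nl <- nchar(left); nr <- nchar(right)
  if (len > nl || len > nr) return(NULL)
  lsub <- substring(left, 1:(nl - len + 1), len:nl)
  rsub <- substring(right, 1:(nr - len + 1), len:nr)
  pos_r <- match(lsub, rsub)           # leftmost right-window occurrence
  i <- which(!is.na(pos_r))
  if (!length(i)) return(NULL)
  i <- i[1]                            # leftmost left-window occurrence
  c(l = i, r = pos_r[i])
}

has_shared_substring <- function(left, right, len) {
  !is.null(lcs_positions(left, right, len))
}

#' Find the attachment core at prophage boundaries
#'
#' Returns the longest exact direct repeat with one copy inside the window
#' `[left_boundary - boundary_search_bp, left_boundary + boundary_search_bp]`
#' and the other in the mirrored right-boundary window; ties are broken by the
#' leftmost attL copy, then the leftmost attR copy. Besides the
#' `min_core_len_bp` floor, the repeat must be long enough that the expected
#' number of chance repeats across the two windows stays below
#' `config$core_alpha` (a 10 bp repeat is shared by essentially any pair of
#' multi-kilobase windows); set `core_alpha = NULL` to disable that bound.
#'
#' @param assembly A `genome_assembly`.
#' @param contig_id Contig carrying the prophage.
#' @param start,end Prophage interval (1-based inclusive).
#' @param config A [pipeline_config()].
#' @return `NULL` if no qualifying repeat, else a list of class `att_core`:
#'   `sequence`, `length`, `attL_start`, `attL_end`, `attR_start`, `attR_end`
#'   (contig coordinates).
#' @export
find_core_repeats <- function(assembly, contig_id, start, end,
                              config = pipeline_config()) {
  if (!contig_id %in% names(assembly$contigs)) {
    abort(sprintf("Unknown contig '%s'.", contig_id), class = "prophagr_lookup_error")
  }
  clen <- contig_lengths(assembly)[[contig_id]]
  if (start < 1 || end > clen || end <= start) {
    abort("Prophage interval outside contig bounds.", class = "prophagr_range_error")
  }
  B <- config$boundary_search_bp
  lw_from <- max(1L, start - B); lw_to <- min(clen, start + B)
  rw_from <- max(1L, end - B);   rw_to <- min(clen, end + B)
  left <- extract_subsequence(assembly, contig_id, lw_from, lw_to)
  right <- extract_subsequence(assembly, contig_id, rw_from, rw_to)
  min_len <- config$min_core_len_bp
  if (!is.null(config$core_alpha)) {
    sig_len <- ceiling(log(as.numeric(nchar(left)) * nchar(right) /
                             config$core_alpha, base = 4))
    min_len <- max(min_len, as.integer(sig_len))
  }
  hi <- min(nchar(left), nchar(right))
  if (min_len > hi || !has_shared_substring(left, right, min_len)) return(NULL)
  # binary search the longest shared length in [min_len, hi]
  lo <- min_len
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (has_shared_substring(left, right, mid)) lo <- mid else hi <- mid - 1L
  }
  pos <- lcs_positions(left, right, lo)
  attL_start <- lw_from + pos[["l"]] - 1L
  attR_start <- rw_from + pos[["r"]] - 1L
  structure(list(
    sequence = substr(left, pos[["l"]], pos[["l"]] + lo - 1L),
    length = lo,
    attL_start = attL_start, attL_end = attL_start + lo - 1L,
    attR_start = attR_start, attR_end = attR_start + lo - 1L,
    contig_id = contig_id
  ), class = "att_core")
}

#' Map att occurrences from many strains onto a reference chromosome
#'
#' Each occurrence is placed by aligning its core plus `flank_bp` of upstream
#' host flank against the reference; placement uses the alignment diagonal so
#' the mapped core interval is exact even when flanking SNPs shave the
#' alignment edges. Occurrences with two or more equally good loci are flagged
#' ambiguous; occurrences with no qualifying alignment are unplaced.
#'
#' @param occurrences Tibble with `strain_id`, `core_seq`, `query_seq` (core +
#'   upstream flank, the core occupying the last `nchar(core_seq)` bases) --
#'   see [att_occurrence_query()].
#' @param reference A single-contig `genome_assembly` (closed chromosome).
#' @param config A [pipeline_config()].
#' @return Tibble: `strain_id`, `status` (`placed`/`ambiguous`/`unplaced`),
#'   `ref_start`, `ref_end` (core interval on the reference), `core_seq`.
#' @export
map_att_to_reference <- function(occurrences, reference,
                                 config = pipeline_config()) {
  if (contig_count(reference) != 1) {
    abort("Reference must be a single closed chromosome.",
          class = "prophagr_validation_error")
  }
  ref_id <- names(reference$contigs)[1]
  ref_seq <- setNames(as.character(reference$contigs[1]), ref_id)
  out <- vector("list", nrow(occurrences))
  for (i in seq_len(nrow(occurrences))) {
    q <- occurrences$query_seq[i]
    core_len <- nchar(occurrences$core_seq[i])
    aln <- find_local_alignments(
      q, ref_seq,
      min_len = max(config$seed_k, floor(0.8 * nchar(q))),
      min_identity = config$min_alignment_identity,
      k = config$seed_k, max_seed_gap = config$max_seed_gap_bp,
      xdrop = config$xdrop)
    aln <- filter(aln, .data$strand == "+")
    row <- tibble(strain_id = occurrences$strain_id[i], status = "unplaced",
                  ref_start = NA_integer_, ref_end = NA_integer_,
                  core_seq = occurrences$core_seq[i])
    if (nrow(aln)) {
      score <- aln$identity * aln$aln_length
      best <- which(score >= max(score) - 1e-9)
      if (length(best) > 1) {
        row$status <- "ambiguous"
      } else {
        a <- aln[best, ]
        offset <- a$s_start - a$q_start      # ungapped diagonal
        core_q_start <- nchar(q) - core_len + 1L
        row$status <- "placed"
        row$ref_start <- core_q_start + offset
        row$ref_end <- row$ref_start + core_len - 1L
      }
    }
    out[[i]] <- row
  }
  bind_rows(out)
}

#' Build the mapping query for an att occurrence
#'
#' Concatenates `flank_bp` of host sequence upstream of attL with the core
#' itself, the query form [map_att_to_reference()] expects.
#'
#' @param assembly Host `genome_assembly`.
#' @param core An `att_core`.
#' @param flank_bp Host flank length (default 200).
#' @return Character query sequence.
#' @export
att_occurrence_query <- function(assembly, core, flank_bp = 200L) {
  from <- max(1L, core$attL_start - flank_bp)
  extract_subsequence(assembly, core$contig_id, from, core$attL_end)
}

#' Consensus attB sites from mapped occurrences
#'
#' Occurrences on one reference are grouped into overlap-connected components
#' along the reference axis; each group's consensus interval is the
#' intersection of its member intervals (the conserved coordinate positions).
#' Groups are numbered attB-1, attB-2, ... by reference position. A
#' pathological chain whose intersection is empty is split at its largest
#' start-coordinate gap and both halves reported, with a warning.
#'
#' @param placed Tibble from [map_att_to_reference()] (status `"placed"` rows
#'   are used) with `strain_id`, `ref_start`, `ref_end`.
#' @return Tibble: `attB_id`, `ref_start`, `ref_end` (consensus interval),
#'   `n_occurrences`, list-column `occurrences` (member tibbles).
#' @export
consensus_attB <- function(placed) {
  placed <- filter(placed, .data$status == "placed") %>%
    arrange(.data$ref_start, .data$ref_end)
  if (!nrow(placed)) {
    return(tibble(attB_id = character(), ref_start = integer(),
                  ref_end = integer(), n_occurrences = integer(),
                  occurrences = list()))
  }
  hi <- cummax(placed$ref_end)
  new_grp <- c(TRUE, placed$ref_start[-1] > hi[-nrow(placed)])
  grp <- cumsum(new_grp)
  groups <- split(placed, grp)
  res <- list()
  for (g in groups) {
    cs <- max(g$ref_start); ce <- min(g$ref_end)
    if (cs > ce && nrow(g) > 1) {
      warn("Overlap chain with empty intersection; splitting at largest gap.")
      gaps <- diff(g$ref_start)
      cut <- which.max(gaps)
      res <- c(res, list(g[1:cut, ], g[(cut + 1):nrow(g), ]))
    } else {
      res <- c(res, list(g))
    }
  }
  out <- lapply(res, function(g) {
    tibble(ref_start = max(g$ref_start), ref_end = min(g$ref_end),
           n_occurrences = nrow(g), occurrences = list(g))
  }) %>% bind_rows() %>% arrange(.data$ref_start)
  out$attB_id <- sprintf("attB-%d", seq_len(nrow(out)))
  select(out, "attB_id", "ref_start", "ref_end", "n_occurrences", "occurrences")
}

#' Reconstruct attP by circularizing a prophage at its core
#'
#' The prophage sequence must begin and end with the core copies (attL ...
#' attR inclusive). The excised circle is linearized at the recombination
#' junction: one core copy followed by the internal phage sequence, so the
#' output length is the prophage length minus one core length. The attP
#' region is the core with `flank_bp` of phage-side flank on each side.
#'
#' @param prophage_seq Prophage DNA (attL through attR).
#' @param core An `att_core` (or a list with `sequence`).
#' @param flank_bp Phage-side flank for the attP region (default 250).
#' @return List: `sequence` (linearized circle), `attP_region`, `core_seq`.
#' @export
reconstruct_attP <- function(prophage_seq, core, flank_bp = 250L) {
  core_seq <- core$sequence
  cl <- nchar(core_seq)
  L <- nchar(prophage_seq)
  if (substr(prophage_seq, 1, cl) != core_seq ||
      substr(prophage_seq, L - cl + 1L, L) != core_seq) {
    abort("Prophage sequence does not begin and end with the att core.",
          class = "prophagr_consistency_error")
  }
  internal <- substr(prophage_seq, cl + 1L, L - cl)
  circle <- paste0(core_seq, internal)
  ilen <- nchar(internal)
  fl <- min(flank_bp, ilen)
  attP_region <- paste0(substr(internal, ilen - fl + 1L, ilen),
                        core_seq,
                        substr(internal, 1, fl))
  list(sequence = circle, attP_region = attP_region, core_seq = core_seq)
}

#' In-silico site-specific integration
#'
#' Integrates a circular phage (linearized with the core first, as produced by
#' [reconstruct_attP()]) into a host sequence at an attB whose core equals the
#' phage core, regenerating attL and attR. The inverse of excision: for any
#' lysogen, excising with [reconstruct_attP()] and reintegrating at the same
#' attB restores the original sequence exactly.
#'
#' @param host_seq Host DNA containing the attB core.
#' @param attB_start 1-based start of the core occurrence in `host_seq`.
#' @param circle_seq Linearized circle (core + internal sequence).
#' @param core_seq The shared core.
#' @return The integrated (lysogen) sequence.
#' @export
integrate_at_attB <- function(host_seq, attB_start, circle_seq, core_seq) {
  cl <- nchar(core_seq)
  if (substr(host_seq, attB_start, attB_start + cl - 1L) != core_seq) {
    abort("Host does not carry the att core at `attB_start`.",
          class = "prophagr_consistency_error")
  }
  if (substr(circle_seq, 1, cl) != core_seq) {
    abort("Circle must be linearized with the core first.",
          class = "prophagr_consistency_error")
  }
  internal <- substr(circle_seq, cl + 1L, nchar(circle_seq))
  paste0(substr(host_seq, 1, attB_start - 1L),
         core_seq, internal, core_seq,
         substr(host_seq, attB_start + cl, nchar(host_seq)))
}

#' Annotate attB overlap with tRNA/tmRNA features
#'
#' Reports the host RNA feature (tRNA with isotype/anticodon, or tmRNA) each
#' consensus attB overlaps by at least 1 bp; ties go to the largest overlap.
#'
#' @param attB Tibble from [consensus_attB()].
#' @param features Feature tibble: `feature_id`, `type` (`tRNA`/`tmRNA`),
#'   `isotype` (e.g. `"tRNA-Arg"` or `"tmRNA"`), `start`, `end`.
#' @return `attB` with `overlap_feature` (isotype or `NA`) added.
#' @export
annotate_overlap <- function(attB, features) {
  attB$overlap_feature <- vapply(seq_len(nrow(attB)), function(i) {
    if (is.null(features) || !nrow(features)) return(NA_character_)
    ov <- pmin(features$end, attB$ref_end[i]) -
      pmax(features$start, attB$ref_start[i]) + 1L
    j <- which(ov >= 1L)
    if (!length(j)) return(NA_character_)
    features$isotype[j[which.max(ov[j])]]
  }, character(1))
  attB
}
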