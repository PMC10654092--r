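# Sliding-window discovery of phage-like genomic regions. A window of
# `window_size_genes` consecutive genes qualifies when it contains at least
# one significant profile hit; the union of qualifying windows is merged into
# maximal runs of gene ranks, and each merged run becomes one region that is
# then classified from the categories of its hits:
#   integrated_element  -- integrase or transposase hit, outside any accepted
#                          prophage call
#   phage_related       -- any archetypal phage gene (incl. major capsid)
#   candidate_PICI      -- both integration machinery and a major capsid gene
#   defective_prophage  -- nucleotide similarity to an intact phage (separate
#                          evidence pass, see flag_defective())

#' Scan one contig's genes with a sliding window
#'
#' @param genes Gene table for a single contig (rank-ordered; see
#'   [as_gene_table()]).
#' @param hits Profile-hit tibble (`gene_id`, `category`, `significant`);
#'   only significant hits count.
#' @param window_size Window width in genes (default 15).
#' @param extent `"window_union"` (default): a region spans every qualifying
#'   window, so a lone hit yields up to `2*window - 1` genes, clipped at
#'   contig ends. `"hit_bounded"`: the region is clipped to its first/last
#'   hit-bearing gene.
#' @return Tibble of regions: `contig_id`, `rank_from`, `rank_to` (inclusive
#'   gene ranks), `start`, `end` (bp, 1-based inclusive, first gene's start to
#'   last gene's end), `n_hit_genes`, and a list-column `hit_gene_ids`.
#' @export
scan_regions <- function(genes, hits, window_size = 15L,
                         extent = c("window_union", "hit_bounded")) {
  extent <- match.arg(extent)
  if (window_size < 1) {
    abort("`window_size` must be >= 1.", class = "prophagr_validation_error")
  }
  if (length(unique(genes$contig_id)) > 1) {
    abort("scan_regions() operates on one contig at a time.",
          class = "prophagr_validation_error")
  }
  empty <- tibble(contig_id = character(), rank_from = integer(),
                  rank_to = integer(), start = integer(), end = integer(),
                  n_hit_genes = integer(), hit_gene_ids = list())
  if (!nrow(genes)) return(empty)
  hits <- filter(hits, .data$significant)
  unknown <- setdiff(hits$gene_id, genes$gene_id)
  if (length(unknown)) {
    abort(sprintf("Hits reference gene id(s) absent from this contig: %s",
                  paste(head(unknown, 3), collapse = ", ")),
          class = "prophagr_validation_error")
  }
  hit_ranks <- sort(unique(genes$rank[genes$gene_id %in% hits$gene_id]))
  if (!length(hit_ranks)) return(empty)
  n <- max(genes$rank)
  w <- min(window_size, n)
  # union of qualifying windows: every window containing a hit rank r spans
  # [max(1, r - w + 1), min(n, r + w - 1)]
  lo <- pmax(1L, hit_ranks - w + 1L)
  hi <- pmin(n, hit_ranks + w - 1L)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  run_hi <- cummax(hi)
  new_run <- c(TRUE, lo[-1] > run_hi[-length(lo)] + 1L)
  run <- cumsum(new_run)
  rank_from <- as.integer(tapply(lo, run, min))
  rank_to <- as.integer(tapply(hi, run, max))
  if (extent == "hit_bounded") {
    rank_from <- vapply(seq_along(rank_from), function(i) {
      min(hit_ranks[hit_ranks >= rank_from[i] & hit_ranks <= rank_to[i]])
    }, integer(1))
    rank_to <- vapply(seq_along(rank_to), function(i) {
      max(hit_ranks[hit_ranks >= rank_from[i] & hit_ranks <= rank_to[i]])
    }, integer(1))
  }
  by_rank <- genes[order(genes$rank), ]
  tibble(
    contig_id = genes$contig_id[1],
    rank_from = rank_from,
    rank_to = rank_to,
    start = by_rank$start[rank_from],
    end = by_rank$end[rank_to],
    n_hit_genes = vapply(seq_along(rank_from), function(i) {
      sum(hit_ranks >= rank_from[i] & hit_ranks <= rank_to[i])
    }, integer(1)),
    hit_gene_ids = lapply(seq_along(rank_from), function(i) {
      by_rank$gene_id[intersect(rank_from[i]:rank_to[i], hit_ranks)]
    })
  )
}

region_classes <- function(categories, overlaps_prophage) {
  cls <- character(0)
  has_int <- any(categories %in% c("integrase", "transposase"))
  has_cap <- "major_capsid" %in% categories
  has_phage <- any(categories %in% c("phage_archetype", "major_capsid"))
  if (has_int && !overlaps_prophage) cls <- c(cls, "integrated_element")
  if (has_phage) cls <- c(cls, "phage_related")
  if (any(categories == "integrase") && has_cap) cls <- c(cls, "candidate_PICI")
  cls
}

#' Classify phage-like regions
#'
#' Applies the category rules to each region: regions with an integrase or
#' transposase are integrated elements (excluding regions overlapping an
#' accepted prophage call); regions with one or more archetypal phage genes
#' are phage-related; regions with both integration machinery and a major
#' capsid gene are candidate PICIs. Classes may co-occur.
#'
#' @param regions Output of [scan_regions()] (any number of contigs bound
#'   together).
#' @param hits Profile-hit tibble (`gene_id`, `category`, `significant`).
#' @param prophage_calls Optional tibble of accepted calls (`contig_id`,
#'   `start`, `end`) used for the prophage-exclusion rule.
#' @return `regions` with a list-column `classes` added.
#' @export
classify_regions <- function(regions, hits, prophage_calls = NULL) {
  hits <- filter(hits, .data$significant)
  cats <- split(hits$category, hits$gene_id)
  regions$classes <- lapply(seq_len(nrow(regions)), function(i) {
    ids <- regions$hit_gene_ids[[i]]
    categories <- unique(unlist(cats[ids], use.names = FALSE))
    ovl <- FALSE
    if (!is.null(prophage_calls) && nrow(prophage_calls)) {
      same <- filter(prophage_calls, .data$contig_id == regions$contig_id[i])
      ovl <- any(same$start <= regions$end[i] & same$end >= regions$start[i])
    }
    region_classes(categories, ovl)
  })
  regions
}

#' Flag a region as a likely defective prophage
#'
#' A phage-like region is a likely defective prophage when its sequence has
#' significant nucleotide alignment to one or more intact phage genomes. The
#' same operation pointed at a phiRv1/phiRv2 reference set identifies
#' phiRv-like elements.
#'
#' @param region_seq DNA sequence of the region.
#' @param db A [phage_db()] of intact phage genomes.
#' @param config A [pipeline_config()]; `min_alignment_len_bp` /
#'   `min_alignment_identity` define significance.
#' @return List with `defective` (logical) and `nt_evidence` (alignment
#'   tibble).
#' @export
flag_defective <- function(region_seq, db, config = pipeline_config()) {
  ev <- find_local_alignments(region_seq, db$sequences,
                              min_len = config$min_alignment_len_bp,
                              min_identity = config$min_alignment_identity,
                              k = config$seed_k,
                              max_seed_gap = config$max_seed_gap_bp,
                              xdrop = config$xdrop)
  list(defective = nrow(ev) > 0, nt_evidence = ev)
}

#' Quality-filter prophage calls
#'
#' Omits calls that are truncated by contig ends (a boundary within
#' `truncation_margin_bp` of a contig end with no attachment core found) or
#' that contain excess bacterial sequence (fraction of genes with significant
#' phage-archetype hits below `bacterial_contamination_threshold`). Omitted
#' calls are retained with `status = "omitted"` and a reason.
#'
#' @param calls Call tibble with `designation`, `contig_id`, `start`, `end`
#'   and logical `has_core` (att core found at the boundaries).
#' @param assembly The `genome_assembly`.
#' @param genes Gene table for the assembly.
#' @param hits Profile-hit tibble.
#' @param config A [pipeline_config()].
#' @return `calls` with `status` (`"kept"`/`"omitted"`), `omit_reason`, and
#'   `phage_gene_fraction` columns.
#' @export
filter_prophage_calls <- function(calls, assembly, genes, hits,
                                  config = pipeline_config()) {
  if (!nrow(calls)) {
    return(mutate(calls, status = character(0), omit_reason = character(0),
                  phage_gene_fraction = numeric(0)))
  }
  clens <- contig_lengths(assembly)
  arch_hits <- filter(hits, .data$significant, .data$category == "phage_archetype")
  res <- calls
  res$phage_gene_fraction <- NA_real_
  res$status <- "kept"
  res$omit_reason <- NA_character_
  for (i in seq_len(nrow(res))) {
    clen <- clens[[res$contig_id[i]]]
    near_end <- (res$start[i] - 1L) <= config$truncation_margin_bp ||
      (clen - res$end[i]) <= config$truncation_margin_bp
    has_core <- isTRUE(res$has_core[i])
    g <- filter(genes, .data$contig_id == res$contig_id[i],
                .data$start >= res$start[i], .data$end <= res$end[i])
    frac <- if (nrow(g)) {
      sum(g$gene_id %in% arch_hits$gene_id) / nrow(g)
    } else 0
    res$phage_gene_fraction[i] <- frac
    if (near_end && !has_core) {
      res$status[i] <- "omitted"; res$omit_reason[i] <- "truncated_by_contig_end"
    } else if (frac < config$bacterial_contamination_threshold) {
      res$status[i] <- "omitted"; res$omit_reason[i] <- "excess_bacterial_sequence"
    }
  }
  res
}

#' Deduplicate prophage calls by sequence
#'
#' Calls are grouped by exact strand-normalized sequence identity (the
#' lexicographically smaller of a sequence and its reverse complement); one
#' representative per group (smallest designation) with multiplicities.
#'
#' @param calls Tibble with `designation` and `sequence`.
#' @return List with `unique` (representative calls, plus `multiplicity`) and
#'   `multiplicity_table` (`canonical_id`, `designation`).
#' @export
dedupe_prophages <- function(calls) {
  if (!nrow(calls)) {
    return(list(unique = mutate(calls, multiplicity = integer(0)),
                multiplicity_table = tibble(canonical_id = character(),
                                            designation = character())))
  }
  canon <- vapply(calls$sequence, function(s) {
    rc <- revcomp(s)
    if (s <= rc) s else rc
  }, character(1), USE.NAMES = FALSE)
  calls$canonical <- canon
  groups <- calls %>%
    group_by(.data$canonical) %>%
    mutate(multiplicity = n(),
           canonical_id = min(.data$designation)) %>%
    ungroup()
  uniq <- groups %>%
    filter(.data$designation == .data$canonical_id) %>%
    select(-"canonical") %>%
    arrange(.data$designation)
  list(unique = uniq,
       multiplicity_table = select(groups, "canonical_id", "designation") %>%
         arrange(.data$canonical_id, .data$designation))
}
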