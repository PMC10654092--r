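# Orchestration: wires the discovery stages end to end -- prophage calling
# against the reference database, att-core boundary refinement, QC filtering,
# contig-end splicing, deduplication, region scanning/classification, attB
# consensus, phamily construction and PEST mining -- and aggregates the
# corpus-level reports.

#' Alignment-backed prophage caller
#'
#' Calls prophages on one assembly by chaining local alignments to each
#' reference genome (same contig, same strand, contig gaps up to
#' `call_max_gap_bp`) and keeping chains covering at least
#' `call_min_coverage` of the reference; overlapping calls to different
#' references keep the best (coverage x identity). Boundaries are then
#' refined to the att-core direct repeats when [find_core_repeats()] locates
#' them.
#'
#' @param assembly A `genome_assembly`.
#' @param db A [phage_db()].
#' @param config A [pipeline_config()].
#' @return Call tibble: `contig_id`, `start`, `end`, `reference_id`,
#'   `coverage`, `identity`, `has_core`, `core` (list-column).
#' @export
call_prophages <- function(assembly, db, config = pipeline_config()) {
  rows <- list()
  for (cid in names(assembly$contigs)) {
    cseq <- as.character(assembly$contigs[[cid]])
    aln <- find_local_alignments(cseq, db$sequences,
                                 min_len = config$min_fragment_len_bp,
                                 min_identity = config$min_alignment_identity,
                                 k = config$seed_k,
                                 max_seed_gap = config$max_seed_gap_bp,
                                 xdrop = config$xdrop, query_id = cid)
    if (!nrow(aln)) next
    for (sid in unique(aln$subject_id)) {
      ref_len <- nchar(db$sequences[[sid]])
      for (st in unique(aln$strand[aln$subject_id == sid])) {
        sub <- aln %>%
          filter(.data$subject_id == sid, .data$strand == st) %>%
          arrange(.data$q_start)
        gap_break <- c(TRUE, sub$q_start[-1] - cummax(sub$q_end)[-nrow(sub)] >
                         config$call_max_gap_bp)
        chain <- cumsum(gap_break)
        for (ch in unique(chain)) {
          cc <- sub[chain == ch, ]
          iv <- arrange(cc[, c("s_start", "s_end")], .data$s_start)
          hi <- cummax(iv$s_end)
          blk <- cumsum(c(TRUE, iv$s_start[-1] > hi[-nrow(iv)] + 1L))
          covered <- sum(tapply(iv$s_end, blk, max) - tapply(iv$s_start, blk, min) + 1L)
          coverage <- covered / ref_len
          if (coverage < config$call_min_coverage) next
          rows[[length(rows) + 1]] <- tibble(
            contig_id = cid,
            start = min(cc$q_start), end = max(cc$q_end),
            reference_id = sid, coverage = coverage,
            identity = sum(cc$identity * cc$aln_length) / sum(cc$aln_length))
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble(contig_id = character(), start = integer(), end = integer(),
                  reference_id = character(), coverage = numeric(),
                  identity = numeric(), has_core = logical(), core = list()))
  }
  calls <- bind_rows(rows)
  # resolve overlapping calls on a contig: best coverage x identity wins
  calls <- calls %>%
    mutate(score = .data$coverage * .data$identity) %>%
    arrange(.data$contig_id, desc(.data$score))
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(calls)) > i &
                 calls$contig_id == calls$contig_id[i] &
                 calls$start <= calls$end[i] & calls$end >= calls$start[i])
    keep[j] <- FALSE
  }
  calls <- calls[keep, ] %>% select(-"score")
  # att-core boundary refinement
  calls$has_core <- FALSE
  calls$core <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    core <- find_core_repeats(assembly, calls$contig_id[i],
                              calls$start[i], calls$end[i], config)
    if (!is.null(core) &&
        abs(core$attL_start - calls$start[i]) <= config$core_max_shift_bp &&
        abs(core$attR_end - calls$end[i]) <= config$core_max_shift_bp) {
      calls$start[i] <- core$attL_start
      calls$end[i] <- core$attR_end
      calls$has_core[i] <- TRUE
      calls$core[[i]] <- core
    }
  }
  arrange(calls, .data$contig_id, .data$start)
}

assign_designations <- function(calls, assembly) {
  ord <- order(match(calls$contig_id, names(assembly$contigs)), calls$start)
  calls <- calls[ord, ]
  calls$designation <- make_designation(assembly$taxon_id, assembly$strain_id,
                                        seq_len(nrow(calls)))
  calls
}

#' Run the full discovery pipeline over a corpus
#'
#' Executes, per assembly: alignment-backed prophage calling with att-core
#' boundary refinement, quality filtering (truncation / bacterial
#' contamination), contig-end fragment splicing with cluster assignment and
#' validation, and region scanning/classification with defective-prophage
#' evidence; then corpus-wide: sequence-level deduplication, consensus attB
#' derivation on the reference chromosome, phamily construction over all
#' genes (assemblies plus reference phages), genome clustering of reference
#' phages and unique prophages, the proteome network, and PEST cassette
#' mining. Deterministic for fixed inputs.
#'
#' @param assemblies Named list of `genome_assembly` objects.
#' @param db A [phage_db()] (reference phages with cluster labels and gene
#'   table).
#' @param profile_db Named list of `protein_profile`s.
#' @param genes Gene table for all assemblies (with `genome_id`).
#' @param config A [pipeline_config()].
#' @param reference Optional single-contig reference `genome_assembly` for
#'   attB mapping.
#' @param reference_features Optional tRNA/tmRNA feature table on the
#'   reference (for attB overlap annotation).
#' @return An object of class `prophage_report` (a list of tibbles; see the
#'   package vignette).
#' @export
run_pipeline <- function(assemblies, db, profile_db, genes,
                         config = pipeline_config(),
                         reference = NULL, reference_features = NULL) {
  set.seed(config$rng_seed)
  genes <- as_tibble(genes)
  hits <- scan_profile_hits(genes, profile_db,
                            threshold = config$profile_score_threshold)
  per_genome_calls <- list()
  spliced_all <- list()
  regions_all <- list()
  failures <- list()
  for (aid in names(assemblies)) {
    asm <- assemblies[[aid]]
    g_asm <- filter(genes, .data$genome_id == aid)
    res <- tryCatch({
      calls <- call_prophages(asm, db, config)
      calls <- assign_designations(calls, asm)
      calls <- filter_prophage_calls(calls, asm, g_asm, hits, config)
      calls$sequence <- vapply(seq_len(nrow(calls)), function(i) {
        extract_subsequence(asm, calls$contig_id[i], calls$start[i], calls$end[i])
      }, character(1))
      calls$cluster_label <- db$clusters$cluster[
        match(calls$reference_id, db$clusters$phage_id)]
      calls$genome_id <- aid

      frags <- find_end_fragments(asm, db, config)
      spliced <- list()
      if (nrow(frags)) {
        for (rid in unique(frags$reference_id)) {
          fr <- filter(frags, .data$reference_id == rid)
          sp <- splice_fragments(fr, asm, db, config)
          sp <- assign_cluster_from_reference(sp, db)
          ref_genes <- filter(db$genes, .data$genome_id == rid)
          sp <- validate_spliced(sp, profile_validator(profile_db, config),
                                 ref_genes)
          sp$genome_id <- aid
          spliced[[length(spliced) + 1]] <- sp
        }
      }

      kept <- filter(calls, .data$status == "kept")
      regions <- list()
      for (cid in names(asm$contigs)) {
        g_c <- filter(g_asm, .data$contig_id == cid)
        if (!nrow(g_c)) next
        h_c <- semi_join(hits, g_c, by = "gene_id")
        reg <- scan_regions(g_c, h_c, window_size = config$window_size_genes,
                            extent = config$region_extent)
        if (!nrow(reg)) next
        reg <- classify_regions(reg, h_c, kept)
        reg$defective <- FALSE
        reg$overlaps_prophage <- FALSE
        for (i in seq_len(nrow(reg))) {
          reg$overlaps_prophage[i] <- any(
            kept$contig_id == cid &
              kept$start <= reg$end[i] & kept$end >= reg$start[i])
          rseq <- extract_subsequence(asm, cid, reg$start[i], reg$end[i])
          reg$defective[i] <- flag_defective(rseq, db, config)$defective
        }
        reg$genome_id <- aid
        regions[[length(regions) + 1]] <- reg
      }
      list(calls = calls, spliced = spliced,
           regions = if (length(regions)) bind_rows(regions) else NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[aid]] <- conditionMessage(res)
      next
    }
    per_genome_calls[[aid]] <- res$calls
    spliced_all <- c(spliced_all, res$spliced)
    if (!is.null(res$regions)) regions_all[[aid]] <- res$regions
  }
  calls <- bind_rows(per_genome_calls)
  if (!nrow(calls)) {
    calls <- tibble(contig_id = character(), start = integer(),
                    end = integer(), reference_id = character(),
                    coverage = numeric(), identity = numeric(),
                    has_core = logical(), core = list(),
                    designation = character(), status = character(),
                    omit_reason = character(), phage_gene_fraction = numeric(),
                    sequence = character(), cluster_label = character(),
                    genome_id = character())
  }
  kept <- filter(calls, .data$status == "kept")
  dedup <- dedupe_prophages(kept)
  regions <- if (length(regions_all)) bind_rows(regions_all) else
    tibble(contig_id = character(), rank_from = integer(), rank_to = integer(),
           start = integer(), end = integer(), n_hit_genes = integer(),
           hit_gene_ids = list(), classes = list(), defective = logical(),
           overlaps_prophage = logical(), genome_id = character())

  # attB machinery on the reference chromosome
  att <- list(occurrences = NULL, consensus = NULL)
  if (!is.null(reference) && nrow(kept)) {
    with_core <- filter(kept, .data$has_core)
    if (nrow(with_core)) {
      occ <- tibble(
        strain_id = with_core$genome_id,
        core_seq = vapply(with_core$core, function(x) x$sequence, character(1)),
        query_seq = vapply(seq_len(nrow(with_core)), function(i) {
          att_occurrence_query(assemblies[[with_core$genome_id[i]]],
                               with_core$core[[i]])
        }, character(1)))
      placed <- map_att_to_reference(occ, reference, config)
      cons <- consensus_attB(placed)
      if (!is.null(reference_features)) {
        cons <- annotate_overlap(cons, reference_features)
      }
      att <- list(occurrences = placed, consensus = cons)
    }
  }

  # phamilies over assembly genes plus the reference phages
  pham_input <- bind_rows(
    genes[, c("gene_id", "protein", "genome_id")],
    db$genes[, c("gene_id", "protein", "genome_id")])
  phams <- build_phams(pham_input,
                       identity_threshold = config$protein_cluster_identity,
                       coverage_threshold = config$protein_cluster_coverage)

  # genome clustering: reference phages + unique prophages
  pham_by_gene <- phams$phams
  proteome_ids <- list()
  for (i in seq_len(nrow(dedup$unique))) {
    u <- dedup$unique[i, ]
    g_u <- filter(genes, .data$genome_id == u$genome_id,
                  .data$contig_id == u$contig_id,
                  .data$start >= u$start, .data$end <= u$end)
    proteome_ids[[u$designation]] <- g_u$gene_id
  }
  for (rid in unique(db$genes$genome_id)) {
    proteome_ids[[rid]] <- db$genes$gene_id[db$genes$genome_id == rid]
  }
  genome_phams <- bind_rows(lapply(names(proteome_ids), function(gid) {
    tibble(genome_id = gid,
           pham_id = pham_by_gene$pham_id[
             match(proteome_ids[[gid]], pham_by_gene$gene_id)])
  })) %>% filter(!is.na(.data$pham_id))
  clusters <- assign_clusters(genome_phams, threshold = config$cluster_threshold,
                              metric = config$sgc_metric)
  network <- build_proteome_network(genome_phams,
                                    threshold = config$network_threshold,
                                    metric = config$sgc_metric)

  # PEST mining over all assembly genes
  gene_phams <- genes %>%
    left_join(pham_by_gene[, c("gene_id", "pham_id")], by = "gene_id")
  roles <- seed_pest_homologs(pham_by_gene, genes[, c("gene_id", "protein")],
                              profile_db, config, hits = hits)
  pt_phams <- roles$pham_id[roles$role == "PT"]
  pest_network <- build_neighborhood_network(
    gene_phams, pt_phams, radius = config$neighborhood_radius_orfs,
    expansion = config$pest_expansion)
  cassettes <- extract_cassettes(gene_phams, roles)
  pt_members <- gene_phams %>%
    filter(.data$pham_id %in% pt_phams) %>%
    select(pham_id = "pham_id", protein = "protein")
  superfamilies <- group_superfamilies(pt_members, config)
  cassettes <- cassettes %>%
    mutate(pt_pham = gene_phams$pham_id[match(.data$pt_gene_id, gene_phams$gene_id)]) %>%
    left_join(superfamilies, by = c(pt_pham = "pham_id"))

  structure(list(
    calls = calls, kept = kept,
    omitted = filter(calls, .data$status == "omitted"),
    unique_prophages = dedup$unique,
    multiplicity = dedup$multiplicity_table,
    spliced = spliced_all,
    regions = regions,
    att_occurrences = att$occurrences,
    attB = att$consensus,
    phams = phams,
    clusters = clusters,
    proteome_network = network,
    pest_roles = roles,
    pest_network = pest_network,
    cassettes = cassettes,
    superfamilies = superfamilies,
    failures = failures,
    config = config),
    class = "prophage_report")
}

#' @export
print.prophage_report <- function(x, ...) {
  cat("<prophage_report>\n")
  cat(sprintf("  prophage calls: %d (%d kept, %d omitted; %d unique)\n",
              nrow(x$calls), nrow(x$kept), nrow(x$omitted),
              nrow(x$unique_prophages)))
  cat(sprintf("  spliced prophages: %d\n", length(x$spliced)))
  cat(sprintf("  regions: %d; consensus attB sites: %d\n",
              nrow(x$regions), if (is.null(x$attB)) 0L else nrow(x$attB)))
  cat(sprintf("  phams: %d; PEST cassettes: %d\n",
              nrow(x$phams$representatives), nrow(x$cassettes)))
  if (length(x$failures)) {
    cat(sprintf("  failed genomes: %s\n", paste(names(x$failures), collapse = ", ")))
  }
  invisible(x)
}

#' Summarize prophage discovery per group
#'
#' Per-group genome counts, genomes with at least one kept prophage, prophage
#' totals, means and unique counts, with a totals row equal to the column
#' sums.
#'
#' @param report A `prophage_report`.
#' @param grouping Named character vector mapping `genome_id` to a group
#'   label.
#' @return Tibble with one row per group plus a `Totals` row.
#' @export
summarize_corpus <- function(report, grouping) {
  ids <- names(grouping)
  if (length(setdiff(unique(report$kept$genome_id), ids))) {
    abort("Grouping lacks labels for some genomes.",
          class = "prophagr_validation_error")
  }
  per_genome <- tibble(genome_id = ids, group = unname(grouping)) %>%
    left_join(count(report$kept, .data$genome_id, name = "n_prophages"),
              by = "genome_id") %>%
    mutate(n_prophages = tidyr::replace_na(.data$n_prophages, 0L))
  uniq <- report$unique_prophages
  per_group <- per_genome %>%
    group_by(.data$group) %>%
    summarise(n_genomes = n(),
              n_with_prophage = sum(.data$n_prophages >= 1),
              mean_prophages = mean(.data$n_prophages),
              n_prophages = sum(.data$n_prophages),
              .groups = "drop") %>%
    select("group", "n_genomes", "n_with_prophage", "n_prophages",
           "mean_prophages")
  uniq_counts <- tibble(genome_id = uniq$genome_id) %>%
    mutate(group = grouping[.data$genome_id]) %>%
    count(.data$group, name = "n_unique")
  per_group <- left_join(per_group, uniq_counts, by = "group") %>%
    mutate(n_unique = tidyr::replace_na(.data$n_unique, 0L))
  totals <- tibble(group = "Totals",
                   n_genomes = sum(per_group$n_genomes),
                   n_with_prophage = sum(per_group$n_with_prophage),
                   n_prophages = sum(per_group$n_prophages),
                   mean_prophages = sum(per_group$n_prophages) /
                     sum(per_group$n_genomes),
                   n_unique = sum(per_group$n_unique))
  bind_rows(per_group, totals)
}

#' Write a report bundle to disk
#'
#' Emits the tabular reports as TSV, prophage and spliced sequences as FASTA,
#' and regions as GFF3, under one directory; byte-identical across reruns
#' with identical inputs.
#'
#' @param report A `prophage_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drop_cols <- function(x, cols) x[, setdiff(names(x), cols)]
  write_tsv_report(drop_cols(report$calls, c("core")),
                   file.path(dir, "prophage_calls.tsv"))
  write_tsv_report(drop_cols(report$unique_prophages, c("core")),
                   file.path(dir, "unique_prophages.tsv"))
  if (nrow(report$kept)) {
    write_fasta(setNames(report$kept$sequence, report$kept$designation),
                file.path(dir, "prophages.fasta"))
  }
  if (length(report$spliced)) {
    sp_seqs <- vapply(report$spliced, function(s) s$sequence, character(1))
    names(sp_seqs) <- vapply(report$spliced, function(s) {
      sprintf("%s|%s|%s|%d_fragments", s$genome_id, s$reference_id,
              s$completeness, nrow(s$fragments))
    }, character(1))
    write_fasta(sp_seqs, file.path(dir, "spliced_prophages.fasta"))
    sp_tbl <- bind_rows(lapply(report$spliced, function(s) {
      mutate(s$fragments, genome_id = s$genome_id,
             completeness = s$completeness, cluster_label = s$cluster_label,
             validated = s$validated)
    }))
    write_tsv_report(sp_tbl, file.path(dir, "splice_report.tsv"))
  }
  write_tsv_report(drop_cols(report$regions, "hit_gene_ids"),
                   file.path(dir, "regions.tsv"))
  write_regions_gff3(report$regions, file.path(dir, "regions.gff3"))
  if (!is.null(report$attB)) {
    write_tsv_report(drop_cols(report$attB, "occurrences"),
                     file.path(dir, "attB_catalog.tsv"))
  }
  write_tsv_report(report$phams$phams, file.path(dir, "phams.tsv"))
  write_tsv_report(report$clusters, file.path(dir, "clusters.tsv"))
  write_tsv_report(report$proteome_network, file.path(dir, "proteome_network.tsv"))
  write_tsv_report(report$pest_network$edges, file.path(dir, "pest_network.tsv"))
  write_tsv_report(report$cassettes, file.path(dir, "pest_cassettes.tsv"))
  invisible(dir)
}
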