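#' Pipeline configuration
#'
#' Collects every tunable threshold used across the toolkit in one object so a
#' whole run is reproducible from a single configuration. Defaults follow the
#' published analysis where a value is stated (admission at <= 100 contigs,
#' 15-gene window, 35% shared gene content for clusters, 25% for the proteome
#' network, 50%/50% identity/coverage for protein phamilies, a 2-ORF
#' neighborhood radius); the remaining cutoffs are explicit, documented
#' defaults.
#'
#' @param max_contigs Admission rule: assemblies with more contigs are rejected
#'   at ingest (overridable there). Default 100.
#' @param window_size_genes Sliding-window width for region scanning, in genes.
#'   Default 15.
#' @param cluster_threshold Shared-gene-content fraction joining genomes into
#'   clusters. Default 0.35.
#' @param network_threshold Shared-gene-content fraction joining nodes in the
#'   proteome network. Default 0.25.
#' @param protein_cluster_identity,protein_cluster_coverage Global identity
#'   (over aligned columns) and coverage (shorter/longer length ratio) for two
#'   proteins to share a phamily. Defaults 0.50 each.
#' @param neighborhood_radius_orfs Gene-neighborhood radius (in ORFs, rank
#'   distance) for the PEST network. Default 2.
#' @param min_fragment_len_bp Minimum contig-end fragment length considered by
#'   the splicer. Default 2000.
#' @param end_margin_bp Maximum distance from a contig end for a fragment to
#'   count as terminal. Default 5000.
#' @param min_alignment_identity Minimum nucleotide identity for significant
#'   local alignments. Default 0.80.
#' @param min_alignment_len_bp Minimum alignment length for defective-prophage
#'   nucleotide evidence. Default 1000.
#' @param min_core_len_bp Minimum attachment-core direct-repeat length.
#'   Default 10.
#' @param core_alpha Significance bound for att cores: the expected number of
#'   chance repeats of the reported length across the two boundary windows must
#'   not exceed this value (set `NULL` to disable and use the raw length floor
#'   only). Default 0.001 (a union bound over the dozens of boundary searches
#'   a corpus run performs).
#' @param boundary_search_bp Half-width of the windows around prophage
#'   boundaries searched for att-core repeats. Default 2000.
#' @param core_max_shift_bp Maximum distance a boundary may move when the
#'   caller snaps call edges to a detected att core; repeats further from the
#'   alignment edges are not treated as this call's attachment core.
#'   Default 1000.
#' @param profile_score_threshold Bit-score threshold above which a profile hit
#'   is significant. Default 30: ungapped log-odds placements of unrelated
#'   proteins rarely exceed ~13 bits, while genuine category members score in
#'   the hundreds.
#' @param truncation_margin_bp A prophage call whose boundary lies within this
#'   distance of a contig end, with no att core found, is omitted as truncated.
#'   Default 100.
#' @param bacterial_contamination_threshold Minimum fraction of a call's genes
#'   with significant phage-archetype hits; below it the call is omitted as
#'   carrying excess bacterial sequence. Default 0.33.
#' @param call_min_coverage Minimum fraction of a reference genome covered by
#'   chained alignments for the alignment-backed prophage caller to emit a
#'   call. Default 0.4.
#' @param call_max_gap_bp Maximum gap on the contig between chained alignments
#'   to the same reference within one call. Default 30000.
#' @param seed_k Nucleotide seed k-mer size for the built-in aligner.
#'   Default 15.
#' @param max_seed_gap_bp Maximum within-diagonal gap between seeds merged into
#'   one ungapped alignment. Default 500.
#' @param xdrop Score drop-off terminating ungapped extension. Default 20.
#' @param sgc_metric Shared-gene-content strategy: `"mean"` (symmetric mean of
#'   directional fractions) or `"min_denominator"`. Default `"mean"`.
#' @param region_extent `"window_union"` (region spans every qualifying window)
#'   or `"hit_bounded"` (region clipped to first/last hit gene).
#' @param pest_expansion `"full"` (all member genes of discovered phamilies
#'   anchor further search) or `"seeds_only"`.
#' @param pp_score_threshold Mean per-column profile-profile similarity above
#'   which two polymorphic-toxin phamilies share a superfamily. Default 0.4:
#'   N-terminal windows from one secretion-domain family score ~0.75-0.85
#'   per column, unrelated families at most ~0.15.
#' @param nterm_window_aa N-terminal window (aa) used to build superfamily
#'   profiles. Default 200.
#' @param rng_seed Integer seed governing every stochastic step. Default 1.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config(rng_seed = 7)
#' cfg$window_size_genes
#' @export
pipeline_config <- function(max_contigs = 100L,
                            window_size_genes = 15L,
                            cluster_threshold = 0.35,
                            network_threshold = 0.25,
                            protein_cluster_identity = 0.50,
                            protein_cluster_coverage = 0.50,
                            neighborhood_radius_orfs = 2L,
                            min_fragment_len_bp = 2000L,
                            end_margin_bp = 5000L,
                            min_alignment_identity = 0.80,
                            min_alignment_len_bp = 1000L,
                            min_core_len_bp = 10L,
                            core_alpha = 0.001,
                            boundary_search_bp = 2000L,
                            core_max_shift_bp = 1000L,
                            profile_score_threshold = 30,
                            truncation_margin_bp = 100L,
                            bacterial_contamination_threshold = 0.33,
                            call_min_coverage = 0.4,
                            call_max_gap_bp = 30000L,
                            seed_k = 15L,
                            max_seed_gap_bp = 500L,
                            xdrop = 20,
                            sgc_metric = c("mean", "min_denominator"),
                            region_extent = c("window_union", "hit_bounded"),
                            pest_expansion = c("full", "seeds_only"),
                            pp_score_threshold = 0.4,
                            nterm_window_aa = 200L,
                            rng_seed = 1L) {
  cfg <- list(
    max_contigs = as.integer(max_contigs),
    window_size_genes = as.integer(window_size_genes),
    cluster_threshold = cluster_threshold,
    network_threshold = network_threshold,
    protein_cluster_identity = protein_cluster_identity,
    protein_cluster_coverage = protein_cluster_coverage,
    neighborhood_radius_orfs = as.integer(neighborhood_radius_orfs),
    min_fragment_len_bp = as.integer(min_fragment_len_bp),
    end_margin_bp = as.integer(end_margin_bp),
    min_alignment_identity = min_alignment_identity,
    min_alignment_len_bp = as.integer(min_alignment_len_bp),
    min_core_len_bp = as.integer(min_core_len_bp),
    core_alpha = core_alpha,
    boundary_search_bp = as.integer(boundary_search_bp),
    core_max_shift_bp = as.integer(core_max_shift_bp),
    profile_score_threshold = profile_score_threshold,
    truncation_margin_bp = as.integer(truncation_margin_bp),
    bacterial_contamination_threshold = bacterial_contamination_threshold,
    call_min_coverage = call_min_coverage,
    call_max_gap_bp = as.integer(call_max_gap_bp),
    seed_k = as.integer(seed_k),
    max_seed_gap_bp = as.integer(max_seed_gap_bp),
    xdrop = xdrop,
    sgc_metric = match.arg(sgc_metric),
    region_extent = match.arg(region_extent),
    pest_expansion = match.arg(pest_expansion),
    pp_score_threshold = pp_score_threshold,
    nterm_window_aa = as.integer(nterm_window_aa),
    rng_seed = as.integer(rng_seed)
  )
  fracs <- c("cluster_threshold", "network_threshold",
             "protein_cluster_identity", "protein_cluster_coverage",
             "min_alignment_identity", "bacterial_contamination_threshold",
             "call_min_coverage")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", f), class = "prophagr_validation_error")
    }
  }
  lens <- c("window_size_genes", "min_fragment_len_bp", "end_margin_bp",
            "min_core_len_bp", "boundary_search_bp", "seed_k",
            "max_contigs", "truncation_margin_bp")
  for (f in lens) {
    if (cfg[[f]] < 1) {
      abort(sprintf("`%s` must be a positive length.", f), class = "prophagr_validation_error")
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-34s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
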