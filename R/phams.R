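# Gene phamily ("pham") construction and genome clustering by shared gene
# content. Phams are the currency of the comparative layer: the cluster
# assignment, the proteome network and the PEST neighborhood graph all operate
# on pham sets rather than raw sequences.

aa_submat <- function() {
  m <- matrix(-1, nrow = 20, ncol = 20, dimnames = list(AA20, AA20))
  diag(m) <- 1
  m
}

# global (Needleman-Wunsch) alignment; identity over aligned columns and
# coverage as shorter/longer length ratio
protein_pair_stats <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = aa_submat(),
    gapOpening = 10, gapExtension = 4, scoreOnly = FALSE)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pv <- split_chars(p); sv <- split_chars(s)
  ident <- sum(pv == sv & pv != "-") / length(pv)
  cov <- min(nchar(a), nchar(b)) / max(nchar(a), nchar(b))
  c(identity = ident, coverage = cov)
}

protein_kmer_pairs <- function(seqs, k = 5L) {
  # candidate pairs sharing at least one exact k-mer
  km <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(substr(s, 1, nchar(s)))
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  idx <- rep(seq_along(seqs), lengths(km))
  tab <- split(idx, unlist(km))
  tab <- tab[lengths(tab) > 1]
  if (!length(tab)) return(matrix(integer(0), ncol = 2))
  prs <- lapply(tab, function(v) {
    v <- sort(unique(v))
    if (length(v) < 2) return(NULL)
    t(utils::combn(v, 2))
  })
  prs <- do.call(rbind, prs)
  unique(prs)
}

#' Cluster proteins into phamilies
#'
#' Two proteins share a pham iff they are connected in the transitive closure
#' of the pairwise relation: global alignment identity >= `identity_threshold`
#' over aligned columns, with the shorter sequence covering at least
#' `coverage_threshold` of the longer. Identical sequences are collapsed
#' first, and only pairs sharing an exact 5-mer (and passing the length-ratio
#' bound) are aligned; phams partition the input gene set.
#'
#' @param proteins Tibble with columns `gene_id`, `protein` and optionally
#'   `genome_id`.
#' @param identity_threshold,coverage_threshold Fractions in (0, 1];
#'   defaults 0.5 / 0.5.
#' @return An object of class `pham_set`: a list with `phams` (tibble
#'   `pham_id`, `gene_id`, `genome_id`) and `representatives` (tibble
#'   `pham_id`, `representative`, `n_members`), where the representative is
#'   the longest member (leftmost on ties in input order).
#' @export
build_phams <- function(proteins, identity_threshold = 0.5,
                        coverage_threshold = 0.5) {
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      coverage_threshold <= 0 || coverage_threshold > 1) {
    abort("Thresholds must lie in (0, 1].", class = "prophagr_validation_error")
  }
  proteins <- as_tibble(proteins)
  if (!nrow(proteins)) {
    return(structure(list(
      phams = tibble(pham_id = character(), gene_id = character(),
                     genome_id = character()),
      representatives = tibble(pham_id = character(), representative = character(),
                               n_members = integer())),
      class = "pham_set"))
  }
  if (anyDuplicated(proteins$gene_id)) {
    abort("Duplicate gene_ids in protein table.", class = "prophagr_validation_error")
  }
  if (!"genome_id" %in% names(proteins)) proteins$genome_id <- NA_character_
  seqs <- toupper(proteins$protein)
  uniq <- !duplicated(seqs)
  useqs <- seqs[uniq]
  umap <- match(seqs, useqs)      # gene -> unique sequence index
  nu <- length(useqs)
  parent <- seq_len(nu)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  if (nu > 1) {
    cand <- protein_kmer_pairs(useqs)
    if (nrow(cand)) {
      la <- nchar(useqs[cand[, 1]]); lb <- nchar(useqs[cand[, 2]])
      keep <- pmin(la, lb) / pmax(la, lb) >= coverage_threshold
      cand <- cand[keep, , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (find(i) == find(j)) next
        st <- protein_pair_stats(useqs[i], useqs[j])
        if (st["identity"] >= identity_threshold &&
            st["coverage"] >= coverage_threshold) unite(i, j)
      }
    }
  }
  roots <- vapply(seq_len(nu), find, integer(1))
  comp_of_gene <- roots[umap]
  comp_levels <- unique(comp_of_gene)          # order of first appearance
  pham_idx <- match(comp_of_gene, comp_levels)
  pham_ids <- sprintf("pham_%04d", pham_idx)
  phams <- tibble(pham_id = pham_ids, gene_id = proteins$gene_id,
                  genome_id = proteins$genome_id)
  reps <- tibble(pham_id = pham_ids, protein = seqs,
                 ord = seq_along(seqs)) %>%
    group_by(.data$pham_id) %>%
    summarise(representative = .data$protein[order(-nchar(.data$protein), .data$ord)][1],
              n_members = n(), .groups = "drop") %>%
    arrange(.data$pham_id)
  structure(list(phams = phams, representatives = reps), class = "pham_set")
}

#' @export
print.pham_set <- function(x, ...) {
  cat(sprintf("<pham_set> %d gene(s) in %d pham(s)\n",
              nrow(x$phams), nrow(x$representatives)))
  invisible(x)
}

#' Shared gene content between two pham sets
#'
#' The fraction of gene phamilies two genomes have in common. The default
#' metric is the symmetric mean of the two directional fractions
#' |A intersect B|/|A| and |A intersect B|/|B|; `"min_denominator"` divides by
#' the larger set instead. Paralogs count once: the metric is over distinct
#' phams.
#'
#' @param phams_a,phams_b Character vectors of pham ids (one genome each).
#' @param metric `"mean"` or `"min_denominator"`.
#' @return Fraction in \\[0, 1\\].
#' @examples
#' shared_gene_content(c("p1", "p2"), c("p2", "p3"))
#' @export
shared_gene_content <- function(phams_a, phams_b,
                                metric = c("mean", "min_denominator")) {
  metric <- match.arg(metric)
  a <- unique(phams_a); b <- unique(phams_b)
  if (!length(a) || !length(b)) {
    abort("Pham sets must be non-empty.", class = "prophagr_validation_error")
  }
  i <- length(intersect(a, b))
  if (metric == "mean") mean(c(i / length(a), i / length(b)))
  else i / max(length(a), length(b))
}

cluster_letters <- function(n) {
  # A, B, ..., Z, AA, AB, ...
  out <- character(n)
  for (i in seq_len(n)) {
    v <- i; s <- ""
    while (v > 0) {
      r <- (v - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      v <- (v - 1) %/% 26
    }
    out[i] <- s
  }
  out
}

pairwise_sgc <- function(pham_table, metric) {
  sets <- split(pham_table$pham_id, pham_table$genome_id)
  ids <- names(sets)
  n <- length(ids)
  if (n < 2) {
    return(tibble(genome_a = character(), genome_b = character(), sgc = numeric()))
  }
  prs <- t(utils::combn(n, 2))
  sgc <- vapply(seq_len(nrow(prs)), function(r) {
    shared_gene_content(sets[[prs[r, 1]]], sets[[prs[r, 2]]], metric)
  }, numeric(1))
  tibble(genome_a = ids[prs[, 1]], genome_b = ids[prs[, 2]], sgc = sgc)
}

#' Assign genomes to clusters by shared gene content
#'
#' Genomes joined by pairwise shared gene content at or above `threshold`
#' (default 35%) fall in one cluster (connected components); genomes with no
#' neighbor are singletons. Labels run A, B, C, ... in decreasing component
#' size, ties broken by the smallest member genome id.
#'
#' @param pham_table Tibble (`pham_id`, `gene_id`, `genome_id`), e.g.
#'   `build_phams(...)$phams`.
#' @param threshold Shared-gene-content threshold (default 0.35).
#' @param metric Passed to [shared_gene_content()].
#' @return Tibble: `genome_id`, `cluster_label`, `singleton`.
#' @export
assign_clusters <- function(pham_table, threshold = 0.35,
                            metric = c("mean", "min_denominator")) {
  metric <- match.arg(metric)
  ids <- sort(unique(pham_table$genome_id))
  pw <- pairwise_sgc(pham_table, metric)
  edges <- filter(pw, .data$sgc >= threshold)
  g <- igraph::graph_from_data_frame(
    edges[, c("genome_a", "genome_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  comp_tbl <- tibble(genome_id = names(comp), comp = as.integer(comp)) %>%
    group_by(.data$comp) %>%
    mutate(size = n(), min_id = min(.data$genome_id)) %>%
    ungroup()
  ord <- comp_tbl %>%
    distinct(.data$comp, .data$size, .data$min_id) %>%
    arrange(desc(.data$size), .data$min_id) %>%
    mutate(cluster_label = cluster_letters(n()))
  comp_tbl %>%
    left_join(select(ord, "comp", "cluster_label"), by = "comp") %>%
    mutate(singleton = .data$size == 1L) %>%
    select("genome_id", "cluster_label", "singleton") %>%
    arrange(.data$genome_id)
}

#' Proteome-equivalence network
#'
#' Undirected edges joining all genome pairs whose shared gene content reaches
#' `threshold` (default 25%, the network display threshold; a supergraph of
#' the 35% cluster graph on the same corpus).
#'
#' @inheritParams assign_clusters
#' @param threshold Edge threshold (default 0.25).
#' @return Tibble edge list: `genome_a`, `genome_b`, `sgc`. The full node set
#'   is attached as attribute `"nodes"`.
#' @export
build_proteome_network <- function(pham_table, threshold = 0.25,
                                   metric = c("mean", "min_denominator")) {
  metric <- match.arg(metric)
  pw <- pairwise_sgc(pham_table, metric)
  out <- filter(pw, .data$sgc >= threshold)
  attr(out, "nodes") <- sort(unique(pham_table$genome_id))
  out
}
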