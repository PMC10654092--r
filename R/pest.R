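# PEST cassette mining. Phage-encoded ESX-secreted toxin systems couple a
# WXG100 effector, a polymorphic toxin (PT) with a conserved N-terminal
# secretion domain and a variable C-terminal TOX domain, and an immunity
# protein (Imm), in three-gene (WXG-PT-Imm) or four-gene (WXG-WXG-PT-Imm)
# cassettes. Discovery is two-step: profile homology seeds PT/WXG/Imm
# phamilies, then an iterative gene-neighborhood network over phamilies
# captures components with novel sequences.

#' Seed PEST role phamilies by profile homology
#'
#' A pham is seeded for a role iff any member protein scores a significant hit
#' against a profile of that role (`polymorphic_toxin` -> PT, `wxg100` -> WXG,
#' `immunity` -> Imm). A pham receives at most one role; on conflicts the
#' higher-scoring role wins and the conflict is recorded.
#'
#' @param pham_table Tibble (`pham_id`, `gene_id`, `genome_id`).
#' @param proteins Tibble (`gene_id`, `protein`).
#' @param profile_db List of `protein_profile`s (roles are taken from
#'   categories `polymorphic_toxin`, `wxg100`, `immunity`).
#' @param config A [pipeline_config()].
#' @param hits Optional precomputed profile-hit tibble (as from
#'   [scan_profile_hits()] over the full database); role categories are
#'   extracted from it instead of rescanning.
#' @return Tibble: `pham_id`, `role` (`PT`/`WXG`/`Imm`), `score`,
#'   `conflict` (logical: the pham also hit another role).
#' @export
seed_pest_homologs <- function(pham_table, proteins, profile_db,
                               config = pipeline_config(), hits = NULL) {
  role_map <- c(polymorphic_toxin = "PT", wxg100 = "WXG", immunity = "Imm")
  role_db <- Filter(function(p) p$category %in% names(role_map), profile_db)
  if (!length(role_db)) {
    abort("Profile database holds no PEST role profiles.",
          class = "prophagr_configuration_error")
  }
  genes <- proteins %>%
    inner_join(pham_table[, c("pham_id", "gene_id")], by = "gene_id")
  if (is.null(hits)) {
    hits <- scan_profile_hits(genes, role_db,
                              threshold = config$profile_score_threshold)
  } else {
    hits <- filter(hits, .data$category %in% names(role_map), .data$significant)
  }
  if (!nrow(hits)) {
    return(tibble(pham_id = character(), role = character(),
                  score = numeric(), conflict = logical()))
  }
  hits %>%
    left_join(genes[, c("gene_id", "pham_id")], by = "gene_id") %>%
    mutate(role = unname(role_map[.data$category])) %>%
    group_by(.data$pham_id) %>%
    summarise(n_roles = dplyr::n_distinct(.data$role),
              best_role = .data$role[which.max(.data$score)],
              score = max(.data$score),
              .groups = "drop") %>%
    rename(role = "best_role") %>%
    mutate(conflict = .data$n_roles > 1) %>%
    select("pham_id", "role", "score", "conflict") %>%
    arrange(.data$pham_id)
}

# rank-adjacency pairs within `radius` ORFs on the same contig of one genome
adjacency_pairs <- function(genes, radius) {
  out <- list()
  for (key in unique(paste(genes$genome_id, genes$contig_id))) {
    g <- genes[paste(genes$genome_id, genes$contig_id) == key, ]
    g <- g[order(g$rank), ]
    n <- nrow(g)
    if (n < 2) next
    for (d in seq_len(min(radius, n - 1))) {
      i <- seq_len(n - d)
      out[[length(out) + 1]] <- tibble(
        gene_a = g$gene_id[i], gene_b = g$gene_id[i + d],
        pham_a = g$pham_id[i], pham_b = g$pham_id[i + d])
    }
  }
  if (!length(out)) {
    return(tibble(gene_a = character(), gene_b = character(),
                  pham_a = character(), pham_b = character()))
  }
  bind_rows(out)
}

#' Iterative gene-neighborhood network over phamilies
#'
#' Starting from seed polymorphic-toxin phams, every gene of an anchor pham
#' contributes the phamilies of genes within `radius` ORFs up/downstream on
#' its contig; newly reached phams become anchors in the next iteration, until
#' no new node appears (a breadth-first fixpoint). With `expansion = "full"`
#' (default) all member genes of a discovered pham anchor the next round,
#' genome-wide; `"seeds_only"` expands only from seed-pham genes. Nodes are
#' phams; edge counts tally the adjacent gene pairs supporting each edge.
#'
#' @param genes Tibble (`gene_id`, `genome_id`, `contig_id`, `rank`,
#'   `pham_id`); every gene must carry a pham.
#' @param seed_phams Character vector of seed (PT) pham ids.
#' @param radius Neighborhood radius in ORFs (default 2).
#' @param expansion `"full"` or `"seeds_only"`.
#' @return An object of class `neighborhood_network`: `nodes`, `edges`
#'   (tibble `pham_a`, `pham_b`, `count`), `seeds`, `iterations_to_fixpoint`.
#' @export
build_neighborhood_network <- function(genes, seed_phams, radius = 2L,
                                       expansion = c("full", "seeds_only")) {
  expansion <- match.arg(expansion)
  if (anyNA(genes$pham_id)) {
    abort("Every gene must be assigned a pham.", class = "prophagr_validation_error")
  }
  seed_phams <- intersect(unique(seed_phams), unique(genes$pham_id))
  empty_edges <- tibble(pham_a = character(), pham_b = character(),
                        count = integer())
  if (!length(seed_phams)) {
    return(structure(list(nodes = character(0), edges = empty_edges,
                          seeds = character(0), iterations_to_fixpoint = 0L),
                     class = "neighborhood_network"))
  }
  adj <- adjacency_pairs(genes, radius)
  nodes <- seed_phams
  anchors <- seed_phams
  iters <- 0L
  while (length(anchors)) {
    iters <- iters + 1L
    nb <- adj %>%
      filter(.data$pham_a %in% anchors | .data$pham_b %in% anchors)
    reached <- union(nb$pham_a, nb$pham_b)
    new_nodes <- setdiff(reached, nodes)
    nodes <- union(nodes, new_nodes)
    anchors <- if (expansion == "full") new_nodes else character(0)
  }
  edges <- adj %>%
    filter(.data$pham_a %in% nodes, .data$pham_b %in% nodes,
           .data$pham_a != .data$pham_b) %>%
    mutate(a = pmin(.data$pham_a, .data$pham_b),
           b = pmax(.data$pham_a, .data$pham_b)) %>%
    count(.data$a, .data$b, name = "count") %>%
    rename(pham_a = "a", pham_b = "b")
  structure(list(nodes = sort(nodes), edges = edges,
                 seeds = sort(seed_phams),
                 iterations_to_fixpoint = iters),
            class = "neighborhood_network")
}

#' @export
print.neighborhood_network <- function(x, ...) {
  cat(sprintf("<neighborhood_network> %d node(s), %d edge(s), %d seed(s), fixpoint in %d iteration(s)\n",
              length(x$nodes), nrow(x$edges), length(x$seeds),
              x$iterations_to_fixpoint))
  invisible(x)
}

#' Extract PEST cassettes around polymorphic-toxin genes
#'
#' For each PT gene, the contiguous same-strand run of role-bearing genes
#' around it is read in transcription order (rank order on `+`, reversed on
#' `-`): `WXG,PT,Imm` is a three-gene cassette, `WXG,WXG,PT,Imm` a four-gene
#' cassette, and any other role pattern containing a PT is reported as
#' incomplete with the observed roles.
#'
#' @param genes Tibble (`gene_id`, `genome_id`, `contig_id`, `rank`, `strand`,
#'   `pham_id`).
#' @param roles Tibble (`pham_id`, `role`) from [seed_pest_homologs()] (or any
#'   role assignment).
#' @return Tibble: `genome_id`, `contig_id`, `pt_gene_id`, `architecture`
#'   (`three_gene`/`four_gene`/`incomplete`), `roles` and `gene_ids`
#'   (comma-separated, transcription order).
#' @export
extract_cassettes <- function(genes, roles) {
  genes <- genes %>%
    left_join(roles[, c("pham_id", "role")], by = "pham_id")
  out <- list()
  for (key in unique(paste(genes$genome_id, genes$contig_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    g <- genes[genes$genome_id == parts[1] & genes$contig_id == parts[2], ]
    g <- g[order(g$rank), ]
    pt_rows <- which(!is.na(g$role) & g$role == "PT")
    for (p in pt_rows) {
      strand <- g$strand[p]
      lo <- p
      while (lo > 1 && !is.na(g$role[lo - 1]) && g$strand[lo - 1] == strand &&
             g$rank[lo - 1] == g$rank[lo] - 1L) lo <- lo - 1
      hi <- p
      while (hi < nrow(g) && !is.na(g$role[hi + 1]) && g$strand[hi + 1] == strand &&
             g$rank[hi + 1] == g$rank[hi] + 1L) hi <- hi + 1
      run <- g[lo:hi, ]
      if (strand == "-") run <- run[rev(seq_len(nrow(run))), ]
      rs <- unname(run$role)
      arch <- if (identical(rs, c("WXG", "PT", "Imm"))) "three_gene"
      else if (identical(rs, c("WXG", "WXG", "PT", "Imm"))) "four_gene"
      else "incomplete"
      out[[length(out) + 1]] <- tibble(
        genome_id = parts[1], contig_id = parts[2],
        pt_gene_id = g$gene_id[p], architecture = arch,
        roles = paste(rs, collapse = ","),
        gene_ids = paste(run$gene_id, collapse = ","))
    }
  }
  if (!length(out)) {
    return(tibble(genome_id = character(), contig_id = character(),
                  pt_gene_id = character(), architecture = character(),
                  roles = character(), gene_ids = character()))
  }
  bind_rows(out) %>% arrange(.data$genome_id, .data$contig_id, .data$pt_gene_id)
}

# cosine similarity of column log-odds vectors (columns centered so the
# shared background structure of log-odds profiles does not inflate unrelated
# pairs, and the score is invariant to profile depth) over the best ungapped
# offset with at least `min_overlap` overlapping columns
profile_profile_score <- function(p1, p2, min_overlap = 100L) {
  center <- function(p) sweep(p, 2, colMeans(p))
  p1 <- center(p1); p2 <- center(p2)
  n1 <- ncol(p1); n2 <- ncol(p2)
  best <- -Inf
  for (off in (-(n2 - min_overlap)):(n1 - min_overlap)) {
    i1 <- max(1L, 1L + off); i2 <- max(1L, 1L - off)
    len <- min(n1 - i1 + 1L, n2 - i2 + 1L)
    if (len < min_overlap) next
    a <- p1[, i1:(i1 + len - 1L)]; b <- p2[, i2:(i2 + len - 1L)]
    s <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
    if (s > best) best <- s
  }
  best
}

#' Group polymorphic-toxin phamilies into PEST superfamilies
#'
#' Builds a per-pham profile from the members' N-terminal windows (the
#' conserved secretion domain) and connects pham pairs whose profile-profile
#' ungapped alignment score exceeds the threshold; superfamilies are the
#' connected components, labeled PEST1, PEST2, PEST3, ... in decreasing size
#' (ties by smallest member pham id); components beyond the third are labeled
#' `unassigned-k`.
#'
#' @param pt_members Tibble (`pham_id`, `protein`) of PT pham member
#'   sequences.
#' @param config A [pipeline_config()]; uses `nterm_window_aa` and
#'   `pp_score_threshold`.
#' @return Tibble: `pham_id`, `superfamily`.
#' @export
group_superfamilies <- function(pt_members, config = pipeline_config()) {
  ids <- sort(unique(pt_members$pham_id))
  if (!length(ids)) return(tibble(pham_id = character(), superfamily = character()))
  profs <- lapply(ids, function(pid) {
    seqs <- pt_members$protein[pt_members$pham_id == pid]
    seqs <- substr(seqs, 1, config$nterm_window_aa)
    build_profile(seqs, profile_id = pid, category = "polymorphic_toxin")$pssm
  })
  n <- length(ids)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (n > 1) {
    prs <- t(utils::combn(n, 2))
    for (r in seq_len(nrow(prs))) {
      s <- profile_profile_score(profs[[prs[r, 1]]], profs[[prs[r, 2]]])
      if (is.finite(s) && s >= config$pp_score_threshold) {
        g <- igraph::add_edges(g, c(prs[r, 1], prs[r, 2]))
      }
    }
  }
  comp <- igraph::components(g)$membership
  tbl <- tibble(pham_id = ids, comp = as.integer(comp)) %>%
    group_by(.data$comp) %>%
    mutate(size = n(), min_id = min(.data$pham_id)) %>%
    ungroup()
  ord <- tbl %>%
    distinct(.data$comp, .data$size, .data$min_id) %>%
    arrange(desc(.data$size), .data$min_id) %>%
    mutate(superfamily = ifelse(row_number() <= 3,
                                paste0("PEST", row_number()),
                                paste0("unassigned-", row_number() - 3L)))
  tbl %>%
    left_join(select(ord, "comp", "superfamily"), by = "comp") %>%
    select("pham_id", "superfamily") %>%
    arrange(.data$pham_id)
}

#' Per-column conservation profile of aligned toxin proteins
#'
#' Per-column conservation is the frequency of the modal residue (gaps
#' excluded from the numerator, included in the denominator), smoothed by a
#' centered moving average. Segments are inferred by thresholding the
#' smoothed values at their mean: the leading high segment is the WXG
#' secretion domain, the trailing high segment the TOX domain, and the middle
#' the linker.
#'
#' @param aligned Character vector (>= 2) of equal-length aligned sequences
#'   (`-` for gaps).
#' @param smooth_window Centered moving-average window (default 15).
#' @return An object of class `conservation_profile`: tibble `column`,
#'   `conservation`, `smoothed`, `segment`, plus `boundaries` (WXG/linker and
#'   linker/TOX columns, `NA` when the high-low-high shape is absent).
#' @export
conservation_profile <- function(aligned, smooth_window = 15L) {
  if (length(aligned) < 2) {
    abort("Need at least two aligned sequences.", class = "prophagr_validation_error")
  }
  if (length(unique(nchar(aligned))) != 1) {
    abort("Aligned sequences must share one length (ragged alignment).",
          class = "prophagr_validation_error")
  }
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  n <- nrow(mat)
  cons <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    max(table(col)) / n
  })
  k <- smooth_window
  half <- k %/% 2
  L <- length(cons)
  sm <- vapply(seq_len(L), function(i) {
    mean(cons[max(1, i - half):min(L, i + half)])
  }, numeric(1))
  thr <- mean(sm)
  high <- sm >= thr
  seg <- rep("linker", L)
  b1 <- NA_integer_; b2 <- NA_integer_
  if (high[1]) {
    b1 <- which(!high)[1] - 1L
    if (is.na(b1)) b1 <- L
    seg[1:b1] <- "WXG"
  }
  if (high[L]) {
    last_low <- max(which(!high), 0L)
    b2 <- last_low + 1L
    if (b2 <= L && (is.na(b1) || b2 > b1)) seg[b2:L] <- "TOX"
  }
  if (all(high)) seg <- rep("conserved", L)
  structure(list(
    profile = tibble(column = seq_len(L), conservation = cons,
                     smoothed = sm, segment = seg),
    boundaries = c(wxg_end = b1, tox_start = b2),
    smooth_window = k),
    class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d column(s); WXG end ~%s, TOX start ~%s\n",
              nrow(x$profile),
              format(x$boundaries[["wxg_end"]]), format(x$boundaries[["tox_start"]])))
  invisible(x)
}
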