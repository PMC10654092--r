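# Independent oracle implementations used only by the tests. These share no
# code with the package's detectors: global identity via a hand-written
# Needleman-Wunsch, local-alignment hit calls via fixed-window diagonal sums,
# components via a minimal base-R union-find, and window scans via literal
# enumeration.

AA <- c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","V","W","Y")

rand_aa <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")
rand_nt <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE), collapse = "")

mutate_aa <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  v[pos] <- sample(AA, k, replace = TRUE)
  paste(v, collapse = "")
}

# Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2);
# returns matches / alignment length
nw_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  gap <- -2
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in 1:n) {
    sub <- ifelse(av[i] == bv, 1, -1)
    row_prev <- S[i, ]
    row <- numeric(m + 1); row[1] <- gap * i
    for (j in 1:m) {
      row[j + 1] <- max(row_prev[j] + sub[j], row_prev[j + 1] + gap, row[j] + gap)
    }
    S[i + 1, ] <- row
  }
  # traceback for matches and alignment length
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 && j > 0) {
    if (S[i + 1, j + 1] == S[i, j] + (if (av[i] == bv[j]) 1 else -1)) {
      matches <- matches + (av[i] == bv[j]); i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1] + gap) i <- i - 1
    else j <- j - 1
    len <- len + 1L
  }
  len <- len + i + j
  matches / len
}

# hit/no-hit oracle for ungapped local similarity: does any strand carry a
# window of exactly `min_len` bases on some diagonal with >= min_id matches?
diagonal_hit_oracle <- function(query, subject, min_len, min_id) {
  one_strand <- function(q, s) {
    qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
    nq <- length(qv); ns <- length(sv)
    for (d in (-(ns - min_len)):(nq - min_len)) {
      i0 <- max(1, 1 + d); j0 <- max(1, 1 - d)
      len <- min(nq - i0 + 1, ns - j0 + 1)
      if (len < min_len) next
      m <- qv[i0:(i0 + len - 1)] == sv[j0:(j0 + len - 1)]
      cs <- c(0, cumsum(m))
      w <- cs[(min_len + 1):(len + 1)] - cs[1:(len - min_len + 1)]
      if (any(w >= min_id * min_len)) return(TRUE)
    }
    FALSE
  }
  one_strand(query, subject) || one_strand(revcomp(query), subject)
}

# minimal union-find over integer ids
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i); rj <- uf_find(p, j)
  if (ri != rj) p[max(ri, rj)] <- min(ri, rj)
  p
}
uf_components <- function(p) vapply(seq_along(p), function(i) uf_find(p, i), integer(1))

# literal enumeration of qualifying sliding windows over gene ranks
window_union_oracle <- function(n_genes, hit_ranks, w) {
  if (!length(hit_ranks)) return(integer(0))
  covered <- rep(FALSE, n_genes)
  w_eff <- min(w, n_genes)
  for (i in 1:max(1, n_genes - w_eff + 1)) {
    win <- i:min(n_genes, i + w_eff - 1)
    if (any(hit_ranks %in% win)) covered[win] <- TRUE
  }
  which(covered)
}

# gene-table builder for scan tests: n genes of 10 bp at 20 bp spacing
toy_gene_table <- function(n, contig = "c1") {
  as_gene_table(tibble::tibble(
    gene_id = sprintf("g%03d", 1:n), contig_id = contig,
    start = 20L * (0:(n - 1)) + 1L, end = 20L * (0:(n - 1)) + 10L,
    strand = "+", protein = "M"))
}

toy_hits <- function(gene_ids, category = "phage_archetype", significant = TRUE) {
  tibble::tibble(gene_id = gene_ids, profile_id = "p", category = category,
                 score = 100, significant = significant)
}

# genomes as rank-ordered pham layouts for network tests
layout_genes <- function(layouts) {
  dplyr::bind_rows(lapply(seq_along(layouts), function(g) {
    ph <- layouts[[g]]
    tibble::tibble(gene_id = sprintf("g%02d_%03d", g, seq_along(ph)),
                   genome_id = sprintf("G%02d", g), contig_id = "c1",
                   rank = seq_along(ph), strand = "+", pham_id = ph)
  }))
}

# independent oracle: nodes = union of components (over the rank-distance
# adjacency graph of phams) containing a seed, via igraph on a graph built
# directly from the layouts
network_nodes_oracle <- function(layouts, seeds, radius) {
  edges <- list()
  for (ph in layouts) {
    n <- length(ph)
    if (n < 2) next
    for (d in 1:min(radius, n - 1)) {
      edges[[length(edges) + 1]] <-
        cbind(ph[seq_len(n - d)], ph[seq_len(n - d) + d])
    }
  }
  all_ph <- unique(unlist(layouts))
  g <- igraph::graph_from_data_frame(
    as.data.frame(do.call(rbind, edges)), directed = FALSE,
    vertices = data.frame(name = all_ph))
  comp <- igraph::components(g)$membership
  seeds <- intersect(seeds, all_ph)
  if (!length(seeds)) return(character(0))
  sort(names(comp)[comp %in% comp[seeds]])
}

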