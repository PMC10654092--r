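# Built-in similarity search: a deterministic seed-and-extend nucleotide
# aligner (BLAST stand-in honoring the same hit contract) and an ungapped
# position-specific score matrix engine standing in for profile HMMs. Both are
# pluggable: any adapter producing the same tabular records can be swapped in
# for real data.

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

# positions of each k-mer of `subject`, excluding k-mers containing N
subject_kmer_index <- function(subject, k) {
  km <- kmer_starts(subject, k)
  keep <- !grepl("N", km, fixed = TRUE)
  uk <- unique(km[keep])
  pos <- split(which(keep), factor(km[keep], levels = uk))
  list(kmers = uk, positions = pos)
}

# ungapped X-drop extension over match/mismatch vectors; returns number of
# bases to extend (match +1, mismatch -2). `a`, `b` are equal-length character
# vectors of single bases read outward from the alignment edge.
xdrop_extend <- function(a, b, xdrop) {
  if (!length(a)) return(0L)
  sc <- ifelse(a == b & a != "N" & b != "N", 1, -2)
  cs <- cumsum(sc)
  run_max <- cummax(cs)
  stop_at <- which(run_max - cs > xdrop)
  lim <- if (length(stop_at)) stop_at[1] - 1L else length(cs)
  if (lim == 0L) return(0L)
  best <- which.max(cs[seq_len(lim)])
  if (cs[best] <= 0) 0L else best
}

split_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# identity over an ungapped pairing of equal-length strings; N never matches
ungapped_identity <- function(a, b) {
  av <- split_chars(a); bv <- split_chars(b)
  mean(av == bv & av != "N" & bv != "N")
}

align_one_strand <- function(query, subject, sidx, k, min_len, min_identity,
                             max_seed_gap, xdrop, qk = NULL) {
  nq <- nchar(query); ns <- nchar(subject)
  if (is.null(qk)) qk <- kmer_starts(query, k)
  if (!length(qk) || !length(sidx$kmers)) return(NULL)
  m <- match(qk, sidx$kmers)
  hit_q <- which(!is.na(m))
  if (!length(hit_q)) return(NULL)
  cnt <- lengths(sidx$positions)[m[hit_q]]
  qpos <- rep(hit_q, cnt)
  spos <- unlist(sidx$positions[m[hit_q]], use.names = FALSE)
  diag <- qpos - spos
  o <- order(diag, qpos)
  qpos <- qpos[o]; spos <- spos[o]; diag <- diag[o]
  new_chain <- c(TRUE, diff(diag) != 0 | diff(qpos) > max_seed_gap)
  chain_id <- cumsum(new_chain)
  qs <- tapply(qpos, chain_id, min)
  qe <- tapply(qpos, chain_id, max) + k - 1L
  ss <- tapply(spos, chain_id, min)
  res <- list()
  for (i in seq_along(qs)) {
    q1 <- qs[[i]]; q2 <- qe[[i]]; s1 <- ss[[i]]
    s2 <- s1 + (q2 - q1)
    # extend left
    ext <- min(q1 - 1L, s1 - 1L)
    if (ext > 0) {
      a <- rev(split_chars(substr(query, q1 - ext, q1 - 1L)))
      b <- rev(split_chars(substr(subject, s1 - ext, s1 - 1L)))
      e <- xdrop_extend(a, b, xdrop)
      q1 <- q1 - e; s1 <- s1 - e
    }
    # extend right
    ext <- min(nq - q2, ns - s2)
    if (ext > 0) {
      a <- split_chars(substr(query, q2 + 1L, q2 + ext))
      b <- split_chars(substr(subject, s2 + 1L, s2 + ext))
      e <- xdrop_extend(a, b, xdrop)
      q2 <- q2 + e; s2 <- s2 + e
    }
    res[[i]] <- c(q1, q2, s1, s2)
  }
  res <- do.call(rbind, res)
  # merge overlapping/adjacent spans on the same diagonal
  d <- res[, 1] - res[, 3]
  o <- order(d, res[, 1])
  res <- res[o, , drop = FALSE]; d <- d[o]
  keep <- list(); cur <- res[1, ]
  if (nrow(res) > 1) {
    for (i in 2:nrow(res)) {
      if (d[i] == (cur[1] - cur[3]) && res[i, 1] <= cur[2] + 1L) {
        cur[2] <- max(cur[2], res[i, 2]); cur[4] <- max(cur[4], res[i, 4])
      } else {
        keep[[length(keep) + 1]] <- cur
        cur <- res[i, ]
      }
    }
  }
  keep[[length(keep) + 1]] <- cur
  res <- do.call(rbind, keep)
  len <- res[, 2] - res[, 1] + 1L
  ok <- len >= min_len
  if (!any(ok)) return(NULL)
  res <- res[ok, , drop = FALSE]
  ident <- vapply(seq_len(nrow(res)), function(i) {
    ungapped_identity(substr(query, res[i, 1], res[i, 2]),
                      substr(subject, res[i, 3], res[i, 4]))
  }, numeric(1))
  ok <- ident >= min_identity
  if (!any(ok)) return(NULL)
  tibble(q_start = res[ok, 1], q_end = res[ok, 2],
         s_start = res[ok, 3], s_end = res[ok, 4],
         identity = ident[ok])
}

#' Find local nucleotide alignments
#'
#' Deterministic seed-and-extend local alignment of one query against a
#' collection of subject sequences: exact k-mer seeds, within-diagonal
#' chaining, ungapped X-drop extension (the stand-in for a BLAST search on the
#' exact / near-exact sequences this toolkit targets; gapped aligners can be
#' plugged in behind the same record contract). Both strands are searched; `N`
#' never matches. Every reported alignment satisfies
#' `aln_length >= min_len` and `identity >= min_identity`.
#'
#' @param query DNA string (character scalar).
#' @param subjects Named character vector or `DNAStringSet` of subjects.
#' @param min_len Minimum alignment length (bp); must be >= `k`.
#' @param min_identity Minimum fraction of matching bases.
#' @param k Seed k-mer size (default 15).
#' @param max_seed_gap Maximum within-diagonal distance between seeds chained
#'   into one alignment (default 500).
#' @param xdrop Extension score drop-off (default 20).
#' @param query_id Identifier recorded in the result.
#' @return Tibble with columns `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end` (1-based inclusive, `q_*` always on the forward query),
#'   `strand`, `identity`, `aln_length`, sorted by (`subject_id`, `s_start`).
#' @examples
#' s <- strrep("ACGT", 100)
#' find_local_alignments(s, c(ref = s), min_len = 100, min_identity = 0.9, k = 11)
#' @export
find_local_alignments <- function(query, subjects, min_len, min_identity,
                                  k = 15L, max_seed_gap = 500L, xdrop = 20,
                                  query_id = "query") {
  if (!is.character(query) || length(query) != 1 || !nzchar(query)) {
    abort("`query` must be a non-empty DNA string.", class = "prophagr_validation_error")
  }
  if (min_len < k) {
    abort("`min_len` must be at least the seed size `k`.",
          class = "prophagr_validation_error")
  }
  if (methods::is(subjects, "DNAStringSet")) {
    subjects <- setNames(as.character(subjects), names(subjects))
  }
  query <- toupper(query)
  nq <- nchar(query)
  qrc <- revcomp(query)
  qk_fwd <- kmer_starts(query, k)
  qk_rev <- kmer_starts(qrc, k)
  out <- list()
  for (sid in names(subjects)) {
    subj <- toupper(subjects[[sid]])
    sidx <- subject_kmer_index(subj, k)
    fwd <- align_one_strand(query, subj, sidx, k, min_len, min_identity,
                            max_seed_gap, xdrop, qk = qk_fwd)
    if (!is.null(fwd) && nrow(fwd)) {
      out[[length(out) + 1]] <- mutate(fwd, subject_id = sid, strand = "+")
    }
    rev <- align_one_strand(qrc, subj, sidx, k, min_len, min_identity,
                            max_seed_gap, xdrop, qk = qk_rev)
    if (!is.null(rev) && nrow(rev)) {
      rev <- mutate(rev,
                    q_start0 = nq - .data$q_end + 1L,
                    q_end = nq - .data$q_start + 1L,
                    q_start = .data$q_start0) %>%
        select(-"q_start0")
      out[[length(out) + 1]] <- mutate(rev, subject_id = sid, strand = "-")
    }
  }
  if (!length(out)) {
    return(tibble(query_id = character(), subject_id = character(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  strand = character(), identity = numeric(),
                  aln_length = integer()))
  }
  bind_rows(out) %>%
    mutate(query_id = query_id,
           aln_length = .data$q_end - .data$q_start + 1L) %>%
    select("query_id", "subject_id", "q_start", "q_end", "s_start", "s_end",
           "strand", "identity", "aln_length") %>%
    arrange(.data$subject_id, .data$s_start, .data$q_start)
}

# ---- protein profiles --------------------------------------------------------

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Build an ungapped protein profile (PSSM)
#'
#' Per-column log2-odds of residue frequency (+1 pseudocount) over a uniform
#' 1/20 background, built from an ungapped stack of member sequences (the
#' deterministic stand-in for a profile HMM; a real HMM engine can be plugged
#' in behind the same hit contract). Members longer than the shortest are
#' truncated to the common length.
#'
#' @param seqs Character vector of amino-acid sequences (ungapped alignment).
#' @param profile_id Identifier.
#' @param category One of the gene categories used downstream
#'   (`phage_archetype`, `integrase`, `transposase`, `major_capsid`,
#'   `polymorphic_toxin`, `wxg100`, `immunity`).
#' @return An object of class `protein_profile` with the score matrix (20 x
#'   ncol), consensus sequence, id and category.
#' @export
build_profile <- function(seqs, profile_id, category) {
  seqs <- toupper(seqs)
  if (!length(seqs) || any(!nzchar(seqs))) {
    abort("Profiles need at least one non-empty training sequence.",
          class = "prophagr_validation_error")
  }
  if (any(grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seqs))) {
    abort("Profile training sequences must use the 20-letter amino-acid alphabet.",
          class = "prophagr_validation_error")
  }
  ncol <- min(nchar(seqs))
  mat <- matrix(0L, nrow = 20, ncol = ncol, dimnames = list(AA20, NULL))
  for (s in seqs) {
    idx <- match(split_chars(substr(s, 1, ncol)), AA20)
    mat[cbind(idx, seq_len(ncol))] <- mat[cbind(idx, seq_len(ncol))] + 1L
  }
  n <- length(seqs)
  pssm <- log2(((mat + 1) / (n + 20)) * 20)
  consensus <- paste(AA20[apply(mat, 2, which.max)], collapse = "")
  structure(list(pssm = pssm, consensus = consensus,
                 profile_id = profile_id, category = category,
                 n_members = n),
            class = "protein_profile")
}

#' @export
print.protein_profile <- function(x, ...) {
  cat(sprintf("<protein_profile> %s [%s]: %d columns from %d member(s)\n",
              x$profile_id, x$category, ncol(x$pssm), x$n_members))
  invisible(x)
}

# best ungapped placement score of protein vs profile; placements slide the
# profile along the protein, or the protein within the profile window when the
# protein is shorter
best_placement_score <- function(protein, pssm) {
  idx <- match(split_chars(protein), rownames(pssm))
  if (anyNA(idx)) {
    abort("Protein contains residues outside the 20-letter alphabet.",
          class = "prophagr_validation_error")
  }
  lp <- length(idx); nc <- ncol(pssm)
  if (lp >= nc) {
    v <- matrix(pssm[idx, , drop = FALSE], nrow = lp)
    s <- numeric(lp - nc + 1)
    for (c in seq_len(nc)) s <- s + v[c:(c + lp - nc), c]
    max(s)
  } else {
    # protein placed within the profile window
    s <- vapply(0:(nc - lp), function(off) {
      sum(pssm[cbind(idx, seq_len(lp) + off)])
    }, numeric(1))
    max(s)
  }
}

#' Score a protein against a profile
#'
#' Score is the best sum of per-position log-odds over all ungapped placements
#' of the profile on the protein (or of the protein within the profile window
#' when shorter). A hit is significant when the score reaches the configured
#' bit threshold.
#'
#' @param protein Amino-acid string.
#' @param profile A [build_profile()] object.
#' @param threshold Significance threshold in bits (default 0: any placement
#'   scoring above the uniform background).
#' @param gene_id Identifier carried into the record.
#' @return One-row tibble: `gene_id`, `profile_id`, `category`, `score`,
#'   `significant`.
#' @export
score_profile <- function(protein, profile, threshold = 0, gene_id = NA_character_) {
  if (!is.character(protein) || length(protein) != 1 || !nzchar(protein)) {
    abort("`protein` must be a non-empty amino-acid string.",
          class = "prophagr_validation_error")
  }
  score <- best_placement_score(toupper(protein), profile$pssm)
  tibble(gene_id = gene_id, profile_id = profile$profile_id,
         category = profile$category, score = score,
         significant = score >= threshold)
}

#' Scan a gene table against a profile database
#'
#' Applies [score_profile()] over all (gene, profile) pairs and returns the
#' significant hits. For speed, pairs are prefiltered by an exact 6-mer shared
#' between the protein and the profile consensus; pairs without one cannot
#' realistically reach a positive log-odds placement and are skipped.
#'
#' @param genes A gene table ([as_gene_table()]).
#' @param profile_db List of `protein_profile` objects.
#' @param threshold Significance threshold in bits.
#' @param prefilter Use the 6-mer prefilter (default TRUE). Set FALSE for an
#'   exhaustive scan.
#' @return Tibble of significant hits: `gene_id`, `profile_id`, `category`,
#'   `score`, `significant`.
#' @export
scan_profile_hits <- function(genes, profile_db, threshold = 0, prefilter = TRUE) {
  if (!length(profile_db)) {
    abort("Empty profile database.", class = "prophagr_configuration_error")
  }
  kmer_set <- function(s, k = 6L) {
    if (nchar(s) < k) return(s)
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  }
  cons_kmers <- lapply(profile_db, function(p) kmer_set(p$consensus))
  out <- vector("list", 256); oi <- 0L
  prot_kmers <- if (prefilter) lapply(genes$protein, kmer_set) else NULL
  for (j in seq_along(profile_db)) {
    p <- profile_db[[j]]
    cand <- if (prefilter) {
      which(vapply(prot_kmers, function(ks) any(ks %in% cons_kmers[[j]]), logical(1)))
    } else seq_len(nrow(genes))
    for (i in cand) {
      h <- score_profile(genes$protein[i], p, threshold, gene_id = genes$gene_id[i])
      if (h$significant) {
        oi <- oi + 1L
        if (oi > length(out)) out <- c(out, vector("list", length(out)))
        out[[oi]] <- h
      }
    }
  }
  if (!oi) {
    return(tibble(gene_id = character(), profile_id = character(),
                  category = character(), score = numeric(),
                  significant = logical()))
  }
  bind_rows(out[seq_len(oi)])
}

#' Write / read a profile database as aligned FASTA files
#'
#' One file per profile, named `<category>__<profile_id>.fasta`, holding the
#' ungapped member stack the profile is rebuilt from.
#'
#' @param profile_db List of `protein_profile` objects (for writing) with a
#'   `members` attribute, or created via [build_profile()] from `seqs` kept in
#'   the object.
#' @param dir Directory path.
#' @return For `read_profile_db`, a named list of `protein_profile`s.
#' @export
write_profile_db <- function(profile_db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in profile_db) {
    seqs <- attr(p, "members")
    if (is.null(seqs)) seqs <- p$consensus
    aa <- Biostrings::AAStringSet(seqs)
    names(aa) <- paste0(p$profile_id, "_", seq_along(aa))
    Biostrings::writeXStringSet(aa, file.path(dir, sprintf("%s__%s.fasta",
                                                           p$category, p$profile_id)))
  }
  invisible(dir)
}

#' @rdname write_profile_db
#' @export
read_profile_db <- function(dir) {
  files <- list.files(dir, pattern = "__.*\\.fasta$", full.names = TRUE)
  db <- lapply(files, function(f) {
    base <- sub("\\.fasta$", "", basename(f))
    parts <- strsplit(base, "__", fixed = TRUE)[[1]]
    seqs <- as.character(Biostrings::readAAStringSet(f))
    p <- build_profile(seqs, profile_id = parts[2], category = parts[1])
    attr(p, "members") <- unname(seqs)
    p
  })
  setNames(db, vapply(db, function(p) p$profile_id, character(1)))
}
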