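# Deterministic synthetic-genome generator. Emulates the study conditions:
# draft mycobacterium-like assemblies (GC ~0.66) sharing one chromosomal
# backbone, lysogenized at a small repertoire of attB loci by reference
# phages, with prophages optionally split across contig ends, planted PICIs
# (integrase + capsid), PEST cassettes from three N-terminal toxin
# archetypes, defective remnants, and truncated/contaminated decoy elements
# -- each with a machine-readable truth record. Generation and detection
# share no logic: elements are composed by string surgery, never by running
# any detector.

# fixed per-category archetype proteins; stable across corpora so profile
# databases and phamilies are comparable between runs
ARCHETYPE_SEEDS <- list(
  phage_archetype = 90001:90018,
  integrase = 90101,
  transposase = 90111,
  major_capsid = 90121,
  polymorphic_toxin = 90201:90203,
  wxg100 = 90301:90302,
  immunity = 90401:90404
)
ARCHETYPE_LEN <- list(
  phage_archetype = c(180, 220, 240, 200, 190, 230, 210, 250, 175, 205,
                      185, 225, 245, 195, 215, 235, 170, 260),
  integrase = 300, transposase = 250, major_capsid = 280,
  polymorphic_toxin = c(200, 200, 200), wxg100 = c(95, 98),
  immunity = c(120, 130, 110, 125)
)

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

rand_dna <- function(n, gc = 0.66) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Archetype protein for a gene category
#'
#' Deterministic founder sequences for each gene category; profile databases
#' and planted genes both derive from these (planted copies carry their own
#' mutations).
#'
#' @param category Category name (see [build_profile()]).
#' @param index Archetype index within the category.
#' @return Amino-acid string.
#' @export
category_archetype <- function(category, index = 1L) {
  seeds <- ARCHETYPE_SEEDS[[category]]
  lens <- ARCHETYPE_LEN[[category]]
  if (is.null(seeds) || index < 1 || index > length(seeds)) {
    abort(sprintf("No archetype %d for category '%s'.", index, category),
          class = "prophagr_validation_error")
  }
  withr::with_seed(seeds[index], rand_protein(lens[index]))
}

mutate_protein <- function(p, rate) {
  if (rate <= 0) return(p)
  v <- split_chars(p)
  k <- rbinom(1, length(v), rate)
  if (k > 0) {
    pos <- sample(length(v), k)
    v[pos] <- sample(AA20, k, replace = TRUE)
  }
  paste(v, collapse = "")
}

# fixed single-codon encoding; genes are DNA renditions of their proteins
CODON <- c(A="GCT", C="TGT", D="GAT", E="GAA", F="TTT", G="GGT", H="CAT",
           I="ATT", K="AAA", L="CTG", M="ATG", N="AAT", P="CCT", Q="CAA",
           R="CGT", S="TCT", T="ACT", V="GTT", W="TGG", Y="TAT")

protein_to_dna <- function(p) {
  paste0(paste(CODON[split_chars(p)], collapse = ""), "TAA")
}

#' Build the default profile database
#'
#' One ungapped profile per archetype, named `<category>_<index>`; the
#' database every synthetic-corpus scan uses.
#'
#' @return Named list of `protein_profile`s.
#' @export
default_profile_db <- function() {
  db <- list()
  for (cat in names(ARCHETYPE_SEEDS)) {
    for (i in seq_along(ARCHETYPE_SEEDS[[cat]])) {
      pid <- sprintf("%s_%d", cat, i)
      p <- build_profile(category_archetype(cat, i), profile_id = pid,
                         category = cat)
      attr(p, "members") <- category_archetype(cat, i)
      db[[pid]] <- p
    }
  }
  db
}

# ---- toy phage genomes -------------------------------------------------------

# internal: gene block (gap + CDS) builders operating under an active RNG
gene_block <- function(protein, category, strand = "+", gap_range = c(60, 140)) {
  gap <- rand_dna(sample(gap_range[1]:gap_range[2], 1))
  dna <- protein_to_dna(protein)
  if (strand == "-") dna <- revcomp(dna)
  list(gap = gap, dna = dna, protein = protein, category = category,
       strand = strand)
}

assemble_blocks <- function(blocks, prefix = "", suffix = "", id_prefix = "g") {
  seq_parts <- character(0)
  genes <- list()
  off <- nchar(prefix)
  seq_parts <- prefix
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    off <- off + nchar(b$gap)
    genes[[i]] <- tibble(
      gene_id = sprintf("%s%02d", id_prefix, i),
      start = off + 1L, end = off + nchar(b$dna),
      strand = b$strand, protein = b$protein, category = b$category)
    seq_parts <- c(seq_parts, b$gap, b$dna)
    off <- off + nchar(b$dna)
  }
  seq_parts <- c(seq_parts, suffix)
  list(sequence = paste(seq_parts, collapse = ""),
       genes = if (length(genes)) bind_rows(genes) else
         tibble(gene_id = character(), start = integer(), end = integer(),
                strand = character(), protein = character(),
                category = character()))
}

#' Generate an annotated toy phage genome
#'
#' Deterministic DNA of (at least) the planned gene content: genes are laid
#' out left to right with random intergenic gaps and the remainder filled
#' with background DNA up to `length` (error if the plan does not fit).
#' Category genes derive from the corresponding archetypes with a small
#' mutation load; `"none"` genes are random proteins.
#'
#' @param seed Integer seed; output is byte-identical across runs.
#' @param length Target genome length (bp).
#' @param gene_plan Tibble with columns `category` and `length_aa` (used for
#'   `"none"` genes; archetype genes use their archetype length), optional
#'   `archetype` index and `mutation` rate (default 0.05).
#' @param gc Background GC content (default 0.66).
#' @return List: `sequence`, `genes` (tibble with `category` kept for truth
#'   checking; detectors never read it).
#' @export
make_toy_phage <- function(seed, length, gene_plan, gc = 0.66) {
  withr::with_seed(seed, {
    if (!"archetype" %in% names(gene_plan)) gene_plan$archetype <- 1L
    if (!"mutation" %in% names(gene_plan)) gene_plan$mutation <- 0.05
    blocks <- lapply(seq_len(nrow(gene_plan)), function(i) {
      cat_i <- gene_plan$category[i]
      prot <- if (cat_i == "none") {
        rand_protein(gene_plan$length_aa[i])
      } else {
        mutate_protein(category_archetype(cat_i, gene_plan$archetype[i]),
                       gene_plan$mutation[i])
      }
      gene_block(prot, cat_i)
    })
    body <- assemble_blocks(blocks)
    if (nchar(body$sequence) > length) {
      abort(sprintf("Gene plan needs %d bp but genome length is %d.",
                    nchar(body$sequence), length),
            class = "prophagr_validation_error")
    }
    filler <- rand_dna(length - nchar(body$sequence), gc)
    list(sequence = paste0(body$sequence, filler), genes = body$genes)
  })
}

#' Plant a prophage into a host genome at an attB locus
#'
#' Emulates lysogeny: the attB core at `locus_start` is replaced by the phage
#' sequence, which must begin and end with that same core, creating attL and
#' attR direct repeats. Host genes downstream shift accordingly.
#'
#' @param host List with `sequence` and `genes` (absolute 1-based coords).
#' @param phage List with `sequence` and `genes` (phage-local coords), the
#'   sequence starting and ending with `att_core_seq`.
#' @param att_core_seq The shared core.
#' @param locus_start 1-based start of the attB core in the host.
#' @return List: `host` (updated sequence/genes), `truth` (one-row tibble
#'   with the planted interval and core).
#' @export
plant_prophage <- function(host, phage, att_core_seq, locus_start) {
  cl <- nchar(att_core_seq)
  if (substr(host$sequence, locus_start, locus_start + cl - 1L) != att_core_seq) {
    abort("Host locus does not carry the att core.",
          class = "prophagr_validation_error")
  }
  L <- nchar(phage$sequence)
  if (substr(phage$sequence, 1, cl) != att_core_seq ||
      substr(phage$sequence, L - cl + 1L, L) != att_core_seq) {
    abort("Phage sequence must begin and end with the att core.",
          class = "prophagr_validation_error")
  }
  shift <- L - cl
  new_seq <- paste0(substr(host$sequence, 1, locus_start - 1L),
                    phage$sequence,
                    substr(host$sequence, locus_start + cl, nchar(host$sequence)))
  host_genes <- host$genes %>%
    mutate(start = ifelse(.data$start >= locus_start + cl, .data$start + shift, .data$start),
           end = ifelse(.data$end >= locus_start + cl, .data$end + shift, .data$end))
  phage_genes <- phage$genes %>%
    mutate(start = .data$start + locus_start - 1L,
           end = .data$end + locus_start - 1L)
  truth <- tibble(element_type = "prophage",
                  start = locus_start, end = locus_start + L - 1L,
                  core_seq = att_core_seq, sequence = phage$sequence)
  list(host = list(sequence = new_seq,
                   genes = bind_rows(host_genes, phage_genes) %>%
                     arrange(.data$start)),
       truth = truth)
}

#' Fragment a genome into a draft assembly
#'
#' Cuts the genome after each breakpoint position; genes spanning a cut are
#' dropped. Deterministic for a fixed breakpoint set.
#'
#' @param genome List with `sequence` and `genes`.
#' @param breakpoints Sorted positions; contig i ends at breakpoint i.
#' @param contig_prefix Contig name prefix (default `"c"`).
#' @return List: `contigs` (named character), `genes` (contig-local coords
#'   with per-contig ranks), `offsets` (tibble `contig_id`, `offset`,
#'   `length` mapping genome coords to contigs).
#' @export
fragment_assembly <- function(genome, breakpoints, contig_prefix = "c") {
  L <- nchar(genome$sequence)
  bps <- sort(unique(as.integer(breakpoints)))
  if (any(bps < 1 | bps >= L)) {
    abort("Breakpoints must lie strictly inside the genome.",
          class = "prophagr_validation_error")
  }
  starts <- c(1L, bps + 1L)
  ends <- c(bps, L)
  ids <- sprintf("%s%d", contig_prefix, seq_along(starts))
  contigs <- setNames(substring(genome$sequence, starts, ends), ids)
  offsets <- tibble(contig_id = ids, offset = starts - 1L,
                    length = ends - starts + 1L)
  genes <- genome$genes
  genes$contig_id <- NA_character_
  for (i in seq_along(starts)) {
    inside <- genes$start >= starts[i] & genes$end <= ends[i]
    genes$contig_id[inside] <- ids[i]
  }
  genes <- genes %>%
    filter(!is.na(.data$contig_id)) %>%
    mutate(off = offsets$offset[match(.data$contig_id, offsets$contig_id)],
           start = .data$start - .data$off,
           end = .data$end - .data$off) %>%
    select(-"off") %>%
    arrange(match(.data$contig_id, ids), .data$start) %>%
    group_by(.data$contig_id) %>%
    mutate(rank = row_number()) %>%
    ungroup()
  list(contigs = contigs, genes = genes, offsets = offsets)
}

# map a genome interval to (contig, local interval); NA if it spans a cut
locate_on_contigs <- function(offsets, start, end) {
  row <- offsets[offsets$offset < start & start <= offsets$offset + offsets$length, ]
  if (!nrow(row)) return(NULL)
  if (end > row$offset[1] + row$length[1]) return(NULL)
  list(contig_id = row$contig_id[1], start = start - row$offset[1],
       end = end - row$offset[1])
}

# ---- backbone ----------------------------------------------------------------

build_backbone <- function(n_genes = 90, att_isotypes, gc = 0.66) {
  att_positions <- round(seq(0.12, 0.9, length.out = length(att_isotypes)) * n_genes)
  units <- list()
  for (i in seq_len(n_genes)) {
    b <- gene_block(rand_protein(sample(180:280, 1)), "none",
                    strand = sample(c("+", "-"), 1), gap_range = c(80, 200))
    units[[length(units) + 1]] <- list(kind = "gene", gap = b$gap, dna = b$dna,
                                       protein = b$protein, strand = b$strand,
                                       category = b$category)
    hit <- which(att_positions == i)
    if (length(hit)) {
      iso <- att_isotypes[hit[1]]
      core <- rand_dna(sample(40:50, 1), gc)
      if (is.na(iso)) {            # bare intergenic core
        pre <- rand_dna(20, gc); post <- rand_dna(20, gc)
        feat <- NULL
      } else if (iso == "tmRNA") {
        pre <- rand_dna(100, gc); post <- rand_dna(200, gc)
        feat <- list(type = "tmRNA", isotype = "tmRNA",
                     rel_start = 1L, rel_end = 100L + nchar(core) + 200L)
      } else {                     # core embedded in a tRNA gene
        pre <- rand_dna(15, gc); post <- rand_dna(max(0, 76 - 15 - nchar(core)), gc)
        feat <- list(type = "tRNA", isotype = iso,
                     rel_start = 1L, rel_end = 15L + nchar(core) +
                       max(0, 76 - 15 - nchar(core)))
      }
      units[[length(units) + 1]] <- list(
        kind = "att", gap = rand_dna(40, gc),
        pre = pre, core = core, post = post, feature = feat,
        locus_id = sprintf("attL%d", hit[1]))
    }
  }
  units
}

unit_seq <- function(u) {
  if (u$kind == "gene") paste0(u$gap, u$dna)
  else paste0(u$gap, u$pre, u$core, u$post)
}

# linearize units into a genome; returns sequence, genes, att table, features
linearize_units <- function(units, id_prefix = "g") {
  pieces <- character(length(units))
  genes <- list(); atts <- list(); feats <- list()
  off <- 0L; gi <- 0L
  for (u in units) {
    s <- unit_seq(u)
    if (u$kind == "gene") {
      gi <- gi + 1L
      genes[[gi]] <- tibble(
        gene_id = sprintf("%s%04d", id_prefix, gi),
        start = off + nchar(u$gap) + 1L,
        end = off + nchar(u$gap) + nchar(u$dna),
        strand = u$strand, protein = u$protein, category = u$category)
    } else {
      core_start <- off + nchar(u$gap) + nchar(u$pre) + 1L
      atts[[length(atts) + 1]] <- tibble(
        locus_id = u$locus_id, core_seq = u$core,
        core_start = core_start,
        core_end = core_start + nchar(u$core) - 1L,
        isotype = if (is.null(u$feature)) NA_character_ else u$feature$isotype)
      if (!is.null(u$feature)) {
        feats[[length(feats) + 1]] <- tibble(
          feature_id = paste0(u$locus_id, "_rna"),
          type = u$feature$type, isotype = u$feature$isotype,
          start = off + nchar(u$gap) + u$feature$rel_start,
          end = off + nchar(u$gap) + u$feature$rel_end)
      }
    }
    off <- off + nchar(s)
  }
  pieces <- vapply(units, unit_seq, character(1))
  list(sequence = paste(pieces, collapse = ""),
       genes = bind_rows(genes),
       att = bind_rows(atts),
       features = if (length(feats)) bind_rows(feats) else
         tibble(feature_id = character(), type = character(),
                isotype = character(), start = integer(), end = integer()))
}

mutate_gaps <- function(units, rate) {
  # per-host SNPs confined to intergenic gaps; genes, cores and RNA features
  # stay exact so planted elements and their flanks remain byte-faithful
  lapply(units, function(u) {
    g <- split_chars(u$gap)
    k <- rbinom(1, length(g), rate)
    if (k > 0) {
      pos <- sample(length(g), k)
      g[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      u$gap <- paste(g, collapse = "")
    }
    u
  })
}

# ---- corpus composition ------------------------------------------------------

# reference phage: core + [integrase, capsid, archetypal phage genes, decoys]
# + core. The first/last four archetype genes draw from disjoint family sets
# so the only long direct repeat spanning the genome ends is the att core.
dna_not <- function(n, forbid_first = NULL, forbid_last = NULL) {
  s <- split_chars(rand_dna(n))
  fix <- function(ch, forbid) {
    while (!is.null(forbid) && ch == forbid) ch <- sample(c("A","C","G","T"), 1)
    ch
  }
  s[1] <- fix(s[1], forbid_first)
  s[length(s)] <- fix(s[length(s)], forbid_last)
  paste(s, collapse = "")
}

build_ref_phage <- function(ref_id, core, cluster, n_arch = 15, n_decoy = 5,
                            host_pre_last = NULL, host_post_first = NULL) {
  blocks <- list()
  ai <- 0
  plan <- c("integrase", "phage_archetype", "phage_archetype", "major_capsid",
            rep(c("phage_archetype", "none"), length.out = n_arch - 6 + n_decoy),
            rep("phage_archetype", 4))
  # distinct archetype families within one phage, so the only direct repeat
  # spanning any pair of windows is the att core
  arch_pool <- sample(1:18, sum(plan == "phage_archetype"))
  for (cat_i in plan) {
    prot <- switch(cat_i,
      integrase = mutate_protein(category_archetype("integrase"), 0.05),
      major_capsid = mutate_protein(category_archetype("major_capsid"), 0.05),
      phage_archetype = {
        ai <- ai + 1
        mutate_protein(category_archetype("phage_archetype", arch_pool[ai]), 0.05)
      },
      none = rand_protein(sample(150:220, 1)))
    blocks[[length(blocks) + 1]] <- gene_block(prot, cat_i)
  }
  # the bases abutting the cores must differ from the host bases abutting the
  # attB core, so attL/attR direct repeats are exactly the planted core
  out <- assemble_blocks(
    blocks,
    prefix = paste0(core, dna_not(80, forbid_first = host_post_first)),
    suffix = paste0(dna_not(80, forbid_last = host_pre_last), core),
    id_prefix = paste0(ref_id, "_g"))
  list(phage_id = ref_id, sequence = out$sequence, genes = out$genes,
       cluster = cluster, core = core)
}

build_pici_payload <- function() {
  blocks <- list(
    gene_block(mutate_protein(category_archetype("integrase"), 0.25), "integrase"),
    gene_block(rand_protein(sample(150:220, 1)), "none"),
    gene_block(mutate_protein(category_archetype("major_capsid"), 0.25), "major_capsid"),
    gene_block(rand_protein(sample(150:220, 1)), "none"),
    gene_block(rand_protein(sample(200:260, 1)), "none"))
  assemble_blocks(blocks, suffix = rand_dna(60))
}

build_cassette_payload <- function(arch_idx, four_gene, strand) {
  pt <- paste0(mutate_protein(category_archetype("polymorphic_toxin", arch_idx), 0.08),
               rand_protein(180))
  wxg1 <- mutate_protein(category_archetype("wxg100", 1), 0.08)
  wxg2 <- mutate_protein(category_archetype("wxg100", 2), 0.08)
  imm <- mutate_protein(category_archetype("immunity", sample(1:4, 1)), 0.08)
  tx_order <- if (four_gene) list(c("wxg100", "w1"), c("wxg100", "w2"),
                                  c("polymorphic_toxin", "pt"), c("immunity", "imm"))
  else list(c("wxg100", "w1"), c("polymorphic_toxin", "pt"), c("immunity", "imm"))
  prots <- list(w1 = wxg1, w2 = wxg2, pt = pt, imm = imm)
  if (strand == "-") tx_order <- rev(tx_order)
  blocks <- lapply(tx_order, function(x) {
    gene_block(prots[[x[2]]], x[1], strand = strand, gap_range = c(60, 120))
  })
  assemble_blocks(blocks, suffix = rand_dna(50))
}

mosaic_payload <- function(ref, middle_bp = 25000) {
  L <- nchar(ref$sequence)
  gh <- ref$genes[ref$genes$end <= 0.25 * L, ]
  gt <- ref$genes[ref$genes$start >= 0.75 * L, ]
  head_end <- max(gh$end) + 20L
  tail_start <- min(gt$start) - 20L
  mid_blocks <- list()
  total <- 0L
  while (total < middle_bp) {
    b <- gene_block(rand_protein(sample(200:260, 1)), "none",
                    gap_range = c(150, 250))
    mid_blocks[[length(mid_blocks) + 1]] <- b
    total <- total + nchar(b$gap) + nchar(b$dna)
  }
  mid <- assemble_blocks(mid_blocks, suffix = rand_dna(100))
  head_seq <- substr(ref$sequence, 1, head_end)
  tail_seq <- substr(ref$sequence, tail_start, L)
  genes <- bind_rows(
    mutate(gh, start = .data$start, end = .data$end, src = "head"),
    mutate(mid$genes, start = .data$start + head_end,
           end = .data$end + head_end, src = "mid"),
    mutate(gt, start = .data$start - tail_start + 1L + head_end + nchar(mid$sequence),
           end = .data$end - tail_start + 1L + head_end + nchar(mid$sequence),
           src = "tail")) %>% select(-"src")
  list(sequence = paste0(head_seq, mid$sequence, tail_seq), genes = genes)
}

remnant_payload <- function(ref, target_bp = 5500) {
  L <- nchar(ref$sequence)
  target_bp <- min(target_bp, floor(0.3 * L))
  g <- ref$genes
  i0 <- 3L
  gs <- g$start[i0] - 10L
  last <- max(which(g$end <= gs + target_bp))
  ge <- g$end[last] + 10L
  keep <- g[i0:last, ]
  list(sequence = substr(ref$sequence, gs, ge),
       genes = mutate(keep, start = .data$start - gs + 1L,
                      end = .data$end - gs + 1L))
}

truncated_payload <- function(ref, frac = 0.6) {
  L <- nchar(ref$sequence)
  g <- ref$genes
  last <- max(which(g$end <= frac * L))
  cut <- g$end[last] + 20L
  list(sequence = substr(ref$sequence, 1, cut),
       genes = g[g$end <= cut, ],
       ref_covered = cut)
}

# apply replacements/insertions to a linearized genome; plantings must be
# non-overlapping and are specified in original coordinates
compose_host <- function(genome0, plantings) {
  if (!length(plantings)) {
    return(list(sequence = genome0$sequence, genes = genome0$genes,
                elements = tibble()))
  }
  anchors <- vapply(plantings, function(p) p$from, numeric(1))
  plantings <- plantings[order(anchors)]
  pieces <- character(0)
  genes_out <- list()
  elements <- list()
  cursor <- 1L
  shift <- 0L
  host_genes <- genome0$genes
  for (p in plantings) {
    stopifnot(p$from >= cursor)
    pre <- substr(genome0$sequence, cursor, p$from - 1L)
    pieces <- c(pieces, pre, p$payload$sequence)
    seg_genes <- host_genes[host_genes$start >= cursor & host_genes$end < p$from, ]
    if (nrow(seg_genes)) {
      genes_out[[length(genes_out) + 1]] <-
        mutate(seg_genes, start = .data$start + shift, end = .data$end + shift)
    }
    elem_start <- p$from + shift
    pay_genes <- p$payload$genes
    if (nrow(pay_genes)) {
      genes_out[[length(genes_out) + 1]] <- pay_genes %>%
        mutate(gene_id = paste0(p$element_id, "_", .data$gene_id),
               start = .data$start + elem_start - 1L,
               end = .data$end + elem_start - 1L)
    }
    elements[[length(elements) + 1]] <- tibble(
      element_id = p$element_id, element_type = p$element_type,
      start = elem_start,
      end = elem_start + nchar(p$payload$sequence) - 1L,
      reference_id = p$reference_id %||% NA_character_,
      locus_id = p$locus_id %||% NA_character_,
      core_seq = p$core_seq %||% NA_character_,
      archetype = p$archetype %||% NA_integer_,
      architecture = p$architecture %||% NA_character_,
      split_at = p$split_at %||% NA_integer_)
    replaced <- p$to - p$from + 1L
    shift <- shift + nchar(p$payload$sequence) - replaced
    cursor <- p$to + 1L
  }
  tail_seq <- substr(genome0$sequence, cursor, nchar(genome0$sequence))
  pieces <- c(pieces, tail_seq)
  seg_genes <- host_genes[host_genes$start >= cursor, ]
  if (nrow(seg_genes)) {
    genes_out[[length(genes_out) + 1]] <-
      mutate(seg_genes, start = .data$start + shift, end = .data$end + shift)
  }
  list(sequence = paste(pieces, collapse = ""),
       genes = bind_rows(genes_out) %>% arrange(.data$start),
       elements = bind_rows(elements))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the default synthetic corpus with planted truth
#'
#' Builds a deterministic corpus of draft assemblies sharing one chromosomal
#' backbone: by default 20 assemblies carrying 30 planted intact prophages
#' (exact copies of 8 reference phages integrated at 5 shared attB loci), 10
#' prophages split across contig ends, 8 PICIs, 25 PEST cassettes drawn from
#' 3 N-terminal toxin archetypes, 6 defective remnants, and 5 + 5
#' truncated/contaminated decoy elements, plus the reference phage database,
#' the pristine reference chromosome, the profile database and a truth table.
#'
#' @param seed Master seed; the whole corpus is byte-identical for a fixed
#'   seed.
#' @param n_assemblies,n_intact,n_split,n_pici,n_cassettes,n_remnants,
#'   n_truncated,n_contaminated Element counts.
#' @param n_backbone_genes Backbone decoy genes per chromosome.
#' @param snp_rate Per-base substitution rate applied to intergenic backbone
#'   of each strain (genes and att cores stay exact).
#' @param gc Background GC content.
#' @return A list of class `synthetic_corpus`: `assemblies` (named list of
#'   `genome_assembly`), `genes` (tibble with `genome_id`), `db` (a
#'   [phage_db()] with reference gene tables), `profile_db`, `reference`
#'   (single-contig `genome_assembly`), `reference_features`, `att_loci`,
#'   `truth` (one row per planted element or fragment), and `settings`.
#' @export
generate_corpus <- function(seed = 1L,
                            n_assemblies = 20L, n_intact = 30L, n_split = 10L,
                            n_pici = 8L, n_cassettes = 25L, n_remnants = 6L,
                            n_truncated = 5L, n_contaminated = 5L,
                            n_backbone_genes = 90L, snp_rate = 0.002,
                            gc = 0.66) {
  n_refs <- 8L
  n_loci <- 5L
  withr::with_seed(seed, {
    att_isotypes <- c("tRNA-Arg(ACG)", "tRNA-Lys(TTT)", NA, "tmRNA",
                      "tRNA-Gly(GGT)")[seq_len(n_loci)]
    units <- build_backbone(n_backbone_genes, att_isotypes, gc)
    ref_lin <- linearize_units(units, id_prefix = "ref_b")
    att_loci <- ref_lin$att %>%
      mutate(locus_id = sprintf("locus%d", row_number()))
    # reference phages; ref r integrates at locus ((r-1) %% n_loci) + 1
    refs <- list()
    for (r in seq_len(n_refs)) {
      locus <- ((r - 1L) %% n_loci) + 1L
      cl <- c("A", "A", "A", "B", "B", "B", "C", "C")[r]
      refs[[r]] <- build_ref_phage(
        sprintf("ref%d", r), att_loci$core_seq[locus], cl,
        n_arch = sample(13:16, 1), n_decoy = sample(4:6, 1),
        host_pre_last = substr(ref_lin$sequence, att_loci$core_start[locus] - 1L,
                               att_loci$core_start[locus] - 1L),
        host_post_first = substr(ref_lin$sequence, att_loci$core_end[locus] + 1L,
                                 att_loci$core_end[locus] + 1L))
      refs[[r]]$locus <- locus
    }
    names(refs) <- vapply(refs, function(x) x$phage_id, character(1))
    ref_of <- function(j, mod = n_refs) ((j - 1L) %% mod) + 1L

    # element assignment tables (arithmetic, so locus/ref conflicts are
    # impossible within an assembly; see methods vignette)
    intact_tbl <- tibble(j = seq_len(n_intact)) %>%
      mutate(assembly = ((.data$j - 1L) %% n_assemblies) + 1L,
             ref = ref_of(.data$j))
    split_tbl <- tibble(j = seq_len(n_split)) %>%
      mutate(assembly = .data$j,
             ref = ref_of(.data$j + 2L))
    trunc_tbl <- tibble(j = seq_len(n_truncated)) %>%
      mutate(assembly = 10L + .data$j,
             ref = ref_of(10L + .data$j + 1L))
    mosaic_tbl <- tibble(j = seq_len(n_contaminated)) %>%
      mutate(assembly = 15L + .data$j,
             ref = ref_of(15L + .data$j + 1L))
    pici_tbl <- tibble(j = seq_len(n_pici)) %>%
      mutate(assembly = ((.data$j - 1L) %% n_assemblies) + 1L)
    cassette_tbl <- tibble(j = seq_len(n_cassettes)) %>%
      mutate(assembly = ((.data$j - 1L) %% n_assemblies) + 1L,
             archetype = ((.data$j - 1L) %% 3L) + 1L,
             four_gene = .data$archetype == 3L,
             strand = ifelse(.data$j %% 2L == 0L, "-", "+"))
    remnant_tbl <- tibble(j = seq_len(n_remnants)) %>%
      mutate(assembly = pmin(3L * .data$j, n_assemblies))
    # remnant reference: first ref not otherwise present in the assembly
    remnant_tbl$ref <- vapply(remnant_tbl$assembly, function(a) {
      used <- c(intact_tbl$ref[intact_tbl$assembly == a],
                split_tbl$ref[split_tbl$assembly == a],
                trunc_tbl$ref[trunc_tbl$assembly == a],
                mosaic_tbl$ref[mosaic_tbl$assembly == a])
      setdiff(seq_len(n_refs), used)[1]
    }, integer(1))

    # insertion slots: backbone gene indices used as anchors, spread apart
    # and away from att loci
    slot_genes <- c(15L, 22L, 35L, 41L, 52L, 58L, 71L, 76L)

    assemblies <- list(); genes_all <- list(); truth <- list()
    for (a in seq_len(n_assemblies)) {
      aid <- sprintf("asm%02d", a)
      units_h <- mutate_gaps(units, snp_rate)
      lin <- linearize_units(units_h, id_prefix = sprintf("a%02d_b", a))
      slot_pos <- lin$genes$start[slot_genes] - 20L
      slot_cursor <- 0L
      next_slot <- function() {
        slot_cursor <<- slot_cursor + 1L
        if (slot_cursor > length(slot_pos)) {
          abort("Out of insertion slots.", class = "prophagr_validation_error")
        }
        slot_pos[slot_cursor]
      }
      plantings <- list()
      add_plant <- function(p) plantings[[length(plantings) + 1L]] <<- p
      ei <- 0L
      new_eid <- function(type) {
        ei <<- ei + 1L
        sprintf("%s_e%02d_%s", aid, ei, type)
      }
      # prophages at att loci (replace the core)
      for (j in which(intact_tbl$assembly == a)) {
        r <- intact_tbl$ref[j]
        loc <- refs[[r]]$locus
        add_plant(list(
          element_id = new_eid("pro"), element_type = "prophage",
          from = att_loci$core_start[loc], to = att_loci$core_end[loc],
          payload = refs[[r]][c("sequence", "genes")],
          reference_id = refs[[r]]$phage_id, locus_id = att_loci$locus_id[loc],
          core_seq = att_loci$core_seq[loc]))
      }
      for (j in which(split_tbl$assembly == a)) {
        r <- split_tbl$ref[j]
        loc <- refs[[r]]$locus
        g <- refs[[r]]$genes
        mid_gene <- which.min(abs(g$end - nchar(refs[[r]]$sequence) / 2))
        split_at <- g$end[mid_gene] + 15L   # phage-local split offset
        add_plant(list(
          element_id = new_eid("split"), element_type = "split_prophage",
          from = att_loci$core_start[loc], to = att_loci$core_end[loc],
          payload = refs[[r]][c("sequence", "genes")],
          reference_id = refs[[r]]$phage_id, locus_id = att_loci$locus_id[loc],
          core_seq = att_loci$core_seq[loc], split_at = split_at))
      }
      for (j in which(trunc_tbl$assembly == a)) {
        r <- trunc_tbl$ref[j]
        pay <- truncated_payload(refs[[r]])
        p <- next_slot()
        add_plant(list(
          element_id = new_eid("trunc"), element_type = "truncated_decoy",
          from = p, to = p - 1L, payload = pay,
          reference_id = refs[[r]]$phage_id))
      }
      for (j in which(mosaic_tbl$assembly == a)) {
        r <- mosaic_tbl$ref[j]
        pay <- mosaic_payload(refs[[r]])
        p <- next_slot()
        add_plant(list(
          element_id = new_eid("mosaic"), element_type = "contaminated_decoy",
          from = p, to = p - 1L, payload = pay,
          reference_id = refs[[r]]$phage_id))
      }
      for (j in which(pici_tbl$assembly == a)) {
        p <- next_slot()
        add_plant(list(
          element_id = new_eid("pici"), element_type = "pici",
          from = p, to = p - 1L, payload = build_pici_payload()))
      }
      for (j in which(remnant_tbl$assembly == a)) {
        r <- remnant_tbl$ref[j]
        p <- next_slot()
        add_plant(list(
          element_id = new_eid("rem"), element_type = "defective_remnant",
          from = p, to = p - 1L, payload = remnant_payload(refs[[r]]),
          reference_id = refs[[r]]$phage_id))
      }
      for (j in which(cassette_tbl$assembly == a)) {
        p <- next_slot()
        add_plant(list(
          element_id = new_eid("pest"), element_type = "pest_cassette",
          from = p, to = p - 1L,
          payload = build_cassette_payload(cassette_tbl$archetype[j],
                                           cassette_tbl$four_gene[j],
                                           cassette_tbl$strand[j]),
          archetype = cassette_tbl$archetype[j],
          architecture = if (cassette_tbl$four_gene[j]) "four_gene" else "three_gene"))
      }
      comp <- compose_host(list(sequence = lin$sequence, genes = lin$genes),
                           plantings)
      elements <- comp$elements
      # breakpoints: forced inside split prophages / at truncated-decoy ends,
      # plus random safe cuts in the backbone far from any element
      forced <- c()
      sp <- elements[elements$element_type == "split_prophage", ]
      if (nrow(sp)) forced <- c(forced, sp$start + sp$split_at - 1L)
      td <- elements[elements$element_type == "truncated_decoy", ]
      if (nrow(td)) forced <- c(forced, td$end)
      backbone_ids <- lin$genes$gene_id
      cand <- comp$genes %>%
        filter(.data$gene_id %in% backbone_ids) %>%
        pull(.data$start) - 40L
      near <- function(x, ys, d) vapply(x, function(v) any(abs(v - ys) < d), logical(1))
      bounds <- c(elements$start, elements$end, forced,
                  1L, nchar(comp$sequence))
      cand <- cand[!near(cand, bounds, 6000)]
      inside <- vapply(cand, function(v) {
        any(elements$start <= v & v <= elements$end)
      }, logical(1))
      cand <- cand[!inside]
      extra <- sort(cand[sample.int(length(cand), min(3L, length(cand)))])
      bps <- sort(unique(c(forced, extra)))
      frag <- fragment_assembly(list(sequence = comp$sequence, genes = comp$genes),
                                bps, contig_prefix = sprintf("a%02d_c", a))
      assemblies[[aid]] <- genome_assembly(frag$contigs, taxon_id = "1761",
                                           strain_id = as.character(a),
                                           species_label = "synthetic")
      genes_all[[aid]] <- mutate(frag$genes, genome_id = aid)
      # truth rows in contig coordinates
      for (i in seq_len(nrow(elements))) {
        e <- elements[i, ]
        if (e$element_type == "split_prophage") {
          cut <- e$start + e$split_at - 1L
          f1 <- locate_on_contigs(frag$offsets, e$start, cut)
          f2 <- locate_on_contigs(frag$offsets, cut + 1L, e$end)
          for (fi in 1:2) {
            f <- list(f1, f2)[[fi]]
            truth[[length(truth) + 1]] <- tibble(
              element_id = e$element_id, element_type = e$element_type,
              genome_id = aid, contig_id = f$contig_id,
              start = f$start, end = f$end,
              reference_id = e$reference_id, locus_id = e$locus_id,
              core_seq = e$core_seq, archetype = e$archetype,
              architecture = e$architecture, fragment_index = fi,
              sequence = NA_character_)
          }
          truth[[length(truth)]]$sequence <- NA_character_
          # full planted sequence on the fragment_index 1 row
          truth[[length(truth) - 1]]$sequence <-
            refs[[e$reference_id]]$sequence
        } else {
          f <- locate_on_contigs(frag$offsets, e$start, e$end)
          truth[[length(truth) + 1]] <- tibble(
            element_id = e$element_id, element_type = e$element_type,
            genome_id = aid, contig_id = f$contig_id,
            start = f$start, end = f$end,
            reference_id = e$reference_id, locus_id = e$locus_id,
            core_seq = e$core_seq, archetype = e$archetype,
            architecture = e$architecture, fragment_index = 1L,
            sequence = substr(comp$sequence, e$start, e$end))
        }
      }
    }
    db <- phage_db(
      setNames(vapply(refs, function(x) x$sequence, character(1)), names(refs)),
      clusters = tibble(phage_id = names(refs),
                        cluster = vapply(refs, function(x) x$cluster, character(1))),
      genes = bind_rows(lapply(refs, function(x) {
        mutate(x$genes, contig_id = x$phage_id, genome_id = x$phage_id)
      })))
    structure(list(
      assemblies = assemblies,
      genes = bind_rows(genes_all),
      db = db,
      profile_db = default_profile_db(),
      reference = genome_assembly(
        setNames(ref_lin$sequence, "ref_chrom"),
        taxon_id = "1761", strain_id = "ref", species_label = "reference"),
      reference_features = ref_lin$features,
      att_loci = att_loci,
      truth = bind_rows(truth),
      settings = list(seed = seed, n_assemblies = n_assemblies,
                      n_intact = n_intact, n_split = n_split,
                      n_pici = n_pici, n_cassettes = n_cassettes,
                      n_remnants = n_remnants, n_truncated = n_truncated,
                      n_contaminated = n_contaminated, snp_rate = snp_rate,
                      gc = gc)),
      class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d assemblies, %d planted elements, %d reference phages\n",
              length(x$assemblies),
              length(unique(x$truth$element_id)),
              length(x$db$sequences)))
  invisible(x)
}

#' Write a synthetic corpus to disk as plain-text files
#'
#' Emits per-assembly FASTA and gene TSVs, the phage database FASTA +
#' cluster TSV, the profile database directory and the truth table.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (aid in names(corpus$assemblies)) {
    write_fasta(corpus$assemblies[[aid]], file.path(dir, paste0(aid, ".fasta")))
  }
  write_tsv_report(corpus$genes, file.path(dir, "genes.tsv"))
  write_fasta(corpus$db$sequences, file.path(dir, "phage_db.fasta"))
  write_tsv_report(corpus$db$clusters, file.path(dir, "phage_clusters.tsv"))
  write_profile_db(corpus$profile_db, file.path(dir, "profiles"))
  write_tsv_report(corpus$truth, file.path(dir, "truth.tsv"))
  write_fasta(corpus$reference, file.path(dir, "reference_chromosome.fasta"))
  invisible(dir)
}
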