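test_that("contigs with no significant hits yield no regions", {
  genes <- toy_gene_table(40)
  expect_equal(nrow(scan_regions(genes, toy_hits(character(0)), 15)), 0L)
  off <- toy_hits("g005", significant = FALSE)
  expect_equal(nrow(scan_regions(genes, off, 15)), 0L)
  expect_error(scan_regions(genes, toy_hits("nope"), 15),
               class = "prophagr_validation_error")
})

test_that("a lone hit spans every window containing it, clipped at contig ends", {
  genes <- toy_gene_table(100)
  reg <- scan_regions(genes, toy_hits("g021"), 15)   # hit at rank 21
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$rank_from, reg$rank_to), c(7L, 35L))   # 21 +/- 14
  # brute-force window enumeration agrees
  expect_equal(reg$rank_from:reg$rank_to, window_union_oracle(100, 21, 15))
  # clipping at the left end
  reg2 <- scan_regions(genes, toy_hits("g003"), 15)
  expect_equal(c(reg2$rank_from, reg2$rank_to), c(1L, 17L))
  # bp interval spans first gene start to last gene end
  expect_equal(reg$start, genes$start[genes$rank == 7])
  expect_equal(reg$end, genes$end[genes$rank == 35])
})

test_that("nearby hits merge and distant hits stay separate regions", {
  genes <- toy_gene_table(100)
  two <- scan_regions(genes, toy_hits(c("g010", "g060")), 15)
  expect_equal(nrow(two), 2L)
  one <- scan_regions(genes, toy_hits(c("g010", "g020")), 15)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$rank_from, one$rank_to), c(1L, 34L))
})

test_that("scan matches brute-force window enumeration on 500 random layouts", {
  withr::with_seed(40, {
    for (trial in 1:500) {
      n <- sample(5:60, 1)
      w <- sample(c(1L, 5L, 15L), 1)
      hits <- sort(sample(n, sample(0:4, 1)))
      genes <- toy_gene_table(n)
      reg <- scan_regions(genes, toy_hits(sprintf("g%03d", hits)), w)
      got <- if (nrow(reg)) {
        sort(unlist(mapply(seq, reg$rank_from, reg$rank_to, SIMPLIFY = FALSE)))
      } else integer(0)
      expect_identical(as.integer(got), as.integer(window_union_oracle(n, hits, w)))
    }
  })
})

test_that("hit-bounded extent clips regions to the outermost hit genes", {
  genes <- toy_gene_table(100)
  reg <- scan_regions(genes, toy_hits(c("g021", "g025")), 15,
                      extent = "hit_bounded")
  expect_equal(c(reg$rank_from, reg$rank_to), c(21L, 25L))
})

test_that("classification follows the exhaustive 8-case truth table", {
  cases <- expand.grid(int = c(FALSE, TRUE), cap = c(FALSE, TRUE),
                       other = c(FALSE, TRUE))
  genes <- toy_gene_table(20)
  for (r in seq_len(nrow(cases))) {
    cats <- c(if (cases$int[r]) "integrase",
              if (cases$cap[r]) "major_capsid",
              if (cases$other[r]) "phage_archetype")
    ids <- sprintf("g%03d", seq_along(cats) + 4)
    hits <- if (length(cats)) {
      tibble::tibble(gene_id = ids, profile_id = "p", category = cats,
                     score = 99, significant = TRUE)
    } else toy_hits(character(0))
    reg <- scan_regions(genes, hits, 15)
    if (!length(cats)) {
      expect_equal(nrow(reg), 0L)
      next
    }
    cls <- classify_regions(reg, hits)$classes[[1]]
    expect_equal("integrated_element" %in% cls, cases$int[r])
    expect_equal("phage_related" %in% cls, cases$cap[r] || cases$other[r])
    expect_equal("candidate_PICI" %in% cls, cases$int[r] && cases$cap[r])
  }
})

test_that("regions overlapping accepted prophage calls lose integrated_element", {
  genes <- toy_gene_table(20)
  hits <- tibble::tibble(gene_id = "g005", profile_id = "p",
                         category = "integrase", score = 99, significant = TRUE)
  reg <- scan_regions(genes, hits, 15)
  calls <- tibble::tibble(contig_id = "c1", start = reg$start, end = reg$end)
  cls_free <- classify_regions(reg, hits)$classes[[1]]
  cls_ovl <- classify_regions(reg, hits, prophage_calls = calls)$classes[[1]]
  expect_true("integrated_element" %in% cls_free)
  expect_false("integrated_element" %in% cls_ovl)
})

test_that("defective flagging needs significant nucleotide evidence", {
  withr::with_seed(41, {
    phage <- rand_nt(20000)
    bg <- rand_nt(12000)
  })
  db <- phage_db(c(p = phage), tibble::tibble(phage_id = "p", cluster = "A"))
  cfg <- pipeline_config()
  remnant_region <- paste0(substr(bg, 1, 2000), substr(phage, 4001, 12000),
                           substr(bg, 2001, 4000))
  fd <- flag_defective(remnant_region, db, cfg)
  expect_true(fd$defective)
  expect_gte(max(fd$nt_evidence$aln_length), 8000L)
  expect_false(flag_defective(bg, db, cfg)$defective)
})

test_that("mutated remnants flip with the identity threshold (DP oracle agrees)", {
  withr::with_seed(42, {
    phage <- rand_nt(20000)
    remnant <- substr(phage, 2001, 7000)
    v <- strsplit(remnant, "")[[1]]
    pos <- sample(length(v), round(0.3 * length(v)))
    v[pos] <- vapply(v[pos], function(ch) sample(setdiff(c("A","C","G","T"), ch), 1), character(1))
    mutated <- paste(v, collapse = "")
  })
  db <- phage_db(c(p = phage), tibble::tibble(phage_id = "p", cluster = "A"))
  strict <- pipeline_config(min_alignment_identity = 0.80)
  loose <- pipeline_config(min_alignment_identity = 0.60)
  expect_false(flag_defective(mutated, db, strict)$defective)
  expect_true(flag_defective(mutated, db, loose)$defective)
})

test_that("QC filter omits truncated and contaminated calls and keeps clean ones", {
  cfg <- pipeline_config()
  asm <- genome_assembly(c(c1 = strrep("ACGT", 5000)), "1", "1")
  genes <- toy_gene_table(30)
  hits <- toy_hits(sprintf("g%03d", 1:20))           # ranks 1-20 are phage-like
  calls <- tibble::tibble(
    designation = c("prophi1.1-1", "prophi1.1-2", "prophi1.1-3"),
    contig_id = "c1",
    start = c(1001L, 19950L, 1L),
    end = c(1400L, 20000L, 420L),
    has_core = c(TRUE, FALSE, FALSE))
  # call 1: mid-contig with core -> kept; call 2: flush to contig end, no core
  # -> truncated; call 3: at contig start but gene-poor -> evaluated on genes
  calls$start <- c(81L, 19950L, 1L)   # call 1 covers genes ranks 5-20
  calls$end <- c(410L, 20000L, 599L)
  out <- filter_prophage_calls(calls, asm, genes, hits, cfg)
  expect_equal(out$status, c("kept", "omitted", "omitted"))
  expect_equal(out$omit_reason[2], "truncated_by_contig_end")
  # call 3 spans ranks 1-30 but only 20 have hits -> fraction 20/30 > 0.33,
  # yet its boundary touches the contig start without a core
  expect_equal(out$omit_reason[3], "truncated_by_contig_end")
  # contamination: a call whose gene fraction is low, away from ends
  calls4 <- tibble::tibble(designation = "prophi1.1-4", contig_id = "c1",
                           start = 401L, end = 610L, has_core = TRUE)
  # genes ranks 21-30 have no hits -> fraction 0
  out4 <- filter_prophage_calls(calls4, asm, genes, hits, cfg)
  expect_equal(out4$omit_reason, "excess_bacterial_sequence")
})

test_that("dedup groups byte-identical and strand-equivalent sequences", {
  s <- "ACGGTTACGGA"
  calls <- tibble::tibble(
    designation = sprintf("prophi1.1-%d", 1:5),
    sequence = c(s, s, revcomp(s), paste0(s, "A"), s))
  dd <- dedupe_prophages(calls)
  expect_equal(nrow(dd$unique), 2L)
  expect_equal(sort(dd$unique$multiplicity), c(1L, 4L))
  expect_equal(dd$unique$designation[dd$unique$multiplicity == 4], "prophi1.1-1")
  expect_equal(nrow(dd$multiplicity_table), 5L)
  one_sub <- dedupe_prophages(tibble::tibble(
    designation = c("a", "b"), sequence = c("ACGTT", "ACGTA")))
  expect_equal(nrow(one_sub$unique), 2L)
})
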