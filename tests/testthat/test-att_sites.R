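# host with an attB core, lysogenized by core + phage + core
att_fixture <- function(core_len = 45, seed = 50) {
  withr::with_seed(seed, {
    core <- rand_nt(core_len)
    # bases abutting the core copies are forced to differ so the planted core
    # is the maximal direct repeat
    host_l <- paste0(rand_nt(4999), "A")
    host_r <- paste0("A", rand_nt(4999))
    internal <- paste0("C", rand_nt(14998), "C")
  })
  host <- paste0(host_l, core, host_r)
  phage <- paste0(core, internal, core)
  lysogen <- paste0(host_l, phage, host_r)
  list(core = core, host = host, phage = phage, lysogen = lysogen,
       pro_start = 5001L, pro_end = 5000L + nchar(phage))
}

test_that("the planted att core is recovered exactly at prophage boundaries", {
  fx <- att_fixture()
  asm <- genome_assembly(c(c1 = fx$lysogen), "1", "1")
  core <- find_core_repeats(asm, "c1", fx$pro_start, fx$pro_end, pipeline_config())
  expect_false(is.null(core))
  expect_equal(core$sequence, fx$core)
  expect_equal(core$length, 45L)
  expect_equal(core$attL_start, fx$pro_start)
  expect_equal(core$attR_end, fx$pro_end)
})

test_that("no qualifying repeat returns NULL and ties break leftmost", {
  withr::with_seed(51, seqs <- rand_nt(4000))
  asm <- genome_assembly(c(c1 = seqs), "1", "1")
  cfg <- pipeline_config(boundary_search_bp = 300, core_alpha = NULL,
                         min_core_len_bp = 12)
  expect_null(find_core_repeats(asm, "c1", 1000, 3000, cfg))
  # two equal-length candidate repeats: leftmost pair wins
  rep1 <- "ACGTACGTGGCCTTAA"
  left_win <- paste0(strrep("C", 50), rep1, strrep("G", 30), rep1, strrep("C", 50))
  right_win <- paste0(strrep("T", 60), rep1, strrep("A", 80))
  withr::with_seed(56, spacer <- rand_nt(1000))
  genome <- paste0(left_win, spacer, right_win)
  asm2 <- genome_assembly(c(k = genome), "1", "1")
  cfg2 <- pipeline_config(boundary_search_bp = 150, core_alpha = NULL,
                          min_core_len_bp = 10)
  core <- find_core_repeats(asm2, "k", 150, nchar(genome) - 150, cfg2)
  expect_equal(core$sequence, rep1)
  expect_equal(core$attL_start, 51L)   # leftmost of the two left copies
  expect_error(find_core_repeats(asm2, "k", 0, 50, cfg2),
               class = "prophagr_range_error")
})

test_that("attP reconstruction circularizes at the core", {
  fx <- att_fixture()
  asm <- genome_assembly(c(c1 = fx$lysogen), "1", "1")
  core <- find_core_repeats(asm, "c1", fx$pro_start, fx$pro_end, pipeline_config())
  attP <- reconstruct_attP(fx$phage, core)
  # exactly one core copy at the junction
  expect_equal(
    length(gregexpr(fx$core, attP$sequence, fixed = TRUE)[[1]]), 1L)
  expect_equal(nchar(attP$sequence), nchar(fx$phage) - nchar(fx$core))
  expect_error(reconstruct_attP(substr(fx$phage, 10, 1000), core),
               class = "prophagr_consistency_error")
})

test_that("integration then excision is the identity on random fixtures", {
  withr::with_seed(52, {
    for (i in 1:100) {
      core <- rand_nt(sample(12:50, 1))
      host <- paste0(rand_nt(sample(200:600, 1)), core,
                     rand_nt(sample(200:600, 1)))
      attB_start <- regexpr(core, host, fixed = TRUE)[1]
      circle <- paste0(core, rand_nt(sample(500:2000, 1)))
      lys <- integrate_at_attB(host, attB_start, circle, core)
      # excise: the prophage spans attL..attR in the lysogen
      pro <- substr(lys, attB_start, attB_start + nchar(circle) + nchar(core) - 1L)
      attP <- reconstruct_attP(pro, list(sequence = core))
      expect_identical(attP$sequence, circle)
      # reintegration restores the lysogen byte-exactly
      expect_identical(integrate_at_attB(host, attB_start, attP$sequence, core), lys)
    }
  })
})

test_that("occurrences map to exact reference coordinates, SNPs tolerated", {
  fx <- att_fixture()
  ref <- genome_assembly(c(chrom = fx$host), "1", "ref")
  asm <- genome_assembly(c(c1 = fx$lysogen), "1", "1")
  core <- find_core_repeats(asm, "c1", fx$pro_start, fx$pro_end, pipeline_config())
  occ <- tibble::tibble(strain_id = "s1", core_seq = core$sequence,
                        query_seq = att_occurrence_query(asm, core))
  placed <- map_att_to_reference(occ, ref, pipeline_config())
  expect_equal(placed$status, "placed")
  expect_equal(placed$ref_start, 5001L)
  expect_equal(placed$ref_end, 5045L)
  # five SNPs in the flank still place at the same locus
  q <- occ$query_seq
  withr::with_seed(53, {
    v <- strsplit(q, "")[[1]]
    pos <- sample(150, 5)      # flank-only positions
    v[pos] <- vapply(v[pos], function(ch) sample(setdiff(c("A","C","G","T"), ch), 1), character(1))
  })
  occ2 <- tibble::tibble(strain_id = "s2", core_seq = core$sequence,
                         query_seq = paste(v, collapse = ""))
  placed2 <- map_att_to_reference(occ2, ref, pipeline_config())
  expect_equal(placed2$status, "placed")
  expect_equal(placed2$ref_start, 5001L)
})

test_that("duplicated loci with identical flanks are flagged ambiguous", {
  withr::with_seed(54, {
    blk <- rand_nt(600)
    filler <- rand_nt(3000)
  })
  ref <- genome_assembly(c(chrom = paste0(blk, filler, blk)), "1", "ref")
  occ <- tibble::tibble(strain_id = "s", core_seq = substr(blk, 401, 445),
                        query_seq = substr(blk, 201, 445))
  placed <- map_att_to_reference(occ, ref, pipeline_config())
  expect_equal(placed$status, "ambiguous")
  # an unplaceable occurrence is reported as such
  withr::with_seed(55, alien <- rand_nt(245))
  occ3 <- tibble::tibble(strain_id = "s3", core_seq = substr(alien, 201, 245),
                         query_seq = alien)
  expect_equal(map_att_to_reference(occ3, ref, pipeline_config())$status,
               "unplaced")
})

test_that("consensus attB is the intersection of overlapping occurrences", {
  one <- tibble::tibble(strain_id = c("a", "b", "c"), status = "placed",
                        ref_start = c(1000L, 1000L, 1000L),
                        ref_end = c(1044L, 1044L, 1044L))
  cons <- consensus_attB(one)
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$ref_start, cons$ref_end), c(1000L, 1044L))
  expect_equal(cons$n_occurrences, 3L)

  jitter <- tibble::tibble(strain_id = c("a", "b", "c"), status = "placed",
                           ref_start = c(1000L, 997L, 1003L),
                           ref_end = c(1044L, 1041L, 1047L))
  cons2 <- consensus_attB(jitter)
  expect_equal(c(cons2$ref_start, cons2$ref_end), c(1003L, 1041L))

  two <- tibble::tibble(strain_id = c("a", "b"), status = "placed",
                        ref_start = c(1000L, 9000L), ref_end = c(1044L, 9044L))
  cons3 <- consensus_attB(two)
  expect_equal(cons3$attB_id, c("attB-1", "attB-2"))
  # consensus intervals always lie inside every member occurrence
  for (i in seq_len(nrow(cons2))) {
    occs <- cons2$occurrences[[i]]
    expect_true(all(occs$ref_start <= cons2$ref_start[i]))
    expect_true(all(occs$ref_end >= cons2$ref_end[i]))
  }
})

test_that("attB overlap annotation reports the overlapping RNA feature", {
  attB <- tibble::tibble(attB_id = c("attB-1", "attB-2", "attB-3"),
                         ref_start = c(100L, 500L, 900L),
                         ref_end = c(145L, 545L, 945L),
                         n_occurrences = 1L, occurrences = list(NULL))
  feats <- tibble::tibble(
    feature_id = c("t1", "t2"), type = c("tRNA", "tmRNA"),
    isotype = c("tRNA-Arg(ACG)", "tmRNA"),
    start = c(90L, 930L), end = c(160L, 1010L))
  out <- annotate_overlap(attB, feats)
  expect_equal(out$overlap_feature, c("tRNA-Arg(ACG)", NA, "tmRNA"))
})
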