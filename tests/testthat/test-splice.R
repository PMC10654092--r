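# a small two-reference database with one phage split across two contigs
splice_fixture <- function(split_frac = 0.4, revcomp_second = FALSE) {
  withr::with_seed(30, {
    ref <- rand_nt(20000)
    other <- rand_nt(15000)
    host1 <- rand_nt(6000); host2 <- rand_nt(7000)
  })
  cut <- round(split_frac * 20000)
  c1 <- paste0(host1, substr(ref, 1, cut))
  frag2 <- substr(ref, cut + 1, 20000)
  if (revcomp_second) frag2 <- revcomp(frag2)
  c2 <- if (revcomp_second) paste0(host2, frag2) else paste0(frag2, host2)
  asm <- genome_assembly(c(c1 = c1, c2 = c2), "7", "3")
  db <- phage_db(c(refA = ref, refB = other),
                 tibble::tibble(phage_id = c("refA", "refB"),
                                cluster = c("HC", "B")))
  list(asm = asm, db = db, ref = ref, cut = cut)
}

test_that("end fragments are found at contig ends with exact coordinates", {
  fx <- splice_fixture()
  fr <- find_end_fragments(fx$asm, fx$db, pipeline_config())
  expect_equal(nrow(fr), 2L)
  expect_setequal(fr$contig_id, c("c1", "c2"))
  expect_true(all(fr$end_distance == 0L))
  expect_true(all(fr$reference_id == "refA"))
  f1 <- fr[fr$contig_id == "c1", ]
  expect_equal(c(f1$ref_start, f1$ref_end), c(1L, fx$cut))
  expect_equal(f1$frag_end, 6000L + fx$cut)
})

test_that("interior similarity and empty databases are handled", {
  withr::with_seed(31, {
    ref <- rand_nt(10000)
    contig <- paste0(rand_nt(20000), substr(ref, 1, 6000), rand_nt(20000))
  })
  asm <- genome_assembly(c(c1 = contig), "1", "1")
  db <- phage_db(c(r = ref), tibble::tibble(phage_id = "r", cluster = "A"))
  fr <- find_end_fragments(asm, db, pipeline_config())
  expect_equal(nrow(fr), 0L)     # 20 kb from both ends, margin 5 kb
  none <- genome_assembly(c(c1 = substr(contig, 1, 5000)), "1", "1")
  expect_equal(nrow(find_end_fragments(none, db, pipeline_config())), 0L)
  expect_error(find_end_fragments(asm, list(sequences = c()), pipeline_config()),
               class = "prophagr_configuration_error")
})

test_that("splicing reconstructs the planted prophage byte-identically", {
  fx <- splice_fixture()
  fr <- find_end_fragments(fx$asm, fx$db, pipeline_config())
  sp <- splice_fragments(fr, fx$asm, fx$db, pipeline_config())
  expect_identical(sp$sequence, fx$ref)
  expect_equal(sp$completeness, "complete_on_reference")
  sp <- assign_cluster_from_reference(sp, fx$db)
  expect_equal(sp$cluster_label, "HC")
})

test_that("reverse-complemented fragments are orientation-corrected", {
  fx <- splice_fixture(revcomp_second = TRUE)
  fr <- find_end_fragments(fx$asm, fx$db, pipeline_config())
  expect_setequal(fr$orientation, c("+", "-"))
  sp <- splice_fragments(fr, fx$asm, fx$db, pipeline_config())
  expect_identical(sp$sequence, fx$ref)
  expect_equal(sp$completeness, "complete_on_reference")
})

test_that("fragment input order never changes the spliced sequence", {
  fx <- splice_fixture(split_frac = 0.55)
  fr <- find_end_fragments(fx$asm, fx$db, pipeline_config())
  sp1 <- splice_fragments(fr, fx$asm, fx$db, pipeline_config())
  sp2 <- splice_fragments(fr[rev(seq_len(nrow(fr))), ], fx$asm, fx$db,
                          pipeline_config())
  expect_identical(sp1$sequence, sp2$sequence)
})

test_that("overlapping reference coverage is trimmed from the later fragment", {
  withr::with_seed(32, ref <- rand_nt(12000))
  asm <- genome_assembly(c(c1 = substr(ref, 1, 7000),
                           c2 = substr(ref, 5001, 12000)), "1", "1")
  db <- phage_db(c(r = ref), tibble::tibble(phage_id = "r", cluster = "A"))
  fr <- find_end_fragments(asm, db, pipeline_config())
  sp <- splice_fragments(fr, asm, db, pipeline_config())
  expect_identical(sp$sequence, ref)   # 2 kb overlap kept from earlier fragment
})

test_that("single fragments splice to partial and errors are classified", {
  fx <- splice_fixture()
  fr <- find_end_fragments(fx$asm, fx$db, pipeline_config())
  one <- fr[1, ]
  sp <- splice_fragments(one, fx$asm, fx$db, pipeline_config())
  expect_equal(sp$completeness, "partial")
  expect_identical(sp$sequence, substr(fx$ref, 1, fx$cut))
  expect_error(splice_fragments(fr[0, ], fx$asm, fx$db, pipeline_config()),
               class = "prophagr_validation_error")
  mixed <- fr; mixed$reference_id <- c("refA", "refB")
  expect_error(splice_fragments(mixed, fx$asm, fx$db, pipeline_config()),
               class = "prophagr_grouping_error")
  bad_db <- phage_db(fx$db$sequences,
                     tibble::tibble(phage_id = "refA", cluster = ""))
  sp2 <- splice_fragments(fr, fx$asm, bad_db, pipeline_config())
  expect_error(assign_cluster_from_reference(sp2, bad_db),
               class = "prophagr_annotation_error")
})

test_that("no chimeras: fragments from different references never concatenate", {
  withr::with_seed(33, {
    refA <- rand_nt(16000); refB <- rand_nt(16000)
    host <- rand_nt(4000)
  })
  asm <- genome_assembly(
    c(c1 = paste0(host, substr(refA, 1, 8000)),
      c2 = paste0(substr(refB, 8001, 16000), host)), "1", "1")
  db <- phage_db(c(refA = refA, refB = refB),
                 tibble::tibble(phage_id = c("refA", "refB"),
                                cluster = c("A", "B")))
  fr <- find_end_fragments(asm, db, pipeline_config())
  expect_equal(sort(unique(fr$reference_id)), c("refA", "refB"))
  for (rid in unique(fr$reference_id)) {
    sp <- splice_fragments(fr[fr$reference_id == rid, ], asm, db, pipeline_config())
    expect_equal(unique(sp$fragments$reference_id), rid)
    expect_equal(sp$completeness, "partial")
  }
})

test_that("the built-in validator accepts phage-gene-rich sequences only", {
  cfg <- pipeline_config()
  prof_db <- default_profile_db()
  v <- profile_validator(prof_db, cfg)
  # genes drawn from archetypes: accept
  genes_good <- as_gene_table(tibble::tibble(
    gene_id = sprintf("g%d", 1:4), contig_id = "x",
    start = c(1, 100, 200, 300), end = c(50, 150, 250, 350), strand = "+",
    protein = c(category_archetype("phage_archetype", 1),
                category_archetype("phage_archetype", 2),
                category_archetype("phage_archetype", 3),
                category_archetype("integrase"))))
  expect_true(v("ACGT", genes_good))
  withr::with_seed(34, genes_bad <- as_gene_table(tibble::tibble(
    gene_id = sprintf("g%d", 1:4), contig_id = "x",
    start = c(1, 100, 200, 300), end = c(50, 150, 250, 350), strand = "+",
    protein = vapply(1:4, function(i) rand_aa(150), character(1)))))
  expect_false(v("ACGT", genes_bad))
  sp <- structure(list(sequence = "ACGT", reference_id = "r"),
                  class = "spliced_prophage")
  boom <- function(sequence, genes) stop("nope")
  expect_error(validate_spliced(sp, boom, genes_good),
               class = "prophagr_validator_error")
})
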