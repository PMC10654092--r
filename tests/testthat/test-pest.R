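test_that("a single toxin gene collects its two-ORF neighborhood", {
  genes <- layout_genes(list(c("a", "b", "PT", "c", "d")))
  net <- build_neighborhood_network(genes, "PT", radius = 2)
  expect_setequal(net$nodes, c("PT", "a", "b", "c", "d"))
  pt_edges <- net$edges[net$edges$pham_a == "PT" | net$edges$pham_b == "PT", ]
  expect_equal(nrow(pt_edges), 4L)
  expect_error(build_neighborhood_network(
    dplyr::mutate(genes, pham_id = replace(pham_id, 1, NA)), "PT"),
    class = "prophagr_validation_error")
})

test_that("neighborhoods sharing a pham merge into one network", {
  genes <- layout_genes(list(c("a", "PT1", "x"), c("x", "PT2", "b")))
  net <- build_neighborhood_network(genes, c("PT1", "PT2"), radius = 2)
  expect_setequal(net$nodes, c("a", "PT1", "x", "PT2", "b"))
  expect_gte(net$iterations_to_fixpoint, 1L)
  empty <- build_neighborhood_network(genes, character(0), radius = 2)
  expect_equal(length(empty$nodes), 0L)
  expect_equal(empty$iterations_to_fixpoint, 0L)
})

test_that("fixpoint equals the component oracle on 100 random layouts", {
  withr::with_seed(60, {
    for (trial in 1:100) {
      radius <- sample(1:3, 1)
      n_gen <- sample(2:5, 1)
      pool <- sprintf("p%02d", 1:25)
      layouts <- lapply(1:n_gen, function(i) sample(pool, sample(4:15, 1), replace = TRUE))
      seeds <- sample(pool, 2)
      genes <- layout_genes(layouts)
      net <- build_neighborhood_network(genes, seeds, radius = radius)
      expect_identical(net$nodes, network_nodes_oracle(layouts, seeds, radius))
    }
  })
})

test_that("seeds_only expansion stops after the first ring", {
  genes <- layout_genes(list(c("PT", "a", "b", "c")))
  full <- build_neighborhood_network(genes, "PT", radius = 1, expansion = "full")
  ring <- build_neighborhood_network(genes, "PT", radius = 1,
                                     expansion = "seeds_only")
  expect_setequal(full$nodes, c("PT", "a", "b", "c"))
  expect_setequal(ring$nodes, c("PT", "a"))
})

cassette_layout <- function(roles_ranked, strand = "+") {
  n <- length(roles_ranked) + 4
  pham <- c("x1", "x2", roles_ranked, "x3", "x4")
  tibble::tibble(gene_id = sprintf("g%02d", seq_along(pham)),
                 genome_id = "G1", contig_id = "c1",
                 rank = seq_along(pham),
                 strand = ifelse(pham %in% roles_ranked, strand, "+"),
                 pham_id = pham)
}

role_table <- tibble::tibble(pham_id = c("W", "W2", "P", "I"),
                             role = c("WXG", "WXG", "PT", "Imm"))

test_that("cassette architectures are read in transcription order", {
  three <- extract_cassettes(cassette_layout(c("W", "P", "I")), role_table)
  expect_equal(three$architecture, "three_gene")
  expect_equal(three$roles, "WXG,PT,Imm")
  four <- extract_cassettes(cassette_layout(c("W", "W2", "P", "I")), role_table)
  expect_equal(four$architecture, "four_gene")
  incomplete <- extract_cassettes(cassette_layout(c("W", "P")), role_table)
  expect_equal(incomplete$architecture, "incomplete")  # Delta-imm construct
  expect_equal(incomplete$roles, "WXG,PT")
})

test_that("cassette calls are strand-consistent and position-invariant", {
  plus <- extract_cassettes(cassette_layout(c("W", "P", "I"), "+"), role_table)
  minus <- extract_cassettes(cassette_layout(c("I", "P", "W"), "-"), role_table)
  expect_equal(minus$architecture, "three_gene")
  expect_equal(minus$roles, plus$roles)
  shifted <- cassette_layout(c("W", "P", "I"))
  shifted$rank <- shifted$rank + 40L
  expect_equal(extract_cassettes(shifted, role_table)$architecture, "three_gene")
})

test_that("role seeding assigns at most one role per pham, best score wins", {
  prof_db <- default_profile_db()
  cfg <- pipeline_config()
  prots <- tibble::tibble(
    gene_id = c("gpt", "gwxg", "gimm", "gnone"),
    protein = c(paste0(category_archetype("polymorphic_toxin", 1),
                       strrep("A", 50)),
                category_archetype("wxg100", 1),
                category_archetype("immunity", 2),
                strrep("MKV", 60)))
  phams <- tibble::tibble(pham_id = c("ph1", "ph2", "ph3", "ph4"),
                          gene_id = prots$gene_id, genome_id = "G1")
  roles <- seed_pest_homologs(phams, prots, prof_db, cfg)
  expect_equal(roles$role[match(c("ph1", "ph2", "ph3"), roles$pham_id)],
               c("PT", "WXG", "Imm"))
  expect_false("ph4" %in% roles$pham_id)
  expect_false(any(roles$conflict))
  expect_error(seed_pest_homologs(phams, prots, list(), cfg),
               class = "prophagr_configuration_error")
})

test_that("superfamilies recover the planted N-terminal archetypes", {
  withr::with_seed(61, {
    members <- dplyr::bind_rows(lapply(1:3, function(arch) {
      dplyr::bind_rows(lapply(1:6, function(j) {
        nterm <- mutate_aa(category_archetype("polymorphic_toxin", arch), 16)
        tibble::tibble(pham_id = sprintf("pt_%d_%d", arch, j),
                       protein = paste0(nterm, rand_aa(180)))
      }))
    }))
  })
  sf <- group_superfamilies(members, pipeline_config())
  expect_equal(length(unique(sf$superfamily)), 3L)
  truth_arch <- sub("^pt_(\\d)_.*$", "\\1", sf$pham_id)
  # zero cross-assignment: superfamily labels partition exactly by archetype
  expect_equal(length(unique(paste(truth_arch, sf$superfamily))), 3L)
  one <- group_superfamilies(members[1, ], pipeline_config())
  expect_equal(one$superfamily, "PEST1")
  # identical N-termini with divergent C-termini share a superfamily
  withr::with_seed(62, {
    nt <- rand_aa(150)
    pair <- tibble::tibble(pham_id = c("a", "b"),
                           protein = c(paste0(nt, rand_aa(100)),
                                       paste0(nt, rand_aa(120))))
  })
  sf2 <- group_superfamilies(pair, pipeline_config(nterm_window_aa = 150))
  expect_equal(length(unique(sf2$superfamily)), 1L)
})

test_that("conservation profiles expose WXG/linker/TOX boundaries", {
  ident <- conservation_profile(rep(strrep("MAVK", 25), 3), smooth_window = 15)
  expect_true(all(ident$profile$conservation == 1))
  expect_equal(unique(ident$profile$segment), "conserved")

  half <- conservation_profile(c("AA", "AV"), smooth_window = 1)
  expect_equal(half$profile$conservation, c(1, 0.5))

  expect_error(conservation_profile("AA"), class = "prophagr_validation_error")
  expect_error(conservation_profile(c("AA", "AAA")),
               class = "prophagr_validation_error")

  # planted domain structure: conserved head, random middle, conserved tail
  withr::with_seed(63, {
    head_c <- rand_aa(100); tail_c <- rand_aa(150)
    seqs <- vapply(1:8, function(i) {
      paste0(head_c, rand_aa(50), tail_c)
    }, character(1))
  })
  prof <- conservation_profile(seqs, smooth_window = 15)
  expect_lte(abs(prof$boundaries[["wxg_end"]] - 100), 10)
  expect_lte(abs(prof$boundaries[["tox_start"]] - 151), 10)
  segs <- prof$profile$segment
  expect_equal(segs[1], "WXG")
  expect_equal(segs[length(segs)], "TOX")
  expect_true("linker" %in% segs)
})

test_that("gaps count in the denominator but not the numerator", {
  prof <- conservation_profile(c("A-", "AA", "AA", "A-"), smooth_window = 1)
  expect_equal(prof$profile$conservation, c(1, 0.5))
})
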