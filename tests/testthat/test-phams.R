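pham_sets <- function(ps) {
  # pham membership as a canonical list of sorted gene-id sets
  unname(lapply(split(ps$phams$gene_id, ps$phams$pham_id), sort))
}

test_that("identical proteins share one pham; duplicates rejected", {
  prots <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          protein = rep(strrep("MAV", 30), 3))
  ps <- build_phams(prots)
  expect_equal(nrow(ps$representatives), 1L)
  expect_equal(ps$representatives$n_members, 3L)
  expect_error(build_phams(tibble::tibble(gene_id = c("a", "a"),
                                          protein = c("MM", "MM"))),
               class = "prophagr_validation_error")
  empty <- build_phams(tibble::tibble(gene_id = character(),
                                      protein = character()))
  expect_equal(nrow(empty$phams), 0L)
})

test_that("unrelated random proteins stay singletons (all-pairs DP oracle)", {
  withr::with_seed(20, prots <- vapply(1:20, function(i) rand_aa(60), character(1)))
  tab <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), protein = prots)
  ps <- build_phams(tab, 0.5, 0.5)
  expect_equal(nrow(ps$representatives), 20L)
  # oracle: exhaustive NW identity on every pair confirms no relation
  prs <- t(utils::combn(20, 2))
  ids <- vapply(seq_len(nrow(prs)), function(r) {
    nw_identity(prots[prs[r, 1]], prots[prs[r, 2]])
  }, numeric(1))
  expect_true(all(ids < 0.5))
})

test_that("transitive chains merge even when the ends are unrelated", {
  withr::with_seed(21, {
    a <- rand_aa(120)
    b <- mutate_aa(a, 48)    # ~60% identity to a
    c_ <- mutate_aa(b, 48)   # ~60% to b, ~lower to a
  })
  expect_gte(nw_identity(a, b), 0.5)
  expect_gte(nw_identity(b, c_), 0.5)
  ps <- build_phams(tibble::tibble(gene_id = c("a", "b", "c"),
                                   protein = c(a, b, c_)), 0.5, 0.5)
  expect_equal(nrow(ps$representatives), 1L)
  expect_setequal(ps$phams$gene_id, c("a", "b", "c"))
})

test_that("phams partition the gene set", {
  withr::with_seed(22, {
    fams <- lapply(1:5, function(i) rand_aa(70))
    prots <- unlist(lapply(fams, function(f) {
      vapply(1:4, function(j) mutate_aa(f, 5), character(1))
    }))
  })
  tab <- tibble::tibble(gene_id = sprintf("g%02d", seq_along(prots)),
                        protein = prots)
  ps <- build_phams(tab)
  expect_equal(sum(ps$representatives$n_members), nrow(tab))
  expect_equal(anyDuplicated(ps$phams$gene_id), 0L)
  expect_equal(nrow(ps$representatives), 5L)
})

test_that("shared gene content follows the symmetric-mean definition", {
  expect_equal(shared_gene_content(c("p1", "p2"), c("p1", "p2")), 1)
  expect_equal(shared_gene_content(c("p1"), c("p2")), 0)
  a <- sprintf("p%d", 1:10); b <- sprintf("p%d", 6:15)
  expect_equal(shared_gene_content(a, b), 0.5)
  expect_equal(shared_gene_content(a, b, metric = "min_denominator"), 0.5)
  # paralogs count once
  expect_equal(shared_gene_content(c("p1", "p1", "p2"), c("p1", "p3")),
               mean(c(1 / 2, 1 / 2)))
  expect_error(shared_gene_content(character(0), "p1"),
               class = "prophagr_validation_error")
})

make_pham_table <- function(sets) {
  dplyr::bind_rows(lapply(names(sets), function(g) {
    tibble::tibble(genome_id = g, pham_id = sets[[g]],
                   gene_id = paste0(g, "_", sets[[g]]))
  }))
}

test_that("cluster assignment equals union-find over exhaustive pairwise content", {
  withr::with_seed(23, {
    for (trial in 1:10) {
      n_gen <- sample(6:10, 1)
      pool <- sprintf("p%02d", 1:30)
      sets <- lapply(1:n_gen, function(i) sample(pool, sample(5:15, 1)))
      names(sets) <- sprintf("G%02d", 1:n_gen)
      tab <- make_pham_table(sets)
      got <- assign_clusters(tab, threshold = 0.35)
      # oracle
      p <- uf_new(n_gen)
      ids <- sort(names(sets))
      for (i in 1:(n_gen - 1)) for (j in (i + 1):n_gen) {
        m <- length(intersect(sets[[ids[i]]], sets[[ids[j]]]))
        sgc <- mean(c(m / length(unique(sets[[ids[i]]])),
                      m / length(unique(sets[[ids[j]]]))))
        if (sgc >= 0.35) p <- uf_union(p, i, j)
      }
      comp <- uf_components(p)
      oracle_part <- split(ids, comp)
      got_part <- split(got$genome_id, got$cluster_label)
      expect_setequal(lapply(unname(oracle_part), sort),
                      lapply(unname(got_part), sort))
      expect_equal(got$singleton,
                   got$cluster_label %in% names(which(table(got$cluster_label) == 1)))
    }
  })
})

test_that("cluster labels are size-ordered letters and straddle thresholds correctly", {
  sets <- list(G1 = c("a", "b", "c"), G2 = c("a", "b", "d"),
               G3 = c("a", "b", "e"), G4 = c("x", "y"), G5 = c("x", "z"),
               G6 = c("q"))
  tab <- make_pham_table(sets)
  got <- assign_clusters(tab, threshold = 0.35)
  expect_equal(got$cluster_label[got$genome_id == "G1"], "A")  # largest first
  expect_equal(got$cluster_label[got$genome_id == "G4"], "B")
  expect_true(got$singleton[got$genome_id == "G6"])
  expect_equal(prophagr:::cluster_letters(28)[27:28], c("AA", "AB"))
})

test_that("the 25% network is a supergraph of the 35% cluster graph", {
  withr::with_seed(24, {
    pool <- sprintf("p%02d", 1:25)
    sets <- lapply(1:8, function(i) sample(pool, sample(6:12, 1)))
    names(sets) <- sprintf("G%d", 1:8)
  })
  # add a pair engineered to straddle: sgc = 0.30
  sets$H1 <- sprintf("q%d", 1:10)
  sets$H2 <- c(sprintf("q%d", 1:3), sprintf("r%d", 1:7))
  tab <- make_pham_table(sets)
  net25 <- build_proteome_network(tab, threshold = 0.25)
  cl35 <- assign_clusters(tab, threshold = 0.35)
  edge_key <- paste(net25$genome_a, net25$genome_b)
  # straddling pair present at 0.25 ...
  expect_true("H1 H2" %in% edge_key)
  # ... but not co-clustered at 0.35
  expect_false(cl35$cluster_label[cl35$genome_id == "H1"] ==
                 cl35$cluster_label[cl35$genome_id == "H2"])
  # supergraph: every 0.35-edge appears in the 0.25 network
  net35 <- build_proteome_network(tab, threshold = 0.35)
  expect_true(all(paste(net35$genome_a, net35$genome_b) %in% edge_key))
  # monotone refinement: clusters at 0.35 refine clusters at 0.25
  cl25 <- assign_clusters(tab, threshold = 0.25)
  for (lab in unique(cl35$cluster_label)) {
    members <- cl35$genome_id[cl35$cluster_label == lab]
    expect_equal(length(unique(cl25$cluster_label[cl25$genome_id %in% members])), 1L)
  }
})

test_that("identical genomes get edge weight 1 and disjoint corpora no edges", {
  sets <- list(G1 = c("a", "b"), G2 = c("a", "b"))
  net <- build_proteome_network(make_pham_table(sets), threshold = 0.25)
  expect_equal(net$sgc, 1)
  disjoint <- list(G1 = c("a"), G2 = c("b"), G3 = c("c"))
  expect_equal(nrow(build_proteome_network(make_pham_table(disjoint), 0.25)), 0L)
})
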