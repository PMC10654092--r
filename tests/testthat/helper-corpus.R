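# The default synthetic corpus and its pipeline report are expensive; build
# them once per test run and share across test files.

.corpus_cache <- new.env(parent = emptyenv())

default_corpus <- function() {
  if (is.null(.corpus_cache$corpus)) {
    .corpus_cache$corpus <- generate_corpus(seed = 1)
  }
  .corpus_cache$corpus
}

default_report <- function() {
  if (is.null(.corpus_cache$report)) {
    corpus <- default_corpus()
    t0 <- cpu_secs()
    .corpus_cache$report <- run_pipeline(
      corpus$assemblies, corpus$db, corpus$profile_db, corpus$genes,
      config = pipeline_config(),
      reference = corpus$reference,
      reference_features = corpus$reference_features)
    .corpus_cache$report_elapsed <- cpu_secs() - t0
  }
  .corpus_cache$report
}

# CPU seconds consumed by this process: the single-CPU runtime budget,
# insensitive to other processes sharing the machine
cpu_secs <- function() {
  pt <- proc.time()
  unname(pt[["user.self"]] + pt[["sys.self"]])
}

report_elapsed <- function() {
  default_report()
  .corpus_cache$report_elapsed
}

truth_of <- function(corpus, type) {
  corpus$truth[corpus$truth$element_type == type, , drop = FALSE]
}

contig_lengths_all <- function(corpus) {
  out <- list()
  for (aid in names(corpus$assemblies)) {
    cl <- contig_lengths(corpus$assemblies[[aid]])
    for (cid in names(cl)) out[[paste(aid, cid)]] <- cl[[cid]]
  }
  out
}
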