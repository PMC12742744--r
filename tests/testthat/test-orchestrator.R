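# Shared fixture: a small registered genome plus a gene with a known number
# of planted guides.
local_pipeline <- function(n_guides = 5L, genome_len = 4000L,
                           config = engine_config(), env = parent.frame()) {
  genome_path <- withr::local_tempfile(fileext = ".fa", .local_envir = env)
  write_fixture_genome(genome_spec(genome_len, seed = 91L), genome_path)
  engine <- crispr_engine(config)
  register_genome(engine, "fixture", genome_path)
  list(engine = engine, genome_path = genome_path,
       gene = generate_gene_with_exact_guides(n_guides, seed = 92L))
}

test_that("job submission is asynchronous, unique, and validated", {
  p <- local_pipeline()
  set.seed(1)
  id1 <- submit_job(p$engine, p$gene, "fixture")
  id2 <- submit_job(p$engine, p$gene, "fixture")
  expect_false(id1 == id2)             # identical submissions never dedupe
  expect_equal(p$engine$jobs[[id1]]$status, "submitted")
  expect_error(submit_job(p$engine, p$gene, "no-such-genome"),
               class = "unknown_genome")
  # nothing has run yet: submission only enqueued the preparation event
  expect_equal(job_progress(p$engine, id1)$ontarget[["total"]], 0)
})

test_that("a complete run produces one dual-assessed record per candidate", {
  p <- local_pipeline(n_guides = 5L)
  set.seed(2)
  id <- submit_job(p$engine, p$gene, "fixture")
  run_until_idle(p$engine)
  prog <- job_progress(p$engine, id)
  expect_equal(prog$status, "complete")
  expect_equal(unname(prog$fraction), c(1, 1))
  res <- job_results(p$engine, id)
  expect_equal(nrow(res), 5L)
  expect_true(all(res$both_complete))
  expect_true(all(!is.na(res$specificity)))
  expect_true(all(res$consensus_votes %in% 0:3))
  expect_equal(res$start, sort(res$start))
})

test_that("dispatch enqueues n messages on each assessment queue", {
  p <- local_pipeline(n_guides = 7L)
  set.seed(3)
  id <- submit_job(p$engine, p$gene, "fixture")
  # drain only genome preparation and indexing
  while (length(p$engine$queues$genome_fetch$messages) > 0L ||
         length(p$engine$queues$index_build$messages) > 0L) {
    run_worker_batch(p$engine, "genome_fetch", 10L)
    run_worker_batch(p$engine, "index_build", 10L)
  }
  expect_length(p$engine$queues$ontarget$messages, 7L)
  expect_length(p$engine$queues$offtarget$messages, 7L)
  expect_equal(p$engine$jobs[[id]]$status, "assessing")
})

test_that("an empty gene completes immediately with zero results", {
  p <- local_pipeline()
  set.seed(4)
  id <- submit_job(p$engine, "", "fixture")
  run_until_idle(p$engine)
  prog <- job_progress(p$engine, id)
  expect_equal(prog$status, "complete")
  expect_equal(unname(prog$fraction), c(1, 1))
  expect_equal(nrow(job_results(p$engine, id)), 0L)
})

test_that("a cached genome makes the second job a warm run", {
  p <- local_pipeline()
  set.seed(5)
  id1 <- submit_job(p$engine, p$gene, "fixture")
  run_until_idle(p$engine)
  fetches <- p$engine$counters$enqueued_genome_fetch
  builds <- p$engine$counters$enqueued_index_build
  id2 <- submit_job(p$engine, p$gene, "fixture")
  run_until_idle(p$engine)
  # only the ensure event itself hits the fetch queue; no ranges, no build
  expect_equal(p$engine$counters$enqueued_genome_fetch, fetches + 1L)
  expect_equal(p$engine$counters$enqueued_index_build, builds)
  expect_equal(job_progress(p$engine, id2)$status, "complete")
})

test_that("large genomes are fetched as one task per planned byte range", {
  cfg <- engine_config(chunk_bytes = 1024L)   # force multi-chunk ingest
  p <- local_pipeline(genome_len = 2500L, config = cfg)
  size <- file.info(p$genome_path)$size
  expected_ranges <- nrow(plan_chunked_fetch(size, 1024L)$ranges)
  expect_gte(expected_ranges, 2L)
  set.seed(6)
  id <- submit_job(p$engine, p$gene, "fixture")
  run_worker_batch(p$engine, "genome_fetch", 1L)    # the ensure event
  expect_length(p$engine$queues$genome_fetch$messages, expected_ranges)
  run_until_idle(p$engine)
  expect_equal(job_progress(p$engine, id)$status, "complete")
})

test_that("a permanently failing fetch fails the job with a recorded cause", {
  engine <- crispr_engine(engine_config(retry_cap = 2L))
  missing <- file.path(tempdir(), "vanished-genome.fa")
  register_genome(engine, "ghost", missing)
  set.seed(7)
  id <- submit_job(engine, "ACGT", "ghost")
  run_until_idle(engine)
  prog <- job_progress(engine, id)
  expect_equal(prog$status, "failed")
  expect_match(prog$error, "not found")
})

test_that("redelivered messages change nothing (idempotency)", {
  p1 <- local_pipeline()
  p2 <- local_pipeline(config = engine_config(duplicate_delivery = TRUE))
  set.seed(8)
  id1 <- submit_job(p1$engine, p1$gene, "fixture")
  run_until_idle(p1$engine)
  set.seed(8)
  id2 <- submit_job(p2$engine, p2$gene, "fixture")
  run_until_idle(p2$engine)
  r1 <- job_results(p1$engine, id1)
  r2 <- job_results(p2$engine, id2)
  r1$job_id <- r2$job_id <- NULL
  expect_identical(r1, r2)
  expect_gt(p2$engine$counters$duplicates_dropped_ontarget, 0L)
})

test_that("batch size and worker count never change the results table", {
  runs <- list()
  for (cfg in list(list(bs = 1L, w = 1L), list(bs = 7L, w = 1L),
                   list(bs = 100L, w = 8L), list(bs = 7L, w = 8L))) {
    p <- local_pipeline(n_guides = 6L)
    set.seed(9)
    id <- submit_job(p$engine, p$gene, "fixture")
    run_until_idle(p$engine, workers = cfg$w, batch_size = cfg$bs)
    res <- job_results(p$engine, id)
    res$job_id <- NULL
    runs[[length(runs) + 1L]] <- res
  }
  for (i in 2:length(runs)) {
    expect_identical(runs[[i]], runs[[1L]])
  }
})

test_that("progress is monotone and partial results are flagged", {
  p <- local_pipeline(n_guides = 6L)
  set.seed(10)
  id <- submit_job(p$engine, p$gene, "fixture")
  prev <- c(0, 0)
  guard <- 0L
  while (job_progress(p$engine, id)$status != "complete" && guard < 500L) {
    for (q in c("genome_fetch", "index_build", "ontarget", "offtarget")) {
      run_worker_batch(p$engine, q, 1L)
    }
    cur <- unname(job_progress(p$engine, id)$fraction)
    expect_true(all(cur >= prev))
    prev <- cur
    guard <- guard + 1L
  }
  expect_equal(job_progress(p$engine, id)$status, "complete")
  expect_error(job_progress(p$engine, "job-nope"), class = "unknown_job")
})

test_that("the engine is event-driven: nothing runs on empty queues", {
  p <- local_pipeline()
  before <- mget(ls(p$engine$counters), envir = p$engine$counters)
  expect_equal(run_until_idle(p$engine), 0L)
  after <- mget(ls(p$engine$counters), envir = p$engine$counters)
  expect_identical(before, after)   # zero batches, zero handler invocations
})

test_that("a batch consumes at most batch_size and at most the queue depth", {
  p <- local_pipeline(n_guides = 7L)
  set.seed(11)
  submit_job(p$engine, p$gene, "fixture")
  while (length(p$engine$queues$ontarget$messages) == 0L) {
    run_worker_batch(p$engine, "genome_fetch", 10L)
    run_worker_batch(p$engine, "index_build", 10L)
  }
  expect_equal(run_worker_batch(p$engine, "ontarget", 3L), 3L)
  expect_equal(run_worker_batch(p$engine, "ontarget", 10L), 4L)
  expect_equal(run_worker_batch(p$engine, "ontarget", 10L), 0L)
})

test_that("results serialize to CSV and JSON and engines snapshot to disk", {
  p <- local_pipeline(n_guides = 3L)
  set.seed(12)
  id <- submit_job(p$engine, p$gene, "fixture")
  run_until_idle(p$engine)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_job_results(p$engine, id, csv, format = "csv")
  back <- read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 3L)
  expect_true(all(c("target23", "specificity", "accepted") %in% names(back)))
  js <- withr::local_tempfile(fileext = ".json")
  write_job_results(p$engine, id, js, format = "json")
  expect_equal(length(jsonlite::read_json(js)), 3L)

  snap <- withr::local_tempfile(fileext = ".rds")
  save_engine(p$engine, snap)
  eng2 <- load_engine(snap)
  expect_identical(job_results(eng2, id), job_results(p$engine, id))
})

test_that("config files override engine defaults", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# engine settings", "chunk_bytes=2048", "max_mm=3",
               "weights=uniform", "batch_size_ontarget=5",
               "duplicate_delivery=false"), path)
  cfg <- read_config(path)
  expect_equal(cfg$chunk_bytes, 2048)
  expect_equal(cfg$max_mm, 3L)
  expect_equal(cfg$weights, "uniform")
  expect_equal(cfg$batch_size$ontarget, 5L)
  expect_false(cfg$duplicate_delivery)
})

test_that("design_guides wraps the engine end to end", {
  genome_path <- withr::local_tempfile(fileext = ".fa")
  write_fixture_genome(genome_spec(3000L, seed = 15L), genome_path)
  gene <- generate_gene_with_exact_guides(4L, seed = 16L)
  set.seed(17)
  res <- design_guides(gene, genome_path)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$both_complete))
})
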