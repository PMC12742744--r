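# Event-driven pipeline engine: jobs, per-stage message queues, stateless
# batch workers, resource limits, progress, and results. Reproduces the
# serverless execution contract locally — queues trigger handlers, handlers
# keep no state between invocations (everything comes from the message and
# the shared stores), re-delivered messages are no-ops, and nothing runs
# while the queues are empty.

QUEUE_NAMES <- c("genome_fetch", "index_build", "ontarget", "offtarget")

#' Engine configuration
#'
#' Worker limits mirror a serverless execution contract: a batch that would
#' exceed `max_task_seconds` stops early and leaves the remaining messages
#' queued (checkpoint-and-requeue) rather than overrun.
#'
#' @param chunk_bytes byte-range portion size for genome fetches.
#' @param num_slices ISSL slice count.
#' @param max_mm off-target mismatch bound.
#' @param consensus_threshold on-target votes needed for acceptance.
#' @param weights off-target weight mode (`"literature"` or `"uniform"`).
#' @param batch_size named list of per-queue batch sizes.
#' @param retry_cap deliveries allowed before a message fails its job.
#' @param max_task_seconds per-batch wall-clock budget (default 900 = 15 min).
#' @param max_memory_bytes advisory memory ceiling (default 10 * 2^30).
#' @param max_concurrency advisory worker ceiling (default 1000).
#' @param duplicate_delivery if `TRUE`, every enqueued message is delivered
#'   twice (a redelivery stress mode; results must not change).
#' @return a named list of class `engine_config`.
#' @export
engine_config <- function(chunk_bytes = DEFAULT_CHUNK_BYTES,
                          num_slices = 5L,
                          max_mm = 4L,
                          consensus_threshold = 2L,
                          weights = "literature",
                          batch_size = list(genome_fetch = 1L,
                                            index_build = 1L,
                                            ontarget = 100L,
                                            offtarget = 10L),
                          retry_cap = 3L,
                          max_task_seconds = 900,
                          max_memory_bytes = 10 * 2^30,
                          max_concurrency = 1000L,
                          duplicate_delivery = FALSE) {
  stopifnot(chunk_bytes > 0, retry_cap >= 1L, max_task_seconds > 0,
            max_memory_bytes > 0, max_concurrency >= 1L)
  structure(
    list(chunk_bytes = chunk_bytes, num_slices = as.integer(num_slices),
         max_mm = as.integer(max_mm),
         consensus_threshold = as.integer(consensus_threshold),
         weights = weights, batch_size = batch_size,
         retry_cap = as.integer(retry_cap),
         max_task_seconds = max_task_seconds,
         max_memory_bytes = max_memory_bytes,
         max_concurrency = as.integer(max_concurrency),
         duplicate_delivery = isTRUE(duplicate_delivery)),
    class = "engine_config"
  )
}

#' Read a plain-text key=value configuration file
#'
#' Lines are `key=value`; blank lines and `#` comments are ignored. Values
#' that parse as numbers are coerced. Keys matching [engine_config()]
#' arguments override its defaults; `batch_size_<queue>` keys set per-queue
#' batch sizes.
#'
#' @param path config file path.
#' @return an `engine_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1L), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1L)))
  coerce <- function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n
    else if (v %in% c("true", "TRUE")) TRUE
    else if (v %in% c("false", "FALSE")) FALSE
    else v
  }
  parsed <- stats::setNames(lapply(vals, coerce), keys)
  args <- parsed[names(parsed) %in% names(formals(engine_config))]
  cfg <- do.call(engine_config, args)
  bs <- grepl("^batch_size_", names(parsed))
  for (k in names(parsed)[bs]) {
    cfg$batch_size[[sub("^batch_size_", "", k)]] <- as.integer(parsed[[k]])
  }
  cfg
}

#' Create a pipeline engine
#'
#' The engine bundles the pluggable stores — job table, per-stage queues,
#' genome registry/cache, result table, idempotency keys, instrumentation
#' counters — behind one handle. All state lives here; handlers are pure
#' functions of a message and these stores.
#'
#' @param config an [engine_config()].
#' @return an environment of class `crispr_engine`.
#' @export
crispr_engine <- function(config = engine_config()) {
  eng <- new.env(parent = emptyenv())
  eng$config <- config
  eng$jobs <- new.env(parent = emptyenv())
  eng$queues <- stats::setNames(
    lapply(QUEUE_NAMES, function(q) {
      e <- new.env(parent = emptyenv()); e$messages <- list(); e
    }), QUEUE_NAMES)
  eng$genomes <- new.env(parent = emptyenv())   # label -> list(path, fetcher)
  eng$cache <- new.env(parent = emptyenv())     # label -> plan/portions/index
  eng$results <- new.env(parent = emptyenv())   # job_id -> list of records
  eng$processed <- new.env(parent = emptyenv()) # idempotency keys
  eng$counters <- new.env(parent = emptyenv())
  for (q in QUEUE_NAMES) {
    eng$counters[[paste0("enqueued_", q)]] <- 0L
    eng$counters[[paste0("handled_", q)]] <- 0L
    eng$counters[[paste0("batches_", q)]] <- 0L
    eng$counters[[paste0("duplicates_dropped_", q)]] <- 0L
  }
  eng$msg_seq <- 0L
  eng$job_seq <- 0L
  class(eng) <- "crispr_engine"
  eng
}

#' @export
print.crispr_engine <- function(x, ...) {
  depths <- vapply(x$queues, function(q) length(q$messages), integer(1L))
  cat(sprintf("<crispr_engine> %d job(s); queue depths: %s\n",
              length(ls(x$jobs)),
              paste(sprintf("%s=%d", names(depths), depths), collapse = " ")))
  invisible(x)
}

#' Register a genome with the engine
#'
#' @param engine a [crispr_engine()].
#' @param label reference name used by jobs (`genome_ref`).
#' @param path local FASTA file backing the genome.
#' @param fetcher byte-range fetcher (default a [local_file_fetcher()] over
#'   `path`); swap in a remote fetcher with the same signature to back the
#'   label by an accession instead.
#' @return `label`, invisibly.
#' @export
register_genome <- function(engine, label, path,
                            fetcher = local_file_fetcher(path)) {
  engine$genomes[[label]] <- list(path = path, fetcher = fetcher)
  invisible(label)
}

.now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")

.set_status <- function(engine, job_id, status, error = NULL) {
  job <- engine$jobs[[job_id]]
  terminal <- c("complete", "failed")
  if (job$status %in% terminal) {
    return(invisible(NULL))
  }
  job$status <- status
  job$updated_at <- .now()
  if (!is.null(error)) {
    job$error <- error
  }
  engine$jobs[[job_id]] <- job
  invisible(NULL)
}

.payload_key <- function(queue_name, payload) {
  paste0(queue_name, "|",
         paste(names(payload),
               vapply(payload, function(v) paste(format(v), collapse = ","),
                      character(1L)),
               sep = "=", collapse = ";"))
}

.enqueue <- function(engine, queue_name, payload) {
  times <- if (engine$config$duplicate_delivery) 2L else 1L
  for (i in seq_len(times)) {
    engine$msg_seq <- engine$msg_seq + 1L
    msg <- list(message_id = sprintf("m%06d", engine$msg_seq),
                queue_name = queue_name, payload = payload,
                delivery_count = i)
    q <- engine$queues[[queue_name]]
    q$messages <- c(q$messages, list(msg))
  }
  ctr <- paste0("enqueued_", queue_name)
  engine$counters[[ctr]] <- engine$counters[[ctr]] + 1L
  invisible(NULL)
}

#' Submit a guide-design job
#'
#' Persists the job, enqueues the genome-preparation event, and returns
#' immediately; all work happens when workers drain the queues (see
#' [run_until_idle()]).
#'
#' @param engine a [crispr_engine()].
#' @param gene_sequence nucleotide string of the gene to target (may be
#'   empty; the job then completes with zero results). Normalized on
#'   submission.
#' @param genome_ref a label previously passed to [register_genome()].
#' @return the new job id (jobs are never deduplicated; identical
#'   submissions get distinct ids).
#' @export
submit_job <- function(engine, gene_sequence, genome_ref) {
  if (is.null(engine$genomes[[genome_ref]])) {
    stop(structure(
      class = c("unknown_genome", "error", "condition"),
      list(message = paste0("unknown genome_ref: ", genome_ref), call = NULL)
    ))
  }
  engine$job_seq <- engine$job_seq + 1L
  token <- paste(sample(c(0:9, letters[1:6]), 8L, replace = TRUE),
                 collapse = "")
  job_id <- sprintf("job-%s-%04d", token, engine$job_seq)
  engine$jobs[[job_id]] <- list(
    job_id = job_id,
    gene_sequence = normalize_sequence(gene_sequence),
    genome_ref = genome_ref,
    status = "submitted",
    error = NULL,
    created_at = .now(),
    updated_at = .now()
  )
  engine$results[[job_id]] <- list()
  .enqueue(engine, "genome_fetch", list(type = "ensure", job_id = job_id))
  job_id
}

# Handlers ---------------------------------------------------------------

#' Ensure a job's genome (and its index) are available
#'
#' Cache hit: the job skips straight to candidate assessment (a warm run —
#' no fetch or index tasks are enqueued). Cache miss: the genome file is
#' chunk-planned and one fetch task per byte range is queued; an index-build
#' task follows once all portions have merged. Jobs arriving while a fetch
#' or build is already in flight wait on the same cache entry.
#'
#' @param engine a [crispr_engine()].
#' @param job_id id of a submitted job.
#' @return invisibly, `NULL`.
#' @export
ensure_genome <- function(engine, job_id) {
  job <- engine$jobs[[job_id]]
  ref <- job$genome_ref
  cache <- engine$cache[[ref]]
  if (!is.null(cache$index)) {
    .start_assessment(engine, job_id)
    return(invisible(NULL))
  }
  .set_status(engine, job_id, "preparing_genome")
  if (!is.null(cache)) {            # fetch/build already in flight
    cache$waiting <- union(cache$waiting, job_id)
    engine$cache[[ref]] <- cache
    return(invisible(NULL))
  }
  info <- file.info(engine$genomes[[ref]]$path)
  if (is.na(info$size)) {
    stop(structure(
      class = c("fetch_error", "error", "condition"),
      list(message = paste0("genome file not found: ",
                            engine$genomes[[ref]]$path), call = NULL)
    ))
  }
  plan <- plan_chunked_fetch(info$size, engine$config$chunk_bytes)
  engine$cache[[ref]] <- list(plan = plan, portions = list(),
                              waiting = job_id, index = NULL)
  for (i in seq_len(nrow(plan$ranges))) {
    .enqueue(engine, "genome_fetch",
             list(type = "range", genome_ref = ref,
                  start = plan$ranges[i, "start"],
                  end = plan$ranges[i, "end"]))
  }
  invisible(NULL)
}

.handle_range <- function(engine, payload) {
  ref <- payload$genome_ref
  cache <- engine$cache[[ref]]
  bytes <- engine$genomes[[ref]]$fetcher(ref, payload$start, payload$end)
  key <- sprintf("%.0f-%.0f", payload$start, payload$end)
  cache$portions[[key]] <- list(start = payload$start, end = payload$end,
                                bytes = bytes)
  engine$cache[[ref]] <- cache
  if (length(cache$portions) == nrow(cache$plan$ranges)) {
    merged <- merge_portions(cache$plan, unname(cache$portions))
    cache$merged <- merged
    cache$portions <- list()        # portions no longer needed
    engine$cache[[ref]] <- cache
    for (jid in cache$waiting) {
      .set_status(engine, jid, "indexing")
    }
    .enqueue(engine, "index_build", list(genome_ref = ref))
  }
  invisible(NULL)
}

.handle_index_build <- function(engine, payload) {
  ref <- payload$genome_ref
  cache <- engine$cache[[ref]]
  text <- rawToChar(cache$merged)
  assembly <- parse_fasta_lines(strsplit(text, "\n", fixed = TRUE)[[1L]],
                                source_label = ref)
  spacers <- dedupe_spacers(extract_candidates_assembly(assembly))
  if (length(spacers) == 0L) {
    # a genome with no targetable site still yields an index over an
    # impossible sentinel spacer so downstream queries return empty
    cache$index <- NULL
    cache$no_sites <- TRUE
  } else {
    cache$index <- build_issl_index(
      spacers, slice_config(engine$config$num_slices))
  }
  cache$merged <- NULL
  cache$ready <- TRUE
  engine$cache[[ref]] <- cache
  waiting <- cache$waiting
  cache$waiting <- character(0L)
  engine$cache[[ref]] <- cache
  for (jid in waiting) {
    .start_assessment(engine, jid)
  }
  invisible(NULL)
}

.start_assessment <- function(engine, job_id) {
  job <- engine$jobs[[job_id]]
  candidates <- extract_candidates(
    list(identifier = "query", sequence = job$gene_sequence))
  dispatch_assessments(engine, job_id, candidates)
}

#' Dispatch per-candidate assessment tasks
#'
#' Creates one result skeleton per candidate locus and adds each candidate
#' to both assessment queues — `n` on-target messages and `n` off-target
#' messages for `n` candidates. A job with zero candidates completes
#' immediately.
#'
#' @param engine a [crispr_engine()].
#' @param job_id the job the candidates belong to.
#' @param candidates candidate data.frame from [extract_candidates()].
#' @return number of candidates dispatched, invisibly.
#' @export
dispatch_assessments <- function(engine, job_id, candidates) {
  n <- nrow(candidates)
  if (n == 0L) {
    .set_status(engine, job_id, "complete")
    return(invisible(0L))
  }
  records <- lapply(seq_len(n), function(i) {
    list(job_id = job_id,
         record_id = candidates$record_id[i],
         start = candidates$start[i],
         strand = candidates$strand[i],
         target23 = candidates$target23[i],
         spacer20 = candidates$spacer20[i],
         ontarget = NULL, offtarget = NULL)
  })
  engine$results[[job_id]] <- records
  .set_status(engine, job_id, "assessing")
  for (i in seq_len(n)) {
    .enqueue(engine, "ontarget", list(job_id = job_id, candidate = i))
    .enqueue(engine, "offtarget", list(job_id = job_id, candidate = i))
  }
  invisible(n)
}

.handle_ontarget <- function(engine, payload) {
  recs <- engine$results[[payload$job_id]]
  rec <- recs[[payload$candidate]]
  rec$ontarget <- assess_ontarget(
    rec$spacer20, threshold = engine$config$consensus_threshold)
  recs[[payload$candidate]] <- rec
  engine$results[[payload$job_id]] <- recs
  .check_completion(engine, payload$job_id)
  invisible(NULL)
}

.handle_offtarget <- function(engine, payload) {
  recs <- engine$results[[payload$job_id]]
  rec <- recs[[payload$candidate]]
  job <- engine$jobs[[payload$job_id]]
  cache <- engine$cache[[job$genome_ref]]
  rec$offtarget <- if (is.null(cache$index)) {
    # genome had no targetable sites: no neighbours at all
    specificity_score(rec$spacer20,
                      data.frame(spacer = character(0L),
                                 distance = integer(0L), count = integer(0L)),
                      max_mm = engine$config$max_mm,
                      weights = engine$config$weights)
  } else {
    assess_offtarget(cache$index, rec$spacer20,
                     max_mm = engine$config$max_mm,
                     weights = engine$config$weights)
  }
  recs[[payload$candidate]] <- rec
  engine$results[[payload$job_id]] <- recs
  .check_completion(engine, payload$job_id)
  invisible(NULL)
}

.check_completion <- function(engine, job_id) {
  recs <- engine$results[[job_id]]
  done <- all(vapply(recs, function(r) {
    !is.null(r$ontarget) && !is.null(r$offtarget)
  }, logical(1L)))
  if (done) {
    .set_status(engine, job_id, "complete")
  }
  invisible(NULL)
}

.job_of_payload <- function(payload) {
  if (!is.null(payload$job_id)) payload$job_id else NA_character_
}

.fail_for_payload <- function(engine, queue_name, payload, msg) {
  jid <- .job_of_payload(payload)
  jids <- character(0L)
  if (!is.na(jid)) {
    jids <- jid
  }
  if (!is.null(payload$genome_ref)) {
    cache <- engine$cache[[payload$genome_ref]]
    jids <- union(jids, cache$waiting)
    # drop the cache entry so a later job can retry the genome afresh
    rm(list = payload$genome_ref, envir = engine$cache)
  }
  for (j in jids) {
    .set_status(engine, j, "failed", error = msg)
  }
  invisible(NULL)
}

# Worker loop ------------------------------------------------------------

.dispatch_message <- function(engine, msg) {
  q <- msg$queue_name
  p <- msg$payload
  if (q == "genome_fetch") {
    if (identical(p$type, "ensure")) ensure_genome(engine, p$job_id)
    else .handle_range(engine, p)
  } else if (q == "index_build") {
    .handle_index_build(engine, p)
  } else if (q == "ontarget") {
    .handle_ontarget(engine, p)
  } else if (q == "offtarget") {
    .handle_offtarget(engine, p)
  } else {
    stop("unknown queue: ", q, call. = FALSE)
  }
}

#' Consume one batch of messages from a queue
#'
#' Takes up to `batch_size` messages from the head of the queue and runs
#' the queue's handler on each. Handlers are stateless: every input comes
#' from the message and the shared stores. A message whose idempotency key
#' `(queue, payload)` has already been processed is dropped without effect.
#' A handler error requeues the message with an incremented delivery count,
#' up to the retry cap, after which the affected job(s) fail. A batch
#' stops early (leaving the rest queued) if it would exceed the per-batch
#' time budget.
#'
#' @param engine a [crispr_engine()].
#' @param queue_name one of `genome_fetch`, `index_build`, `ontarget`,
#'   `offtarget`.
#' @param batch_size messages per batch; defaults to the configured
#'   per-queue size.
#' @return number of messages consumed (including dropped duplicates).
#' @export
run_worker_batch <- function(engine, queue_name,
                             batch_size = engine$config$batch_size[[queue_name]]) {
  q <- engine$queues[[queue_name]]
  if (is.null(q)) {
    stop("run_worker_batch: unknown queue: ", queue_name, call. = FALSE)
  }
  if (length(q$messages) == 0L) {
    return(0L)
  }
  engine$counters[[paste0("batches_", queue_name)]] <-
    engine$counters[[paste0("batches_", queue_name)]] + 1L
  n_take <- min(batch_size, length(q$messages))
  started <- proc.time()[["elapsed"]]
  processed <- 0L
  for (i in seq_len(n_take)) {
    if (proc.time()[["elapsed"]] - started > engine$config$max_task_seconds) {
      break   # checkpoint: remaining messages stay queued
    }
    msg <- q$messages[[1L]]
    q$messages <- q$messages[-1L]
    key <- .payload_key(queue_name, msg$payload)
    if (isTRUE(engine$processed[[key]])) {
      ctr <- paste0("duplicates_dropped_", queue_name)
      engine$counters[[ctr]] <- engine$counters[[ctr]] + 1L
      processed <- processed + 1L
      next
    }
    jid <- .job_of_payload(msg$payload)
    if (!is.na(jid)) {
      st <- engine$jobs[[jid]]$status
      if (!is.null(st) && st == "failed") {     # job already failed: drop
        processed <- processed + 1L
        next
      }
    }
    ok <- tryCatch({
      .dispatch_message(engine, msg)
      TRUE
    }, error = function(e) e)
    if (isTRUE(ok)) {
      engine$processed[[key]] <- TRUE
      engine$counters[[paste0("handled_", queue_name)]] <-
        engine$counters[[paste0("handled_", queue_name)]] + 1L
    } else {
      if (msg$delivery_count >= engine$config$retry_cap) {
        .fail_for_payload(engine, queue_name, msg$payload,
                          conditionMessage(ok))
      } else {
        msg$delivery_count <- msg$delivery_count + 1L
        q$messages <- c(q$messages, list(msg))
      }
    }
    processed <- processed + 1L
  }
  processed
}

#' Drain all queues with a pool of round-robin workers
#'
#' Event-driven: returns immediately (zero batches) when every queue is
#' empty — no polling loop runs without work. With `workers > 1`, each
#' round hands one batch to each logical worker, rotating the queue order
#' per worker, which interleaves the stages differently without changing
#' any result (schedule invariance).
#'
#' @param engine a [crispr_engine()].
#' @param workers number of logical workers (capped by the configured
#'   `max_concurrency`).
#' @param batch_size optional single batch size overriding every queue's
#'   configured size.
#' @return total messages processed, invisibly.
#' @export
run_until_idle <- function(engine, workers = 1L, batch_size = NULL) {
  workers <- min(as.integer(workers), engine$config$max_concurrency)
  total <- 0L
  repeat {
    depths <- vapply(engine$queues, function(q) length(q$messages),
                     integer(1L))
    if (all(depths == 0L)) {
      break
    }
    progressed <- FALSE
    for (w in seq_len(workers)) {
      order <- QUEUE_NAMES[((seq_along(QUEUE_NAMES) + w - 2L) %%
                              length(QUEUE_NAMES)) + 1L]
      nonempty <- order[vapply(order, function(q) {
        length(engine$queues[[q]]$messages) > 0L
      }, logical(1L))]
      if (length(nonempty) == 0L) {
        next
      }
      bs <- if (is.null(batch_size)) {
        engine$config$batch_size[[nonempty[1L]]]
      } else {
        batch_size
      }
      n <- run_worker_batch(engine, nonempty[1L], batch_size = bs)
      total <- total + n
      progressed <- progressed || n > 0L
    }
    if (!progressed) {
      break
    }
  }
  invisible(total)
}

# Introspection ----------------------------------------------------------

#' Job status and assessment progress
#'
#' @param engine a [crispr_engine()].
#' @param job_id a job id from [submit_job()].
#' @return a list: `status`; `ontarget` and `offtarget`, each
#'   `c(done, total)`; and `fraction`, the two completion fractions (both 1
#'   exactly when the job is complete; a complete job with zero candidates
#'   reports 1 by convention).
#' @export
job_progress <- function(engine, job_id) {
  job <- engine$jobs[[job_id]]
  if (is.null(job)) {
    stop(structure(
      class = c("unknown_job", "error", "condition"),
      list(message = paste0("unknown job_id: ", job_id), call = NULL)
    ))
  }
  recs <- engine$results[[job_id]]
  total <- length(recs)
  on_done <- sum(vapply(recs, function(r) !is.null(r$ontarget), logical(1L)))
  off_done <- sum(vapply(recs, function(r) !is.null(r$offtarget), logical(1L)))
  frac <- function(done) {
    if (total > 0L) done / total else if (job$status == "complete") 1 else 0
  }
  list(status = job$status,
       ontarget = c(done = on_done, total = total),
       offtarget = c(done = off_done, total = total),
       fraction = c(ontarget = frac(on_done), offtarget = frac(off_done)),
       error = job$error)
}

#' Retrieve a job's result records
#'
#' Partial results are visible while a job is in flight; records whose
#' assessments are pending carry `NA` in the corresponding columns and
#' `both_complete = FALSE`.
#'
#' @param engine a [crispr_engine()].
#' @param job_id a job id.
#' @return data.frame sorted by `(record_id, start, strand)` with candidate
#'   coordinates, the three per-method on-target booleans, consensus votes
#'   and acceptance, the off-target specificity, neighbour counts per
#'   mismatch distance (`mm0`, `mm1`, ...), and `both_complete`.
#' @export
job_results <- function(engine, job_id) {
  job <- engine$jobs[[job_id]]
  if (is.null(job)) {
    stop(structure(
      class = c("unknown_job", "error", "condition"),
      list(message = paste0("unknown job_id: ", job_id), call = NULL)
    ))
  }
  recs <- engine$results[[job_id]]
  max_mm <- engine$config$max_mm
  mm_cols <- paste0("mm", 0:max_mm)
  if (length(recs) == 0L) {
    out <- data.frame(job_id = character(0L), record_id = character(0L),
                      start = integer(0L), strand = character(0L),
                      target23 = character(0L), spacer20 = character(0L),
                      passes_g20 = logical(0L),
                      passes_composition = logical(0L),
                      passes_structure = logical(0L),
                      consensus_votes = integer(0L), accepted = logical(0L),
                      specificity = numeric(0L), stringsAsFactors = FALSE)
    for (cc in mm_cols) out[[cc]] <- numeric(0L)
    out$both_complete <- logical(0L)
    return(out)
  }
  rows <- lapply(recs, function(r) {
    ot <- r$ontarget
    ft <- r$offtarget
    row <- data.frame(
      job_id = r$job_id, record_id = r$record_id, start = r$start,
      strand = r$strand, target23 = r$target23, spacer20 = r$spacer20,
      passes_g20 = if (is.null(ot)) NA else ot$passes_g20,
      passes_composition = if (is.null(ot)) NA else ot$passes_composition,
      passes_structure = if (is.null(ot)) NA else ot$passes_structure,
      consensus_votes = if (is.null(ot)) NA_integer_ else ot$consensus_votes,
      accepted = if (is.null(ot)) NA else ot$accepted,
      specificity = if (is.null(ft)) NA_real_ else ft$specificity,
      stringsAsFactors = FALSE
    )
    for (d in 0:max_mm) {
      row[[paste0("mm", d)]] <-
        if (is.null(ft)) NA_real_ else ft$neighbour_counts[[as.character(d)]]
    }
    row$both_complete <- !is.null(ot) && !is.null(ft)
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$record_id, out$start,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write job results to CSV or JSON
#'
#' @param engine a [crispr_engine()].
#' @param job_id a job id.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @param include_job_id drop the job id column when `FALSE` (useful when
#'   comparing runs).
#' @return `path`, invisibly.
#' @export
write_job_results <- function(engine, job_id, path,
                              format = c("csv", "json"),
                              include_job_id = TRUE) {
  format <- match.arg(format)
  res <- job_results(engine, job_id)
  if (!include_job_id) {
    res$job_id <- NULL
  }
  if (format == "csv") {
    utils::write.csv(res, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(res, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Snapshot an engine to disk / restore it
#'
#' Serializes the whole engine state (jobs, queues, caches, results) so a
#' command-line session can span multiple invocations.
#'
#' @param engine a [crispr_engine()].
#' @param path file path for the snapshot.
#' @return `path` invisibly / the restored engine.
#' @export
save_engine <- function(engine, path) {
  saveRDS(engine, path)
  invisible(path)
}

#' @rdname save_engine
#' @export
load_engine <- function(path) {
  readRDS(path)
}
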