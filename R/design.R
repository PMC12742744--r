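# One-shot convenience front end: submit a job against a genome file, drain
# the queues, return the results table.

#' Design guides for a gene against a genome, end to end
#'
#' Convenience wrapper over the engine: registers the genome, submits one
#' job, drains all queues, and returns the completed results table. For
#' multi-job or incremental use, drive [crispr_engine()], [submit_job()]
#' and [run_until_idle()] directly.
#'
#' @param gene a nucleotide string, or a path to a single-record FASTA file.
#' @param genome path to a (possibly gzipped) FASTA genome file.
#' @param config an [engine_config()].
#' @param workers logical worker count for the drain.
#' @return the [job_results()] data.frame of the completed job, with the
#'   engine and job id attached as attributes `engine` and `job_id`.
#' @examples
#' gene <- generate_gene_with_exact_guides(5, seed = 7)
#' genome <- tempfile(fileext = ".fa")
#' write_fixture_genome(genome_spec(5000, seed = 7), genome)
#' res <- design_guides(gene, genome)
#' res[, c("start", "strand", "accepted", "specificity")]
#' @export
design_guides <- function(gene, genome, config = engine_config(),
                          workers = 1L) {
  gene_seq <- if (file.exists(gene)) {
    asm <- read_fasta(gene)
    if (length(asm$records) != 1L) {
      stop("design_guides: gene FASTA must contain exactly one record",
           call. = FALSE)
    }
    asm$records[[1L]]$sequence
  } else {
    gene
  }
  engine <- crispr_engine(config)
  register_genome(engine, "genome", genome)
  job_id <- submit_job(engine, gene_seq, "genome")
  run_until_idle(engine, workers = workers)
  prog <- job_progress(engine, job_id)
  if (prog$status == "failed") {
    stop("design_guides: job failed: ", prog$error, call. = FALSE)
  }
  res <- job_results(engine, job_id)
  attr(res, "engine") <- engine
  attr(res, "job_id") <- job_id
  res
}
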