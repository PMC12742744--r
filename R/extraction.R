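# Candidate target-site enumeration: every SpCas9 site (20-nt spacer + NGG
# PAM) on both strands, overlapping matches included, N-containing sites
# excluded.

.RC_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a nucleotide string
#' @param x character vector over `{A,C,G,T,N}`.
#' @return reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

# Overlapping regex matches via a zero-width lookahead with a capture group.
.overlapping_starts <- function(sequence, pattern) {
  m <- gregexpr(pattern, sequence, perl = TRUE)[[1L]]
  st <- attr(m, "capture.start")
  if (is.null(st) || (length(m) == 1L && m[1L] == -1L)) {
    return(integer(0L))
  }
  as.integer(st[, 1L])
}

#' Extract all candidate guides from one sequence record
#'
#' A forward candidate is any 23-mer matching `[ACGT]{21}GG` (20-nt spacer,
#' then NGG PAM); a reverse candidate is any 23-mer matching `CC[ACGT]{21}`,
#' reported as its reverse complement so that `target23` always ends in GG.
#' Every offset is tested, so overlapping sites are all reported; sites
#' containing N are excluded.
#'
#' @param record a [sequence_record()] (or any list with `identifier` and
#'   `sequence` fields, already normalized).
#' @return a data.frame with columns `record_id`, `start` (0-based
#'   forward-strand offset of the 23-nt footprint), `strand` (`+`/`-`),
#'   `target23`, `spacer20`, sorted by `(start, strand)` with `+` before `-`.
#' @export
extract_candidates <- function(record) {
  seq <- record$sequence
  fwd <- .overlapping_starts(seq, "(?=([ACGT]{21}GG))")
  rev <- .overlapping_starts(seq, "(?=(CC[ACGT]{21}))")
  empty <- data.frame(
    record_id = character(0L), start = integer(0L), strand = character(0L),
    target23 = character(0L), spacer20 = character(0L),
    stringsAsFactors = FALSE
  )
  if (length(fwd) == 0L && length(rev) == 0L) {
    return(empty)
  }
  fwd_t23 <- if (length(fwd)) substring(seq, fwd, fwd + 22L) else character(0L)
  rev_t23 <- if (length(rev)) {
    reverse_complement(substring(seq, rev, rev + 22L))
  } else {
    character(0L)
  }
  out <- data.frame(
    record_id = record$identifier,
    start = c(fwd - 1L, rev - 1L),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    target23 = c(fwd_t23, rev_t23),
    stringsAsFactors = FALSE
  )
  out$spacer20 <- substr(out$target23, 1L, 20L)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract candidates from every record of an assembly
#'
#' @param assembly a [genome_assembly()].
#' @return row-bound candidate data.frame (see [extract_candidates()]),
#'   records in assembly order.
#' @export
extract_candidates_assembly <- function(assembly) {
  do.call(rbind, lapply(assembly$records, extract_candidates))
}

#' Count CRISPR target sites genome-wide
#'
#' Streams over records, counting matches on both strands without
#' materializing the candidate table.
#'
#' @param assembly a [genome_assembly()].
#' @return total number of candidate sites (numeric, to allow genome-scale
#'   counts).
#' @export
count_genome_sites <- function(assembly) {
  sum(vapply(assembly$records, function(rec) {
    length(.overlapping_starts(rec$sequence, "(?=([ACGT]{21}GG))")) +
      length(.overlapping_starts(rec$sequence, "(?=(CC[ACGT]{21}))"))
  }, numeric(1L)))
}

#' Tally distinct spacers with occurrence counts
#'
#' Feeds the off-target index: the genome-wide spacer set is deduplicated
#' with per-sequence occurrence counts, while gene candidates remain
#' per-locus.
#'
#' @param candidates a candidate data.frame from [extract_candidates()].
#' @return named integer vector: names are distinct `spacer20` strings,
#'   values their occurrence counts (counts sum to `nrow(candidates)`).
#' @export
dedupe_spacers <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(structure(integer(0L), names = character(0L)))
  }
  tab <- table(candidates$spacer20)
  structure(as.integer(tab), names = names(tab))
}

#' Write candidates as BED
#'
#' Columns: record_id, start, start + 23, target23, score placeholder (0),
#' strand.
#' @param candidates candidate data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(candidates, path) {
  bed <- data.frame(
    chrom = candidates$record_id,
    start = candidates$start,
    end = candidates$start + 23L,
    name = candidates$target23,
    score = 0L,
    strand = candidates$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write candidates as CSV
#' @param candidates candidate data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_csv <- function(candidates, path) {
  utils::write.csv(candidates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
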