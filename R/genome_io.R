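# Genome sequence I/O: FASTA parsing with normalization, byte-range chunk
# planning, and portion merging. The local stand-in for the remote genome
# preparation stage of the pipeline.

#' Default chunk size for byte-range genome fetches
#'
#' One "megabyte" is taken as 2^20 bytes; genomes larger than 50 MB are
#' fetched in portions of this size.
#' @export
DEFAULT_CHUNK_BYTES <- 50L * 2L^20L

.norm_map <- {
  m <- rep("N", 256L)
  m[utf8ToInt("A") + 1L] <- "A"
  m[utf8ToInt("C") + 1L] <- "C"
  m[utf8ToInt("G") + 1L] <- "G"
  m[utf8ToInt("T") + 1L] <- "T"
  m
}

#' Normalize a nucleotide string
#'
#' Uppercases, maps U to T (RNA input), and replaces every other symbol
#' outside `{A,C,G,T}` with `N`. Lossless with respect to sequence length.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences over `{A,C,G,T,N}`.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  # anything not ACGT becomes N
  gsub("[^ACGT]", "N", x, perl = TRUE)
}

#' Construct a sequence record
#'
#' @param identifier FASTA header token (non-empty).
#' @param sequence nucleotide string; normalized on construction.
#' @return an object of class `sequence_record` with fields `identifier`,
#'   `sequence`, `length`.
#' @export
sequence_record <- function(identifier, sequence) {
  if (!is.character(identifier) || length(identifier) != 1L || !nzchar(identifier)) {
    stop("sequence_record: identifier must be a non-empty string", call. = FALSE)
  }
  seq <- normalize_sequence(sequence)
  structure(
    list(identifier = identifier, sequence = seq, length = nchar(seq)),
    class = "sequence_record"
  )
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d bp)\n", x$identifier, x$length))
  invisible(x)
}

#' Construct a genome assembly from sequence records
#'
#' @param records list of [sequence_record()] objects.
#' @param source_label accession or file path the assembly came from.
#' @return an object of class `genome_assembly` with fields `records`,
#'   `total_bases`, `source_label`.
#' @export
genome_assembly <- function(records, source_label = "<in-memory>") {
  ids <- vapply(records, `[[`, character(1L), "identifier")
  if (anyDuplicated(ids)) {
    stop("genome_assembly: duplicate record identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      records = records,
      total_bases = sum(vapply(records, `[[`, numeric(1L), "length")),
      source_label = source_label
    ),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s: %d record(s), %s bases\n",
              x$source_label, length(x$records),
              format(x$total_bases, big.mark = ",")))
  invisible(x)
}

# Distinct, named parse errors -------------------------------------------

.parse_error <- function(subclass, msg) {
  stop(structure(
    class = c(subclass, "fasta_parse_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

.is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)
}

#' Read a (possibly gzip-compressed) FASTA file
#'
#' Parses every record, uppercases sequences, maps U to T and any other
#' non-ACGT symbol to N. Gzip input is detected by its magic bytes, not by
#' file extension.
#'
#' @param path path to a FASTA file.
#' @return a [genome_assembly()] with one record per FASTA entry, in file
#'   order.
#' @section Errors: a missing file raises `fasta_missing_file`; a file with
#'   no records raises `fasta_no_records`; a header with no sequence lines
#'   raises `fasta_empty_record`. All are subclasses of `fasta_parse_error`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    .parse_error("fasta_missing_file", paste0("FASTA file not found: ", path))
  }
  con <- if (.is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  lines <- tryCatch(readLines(con, warn = FALSE), finally = close(con))
  parse_fasta_lines(lines, source_label = path)
}

#' Parse FASTA text already split into lines
#'
#' @param lines character vector of FASTA lines.
#' @param source_label label stored on the returned assembly.
#' @return a [genome_assembly()].
#' @export
parse_fasta_lines <- function(lines, source_label = "<text>") {
  lines <- lines[nzchar(trimws(lines))]
  headers <- grepl("^>", lines)
  if (!any(headers)) {
    .parse_error("fasta_no_records", "no FASTA records found")
  }
  if (!headers[1L]) {
    .parse_error("fasta_no_records", "sequence data before first FASTA header")
  }
  grp <- cumsum(headers)
  records <- lapply(split(seq_along(lines), grp), function(idx) {
    hdr <- lines[idx[1L]]
    id <- strsplit(sub("^>", "", hdr), "[ \t]")[[1L]][1L]
    if (is.na(id) || !nzchar(id)) {
      .parse_error("fasta_empty_record", "FASTA header with empty identifier")
    }
    body <- lines[idx[-1L]]
    if (length(body) == 0L) {
      .parse_error("fasta_empty_record",
                   paste0("FASTA record '", id, "' has a header but no sequence"))
    }
    sequence_record(id, paste(body, collapse = ""))
  })
  names(records) <- NULL
  genome_assembly(records, source_label = source_label)
}

#' Write an assembly to a FASTA file
#'
#' @param assembly a [genome_assembly()].
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (rec in assembly$records) {
    writeLines(paste0(">", rec$identifier), con)
    starts <- seq(1L, max(rec$length, 1L), by = width)
    if (rec$length == 0L) {
      next
    }
    writeLines(substring(rec$sequence, starts, pmin(starts + width - 1L, rec$length)), con)
  }
  invisible(path)
}

# Byte-range chunk planning ----------------------------------------------

#' Plan a chunked byte-range fetch
#'
#' Splits `[0, total_bytes)` into consecutive ranges of `chunk_bytes`, the
#' last possibly shorter. A file no larger than one chunk is fetched whole
#' (the "larger than" threshold is strict).
#'
#' @param total_bytes total file size in bytes (> 0).
#' @param chunk_bytes portion size in bytes (> 0); default 50 * 2^20.
#' @return an object of class `fetch_plan`: fields `total_bytes`,
#'   `chunk_bytes`, and `ranges`, a two-column matrix of
#'   `(start inclusive, end exclusive)` byte offsets.
#' @export
plan_chunked_fetch <- function(total_bytes, chunk_bytes = DEFAULT_CHUNK_BYTES) {
  total_bytes <- as.numeric(total_bytes)
  chunk_bytes <- as.numeric(chunk_bytes)
  if (length(total_bytes) != 1L || is.na(total_bytes) || total_bytes <= 0) {
    stop("plan_chunked_fetch: total_bytes must be a positive number", call. = FALSE)
  }
  if (length(chunk_bytes) != 1L || is.na(chunk_bytes) || chunk_bytes <= 0) {
    stop("plan_chunked_fetch: chunk_bytes must be a positive number", call. = FALSE)
  }
  starts <- seq(0, total_bytes - 1, by = chunk_bytes)
  ends <- pmin(starts + chunk_bytes, total_bytes)
  structure(
    list(total_bytes = total_bytes, chunk_bytes = chunk_bytes,
         ranges = cbind(start = starts, end = ends)),
    class = "fetch_plan"
  )
}

#' @export
print.fetch_plan <- function(x, ...) {
  cat(sprintf("<fetch_plan> %s bytes in %d range(s) of <= %s bytes\n",
              format(x$total_bytes, big.mark = ","), nrow(x$ranges),
              format(x$chunk_bytes, big.mark = ",")))
  invisible(x)
}

#' Serialize a fetch plan as plain text
#'
#' One range per line, `start<TAB>end` (end exclusive).
#' @param plan a `fetch_plan`.
#' @param path output path; if `NULL`, the lines are returned.
#' @return the text lines (invisibly when written to a file).
#' @export
write_fetch_plan <- function(plan, path = NULL) {
  lines <- sprintf("%.0f\t%.0f", plan$ranges[, "start"], plan$ranges[, "end"])
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(lines)
}

#' Read a fetch plan from its plain-text form
#' @param path path to a `start<TAB>end` file.
#' @return a `fetch_plan`.
#' @export
read_fetch_plan <- function(path) {
  m <- utils::read.table(path, sep = "\t", col.names = c("start", "end"))
  plan <- plan_chunked_fetch(max(m$end), chunk_bytes = m$end[1L] - m$start[1L])
  stopifnot(nrow(plan$ranges) == nrow(m))
  plan
}

#' Split a raw byte string according to a fetch plan
#'
#' The inverse of [merge_portions()]; used by the engine's fetch workers and
#' by round-trip tests.
#'
#' @param bytes raw vector of length `plan$total_bytes`.
#' @param plan a `fetch_plan`.
#' @return a list of portions, each `list(start, end, bytes)`.
#' @export
split_portions <- function(bytes, plan) {
  if (length(bytes) != plan$total_bytes) {
    stop("split_portions: byte length does not match plan", call. = FALSE)
  }
  lapply(seq_len(nrow(plan$ranges)), function(i) {
    s <- plan$ranges[i, "start"]
    e <- plan$ranges[i, "end"]
    list(start = s, end = e, bytes = bytes[(s + 1):e])
  })
}

#' Merge fetched portions back into one byte stream
#'
#' Portions may arrive in any order; they are placed by their byte range.
#'
#' @param plan the `fetch_plan` the portions were fetched under.
#' @param portions list of `list(start, end, bytes)` entries, one per plan
#'   range, in any order.
#' @return a raw vector of length `plan$total_bytes`.
#' @section Errors: a plan range with no portion raises `portion_missing`; a
#'   range supplied twice raises `portion_duplicate`; a portion whose byte
#'   length differs from its range size raises `portion_length_mismatch`.
#' @export
merge_portions <- function(plan, portions) {
  perr <- function(subclass, msg) {
    stop(structure(
      class = c(subclass, "portion_error", "error", "condition"),
      list(message = msg, call = NULL)
    ))
  }
  key <- function(s, e) sprintf("%.0f-%.0f", s, e)
  seen <- character(0L)
  out <- raw(plan$total_bytes)
  plan_keys <- key(plan$ranges[, "start"], plan$ranges[, "end"])
  for (p in portions) {
    k <- key(p$start, p$end)
    if (!k %in% plan_keys) {
      perr("portion_unknown", paste0("portion ", k, " is not in the plan"))
    }
    if (k %in% seen) {
      perr("portion_duplicate", paste0("portion ", k, " supplied twice"))
    }
    if (length(p$bytes) != p$end - p$start) {
      perr("portion_length_mismatch",
           paste0("portion ", k, " has ", length(p$bytes), " bytes"))
    }
    out[(p$start + 1):p$end] <- p$bytes
    seen <- c(seen, k)
  }
  missing <- setdiff(plan_keys, seen)
  if (length(missing) > 0L) {
    perr("portion_missing", paste0("missing portion(s): ",
                                   paste(missing, collapse = ", ")))
  }
  out
}

# Fetcher contract -------------------------------------------------------

#' Create a byte-range fetcher over a local file
#'
#' The fetcher contract is `function(source_label, start, end)` returning the
#' raw bytes of `[start, end)`. This implementation reads local files; a
#' remote/accession fetcher is a pluggable extension point with the same
#' signature.
#'
#' @param path file the fetcher serves.
#' @return a fetcher function.
#' @export
local_file_fetcher <- function(path) {
  force(path)
  function(source_label, start, end) {
    if (!file.exists(path)) {
      stop(structure(
        class = c("fetch_error", "error", "condition"),
        list(message = paste0("fetch failed: file not found: ", path),
             call = NULL)
      ))
    }
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, where = start)
    bytes <- readBin(con, "raw", n = end - start)
    if (length(bytes) != end - start) {
      stop(structure(
        class = c("fetch_error", "error", "condition"),
        list(message = sprintf("fetch failed: short read [%.0f,%.0f) from %s",
                               start, end, path), call = NULL)
      ))
    }
    bytes
  }
}
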