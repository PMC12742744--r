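# Inverted signature slice list (ISSL) index over 2-bit encoded genome
# spacers: build, query, save/load. The heavy lifting lives in src/issl.cpp.

#' Slice configuration for the ISSL index
#'
#' The 20-nt spacer is cut into `num_slices` equal-width slices. Exact
#' recall of all Hamming neighbours at up to `max_mm` mismatches requires
#' `num_slices >= max_mm + 1` (pigeonhole: at least one slice is then
#' mismatch-free and matches its signature exactly).
#'
#' @param num_slices number of slices; must divide 20. Default 5, the
#'   minimal configuration covering 4 mismatches.
#' @return an object of class `slice_config` with `num_slices` and
#'   `slice_width_bases`.
#' @export
slice_config <- function(num_slices = 5L) {
  num_slices <- as.integer(num_slices)
  if (is.na(num_slices) || num_slices < 1L || 20L %% num_slices != 0L) {
    stop("slice_config: num_slices must divide 20", call. = FALSE)
  }
  structure(
    list(num_slices = num_slices, slice_width_bases = 20L %/% num_slices),
    class = "slice_config"
  )
}

#' Encode a 20-nt spacer as a 40-bit integer
#'
#' 2 bits per base (A=0, C=1, G=2, T=3), leftmost base most significant.
#' Returned as a double: 40-bit values are exact in doubles but overflow
#' R integers.
#'
#' @param spacer20 character vector of 20-nt spacers over `{A,C,G,T}`.
#' @return numeric vector of encoded values in `[0, 4^20)`.
#' @export
encode_spacer <- function(spacer20) {
  .issl_encode_cpp(spacer20)
}

#' Decode 40-bit spacer values back to strings
#' @param value numeric vector of encoded values.
#' @return character vector of 20-nt spacers.
#' @export
decode_spacer <- function(value) {
  .issl_decode_cpp(value)
}

#' Build the ISSL index over a deduplicated spacer set
#'
#' @param spacers named integer vector as returned by [dedupe_spacers()]:
#'   names are distinct spacer sequences, values their genome occurrence
#'   counts.
#' @param config a [slice_config()].
#' @return an object of class `issl_index`: `config`; `values` (sorted
#'   distinct encoded spacers); `counts`; `slices` (per-slice signature
#'   tables); `num_distinct`; `num_sites`.
#' @export
build_issl_index <- function(spacers, config = slice_config()) {
  if (length(spacers) == 0L) {
    stop("build_issl_index: spacer set is empty", call. = FALSE)
  }
  if (is.null(names(spacers)) || any(!nzchar(names(spacers)))) {
    stop("build_issl_index: spacers must be a named count vector", call. = FALSE)
  }
  counts <- as.integer(spacers)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("build_issl_index: every spacer count must be >= 1", call. = FALSE)
  }
  values <- encode_spacer(names(spacers))
  ord <- order(values)
  values <- values[ord]
  counts <- counts[ord]
  if (anyDuplicated(values)) {
    stop("build_issl_index: duplicate spacers in the input set", call. = FALSE)
  }
  w <- config$slice_width_bases
  slices <- lapply(seq_len(config$num_slices) - 1L, function(s) {
    .issl_build_slice_cpp(values, s, w)
  })
  structure(
    list(config = config, values = values, counts = counts, slices = slices,
         num_distinct = length(values), num_sites = sum(as.numeric(counts))),
    class = "issl_index"
  )
}

#' @export
print.issl_index <- function(x, ...) {
  cat(sprintf(
    "<issl_index> %d distinct spacers, %s sites, %d slices x %d bases\n",
    x$num_distinct, format(x$num_sites, big.mark = ","),
    x$config$num_slices, x$config$slice_width_bases))
  invisible(x)
}

#' Query all indexed spacers within a Hamming-distance bound
#'
#' Gathers bucket members by exact slice-signature match in every slice
#' table, then verifies each candidate by full Hamming distance. With
#' `num_slices >= max_mm + 1` this returns exactly the Hamming ball.
#'
#' @param index an [build_issl_index()] result.
#' @param spacer20 a single 20-nt query spacer.
#' @param max_mm maximum mismatches (default 4).
#' @return data.frame with columns `spacer`, `value`, `distance`, `count`,
#'   sorted by `(distance, value)`.
#' @export
query_neighbours <- function(index, spacer20, max_mm = 4L) {
  max_mm <- as.integer(max_mm)
  if (max_mm >= index$config$num_slices) {
    stop("query_neighbours: max_mm must be < num_slices (",
         index$config$num_slices,
         ") or the exact-recall guarantee is void", call. = FALSE)
  }
  q <- encode_spacer(spacer20)
  res <- .issl_query_cpp(index$values, index$counts, index$slices,
                         index$config$slice_width_bases, q, max_mm)
  data.frame(
    spacer = decode_spacer(res$value),
    value = res$value,
    distance = res$distance,
    count = res$count,
    stringsAsFactors = FALSE
  )
}

# Index serialization ----------------------------------------------------
# Little-endian binary layout:
#   magic "ISSL" (4 bytes) | version int32 | num_slices int32 |
#   slice_width int32 | num_distinct int32 | num_sites double |
#   values double[num_distinct] | counts int32[num_distinct] |
#   per slice: nsig int32 | sig double[nsig] | ptr int32[nsig+1] |
#              items int32[num_distinct]

#' Save an ISSL index to its binary file format
#' @param index an `issl_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_issl_index <- function(index, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("ISSL"), con)
  writeBin(c(1L, index$config$num_slices, index$config$slice_width_bases,
             index$num_distinct), con, size = 4L, endian = "little")
  writeBin(as.numeric(index$num_sites), con, endian = "little")
  writeBin(as.numeric(index$values), con, endian = "little")
  writeBin(as.integer(index$counts), con, size = 4L, endian = "little")
  for (tab in index$slices) {
    writeBin(length(tab$sig), con, size = 4L, endian = "little")
    writeBin(as.numeric(tab$sig), con, endian = "little")
    writeBin(as.integer(tab$ptr), con, size = 4L, endian = "little")
    writeBin(as.integer(tab$items), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Load an ISSL index from its binary file format
#' @param path path written by [save_issl_index()].
#' @return an `issl_index` identical to the one saved.
#' @export
load_issl_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "ISSL") {
    stop("load_issl_index: not an ISSL index file", call. = FALSE)
  }
  hdr <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  version <- hdr[1L]
  if (version != 1L) {
    stop("load_issl_index: unsupported version ", version, call. = FALSE)
  }
  num_slices <- hdr[2L]
  num_distinct <- hdr[4L]
  num_sites <- readBin(con, "numeric", 1L, endian = "little")
  values <- readBin(con, "numeric", num_distinct, endian = "little")
  counts <- readBin(con, "integer", num_distinct, size = 4L, endian = "little")
  slices <- lapply(seq_len(num_slices), function(i) {
    nsig <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    list(
      sig = readBin(con, "numeric", nsig, endian = "little"),
      ptr = readBin(con, "integer", nsig + 1L, size = 4L, endian = "little"),
      items = readBin(con, "integer", num_distinct, size = 4L, endian = "little")
    )
  })
  structure(
    list(config = slice_config(num_slices), values = values, counts = counts,
         slices = slices, num_distinct = num_distinct, num_sites = num_sites),
    class = "issl_index"
  )
}

#' Dump an ISSL index as plain text (debugging aid)
#'
#' One line per distinct spacer: sequence, encoded value, count; then one
#' block per slice listing `signature: member-spacer-indices`.
#'
#' @param index an `issl_index`.
#' @param path output path; `NULL` returns the lines.
#' @return character lines, invisibly when written.
#' @export
dump_issl_index <- function(index, path = NULL) {
  lines <- c(
    sprintf("# ISSL index: %d distinct, %.0f sites, %d slices x %d bases",
            index$num_distinct, index$num_sites,
            index$config$num_slices, index$config$slice_width_bases),
    sprintf("%s\t%.0f\t%d", decode_spacer(index$values), index$values,
            index$counts)
  )
  for (s in seq_along(index$slices)) {
    tab <- index$slices[[s]]
    lines <- c(lines, sprintf("# slice %d", s - 1L))
    for (b in seq_along(tab$sig)) {
      members <- tab$items[(tab$ptr[b] + 1L):tab$ptr[b + 1L]]
      lines <- c(lines, sprintf("%.0f: %s", tab$sig[b],
                                paste(members, collapse = ",")))
    }
  }
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(lines)
}
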