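# Independent oracles used across the suite. Deliberately naive: character
# scans and per-position comparisons, sharing no code with the implementation
# paths they check.

BASES <- c("A", "C", "G", "T")

random_sequence <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_spacer <- function() random_sequence(20L)

# Naive both-strand, every-offset candidate scanner working on character
# vectors (no regular expressions): a forward site at offset i needs 23
# clean ACGT characters with G,G at positions i+21,i+22; a reverse site
# needs C,C at i,i+1, and is reported as the reverse complement. Window
# cleanliness is a running count of ACGT characters.
naive_extract <- function(record) {
  empty <- data.frame(record_id = character(0L), start = integer(0L),
                      strand = character(0L), target23 = character(0L),
                      spacer20 = character(0L), stringsAsFactors = FALSE)
  chars <- strsplit(record$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 23L) {
    return(empty)
  }
  rc1 <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ok <- cumsum(c(0L, chars %in% BASES))
  starts <- 1:(n - 22L)
  clean <- (ok[starts + 23L] - ok[starts]) == 23L
  fwd <- starts[clean & chars[starts + 21L] == "G" & chars[starts + 22L] == "G"]
  rev <- starts[clean & chars[starts] == "C" & chars[starts + 1L] == "C"]
  row_of <- function(i, strand) {
    win <- chars[i:(i + 22L)]
    t23 <- if (strand == "+") {
      paste(win, collapse = "")
    } else {
      paste(base::rev(unname(rc1[win])), collapse = "")
    }
    data.frame(record_id = record$identifier, start = i - 1L,
               strand = strand, target23 = t23,
               spacer20 = substr(t23, 1L, 20L), stringsAsFactors = FALSE)
  }
  out <- c(lapply(fwd, row_of, strand = "+"),
           lapply(rev, row_of, strand = "-"))
  if (length(out) == 0L) {
    return(empty)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, match(df$strand, c("+", "-"))), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Per-position Hamming distance between 20-mers.
hamming_str <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# Brute-force Hamming ball over a character matrix of spacers (rows =
# spacers, 20 columns). Returns data.frame(spacer, distance).
brute_force_neighbours <- function(spacer_matrix, spacer_names, query,
                                   max_mm) {
  qc <- strsplit(query, "", fixed = TRUE)[[1L]]
  d <- rowSums(spacer_matrix != matrix(qc, nrow = nrow(spacer_matrix),
                                       ncol = 20L, byrow = TRUE))
  keep <- d <= max_mm
  df <- data.frame(spacer = spacer_names[keep], distance = d[keep],
                   stringsAsFactors = FALSE)
  df[order(df$distance, df$spacer), , drop = FALSE]
}

spacer_char_matrix <- function(spacers) {
  matrix(unlist(strsplit(spacers, "", fixed = TRUE)), ncol = 20L,
         byrow = TRUE)
}

# A small synthetic genome plus its index, shared by index tests.
make_indexed_genome <- function(length = 20000L, seed = 42L,
                                num_slices = 5L) {
  rec <- generate_genome(genome_spec(length, gc_fraction = 0.5, seed = seed))
  spacers <- dedupe_spacers(extract_candidates(rec))
  list(record = rec, spacers = spacers,
       index = build_issl_index(spacers, slice_config(num_slices)))
}
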