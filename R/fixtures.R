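# Synthetic genomes and gene sequences with controlled properties: random
# backgrounds of chosen GC content, planted guide sites, off-target families
# at exact mismatch distances, and artificial genes containing a precise
# number of extractable guides. Everything is deterministic given its seed.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic genome
#'
#' @param length genome length in bases.
#' @param gc_fraction target GC content in `[0, 1]` (default 0.5).
#' @param seed RNG seed; the genome is a pure function of the spec.
#' @param planted list of `list(spacer20, position, mismatches)` entries:
#'   each writes `spacer (mutated at `mismatches` random positions) + "TGG"`
#'   at the given 0-based position. Footprints must fit and not overlap.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(length, gc_fraction = 0.5, seed = 1L,
                        planted = list()) {
  length <- as.integer(length)
  if (is.na(gc_fraction) || gc_fraction < 0 || gc_fraction > 1) {
    stop("genome_spec: gc_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (p in planted) {
    if (p$position < 0L || p$position + 23L > length) {
      stop("genome_spec: planted site at ", p$position,
           " does not fit a 23-nt footprint", call. = FALSE)
    }
  }
  if (length(planted) > 1L) {
    pos <- sort(vapply(planted, `[[`, numeric(1L), "position"))
    if (any(diff(pos) < 23)) {
      stop("genome_spec: planted sites overlap", call. = FALSE)
    }
  }
  structure(
    list(length = length, gc_fraction = gc_fraction, seed = as.integer(seed),
         planted = planted),
    class = "genome_spec"
  )
}

.mutate_spacer <- function(spacer, n_mut) {
  if (n_mut == 0L) {
    return(spacer)
  }
  chars <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  pos <- sample.int(20L, n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome record
#'
#' Background bases are i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`; planted entries overwrite the
#' background with `mutated-spacer + "TGG"`. Each mutation changes a
#' distinct position to a different base, so the planted site sits at
#' exactly the requested Hamming distance from its source spacer; the
#' distance is re-verified before the record is returned.
#'
#' @param spec a [genome_spec()].
#' @param identifier record identifier (default `"synthetic"`).
#' @return a [sequence_record()].
#' @export
generate_genome <- function(spec, identifier = "synthetic") {
  .with_seed(spec$seed, {
    p_gc <- spec$gc_fraction / 2
    p_at <- (1 - spec$gc_fraction) / 2
    chars <- sample(c("A", "C", "G", "T"), spec$length, replace = TRUE,
                    prob = c(p_at, p_gc, p_gc, p_at))
    for (pl in spec$planted) {
      mutated <- .mutate_spacer(pl$spacer20, pl$mismatches)
      stopifnot(length(mismatch_positions(pl$spacer20, mutated)) ==
                  pl$mismatches)
      site <- strsplit(paste0(mutated, "TGG"), "", fixed = TRUE)[[1L]]
      chars[(pl$position + 1L):(pl$position + 23L)] <- site
    }
    sequence_record(identifier, paste(chars, collapse = ""))
  })
}

#' Add an off-target family around a query spacer to a genome spec
#'
#' For each requested distance `d`, plants one site at exact Hamming
#' distance `d` from `query_spacer`, at evenly spaced non-overlapping
#' positions. Planted distances are exact by construction (each mutation
#' hits a distinct position and changes the base) and re-verified by a
#' direct Hamming count when the genome is generated.
#'
#' @param spec a [genome_spec()].
#' @param query_spacer the 20-nt spacer the family surrounds.
#' @param distances integer mismatch distances in `0..20`.
#' @return the augmented `genome_spec`.
#' @export
plant_offtarget_family <- function(spec, query_spacer, distances) {
  distances <- as.integer(distances)
  if (any(distances < 0L) || any(distances > 20L)) {
    stop("plant_offtarget_family: distances must lie in 0..20", call. = FALSE)
  }
  occupied <- vapply(spec$planted, `[[`, numeric(1L), "position")
  n <- length(distances)
  # lay new plants on a 30-bp grid from the end of the genome, skipping
  # positions that collide with existing plants
  pos <- integer(0L)
  cursor <- spec$length - 23L
  while (length(pos) < n && cursor >= 0L) {
    if (all(abs(cursor - c(occupied, pos)) >= 23L) || length(c(occupied, pos)) == 0L) {
      pos <- c(pos, cursor)
    }
    cursor <- cursor - 30L
  }
  if (length(pos) < n) {
    stop("plant_offtarget_family: genome too small to host all plants",
         call. = FALSE)
  }
  new_plants <- lapply(seq_len(n), function(i) {
    list(spacer20 = query_spacer, position = pos[i],
         mismatches = distances[i])
  })
  genome_spec(spec$length, spec$gc_fraction, spec$seed,
              planted = c(spec$planted, new_plants))
}

#' Generate an artificial gene containing a precise number of guides
#'
#' The gene is a concatenation of `n` blocks, each `spacer + "TGG"`. Spacers
#' are drawn uniformly over ACGT and rejection-sampled to contain no `GG` or
#' `CC` dinucleotide and to not start with G; under those constraints each
#' block's PAM contributes exactly one `GG` occurrence and the sequence
#' contains no `CC`, so the extractor finds exactly `n` forward candidates
#' and no reverse ones. The count is re-verified with [extract_candidates()]
#' before the sequence is returned.
#'
#' @param n number of guides the gene must contain (>= 0).
#' @param seed RNG seed.
#' @return a nucleotide string with exactly `n` extractable candidates.
#' @export
generate_gene_with_exact_guides <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) {
    stop("generate_gene_with_exact_guides: n must be >= 0", call. = FALSE)
  }
  gene <- if (n == 0L) {
    paste(rep(c("A", "T"), 25L), collapse = "")
  } else {
    .with_seed(seed, {
      blocks <- vapply(seq_len(n), function(i) {
        repeat {
          sp <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                      collapse = "")
          if (!grepl("GG|CC", sp) && substr(sp, 1L, 1L) != "G") {
            return(paste0(sp, "TGG"))
          }
        }
      }, character(1L))
      paste(blocks, collapse = "")
    })
  }
  found <- nrow(extract_candidates(sequence_record("gene", gene)))
  stopifnot(found == n)
  gene
}

#' Write a fixture genome as FASTA plus a plain-text manifest
#'
#' The manifest records the generating spec and seed so the fixture can be
#' regenerated byte-identically.
#'
#' @param spec a [genome_spec()].
#' @param path output FASTA path; the manifest goes to `<path>.manifest`.
#' @param identifier record identifier.
#' @return `path`, invisibly.
#' @export
write_fixture_genome <- function(spec, path, identifier = "synthetic") {
  rec <- generate_genome(spec, identifier = identifier)
  write_fasta(genome_assembly(list(rec), source_label = path), path)
  manifest <- c(
    sprintf("length=%d", spec$length),
    sprintf("gc_fraction=%g", spec$gc_fraction),
    sprintf("seed=%d", spec$seed),
    vapply(spec$planted, function(p) {
      sprintf("planted=%s:%d:%d", p$spacer20, p$position, p$mismatches)
    }, character(1L))
  )
  writeLines(manifest, paste0(path, ".manifest"))
  invisible(path)
}
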