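# Off-target scoring: per-hit multiplicative mismatch penalty and the
# aggregate specificity score over all genome-wide neighbours of a guide.

#' Position-dependent mismatch weights (literature mode)
#'
#' The experimentally derived per-position mismatch tolerance weights of
#' Hsu et al. (2013, Nat Biotechnol 31:827-832), indexed 5' to 3' along the
#' 20-nt spacer, so position 20 is PAM-proximal. A higher weight means a
#' mismatch at that position suppresses cutting more strongly.
#' @export
MISMATCH_WEIGHTS_HSU <- c(
  0.000, 0.000, 0.014, 0.000, 0.000,
  0.395, 0.317, 0.000, 0.389, 0.079,
  0.445, 0.508, 0.613, 0.851, 0.732,
  0.828, 0.615, 0.804, 0.685, 0.583
)

.mismatch_weights <- function(weights) {
  if (is.numeric(weights)) {
    if (length(weights) != 20L || any(weights < 0) || any(weights > 1)) {
      stop("hit_score: a numeric weight vector must have 20 entries in [0,1]",
           call. = FALSE)
    }
    return(weights)
  }
  switch(match.arg(weights, c("literature", "uniform")),
    literature = MISMATCH_WEIGHTS_HSU,
    uniform = rep(0.5, 20L)
  )
}

#' Single-hit off-target score
#'
#' `100 * prod(1 - w[p])` over the mismatched positions `p`: 100 for a
#' perfect (0-mismatch) hit, decaying multiplicatively with each mismatch.
#' In `"uniform"` mode every weight is 0.5, so scores are the closed forms
#' 100, 50, 25, 12.5, ... for 0, 1, 2, 3, ... mismatches.
#'
#' @param mismatch_positions integer positions in 1..20 (position 20 is
#'   PAM-proximal).
#' @param weights `"literature"` (default), `"uniform"`, or a numeric
#'   vector of 20 weights in `[0,1]`.
#' @return score in `[0, 100]`.
#' @export
hit_score <- function(mismatch_positions, weights = "literature") {
  w <- .mismatch_weights(weights)
  p <- as.integer(mismatch_positions)
  if (length(p) > 0L && (any(is.na(p)) || any(p < 1L) || any(p > 20L))) {
    stop("hit_score: mismatch positions must lie in 1..20", call. = FALSE)
  }
  100 * prod(1 - w[p])
}

#' Positions at which two equal-length sequences differ
#' @param a,b equal-length strings.
#' @return integer vector of 1-based mismatch positions.
#' @export
mismatch_positions <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) {
    stop("mismatch_positions: sequences differ in length", call. = FALSE)
  }
  which(ca != cb)
}

#' Aggregate genome-wide specificity of a guide
#'
#' One exact occurrence at distance 0 is the guide's own on-target site and
#' is excluded; every other neighbour occurrence contributes its
#' [hit_score()]. The aggregate is `10000 / (100 + sum of hit scores)`:
#' 100 when no off-targets exist, 50 with one additional exact duplicate,
#' and decreasing as off-targets accumulate. A guide whose spacer never
#' occurs in the genome has no self-hit to discount and is scored on its
#' neighbours alone.
#'
#' @param query_spacer the 20-nt spacer being assessed.
#' @param neighbours data.frame from [query_neighbours()] (columns `spacer`,
#'   `distance`, `count`).
#' @param max_mm mismatch bound used for the neighbour query; sets the range
#'   of the tally.
#' @param weights passed to [hit_score()].
#' @return an object of class `offtarget_result`: `specificity` in
#'   `[0, 100]`, and `neighbour_counts`, a named vector tallying site
#'   occurrences per mismatch distance `0..max_mm` (self included at d=0).
#' @export
specificity_score <- function(query_spacer, neighbours, max_mm = 4L,
                              weights = "literature") {
  tally <- structure(numeric(max_mm + 1L), names = as.character(0:max_mm))
  total_penalty <- 0
  self_discounted <- FALSE
  if (nrow(neighbours) > 0L) {
    for (i in seq_len(nrow(neighbours))) {
      d <- neighbours$distance[i]
      n <- neighbours$count[i]
      tally[as.character(d)] <- tally[as.character(d)] + n
      mm <- mismatch_positions(query_spacer, neighbours$spacer[i])
      if (length(mm) != d) {
        stop("specificity_score: neighbour distance disagrees with sequence",
             call. = FALSE)
      }
      if (d == 0L && !self_discounted) {
        n <- n - 1L          # one exact occurrence is the on-target site
        self_discounted <- TRUE
      }
      if (n > 0L) {
        total_penalty <- total_penalty + n * hit_score(mm, weights = weights)
      }
    }
  }
  structure(
    list(specificity = 10000 / (100 + total_penalty),
         neighbour_counts = tally, max_mm = as.integer(max_mm)),
    class = "offtarget_result"
  )
}

#' @export
print.offtarget_result <- function(x, ...) {
  cat(sprintf("<offtarget_result> specificity %.2f; sites by distance: %s\n",
              x$specificity,
              paste(sprintf("%s=%g", names(x$neighbour_counts),
                            x$neighbour_counts), collapse = " ")))
  invisible(x)
}

#' Assess one spacer's off-target risk against an index
#'
#' Convenience wrapper: [query_neighbours()] then [specificity_score()].
#'
#' @inheritParams specificity_score
#' @param index an `issl_index`.
#' @param spacer20 20-nt spacer.
#' @return an `offtarget_result`.
#' @export
assess_offtarget <- function(index, spacer20, max_mm = 4L,
                             weights = "literature") {
  specificity_score(spacer20, query_neighbours(index, spacer20, max_mm),
                    max_mm = max_mm, weights = weights)
}
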