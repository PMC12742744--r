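# Consensus on-target filtering: three independent rule-based methods vote
# on each candidate; a candidate is accepted when enough methods agree.
# The built-in methods are documented stand-ins with the pipeline's
# interface — any method taking a spacer and returning a logical can be
# substituted.

.spacer_of <- function(candidate) {
  if (is.character(candidate)) {
    s <- candidate
  } else {
    s <- candidate$spacer20
  }
  if (nchar(s) == 23L) {
    s <- substr(s, 1L, 20L)
  }
  if (nchar(s) != 20L) {
    stop("on-target method: expected a 20-nt spacer (or 23-nt target)",
         call. = FALSE)
  }
  s
}

#' On-target method: PAM-proximal guanine
#'
#' Accepts a spacer whose 3'-terminal base (position 20, adjacent to the
#' PAM) is G — a feature repeatedly associated with higher cutting
#' efficiency.
#'
#' @param candidate a 20-nt spacer string, 23-nt target string, or a list
#'   with a `spacer20` field.
#' @return logical.
#' @export
method_g20 <- function(candidate) {
  substr(.spacer_of(candidate), 20L, 20L) == "G"
}

#' On-target method: nucleotide composition
#'
#' Accepts a spacer with GC fraction in `[0.30, 0.70]` and no `TTTT` run
#' (poly-T stretches terminate Pol III transcription of the guide).
#'
#' @inheritParams method_g20
#' @return logical.
#' @export
method_composition <- function(candidate) {
  s <- .spacer_of(candidate)
  gc <- (nchar(gsub("[^GC]", "", s))) / 20
  gc >= 0.30 && gc <= 0.70 && !grepl("TTTT", s, fixed = TRUE)
}

#' On-target method: secondary-structure heuristic
#'
#' Rejects a spacer containing two non-overlapping substrings of length >= 6
#' that are exact reverse complements of each other — a proxy for guide
#' self-hairpins. Checking length exactly 6 suffices: any longer
#' complementary pair contains a non-overlapping length-6 pair.
#'
#' @inheritParams method_g20
#' @return logical (`TRUE` = no hairpin-like pair found).
#' @export
method_structure <- function(candidate) {
  s <- .spacer_of(candidate)
  k <- 6L
  subs <- substring(s, 1:(20L - k + 1L), k:20L)
  rcs <- reverse_complement(subs)
  for (i in seq_along(subs)) {
    for (j in seq_along(subs)) {
      if (abs(i - j) >= k && subs[j] == rcs[i]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Default on-target method set
#'
#' Named list of the three built-in methods, in voting order.
#' @export
default_ontarget_methods <- function() {
  list(g20 = method_g20, composition = method_composition,
       structure = method_structure)
}

#' Combine method verdicts by consensus vote
#'
#' @param verdicts logical vector of three method outcomes (order: g20,
#'   composition, structure), or any named logical vector.
#' @param threshold minimum number of passing methods for acceptance
#'   (default 2, i.e. majority of three).
#' @return an object of class `ontarget_verdict`: per-method booleans,
#'   `consensus_votes`, `accepted`.
#' @export
consensus <- function(verdicts, threshold = 2L) {
  verdicts <- as.logical(verdicts)
  if (any(is.na(verdicts))) {
    stop("consensus: verdicts must be TRUE/FALSE", call. = FALSE)
  }
  votes <- sum(verdicts)
  structure(
    list(passes_g20 = verdicts[1L], passes_composition = verdicts[2L],
         passes_structure = verdicts[3L],
         consensus_votes = votes, accepted = votes >= threshold),
    class = "ontarget_verdict"
  )
}

#' @export
print.ontarget_verdict <- function(x, ...) {
  cat(sprintf("<ontarget_verdict> %d/3 votes -> %s\n", x$consensus_votes,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Run the full on-target assessment for one candidate
#'
#' @inheritParams method_g20
#' @param methods list of method functions (default
#'   [default_ontarget_methods()]).
#' @param threshold consensus threshold (default 2).
#' @return an `ontarget_verdict`.
#' @export
assess_ontarget <- function(candidate, methods = default_ontarget_methods(),
                            threshold = 2L) {
  consensus(vapply(methods, function(f) isTRUE(f(candidate)), logical(1L)),
            threshold = threshold)
}
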