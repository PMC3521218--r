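#' Construct a candidate set
#'
#' Holds the duplicate-free candidate motifs produced by the exact stage as
#' sorted integer codes (ascending code order = lexicographic order).
#'
#' @param l motif length.
#' @param codes numeric vector of l-mer codes (sorted, duplicate-free).
#' @param source_count number of first-sequence l-mers processed.
#' @return An object of class `CandidateSet`.
#' @export
candidate_set <- function(l, codes, source_count = NA_integer_) {
  structure(list(l = as.integer(l), codes = as.numeric(codes),
                 source_count = as.integer(source_count)),
            class = "CandidateSet")
}

#' @export
length.CandidateSet <- function(x) length(x$codes)

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet: %d candidate l-mer(s) of length %d\n",
              length(x$codes), x$l))
  invisible(x)
}

#' @export
as.character.CandidateSet <- function(x, ...) decode_lmer(x$codes, x$l)

#' Exact candidate-generation stage
#'
#' For every l-mer `y` of the first sequence (optionally restricted to a
#' contiguous block of window start indices, which is how parallel lanes
#' are formed), enumerates the d-mismatch ball of `y` and keeps the l-mers
#' whose set distance to the whole subset is at most `d`. The result equals
#' [brute_force_motifs()] on the same subset, because any l-mer within
#' distance `d` of every sequence is in particular within `d` of some
#' window of the first one.
#'
#' Two engines share this contract: `"pruned"` (default) tests each
#' distinct l-mer at most once across all balls, using a presence bitmap
#' over the `4^l` code space for small `l` and a hash set otherwise;
#' `"reference"` re-tests duplicates and deduplicates output only — slower,
#' kept as an independent baseline.
#'
#' @param S a [sequence_set()] (the q-sequence subset) or character vector.
#' @param l motif length.
#' @param d maximum mismatches.
#' @param engine `"pruned"` or `"reference"`.
#' @param window_range optional `c(from, to)` 0-based half-open range of
#'   first-sequence window start indices; default all windows.
#' @param bitmap_max_l largest `l` for which the flat `4^l` presence bitmap
#'   is used for deduplication (memory budget); beyond it a hash set is
#'   used.
#' @return A [candidate_set()].
#' @export
candidate_search <- function(S, l, d, engine = c("pruned", "reference"),
                             window_range = NULL, bitmap_max_l = 14L) {
  engine <- match.arg(engine)
  S <- as_sequence_set(S)
  check_search_params(S, l, d)
  m <- S$lengths[1] - l + 1
  if (is.null(window_range)) window_range <- c(0L, m)
  from <- as.integer(window_range[1])
  to <- as.integer(window_range[2])
  if (from < 0 || to > m || from > to)
    stop("window_range [", from, ",", to, ") outside [0,", m, ")")
  codes <- cpp_candidate_search(S$seqs, as.integer(l), as.integer(d),
                                from, to, engine == "pruned",
                                as.integer(bitmap_max_l))
  candidate_set(l, codes, source_count = to - from)
}
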