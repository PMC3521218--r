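#' Hamming distance between two equal-length DNA strings
#'
#' @param x,y strings over \{A,C,G,T\} of equal length.
#' @return Integer number of mismatching positions.
#' @examples
#' hamming_distance("ACGT", "AGGA")
#' @export
hamming_distance <- function(x, y) {
  cpp_hamming(toupper(x), toupper(y))
}

#' Minimum distance from an l-mer to a sequence
#'
#' The minimum, over all l-length windows of `s`, of the Hamming distance
#' between `x` and the window.
#'
#' @param x an l-mer.
#' @param s a DNA sequence of length at least `nchar(x)`.
#' @return Integer minimum window distance.
#' @export
min_distance <- function(x, s) {
  if (nchar(s) < nchar(x)) stop("sequence shorter than the l-mer")
  cpp_min_distance(toupper(x), toupper(s))
}

#' Distance from an l-mer to a sequence set
#'
#' The maximum over sequences of [min_distance()]; an l-mer `x` is an
#' (l,d) motif of `S` exactly when this value is at most d.
#'
#' @param x an l-mer.
#' @param S a [sequence_set()] or character vector of sequences.
#' @return Integer set distance.
#' @export
set_distance <- function(x, S) {
  S <- as_sequence_set(S)
  max(vapply(S$seqs, function(s) min_distance(x, s), integer(1), USE.NAMES = FALSE))
}

#' d-mismatch neighborhood of an l-mer
#'
#' All l-length strings within Hamming distance `d` of `x`, duplicate-free,
#' in lexicographic order. The size is [neighborhood_size()] of (l, d).
#'
#' @param x an l-mer.
#' @param d maximum number of mismatches, in `[0, nchar(x)]`.
#' @return Character vector of l-mers.
#' @examples
#' length(neighborhood("AAA", 1)) # 10
#' @export
neighborhood <- function(x, d) {
  l <- nchar(x)
  if (d < 0 || d > l) stop("d must be in [0, l]")
  cpp_neighborhood(toupper(x), as.integer(d))
}

#' Size of the d-mismatch neighborhood
#'
#' `v(l, d) = sum_{i=0}^{d} choose(l, i) 3^i`, the number of l-length
#' strings within Hamming distance d of a fixed l-mer.
#'
#' @param l motif length.
#' @param d maximum mismatches, in `[0, l]`.
#' @return Exact count (double; exact for all practically relevant l, d).
#' @export
neighborhood_size <- function(l, d) {
  if (d < 0 || d > l) stop("d must be in [0, l]")
  i <- 0:d
  sum(choose(l, i) * 3^i)
}

#' Brute-force (l,d) motif search
#'
#' Enumerates all `4^l` candidate l-mers and keeps those whose
#' [set_distance()] to `S` is at most `d`. Exponential in `l`; it exists as
#' the ground-truth oracle against which the hybrid search is tested, and is
#' guarded to small `l` by default.
#'
#' @param S a [sequence_set()] or character vector.
#' @param l motif length.
#' @param d maximum mismatches.
#' @param max_l guard on `l` (default 14); raise explicitly to override.
#' @return Character vector of motifs in lexicographic order.
#' @export
brute_force_motifs <- function(S, l, d, max_l = 14L) {
  S <- as_sequence_set(S)
  check_search_params(S, l, d)
  if (l > max_l)
    stop("l = ", l, " exceeds the brute-force guard (max_l = ", max_l,
         "); raise max_l to override")
  codes <- cpp_brute_force(S$seqs, as.integer(l), as.integer(d))
  cpp_decode(codes, as.integer(l))
}

#' Encode l-mers as integer codes
#'
#' Bijection between l-mers and `[0, 4^l)` under A=0, C=1, G=2, T=3 with the
#' leftmost character most significant. Ascending code order equals
#' lexicographic order.
#'
#' @param x character vector of l-mers.
#' @return Numeric vector of codes (exact integers for l <= 26).
#' @export
encode_lmer <- function(x) cpp_encode(toupper(x))

#' @rdname encode_lmer
#' @param code numeric vector of codes.
#' @param l motif length.
#' @export
decode_lmer <- function(code, l) cpp_decode(as.numeric(code), as.integer(l))

# shared parameter validation at search entry
check_search_params <- function(S, l, d) {
  if (l < 1) stop("l must be >= 1")
  if (l > 26) stop("l must be <= 26 (integer code exactness limit)")
  if (d < 0 || d > l) stop("d must be in [0, l]")
  short <- which(S$lengths < l)
  if (length(short) > 0)
    stop("sequence '", S$ids[short[1]], "' (length ", S$lengths[short[1]],
         ") is shorter than l = ", l)
  invisible(TRUE)
}
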