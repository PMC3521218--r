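#' Partition the first sequence's l-mers into contiguous lanes
#'
#' Splits the `n - l + 1` window start indices of `s1` into `p` contiguous,
#' disjoint blocks whose sizes differ by at most one. Lanes beyond the
#' window count receive empty ranges.
#'
#' @param s1 the first sequence (character scalar), or an integer taken
#'   directly as the number of windows.
#' @param l motif length (ignored when `s1` is already a count).
#' @param p number of lanes, `p >= 1`.
#' @return A data frame with columns `from`, `to` (0-based, half-open) and
#'   `size`, one row per lane.
#' @examples
#' partition_lmers(10L, p = 3) # sizes 4, 3, 3
#' @export
partition_lmers <- function(s1, l = NULL, p) {
  if (p < 1) stop("p must be >= 1")
  m <- if (is.character(s1)) {
    if (is.null(l)) stop("l is required when s1 is a sequence")
    if (nchar(s1) < l) stop("sequence shorter than l")
    nchar(s1) - l + 1L
  } else {
    as.integer(s1)
  }
  base <- m %/% p
  extra <- m %% p
  sizes <- rep(base, p) + c(rep(1L, extra), rep(0L, p - extra))
  to <- cumsum(sizes)
  from <- to - sizes
  data.frame(from = as.integer(from), to = as.integer(to),
             size = as.integer(sizes))
}

#' Merge per-lane candidate lists into one duplicate-free set
#'
#' Incrementally appends each lane's list in lane order, discarding
#' elements already present — a presence lookup table over the `4^l` code
#' space for small `l`, a hash index otherwise — and finally sorts. As a
#' set the result is the union of the inputs, so it does not depend on the
#' lane order.
#'
#' @param lists a list of [candidate_set()] objects (or numeric code
#'   vectors) sharing the same `l`.
#' @param l motif length; required when `lists` holds bare code vectors.
#' @param bitmap_max_l memory-budget cutoff for the lookup-table strategy.
#' @return A [candidate_set()] holding the union.
#' @export
merge_candidate_lists <- function(lists, l = NULL, bitmap_max_l = 14L) {
  if (length(lists) == 0) stop("nothing to merge")
  code_lists <- lapply(lists, function(x) {
    if (inherits(x, "CandidateSet")) {
      if (is.null(l)) l <<- x$l
      if (x$l != l) stop("mixed l across candidate lists")
      x$codes
    } else {
      as.numeric(x)
    }
  })
  if (is.null(l)) stop("l is required")
  src <- sum(vapply(lists, function(x)
    if (inherits(x, "CandidateSet")) x$source_count else 0L, integer(1)))
  codes <- cpp_merge_lists(code_lists, as.integer(l), as.integer(bitmap_max_l))
  candidate_set(l, codes, source_count = src)
}

# fork-based map that degrades to lapply where forking is unavailable;
# result order is always the input order, so output never depends on
# scheduling
lane_apply <- function(xs, fn, workers) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(xs, fn, mc.cores = workers, mc.preschedule = TRUE)
    failed <- vapply(res, inherits, logical(1), what = "try-error")
    if (any(failed))
      stop("parallel lane ", which(failed)[1], " failed: ",
           attr(res[[which(failed)[1]]], "condition")$message)
    res
  } else {
    lapply(xs, fn)
  }
}

# run the exact stage lane-wise over blocks of first-sequence l-mers;
# returns the per-lane candidate sets and their duplicate-free merge
lane_candidates <- function(S_q, l, d, workers, engine = "pruned",
                            bitmap_max_l = 14L) {
  lanes <- partition_lmers(S_q$seqs[1], l, workers)
  per_lane <- lane_apply(seq_len(nrow(lanes)), function(j) {
    candidate_search(S_q, l, d, engine = engine,
                     window_range = c(lanes$from[j], lanes$to[j]),
                     bitmap_max_l = bitmap_max_l)
  }, workers)
  list(lanes = lanes, per_lane = per_lane,
       merged = merge_candidate_lists(per_lane, l, bitmap_max_l))
}

# validate candidates in contiguous blocks of the sorted candidate list
parallel_validate <- function(C, S_rest, d, workers) {
  if (length(C) == 0) return(C)
  blocks <- partition_lmers(length(C$codes), p = workers)
  keep_blocks <- lane_apply(seq_len(nrow(blocks)), function(j) {
    if (blocks$size[j] == 0) return(logical(0))
    idx <- seq.int(blocks$from[j] + 1L, blocks$to[j])
    cpp_validate(C$codes[idx], S_rest$seqs, C$l, as.integer(d))
  }, workers)
  candidate_set(C$l, C$codes[unlist(keep_blocks)], C$source_count)
}

#' Lane-parallel hybrid search
#'
#' Convenience wrapper around [hep_search()] with `workers > 1`: the first
#' sequence's l-mers are partitioned across lanes, each lane runs the
#' exact stage independently with no shared mutable state, lane candidate
#' lists are merged duplicate-free in lane order, and validation work is
#' distributed in contiguous candidate blocks. The motif set, distances
#' and report bytes are identical to the serial run for every worker
#' count.
#'
#' @inheritParams hep_search
#' @return A `MotifResult`, identical to the serial result.
#' @export
parallel_hep <- function(S, l, d, q = "auto", workers = 2L,
                         engine = c("pruned", "reference"),
                         dprime_threshold = 0.9, bitmap_max_l = 14L) {
  hep_search(S, l, d, q = q, engine = match.arg(engine), workers = workers,
             dprime_threshold = dprime_threshold, bitmap_max_l = bitmap_max_l)
}
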