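#' Validate candidate motifs against the remaining sequences
#'
#' Keeps the candidates whose minimum window distance is at most `d` in
#' every sequence of `S_rest`, abandoning a candidate at the first failing
#' sequence. With an empty `S_rest` (q = t) the candidate set is returned
#' unchanged.
#'
#' @param C a [candidate_set()].
#' @param S_rest a [sequence_set()] with the t - q held-out sequences, or
#'   `NULL`/empty for none.
#' @param d maximum mismatches.
#' @return A [candidate_set()] containing the surviving candidates.
#' @export
validate_candidates <- function(C, S_rest, d) {
  stopifnot(inherits(C, "CandidateSet"))
  if (is.null(S_rest) || (inherits(S_rest, "SequenceSet") && S_rest$t == 0) ||
      (is.character(S_rest) && length(S_rest) == 0))
    return(C)
  S_rest <- as_sequence_set(S_rest)
  check_search_params(S_rest, C$l, d)
  keep <- cpp_validate(C$codes, S_rest$seqs, C$l, as.integer(d))
  candidate_set(C$l, C$codes[keep], C$source_count)
}

new_motif_result <- function(S, l, d, codes, q_used, candidate_count,
                             engine, workers) {
  motifs <- decode_lmer(codes, l)
  t <- S$t
  pos <- matrix(NA_integer_, nrow = length(motifs), ncol = t,
                dimnames = list(NULL, S$ids))
  dist <- integer(length(motifs))
  for (i in seq_along(motifs)) {
    bp <- cpp_best_positions(motifs[i], S$seqs)
    pos[i, ] <- bp$position
    dist[i] <- max(bp$distance)
  }
  structure(list(
    l = as.integer(l), d = as.integer(d),
    motifs = motifs, max_distance = dist, positions = pos,
    seq_ids = S$ids,
    q_used = as.integer(q_used),
    candidate_count = as.integer(candidate_count),
    validated_count = length(motifs),
    engine = engine, workers = as.integer(workers)
  ), class = "MotifResult")
}

#' @export
print.MotifResult <- function(x, ...) {
  cat(sprintf("MotifResult (l=%d, d=%d): %d motif(s)\n", x$l, x$d,
              length(x$motifs)))
  cat(sprintf("  q used = %d, candidates = %d, validated = %d, engine = %s, workers = %d\n",
              x$q_used, x$candidate_count, x$validated_count, x$engine,
              x$workers))
  if (length(x$motifs) > 0) {
    show <- utils::head(seq_along(x$motifs), 10)
    for (i in show)
      cat(sprintf("  %s  (max distance %d)\n", x$motifs[i], x$max_distance[i]))
    if (length(x$motifs) > 10)
      cat("  ... and", length(x$motifs) - 10, "more\n")
  }
  invisible(x)
}

#' @export
as.data.frame.MotifResult <- function(x, ...) {
  df <- data.frame(motif = x$motifs, max_distance = x$max_distance,
                   stringsAsFactors = FALSE)
  if (length(x$seq_ids) > 0) {
    posdf <- as.data.frame(x$positions)
    names(posdf) <- paste0("pos_", x$seq_ids)
    df <- cbind(df, posdf)
  }
  df[order(df$motif), , drop = FALSE]
}

#' Hybrid exact planted (l,d) motif search
#'
#' Finds every l-mer whose set distance to `S` is at most `d`, in three
#' steps: pick the subset size `q` (explicitly, or from the analytic
#' planner when `q = "auto"`), run the exact candidate-generation stage on
#' the first `q` sequences, then validate the candidates against the
#' remaining `t - q` sequences by approximate pattern matching. The
#' reported motif set is independent of `q` — a smaller `q` only shifts
#' work between the two stages — and equals [brute_force_motifs()] on the
#' full set.
#'
#' @param S a [sequence_set()] or character vector of DNA sequences.
#' @param l motif length.
#' @param d maximum mismatches.
#' @param q subset size in `[1, t]`, or `"auto"` to resolve via the q-plan
#'   cache / [compute_ons()] (the planner uses `n` = rounded mean sequence
#'   length).
#' @param engine exact-stage engine, `"pruned"` (default) or `"reference"`.
#' @param workers number of parallel lanes; `1` runs serially. Results are
#'   identical for every worker count.
#' @param dprime_threshold threshold for [estimate_dprime()] when
#'   `q = "auto"`.
#' @param cache_path q-plan cache file for `q = "auto"`; `NULL` disables
#'   the cache.
#' @param bitmap_max_l memory-budget cutoff passed to [candidate_search()].
#' @return A `MotifResult`: sorted motifs, their set distances, per-sequence
#'   best-match positions (0-based), and run statistics.
#' @examples
#' inst <- generate_planted_instance(t = 6, n = 60, l = 7, d = 1, seed = 42)
#' res <- hep_search(inst$sequences, l = 7, d = 1)
#' inst$motif %in% res$motifs
#' @export
hep_search <- function(S, l, d, q = "auto", engine = c("pruned", "reference"),
                       workers = 1L, dprime_threshold = 0.9,
                       cache_path = NULL, bitmap_max_l = 14L) {
  engine <- match.arg(engine)
  S <- as_sequence_set(S)
  check_search_params(S, l, d)
  t <- S$t
  if (identical(q, "auto")) {
    n_model <- as.integer(round(mean(S$lengths)))
    q <- if (is.null(cache_path)) {
      compute_ons(l, d, n_model, t, dprime_threshold = dprime_threshold)
    } else {
      q_lookup(l, d, n_model, t, dprime_threshold = dprime_threshold,
               cache_path = cache_path)
    }
  }
  q <- as.integer(q)
  if (q < 1 || q > t) stop("q must be in [1, t]")
  if (workers < 1) stop("workers must be >= 1")

  S_q <- subset_sequences(S, seq_len(q))
  if (workers == 1L) {
    C <- candidate_search(S_q, l, d, engine = engine,
                          bitmap_max_l = bitmap_max_l)
  } else {
    C <- lane_candidates(S_q, l, d, workers, engine = engine,
                         bitmap_max_l = bitmap_max_l)$merged
  }
  C_valid <- if (q < t) {
    S_rest <- subset_sequences(S, seq.int(q + 1L, t))
    if (workers == 1L) {
      validate_candidates(C, S_rest, d)
    } else {
      parallel_validate(C, S_rest, d, workers)
    }
  } else {
    C
  }
  new_motif_result(S, l, d, C_valid$codes, q_used = q,
                   candidate_count = length(C),
                   engine = engine, workers = workers)
}
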