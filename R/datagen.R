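DNA_BASES <- c("A", "C", "G", "T")

# deterministic per-stream sub-seed below 2^31, so growing t never
# reshuffles earlier sequences
sub_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + 1000003 * i) %% 2147483647)
}

mutate_lmer <- function(motif_chars, k) {
  l <- length(motif_chars)
  if (k == 0) return(motif_chars)
  pos <- sample.int(l, k)
  for (p in pos) {
    motif_chars[p] <- sample(setdiff(DNA_BASES, motif_chars[p]), 1)
  }
  motif_chars
}

#' Generate a planted (l,d) problem instance
#'
#' Emulates the standard benchmark protocol: draw a random l-length motif
#' `M`; for each of `t` sequences, draw an i.i.d. uniform background of
#' length `n - l`, mutate an independent copy of `M`, and insert it at a
#' uniform position, giving sequences of length exactly `n`. In mode
#' `"exact_d"` (default, the hardest case) each copy receives substitutions
#' at exactly `d` distinct positions; in `"uniform_0_to_d"` the number of
#' substituted positions is drawn uniformly from `{0, ..., d}`. Either way
#' every planted occurrence is within Hamming distance `d` of `M`, so `M`
#' is guaranteed to be an (l,d) motif of the instance.
#'
#' @param t number of sequences.
#' @param n sequence length.
#' @param l motif length.
#' @param d maximum mismatches.
#' @param seed integer seed; the instance is fully reproducible from it.
#' @param mutation_mode `"exact_d"` or `"uniform_0_to_d"`.
#' @return An object of class `PlantedInstance`: list with `sequences`
#'   (a [sequence_set()]), `motif`, `positions` (0-based plant starts),
#'   `mutation_counts`, `params` and `seed`.
#' @examples
#' inst <- generate_planted_instance(t = 5, n = 40, l = 6, d = 1, seed = 1)
#' set_distance(inst$motif, inst$sequences) <= 1
#' @export
generate_planted_instance <- function(t, n, l, d, seed,
                                      mutation_mode = c("exact_d", "uniform_0_to_d")) {
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(t >= 1, l >= 1, l <= n, d >= 0, d <= l)
  seed <- as.integer(seed)

  set.seed(sub_seed(seed, 0L))
  motif_chars <- sample(DNA_BASES, l, replace = TRUE)

  seqs <- character(t)
  positions <- integer(t)
  mut_counts <- integer(t)
  for (i in seq_len(t)) {
    set.seed(sub_seed(seed, i))
    background <- sample(DNA_BASES, n - l, replace = TRUE)
    k <- switch(mutation_mode,
                exact_d = d,
                uniform_0_to_d = sample.int(d + 1L, 1) - 1L)
    occ <- mutate_lmer(motif_chars, k)
    pos <- sample.int(n - l + 1L, 1) - 1L  # 0-based plant start
    seqs[i] <- paste(c(background[seq_len(pos)], occ,
                       background[seq_len(n - l - pos) + pos]), collapse = "")
    positions[i] <- pos
    mut_counts[i] <- k
  }
  structure(list(
    sequences = sequence_set(seqs, sprintf("seq_%03d", seq_len(t))),
    motif = paste(motif_chars, collapse = ""),
    positions = positions,
    mutation_counts = mut_counts,
    params = list(t = t, n = n, l = l, d = d, mutation_mode = mutation_mode),
    seed = seed
  ), class = "PlantedInstance")
}

#' @export
print.PlantedInstance <- function(x, ...) {
  cat(sprintf("PlantedInstance: t=%d, n=%d, (l,d)=(%d,%d), mode=%s, seed=%d\n",
              x$params$t, x$params$n, x$params$l, x$params$d,
              x$params$mutation_mode, x$seed))
  cat("  planted motif:", x$motif, "\n")
  invisible(x)
}

#' Write a planted instance to FASTA plus a JSON ground-truth file
#'
#' @param inst a [generate_planted_instance()] result.
#' @param fasta_path output FASTA path for the sequences.
#' @param truth_path output JSON path for the ground truth (motif, 0-based
#'   plant positions, per-sequence mutation counts, parameters, seed).
#' @return `fasta_path`, invisibly.
#' @export
write_instance <- function(inst, fasta_path, truth_path) {
  stopifnot(inherits(inst, "PlantedInstance"))
  write_fasta(inst$sequences, fasta_path)
  jsonlite::write_json(list(
    motif = inst$motif,
    positions = inst$positions,
    mutation_counts = inst$mutation_counts,
    params = inst$params,
    seed = inst$seed
  ), truth_path, auto_unbox = TRUE, digits = NA)
  invisible(fasta_path)
}

#' Read a ground-truth JSON file written by [write_instance()]
#'
#' @param truth_path path to the JSON ground truth.
#' @return A list with `motif`, `positions`, `mutation_counts`, `params`
#'   and `seed`.
#' @export
read_truth <- function(truth_path) {
  jsonlite::read_json(truth_path, simplifyVector = TRUE)
}
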