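#' Probability that two random l-mers are within Hamming distance d
#'
#' For two i.i.d. uniform strings over a 4-letter alphabet,
#' `p_d = sum_{i=0}^{d} choose(l, i) (3/4)^i (1/4)^(l-i)`.
#' Terms are evaluated in log space so the value stays accurate for long
#' motifs (tested to l = 25 and beyond).
#'
#' @param l string length.
#' @param d maximum mismatches; values above `l` are truncated to `l`.
#' @return Probability in `[0, 1]`.
#' @export
match_prob <- function(l, d) {
  if (d < 0) stop("d must be >= 0")
  d <- min(d, l)
  i <- 0:d
  sum(exp(lchoose(l, i) + i * log(3 / 4) + (l - i) * log(1 / 4)))
}

#' Probability that every sequence contains a window within distance d
#'
#' Under the independence approximation, a random l-mer `x` has at least one
#' window within Hamming distance `d` in a random length-`n` sequence with
#' probability `1 - (1 - p_d)^(n-l+1)`; raising this to `t` gives the
#' probability that all `t` sequences contain such a window, i.e. that the
#' set distance of `x` is at most `d`.
#'
#' @param l motif length.
#' @param d maximum mismatches.
#' @param n sequence length.
#' @param t number of sequences (`t = 0` gives 1, the empty product).
#' @return Probability in `[0, 1]`.
#' @export
prob_all_sequences_hit <- function(l, d, n, t) {
  if (n < l) stop("n must be >= l")
  if (t < 0) stop("t must be >= 0")
  if (t == 0) return(1)
  pd <- match_prob(l, d)
  if (pd >= 1) return(1)
  # 1 - (1-pd)^(n-l+1), then ^t, all guarded against underflow
  per_seq <- -expm1((n - l + 1) * log1p(-pd))
  if (per_seq <= 0) return(0)
  exp(t * log(per_seq))
}

#' Expected number of chance (l,d) motifs in random sequences
#'
#' `E(l, d, q, n) = 4^l (1 - (1 - p_d)^(n-l+1))^q`: the expected number of
#' l-mers whose set distance to `q` random length-`n` sequences is at most
#' `d`. At `q = 0` this is exactly `4^l` (every l-mer), and it decreases
#' geometrically in `q`. It predicts the size of the candidate set the
#' exact stage hands to validation.
#'
#' @inheritParams prob_all_sequences_hit
#' @param q number of sequences the candidates are required to match.
#' @return Expected count (real).
#' @export
expected_motif_count <- function(l, d, q, n) {
  4^l * prob_all_sequences_hit(l, d, n, q)
}

#' Estimate the distance parameter d' of the exact-stage cost model
#'
#' The branch-and-bound cost model depends on a distance d' chosen so that a
#' random l-mer is, with probability close to 1, at distance at least d'
#' from the sequence set. We take the largest `d'` in `[0, 2d]` such that
#' `P(set distance >= d') = 1 - prob_all_sequences_hit(l, d'-1, n, t)` is at
#' least `threshold`. The default threshold 0.9 reproduces the published
#' benchmark plans for the standard t=20, n=600 challenge instances; the
#' planner is insensitive to the exact value because d' enters the
#' subset-size bound only inside a logarithm.
#'
#' @inheritParams prob_all_sequences_hit
#' @param threshold probability in (0, 1) read as "close to 1".
#' @return Integer d' in `[0, 2d]`.
#' @export
estimate_dprime <- function(l, d, n, t, threshold = 0.9) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  dp <- 0L
  if (d == 0) return(dp)
  for (k in seq_len(2L * d)) {
    surv <- 1 - prob_all_sequences_hit(l, min(k - 1L, l), n, t)
    if (surv >= threshold) dp <- as.integer(k) else break
  }
  dp
}
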