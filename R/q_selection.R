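#' @noRd
resolve_dprime <- function(l, d, n, t, d_prime = NULL, dprime_threshold = 0.9) {
  if (is.null(d_prime)) d_prime <- estimate_dprime(l, d, n, t, dprime_threshold)
  d_prime <- as.integer(d_prime)
  if (d_prime < 0 || d_prime > 2 * d) stop("d_prime must be in [0, 2d]")
  d_prime
}

# per-sequence operation count of the exact (branch-and-bound) stage:
# (n-l+1)^2 (l + p_2d * sum_{i=1}^{2d-d'+1} choose(l,i) 3^i)
exact_stage_ops_per_seq <- function(l, d, n, d_prime) {
  p2d <- match_prob(l, min(2 * d, l))
  up <- 2 * d - d_prime + 1
  s <- if (up >= 1) sum(choose(l, seq_len(up)) * 3^seq_len(up)) else 0
  (n - l + 1)^2 * (l + p2d * s)
}

#' Predicted cost of the exact stage on q sequences
#'
#' Expected operation count (unitless, never seconds) of running the
#' neighborhood branch-and-bound search on `q` random sequences of length
#' `n`: `q (n-l+1)^2 (l + p_2d sum_{i=1}^{2d-d'+1} choose(l,i) 3^i)`, where
#' `p_2d` is [match_prob()] at `min(2d, l)` and `d'` comes from
#' [estimate_dprime()] unless given.
#'
#' @param q number of sequences processed by the exact stage.
#' @param l motif length.
#' @param d maximum mismatches.
#' @param n sequence length.
#' @param t total number of sequences (used only to estimate `d'`).
#' @param d_prime optional explicit d'; overrides the estimate.
#' @param dprime_threshold threshold passed to [estimate_dprime()].
#' @return Predicted operation count (real).
#' @export
predicted_time_exact <- function(q, l, d, n, t = q, d_prime = NULL,
                                 dprime_threshold = 0.9) {
  d_prime <- resolve_dprime(l, d, n, t, d_prime, dprime_threshold)
  q * exact_stage_ops_per_seq(l, d, n, d_prime)
}

#' Predicted cost of the hybrid search at subset size q
#'
#' The exact-stage cost on `q` sequences plus the validation cost
#' `l (t-q) (n-l+1) E(l,d,q,n)` of pattern-matching the expected candidate
#' set against the remaining `t - q` sequences. At `q = t` the validation
#' term vanishes; at `q = 0` the value is the brute-force cost
#' `l t (n-l+1) 4^l`.
#'
#' @inheritParams predicted_time_exact
#' @param t total number of sequences.
#' @return Predicted operation count (real).
#' @export
predicted_time_hep <- function(q, l, d, n, t, d_prime = NULL,
                               dprime_threshold = 0.9) {
  d_prime <- resolve_dprime(l, d, n, t, d_prime, dprime_threshold)
  predicted_time_exact(q, l, d, n, t, d_prime) +
    l * (t - q) * (n - l + 1) * expected_motif_count(l, d, q, n)
}

#' Minimum number of sequences (mns) for which the hybrid pays off
#'
#' The smallest subset size `q` for which the predicted hybrid cost beats
#' running the exact stage on all `t` sequences. Solving the cost
#' inequality for `q` gives the bound
#' `[log((n-l+1)(l + p_2d S)) - log(l 4^l)] / log(1 - (1-p_d)^(n-l+1))`
#' with `S = sum_{i=1}^{2d-d'+1} choose(l,i) 3^i`; `mns` is the ceiling of
#' this bound plus one, clamped to `[1, t]`. This rounding reproduces the
#' published benchmark plans for the t=20, n=600 challenge instances.
#'
#' @inheritParams predicted_time_hep
#' @return Integer subset size in `[1, t]`.
#' @examples
#' compute_mns(11, 3, 600, 20) # 9
#' @export
compute_mns <- function(l, d, n, t, d_prime = NULL, dprime_threshold = 0.9) {
  d_prime <- resolve_dprime(l, d, n, t, d_prime, dprime_threshold)
  pd <- match_prob(l, d)
  if (pd <= 0 || pd >= 1)
    stop("model undefined: p_d = ", pd, " must lie strictly between 0 and 1")
  p2d <- match_prob(l, min(2 * d, l))
  up <- 2 * d - d_prime + 1
  s <- if (up >= 1) sum(choose(l, seq_len(up)) * 3^seq_len(up)) else 0
  num <- log((n - l + 1) * (l + p2d * s)) - log(l) - l * log(4)
  den <- log(-expm1((n - l + 1) * log1p(-pd)))
  bound <- num / den
  mns <- as.integer(ceiling(bound)) + 1L
  if (mns > t) {
    warning("mns bound ", mns, " exceeds t = ", t,
            "; the hybrid is not predicted to help, clamping to t")
    mns <- as.integer(t)
  }
  max(1L, mns)
}

#' Optimal number of sequences (ons) minimizing the predicted hybrid cost
#'
#' Scans the predicted hybrid cost curve: initialize at `q = 1`, then test
#' `q = mns .. t`, updating only on strict improvement so the smallest
#' minimizing `q` wins.
#'
#' @inheritParams predicted_time_hep
#' @return Integer subset size in `{1} U [mns, t]`.
#' @examples
#' compute_ons(11, 3, 600, 20) # 10
#' @export
compute_ons <- function(l, d, n, t, d_prime = NULL, dprime_threshold = 0.9) {
  d_prime <- resolve_dprime(l, d, n, t, d_prime, dprime_threshold)
  mns <- suppressWarnings(compute_mns(l, d, n, t, d_prime))
  ons <- 1L
  t_min <- predicted_time_hep(1, l, d, n, t, d_prime)
  for (q in seq.int(mns, t)) {
    tq <- predicted_time_hep(q, l, d, n, t, d_prime)
    if (tq < t_min) {
      t_min <- tq
      ons <- as.integer(q)
    }
  }
  ons
}

#' Full analytic plan for a problem instance
#'
#' Bundles the probabilities, the estimated d', the predicted cost curves
#' and the two subset sizes into one object.
#'
#' @inheritParams predicted_time_hep
#' @return An object of class `QPlan`: a list with `l`, `d`, `n`, `t`,
#'   `p_d`, `p_2d`, `d_prime`, `dprime_threshold`, `mns`, `ons`,
#'   `T_exact_full` (exact-stage cost at `q = t`) and `T_hep` (cost curve
#'   over `q = 1..t`).
#' @export
q_plan <- function(l, d, n, t, dprime_threshold = 0.9, d_prime = NULL) {
  stopifnot(l >= 1, d >= 0, d <= l, n >= l, t >= 1)
  d_prime <- resolve_dprime(l, d, n, t, d_prime, dprime_threshold)
  curve <- vapply(seq_len(t), function(q)
    predicted_time_hep(q, l, d, n, t, d_prime), numeric(1))
  structure(list(
    l = l, d = d, n = n, t = t,
    p_d = match_prob(l, d),
    p_2d = match_prob(l, min(2 * d, l)),
    d_prime = d_prime,
    dprime_threshold = dprime_threshold,
    mns = suppressWarnings(compute_mns(l, d, n, t, d_prime)),
    ons = compute_ons(l, d, n, t, d_prime),
    T_exact_full = predicted_time_exact(t, l, d, n, t, d_prime),
    T_hep = curve
  ), class = "QPlan")
}

#' @export
print.QPlan <- function(x, ...) {
  cat(sprintf("QPlan (l=%d, d=%d, n=%d, t=%d)\n", x$l, x$d, x$n, x$t))
  cat(sprintf("  p_d = %.3g, p_2d = %.3g, d' = %d\n", x$p_d, x$p_2d, x$d_prime))
  cat(sprintf("  mns = %d, ons = %d\n", x$mns, x$ons))
  cat(sprintf("  predicted cost: exact on all t = %.3g ops, hybrid at ons = %.3g ops\n",
              x$T_exact_full, x$T_hep[x$ons]))
  invisible(x)
}

#' Default location of the q lookup cache
#' @return A file path under the user cache directory.
#' @export
qplan_cache_path <- function() {
  file.path(tools::R_user_dir("hepmotif", "cache"), "qplan-cache.json")
}

#' Cached lookup of the optimal subset size
#'
#' Returns the cached `ons` for a previously seen `(l, d, n, t, threshold)`
#' tuple, computing (and caching) it on a miss. The cache is a plain JSON
#' file and is purely an optimization: deleting it, or any failure to read
#' or write it, never changes results.
#'
#' @inheritParams predicted_time_hep
#' @param cache_path cache file; default [qplan_cache_path()].
#' @return Integer `ons`, identical to [compute_ons()].
#' @export
q_lookup <- function(l, d, n, t, dprime_threshold = 0.9,
                     cache_path = qplan_cache_path()) {
  key <- sprintf("l=%d,d=%d,n=%d,t=%d,thr=%g", l, d, n, t, dprime_threshold)
  cache <- list()
  if (!is.null(cache_path) && file.exists(cache_path)) {
    cache <- tryCatch(jsonlite::read_json(cache_path, simplifyVector = TRUE),
                      error = function(e) {
                        warning("corrupt q-plan cache at '", cache_path,
                                "'; recomputing")
                        list()
                      })
    if (!is.list(cache)) cache <- list()
    if (!is.null(cache[[key]])) return(as.integer(cache[[key]]))
  }
  ons <- compute_ons(l, d, n, t, dprime_threshold = dprime_threshold)
  if (!is.null(cache_path)) {
    tryCatch({
      dir.create(dirname(cache_path), recursive = TRUE, showWarnings = FALSE)
      cache[[key]] <- ons
      jsonlite::write_json(cache, cache_path, auto_unbox = TRUE)
    }, error = function(e) invisible(NULL))
  }
  ons
}
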