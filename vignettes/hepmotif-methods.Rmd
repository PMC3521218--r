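---
title: "Methods: the hybrid exact planted (l,d) motif search"
author: "hepmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hybrid exact planted (l,d) motif search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepmotif)
```

## The model

An (l,d) motif of a sequence set S = {s_1, ..., s_t} is an l-length
string x — not necessarily occurring verbatim anywhere — whose distance
to the set, d̄_H(x, S) = max_i min over windows w of s_i of d_H(x, w),
is at most d. The planted benchmark generates instances where such a
motif exists by construction: a hidden l-mer M is mutated and inserted
once per sequence.

Two facts drive everything in this package.

*Every motif is anchored in the first sequence.* If d̄_H(x, S) ≤ d
then in particular some window y of s_1 has d_H(x, y) ≤ d, i.e. x lies
in the d-mismatch ball B_d(y). The union of the balls of s_1's windows
is therefore a complete candidate space, for any subset of sequences
used to filter it. This also means that a seemingly stronger motif
definition which additionally requires membership in some B_d(y) of
s_1 is equivalent to the plain distance condition; the package
implements the single common definition.

*Chance motifs are predictable.* For i.i.d. uniform sequences over 4
letters, two random l-mers match within d with probability
p_d = Σ_{i=0}^{d} C(l,i)(3/4)^i(1/4)^{l-i}. Treating windows as
independent — an approximation that ignores window overlap — a random
l-mer has a window within d in one length-n sequence with probability
1 − (1 − p_d)^{n−l+1}, and in all q sequences with that probability to
the q-th power. The expected number of l-mers surviving q sequences is

E(l, d, q, n) = 4^l (1 − (1 − p_d)^{n−l+1})^q,

exactly 4^l at q = 0 and geometrically decreasing in q. The test suite
checks this against brute-force simulation at (l=5, d=1, n=30): the
approximation's bias is well inside Monte-Carlo noise at 200
replicates, which is the regime the planner needs — it only has to
rank subset sizes, not predict counts to high accuracy.

## The cost model and the choice of q

The exact candidate-generation stage is modeled with a per-sequence
operation count

(n − l + 1)^2 · (l + p_2d · Σ_{i=1}^{2d−d′+1} C(l,i) 3^i),

where p_2d is the match probability at distance min(2d, l) and d′ is
the distance a random l-mer typically keeps from the set (below).
Validation of the expected E(l, d, q, n) candidates against the
remaining t − q sequences costs l (t − q)(n − l + 1) E(l, d, q, n).
The total predicted cost T(q) is the sum; its endpoints are sanity
anchors: q = 0 gives the brute-force count l·t·(n−l+1)·4^l, and q = t
the exact stage on everything. All costs are abstract operation
counts, never seconds; the package makes no wall-clock claims.

**The d′ estimate.** The exact stage's effective work depends on how
far random l-mers sit from the set. We take d′ as the largest integer
in [0, 2d] such that P(d̄_H(x, S) ≥ d′) = 1 − (1 − (1 −
p_{d′−1})^{n−l+1})^t is at least a threshold θ, default θ = 0.9 —
"close to 1" while still informative. The planner is deliberately
insensitive to θ: d′ enters the subset-size bound only inside a
logarithm, and any θ in roughly (0.83, 0.97] yields identical plans
across the standard t = 20, n = 600 challenge instances. The threshold
is exposed (`dprime_threshold`) for users who want to probe that
sensitivity.

**mns.** Requiring the hybrid cost to beat the exact stage on all t
sequences and solving for q gives the bound

q > [log((n−l+1)(l + p_2d Σ C(l,i)3^i)) − log(l·4^l)] /
    log(1 − (1−p_d)^{n−l+1}).

`compute_mns()` returns the ceiling of this bound plus one, clamped to
[1, t] — a deliberately conservative rounding: the bound sits on the
flat shoulder of the cost curve, where one extra subset sequence costs
little but guards against the independence approximation
underestimating the candidate load. When the bound exceeds t the
hybrid is not predicted to help; the value clamps to t with a warning.

**ons.** `compute_ons()` scans the cost curve: initialize at q = 1,
test q = mns..t, update only on strict improvement, so the smallest
minimizing q wins ties. The test suite verifies against an independent
full-scan argmin. A JSON lookup cache (`q_lookup()`) memoizes plans;
it is purely an optimization and every failure mode (missing, deleted,
corrupt) silently recomputes.

## The search engines

Candidates are generated by enumerating B_d(y) for each window y of
s_1 and keeping l-mers within d of every subset sequence. l-mers are
2-bit codes (A=0, C=1, G=2, T=3, leftmost most significant), so a
mismatch count is an XOR, a bit-fold and a popcount, and ascending
code order is lexicographic order — output everywhere is sorted and
bit-reproducible. Ball enumeration chooses mismatch positions strictly
left-to-right with non-identity substitutions, so each member is
produced exactly once per ball with no set-membership pass.

Two engines satisfy the same output contract and are cross-checked
against each other and the brute-force oracle:

- `pruned` (default): a presence bitmap over the 4^l code space
  records every l-mer already tested, so work is linear in the number
  of *distinct* candidates; sequences are scanned in input order and a
  candidate is abandoned at the first sequence with no window within d
  (failures are cheap because the max-over-min structure fails early).
- `reference`: materializes each ball independently and re-tests
  duplicates, deduplicating output only — slower but structurally
  simpler, kept as the falsification baseline.

Deduplication uses the flat bitmap while 4^l fits a memory budget
(default cutoff l ≤ 14, i.e. 32 MiB of bits; configurable via
`bitmap_max_l`) and a hash set beyond it. `l` is capped at 26 so codes
stay exact in doubles at the R boundary.

`brute_force_motifs()` enumerates all 4^l candidates and is guarded to
l ≤ 14 by default; it exists so users can falsify the main engine, and
it backs the CLI `oracle` subcommand.

## Parallel execution

The first sequence's n−l+1 window start indices are split into p
contiguous blocks whose sizes differ by at most one
(`partition_lmers()`). Each lane runs the exact stage on its block
with no shared mutable state; lane lists are merged in lane-index
order, discarding already-seen elements (lookup table for small l,
hash index otherwise), and validation work is distributed as
contiguous blocks of the sorted candidate list. Because every step is
deterministic and merge order is fixed, the motif set — and the
report bytes — are identical for every worker count; the suite checks
workers ∈ {1, 2, 4, 8} on a benchmark-scale instance. Lanes map to
forked processes where available and degrade to sequential execution
elsewhere, which changes nothing but elapsed time.

## The instance generator

`generate_planted_instance()` draws an l-mer M uniformly, then per
sequence: an i.i.d. uniform background of length n − l, an
independently mutated copy of M, and a uniform insertion point in
{0..n−l}. Two mutation modes ship because "at most d mutations" is
genuinely ambiguous as a benchmark protocol: `exact_d` (default)
substitutes exactly d distinct positions — the hardest, standard
setting for (l,d) benchmarks — and `uniform_0_to_d` first draws the
substitution count uniformly from {0..d}. The mode is recorded in the
ground truth. Sub-seeds are derived per sequence from the global seed
by a fixed affine map, so growing t extends an instance without
reshuffling earlier sequences.

What the generator does *not* emulate: real promoters are not i.i.d.
uniform (GC skew, repeats, CpG structure), motifs occur zero or
multiple times per sequence, and instances can contain decoy signals.
Passing the recovery suite therefore demonstrates exactness under the
benchmark's statistical model, not biological sensitivity; on real
data the search is still exact for the stated definition, but the
count of chance motifs will deviate from E(l, d, q, n).

## Numerical and degenerate-case choices

- p_d terms are evaluated in log space (`lchoose` + log powers);
  naive products underflow around l ≈ 25. Survival-type expressions
  use `expm1`/`log1p` guards.
- `compute_mns()` refuses p_d ∈ {0, 1} ("model undefined"): the bound's
  denominator degenerates. d = l makes every l-mer a motif and is legal
  everywhere else.
- Ties in the ons scan keep the smaller q (strict-improvement update).
- Sequences of unequal length are searched correctly (each sequence
  uses its own window count); the planner, whose model assumes equal
  n, uses the rounded mean length when `q = "auto"`.
- The alphabet is strictly {A,C,G,T}; ambiguity codes are rejected
  with the record and position named, rather than silently skipped,
  because the probability model is 4-letter.
- All reported positions are 0-based window starts, half-open
  [p, p + l), consistent with the integer k-mer indexing.

## Validation scales

The suite validates exactness (set-equality with the 4^l oracle and
q-invariance) on 50 random instances with t ∈ 3..8, n ∈ 25..60,
l ∈ 5..8, d ∈ 0..2; end-to-end planted-motif recovery on ten (11,3)
and three (13,4) instances at the benchmark shape t = 20, n = 600;
parallel determinism on a benchmark-scale (11,3) instance; and the
expected-count model on 200 simulated (5,1) instances. These sizes
exercise every code path — both dedup strategies, both engines, auto
and explicit q — while keeping a full run in a few CPU-minutes.
Instances near the statistical limit with long motifs, such as (19,7)
or (21,8) at t = 20, are out of reach of a single desk CPU for the
search itself; for those the package computes the analytic plan only.

## Known limitations

- The cost model ranks subset sizes; it does not predict wall-clock
  time, and no calibration to seconds is attempted.
- Only the i.i.d. uniform 4-letter background is modeled; no Markov
  or composition-matched backgrounds.
- One planted occurrence per sequence is assumed by the generator
  (the search itself does not care).
- No motif scoring, ranking or degenerate-consensus reporting; the
  output is the exact motif set with distances and positions.
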