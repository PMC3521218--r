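# hepmotif

Exact discovery of planted (l,d) DNA motifs by a hybrid two-stage search,
with an analytic planner that decides how much of the input the expensive
exact stage should see.

## The problem

Transcription-factor binding sites are short, degenerate signals. The
planted (l,d) motif problem formalizes their discovery: given t DNA
sequences s_1..s_t over {A,C,G,T}, find every l-length string x such that
each sequence contains at least one l-length window within Hamming
distance d of x. Writing d̄_H(x, s) for the minimum Hamming distance
between x and any window of s, the motifs are

    { x : d̄_H(x, S) = max_i d̄_H(x, s_i) ≤ d }.

Exhaustive search over all 4^l candidates is exact but hopeless for long
motifs; neighborhood search engines (which explore the d-mismatch balls
B_d(y) of the first sequence's l-mers, |B_d(y)| = v(l,d) = Σ_{i≤d}
C(l,i)·3^i) are exact and much faster, but their cost still grows with
the number of sequences they must check against.

## The method

`hepmotif` splits the work:

1. **Plan.** For two random l-mers, P(d_H ≤ d) = p_d = Σ_{i≤d}
   C(l,i)(3/4)^i(1/4)^{l-i}, so a random l-mer survives q random
   sequences of length n with probability (1-(1-p_d)^{n-l+1})^q and the
   expected number of chance motifs is E(l,d,q,n) =
   4^l(1-(1-p_d)^{n-l+1})^q — geometrically decreasing in q. Balancing
   the exact stage's per-sequence cost against the pattern-matching cost
   l(t-q)(n-l+1)E(l,d,q,n) of checking leftover candidates yields a
   predicted total-cost curve over q; `compute_mns()` gives the smallest
   subset size predicted to beat running the exact stage on everything,
   and `compute_ons()` scans the curve for the optimum.
2. **Generate.** The exact stage (`candidate_search()`) enumerates the
   d-mismatch balls of the first sequence's l-mers (2-bit integer codes,
   XOR + popcount mismatch counting, presence-bitmap deduplication) and
   keeps the l-mers within distance d of all q subset sequences.
3. **Validate.** Each candidate is checked against the remaining t−q
   sequences by approximate pattern matching, abandoning it at the first
   failing sequence (`validate_candidates()`).

The output is provably independent of q — every true motif is within d
of some window of s_1, hence inside the candidate set for any q — and
equals the brute-force reference `brute_force_motifs()`, which the test
suite verifies on dozens of random instances. A lane-parallel mode
partitions s_1's l-mers across workers and merges duplicate-free
candidate lists deterministically; results are byte-identical for every
worker count.

## Worked example

```r
library(hepmotif)

q_plan(11, 3, n = 600, t = 20)
#> QPlan (l=11, d=3, n=600, t=20)
#>   p_d = 0.00119, p_2d = 0.115, d' = 4
#>   mns = 9, ons = 10
#>   predicted cost: exact on all t = 4.05e+09 ops, hybrid at ons = 2.32e+09 ops

inst <- generate_planted_instance(t = 20, n = 600, l = 11, d = 3, seed = 7)
inst$motif
#> [1] "TCCCTGGATAG"

res <- hep_search(inst$sequences, l = 11, d = 3, q = "auto")
res
#> MotifResult (l=11, d=3): 4 motif(s)
#>   q used = 10, candidates = 4614, validated = 4, engine = pruned, workers = 1
#>   AAGATATAGTT  (max distance 3)
#>   CACTTCCTAGA  (max distance 3)
#>   CCACTTTAACC  (max distance 3)
#>   TCCCTGGATAG  (max distance 3)
```

The plan says: below q = 9 subset sequences the candidate set is
expected to be too large for validation to pay off; the cost optimum is
q = 10. The search then processed 10 sequences exactly, found 4614
candidates, and validation against the other 10 sequences left 4 true
(11,3) motifs — the planted one plus three chance motifs, which is
normal at this instance's statistical difficulty. Every reported motif
has `max_distance` ≤ d by construction; positions of best-matching
windows (0-based) are in `res$positions` and in the TSV/JSON reports
written by `write_motif_report()`.

A command-line interface wrapping the same functions ships in
`inst/cli/hepmotif.R` with subcommands `plant`, `qplan`, `find` and
`oracle`.

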