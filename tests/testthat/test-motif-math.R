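test_that("hamming distance matches position-wise comparison", {
  expect_equal(hamming_distance("ACGT", "ACGT"), 0L)
  expect_equal(hamming_distance("AAA", "TTT"), 3L)
  expect_equal(hamming_distance("ACGT", "AGGA"), 2L)
  expect_error(hamming_distance("ACG", "ACGT"), "length mismatch")
  set.seed(101)
  for (i in 1:20) {
    l <- sample(3:12, 1)
    x <- random_dna(l); y <- random_dna(l)
    expect_equal(hamming_distance(x, y), r_hamming(x, y))
    expect_equal(hamming_distance(x, y), hamming_distance(y, x))
  }
})

test_that("min and set distance agree with window-scan oracles", {
  expect_equal(min_distance("ACG", "TTACGTT"), 0L)
  expect_equal(min_distance("AAA", "TTTT"), 3L)
  expect_equal(min_distance("ACGT", "ACTTACAT"), 1L)
  expect_error(min_distance("ACGT", "ACG"), "shorter")
  set.seed(102)
  for (i in 1:15) {
    l <- sample(3:6, 1)
    x <- random_dna(l)
    seqs <- random_sequences(sample(1:4, 1), sample(10:25, 1))
    expect_equal(min_distance(x, seqs[1]), r_min_distance(x, seqs[1]))
    expect_equal(set_distance(x, seqs), r_set_distance(x, seqs))
  }
  # single-sequence degenerate case and zero-distance iff substring
  x <- "ACGT"
  s <- "GGACGTGG"
  expect_equal(set_distance(x, s), min_distance(x, s))
  expect_identical(min_distance(x, s) == 0L, grepl(x, s, fixed = TRUE))
  expect_identical(min_distance("ACGA", s) == 0L, grepl("ACGA", s, fixed = TRUE))
})

test_that("neighborhoods are exact Hamming balls of the predicted size", {
  expect_equal(neighborhood("ACGT", 0), "ACGT")
  expect_length(neighborhood("AAA", 1), 10)
  nb <- neighborhood("ACGT", 2)
  expect_length(nb, 67)  # 1 + 12 + 54, verified by full enumeration below
  all4 <- r_all_lmers(4)
  expect_setequal(nb, all4[vapply(all4, r_hamming, integer(1), y = "ACGT") <= 2])
  expect_false(any(duplicated(nb)))
  expect_equal(nb, sort(nb))
  expect_error(neighborhood("ACGT", 5), "d must be")

  # |B_d(x)| = v(l,d) across parameter grid
  set.seed(103)
  for (l in 3:7) for (d in 0:min(l, 3)) {
    x <- random_dna(l)
    expect_length(neighborhood(x, d), neighborhood_size(l, d))
  }
})

test_that("ball membership is symmetric", {
  set.seed(104)
  for (i in 1:25) {
    l <- sample(3:6, 1); d <- sample(0:2, 1)
    x <- random_dna(l); y <- random_dna(l)
    expect_equal(y %in% neighborhood(x, d), x %in% neighborhood(y, d))
  }
})

test_that("neighborhood_size follows the closed form", {
  expect_equal(neighborhood_size(7, 0), 1)
  expect_equal(neighborhood_size(3, 1), 10)
  for (l in c(3, 5, 9)) expect_equal(neighborhood_size(l, l), 4^l)
  expect_error(neighborhood_size(4, 5), "d must be")
})

test_that("brute force search equals the pure-R oracle and is monotone in d", {
  expect_equal(brute_force_motifs("AAAA", 4, 0), "AAAA")
  expect_length(brute_force_motifs(c("ACGTA", "TTTTT"), 3, 3), 64)
  set.seed(105)
  for (i in 1:5) {
    seqs <- random_sequences(3, 12)
    prev <- character(0)
    for (d in 0:2) {
      got <- brute_force_motifs(seqs, 4, d)
      expect_equal(got, r_brute_force(seqs, 4, d))
      expect_true(all(prev %in% got))  # monotone in d
      prev <- got
    }
  }
  expect_error(brute_force_motifs("ACGT", 4, 1, max_l = 3), "guard")
})

test_that("2-bit integer coding is a sorted bijection", {
  set.seed(106)
  for (l in c(1, 4, 9, 13)) {
    xs <- unique(vapply(1:20, function(i) random_dna(l), character(1)))
    codes <- encode_lmer(xs)
    expect_equal(decode_lmer(codes, l), xs)
    expect_equal(order(codes), order(xs))  # code order = lexicographic
  }
  expect_equal(encode_lmer(c("AAA", "ACA", "TTT")), c(0, 4, 63))
})

test_that("planted instances always contain their motif in the oracle output", {
  for (seed in 1:3) {
    inst <- generate_planted_instance(t = 5, n = 30, l = 5, d = 1, seed = seed)
    got <- brute_force_motifs(inst$sequences, 5, 1)
    expect_true(inst$motif %in% got)
  }
})
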