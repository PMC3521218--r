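test_that("planting obeys the mutation budget and position ranges", {
  inst0 <- generate_planted_instance(t = 8, n = 50, l = 6, d = 0, seed = 1)
  expect_true(all(vapply(inst0$sequences$seqs, grepl, logical(1),
                         pattern = inst0$motif, fixed = TRUE)))

  inst <- generate_planted_instance(t = 10, n = 50, l = 8, d = 2, seed = 2,
                                    mutation_mode = "exact_d")
  expect_true(all(inst$sequences$lengths == 50L))
  expect_true(all(inst$positions >= 0 & inst$positions <= 50 - 8))
  occ <- substring(inst$sequences$seqs, inst$positions + 1, inst$positions + 8)
  dists <- vapply(occ, r_hamming, integer(1), y = inst$motif)
  expect_true(all(dists == 2L))  # exact_d plants at exactly d mismatches
  expect_lte(set_distance(inst$motif, inst$sequences), 2L)

  instu <- generate_planted_instance(t = 30, n = 40, l = 8, d = 3, seed = 3,
                                     mutation_mode = "uniform_0_to_d")
  occu <- substring(instu$sequences$seqs, instu$positions + 1, instu$positions + 8)
  du <- vapply(occu, r_hamming, integer(1), y = instu$motif)
  expect_true(all(du <= 3L))
  expect_equal(unname(du), instu$mutation_counts)
  expect_gt(length(unique(du)), 1L)  # the mutation count actually varies
})

test_that("instances are reproducible and prefix-stable in t", {
  a <- generate_planted_instance(t = 6, n = 40, l = 6, d = 1, seed = 42)
  b <- generate_planted_instance(t = 6, n = 40, l = 6, d = 1, seed = 42)
  expect_identical(a, b)
  c <- generate_planted_instance(t = 6, n = 40, l = 6, d = 1, seed = 43)
  expect_false(identical(a$sequences$seqs, c$sequences$seqs))
  # growing t extends the instance without reshuffling earlier sequences
  big <- generate_planted_instance(t = 9, n = 40, l = 6, d = 1, seed = 42)
  expect_identical(big$sequences$seqs[1:6], a$sequences$seqs)
  expect_identical(big$motif, a$motif)
})

test_that("background composition is approximately uniform", {
  inst <- generate_planted_instance(t = 30, n = 300, l = 11, d = 3, seed = 5)
  # strip the planted windows, then tabulate the remaining background
  bg <- vapply(seq_len(30), function(i) {
    s <- inst$sequences$seqs[i]; p <- inst$positions[i]
    paste0(substr(s, 1, p), substr(s, p + 12, 300))
  }, character(1))
  counts <- table(factor(strsplit(paste(bg, collapse = ""), "")[[1]],
                         levels = c("A", "C", "G", "T")))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 1e-6)
})

test_that("instances round-trip through FASTA + ground-truth JSON", {
  inst <- generate_planted_instance(t = 5, n = 40, l = 7, d = 1, seed = 8)
  fa <- withr::local_tempfile(fileext = ".fa")
  tr <- withr::local_tempfile(fileext = ".json")
  write_instance(inst, fa, tr)
  S2 <- read_fasta(fa)
  expect_equal(S2$seqs, inst$sequences$seqs)
  expect_equal(S2$ids, inst$sequences$ids)
  truth <- read_truth(tr)
  expect_equal(truth$motif, inst$motif)
  expect_equal(truth$positions, inst$positions)
  expect_equal(truth$mutation_counts, inst$mutation_counts)
  expect_equal(truth$params$mutation_mode, "exact_d")
  expect_equal(truth$seed, inst$seed)
})

test_that("the planted motif is always recovered end to end", {
  for (seed in 1:4) {
    inst <- generate_planted_instance(t = 7, n = 60, l = 7, d = 1, seed = seed)
    res <- hep_search(inst$sequences, 7, 1, q = "auto")
    expect_true(inst$motif %in% res$motifs)
  }
})
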