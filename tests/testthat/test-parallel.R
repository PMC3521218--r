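test_that("l-mer partitioning is contiguous, disjoint, balanced and covering", {
  p <- partition_lmers(10L, p = 2)
  expect_equal(p$size, c(5L, 5L))
  p <- partition_lmers(10L, p = 3)
  expect_equal(p$size, c(4L, 3L, 3L))
  p <- partition_lmers(10L, p = 1)
  expect_equal(p$from, 0L); expect_equal(p$to, 10L)
  # lanes beyond the window count get empty ranges
  p <- partition_lmers(3L, p = 5)
  expect_equal(p$size, c(1L, 1L, 1L, 0L, 0L))
  # from a sequence: n - l + 1 windows
  p <- partition_lmers("ACGTACGT", l = 4, p = 2)
  expect_equal(sum(p$size), 5L)
  for (m in c(1L, 7L, 23L)) for (k in c(1L, 2L, 4L, 8L)) {
    pp <- partition_lmers(m, p = k)
    expect_equal(pp$from, c(0L, cumsum(pp$size))[1:k])  # contiguous
    expect_equal(sum(pp$size), m)                       # covering
    expect_lte(diff(range(pp$size)), 1L)                # balanced
  }
  expect_error(partition_lmers(10L, p = 0), "p must be")
})

test_that("candidate-list merging is an exact duplicate-free union", {
  set.seed(501)
  a <- candidate_set(4, c(0, 3, 17, 200))
  expect_equal(merge_candidate_lists(list(a, a))$codes, a$codes)  # idempotent
  b <- candidate_set(4, c(1, 5, 99))
  expect_equal(merge_candidate_lists(list(a, b))$codes,
               sort(c(a$codes, b$codes)))  # disjoint: sizes add
  for (i in 1:10) {
    xs <- lapply(1:3, function(j)
      candidate_set(5, sort(sample(0:1023, sample(5:40, 1)))))
    merged <- merge_candidate_lists(xs)
    expect_equal(merged$codes,
                 sort(unique(unlist(lapply(xs, `[[`, "codes")))))
    shuffled <- merge_candidate_lists(xs[c(3, 1, 2)])
    expect_setequal(shuffled$codes, merged$codes)  # order-free as a set
  }
  expect_error(merge_candidate_lists(list(a, candidate_set(5, 1))), "mixed l")
})

test_that("lane candidate sets lose nothing relative to the serial run", {
  set.seed(502)
  inst <- generate_planted_instance(t = 6, n = 60, l = 6, d = 1, seed = 11)
  S_q <- sequence_set(inst$sequences$seqs[1:4])
  serial <- candidate_search(S_q, 6, 1)
  lanes <- hepmotif:::lane_candidates(S_q, 6, 1, workers = 3)
  expect_identical(lanes$merged$codes, serial$codes)
  union_of_lanes <- sort(unique(unlist(lapply(lanes$per_lane, `[[`, "codes"))))
  expect_equal(union_of_lanes, serial$codes)
})

test_that("results are identical for every worker count, byte for byte", {
  inst <- generate_planted_instance(t = 8, n = 80, l = 7, d = 2, seed = 13)
  S <- inst$sequences
  reports <- lapply(c(1, 2, 4), function(w) {
    res <- hep_search(S, 7, 2, q = 4, workers = w)
    path <- tempfile(fileext = ".tsv")
    write_motif_report(res, path, "tsv")
    on.exit(unlink(path))
    list(res = res, bytes = readBin(path, "raw", file.size(path)))
  })
  for (r in reports[-1]) {
    expect_identical(r$res$motifs, reports[[1]]$res$motifs)
    expect_identical(r$res$max_distance, reports[[1]]$res$max_distance)
    expect_identical(r$res$candidate_count, reports[[1]]$res$candidate_count)
    expect_identical(r$bytes, reports[[1]]$bytes)
  }
  expect_true(inst$motif %in% reports[[1]]$res$motifs)
  # the exported wrapper takes the same path
  pw <- parallel_hep(S, 7, 2, q = 4, workers = 2)
  expect_identical(pw$motifs, reports[[1]]$res$motifs)
})
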