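# Pure-R oracles, independent of the C++ search path. Only used at tiny l.

r_hamming <- function(x, y) {
  sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
}

r_windows <- function(s, l) {
  vapply(seq_len(nchar(s) - l + 1), function(i) substr(s, i, i + l - 1),
         character(1))
}

r_min_distance <- function(x, s) {
  min(vapply(r_windows(s, nchar(x)), r_hamming, integer(1), y = x))
}

r_set_distance <- function(x, seqs) {
  max(vapply(seqs, r_min_distance, integer(1), x = x))
}

r_all_lmers <- function(l) {
  g <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), l),
                              stringsAsFactors = FALSE))
  sort(apply(g[, rev(seq_len(l)), drop = FALSE], 1, paste, collapse = ""))
}

r_brute_force <- function(seqs, l, d) {
  all_l <- r_all_lmers(l)
  all_l[vapply(all_l, r_set_distance, integer(1), seqs = seqs) <= d]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_sequences <- function(t, n) {
  vapply(seq_len(t), function(i) random_dna(n), character(1))
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
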