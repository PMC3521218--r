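#' Construct a sequence set
#'
#' A `SequenceSet` holds an ordered collection of DNA sequences over the
#' strict alphabet \{A,C,G,T\}. Sequences are uppercased on construction;
#' any other character (including IUPAC ambiguity codes such as `N`) is
#' rejected with an error naming the offending record and position, because
#' the probability model underlying the search assumes a 4-letter alphabet.
#'
#' @param seqs character vector of DNA sequences.
#' @param ids optional character vector of record ids; defaults to
#'   `seq_1 ... seq_t`.
#' @return An object of class `SequenceSet`: a list with elements `ids`,
#'   `seqs`, `t` (number of records) and `lengths`.
#' @examples
#' s <- sequence_set(c("ACGTACGT", "TTGACCA"))
#' s$t
#' @export
sequence_set <- function(seqs, ids = NULL) {
  if (length(seqs) < 1) stop("no sequences")
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq_", seq_along(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (any(!nzchar(seqs))) stop("no sequences: record ", ids[which(!nzchar(seqs))[1]], " is empty")
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("invalid alphabet: record '%s' has character '%s' at position %d",
                 ids[i], substr(seqs[i], bad[i], bad[i]), bad[i]))
  }
  structure(list(ids = as.character(ids), seqs = seqs,
                 t = length(seqs), lengths = nchar(seqs)),
            class = "SequenceSet")
}

#' @export
print.SequenceSet <- function(x, ...) {
  cat(sprintf("SequenceSet: %d sequence(s), lengths %d..%d\n",
              x$t, min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' @export
length.SequenceSet <- function(x) x$t

as_sequence_set <- function(x) {
  if (inherits(x, "SequenceSet")) return(x)
  if (is.character(x)) return(sequence_set(x))
  stop("cannot coerce object of class '", class(x)[1], "' to SequenceSet")
}

# subset of records, keeping ids
subset_sequences <- function(S, idx) {
  sequence_set(S$seqs[idx], S$ids[idx])
}

#' Read a multi-FASTA file into a SequenceSet
#'
#' Line wrapping is collapsed and sequences are uppercased. The file must
#' contain at least one record and only \{A,C,G,T\} letters (case
#' insensitive); ambiguity codes are rejected rather than skipped.
#'
#' @param path path to a FASTA file.
#' @return A [sequence_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("invalid alphabet or malformed FASTA in '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (length(dss) == 0) stop("no sequences in '", path, "'")
  sequence_set(as.character(dss), names(dss))
}

#' Write a SequenceSet to a FASTA file
#'
#' @param S a [sequence_set()] (or character vector).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(S, path, width = 70L) {
  S <- as_sequence_set(S)
  dss <- Biostrings::DNAStringSet(S$seqs)
  names(dss) <- S$ids
  Biostrings::writeXStringSet(dss, filepath = path, width = width)
  invisible(path)
}

#' Write a motif search report
#'
#' TSV columns are `motif`, `max_distance` (the motif's distance to the
#' sequence set, i.e. the maximum over sequences of the minimum window
#' distance) and one `pos_<id>` column per input sequence holding the
#' 0-based start of a best-matching window. Motifs are sorted
#' lexicographically so output is byte-stable. The JSON format mirrors the
#' table and adds run statistics.
#'
#' @param result a `MotifResult` from [hep_search()] or [brute_force_motifs()]
#'   wrapped via [hep_search()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_motif_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "MotifResult"))
  df <- as.data.frame(result)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(
      motifs = df,
      stats = list(l = result$l, d = result$d, q_used = result$q_used,
                   candidate_count = result$candidate_count,
                   validated_count = result$validated_count,
                   engine = result$engine, workers = result$workers,
                   t = length(result$seq_ids))
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Read back a motif report written by [write_motif_report()]
#'
#' @param path report path.
#' @param format `"tsv"` or `"json"`.
#' @return A list with elements `motifs` (data frame) and, for JSON, `stats`.
#' @export
read_motif_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    if (nrow(df) > 0) {
      df$max_distance <- as.integer(df$max_distance)
      for (cn in grep("^pos_", names(df), value = TRUE))
        df[[cn]] <- as.integer(df[[cn]])
    }
    list(motifs = df)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    list(motifs = as.data.frame(obj$motifs), stats = obj$stats)
  }
}
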