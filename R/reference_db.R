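# Reference sequences and k-mer presence/occurrence indices.
#
# Nullomer calling rests on two reference structures: a presence index of
# every length-k word in the coding sequences (forward strand only, since
# coding sequence is stranded), and a saturating occurrence counter over the
# genome (both strands, since transcription can originate from either).

#' Read a FASTA file into a sequence table
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] /
#' [Biostrings::readAAStringSet()] that uppercases residues and validates the
#' declared alphabet. gzip-compressed files are handled transparently.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` for nucleotide (A/C/G/T/N after uppercasing) or
#'   `"aa"` for amino-acid records.
#' @return A tibble with columns `id` (first word of each header) and
#'   `residues`, in file order.
#' @export
read_sequences <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "neonull_io_error")
  }
  set <- tryCatch(
    if (alphabet == "nt") {
      # read as BString first so we can report offending characters ourselves
      Biostrings::readBStringSet(path)
    } else {
      Biostrings::readBStringSet(path)
    },
    error = function(e) {
      abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)),
            class = "neonull_format_error")
    }
  )
  res <- toupper(as.character(set))
  ids <- stringr::str_extract(names(set), "^\\S+")
  validate_residues(res, ids, alphabet)
  tibble(id = ids, residues = unname(res))
}

validate_residues <- function(res, ids, alphabet) {
  if (any(!nzchar(res))) {
    abort(sprintf("empty sequence record: %s", ids[!nzchar(res)][1]),
          class = "neonull_format_error")
  }
  pattern <- if (alphabet == "nt") "[^ACGTN]" else "[^A-Z]"
  bad <- stringr::str_detect(res, pattern)
  if (any(bad)) {
    ch <- stringr::str_extract(res[bad][1], pattern)
    abort(sprintf("record %s contains character '%s' outside the %s alphabet",
                  ids[bad][1], ch, alphabet),
          class = "neonull_format_error")
  }
  invisible(TRUE)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translation stops at (and excludes) the first stop codon. A trailing
#' incomplete codon is ignored with a warning. Codons containing a non-ACGT
#' character translate to `X`.
#'
#' @param nt Character vector of nucleotide strings (each of length >= 3).
#' @param details If `TRUE`, return a tibble with columns `protein` and
#'   `partial` (whether a trailing incomplete codon was dropped) instead of a
#'   bare character vector.
#' @return Character vector of peptides, or a tibble when `details = TRUE`.
#' @export
#' @examples
#' translate_cds("ATGGCT")
translate_cds <- function(nt, details = FALSE) {
  stopifnot(is.character(nt))
  nt <- toupper(nt)
  if (any(nchar(nt) < 3)) {
    abort("coding sequence shorter than one codon", class = "neonull_format_error")
  }
  code <- Biostrings::GENETIC_CODE
  out <- character(length(nt))
  partial <- nchar(nt) %% 3L != 0L
  for (i in seq_along(nt)) {
    s <- nt[[i]]
    n <- nchar(s) - nchar(s) %% 3L
    codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1] - 1L)]
    out[[i]] <- paste(aa, collapse = "")
  }
  if (any(partial)) {
    warn(sprintf("%d sequence(s) had a trailing incomplete codon (ignored)",
                 sum(partial)))
  }
  if (details) tibble(protein = out, partial = partial) else out
}

#' Build a k-mer presence index
#'
#' Enumerates every length-`k` substring of the supplied nucleotide sequences
#' (forward orientation only; coding sequences are stranded). Windows
#' containing `N` are skipped: an ambiguous base cannot support exact k-mer
#' identity.
#'
#' @param seqs Sequence table (columns `id`, `residues`) or character vector.
#' @param k Word length (the coding-sequence nullomer definition uses 16).
#' @return An object of class `kmer_index` with elements `k` and `members`
#'   (sorted character vector of distinct words).
#' @export
kmer_index <- function(seqs, k = 16L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) {
    abort("k must be a positive integer", class = "neonull_config_error")
  }
  res <- toupper(seq_vector(seqs))
  words <- unlist(lapply(res, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }), use.names = FALSE)
  words <- words[!stringr::str_detect(words, "N")]
  structure(list(k = k, members = sort(unique(words))), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d distinct words\n", x$k, length(x$members)))
  invisible(x)
}

#' Query k-mer membership
#'
#' @param index A [kmer_index()].
#' @param words Character vector of words; words whose length differs from
#'   `index$k` are never members.
#' @return Logical vector.
#' @export
kmer_contains <- function(index, words) {
  stopifnot(inherits(index, "kmer_index"))
  nchar(words) == index$k & toupper(words) %in% index$members
}

#' Is a word a nullomer with respect to an index?
#'
#' A nullomer is a length-`k` word absent from the indexed collection.
#' Querying a word of the wrong length is an error (it is neither a member
#' nor a meaningful nullomer).
#'
#' @inheritParams kmer_contains
#' @return Logical vector.
#' @export
is_nullomer <- function(index, words) {
  stopifnot(inherits(index, "kmer_index"))
  if (any(nchar(words) != index$k)) {
    abort(sprintf("nullomer query requires words of length k=%d", index$k),
          class = "neonull_config_error")
  }
  !kmer_contains(index, words)
}

#' Saturating genome occurrence counter
#'
#' Counts occurrences of a word and of its reverse complement across all
#' genome records (overlapping occurrences included), saturating at
#' `cap + 1`. Used to drop nullomers that recur too often in the genome
#' (default ceiling 300 occurrences) and would invite false-positive matches
#' from non-coding transcription.
#'
#' @param genome Sequence table or character vector of genome records.
#' @param cap Occurrence ceiling; counts saturate at `cap + 1`.
#' @param k Word length the counter serves.
#' @param double_stranded Count the reverse complement too (default `TRUE`;
#'   transcription can originate from either strand).
#' @return Object of class `genome_counter`.
#' @export
genome_counter <- function(genome, cap = 300L, k = 16L, double_stranded = TRUE) {
  res <- toupper(seq_vector(genome))
  structure(
    list(subject = Biostrings::DNAStringSet(res), cap = as.integer(cap),
         k = as.integer(k), double_stranded = isTRUE(double_stranded)),
    class = "genome_counter"
  )
}

#' @export
print.genome_counter <- function(x, ...) {
  cat(sprintf("<genome_counter> k=%d, cap=%d, %d record(s), %s-stranded\n",
              x$k, x$cap, length(x$subject),
              if (x$double_stranded) "double" else "single"))
  invisible(x)
}

#' Count genome occurrences of words (saturating)
#'
#' @param counter A [genome_counter()].
#' @param words Character vector of words of length `counter$k`.
#' @return Integer vector of counts, saturated at `counter$cap + 1`.
#' @export
count_occurrences <- function(counter, words) {
  stopifnot(inherits(counter, "genome_counter"))
  if (!length(words)) return(integer())
  if (any(nchar(words) != counter$k)) {
    abort(sprintf("occurrence query requires words of length k=%d", counter$k),
          class = "neonull_config_error")
  }
  words <- toupper(words)
  vapply(words, function(w) {
    n <- sum(Biostrings::vcountPattern(w, counter$subject))
    if (counter$double_stranded) {
      n <- n + sum(Biostrings::vcountPattern(revcomp(w), counter$subject))
    }
    min(n, counter$cap + 1L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Write / read a k-mer index in the flat interchange format
#'
#' One word per line, sorted; a single comment header records `k`. This flat
#' file is the interchange contract for presence indices.
#'
#' @param index A [kmer_index()].
#' @param path Output (or input) path.
#' @return `write_kmer_index()` returns `path` invisibly; `read_kmer_index()`
#'   returns a `kmer_index`.
#' @export
write_kmer_index <- function(index, path) {
  stopifnot(inherits(index, "kmer_index"))
  writeLines(c(sprintf("# k=%d", index$k), index$members), path)
  invisible(path)
}

#' @rdname write_kmer_index
#' @export
read_kmer_index <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  k <- as.integer(stringr::str_match(header, "k=(\\d+)")[, 2])
  if (is.na(k)) {
    abort("k-mer index file lacks '# k=' header", class = "neonull_format_error")
  }
  members <- lines[-1]
  members <- members[nzchar(members)]
  if (any(nchar(members) != k)) {
    abort("k-mer index file contains words of the wrong length",
          class = "neonull_format_error")
  }
  structure(list(k = k, members = sort(unique(members))), class = "kmer_index")
}
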