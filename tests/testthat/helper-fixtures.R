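# Shared toy fixtures, built once per test run. All deterministic under
# fixed seeds; scale chosen so the whole build stays in the tens of
# seconds.

toy <- local({
  ref <- make_toy_reference(seed = 7, n_genes = 6, cds_len = 300)
  ep <- plant_epitope_db(ref, n_records = 10, n_subs = 1, seed = 7,
                         n_negative = 1)
  idx <- neonull:::reference_indices(ep$ref)
  mapping <- build_epitope_mapping(ep$records, ep$ref$ccds,
                                   idx$presence, idx$counter)
  fu <- plant_fusion_db(ep$ref, n_fusions = 3, seed = 7)
  fusion_mapping <- build_fusion_mapping(fu$junctions, ep$ref$genome,
                                         idx$presence, idx$counter,
                                         cds_anno = fu$cds_anno,
                                         proteome = ep$ref$proteome)
  list(ref = ep$ref, ep = ep, idx = idx, mapping = mapping,
       fu = fu, fusion_mapping = fusion_mapping,
       ccds_targets = stats::setNames(ep$ref$ccds$nt,
                                      ep$ref$ccds$transcript_id))
})

# Independent naive enumeration of all k-mers of a set of sequences
# (forward strand, N windows skipped) -- the oracle for the presence index.
naive_kmer_set <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (!grepl("N", w, fixed = TRUE)) out <- c(out, w)
    }
  }
  sort(unique(out))
}

# Independent position-by-position occurrence count of `word` (and its
# reverse complement) over sequences, overlapping occurrences included.
naive_occurrences <- function(word, seqs, double_stranded = TRUE) {
  count_one <- function(w, s) {
    n <- 0L
    if (nchar(s) < nchar(w)) return(0L)
    for (i in seq_len(nchar(s) - nchar(w) + 1)) {
      if (substr(s, i, i + nchar(w) - 1) == w) n <- n + 1L
    }
    n
  }
  total <- sum(vapply(seqs, count_one, integer(1), w = word))
  if (double_stranded) {
    rc <- revcomp(word)
    total <- total + sum(vapply(seqs, count_one, integer(1), w = rc))
  }
  total
}

# Naive per-window scan of read pairs: every k-window of mate 1 compared
# against the patterns, every k-window of mate 2 against their reverse
# complements. Independent of the dictionary-based implementation.
naive_scan <- function(pairs, patterns) {
  k <- nchar(patterns[1])
  rc <- revcomp(patterns)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    for (m in 1:2) {
      s <- if (m == 1) pairs$seq1[i] else pairs$seq2[i]
      if (nchar(s) < k) next
      for (off in seq_len(nchar(s) - k + 1)) {
        w <- substr(s, off, off + k - 1)
        hit <- if (m == 1) match(w, patterns) else match(w, rc)
        if (!is.na(hit)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            read_id = pairs$read_id[i], mate = m,
            nullomer = patterns[hit], offset = off - 1L)
        }
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(read_id = character(), mate = integer(),
                   nullomer = character(), offset = integer())
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_temp_fasta <- function(seqs, ids = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}

sort_hits <- function(h) {
  dplyr::arrange(h, read_id, mate, nullomer, offset)
}
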