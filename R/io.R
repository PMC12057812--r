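# Paired FASTQ and SAM interfaces.

#' Read paired FASTQ files into a read-pair tibble
#'
#' gzip-compressed files are handled transparently. Mate records are paired
#' positionally; read ids are taken from mate 1 with any `/1`, `/2` or
#' trailing mate comment stripped.
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @return Tibble with `read_id`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE)
    tibble(id = stringr::str_extract(names(x), "^\\S+"),
           seq = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities))
  }
  r1 <- rd(path1); r2 <- rd(path2)
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf("mate count mismatch: %d reads in %s vs %d in %s",
                  nrow(r1), path1, nrow(r2), path2),
          class = "neonull_format_error")
  }
  if (!nrow(r1)) {
    return(tibble(read_id = character(), seq1 = character(),
                  seq2 = character(), qual1 = character(),
                  qual2 = character()))
  }
  tibble(read_id = sub("/[12]$", "", r1$id),
         seq1 = toupper(r1$seq), seq2 = toupper(r2$seq),
         qual1 = r1$qual, qual2 = r2$qual)
}

#' Write a read-pair tibble as two FASTQ files
#'
#' @param pairs Read-pair tibble.
#' @param path1,path2 Output FASTQ paths.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  fmt <- function(ids, seqs, quals, mate) {
    if (!length(ids)) return(character())
    as.vector(rbind(paste0("@", ids, "/", mate), seqs, "+", quals))
  }
  writeLines(fmt(pairs$read_id, pairs$seq1, pairs$qual1, 1L), path1)
  writeLines(fmt(pairs$read_id, pairs$seq2, pairs$qual2, 2L), path2)
  invisible(c(path1, path2))
}

#' Read alignment records from a SAM file
#'
#' Parses a SAM file (converted through `Rsamtools`) into the
#' alignment-record tibble used by the detection filters: soft-clips from
#' the CIGAR, aligned (reference-consuming) length, MAPQ, and the `AS` tag.
#' Mate assignment comes from the FLAG first/last-segment bits.
#'
#' @param path Path to a SAM file.
#' @return Alignment-record tibble compatible with [deduplicate()] and the
#'   filter functions.
#' @export
read_sam_records <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "AS")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (!n) {
    return(tibble(read_id = character(), mate = integer(),
                  target_id = character(), target_start = integer(),
                  target_end = integer(), aligned_length = integer(),
                  alignment_score = double(), mapq = integer(),
                  softclip_left = integer(), softclip_right = integer(),
                  read_length = integer(), qual_sum = integer(),
                  fragment_key = character()))
  }
  cig <- x$cigar
  scl <- as.integer(stringr::str_match(cig, "^(\\d+)S")[, 2])
  scr <- as.integer(stringr::str_match(cig, "(\\d+)S$")[, 2])
  scl[is.na(scl)] <- 0L; scr[is.na(scr)] <- 0L
  ref_len <- vapply(cig, function(c) {
    ops <- stringr::str_match_all(c, "(\\d+)([MIDNSHP=X])")[[1]]
    sum(as.integer(ops[, 2])[ops[, 3] %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  mate <- dplyr::if_else(bitwAnd(x$flag, 64L) > 0L, 1L, 2L)
  recs <- tibble(
    read_id = x$qname,
    mate = mate,
    target_id = as.character(x$rname),
    target_start = x$pos - 1L,
    target_end = x$pos - 1L + ref_len,
    aligned_length = ref_len,
    alignment_score = as.double(x$tag$AS %||% rep(NA_real_, n)),
    mapq = as.integer(x$mapq),
    softclip_left = scl,
    softclip_right = scr,
    read_length = nchar(as.character(x$seq)),
    qual_sum = phred_sum(as.character(x$qual))
  )
  recs %>%
    group_by(.data$read_id) %>%
    mutate(fragment_key = sprintf("%s:%d-%d:FR",
                                  .data$target_id[.data$mate == 1][1],
                                  min(.data$target_start),
                                  max(.data$target_end))) %>%
    ungroup()
}

#' Write alignment records as a minimal SAM file
#'
#' Emits one line per record with CIGAR `xS yM zS`, the `AS` tag, and
#' first/last-segment FLAG bits; mate 2 carries the reverse FLAG bit since
#' records store its aligned (reverse-complemented) orientation. Intended
#' for interoperability tests and pipelines that feed an external aligner's
#' output back in.
#'
#' @param records Alignment-record tibble.
#' @param pairs The read pairs the records came from (for SEQ/QUAL).
#' @param targets Sequence table or named character vector of targets (for
#'   header lengths).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sam <- function(records, pairs, targets, path) {
  tv <- seq_vector(targets)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(tv), nchar(tv)))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    pr <- pairs[pairs$read_id == r$read_id, , drop = FALSE]
    seq <- if (r$mate == 1L) pr$seq1 else revcomp(pr$seq2)
    qual <- if (r$mate == 1L) pr$qual1 else
      paste(rev(strsplit(pr$qual2, "")[[1]]), collapse = "")
    flag <- 1L + if (r$mate == 1L) 64L else 128L + 16L
    cigar <- paste0(
      if (r$softclip_left > 0) paste0(r$softclip_left, "S") else "",
      r$aligned_length, "M",
      if (r$softclip_right > 0) paste0(r$softclip_right, "S") else "")
    paste(r$read_id, flag, r$target_id, r$target_start + 1L, r$mapq, cigar,
          "*", 0L, 0L, seq, qual, sprintf("AS:i:%d", round(r$alignment_score)),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
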