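# Fused junction sequences, junction-spanning nullomers, and junction
# neoepitopes.
#
# For each curated fusion, a junction-centred target sequence is built from
# the genome (default 500 nt from each partner, in transcript orientation),
# the k-mer windows straddling the junction are tested for nullomer status,
# and -- when both breakpoints fall inside annotated coding sequence, the 5'
# junction is past the start codon, and the 3' gene stays in frame -- the
# 9-aa peptides spanning the junction that are absent from the reference
# proteome are reported as putative junction neoepitopes.

#' Build a fused junction-centred sequence
#'
#' Takes the last `flank` transcribed nucleotides of the 5' partner (ending
#' at its breakpoint) and the first `flank` of the 3' partner (starting at
#' its breakpoint), each reverse-complemented when the partner lies on the
#' minus strand, and joins them at the junction. Flanks are truncated at
#' chromosome ends; `junction_offset` records the actual 5' contribution.
#'
#' Breakpoint convention: `pos5` is the last transcribed base of the 5'
#' partner and `pos3` the first of the 3' partner, 1-based genomic
#' coordinates as in curated fusion tables.
#'
#' @param genome Sequence table (columns `id`, `residues`) or named character
#'   vector of chromosomes.
#' @param junction One-row data frame (or list) with `fusion_id`, `chrom5`,
#'   `pos5`, `strand5`, `chrom3`, `pos3`, `strand3`.
#' @param flank Nucleotides requested from each partner (default 500).
#' @return A list of class `fused_sequence`: `nt`, `junction_offset`,
#'   `flank_requested`, `fusion_id`.
#' @export
build_fused_sequence <- function(genome, junction, flank = 500L) {
  g <- seq_vector(genome)
  jx <- as.list(junction)
  flank <- as.integer(flank)
  get_chrom <- function(chrom) {
    if (!chrom %in% names(g)) {
      abort(sprintf("fusion %s: chromosome %s not in genome",
                    jx$fusion_id %||% "?", chrom),
            class = "neonull_record_error")
    }
    g[[chrom]]
  }
  slice5 <- function(chrom, pos, strand) {
    s <- get_chrom(chrom); L <- nchar(s)
    if (pos < 1 || pos > L) {
      abort(sprintf("fusion %s: breakpoint %s:%d outside chromosome",
                    jx$fusion_id %||% "?", chrom, pos),
            class = "neonull_record_error")
    }
    if (strand == "+") {
      substr(s, max(1L, pos - flank + 1L), pos)
    } else {
      revcomp(substr(s, pos, min(L, pos + flank - 1L)))
    }
  }
  slice3 <- function(chrom, pos, strand) {
    s <- get_chrom(chrom); L <- nchar(s)
    if (pos < 1 || pos > L) {
      abort(sprintf("fusion %s: breakpoint %s:%d outside chromosome",
                    jx$fusion_id %||% "?", chrom, pos),
            class = "neonull_record_error")
    }
    if (strand == "+") {
      substr(s, pos, min(L, pos + flank - 1L))
    } else {
      revcomp(substr(s, max(1L, pos - flank + 1L), pos))
    }
  }
  up <- slice5(jx$chrom5, as.integer(jx$pos5), jx$strand5)
  down <- slice3(jx$chrom3, as.integer(jx$pos3), jx$strand3)
  structure(list(nt = paste0(up, down), junction_offset = nchar(up),
                 flank_requested = flank,
                 fusion_id = jx$fusion_id %||% NA_character_),
            class = "fused_sequence")
}

#' @export
print.fused_sequence <- function(x, ...) {
  cat(sprintf("<fused_sequence> %s: %d nt, junction at %d\n",
              x$fusion_id, nchar(x$nt), x$junction_offset))
  invisible(x)
}

#' Junction-spanning nullomers of a fused sequence
#'
#' Tests every length-`k` window with at least one base on each side of the
#' junction (at most k-1 candidates) for absence from the coding-sequence
#' index and a genome occurrence count within the cap.
#'
#' @param fused A [build_fused_sequence()] result.
#' @param presence A [kmer_index()].
#' @param counter A [genome_counter()].
#' @return Tibble with `nullomer` and 0-based `window_start`.
#' @export
extract_junction_nullomers <- function(fused, presence, counter) {
  stopifnot(inherits(fused, "fused_sequence"))
  k <- presence$k
  L <- nchar(fused$nt)
  jo <- fused$junction_offset
  starts <- seq.int(max(0L, jo - k + 1L), min(jo - 1L, L - k))
  starts <- starts[starts >= 0L & starts <= L - k]
  if (!length(starts)) {
    return(tibble(nullomer = character(), window_start = integer()))
  }
  words <- substring(fused$nt, starts + 1L, starts + k)
  keep <- !stringr::str_detect(words, "N") & !kmer_contains(presence, words)
  starts <- starts[keep]; words <- words[keep]
  if (length(words)) {
    keep <- count_occurrences(counter, words) <= counter$cap
    starts <- starts[keep]; words <- words[keep]
  }
  tibble(nullomer = words, window_start = starts)
}

# Coding-sequence phase bookkeeping for one junction.
# cds_anno: tibble(gene_id, chrom, start, end, strand) -- contiguous CDS
# intervals, 1-based inclusive, `start`..`end` in genomic coordinates.
junction_frames <- function(junction, cds_anno) {
  jx <- as.list(junction)
  a5 <- cds_anno[cds_anno$gene_id == jx$gene5, , drop = FALSE]
  a3 <- cds_anno[cds_anno$gene_id == jx$gene3, , drop = FALSE]
  if (!nrow(a5) || !nrow(a3)) return(NULL)
  inside <- function(a, pos, chrom) {
    a$chrom == chrom && pos >= a$start && pos <= a$end
  }
  if (!inside(a5[1, ], jx$pos5, jx$chrom5) ||
      !inside(a3[1, ], jx$pos3, jx$chrom3)) return(NULL)
  u <- if (a5$strand[1] == "+") jx$pos5 - a5$start[1] + 1L
       else a5$end[1] - jx$pos5 + 1L           # 5' CDS nt retained
  v <- if (a3$strand[1] == "+") jx$pos3 - a3$start[1]
       else a3$end[1] - jx$pos3                 # 0-based offset into 3' CDS
  list(u = as.integer(u), v = as.integer(v),
       len3 = a3$end[1] - a3$start[1] + 1L)
}

#' Scan a fusion junction for putative neoepitopes
#'
#' Requires coding-sequence annotation for both partners. A junction is
#' scanned only when (i) both breakpoints fall inside the coding sequence,
#' (ii) the 5' junction lies past the start codon, and (iii) the 3' gene
#' remains in its original reading frame after fusion. The fused coding
#' sequence is translated in the 5' partner's frame and every 9-aa window
#' whose encoding nucleotide interval strictly contains the junction is
#' tested for absence from the reference proteome.
#'
#' @param fused A [build_fused_sequence()] result.
#' @param junction One-row junction record (needs `gene5`, `gene3` plus the
#'   breakpoint fields).
#' @param cds_anno Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   for each partner's (contiguous) coding region, and the coding sequences
#'   themselves in `nt` (transcript orientation).
#' @param proteome Sequence table or character vector of reference proteins.
#' @return A list: `peptides` (tibble `peptide`, `frame`, `spans_junction`),
#'   `reason` (`NA` when scanned, otherwise why the junction was skipped).
#' @export
scan_junction_neoepitopes <- function(fused, junction, cds_anno, proteome) {
  empty <- tibble(peptide = character(), frame = integer(),
                  spans_junction = logical())
  fr <- junction_frames(junction, cds_anno)
  if (is.null(fr)) {
    return(list(peptides = empty, reason = "non-coding junction"))
  }
  if (fr$u < 3L) {
    return(list(peptides = empty, reason = "start codon overlap"))
  }
  if (fr$u %% 3L != fr$v %% 3L) {
    return(list(peptides = empty, reason = "frame shift"))
  }
  jx <- as.list(junction)
  nt5 <- cds_anno$nt[cds_anno$gene_id == jx$gene5][1]
  nt3 <- cds_anno$nt[cds_anno$gene_id == jx$gene3][1]
  fused_cds <- paste0(substr(nt5, 1L, fr$u),
                      substr(nt3, fr$v + 1L, nchar(nt3)))
  u <- fr$u
  frame <- u %% 3L
  L <- nchar(fused_cds)
  # 9-codon windows (27 nt) whose nt interval strictly contains the junction
  cand <- seq.int(0L, L %/% 3L - 9L)
  cand <- cand[3L * cand < u & 3L * cand + 27L > u]
  if (!length(cand)) return(list(peptides = empty, reason = NA_character_))
  prot <- seq_vector(proteome)
  peps <- vapply(cand, function(i) {
    translate_cds(substr(fused_cds, 3L * i + 1L, 3L * i + 27L))
  }, character(1))
  ok <- nchar(peps) == 9L   # windows hitting a stop codon are not peptides
  cand <- cand[ok]; peps <- peps[ok]
  absent <- vapply(peps, function(p) {
    !any(stringi::stri_detect_fixed(prot, p))
  }, logical(1), USE.NAMES = FALSE)
  list(peptides = tibble(peptide = peps[absent],
                         frame = rep(frame, sum(absent)),
                         spans_junction = rep(TRUE, sum(absent))),
       reason = NA_character_)
}

#' Build the gene-fusion nullomer mapping
#'
#' For each junction, builds the fused target sequence, extracts
#' junction-spanning nullomers, and (where the coding context allows) the
#' junction neoepitopes. Junctions with no surviving nullomer are dropped
#' with a reason.
#'
#' @param junctions Tibble with columns `fusion_id`, `chrom5`, `pos5`,
#'   `strand5`, `chrom3`, `pos3`, `strand3`, `gene5`, `gene3` (+ optional
#'   `gene_function`).
#' @param genome Sequence table or named character vector of chromosomes.
#' @param presence A [kmer_index()] over the coding sequences.
#' @param counter A [genome_counter()].
#' @param cds_anno Optional coding annotation (see
#'   [scan_junction_neoepitopes()]); when `NULL`, no junction peptides are
#'   scanned.
#' @param proteome Optional reference proteome for the peptide scan.
#' @param flank Flank length per partner (default 500).
#' @return A `nullomer_mapping` object whose `targets` element holds the
#'   fused sequences (tibble `id`, `residues`) used as alignment targets.
#' @export
build_fusion_mapping <- function(junctions, genome, presence, counter,
                                 cds_anno = NULL, proteome = NULL,
                                 flank = 500L) {
  stopifnot(is.data.frame(junctions))
  junctions <- distinct(as_tibble(junctions))
  entries <- list(); dropped <- list(); targets <- list()
  jinfo <- list()
  for (i in seq_len(nrow(junctions))) {
    jx <- junctions[i, , drop = FALSE]
    fused <- tryCatch(build_fused_sequence(genome, jx, flank = flank),
                      neonull_record_error = function(e) e)
    if (inherits(fused, "error")) {
      dropped[[length(dropped) + 1L]] <- tibble(
        fusion_id = jx$fusion_id, reason = "breakpoint outside chromosome")
      next
    }
    nulls <- extract_junction_nullomers(fused, presence, counter)
    if (!nrow(nulls)) {
      dropped[[length(dropped) + 1L]] <- tibble(
        fusion_id = jx$fusion_id, reason = "no_nullomer")
      next
    }
    peps <- if (!is.null(cds_anno) && !is.null(proteome)) {
      scan_junction_neoepitopes(fused, jx, cds_anno, proteome)
    } else list(peptides = tibble(peptide = character()), reason = "not scanned")
    pep_str <- if (nrow(peps$peptides)) {
      paste(peps$peptides$peptide, collapse = ",")
    } else NA_character_
    targets[[length(targets) + 1L]] <- tibble(
      id = jx$fusion_id, residues = fused$nt)
    jinfo[[length(jinfo) + 1L]] <- tibble(
      fusion_id = jx$fusion_id, junction_offset = fused$junction_offset)
    entries[[length(entries) + 1L]] <- tibble(
      target_kind = "fusion",
      target_id = jx$fusion_id,
      target_seq = jx$fusion_id,
      nullomer = nulls$nullomer,
      window_start = nulls$window_start,
      junction_offset = fused$junction_offset,
      gene5 = jx$gene5 %||% NA_character_,
      gene3 = jx$gene3 %||% NA_character_,
      neoepitopes = pep_str,
      gene_function = if ("gene_function" %in% names(jx)) jx$gene_function
                      else NA_character_,
      locus5 = sprintf("%s:%d:%s", jx$chrom5, jx$pos5, jx$strand5),
      locus3 = sprintf("%s:%d:%s", jx$chrom3, jx$pos3, jx$strand3)
    )
  }
  entries <- if (length(entries)) bind_rows(entries) else
    tibble(target_kind = character(), target_id = character(),
           target_seq = character(), nullomer = character(),
           window_start = integer(), junction_offset = integer(),
           gene5 = character(), gene3 = character(),
           neoepitopes = character(), gene_function = character(),
           locus5 = character(), locus3 = character())
  dropped <- if (length(dropped)) bind_rows(dropped) else
    tibble(fusion_id = character(), reason = character())
  m <- new_nullomer_mapping(entries, dropped, kind = "fusion",
                            n_input = nrow(junctions),
                            targets = if (length(targets)) bind_rows(targets)
                                      else tibble(id = character(),
                                                  residues = character()))
  m$junction_offsets <- if (length(jinfo)) bind_rows(jinfo) else
    tibble(fusion_id = character(), junction_offset = integer())
  m
}
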