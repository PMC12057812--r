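# From (wildtype epitope, neoepitope, transcript) records to nullomer
# mapping entries.
#
# Each accepted epitope pair is located on the protein translation of its
# coding sequence, every codon conformation of the mutated residues is
# enumerated, and the mutated context is scanned for k-mers absent from the
# coding-sequence presence index (and rare enough in the genome).

#' Protein alignment scoring configuration
#'
#' Defaults: BLOSUM62, gap open 10, gap extend 1. For the accepted records
#' (at most two substitutions, no indels) the alignment almost always reduces
#' to an ungapped column-wise comparison, which is used as a fast path when
#' the two peptides have equal length.
#'
#' @param matrix Substitution matrix name understood by
#'   [Biostrings::pairwiseAlignment()].
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return A list of class `epitope_scoring`.
#' @export
epitope_scoring <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "epitope_scoring")
}

#' Align a neoepitope to its wildtype epitope
#'
#' Smith-Waterman local alignment of the two peptides; the aligned columns
#' give the substitution sites and whether an insertion or deletion occurred.
#' Equal-length pairs take an ungapped fast path.
#'
#' @param wt,neo Wildtype and neoepitope peptide strings (non-empty).
#' @param scoring An [epitope_scoring()] configuration.
#' @return An object of class `mutation_alignment`: `aligned_wt`,
#'   `aligned_neo` (gapped strings), `substitution_sites` (tibble with
#'   0-based `pos` on the epitope, `wt_aa`, `neo_aa`), `has_indel`, and the
#'   original `wt`/`neo`.
#' @export
align_epitopes <- function(wt, neo, scoring = epitope_scoring()) {
  if (!nzchar(wt) || !nzchar(neo)) {
    abort("empty epitope sequence", class = "neonull_format_error")
  }
  wt <- toupper(wt); neo <- toupper(neo)
  if (nchar(wt) == nchar(neo)) {
    a <- strsplit(wt, "")[[1]]
    b <- strsplit(neo, "")[[1]]
    diff <- which(a != b)
    sites <- tibble(pos = diff - 1L, wt_aa = a[diff], neo_aa = b[diff])
    return(structure(list(aligned_wt = wt, aligned_neo = neo,
                          substitution_sites = sites, has_indel = FALSE,
                          wt = wt, neo = neo),
                     class = "mutation_alignment"))
  }
  pal <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(neo), Biostrings::AAString(wt),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
  )
  an <- as.character(Biostrings::alignedPattern(pal))
  aw <- as.character(Biostrings::alignedSubject(pal))
  cols_n <- strsplit(an, "")[[1]]
  cols_w <- strsplit(aw, "")[[1]]
  gaps <- cols_n == "-" | cols_w == "-"
  # epitope (neo) coordinate of each alignment column
  neo_pos <- cumsum(cols_n != "-") - 1L
  neo_start0 <- BiocGenerics::start(Biostrings::pattern(pal)) - 1L
  diff <- which(!gaps & cols_n != cols_w)
  sites <- tibble(pos = neo_start0 + neo_pos[diff],
                  wt_aa = cols_w[diff], neo_aa = cols_n[diff])
  # a length difference implies an indel even if the local alignment clips it
  has_indel <- any(gaps) || nchar(wt) != nchar(neo)
  structure(list(aligned_wt = aw, aligned_neo = an,
                 substitution_sites = sites, has_indel = has_indel,
                 wt = wt, neo = neo),
            class = "mutation_alignment")
}

#' @export
print.mutation_alignment <- function(x, ...) {
  cat(sprintf("<mutation_alignment> %d substitution(s)%s\n",
              nrow(x$substitution_sites),
              if (x$has_indel) ", indel" else ""))
  invisible(x)
}

#' Accept or exclude an epitope pair
#'
#' Pairs with an amino-acid insertion or deletion, or more than two
#' substitutions, are excluded from the database build.
#'
#' @param alignment A [align_epitopes()] result.
#' @return `"accept"` or `"exclude"`, with a `reason` attribute when
#'   excluded.
#' @export
classify_epitope <- function(alignment) {
  stopifnot(inherits(alignment, "mutation_alignment"))
  if (alignment$has_indel) {
    return(structure("exclude", reason = "indel"))
  }
  if (nrow(alignment$substitution_sites) > 2L) {
    return(structure("exclude", reason = "gt2_substitutions"))
  }
  "accept"
}

#' Locate a wildtype epitope on a protein
#'
#' @param peptide Peptide to search for.
#' @param protein Protein string (e.g. the translation of a coding sequence).
#' @return Integer vector of all 0-based exact-match offsets (overlapping
#'   matches retained); empty when absent.
#' @export
locate_on_ccds <- function(peptide, protein) {
  loc <- stringi::stri_locate_all_fixed(toupper(protein), toupper(peptide),
                                        overlap = TRUE)[[1]]
  if (all(is.na(loc[, 1]))) return(integer())
  as.integer(loc[, 1]) - 1L
}

#' Codons encoding an amino acid (standard genetic code)
#'
#' @param aa Single amino-acid letter.
#' @return Character vector of codons.
#' @export
codons_for <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  names(code)[code == toupper(aa)]
}

#' Enumerate codon conformations of a neoepitope
#'
#' Within the coding sequence, wildtype codons are retained everywhere except
#' at the substitution sites, where every codon of the new amino acid is
#' enumerated; the cartesian product over sites gives all DNA conformations
#' consistent with the neoepitope.
#'
#' @param ccds_nt Nucleotide string of the full coding sequence.
#' @param offset 0-based protein offset of the epitope on the translation.
#' @param alignment A [align_epitopes()] result with no indel.
#' @return Tibble with one row per conformation: `conf_id`, `ccds_nt`
#'   (mutated full coding sequence), `segment_nt` (mutated epitope-coding
#'   segment), and `mutated` (list-column tibble with 0-based `ccds_pos` of
#'   each changed nucleotide and the epitope `site` it belongs to).
#' @export
enumerate_conformations <- function(ccds_nt, offset, alignment) {
  stopifnot(inherits(alignment, "mutation_alignment"), !alignment$has_indel)
  ccds_nt <- toupper(ccds_nt)
  ep_len <- nchar(alignment$neo)
  seg_start <- 3L * offset                 # 0-based nt start of the segment
  if (seg_start + 3L * ep_len > nchar(ccds_nt)) {
    abort("epitope does not fit within the coding sequence at this offset",
          class = "neonull_record_error")
  }
  sites <- alignment$substitution_sites
  bad <- sites$neo_aa %in% c("X", "*") | !sites$neo_aa %in% Biostrings::GENETIC_CODE
  if (any(bad)) {
    abort(sprintf("neoepitope residue '%s' has no codon", sites$neo_aa[bad][1]),
          class = "neonull_record_error")
  }
  codon_sets <- lapply(sites$neo_aa, codons_for)
  combos <- if (nrow(sites)) expand.grid(codon_sets, stringsAsFactors = FALSE,
                                         KEEP.OUT.ATTRS = FALSE)
            else data.frame(row.names = 1)
  purrr::map_dfr(seq_len(max(1L, nrow(combos))), function(ci) {
    mut_nt <- ccds_nt
    mutated <- tibble(ccds_pos = integer(), site = integer())
    if (nrow(sites)) {
      for (si in seq_len(nrow(sites))) {
        codon_start0 <- seg_start + 3L * sites$pos[si]
        old <- substr(mut_nt, codon_start0 + 1L, codon_start0 + 3L)
        new <- combos[ci, si]
        substr(mut_nt, codon_start0 + 1L, codon_start0 + 3L) <- new
        changed <- which(strsplit(old, "")[[1]] != strsplit(new, "")[[1]])
        mutated <- bind_rows(mutated, tibble(
          ccds_pos = codon_start0 + changed - 1L,
          site = sites$pos[si]
        ))
      }
    }
    segment <- substr(mut_nt, seg_start + 1L, seg_start + 3L * ep_len)
    tibble(conf_id = ci, ccds_nt = mut_nt, segment_nt = segment,
           mutated = list(arrange(mutated, .data$ccds_pos)))
  })
}

#' Extract nullomers witnessing a mutation
#'
#' Scans every length-`k` window of the mutated coding sequence that overlaps
#' at least one mutated nucleotide, and keeps those that are absent from the
#' coding-sequence presence index and occur at most `cap` times in the
#' genome. Windows near a sequence end are truncated at the boundary (no
#' padding), so fewer candidates exist there.
#'
#' @param ccds_mut Mutated full coding sequence (one conformation).
#' @param mutated Tibble with 0-based `ccds_pos` (and optionally `site`)
#'   of the mutated nucleotides.
#' @param presence A [kmer_index()] over the coding sequences.
#' @param counter A [genome_counter()].
#' @return Tibble with `nullomer`, `window_start` (0-based), `sites`
#'   (list-column of epitope substitution sites overlapped by the window).
#' @export
extract_neoepitope_nullomers <- function(ccds_mut, mutated, presence, counter) {
  k <- presence$k
  L <- nchar(ccds_mut)
  if (!nrow(mutated) || L < k) {
    return(tibble(nullomer = character(), window_start = integer(),
                  sites = list()))
  }
  starts <- sort(unique(unlist(lapply(mutated$ccds_pos, function(p) {
    seq.int(max(0L, p - k + 1L), min(p, L - k))
  }))))
  words <- substring(ccds_mut, starts + 1L, starts + k)
  keep <- !kmer_contains(presence, words)
  starts <- starts[keep]; words <- words[keep]
  if (length(words)) {
    keep <- count_occurrences(counter, words) <= counter$cap
    starts <- starts[keep]; words <- words[keep]
  }
  site_col <- if ("site" %in% names(mutated)) mutated$site else
    rep(NA_integer_, nrow(mutated))
  sites <- lapply(starts, function(s) {
    sort(unique(site_col[mutated$ccds_pos >= s & mutated$ccds_pos < s + k]))
  })
  distinct(tibble(nullomer = words, window_start = starts, sites = sites),
           .data$nullomer, .data$window_start, .keep_all = TRUE)
}

site_descriptor <- function(offset, sites) {
  paste(sprintf("p.%d%s>%s", offset + sites$pos + 1L, sites$wt_aa, sites$neo_aa),
        collapse = "+")
}

#' Build the neoepitope nullomer mapping
#'
#' Runs the full database build: align and classify each epitope pair,
#' locate the wildtype on its coding sequence, enumerate codon conformations,
#' extract surviving nullomers, and group neoepitopes produced by the same
#' mutation into a single target. Records that cannot be processed are
#' dropped with a reason, never raised.
#'
#' @param records Tibble with columns `wildtype_peptide`, `neo_peptide`,
#'   `transcript_id`, `source_db`, plus optional passthrough metadata columns
#'   (`gene_id`, `hgnc_symbol`, `gene_function`).
#' @param ccds Tibble with columns `transcript_id`, `nt` and optionally
#'   `protein` (computed by translation when absent).
#' @param presence A [kmer_index()] built over `ccds$nt`.
#' @param counter A [genome_counter()] over the genome.
#' @param scoring An [epitope_scoring()] configuration.
#' @return A `nullomer_mapping` object: `entries` (one row per
#'   mutation-target and nullomer), `dropped`, `report`, `kind`.
#' @export
build_epitope_mapping <- function(records, ccds, presence, counter,
                                  scoring = epitope_scoring()) {
  stopifnot(is.data.frame(records), is.data.frame(ccds))
  need <- c("wildtype_peptide", "neo_peptide", "transcript_id", "source_db")
  if (!all(need %in% names(records))) {
    abort(sprintf("epitope table lacks column(s): %s",
                  paste(setdiff(need, names(records)), collapse = ", ")),
          class = "neonull_format_error")
  }
  if (!"protein" %in% names(ccds)) {
    # records with a trailing partial codon (e.g. context-only fragments)
    # still translate; the dangling bases are irrelevant for locating
    ccds$protein <- suppressWarnings(translate_cds(ccds$nt))
  }
  records <- distinct(as_tibble(records),
                      .data$wildtype_peptide, .data$neo_peptide,
                      .data$transcript_id, .keep_all = TRUE)
  meta_cols <- intersect(c("gene_id", "hgnc_symbol", "gene_function"),
                         names(records))

  entries <- list()
  dropped <- list()
  drop <- function(i, reason) {
    dropped[[length(dropped) + 1L]] <<- tibble(
      wildtype_peptide = records$wildtype_peptide[i],
      neo_peptide = records$neo_peptide[i],
      transcript_id = records$transcript_id[i],
      reason = reason
    )
  }

  for (i in seq_len(nrow(records))) {
    tr <- records$transcript_id[i]
    row_cds <- ccds[ccds$transcript_id == tr, , drop = FALSE]
    if (!nrow(row_cds)) { drop(i, "transcript_missing"); next }
    al <- align_epitopes(records$wildtype_peptide[i], records$neo_peptide[i],
                         scoring)
    verdict <- classify_epitope(al)
    if (identical(as.character(verdict), "exclude")) {
      drop(i, paste0("excluded_", attr(verdict, "reason"))); next
    }
    offsets <- locate_on_ccds(al$wt, row_cds$protein[1])
    if (!length(offsets)) { drop(i, "wildtype_not_found"); next }
    got_any <- FALSE
    for (off in offsets) {
      confs <- tryCatch(
        enumerate_conformations(row_cds$nt[1], off, al),
        neonull_record_error = function(e) NULL
      )
      if (is.null(confs)) next
      nulls <- purrr::map_dfr(seq_len(nrow(confs)), function(ci) {
        extract_neoepitope_nullomers(confs$ccds_nt[ci], confs$mutated[[ci]],
                                     presence, counter)
      })
      nulls <- distinct(nulls, .data$nullomer, .keep_all = TRUE)
      if (!nrow(nulls)) next
      got_any <- TRUE
      target_id <- if (nrow(al$substitution_sites)) {
        paste0(tr, ":", site_descriptor(off, al$substitution_sites))
      } else paste0(tr, ":identity")
      meta <- records[i, meta_cols, drop = FALSE]
      entries[[length(entries) + 1L]] <- bind_rows(lapply(
        seq_len(nrow(nulls)), function(ni) {
          tibble(
            target_kind = "neoepitope",
            target_id = target_id,
            target_seq = tr,
            nullomer = nulls$nullomer[ni],
            transcript_id = tr,
            gene_id = if ("gene_id" %in% meta_cols) meta$gene_id else NA_character_,
            hgnc_symbol = if ("hgnc_symbol" %in% meta_cols) meta$hgnc_symbol
                          else NA_character_,
            neoepitopes = records$neo_peptide[i],
            wildtype_peptides = records$wildtype_peptide[i],
            source_db = records$source_db[i],
            gene_function = if ("gene_function" %in% meta_cols)
                              meta$gene_function else NA_character_,
            protein_offset = off,
            n_sites = nrow(al$substitution_sites)
          )
        }))
    }
    if (!got_any) drop(i, "no_nullomer")
  }

  entries <- if (length(entries)) bind_rows(entries) else empty_entries()
  if (nrow(entries)) {
    # neoepitopes produced by the same mutation are reported together
    entries <- entries %>%
      group_by(.data$target_kind, .data$target_id, .data$target_seq,
               .data$nullomer) %>%
      summarise(
        transcript_id = .data$transcript_id[1],
        gene_id = .data$gene_id[1],
        hgnc_symbol = .data$hgnc_symbol[1],
        neoepitopes = paste(sort(unique(.data$neoepitopes)), collapse = ","),
        wildtype_peptides = paste(sort(unique(.data$wildtype_peptides)),
                                  collapse = ","),
        source_db = paste(sort(unique(.data$source_db)), collapse = ","),
        gene_function = .data$gene_function[1],
        protein_offset = min(.data$protein_offset),
        n_sites = .data$n_sites[1],
        .groups = "drop"
      ) %>%
      arrange(.data$target_id, .data$nullomer)
  }
  dropped <- if (length(dropped)) bind_rows(dropped) else
    tibble(wildtype_peptide = character(), neo_peptide = character(),
           transcript_id = character(), reason = character())
  new_nullomer_mapping(entries, dropped, kind = "neoepitope",
                       n_input = nrow(records))
}

empty_entries <- function() {
  tibble(target_kind = character(), target_id = character(),
         target_seq = character(), nullomer = character(),
         transcript_id = character(), gene_id = character(),
         hgnc_symbol = character(), neoepitopes = character(),
         wildtype_peptides = character(), source_db = character(),
         gene_function = character(), protein_offset = integer(),
         n_sites = integer())
}

new_nullomer_mapping <- function(entries, dropped, kind, n_input,
                                 targets = NULL) {
  report <- dropped %>% dplyr::count(.data$reason, name = "n")
  recovered <- n_input - nrow(dropped)
  report <- bind_rows(tibble(reason = "recovered", n = recovered), report)
  structure(list(entries = entries, dropped = dropped, report = report,
                 kind = kind, n_input = n_input, targets = targets),
            class = "nullomer_mapping")
}

#' @export
print.nullomer_mapping <- function(x, ...) {
  cat(sprintf("<nullomer_mapping> kind=%s: %d entries, %d target(s), %d/%d records recovered\n",
              x$kind, nrow(x$entries), length(unique(x$entries$target_id)),
              x$n_input - nrow(x$dropped), x$n_input))
  invisible(x)
}

#' @rdname build_epitope_mapping
#' @param x A `nullomer_mapping` object.
#' @param ... Unused.
#' @export
tidy.nullomer_mapping <- function(x, ...) x$entries

#' @rdname build_epitope_mapping
#' @export
glance.nullomer_mapping <- function(x, ...) {
  tibble(kind = x$kind,
         n_input = x$n_input,
         n_recovered = x$n_input - nrow(x$dropped),
         n_dropped = nrow(x$dropped),
         n_targets = length(unique(x$entries$target_id)),
         n_nullomers = length(unique(x$entries$nullomer)))
}

#' Write / read a nullomer mapping table
#'
#' The mapping file is a TSV with a provenance comment header, one row per
#' (target, nullomer), column order stable as documented in the entry tibble.
#'
#' @param mapping A `nullomer_mapping` object (or its entries tibble).
#' @param path Output path.
#' @param config,seed Provenance fields recorded in the header.
#' @return The path, invisibly.
#' @export
write_mapping <- function(mapping, path, config = NULL, seed = NULL) {
  entries <- if (inherits(mapping, "nullomer_mapping")) mapping$entries
             else mapping
  write_report_tsv(entries, path, config = config, seed = seed)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  read_report_tsv(path)
}
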