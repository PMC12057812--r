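# Nullomer scanning in stranded paired-end reads, candidate-alignment
# filtering, and coverage aggregation.
#
# Step 1: nullomers are searched forward on mate 1 and as reverse
# complements on mate 2 (mate 1 carries the sense strand in a stranded
# library; antisense orientations are ignored).
# Step 2: hit pairs are aligned locally to their nullomers' own targets,
# duplicates removed, then soft-clip / MAPQ / minimum-expected-score (MES)
# filters applied -- plus the junction-flank rule for fusions.
# Step 3: per-nullomer read coverage is aggregated; each target's coverage
# is the coverage of its most covered nullomer.

#' Detection filter configuration
#'
#' Houses the MES line and the read-filter thresholds. The MES is the linear
#' alignment-score threshold `MES = slope * (AL - 35) + 64`, anchored at
#' AS 64 for an aligned length (AL) of 35 nt (one medium-quality mismatch)
#' and AS 277 at 150 nt (about four), so the default slope is the exact
#' rational (277-64)/(150-35) = 213/115. `compat_slope_1.85` reproduces the
#' printed two-decimal slope instead.
#'
#' @param mes_slope Slope of the MES line.
#' @param mes_anchor_al,mes_anchor_as Anchor point of the line (35, 64).
#' @param strict_mes Use a strict `AS > MES` comparison instead of the
#'   default `AS >= MES` (under the exact slope the documented anchor cases
#'   sit exactly on the line and are meant to pass).
#' @param softclip_max_fraction Reads with a soft-clipped fraction strictly
#'   above this (of full read length) are removed; default exactly 1/3.
#' @param mapq_min_neoepitope,mapq_min_fusion MAPQ values strictly above
#'   these pass regardless of AS (10 for coding targets, 30 for fused
#'   targets where MAPQ is less informative).
#' @param junction_min_flank Minimum aligned bases required on each side of
#'   a fusion junction (5).
#' @param min_reads_neoepitope,min_reads_fusion,min_nullomers_fusion
#'   Reporting thresholds: neoepitopes need >= 3 mapped reads; fusions >= 2
#'   mapped reads and >= 2 distinct nullomers.
#' @param compat_slope_1.85 Use slope 1.85 instead of 213/115.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(mes_slope = 213 / 115,
                          mes_anchor_al = 35L,
                          mes_anchor_as = 64L,
                          strict_mes = FALSE,
                          softclip_max_fraction = 1 / 3,
                          mapq_min_neoepitope = 10L,
                          mapq_min_fusion = 30L,
                          junction_min_flank = 5L,
                          min_reads_neoepitope = 3L,
                          min_reads_fusion = 2L,
                          min_nullomers_fusion = 2L,
                          `compat_slope_1.85` = FALSE) {
  if (isTRUE(`compat_slope_1.85`)) mes_slope <- 1.85
  cfg <- list(mes_slope = mes_slope, mes_anchor_al = mes_anchor_al,
              mes_anchor_as = mes_anchor_as, strict_mes = isTRUE(strict_mes),
              softclip_max_fraction = softclip_max_fraction,
              mapq_min_neoepitope = mapq_min_neoepitope,
              mapq_min_fusion = mapq_min_fusion,
              junction_min_flank = junction_min_flank,
              min_reads_neoepitope = min_reads_neoepitope,
              min_reads_fusion = min_reads_fusion,
              min_nullomers_fusion = min_nullomers_fusion)
  if (any(unlist(cfg[c("softclip_max_fraction", "mapq_min_neoepitope",
                       "mapq_min_fusion", "junction_min_flank",
                       "min_reads_neoepitope", "min_reads_fusion",
                       "min_nullomers_fusion")]) < 0)) {
    abort("filter thresholds must be nonnegative", class = "neonull_config_error")
  }
  structure(cfg, class = "filter_config")
}

#' Minimum expected score for an aligned length
#'
#' @param al Aligned length(s) in nucleotides.
#' @param cfg A [filter_config()].
#' @return Numeric vector `slope * (al - 35) + 64`.
#' @export
#' @examples
#' compute_mes(35)   # 64
#' compute_mes(150)  # 277 under the exact slope
compute_mes <- function(al, cfg = filter_config()) {
  cfg$mes_slope * (al - cfg$mes_anchor_al) + cfg$mes_anchor_as
}

#' Read-to-target local alignment scoring
#'
#' Local alignment score calibrated so that `AS = 2*matches - penalties`:
#' match +2, mismatch -4 (a medium-quality mismatch), gap open -5, gap
#' extend -3. A 35-nt read with one mismatch scores 34*2 - 4 = 64, the MES
#' anchor.
#'
#' @param match,mismatch,gap_open,gap_extend Score components.
#' @return A list of class `read_scoring`.
#' @export
read_scoring <- function(match = 2, mismatch = -4, gap_open = 5, gap_extend = 3) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "read_scoring")
}

#' Scan read pairs for nullomers
#'
#' Exact multi-pattern matching (preprocessed dictionary): forward patterns
#' on mate 1, reverse-complement patterns on mate 2. Reads containing `N`
#' at the pattern site never match. Pairs with zero hits simply contribute
#' no rows.
#'
#' @param pairs Tibble with columns `read_id`, `seq1`, `seq2` (and
#'   optionally `qual1`, `qual2`).
#' @param patterns Character vector of same-length nullomer words.
#' @return Tibble of hits: `read_id`, `mate` (1 or 2), `nullomer`, `offset`
#'   (0-based position in the read as sequenced).
#' @export
scan_read_pairs <- function(pairs, patterns) {
  patterns <- unique(toupper(patterns))
  empty <- tibble(read_id = character(), mate = integer(),
                  nullomer = character(), offset = integer())
  if (!nrow(pairs) || !length(patterns)) return(empty)
  if (length(unique(nchar(patterns))) != 1L) {
    abort("all patterns must have the same length", class = "neonull_config_error")
  }
  scan_one_side <- function(seqs, pats, mate) {
    d <- Biostrings::DNAStringSet(toupper(seqs))
    pd <- Biostrings::PDict(pats)
    counts <- Biostrings::vcountPDict(pd, d)   # patterns x reads
    idx <- which(counts > 0L, arr.ind = TRUE)
    if (!nrow(idx)) return(empty)
    purrr::map_dfr(seq_len(nrow(idx)), function(r) {
      pi <- idx[r, 1]; ri <- idx[r, 2]
      m <- Biostrings::matchPattern(pats[pi], d[[ri]])
      tibble(read_id = pairs$read_id[ri], mate = mate,
             nullomer = patterns[pi],
             offset = BiocGenerics::start(m) - 1L)
    })
  }
  h1 <- scan_one_side(pairs$seq1, patterns, 1L)
  h2 <- scan_one_side(pairs$seq2, revcomp(patterns), 2L)
  # for mate 2 the searched pattern is the reverse complement but hits are
  # reported under the nullomer itself
  out <- bind_rows(h1, h2)
  arrange(out, match(.data$read_id, pairs$read_id), .data$mate, .data$offset)
}

phred_sum <- function(qual) {
  vapply(qual, function(q) sum(utf8ToInt(q) - 33L), integer(1),
         USE.NAMES = FALSE)
}

#' Local alignment of a read against a target
#'
#' Smith-Waterman local alignment under the [read_scoring()] scheme. The
#' unaligned read ends are reported as soft-clips; MAPQ is fixed at 0 so
#' built-in alignments are judged by the alignment-score branch of the
#' filters only.
#'
#' @param read Read sequence (aligned orientation).
#' @param target Target sequence.
#' @param scoring A [read_scoring()].
#' @return One-row tibble: `target_start` (0-based), `target_end`
#'   (exclusive), `aligned_length` (reference-consuming), `alignment_score`,
#'   `mapq`, `softclip_left`, `softclip_right`, `read_length`.
#' @export
local_align <- function(read, target, scoring = read_scoring()) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  pal <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(target),
    type = "local", substitutionMatrix = sm,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  rs <- BiocGenerics::start(Biostrings::pattern(pal))
  re <- BiocGenerics::end(Biostrings::pattern(pal))
  ts <- BiocGenerics::start(Biostrings::subject(pal))
  te <- BiocGenerics::end(Biostrings::subject(pal))
  tibble(
    target_start = ts - 1L,
    target_end = te,
    aligned_length = te - ts + 1L,
    alignment_score = BiocGenerics::score(pal),
    mapq = 0L,
    softclip_left = rs - 1L,
    softclip_right = nchar(read) - re,
    read_length = nchar(read)
  )
}

# Align every mate of the hit pairs to the candidate targets of its
# nullomers; keep the best-scoring target per mate.
align_hit_pairs <- function(pairs, hits, entries, targets,
                            scoring = read_scoring()) {
  tv <- seq_vector(targets)
  empty <- tibble(read_id = character(), mate = integer(),
                  target_id = character(), target_start = integer(),
                  target_end = integer(), aligned_length = integer(),
                  alignment_score = double(), mapq = integer(),
                  softclip_left = integer(), softclip_right = integer(),
                  read_length = integer(), qual_sum = integer(),
                  fragment_key = character())
  if (!nrow(hits)) return(empty)
  recs <- purrr::map_dfr(unique(hits$read_id), function(rid) {
    pr <- pairs[pairs$read_id == rid, , drop = FALSE]
    cand <- unique(entries$target_seq[
      entries$nullomer %in% hits$nullomer[hits$read_id == rid]])
    cand <- cand[cand %in% names(tv)]
    if (!length(cand)) return(empty)
    q1 <- if ("qual1" %in% names(pr)) phred_sum(pr$qual1) else 0L
    q2 <- if ("qual2" %in% names(pr)) phred_sum(pr$qual2) else 0L
    per_mate <- function(seq, mate, qsum) {
      als <- purrr::map_dfr(cand, function(tid) {
        mutate(local_align(seq, tv[[tid]], scoring), target_id = tid)
      })
      best <- als[which.max(als$alignment_score), , drop = FALSE]
      mutate(best, read_id = rid, mate = mate, qual_sum = qsum)
    }
    r1 <- per_mate(pr$seq1, 1L, q1)
    r2 <- per_mate(revcomp(pr$seq2), 2L, q2)
    pairrec <- bind_rows(r1, r2)
    # fragment key from the pair's span on mate 1's target
    tid <- r1$target_id
    on_t <- pairrec[pairrec$target_id == tid, , drop = FALSE]
    key <- sprintf("%s:%d-%d:FR", tid, min(on_t$target_start),
                   max(on_t$target_end))
    mutate(pairrec, fragment_key = key)
  })
  select(recs, "read_id", "mate", "target_id", "target_start", "target_end",
         "aligned_length", "alignment_score", "mapq", "softclip_left",
         "softclip_right", "read_length", "qual_sum", "fragment_key")
}

#' Remove duplicate fragments
#'
#' Among alignment records sharing a fragment key (target, fragment start,
#' fragment end, orientation), only the read pair with the highest summed
#' base quality is kept; ties keep the pair appearing first in input order.
#'
#' @param records Alignment-record tibble with columns `read_id`,
#'   `fragment_key`, `qual_sum`.
#' @return The surviving records, input order preserved.
#' @export
deduplicate <- function(records) {
  if (!nrow(records)) return(records)
  pairq <- records %>%
    group_by(.data$read_id, .data$fragment_key) %>%
    summarise(pair_qual = sum(.data$qual_sum), first_row = min(row_number()),
              .groups = "drop")
  # preserve encounter order for deterministic tie-breaking
  ord <- records %>% mutate(.row = row_number()) %>%
    group_by(.data$read_id) %>% summarise(.first = min(.data$.row))
  pairq <- left_join(pairq, ord, by = "read_id") %>%
    arrange(.data$fragment_key, dplyr::desc(.data$pair_qual), .data$.first)
  keep_ids <- pairq %>% group_by(.data$fragment_key) %>%
    slice(1) %>% pull(.data$read_id)
  records[records$read_id %in% keep_ids, , drop = FALSE]
}

#' Neoepitope read filters
#'
#' A read is removed when its soft-clipped fraction (of full read length)
#' strictly exceeds 1/3; otherwise it is retained when MAPQ > 10 or its
#' alignment score reaches the minimum expected score for its aligned
#' length.
#'
#' @param records Alignment-record tibble.
#' @param cfg A [filter_config()].
#' @return `records` with added `pass` (logical) and `reason` columns.
#' @export
passes_neoepitope_filters <- function(records, cfg = filter_config()) {
  if (!nrow(records)) return(mutate(records, pass = logical(), reason = character()))
  sc_frac <- (records$softclip_left + records$softclip_right) / records$read_length
  mes <- compute_mes(records$aligned_length, cfg)
  as_ok <- if (cfg$strict_mes) records$alignment_score > mes
           else records$alignment_score >= mes
  mapq_ok <- records$mapq > cfg$mapq_min_neoepitope
  mutate(records,
         pass = sc_frac <= cfg$softclip_max_fraction & (mapq_ok | as_ok),
         reason = case_when(
           sc_frac > cfg$softclip_max_fraction ~ "softclip_fraction",
           !(mapq_ok | as_ok) ~ "below_mes_and_mapq",
           TRUE ~ NA_character_
         ))
}

#' Fusion read filters
#'
#' As [passes_neoepitope_filters()] but with the junction rules: at least 5
#' aligned bases are required on each side of the fusion junction, and the
#' MAPQ escape threshold is 30 (mapping quality is less informative against
#' a small set of fused targets).
#'
#' @param records Alignment-record tibble (targets are fused sequences).
#' @param junction_offsets Tibble with `fusion_id` and `junction_offset`
#'   (0-based 5' contribution), or a named integer vector.
#' @param cfg A [filter_config()].
#' @return `records` with added `pass` and `reason` columns.
#' @export
passes_fusion_filters <- function(records, junction_offsets,
                                  cfg = filter_config()) {
  if (!nrow(records)) return(mutate(records, pass = logical(), reason = character()))
  jo <- if (is.data.frame(junction_offsets)) {
    setNames(as.integer(junction_offsets$junction_offset),
             junction_offsets$fusion_id)
  } else junction_offsets
  j <- unname(jo[records$target_id])
  sc_frac <- (records$softclip_left + records$softclip_right) / records$read_length
  side5 <- pmax(0L, pmin(records$target_end, j) - records$target_start)
  side3 <- pmax(0L, records$target_end - pmax(records$target_start, j))
  mes <- compute_mes(records$aligned_length, cfg)
  as_ok <- if (cfg$strict_mes) records$alignment_score > mes
           else records$alignment_score >= mes
  mapq_ok <- records$mapq > cfg$mapq_min_fusion
  flank_ok <- side5 >= cfg$junction_min_flank & side3 >= cfg$junction_min_flank
  mutate(records,
         pass = sc_frac <= cfg$softclip_max_fraction & flank_ok &
                (mapq_ok | as_ok),
         reason = case_when(
           sc_frac > cfg$softclip_max_fraction ~ "softclip_fraction",
           !flank_ok ~ "junction_flank",
           !(mapq_ok | as_ok) ~ "below_mes_and_mapq",
           TRUE ~ NA_character_
         ))
}

#' Aggregate per-nullomer and per-target read coverage
#'
#' The coverage of a nullomer is the number of surviving reads that contain
#' it and are aligned to that nullomer's own target sequence; reads whose
#' alignment landed elsewhere count for nothing. A target's coverage is the
#' coverage of its most covered nullomer.
#'
#' @param hits [scan_read_pairs()] output.
#' @param records Surviving (deduplicated, filter-passing) alignment
#'   records.
#' @param entries Mapping entries tibble.
#' @param cfg A [filter_config()].
#' @param sample_id Sample label for the report rows.
#' @return Coverage tibble, one row per detected target, with `pass` flag
#'   and `fail_reason`.
#' @export
aggregate_coverage <- function(hits, records, entries,
                               cfg = filter_config(), sample_id = "sample") {
  kind <- if (nrow(entries)) entries$target_kind[1] else "neoepitope"
  empty <- tibble(sample_id = character(), target_kind = character(),
                  target_id = character(), best_nullomer = character(),
                  neoepitopes = character(), mapped_reads = integer(),
                  n_nullomers_detected = integer(),
                  max_nullomers_per_read = integer(), pass = logical(),
                  fail_reason = character())
  if (!nrow(hits) || !nrow(records) || !nrow(entries)) return(empty)
  counted <- hits %>%
    dplyr::inner_join(entries %>%
                        select("target_id", "target_seq", "nullomer") %>%
                        distinct(),
                      by = "nullomer", relationship = "many-to-many") %>%
    dplyr::inner_join(records %>% select("read_id", "mate", "target_id") %>%
                        rename(aligned_target = "target_id") %>% distinct(),
                      by = c("read_id", "mate"),
                      relationship = "many-to-many") %>%
    filter(.data$aligned_target == .data$target_seq) %>%
    distinct(.data$target_id, .data$nullomer, .data$read_id, .data$mate)
  if (!nrow(counted)) return(empty)
  per_null <- counted %>%
    group_by(.data$target_id, .data$nullomer) %>%
    summarise(reads = dplyr::n_distinct(paste(.data$read_id, .data$mate)),
              .groups = "drop")
  per_read <- counted %>%
    group_by(.data$target_id, .data$read_id, .data$mate) %>%
    summarise(nulls = dplyr::n_distinct(.data$nullomer), .groups = "drop") %>%
    group_by(.data$target_id) %>%
    summarise(max_nullomers_per_read = max(.data$nulls), .groups = "drop")
  cov <- per_null %>%
    group_by(.data$target_id) %>%
    summarise(
      best_nullomer = .data$nullomer[order(-.data$reads, .data$nullomer)][1],
      mapped_reads = max(.data$reads),
      n_nullomers_detected = dplyr::n(),
      .groups = "drop") %>%
    left_join(per_read, by = "target_id")
  meta <- entries %>%
    select(dplyr::any_of(c("target_id", "target_kind", "transcript_id",
                           "gene_id", "hgnc_symbol", "neoepitopes",
                           "wildtype_peptides", "source_db", "gene_function",
                           "gene5", "gene3", "locus5", "locus3",
                           "wt_hla", "neo_hla", "germline_af"))) %>%
    distinct(.data$target_id, .keep_all = TRUE)
  cov <- left_join(cov, meta, by = "target_id")
  if (kind == "fusion") {
    cov <- mutate(cov,
      pass = .data$mapped_reads >= cfg$min_reads_fusion &
             .data$n_nullomers_detected >= cfg$min_nullomers_fusion,
      fail_reason = case_when(
        .data$mapped_reads < cfg$min_reads_fusion ~ "below_min_reads",
        .data$n_nullomers_detected < cfg$min_nullomers_fusion ~ "below_min_nullomers",
        TRUE ~ NA_character_))
  } else {
    cov <- mutate(cov,
      pass = .data$mapped_reads >= cfg$min_reads_neoepitope,
      fail_reason = dplyr::if_else(.data$pass, NA_character_,
                                   "below_min_reads"))
  }
  cov %>%
    mutate(sample_id = sample_id) %>%
    select("sample_id", "target_kind", "target_id",
           dplyr::any_of(c("gene_id", "hgnc_symbol", "gene5", "gene3")),
           "best_nullomer", "neoepitopes", "mapped_reads",
           "n_nullomers_detected", "max_nullomers_per_read",
           dplyr::any_of(c("source_db", "gene_function", "wt_hla", "neo_hla",
                           "germline_af", "locus5", "locus3")),
           "pass", "fail_reason") %>%
    arrange(dplyr::desc(.data$mapped_reads), .data$target_id)
}

# One detection arm (neoepitope or fusion) from pairs to coverage rows.
detect_arm <- function(pairs, entries, targets, cfg, sample_id, kind,
                       junction_offsets = NULL, scoring = read_scoring(),
                       alignments = NULL) {
  hits <- scan_read_pairs(pairs, unique(entries$nullomer))
  records <- if (is.null(alignments)) {
    align_hit_pairs(pairs, hits, entries, targets, scoring)
  } else alignments
  records <- deduplicate(records)
  flt <- if (kind == "fusion") {
    passes_fusion_filters(records, junction_offsets, cfg)
  } else {
    passes_neoepitope_filters(records, cfg)
  }
  surviving <- filter(flt, .data$pass)
  rejects <- flt %>% filter(!.data$pass) %>%
    select("read_id", "mate", "target_id", "reason")
  cov <- aggregate_coverage(hits, surviving, entries, cfg, sample_id)
  list(coverage = cov, rejects = rejects, hits = hits, records = flt)
}

#' Detect neoepitopes and gene fusions in paired reads
#'
#' Runs the full detection pipeline against one or both mapping databases.
#'
#' @param pairs Read-pair tibble (`read_id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`), e.g. from [read_fastq_pairs()].
#' @param neo_mapping A neoepitope `nullomer_mapping` (or its entries
#'   tibble), or `NULL`.
#' @param ccds_targets Coding sequences to align neoepitope hits against
#'   (sequence table or named character vector keyed by transcript id).
#' @param fusion_mapping A fusion `nullomer_mapping` (with `targets` and
#'   `junction_offsets`), or `NULL`.
#' @param cfg A [filter_config()].
#' @param sample_id Sample label.
#' @param library_type `"mate1-sense"` (default) or `"mate2-sense"`; the
#'   latter swaps mates before scanning.
#' @param scoring A [read_scoring()].
#' @return An object of class `neonull_detection` with elements
#'   `neoepitopes`, `fusions` (coverage tibbles), `rejects`, `config`.
#' @export
detect <- function(pairs, neo_mapping = NULL, ccds_targets = NULL,
                   fusion_mapping = NULL, cfg = filter_config(),
                   sample_id = "sample", library_type = c("mate1-sense",
                                                          "mate2-sense"),
                   scoring = read_scoring()) {
  library_type <- match.arg(library_type)
  if (library_type == "mate2-sense" && nrow(pairs)) {
    pairs <- mutate(pairs, .s = .data$seq1, seq1 = .data$seq2, seq2 = .data$.s)
    if ("qual1" %in% names(pairs)) {
      pairs <- mutate(pairs, .q = .data$qual1, qual1 = .data$qual2,
                      qual2 = .data$.q)
    }
    pairs <- select(pairs, -dplyr::any_of(c(".s", ".q")))
  }
  rejects <- list()
  neo_cov <- NULL; fus_cov <- NULL
  if (!is.null(neo_mapping)) {
    entries <- if (inherits(neo_mapping, "nullomer_mapping"))
      neo_mapping$entries else as_tibble(neo_mapping)
    if (is.null(ccds_targets)) {
      abort("neoepitope detection requires `ccds_targets`",
            class = "neonull_config_error")
    }
    arm <- detect_arm(pairs, entries, ccds_targets, cfg, sample_id,
                      kind = "neoepitope", scoring = scoring)
    neo_cov <- arm$coverage
    rejects$neo <- mutate(arm$rejects, target_kind = "neoepitope")
  }
  if (!is.null(fusion_mapping)) {
    stopifnot(inherits(fusion_mapping, "nullomer_mapping"))
    arm <- detect_arm(pairs, fusion_mapping$entries, fusion_mapping$targets,
                      cfg, sample_id, kind = "fusion",
                      junction_offsets = fusion_mapping$junction_offsets,
                      scoring = scoring)
    fus_cov <- arm$coverage
    rejects$fus <- mutate(arm$rejects, target_kind = "fusion")
  }
  structure(list(
    neoepitopes = neo_cov %||% aggregate_coverage(
      tibble(read_id = character(), mate = integer(), nullomer = character(),
             offset = integer()),
      tibble(), empty_entries(), cfg, sample_id),
    fusions = fus_cov,
    rejects = bind_rows(rejects),
    config = cfg, sample_id = sample_id
  ), class = "neonull_detection")
}

#' @export
print.neonull_detection <- function(x, ...) {
  npass <- if (!is.null(x$neoepitopes)) sum(x$neoepitopes$pass) else 0L
  fpass <- if (!is.null(x$fusions)) sum(x$fusions$pass) else 0L
  cat(sprintf("<neonull_detection> sample=%s: %d neoepitope target(s) pass, %d fusion target(s) pass, %d rejected read(s)\n",
              x$sample_id, npass, fpass,
              if (is.null(x$rejects)) 0L else nrow(x$rejects)))
  invisible(x)
}

#' @rdname detect
#' @param x A `neonull_detection`.
#' @param type Which table to return: `"neoepitope"`, `"fusion"` or
#'   `"rejects"`.
#' @param ... Unused.
#' @export
tidy.neonull_detection <- function(x, type = c("neoepitope", "fusion",
                                               "rejects"), ...) {
  type <- match.arg(type)
  switch(type,
         neoepitope = x$neoepitopes %||% tibble(),
         fusion = x$fusions %||% tibble(),
         rejects = x$rejects %||% tibble())
}

#' @rdname detect
#' @export
glance.neonull_detection <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    n_neoepitope_detected = if (is.null(x$neoepitopes)) 0L else nrow(x$neoepitopes),
    n_neoepitope_pass = if (is.null(x$neoepitopes)) 0L else sum(x$neoepitopes$pass),
    n_fusion_detected = if (is.null(x$fusions)) 0L else nrow(x$fusions),
    n_fusion_pass = if (is.null(x$fusions)) 0L else sum(x$fusions$pass),
    n_rejected_reads = if (is.null(x$rejects)) 0L else nrow(x$rejects)
  )
}

#' Plot detected target coverage
#'
#' Bar chart of mapped reads per detected target, coloured by pass/fail
#' against the reporting thresholds.
#'
#' @param object A `neonull_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neonull_detection <- function(object, ...) {
  cov <- bind_rows(object$neoepitopes, object$fusions)
  if (!nrow(cov)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no detections") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(cov, ggplot2::aes(
    x = stats::reorder(.data$target_id, .data$mapped_reads),
    y = .data$mapped_reads, fill = .data$pass)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$target_kind),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = "mapped reads (most covered nullomer)",
                  fill = "passes threshold") +
    ggplot2::theme_minimal()
}
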