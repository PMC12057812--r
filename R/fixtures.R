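# Deterministic synthetic reference and read simulation.
#
# The toy reference emulates the real inputs at kilobase scale: a random
# genome with embedded open reading frames standing in for the coding
# sequence set, its translations standing in for the proteome. Epitope and
# fusion databases are planted with known truth so every stage of the
# pipeline is testable end to end without downloads.

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a deterministic toy reference
#'
#' Random open reading frames (start codon, random sense codons, stop) are
#' embedded in a random background genome at roughly uniform base
#' composition. Regeneration with the same seed is byte-identical.
#'
#' @param seed RNG seed.
#' @param n_genes Number of genes / coding sequences.
#' @param cds_len Coding length per gene in nt (>= 48, multiple of 3).
#' @param intergenic Background nucleotides between genes.
#' @param strands Strand per gene, recycled (default all `+`, so every
#'   coding sequence is a forward substring of the genome).
#' @return A list of class `toy_reference`: `genome`, `ccds` (with genomic
#'   placement), `proteome`, `seed`.
#' @export
make_toy_reference <- function(seed = 1L, n_genes = 5L, cds_len = 300L,
                               intergenic = 150L, strands = "+") {
  stopifnot(cds_len >= 48L, cds_len %% 3L == 0L)
  set.seed(seed)
  strands <- rep_len(strands, n_genes)
  codons <- sense_codons()
  chrom <- "chr1"
  pieces <- character(0)
  cursor <- 0L
  rows <- list()
  for (i in seq_len(n_genes)) {
    spacer <- random_nt(intergenic)
    orf <- paste0("ATG",
                  paste(sample(codons, cds_len / 3L - 2L, replace = TRUE),
                        collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    genomic <- if (strands[i] == "+") orf else revcomp(orf)
    pieces <- c(pieces, spacer, genomic)
    start <- cursor + intergenic + 1L
    end <- start + cds_len - 1L
    cursor <- end
    rows[[i]] <- tibble(
      transcript_id = sprintf("TX%02d", i),
      gene_id = sprintf("GENE%02d", i),
      hgnc_symbol = sprintf("TOY%02d", i),
      nt = orf, chrom = chrom, start = start, end = end,
      strand = strands[i]
    )
  }
  pieces <- c(pieces, random_nt(intergenic))
  ccds <- bind_rows(rows)
  ccds$protein <- translate_cds(ccds$nt)
  structure(list(
    genome = tibble(id = chrom, residues = paste(pieces, collapse = "")),
    ccds = ccds,
    proteome = tibble(id = ccds$transcript_id, residues = ccds$protein),
    seed = seed
  ), class = "toy_reference")
}

#' @export
print.toy_reference <- function(x, ...) {
  cat(sprintf("<toy_reference> seed=%d: %d gene(s), genome %d nt\n",
              x$seed, nrow(x$ccds), sum(nchar(x$genome$residues))))
  invisible(x)
}

reference_indices <- function(ref, k = 16L, cap = 300L) {
  list(presence = kmer_index(ref$ccds$nt, k = k),
       counter = genome_counter(ref$genome, cap = cap, k = k))
}

#' Plant an epitope database with known truth
#'
#' Generates substitution neoepitope records against a toy reference,
#' resampling until the planted conformation yields at least one nullomer
#' that is absent from the toy genome and disjoint from every previously
#' planted record's nullomers. Negative controls are constructed by
#' embedding "decoy" coding records carrying the mutated context into the
#' reference, so every candidate window of the negative record is present
#' in the coding set and the build drops it as having no nullomer.
#'
#' @param ref A [make_toy_reference()] result.
#' @param n_records Positive (recoverable) records to plant.
#' @param n_subs Substitutions per record (1 or 2).
#' @param seed RNG seed.
#' @param epitope_len Peptide length (default 9).
#' @param n_negative Negative-control records.
#' @param k,cap Nullomer word length and genome-occurrence cap.
#' @param max_resample Resampling budget per record before erroring.
#' @return A list of class `toy_epitope_db`: `records` (builder input
#'   tibble), `truth`, and `ref` (the reference, now including any decoy
#'   records).
#' @export
plant_epitope_db <- function(ref, n_records = 10L, n_subs = 1L, seed = 1L,
                             epitope_len = 9L, n_negative = 1L,
                             k = 16L, cap = 300L, max_resample = 500L) {
  stopifnot(inherits(ref, "toy_reference"), n_subs %in% c(1L, 2L))
  set.seed(seed)
  genes <- ref$ccds   # decoys added below never host planted records

  # single-nucleotide neighbours of a codon that change the amino acid
  snv_neighbours <- function(codon) {
    code <- Biostrings::GENETIC_CODE
    wt_aa <- unname(code[codon])
    out <- list()
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (substr(codon, p, p) == b) next
      c2 <- codon
      substr(c2, p, p) <- b
      aa <- unname(code[c2])
      if (aa != "*" && aa != wt_aa) {
        out[[length(out) + 1L]] <- tibble(codon = c2, aa = aa, pos = p)
      }
    }
    if (length(out)) bind_rows(out)
    else tibble(codon = character(), aa = character(), pos = integer())
  }

  # The planted tumour allele differs by one nucleotide per substitution
  # site (the single-nucleotide-variant case the epitope databases
  # describe); the builder still enumerates every codon conformation.
  sample_record <- function() {
    tx <- genes[sample(nrow(genes), 1L), , drop = FALSE]
    plen <- nchar(tx$protein)
    off <- sample(1L:(plen - epitope_len), 1L)   # skip the start codon
    wt <- substr(tx$protein, off + 1L, off + epitope_len)
    sites <- sort(sample(0L:(epitope_len - 1L), n_subs))
    neo <- wt
    planted <- tx$nt
    mut_pos <- integer(n_subs)
    for (j in seq_along(sites)) {
      cs0 <- 3L * (off + sites[j])
      wt_codon <- substr(tx$nt, cs0 + 1L, cs0 + 3L)
      nb <- snv_neighbours(wt_codon)
      if (!nrow(nb)) return(NULL)
      pick <- nb[sample(nrow(nb), 1L), , drop = FALSE]
      substr(neo, sites[j] + 1L, sites[j] + 1L) <- pick$aa
      substr(planted, cs0 + 1L, cs0 + 3L) <- pick$codon
      mut_pos[j] <- cs0 + pick$pos - 1L
    }
    list(tx = tx, offset = off, wt = wt, neo = neo,
         planted_ccds = planted,
         mutated = tibble(ccds_pos = mut_pos, site = sites))
  }

  # negatives first: their decoys become part of the reference the
  # positives are validated against
  negatives <- list()
  decoy_ccds <- list()
  for (i in seq_len(n_negative)) {
    cand <- NULL
    while (is.null(cand)) cand <- sample_record()
    al <- align_epitopes(cand$wt, cand$neo)
    confs <- enumerate_conformations(cand$tx$nt, cand$offset, al)
    for (ci in seq_len(nrow(confs))) {
      mut <- confs$mutated[[ci]]
      lo <- max(0L, min(mut$ccds_pos) - (k - 1L))
      hi <- min(nchar(confs$ccds_nt[ci]), max(mut$ccds_pos) + k)
      decoy_ccds[[length(decoy_ccds) + 1L]] <- tibble(
        transcript_id = sprintf("DECOY%02d_%02d", i, ci),
        gene_id = sprintf("DECOYG%02d", i), hgnc_symbol = NA_character_,
        nt = substr(confs$ccds_nt[ci], lo + 1L, hi),
        chrom = "chr_decoy", start = NA_integer_, end = NA_integer_,
        strand = "+", protein = NA_character_
      )
    }
    negatives[[i]] <- cand
  }
  if (length(decoy_ccds)) {
    decoys <- bind_rows(decoy_ccds)
    spacer <- random_nt(50L)
    decoy_chrom <- paste0(spacer,
                          paste(vapply(seq_len(nrow(decoys)), function(j) {
                            paste0(decoys$nt[j], random_nt(50L))
                          }, character(1)), collapse = ""))
    ref$genome <- bind_rows(ref$genome,
                            tibble(id = "chr_decoy", residues = decoy_chrom))
    # decoys carry mutated context only; genomic placement is synthetic
    decoys$start <- NA_integer_; decoys$end <- NA_integer_
    ref$ccds <- bind_rows(ref$ccds, decoys)
  }

  idx <- reference_indices(ref, k = k, cap = cap)
  used_nullomers <- character(0)
  used_records <- character(0)
  positives <- list()
  for (i in seq_len(n_records)) {
    ok <- FALSE
    for (try in seq_len(max_resample)) {
      cand <- sample_record()
      if (is.null(cand)) next
      key <- paste(cand$wt, cand$neo, cand$tx$transcript_id)
      if (key %in% used_records) next
      al <- align_epitopes(cand$wt, cand$neo)
      nulls <- extract_neoepitope_nullomers(cand$planted_ccds, cand$mutated,
                                            idx$presence, idx$counter)
      if (!nrow(nulls)) next
      if (any(count_occurrences(idx$counter, nulls$nullomer) > 0L)) next
      if (any(nulls$nullomer %in% used_nullomers)) next
      used_nullomers <- c(used_nullomers, nulls$nullomer)
      used_records <- c(used_records, key)
      positives[[i]] <- c(cand, list(alignment = al, nullomers = nulls))
      ok <- TRUE
      break
    }
    if (!ok) {
      abort("could not plant a recoverable epitope record within the resampling budget",
            class = "neonull_fixture_error")
    }
  }

  mk_row <- function(cand, src) {
    tibble(wildtype_peptide = cand$wt, neo_peptide = cand$neo,
           transcript_id = cand$tx$transcript_id, source_db = src,
           gene_id = cand$tx$gene_id, hgnc_symbol = cand$tx$hgnc_symbol,
           gene_function = "toy gene")
  }
  records <- bind_rows(
    purrr::map_dfr(seq_along(positives), function(i) {
      mk_row(positives[[i]], if (i %% 2L) "IEDB" else "TSNAdb")
    }),
    purrr::map_dfr(negatives, mk_row, src = "IEDB")
  )
  truth <- bind_rows(
    purrr::map_dfr(seq_along(positives), function(i) {
      p <- positives[[i]]
      tibble(
        record_id = sprintf("EP%02d", i),
        transcript_id = p$tx$transcript_id,
        protein_offset = p$offset,
        wildtype_peptide = p$wt, neo_peptide = p$neo,
        target_id = paste0(p$tx$transcript_id, ":",
                           site_descriptor(p$offset, p$alignment$substitution_sites)),
        negative = FALSE,
        planted_seq = p$planted_ccds,
        nullomers = list(p$nullomers$nullomer),
        windows = list(p$nullomers$window_start)
      )
    }),
    purrr::map_dfr(seq_along(negatives), function(i) {
      p <- negatives[[i]]
      tibble(record_id = sprintf("NEG%02d", i),
             transcript_id = p$tx$transcript_id,
             protein_offset = p$offset,
             wildtype_peptide = p$wt, neo_peptide = p$neo,
             target_id = NA_character_, negative = TRUE,
             planted_seq = NA_character_,
             nullomers = list(character(0)), windows = list(integer(0)))
    })
  )
  structure(list(records = records, truth = truth, ref = ref,
                 k = k, cap = cap, seed = seed),
            class = "toy_epitope_db")
}

#' Plant a fusion junction database with known truth
#'
#' Chooses gene pairs and in-frame coding breakpoints (alternating
#' between-codon and mid-codon phases), resampling until each junction
#' carries at least `min_nullomers` junction-spanning nullomers that are
#' absent from the toy genome and disjoint across junctions.
#'
#' @param ref A [make_toy_reference()] result (decoy-extended refs work
#'   too).
#' @param n_fusions Junctions to plant.
#' @param seed RNG seed.
#' @param flank Flank length per partner for the fused targets.
#' @param k,cap Nullomer length and genome-occurrence cap.
#' @param min_nullomers Minimum surviving junction nullomers per fusion.
#' @param max_resample Resampling budget.
#' @return A list of class `toy_fusion_db`: `junctions` (builder input),
#'   `truth`, `cds_anno`.
#' @export
plant_fusion_db <- function(ref, n_fusions = 3L, seed = 1L, flank = 500L,
                            k = 16L, cap = 300L, min_nullomers = 2L,
                            max_resample = 500L) {
  stopifnot(inherits(ref, "toy_reference"))
  set.seed(seed)
  idx <- reference_indices(ref, k = k, cap = cap)
  placed <- ref$ccds[!is.na(ref$ccds$start), , drop = FALSE]
  cds_anno <- placed %>% select("gene_id", "chrom", "start", "end",
                                "strand", "nt")
  used <- character(0)
  out <- list(); truth <- list()
  for (i in seq_len(n_fusions)) {
    phase_mid <- i %% 2L == 0L   # alternate between-codon / mid-codon
    ok <- FALSE
    for (try in seq_len(max_resample)) {
      gi <- sample(nrow(placed), 2L)
      g5 <- placed[gi[1], ]; g3 <- placed[gi[2], ]
      len5 <- nchar(g5$nt); len3 <- nchar(g3$nt)
      u_lo <- 21L; u_hi <- len5 - 21L
      u <- sample(seq.int(u_lo, u_hi), 1L)
      u <- u - u %% 3L + if (phase_mid) 1L else 0L   # set junction phase
      vmods <- seq.int(21L, len3 - 45L)
      vmods <- vmods[vmods %% 3L == u %% 3L]          # keep 3' gene in frame
      v <- sample(vmods, 1L)
      pos5 <- if (g5$strand == "+") g5$start + u - 1L else g5$end - u + 1L
      pos3 <- if (g3$strand == "+") g3$start + v else g3$end - v
      jx <- tibble(fusion_id = sprintf("FUS%02d", i),
                   chrom5 = g5$chrom, pos5 = pos5, strand5 = g5$strand,
                   chrom3 = g3$chrom, pos3 = pos3, strand3 = g3$strand,
                   gene5 = g5$gene_id, gene3 = g3$gene_id,
                   gene_function = "toy fusion")
      fused <- build_fused_sequence(ref$genome, jx, flank = flank)
      nulls <- extract_junction_nullomers(fused, idx$presence, idx$counter)
      if (nrow(nulls) < min_nullomers) next
      if (any(count_occurrences(idx$counter, nulls$nullomer) > 0L)) next
      if (any(nulls$nullomer %in% used)) next
      peps <- scan_junction_neoepitopes(fused, jx, cds_anno, ref$proteome)
      used <- c(used, nulls$nullomer)
      out[[i]] <- jx
      truth[[i]] <- tibble(
        fusion_id = jx$fusion_id,
        junction_offset = fused$junction_offset,
        phase = u %% 3L,
        planted_seq = fused$nt,
        nullomers = list(nulls$nullomer),
        windows = list(nulls$window_start),
        n_junction_peptides = nrow(peps$peptides)
      )
      ok <- TRUE
      break
    }
    if (!ok) {
      abort("could not plant a fusion junction within the resampling budget",
            class = "neonull_fixture_error")
    }
  }
  structure(list(junctions = bind_rows(out), truth = bind_rows(truth),
                 cds_anno = cds_anno, flank = flank, seed = seed),
            class = "toy_fusion_db")
}

#' Simulate stranded paired-end reads over planted targets
#'
#' Fragments are drawn from each planted (mutated or fused) sequence so
#' that mate 1 (sense) fully contains a known nullomer window -- and, for
#' fusions, at least `flank_margin` bases on each side of the junction.
#' Fragment start positions are distinct so duplicate removal keeps all
#' planted pairs. Background pairs are drawn from unmutated coding
#' sequences. Base qualities are constant `I` (Q40) and, at the default
#' error rate of zero, reads carry no indels, so aligned length plus
#' soft-clips equals read length exactly.
#'
#' @param ref A [make_toy_reference()] result.
#' @param epitope_truth,fusion_truth Truth tibbles from [plant_epitope_db()]
#'   / [plant_fusion_db()] (either may be `NULL`).
#' @param coverage_per_target Planted read pairs per target: a single
#'   number, or a named vector keyed by `record_id` / `fusion_id`.
#' @param read_len,frag_len Read and fragment length (`frag_len >=
#'   read_len`).
#' @param error_rate Per-base substitution error probability.
#' @param n_background Background pairs per coding sequence.
#' @param seed RNG seed.
#' @return A list of class `toy_reads`: `pairs` (read-pair tibble) and
#'   `expected` (per-target planted pair counts).
#' @export
simulate_reads <- function(ref, epitope_truth = NULL, fusion_truth = NULL,
                           coverage_per_target = 6L, read_len = 100L,
                           frag_len = 160L, error_rate = 0, seed = 1L,
                           n_background = 3L) {
  stopifnot(frag_len >= read_len)
  set.seed(seed)
  cov_for <- function(id) {
    if (!is.null(names(coverage_per_target))) {
      as.integer(coverage_per_target[[id]] %||% 0L)
    } else as.integer(coverage_per_target)
  }
  add_errors <- function(s) {
    if (error_rate <= 0) return(s)
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < error_rate)
    for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    paste(ch, collapse = "")
  }
  pairs <- list(); expected <- list()
  emit <- function(prefix, src, starts, L) {
    purrr::map_dfr(seq_along(starts), function(j) {
      s <- starts[j]
      frag <- substr(src, s + 1L, min(L, s + frag_len))
      m1 <- add_errors(substr(frag, 1L, read_len))
      m2 <- add_errors(revcomp(substr(frag, nchar(frag) - read_len + 1L,
                                      nchar(frag))))
      tibble(read_id = sprintf("%s_f%03d", prefix, s),
             seq1 = m1, seq2 = m2,
             qual1 = strrep("I", read_len), qual2 = strrep("I", read_len))
    })
  }
  plant <- function(truth_row, prefix, kind) {
    src <- truth_row$planted_seq
    L <- nchar(src)
    w <- truth_row$windows[[1]][1]
    k <- nchar(truth_row$nullomers[[1]][1])
    lo <- max(0L, w + k - read_len)
    hi <- min(w, L - read_len)
    if (kind == "fusion") {
      jo <- truth_row$junction_offset
      lo <- max(lo, jo + 5L - read_len)
      hi <- min(hi, jo - 5L)
    }
    ncov <- cov_for(truth_row[[1]])
    if (ncov < 1L) return(NULL)
    if (hi < lo) {
      abort("read length too short to contain the planted window",
            class = "neonull_fixture_error")
    }
    starts <- sort(sample(seq.int(lo, hi),
                          min(ncov, hi - lo + 1L)))
    pairs[[length(pairs) + 1L]] <<- emit(prefix, src, starts, L)
    expected[[length(expected) + 1L]] <<- tibble(
      id = truth_row[[1]], kind = kind,
      target_id = if (kind == "fusion") truth_row$fusion_id
                  else truth_row$target_id,
      planted_pairs = length(starts))
  }
  if (!is.null(epitope_truth)) {
    pos <- epitope_truth[!epitope_truth$negative, , drop = FALSE]
    for (i in seq_len(nrow(pos))) {
      plant(pos[i, ], prefix = pos$record_id[i], kind = "neoepitope")
    }
  }
  if (!is.null(fusion_truth)) {
    for (i in seq_len(nrow(fusion_truth))) {
      plant(fusion_truth[i, ], prefix = fusion_truth$fusion_id[i],
            kind = "fusion")
    }
  }
  placed <- ref$ccds[!is.na(ref$ccds$start), , drop = FALSE]
  for (i in seq_len(nrow(placed))) {
    src <- placed$nt[i]; L <- nchar(src)
    if (L < frag_len || n_background < 1L) next
    starts <- sample(seq.int(0L, L - frag_len), min(n_background, L - frag_len))
    pairs[[length(pairs) + 1L]] <- emit(
      sprintf("BG_%s", placed$transcript_id[i]), src, starts, L)
  }
  structure(list(
    pairs = if (length(pairs)) bind_rows(pairs) else
      tibble(read_id = character(), seq1 = character(), seq2 = character(),
             qual1 = character(), qual2 = character()),
    expected = if (length(expected)) bind_rows(expected) else
      tibble(id = character(), kind = character(), target_id = character(),
             planted_pairs = integer()),
    read_len = read_len, frag_len = frag_len, seed = seed
  ), class = "toy_reads")
}
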