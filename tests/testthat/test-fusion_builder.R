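test_that("fused sequences are sliced and oriented per strand, truncated at ends", {
  set.seed(3)
  g <- tibble::tibble(id = c("cA", "cB"),
                      residues = c(random_seq(40), random_seq(40)))
  jx <- tibble::tibble(fusion_id = "F1", chrom5 = "cA", pos5 = 20L,
                       strand5 = "+", chrom3 = "cB", pos3 = 11L,
                       strand3 = "+")
  f <- build_fused_sequence(g, jx, flank = 6)
  expect_equal(f$nt, paste0(substr(g$residues[1], 15, 20),
                            substr(g$residues[2], 11, 16)))
  expect_equal(f$junction_offset, 6L)

  # minus-strand 5' partner contributes the reverse complement
  jx_m <- dplyr::mutate(jx, strand5 = "-")
  f_m <- build_fused_sequence(g, jx_m, flank = 6)
  expect_equal(substr(f_m$nt, 1, 6), revcomp(substr(g$residues[1], 20, 25)))

  # minus-strand 3' partner
  jx_m3 <- dplyr::mutate(jx, strand3 = "-")
  f_m3 <- build_fused_sequence(g, jx_m3, flank = 6)
  expect_equal(substr(f_m3$nt, 7, 12), revcomp(substr(g$residues[2], 6, 11)))

  # truncation at the chromosome start: only 3 nt available upstream
  jx_t <- dplyr::mutate(jx, pos5 = 3L)
  expect_equal(build_fused_sequence(g, jx_t, flank = 6)$junction_offset, 3L)

  jx_bad <- dplyr::mutate(jx, pos5 = 99L)
  expect_error(build_fused_sequence(g, jx_bad, flank = 6),
               class = "neonull_record_error")
})

test_that("junction windows are the k-1 straddling windows, filtered by presence", {
  set.seed(9)
  # empty coding set: every straddling window is a nullomer
  empty_presence <- kmer_index(character(0), 16)
  counter <- genome_counter(random_seq(100), cap = 300, k = 16)
  g <- tibble::tibble(id = "c", residues = random_seq(1200))
  jx <- tibble::tibble(fusion_id = "F", chrom5 = "c", pos5 = 500L,
                       strand5 = "+", chrom3 = "c", pos3 = 700L,
                       strand3 = "+")
  fused <- build_fused_sequence(g, jx, flank = 500)
  expect_equal(fused$junction_offset, 500L)
  nulls <- extract_junction_nullomers(fused, empty_presence, counter)
  expect_equal(nrow(nulls), 15L)
  expect_equal(nulls$window_start, seq(485L, 499L))

  # a fused sequence equal to an unbroken coding region has no nullomers
  ccds <- random_seq(200)
  presence <- kmer_index(ccds, 16)
  unbroken <- structure(list(nt = substr(ccds, 1, 120), junction_offset = 60L,
                             flank_requested = 60L, fusion_id = "U"),
                        class = "fused_sequence")
  expect_equal(nrow(extract_junction_nullomers(unbroken, presence, counter)),
               0L)
})

test_that("every junction nullomer straddles the junction", {
  for (i in seq_len(nrow(toy$fu$truth))) {
    tr <- toy$fu$truth[i, ]
    jo <- tr$junction_offset
    side5 <- substr(tr$planted_seq, 1, jo)
    side3 <- substr(tr$planted_seq, jo + 1, nchar(tr$planted_seq))
    for (w in tr$nullomers[[1]]) {
      expect_true(stringi::stri_detect_fixed(tr$planted_seq, w))
      # removing either side's contribution removes the match
      expect_false(stringi::stri_detect_fixed(side5, w))
      expect_false(stringi::stri_detect_fixed(side3, w))
    }
  }
})

test_that("junction peptide counts are 8 between codons and 9 mid-codon, all phases", {
  # one synthetic gene pair per phase; empty proteome so no peptide is
  # filtered and the combinatorics are visible
  set.seed(21)
  codons <- neonull:::sense_codons()
  mk_cds <- function(n) paste0("ATG", paste(sample(codons, n, replace = TRUE),
                                            collapse = ""), "TAA")
  for (phase in 0:2) {
    cdsA <- mk_cds(40); cdsB <- mk_cds(40)
    u <- 60L + phase                      # 5' nt retained, junction phase
    v <- 33L + phase                      # same phase: 3' gene in frame
    genome <- tibble::tibble(id = "c", residues = paste0(cdsA, cdsB))
    anno <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "c",
                           start = c(1L, nchar(cdsA) + 1L),
                           end = c(nchar(cdsA), nchar(cdsA) + nchar(cdsB)),
                           strand = "+", nt = c(cdsA, cdsB))
    jx <- tibble::tibble(fusion_id = "F", chrom5 = "c", pos5 = u,
                         strand5 = "+", chrom3 = "c",
                         pos3 = nchar(cdsA) + v + 1L, strand3 = "+",
                         gene5 = "gA", gene3 = "gB")
    fused <- build_fused_sequence(genome, jx, flank = 50)
    res <- scan_junction_neoepitopes(fused, jx, anno,
                                     character(0))
    expect_equal(nrow(res$peptides), if (phase == 0) 8L else 9L,
                 info = sprintf("phase %d", phase))
    expect_true(all(res$peptides$frame == phase))
    expect_true(is.na(res$reason))
  }
})

test_that("junction scan refuses out-of-frame, start-codon and non-coding junctions", {
  set.seed(22)
  codons <- neonull:::sense_codons()
  cdsA <- paste0("ATG", paste(sample(codons, 40, replace = TRUE), collapse = ""), "TAA")
  cdsB <- paste0("ATG", paste(sample(codons, 40, replace = TRUE), collapse = ""), "TAA")
  genome <- tibble::tibble(id = "c", residues = paste0(cdsA, cdsB))
  anno <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "c",
                         start = c(1L, nchar(cdsA) + 1L),
                         end = c(nchar(cdsA), nchar(cdsA) + nchar(cdsB)),
                         strand = "+", nt = c(cdsA, cdsB))
  base <- tibble::tibble(fusion_id = "F", chrom5 = "c", pos5 = 60L,
                         strand5 = "+", chrom3 = "c",
                         pos3 = nchar(cdsA) + 34L, strand3 = "+",
                         gene5 = "gA", gene3 = "gB")
  fused <- build_fused_sequence(genome, base, flank = 50)

  shifted <- dplyr::mutate(base, pos3 = pos3 + 1L)   # breaks the frame
  expect_equal(scan_junction_neoepitopes(
    build_fused_sequence(genome, shifted, flank = 50), shifted, anno,
    character(0))$reason, "frame shift")

  early <- dplyr::mutate(base, pos5 = 2L)            # inside the start codon
  expect_equal(scan_junction_neoepitopes(
    build_fused_sequence(genome, early, flank = 50), early, anno,
    character(0))$reason, "start codon overlap")

  nc <- dplyr::mutate(base, gene5 = "absent")
  expect_equal(scan_junction_neoepitopes(fused, nc, anno,
                                         character(0))$reason,
               "non-coding junction")

  # a "fusion" that reconstructs the original gene yields no neoepitopes
  self <- tibble::tibble(fusion_id = "S", chrom5 = "c", pos5 = 60L,
                         strand5 = "+", chrom3 = "c", pos3 = 61L,
                         strand3 = "+", gene5 = "gA", gene3 = "gA")
  res <- scan_junction_neoepitopes(
    build_fused_sequence(genome, self, flank = 50), self, anno,
    translate_cds(cdsA))
  expect_equal(nrow(res$peptides), 0L)
})

test_that("the fusion mapping build reports, deduplicates, and carries offsets", {
  fm <- toy$fusion_mapping
  expect_equal(glance(fm)$n_recovered, 3L)
  expect_true(all(table(fm$entries$target_id) >= 2))
  dup <- build_fusion_mapping(dplyr::bind_rows(toy$fu$junctions,
                                               toy$fu$junctions[1, ]),
                              toy$ref$genome, toy$idx$presence,
                              toy$idx$counter)
  expect_equal(dup$n_input, 3L)
  expect_equal(sort(fm$junction_offsets$fusion_id),
               sort(toy$fu$truth$fusion_id))
  expect_equal(fm$targets$id, toy$fu$truth$fusion_id)
})
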