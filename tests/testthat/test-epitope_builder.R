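test_that("epitope alignment finds substitution sites and indels", {
  # the MUC12 pair: one T>I substitution at epitope position 2
  al <- align_epitopes("STTSGHSEK", "STISGHSEK")
  expect_false(al$has_indel)
  expect_equal(al$substitution_sites$pos, 2L)
  expect_equal(al$substitution_sites$wt_aa, "T")
  expect_equal(al$substitution_sites$neo_aa, "I")

  expect_equal(nrow(align_epitopes("AAAA", "AAAA")$substitution_sites), 0L)
  expect_true(align_epitopes("KLMNP", "KLNP")$has_indel)
  expect_error(align_epitopes("", "AA"), class = "neonull_format_error")
})

test_that("classification excludes indels and more than two substitutions", {
  one <- align_epitopes("STTSGHSEK", "STISGHSEK")
  expect_equal(as.character(classify_epitope(one)), "accept")
  two <- align_epitopes("AAAAA", "ACACA")
  expect_equal(as.character(classify_epitope(two)), "accept")
  three <- align_epitopes("AAAAA", "CCCAA")
  expect_equal(as.character(classify_epitope(three)), "exclude")
  indel <- align_epitopes("KLMNP", "KLNP")
  v <- classify_epitope(indel)
  expect_equal(as.character(v), "exclude")
  expect_equal(attr(v, "reason"), "indel")
})

test_that("wildtype location returns all overlapping 0-based offsets", {
  expect_equal(locate_on_ccds("MA", "KMAK"), 1L)
  expect_equal(locate_on_ccds("QQ", "KMAK"), integer())
  expect_equal(locate_on_ccds("AA", "AAA"), c(0L, 1L))
})

test_that("conformation enumeration covers the codon degeneracy product", {
  # T>I at one site: isoleucine has three codons
  ccds <- paste0("ATG", "ACT", "AAA", "TGA")   # M T K *
  al <- align_epitopes("TK", "IK")
  confs <- enumerate_conformations(ccds, 1L, al)
  expect_equal(nrow(confs), 3L)
  expect_setequal(substr(confs$segment_nt, 1, 3), c("ATT", "ATC", "ATA"))
  expect_true(all(vapply(confs$segment_nt, translate_cds, "") == "IK"))

  # two sites I and M: 3 x 1 conformations
  al2 <- align_epitopes("TKT", "IKM")
  ccds2 <- paste0("ATG", "ACT", "AAA", "ACA", "TGA")
  confs2 <- enumerate_conformations(ccds2, 1L, al2)
  expect_equal(nrow(confs2), 3L)

  # zero sites: the wildtype segment itself
  al0 <- align_epitopes("TK", "TK")
  confs0 <- enumerate_conformations(ccds, 1L, al0)
  expect_equal(nrow(confs0), 1L)
  expect_equal(confs0$ccds_nt, ccds)

  # degeneracy-product property over random single-site records
  set.seed(5)
  code <- Biostrings::GENETIC_CODE
  for (rep in 1:20) {
    aa <- sample(setdiff(unique(code), "*"), 2)
    al <- align_epitopes(paste0(aa[1], "K"), paste0(aa[2], "K"))
    cds <- paste0("ATG", codons_for(aa[1])[1], "AAA", "TGA")
    expect_equal(nrow(enumerate_conformations(cds, 1L, al)),
                 length(codons_for(aa[2])))
  }
})

test_that("conformation enumeration rejects untranslatable residues", {
  al <- align_epitopes("TK", "XK")
  expect_error(enumerate_conformations("ATGACTAAATGA", 1L, al),
               class = "neonull_record_error")
})

test_that("mutation-window nullomer extraction matches a brute-force oracle", {
  set.seed(31)
  k <- 16L
  for (rep in 1:5) {
    ccds <- random_seq(120)
    presence <- kmer_index(ccds, k)
    genome <- random_seq(400)
    counter <- genome_counter(genome, cap = 300, k = k)
    p <- sample(20:100, 1)                      # 0-based mutated position
    mut <- ccds
    old <- substr(mut, p + 1, p + 1)
    substr(mut, p + 1, p + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
    got <- extract_neoepitope_nullomers(
      mut, tibble::tibble(ccds_pos = p, site = 0L), presence, counter)
    # oracle: filter all windows of the mutated sequence by first principles
    starts <- seq.int(max(0, p - k + 1), min(p, nchar(mut) - k))
    words <- substring(mut, starts + 1, starts + k)
    keep <- !words %in% naive_kmer_set(ccds, k) &
      vapply(words, function(w) naive_occurrences(w, genome), integer(1)) <= 300
    expect_equal(got$nullomer, unname(words[keep]))
    expect_equal(got$window_start, unname(starts[keep]))
  }
})

test_that("unmutated conformations yield no nullomers and distant sites share no window", {
  ccds <- random_seq(120)
  presence <- kmer_index(ccds, 16)
  counter <- genome_counter(random_seq(200), cap = 300, k = 16)
  expect_equal(nrow(extract_neoepitope_nullomers(
    ccds, tibble::tibble(ccds_pos = integer(), site = integer()),
    presence, counter)), 0L)

  # two mutated bases 20 nt apart can never share a 16-nt window
  mut <- ccds
  for (p in c(40L, 60L)) {
    old <- substr(mut, p + 1, p + 1)
    substr(mut, p + 1, p + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  got <- extract_neoepitope_nullomers(
    mut, tibble::tibble(ccds_pos = c(40L, 60L), site = c(0L, 6L)),
    kmer_index(ccds, 16), counter)
  expect_true(all(vapply(got$sites, length, integer(1)) == 1L))
})

test_that("the mapping build reports drops and deduplicates records", {
  m <- toy$mapping
  expect_s3_class(m, "nullomer_mapping")
  rep <- m$report
  expect_equal(rep$n[rep$reason == "recovered"], 10L)
  expect_equal(rep$n[rep$reason == "no_nullomer"], 1L)

  # an unmappable transcript and a duplicate row are handled gracefully
  recs <- dplyr::bind_rows(
    toy$ep$records,
    toy$ep$records[1, ],
    tibble::tibble(wildtype_peptide = "AAAAAAAAA", neo_peptide = "AAAAWAAAA",
                   transcript_id = "MISSING", source_db = "IEDB",
                   gene_id = NA, hgnc_symbol = NA, gene_function = NA))
  m2 <- build_epitope_mapping(recs, toy$ref$ccds, toy$idx$presence,
                              toy$idx$counter)
  expect_equal(m2$n_input, nrow(toy$ep$records) + 1L)  # duplicate collapsed
  expect_true("transcript_missing" %in% m2$dropped$reason)
  expect_equal(m2$entries, m$entries)
  expect_equal(glance(m)$n_targets, 10L)
})

test_that("every emitted nullomer is sound", {
  entries <- tidy(toy$mapping)
  # absent from the coding k-mer set
  expect_true(all(is_nullomer(toy$idx$presence, entries$nullomer)))
  # within the genome occurrence cap
  expect_true(all(count_occurrences(toy$idx$counter, entries$nullomer) <= 300))
  # present in the planted conformation, absent from the wildtype sequence
  truth <- toy$ep$truth[!toy$ep$truth$negative, ]
  for (i in seq_len(nrow(truth))) {
    nulls <- truth$nullomers[[i]]
    wt_nt <- toy$ref$ccds$nt[toy$ref$ccds$transcript_id ==
                               truth$transcript_id[i]]
    expect_true(all(stringi::stri_detect_fixed(truth$planted_seq[i], nulls)))
    expect_false(any(stringi::stri_detect_fixed(wt_nt, nulls)))
    # the planted single-nucleotide conformation is among the entries
    tgt <- entries[entries$target_id == truth$target_id[i], ]
    expect_true(all(nulls %in% tgt$nullomer))
  }
})
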