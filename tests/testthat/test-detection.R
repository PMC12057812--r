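# deliberately not its own reverse complement, so the strand contract is visible
pattern16 <- "AACCGGTTACGTACGT"

test_that("scanning is strand-aware: forward on mate 1, reverse complement on mate 2", {
  set.seed(2)
  bg <- function() random_seq(50)
  pairs <- tibble::tibble(
    read_id = c("r1", "r2", "r3", "r4"),
    seq1 = c(paste0("AAAA", pattern16, "TT"), bg(), bg(),
             paste0("AAAA", substr(pattern16, 1, 8), "N",
                    substr(pattern16, 10, 16))),
    seq2 = c(bg(), paste0("GG", revcomp(pattern16), "CC"),
             paste0("GG", pattern16, "CC"), bg()))
  hits <- scan_read_pairs(pairs, pattern16)
  expect_equal(hits$read_id, c("r1", "r2"))
  expect_equal(hits$mate, c(1L, 2L))
  expect_equal(hits$offset, c(4L, 2L))
  expect_equal(hits$nullomer, rep(pattern16, 2))
  # r3: forward pattern on mate 2 is the antisense orientation -> ignored
  # r4: N at the pattern site never matches
})

test_that("dictionary scanning equals the naive per-window oracle", {
  set.seed(13)
  patterns <- unique(replicate(12, random_seq(16)))
  pairs <- tibble::tibble(
    read_id = sprintf("r%04d", 1:300),
    seq1 = replicate(300, random_seq(80)),
    seq2 = replicate(300, random_seq(80)))
  # plant forward and reverse-complement occurrences in both mates
  for (i in seq(1, 300, by = 7)) {
    p <- patterns[1 + (i %% length(patterns))]
    substr(pairs$seq1[i], 10, 25) <- p
    substr(pairs$seq2[i], 40, 55) <- revcomp(p)
  }
  expect_equal(sort_hits(scan_read_pairs(pairs, patterns)),
               sort_hits(naive_scan(pairs, patterns)))
})

test_that("the MES line reproduces its anchors and is linear", {
  expect_equal(compute_mes(35), 64)
  expect_equal(compute_mes(150), 277)
  expect_equal(compute_mes(92.5), (64 + 277) / 2)
  # linearity: f(a) + f(b) = 2 f((a+b)/2)
  set.seed(1)
  a <- runif(20, 20, 200); b <- runif(20, 20, 200)
  expect_equal(compute_mes(a) + compute_mes(b), 2 * compute_mes((a + b) / 2))
  # the printed slope is the rounded exact one
  expect_equal(round(filter_config()$mes_slope, 2), 1.85)
  cfg185 <- filter_config(`compat_slope_1.85` = TRUE)
  expect_equal(compute_mes(150, cfg185), 1.85 * 115 + 64)
})

test_that("local alignment scores 2*matches - penalties with soft-clipped ends", {
  set.seed(8)
  target <- random_seq(400)
  # a 35-nt read with one mismatch: 34*2 - 4 = 64, the MES anchor
  read35 <- substr(target, 100, 134)
  substr(read35, 18, 18) <- setdiff(c("A", "C", "G", "T"),
                                    substr(read35, 18, 18))[1]
  rec <- local_align(read35, target)
  expect_equal(rec$alignment_score, 64)
  expect_equal(rec$aligned_length, 35L)
  expect_equal(rec$mapq, 0L)

  # a perfect 150-nt read scores 300
  target150 <- random_seq(200)
  rec2 <- local_align(substr(target150, 20, 169), target150)
  expect_equal(rec2$alignment_score, 300)
  expect_equal(rec2$target_start, 19L)
  expect_equal(rec2$target_end, 169L)

  # unrelated bases at the read ends become soft-clips; the aligned core
  # plus clips add up to the read length
  junk <- strrep("A", 12)
  core <- substr(target, 200, 260)
  rec3 <- local_align(paste0(junk, core), target)
  expect_equal(rec3$softclip_left + rec3$aligned_length +
                 rec3$softclip_right, rec3$read_length)
  expect_gte(rec3$softclip_left, 10L)
})

test_that("duplicate removal keeps the best pair per fragment and is idempotent", {
  rec <- function(id, key, q) {
    tibble::tibble(read_id = id, mate = 1:2, fragment_key = key,
                   qual_sum = c(q, q))
  }
  x <- dplyr::bind_rows(rec("a", "t:0-100:FR", 50), rec("b", "t:0-100:FR", 45))
  expect_equal(unique(deduplicate(x)$read_id), "a")
  # ties keep the first pair in input order
  y <- dplyr::bind_rows(rec("m", "t:0-100:FR", 50), rec("n", "t:0-100:FR", 50))
  expect_equal(unique(deduplicate(y)$read_id), "m")
  # distinct fragments both survive
  z <- dplyr::bind_rows(rec("a", "t:0-100:FR", 50), rec("b", "t:5-105:FR", 10))
  expect_equal(sort(unique(deduplicate(z)$read_id)), c("a", "b"))
  # three duplicates leave exactly one survivor; idempotence
  w <- dplyr::bind_rows(rec("a", "k", 10), rec("b", "k", 30), rec("c", "k", 20))
  expect_equal(unique(deduplicate(w)$read_id), "b")
  expect_equal(deduplicate(deduplicate(w)), deduplicate(w))
})

base_rec <- function(...) {
  defaults <- list(read_id = "r", mate = 1L, target_id = "t",
                   target_start = 0L, target_end = 100L,
                   aligned_length = 100L, alignment_score = 200,
                   mapq = 0L, softclip_left = 0L, softclip_right = 0L,
                   read_length = 100L, qual_sum = 4000L,
                   fragment_key = "t:0-100:FR")
  do.call(tibble::tibble, utils::modifyList(defaults, list(...)))
}

test_that("neoepitope filters implement the soft-clip, MAPQ and MES rules", {
  # soft-clip boundary: exactly 1/3 retained, above removed
  at_third <- base_rec(read_length = 150L, softclip_left = 50L,
                       aligned_length = 100L, alignment_score = 200)
  expect_true(passes_neoepitope_filters(at_third)$pass)
  above <- base_rec(read_length = 150L, softclip_left = 51L,
                    aligned_length = 99L, alignment_score = 198)
  flt <- passes_neoepitope_filters(above)
  expect_false(flt$pass)
  expect_equal(flt$reason, "softclip_fraction")

  # the AS anchor passes non-strictly; strict mode rejects it
  anchor <- base_rec(aligned_length = 35L, alignment_score = 64,
                     read_length = 35L, target_end = 35L)
  expect_true(passes_neoepitope_filters(anchor)$pass)
  expect_false(passes_neoepitope_filters(
    anchor, filter_config(strict_mes = TRUE))$pass)

  # the MAPQ branch rescues low-scoring reads only above 10
  low_as <- base_rec(aligned_length = 35L, alignment_score = 60,
                     read_length = 35L, mapq = 42L)
  expect_true(passes_neoepitope_filters(low_as)$pass)
  expect_true(passes_neoepitope_filters(
    dplyr::mutate(low_as, mapq = 11L))$pass)
  expect_false(passes_neoepitope_filters(
    dplyr::mutate(low_as, mapq = 10L))$pass)
})

test_that("fusion filters add the junction-flank rule and MAPQ > 30", {
  jo <- tibble::tibble(fusion_id = "t", junction_offset = 500L)
  ok <- base_rec(target_start = 495L, target_end = 530L,
                 aligned_length = 35L, alignment_score = 70,
                 read_length = 35L)
  expect_true(passes_fusion_filters(ok, jo)$pass)
  short5 <- dplyr::mutate(ok, target_start = 496L, aligned_length = 34L)
  flt <- passes_fusion_filters(short5, jo)
  expect_false(flt$pass)
  expect_equal(flt$reason, "junction_flank")

  lowas <- base_rec(target_start = 480L, target_end = 515L,
                    aligned_length = 35L, alignment_score = 50,
                    read_length = 35L, mapq = 31L)
  expect_true(passes_fusion_filters(lowas, jo)$pass)
  expect_false(passes_fusion_filters(dplyr::mutate(lowas, mapq = 30L),
                                     jo)$pass)
})

test_that("filters are monotone in alignment score and soft-clipping", {
  set.seed(17)
  jo <- tibble::tibble(fusion_id = "t", junction_offset = 50L)
  for (rep in 1:50) {
    al <- sample(20:100, 1)
    sc <- sample(0:40, 1)
    rec <- base_rec(target_start = 10L, target_end = 10L + al,
                    aligned_length = al, read_length = al + sc,
                    softclip_left = sc,
                    alignment_score = runif(1, 0, 250),
                    mapq = sample(0:40, 1))
    up <- dplyr::mutate(rec, alignment_score = alignment_score + runif(1, 0, 50))
    expect_true(!passes_neoepitope_filters(rec)$pass |
                  passes_neoepitope_filters(up)$pass)
    expect_true(!passes_fusion_filters(rec, jo)$pass |
                  passes_fusion_filters(up, jo)$pass)
    more_clip <- dplyr::mutate(rec, softclip_left = softclip_left + 20L,
                               read_length = read_length + 20L)
    expect_true(passes_neoepitope_filters(rec)$pass |
                  !passes_neoepitope_filters(more_clip)$pass)
  }
})

test_that("coverage aggregation follows the most-covered-nullomer rule", {
  entries <- tibble::tibble(
    target_kind = "neoepitope", target_id = c("T1", "T1"),
    target_seq = "tx1", nullomer = c("n1", "n2"), neoepitopes = "PEPTIDE")
  mk_hits <- function(n, nullomer, start = 0) {
    tibble::tibble(read_id = sprintf("r%d", start + seq_len(n)), mate = 1L,
                   nullomer = nullomer, offset = 0L)
  }
  hits <- dplyr::bind_rows(mk_hits(4, "n1"), mk_hits(2, "n2", start = 10))
  recs <- tibble::tibble(read_id = hits$read_id, mate = 1L,
                         target_id = "tx1")
  cov <- aggregate_coverage(hits, recs, entries)
  expect_equal(nrow(cov), 1L)
  expect_equal(cov$mapped_reads, 4L)
  expect_equal(cov$best_nullomer, "n1")
  expect_equal(cov$n_nullomers_detected, 2L)
  expect_true(cov$pass)

  # two surviving reads sit below the >= 3 threshold
  cov2 <- aggregate_coverage(mk_hits(2, "n1"),
                             tibble::tibble(read_id = c("r1", "r2"),
                                            mate = 1L, target_id = "tx1"),
                             entries)
  expect_false(cov2$pass)
  expect_equal(cov2$fail_reason, "below_min_reads")

  # a fusion with three reads but a single distinct nullomer fails
  fent <- dplyr::mutate(entries[1, ], target_kind = "fusion")
  cov3 <- aggregate_coverage(mk_hits(3, "n1"),
                             tibble::tibble(read_id = sprintf("r%d", 1:3),
                                            mate = 1L, target_id = "tx1"),
                             fent)
  expect_false(cov3$pass)
  expect_equal(cov3$fail_reason, "below_min_nullomers")

  # reads aligned to a different target count for nothing
  cov4 <- aggregate_coverage(mk_hits(4, "n1"),
                             tibble::tibble(read_id = sprintf("r%d", 1:4),
                                            mate = 1L, target_id = "elsewhere"),
                             entries)
  expect_equal(nrow(cov4), 0L)
})

test_that("max nullomers per read counts co-occurring nullomers on one read", {
  entries <- tibble::tibble(
    target_kind = "neoepitope", target_id = "T1", target_seq = "tx1",
    nullomer = c("n1", "n2", "n3"), neoepitopes = "P")
  hits <- tibble::tibble(read_id = c("a", "a", "a", "b"), mate = 1L,
                         nullomer = c("n1", "n2", "n3", "n1"),
                         offset = 0L)
  recs <- tibble::tibble(read_id = c("a", "b"), mate = 1L, target_id = "tx1")
  cov <- aggregate_coverage(hits, recs, entries)
  expect_equal(cov$max_nullomers_per_read, 3L)
  expect_equal(cov$mapped_reads, 2L)
})

test_that("external SAM alignments reproduce the built-in path on clean reads", {
  reads <- simulate_reads(toy$ref, toy$ep$truth, NULL,
                          coverage_per_target = 4, seed = 3,
                          n_background = 0)
  entries <- toy$mapping$entries
  hits <- scan_read_pairs(reads$pairs, unique(entries$nullomer))
  recs <- neonull:::align_hit_pairs(reads$pairs, hits, entries,
                                    toy$ccds_targets)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(recs, reads$pairs, toy$ccds_targets, sam)
  back <- read_sam_records(sam)
  merged <- dplyr::inner_join(
    recs, back, by = c("read_id", "mate"), suffix = c("", ".sam"))
  expect_equal(nrow(merged), nrow(recs))
  expect_equal(merged$target_id, merged$target_id.sam)
  expect_equal(merged$target_start, merged$target_start.sam)
  expect_equal(merged$aligned_length, merged$aligned_length.sam)
  expect_equal(merged$alignment_score, merged$alignment_score.sam)
  expect_equal(merged$softclip_left, merged$softclip_left.sam)
  expect_equal(merged$qual_sum, merged$qual_sum.sam)
  # identical filter decisions and coverage either way
  cov_builtin <- aggregate_coverage(
    hits, dplyr::filter(passes_neoepitope_filters(deduplicate(recs)), pass),
    entries)
  cov_sam <- aggregate_coverage(
    hits, dplyr::filter(passes_neoepitope_filters(deduplicate(back)), pass),
    entries)
  expect_equal(cov_builtin, cov_sam)
})

test_that("detection handles empty input and missing targets gracefully", {
  empty <- tibble::tibble(read_id = character(), seq1 = character(),
                          seq2 = character(), qual1 = character(),
                          qual2 = character())
  det <- detect(empty, neo_mapping = toy$mapping,
                ccds_targets = toy$ccds_targets)
  expect_equal(nrow(tidy(det, "neoepitope")), 0L)
  expect_error(detect(empty, neo_mapping = toy$mapping),
               class = "neonull_config_error")
})
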