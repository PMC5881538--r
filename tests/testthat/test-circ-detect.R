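test_that("segment pairing applies the retention rules", {
  seg <- function(rid, rs, re, chrom, strand, gs) {
    tibble::tibble(read_id = rid, read_start = rs, read_end = re,
                   chrom = chrom, strand = strand,
                   g_start = gs, g_end = gs + (re - rs),
                   mismatches = 0L, score = re - rs)
  }
  # prefix downstream, suffix upstream: head-to-tail, span 4050
  s1 <- dplyr::bind_rows(seg("r1", 0, 25, "chr1", "+", 5000),
                         seg("r1", 25, 50, "chr1", "+", 1000))
  p1 <- find_segment_pairs(s1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$acceptor_pos, 1000)
  expect_equal(p1$donor_end, 5025)
  expect_lte(p1$span, 1e6)
  # different chromosomes: no candidate
  s2 <- dplyr::bind_rows(seg("r2", 0, 25, "chr1", "+", 5000),
                         seg("r2", 25, 50, "chr2", "+", 1000))
  expect_equal(nrow(find_segment_pairs(s2)), 0)
  # span beyond 1 Mb: no candidate
  s3 <- dplyr::bind_rows(seg("r3", 0, 25, "chr1", "+", 2000025),
                         seg("r3", 25, 50, "chr1", "+", 0))
  expect_equal(nrow(find_segment_pairs(s3)), 0)
  # forward order (ordinary splice): no candidate
  s4 <- dplyr::bind_rows(seg("r4", 0, 25, "chr1", "+", 1000),
                         seg("r4", 25, 50, "chr1", "+", 5000))
  expect_equal(nrow(find_segment_pairs(s4)), 0)
  # opposite strands: no candidate
  s5 <- dplyr::bind_rows(seg("r5", 0, 25, "chr1", "+", 5000),
                         seg("r5", 25, 50, "chr1", "-", 1000))
  expect_equal(nrow(find_segment_pairs(s5)), 0)
})

test_that("pairing matches brute-force rule application on random sets", {
  for (seed in 1:12) {
    segs <- random_segments(12, seed = seed)
    got <- find_segment_pairs(segs)
    want <- brute_pairs(segs)
    key <- function(x) sort(paste(x$read_id, x$chrom, x$strand,
                                  x$acceptor_pos, x$donor_end))
    expect_identical(key(got), key(want), info = paste("seed", seed))
  }
})

test_that("splice scoring is log-odds with the documented arithmetic", {
  # uniform model equals background: every window scores 0
  uni_d <- matrix(0.25, 4, 9, dimnames = list(c("A","C","G","T"), NULL))
  uni_a <- matrix(0.25, 4, 23, dimnames = list(c("A","C","G","T"), NULL))
  sc0 <- splice_scorer(uni_d, uni_a)
  out <- score_splice_sites(sc0, strrep("A", 9), strrep("C", 23))
  expect_equal(out$donor_score, 0)
  expect_equal(out$acceptor_score, 0)
  # hand-computed log-odds: one column at 0.5 adds log2(0.5/0.25) = 1
  d2 <- uni_d
  d2[, 1] <- c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3)
  sc1 <- splice_scorer(d2, uni_a)
  out1 <- score_splice_sites(sc1, paste0("A", strrep("A", 8)),
                             strrep("A", 23))
  expect_equal(out1$donor_score, 1)
  # N in a window gives the -Inf sentinel
  outN <- score_splice_sites(sc0, paste0("N", strrep("A", 8)),
                             strrep("A", 23))
  expect_identical(outN$donor_score, -Inf)
  # window of the wrong width errors
  expect_error(score_splice_sites(sc0, "ACGT", strrep("A", 23)),
               "width")
})

test_that("the trained scorer prefers canonical GT over a mutated site", {
  sc <- small_scenario()
  scorer <- train_splice_scorer(sc$bundle)
  circ <- sc$circles[sc$circles$strand == "+", ][1, ]
  seq <- sc$bundle$sequences[[circ$chrom]]
  dw <- circprofiler:::donor_window(seq, "+", circ$end)
  dw_mut <- paste0(substring(dw, 1, 3), "AA", substring(dw, 6))
  scores <- score_splice_sites(scorer, c(dw, dw_mut),
                               rep(strrep("A", 23), 2))
  expect_gt(scores$donor_score[1], scores$donor_score[2])
})

test_that("junction refinement picks the strongest consistent shift", {
  # junction with micro-homology: genome[a..a+h) == genome[d..d+h) so the
  # candidate can sit anywhere in the run; the motif sits at shift 0
  sc <- small_scenario()
  scorer <- train_splice_scorer(sc$bundle)
  circ <- sc$circles[1, ]
  seq <- sc$bundle$sequences[[circ$chrom]]
  h <- length(circprofiler:::consistent_shift_range(seq, circ$start,
                                                    circ$end, 10L))
  for (s in circprofiler:::consistent_shift_range(seq, circ$start,
                                                  circ$end, 10L)) {
    cand <- tibble::tibble(read_id = "r1", chrom = circ$chrom,
                           strand = circ$strand,
                           acceptor_pos = circ$start + s,
                           donor_end = circ$end + s,
                           span = circ$end - circ$start)
    ref <- refine_junctions(cand, sc$bundle, scorer)
    expect_equal(ref$acceptor_pos, circ$start)
    expect_equal(ref$donor_end, circ$end)
  }
  # tie rule: equal scores resolve to the smallest acceptor position
  flat <- splice_scorer(
    matrix(0.25, 4, 9, dimnames = list(c("A","C","G","T"), NULL)),
    matrix(0.25, 4, 23, dimnames = list(c("A","C","G","T"), NULL))
  )
  cand0 <- tibble::tibble(read_id = "r1", chrom = circ$chrom,
                          strand = circ$strand,
                          acceptor_pos = circ$start, donor_end = circ$end,
                          span = circ$end - circ$start)
  ref0 <- refine_junctions(cand0, sc$bundle, flat)
  shifts <- circprofiler:::consistent_shift_range(seq, circ$start,
                                                  circ$end, 10L)
  expect_equal(ref0$acceptor_pos, circ$start + min(shifts))
})

test_that("calling enforces the inclusive support and score thresholds", {
  sc <- small_scenario()
  mkref <- function(n_reads, score) {
    tibble::tibble(
      read_id = sprintf("r%02d", seq_len(n_reads)),
      chrom = "chr1", strand = "+",
      acceptor_pos = 2000L, donor_end = 2600L, span = 600L,
      donor_score = score / 2, acceptor_score = score / 2,
      splice_score = score
    )
  }
  # one read, high score: never reported
  expect_equal(nrow(call_circrnas(mkref(1, 15), sc$bundle)), 0)
  # two reads at exactly the score threshold: reported (>= is inclusive)
  got <- call_circrnas(mkref(2, 10), sc$bundle, min_score = 10)
  expect_equal(nrow(got), 1)
  expect_equal(got$n_backspliced_reads, 2)
  # five reads just under the threshold: not reported
  expect_equal(nrow(call_circrnas(mkref(5, 9.9), sc$bundle)), 0)
  # monotonicity: raising either threshold never increases the call count
  det <- detect_circrnas(sc$aln$unmapped, sc$index, sc$bundle,
                         mismatch_per = Inf)
  n_base <- nrow(det$calls)
  for (mr in c(3L, 5L, 10L)) {
    expect_lte(nrow(call_circrnas(det$refined, sc$bundle, min_reads = mr)),
               n_base)
  }
  for (ms in c(12, 15, 30)) {
    expect_lte(nrow(call_circrnas(det$refined, sc$bundle, min_score = ms)),
               n_base)
  }
})

test_that("known/novel comparison is exact-match only", {
  calls <- tibble::tibble(
    circ_id = c("a", "b", "c"), chrom = "chr1", strand = "+",
    start = c(100L, 200L, 300L), end = c(500L, 600L, 700L),
    n_backspliced_reads = 3L, splice_score = 12,
    host_gene = NA_character_, host_genes = "", exonic_length = 400L
  )
  known <- tibble::tibble(chrom = "chr1", strand = "+",
                          start = c(100L, 201L), end = c(500L, 600L))
  out <- compare_to_known(calls, known)
  expect_equal(out$novelty, c("known", "novel", "novel"))
  # off by one is novel; empty known set means everything is novel
  empty <- known[0, ]
  expect_true(all(compare_to_known(calls, empty)$novelty == "novel"))
  # malformed BED errors with the line number
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t100\tx\t0\t+", "chr1\toops\t200\ty\t0\t+"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("end-to-end detection recovers simulated circles", {
  sc <- small_scenario()
  det <- detect_circrnas(sc$aln$unmapped, sc$index, sc$bundle,
                         mismatch_per = Inf)
  tr <- dplyr::arrange(sc$circles, chrom, start)
  cl <- dplyr::arrange(det$calls, chrom, start)
  expect_equal(nrow(cl), nrow(tr))
  expect_equal(cl$start, tr$start)
  expect_equal(cl$end, tr$end)
  expect_equal(cl$chrom, tr$chrom)
  expect_equal(cl$strand, tr$strand)
  expect_equal(cl$host_gene, tr$host_gene)
  # exonic length equals the truth circumference (exon-bounded circles)
  expect_equal(cl$exonic_length, tr$circ_length)
})
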