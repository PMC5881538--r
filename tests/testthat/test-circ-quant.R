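test_that("the junction construct concatenates circle tail and head", {
  b <- toy_bundle(c(chr1 = paste0(strrep("T", 10), "AAACCCGGG",
                                  strrep("T", 10))))
  calls <- tibble::tibble(circ_id = "c1", chrom = "chr1", strand = "+",
                          start = 10L, end = 19L)
  # circle sequence "AAACCCGGG": last 5 bases then first 5 bases
  ref <- build_pseudo_reference(calls, b, read_length = 6L,
                                min_overhang = 1L)
  expect_equal(ref$junction_sequence, paste0("CCGGG", "AAACC"))
  expect_equal(ref$circ_length, 9L)
  # midpoint base pair is (circle last base, circle first base)
  w <- 5
  expect_equal(substring(ref$junction_sequence, w, w + 1), "GA")
  # circles shorter than one arm wrap around
  ref2 <- build_pseudo_reference(calls, b, read_length = 13L,
                                 min_overhang = 1L)
  expect_equal(nchar(ref2$junction_sequence), 24L)
  # each 12-nt arm wraps the 9-nt circle
  expect_equal(substring(ref2$junction_sequence, 1, 12), "GGGAAACCCGGG")
  expect_equal(substring(ref2$junction_sequence, 13, 24), "AAACCCGGGAAA")
})

test_that("exonic circles use the spliced sequence, not the intron", {
  sc <- small_scenario()
  circ <- sc$circles[sc$circles$exon_to > sc$circles$exon_from, ][1, ]
  call <- tibble::tibble(circ_id = "c", chrom = circ$chrom,
                         strand = circ$strand, start = circ$start,
                         end = circ$end, host_gene = circ$host_gene)
  ref <- build_pseudo_reference(call, sc$bundle, sc$cfg$read_length)
  cs <- circprofiler:::circle_sequence_from_truth(sc$bundle, circ)
  w <- sc$cfg$read_length - 6L
  expect_equal(ref$junction_sequence,
               paste0(substring(cs, nchar(cs) - w + 1), substring(cs, 1, w)))
  expect_lt(nchar(cs), circ$end - circ$start)  # introns excluded
})

test_that("the overhang rule is sharp at six bases", {
  sc <- small_scenario()
  circ <- sc$circles[1, ]
  call <- tibble::tibble(circ_id = circ$circ_id, chrom = circ$chrom,
                         strand = circ$strand, start = circ$start,
                         end = circ$end, host_gene = circ$host_gene)
  L <- sc$cfg$read_length
  refs <- build_pseudo_reference(call, sc$bundle, L)
  cs <- circprofiler:::circle_sequence_from_truth(sc$bundle, circ)
  n <- nchar(cs)
  mk_read <- function(left) {
    read_tbl(sprintf("ov%d", left),
             circprofiler:::circular_substr(cs, n - left, L))
  }
  # 5 nt on the left of the junction: never counted
  expect_equal(sum(count_junction_reads(refs, mk_read(5))$junction_reads), 0)
  # 6 nt on the left: always counted
  expect_equal(sum(count_junction_reads(refs, mk_read(6))$junction_reads), 1)
  # 5 nt on the right: never counted
  expect_equal(sum(count_junction_reads(refs,
                                        mk_read(L - 5))$junction_reads), 0)
  # entirely on one side of the midpoint: not counted
  linear_read <- read_tbl("lin", substring(cs, 10, 9 + L))
  expect_equal(sum(count_junction_reads(refs, linear_read)$junction_reads),
               0)
})

test_that("counts are exact on simulation, unique, and overhang-monotone", {
  sc <- small_scenario()
  det <- detect_circrnas(sc$aln$unmapped, sc$index, sc$bundle,
                         mismatch_per = Inf)
  refs <- build_pseudo_reference(det$calls, sc$bundle, sc$cfg$read_length)
  cnt <- count_junction_reads(refs, sc$aln$unmapped)
  truth_key <- sprintf("%s:%d-%d:%s", sc$circles$chrom, sc$circles$start,
                       sc$circles$end, sc$circles$strand)
  expect_equal(cnt$junction_reads[match(truth_key, cnt$circ_id)],
               sc$circles$true_junction_reads)
  # no double counting
  expect_lte(sum(cnt$junction_reads), nrow(sc$aln$unmapped))
  # increasing the overhang never increases any count
  prev <- cnt$junction_reads
  for (mo in c(10L, 15L, 20L)) {
    refs_mo <- build_pseudo_reference(det$calls, sc$bundle,
                                      sc$cfg$read_length, min_overhang = mo)
    cnt_mo <- count_junction_reads(refs_mo, sc$aln$unmapped,
                                   min_overhang = mo)
    expect_true(all(cnt_mo$junction_reads <= prev))
    prev <- cnt_mo$junction_reads
  }
})

test_that("summaries report medians, multiplicity and totals", {
  calls <- tibble::tibble(
    circ_id = c("c1", "c2", "c3", "c4"),
    chrom = "chr1", strand = "+",
    start = c(0L, 100L, 200L, 300L), end = c(90L, 190L, 290L, 390L),
    n_backspliced_reads = c(3L, 12L, 2L, 7L),
    splice_score = 15, host_gene = c("g1", "g2", "g2", "g2"),
    host_genes = c("g1", "g2", "g2", "g2"),
    exonic_length = c(100L, 530L, 900L, 530L)
  )
  expr <- tibble::tibble(circ_id = calls$circ_id,
                         junction_reads = c(3L, 12L, 2L, 7L))
  s <- summarize_circ(calls, expr)
  expect_equal(s$summary$median_length, 530)
  expect_equal(s$summary$n_single_circ_genes, 1)
  expect_equal(s$summary$max_multiplicity_gene, "g2")
  expect_equal(s$summary$max_multiplicity, 3)
  expect_equal(s$summary$total_backspliced_reads, sum(expr$junction_reads))
  expect_equal(s$summary$frac_lt10_reads, 0.75)
})
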