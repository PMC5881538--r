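test_that("k-mer lookup returns self-positions and both-strand palindromes", {
  seq <- paste0("ACGTACGTAA", strrep("G", 10), "TTTCCCAAAGGG")
  b <- toy_bundle(c(chr1 = seq))
  idx <- build_kmer_index(b, k = 8)
  # any genomic 8-mer finds its own position
  for (pos in c(0, 5, 12)) {
    kmer <- substring(seq, pos + 1, pos + 8)
    hits <- lookup_kmer(idx, kmer)
    expect_true(any(hits$chrom == "chr1" & hits$pos == pos &
                      hits$strand == "+"))
  }
  expect_equal(nrow(lookup_kmer(idx, "TACGCGAT")), 0)
  # reverse-complement-equal 8-mer hits both strands at the same locus
  hits <- lookup_kmer(idx, "ACGTACGT")
  expect_true(any(hits$pos == 0 & hits$strand == "+"))
  expect_true(any(hits$pos == 0 & hits$strand == "-"))
})

test_that("exonic and junction-spanning reads align as expected", {
  sc <- small_scenario()
  b <- sc$bundle
  # exact exonic substring: one block, zero mismatches
  ex <- b$exons[b$exons$end - b$exons$start >= 80, ][1, ]
  read <- read_tbl("exonic", substring(b$sequences[[ex$chrom]],
                                       ex$start + 11, ex$start + 60))
  res <- align_linear(read, sc$index, max_mismatches = 0L)
  expect_equal(nrow(res$alignments), 1)
  expect_equal(res$alignments$n_blocks, 1)
  expect_equal(res$alignments$mismatches, 0)
  expect_equal(res$alignments$start, ex$start + 10)

  # read spanning an annotated exon-exon junction: two blocks abutting the
  # intron, with coordinates equal to the flanking exon ends
  g <- b$genes$gene_id[b$genes$strand == "+" & b$genes$n_exons >= 2][1]
  exg <- b$exons[b$exons$gene_id == g, ]
  exg <- exg[order(exg$start), ]
  seq <- b$sequences[[exg$chrom[1]]]
  span_read <- paste0(
    substring(seq, exg$end[1] - 24, exg$end[1]),
    substring(seq, exg$start[2] + 1, exg$start[2] + 25)
  )
  res2 <- align_linear(read_tbl("spliced", span_read), sc$index,
                       max_mismatches = 0L)
  expect_equal(res2$alignments$n_blocks, 2)
  expect_equal(res2$alignments$b1_end, exg$end[1])
  expect_equal(res2$alignments$b2_start, exg$start[2])

  # a simulated backsplice-junction read lands in the unmapped pool
  org <- parse_read_origin(sc$reads$read_id)
  circ_ids <- org$read_id[org$origin == "circ"]
  expect_true(all(circ_ids %in% sc$aln$unmapped$read_id))
})

test_that("mapped/unmapped verdicts match a brute-force scan", {
  cfg <- sim_config(seed = 21, n_chromosomes = 1, chrom_length = 15000,
                    n_genes = 3, read_length = 30, n_circles = 1,
                    linear_depth = 4, n_noise = 4)
  b <- generate_genome(cfg)
  ci <- simulate_circles(b, cfg)
  reads <- simulate_reads(b, ci, cfg)
  idx <- build_kmer_index(b, k = 10, read_length = 30L)
  for (mm in c(0L, 1L)) {
    res <- align_linear(reads, idx, max_mismatches = mm)
    for (i in seq_len(nrow(reads))) {
      expect_equal(
        reads$read_id[i] %in% res$alignments$read_id,
        brute_mapped(reads$sequence[i], b, mm),
        info = sprintf("read %s mm=%d", reads$read_id[i], mm)
      )
    }
  }
})

test_that("every clean read is exactly one of mapped or unmapped", {
  sc <- small_scenario()
  expect_equal(nrow(sc$aln$alignments) + nrow(sc$aln$unmapped),
               nrow(sc$reads))
  expect_equal(length(intersect(sc$aln$alignments$read_id,
                                sc$aln$unmapped$read_id)), 0)
})

test_that("region annotation partitions alignments by fixed priority", {
  sc <- small_scenario()
  ann <- annotate_regions(sc$aln$alignments, sc$bundle)
  tally <- region_tally(ann)
  expect_equal(sum(tally$n), nrow(sc$aln$alignments))
  expect_true(all(ann$region %in% tally$region))
  # a read fully inside an internal exon far from gene ends is 'exon'
  g <- sc$bundle$genes[sc$bundle$genes$n_exons >= 4, ][1, ]
  exg <- sc$bundle$exons[sc$bundle$exons$gene_id == g$gene_id, ]
  exg <- exg[order(exg$start), ]
  mid <- exg[2, ]
  inside <- tibble::tibble(
    read_id = "x", chrom = mid$chrom, strand = mid$strand,
    start = mid$start + 5L, end = mid$start + 45L, n_blocks = 1L,
    b1_start = mid$start + 5L, b1_end = mid$start + 45L,
    b2_start = NA_integer_, b2_end = NA_integer_, mismatches = 0L
  )
  if (mid$start - g$start > 1000 && g$end - mid$start > 1050) {
    expect_equal(annotate_regions(inside, sc$bundle)$region, "exon")
  }
  # a read overlapping the transcript start window is TSS regardless
  tss_read <- inside
  tss_pos <- if (g$strand == "+") g$start else g$end
  tss_read$start <- tss_pos - 10L; tss_read$end <- tss_pos + 40L
  tss_read$b1_start <- tss_read$start; tss_read$b1_end <- tss_read$end
  expect_equal(annotate_regions(tss_read, sc$bundle)$region, "TSS")
})

test_that("chromosome tallies preserve totals and order invariance", {
  sc <- small_scenario()
  tal <- chromosome_tally(sc$aln$alignments)
  expect_equal(sum(tal$n), nrow(sc$aln$alignments))
  shuffled <- sc$aln$alignments[sample(nrow(sc$aln$alignments)), ]
  expect_identical(chromosome_tally(shuffled), tal)
  expect_equal(nrow(chromosome_tally(sc$aln$alignments[0, ])), 0)
})
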