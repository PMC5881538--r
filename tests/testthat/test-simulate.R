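test_that("genome generation is deterministic and canonical", {
  cfg <- sim_config(seed = 3, n_chromosomes = 2, chrom_length = 20000,
                    n_genes = 6)
  b1 <- generate_genome(cfg)
  b2 <- generate_genome(cfg)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(b1, f1); write_genome_fasta(b2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # every annotated intron starts GT and ends AG on the gene strand
  for (g in unique(b1$exons$gene_id)) {
    ex <- b1$exons[b1$exons$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) next
    seq <- b1$sequences[[ex$chrom[1]]]
    for (ii in seq_len(nrow(ex) - 1)) {
      intron <- substring(seq, ex$end[ii] + 1, ex$start[ii + 1])
      if (ex$strand[1] == "-") intron <- revcomp(intron)
      expect_identical(substring(intron, 1, 2), "GT")
      expect_identical(substring(intron, nchar(intron) - 1), "AG")
    }
  }
})

test_that("zero genes give an empty annotation but a valid genome", {
  cfg <- sim_config(seed = 1, n_genes = 0, n_chromosomes = 1,
                    chrom_length = 5000)
  b <- generate_genome(cfg)
  expect_equal(nrow(b$genes), 0)
  expect_equal(nrow(b$exons), 0)
  expect_equal(nchar(b$sequences[["chr1"]]), 5000)
})

test_that("an undersized chromosome raises a sizing error", {
  cfg <- sim_config(seed = 1, n_chromosomes = 1, chrom_length = 3000,
                    n_genes = 10)
  expect_error(generate_genome(cfg), "too small to place")
})

test_that("circle truth is exon-bounded with multiplicity and bounded span", {
  sc <- small_scenario()
  circles <- sc$circles
  expect_gte(nrow(circles), 2)
  expect_true(all(circles$end - circles$start <= 1e6))
  expect_true(all(circles$start < circles$end))
  # at least one host gene carries two distinct circles
  expect_gte(max(table(circles$host_gene)), 2)
  expect_equal(nrow(dplyr::distinct(circles, chrom, start, end)),
               nrow(circles))
  for (i in seq_len(nrow(circles))) {
    circ <- circles[i, ]
    ex <- sc$bundle$exons[sc$bundle$exons$gene_id == circ$host_gene, ]
    expect_true(circ$start %in% ex$start)   # acceptor at an exon start
    expect_true(circ$end %in% ex$end)       # donor at an exon end
  }
  # junction flanks carry the canonical dinucleotides on the coding strand:
  # AG on the intron side upstream of the start, GT downstream of the end
  for (i in seq_len(nrow(circles))) {
    circ <- circles[i, ]
    seq <- sc$bundle$sequences[[circ$chrom]]
    if (circ$strand == "+") {
      expect_identical(substring(seq, circ$start - 1, circ$start), "AG")
      expect_identical(substring(seq, circ$end + 1, circ$end + 2), "GT")
    } else {
      expect_identical(substring(seq, circ$start - 1, circ$start),
                       revcomp("GT"))
      expect_identical(substring(seq, circ$end + 1, circ$end + 2),
                       revcomp("AG"))
    }
  }
})

test_that("simulated reads honour the truth encoded in their names", {
  sc <- small_scenario()
  org <- parse_read_origin(sc$reads$read_id)
  # junction reads: exactly true_junction_reads per circle, wrap-around
  tab <- table(org$source[org$origin == "circ"])
  for (i in seq_len(nrow(sc$circles))) {
    circ <- sc$circles[i, ]
    expect_equal(unname(tab[circ$circ_id]), circ$true_junction_reads)
  }
  expect_equal(sum(org$origin == "circ"),
               sum(sc$circles$true_junction_reads))
  # with zero error rate every linear read is a substring of its transcript
  lin <- sc$reads[org$origin == "linear", ]
  lin_org <- org[org$origin == "linear", ]
  for (i in sample(nrow(lin), 20)) {
    tseq <- circprofiler:::transcript_sequence(sc$bundle, lin_org$source[i])
    expect_true(grepl(lin$sequence[i], tseq, fixed = TRUE))
  }
  # junction reads wrap the backsplice with >= 6 nt on each side: the read
  # occurs in the doubled circle sequence but not in the linear transcript
  jr <- sc$reads[org$origin == "circ", ][1:10, ]
  jr_org <- org[org$origin == "circ", ][1:10, ]
  for (i in seq_len(nrow(jr))) {
    circ <- sc$circles[sc$circles$circ_id == jr_org$source[i], ]
    cs <- circprofiler:::circle_sequence_from_truth(sc$bundle, circ)
    expect_true(grepl(jr$sequence[i], strrep(cs, 2), fixed = TRUE))
  }
})

test_that("reads are deterministic given the seed", {
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chrom_length = 15000,
                    n_genes = 4, n_circles = 2, linear_depth = 5)
  b <- generate_genome(cfg)
  ci <- simulate_circles(b, cfg)
  r1 <- simulate_reads(b, ci, cfg)
  r2 <- simulate_reads(b, ci, cfg)
  expect_identical(r1, r2)
})

test_that("a read longer than the circumference is rejected", {
  sc <- small_scenario()
  cfg_long <- sc$cfg
  cfg_long$read_length <- max(sc$circles$circ_length) + 10L
  expect_error(simulate_reads(sc$bundle, sc$circles, cfg_long),
               "circumference")
})

test_that("count simulation spikes and reproduces deterministically", {
  sim0 <- simulate_counts(n_features = 200, dispersion = 0.1, seed = 4)
  expect_equal(nrow(sim0$truth), 0)
  expect_equal(dim(sim0$counts), c(200, 8))
  sim1 <- simulate_counts(n_features = 500, dispersion = 0, seed = 5,
                          fold_changes = 8, mean_sdlog = 0)
  ratio <- {
    sp <- sim1$counts[sim1$counts$feature_id == sim1$truth$feature_id, ]
    mean(as.numeric(sp[1, 6:8])) / mean(as.numeric(sp[1, 3:5]))
  }
  expect_gt(ratio, 4)  # Poisson noise around the 8-fold spike
  expect_identical(simulate_counts(n_features = 100, seed = 6)$counts,
                   simulate_counts(n_features = 100, seed = 6)$counts)
  expect_error(simulate_counts(n_per_condition = 1), ">= 2 samples")
  expect_error(simulate_counts(dispersion = -1), "non-negative")
})

test_that("GTF round-trips through the reader", {
  sc <- small_scenario()
  fa <- tempfile(fileext = ".fa"); gtf <- tempfile(fileext = ".gtf")
  write_genome_fasta(sc$bundle, fa)
  write_annotation_gtf(sc$bundle, gtf)
  b2 <- read_genome_bundle(fa, gtf)
  expect_identical(b2$sequences, sc$bundle$sequences)
  e1 <- dplyr::arrange(sc$bundle$exons, gene_id, start)
  e2 <- dplyr::arrange(b2$exons, gene_id, start)
  expect_equal(e1$start, e2$start)
  expect_equal(e1$end, e2$end)
  expect_equal(e1$exon_rank, e2$exon_rank)
  g1 <- dplyr::arrange(sc$bundle$genes, gene_id)
  g2 <- dplyr::arrange(b2$genes, gene_id)
  expect_equal(g1$biotype, g2$biotype)
  expect_equal(g1$start, g2$start)
})
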