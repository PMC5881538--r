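# Shared fixtures, built once per test run. All synthetic, all seeded.

fixture_env <- new.env(parent = emptyenv())

# a small but complete scenario: genome, circles, reads, index, alignment
small_scenario <- function() {
  if (!is.null(fixture_env$sc)) return(fixture_env$sc)
  cfg <- sim_config(seed = 11, n_chromosomes = 2, chrom_length = 30000,
                    n_genes = 10, exons_per_gene = c(3L, 5L),
                    n_circles = 5, linear_depth = 15, n_noise = 10)
  bundle <- generate_genome(cfg)
  circles <- simulate_circles(bundle, cfg)
  reads <- simulate_reads(bundle, circles, cfg)
  index <- build_kmer_index(bundle, read_length = cfg$read_length)
  aln <- align_linear(reads, index, max_mismatches = 0L)
  fixture_env$sc <- list(cfg = cfg, bundle = bundle, circles = circles,
                         reads = reads, index = index, aln = aln)
  fixture_env$sc
}

# hand-built genome bundle for surgical tests
toy_bundle <- function(sequences, genes = NULL, exons = NULL, utrs = NULL) {
  empty_genes <- tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), biotype = character(),
    n_exons = integer()
  )
  empty_exons <- tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    exon_index = integer(), exon_rank = integer(),
    start = integer(), end = integer()
  )
  empty_utrs <- tibble::tibble(
    gene_id = character(), chrom = character(), strand = character(),
    type = character(), start = integer(), end = integer()
  )
  structure(
    list(sequences = sequences,
         genes = genes %||% empty_genes,
         exons = exons %||% empty_exons,
         utrs = utrs %||% empty_utrs),
    class = "genome_bundle"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_tbl <- function(read_id, sequence, quality = NULL) {
  if (is.null(quality)) quality <- strrep("D", nchar(sequence))
  tibble::tibble(read_id = read_id, sequence = sequence, quality = quality)
}

# brute-force full-length alignment verdict: scan every placement on every
# chromosome (both strands) and every annotated exon-exon junction
brute_mapped <- function(read, bundle, max_mm) {
  L <- nchar(read)
  hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))
  for (ch in names(bundle$sequences)) {
    for (seq in c(bundle$sequences[[ch]], revcomp(bundle$sequences[[ch]]))) {
      n <- nchar(seq)
      if (n < L) next
      subs <- substring(seq, 1:(n - L + 1), L:n)
      if (any(vapply(subs, hamming, numeric(1), b = read) <= max_mm)) {
        return(TRUE)
      }
    }
  }
  for (g in unique(bundle$exons$gene_id)) {
    ex <- bundle$exons[bundle$exons$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) next
    seq <- bundle$sequences[[ex$chrom[1]]]
    for (ii in seq_len(nrow(ex) - 1)) {
      w1 <- min(L - 1, ex$end[ii] - ex$start[ii])
      w2 <- min(L - 1, ex$end[ii + 1] - ex$start[ii + 1])
      cons <- paste0(substring(seq, ex$end[ii] - w1 + 1, ex$end[ii]),
                     substring(seq, ex$start[ii + 1] + 1,
                               ex$start[ii + 1] + w2))
      for (cseq in c(cons, revcomp(cons))) {
        n <- nchar(cseq)
        if (n < L) next
        subs <- substring(cseq, 1:(n - L + 1), L:n)
        if (any(vapply(subs, hamming, numeric(1), b = read) <= max_mm)) {
          return(TRUE)
        }
      }
    }
  }
  FALSE
}

# brute-force application of the junction retention rules to segment pairs
brute_pairs <- function(segments, max_span = 1000000L) {
  out <- list()
  for (rid in unique(segments$read_id)) {
    s <- segments[segments$read_id == rid, ]
    if (nrow(s) < 2) next
    for (i in seq_len(nrow(s))) {
      for (j in seq_len(nrow(s))) {
        if (i == j) next
        a <- s[i, ]; b <- s[j, ]
        if (a$read_start >= b$read_start) next       # A earlier on read
        if (a$read_end > b$read_start) next          # non-overlap on read
        if (a$chrom != b$chrom) next                 # rule (a)
        if (a$strand != b$strand) next               # rule (b)
        rev_order <- if (a$strand == "+") {
          b$g_end <= a$g_start                       # rule (c)
        } else {
          a$g_end <= b$g_start
        }
        if (!rev_order) next
        acc <- if (a$strand == "+") b$g_start else a$g_start
        don <- if (a$strand == "+") a$g_end else b$g_end
        span <- don - acc
        if (span <= 0 || span > max_span) next
        out[[length(out) + 1]] <- tibble::tibble(
          read_id = rid, chrom = a$chrom, strand = a$strand,
          acceptor_pos = as.integer(acc), donor_end = as.integer(don),
          span = as.integer(span)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      read_id = character(), chrom = character(), strand = character(),
      acceptor_pos = integer(), donor_end = integer(), span = integer()
    ))
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

# random segment sets for pairing tests
random_segments <- function(n_reads, seed) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_reads)) {
    nseg <- sample(2:5, 1)
    # non-overlapping read intervals in order, then shuffled genomic homes
    cuts <- sort(sample(0:50, nseg * 2, replace = FALSE))
    starts <- cuts[seq(1, by = 2, length.out = nseg)]
    ends <- cuts[seq(2, by = 2, length.out = nseg)]
    keep <- ends - starts >= 3
    if (!any(keep)) next
    out[[i]] <- tibble::tibble(
      read_id = sprintf("r%03d", i),
      read_start = starts[keep], read_end = ends[keep],
      chrom = sample(c("chr1", "chr2"), sum(keep), replace = TRUE),
      strand = sample(c("+", "-"), sum(keep), replace = TRUE),
      g_start = sample(c(0:5000, 990000:1100000), sum(keep)),
      mismatches = 0L
    )
    out[[i]]$g_end <- out[[i]]$g_start +
      (out[[i]]$read_end - out[[i]]$read_start)
    out[[i]]$score <- out[[i]]$read_end - out[[i]]$read_start
  }
  dplyr::bind_rows(out)
}

# brute-force W-core: union of all vertex subsets whose induced subgraph has
# minimum degree >= W (the W-core is the unique maximal such subset)
brute_w_core <- function(nodes, edges, W) {
  n <- length(nodes)
  best <- character(0)
  for (mask in seq_len(2^n) - 1L) {
    sel <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (length(sel) <= length(best)) next
    sub <- edges[edges$from %in% sel & edges$to %in% sel, ]
    deg <- table(factor(c(sub$from, sub$to), levels = sel))
    if (length(sel) == 0 || all(deg >= W)) {
      best <- sel
    }
  }
  sort(best)
}

random_graph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2])
  network_from_edges(edges, nodes = nodes)
}
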