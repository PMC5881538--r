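# Synthetic-data generator: a toy multi-chromosome genome with multi-exon
# genes (canonical GT/AG introns whose flanks are drawn from consensus-biased
# donor/acceptor motifs), a circRNA truth set with exon-bounded junctions,
# and single-end FASTQ reads: linear transcript reads, backsplice-junction
# reads with controlled overhangs, and optional noise/contaminant reads.
# Everything is a pure function of the configuration (seed included).

# Generator splice-site motif models (columns = positions, rows = A,C,G,T).
# Donor window: 3 exonic + 6 intronic positions with the canonical GT fixed;
# acceptor window: 20 intronic (pyrimidine tract then the canonical AG) + 3
# exonic positions. Annotated sites are drawn from these matrices subject to
# a minimum log-odds strength floor, reflecting that functional splice sites
# are consensus-constrained.
donor_motif <- function() {
  m <- matrix(c(
    0.33, 0.37, 0.18, 0.12,  # -3
    0.60, 0.13, 0.14, 0.13,  # -2
    0.10, 0.05, 0.80, 0.05,  # -1
    0.00, 0.00, 1.00, 0.00,  # +1 G
    0.00, 0.00, 0.00, 1.00,  # +2 T
    0.60, 0.08, 0.25, 0.07,  # +3
    0.70, 0.10, 0.10, 0.10,  # +4
    0.10, 0.05, 0.80, 0.05,  # +5
    0.20, 0.15, 0.15, 0.50   # +6
  ), nrow = 4)
  rownames(m) <- BASES
  m
}

acceptor_motif <- function() {
  tract <- c(0.10, 0.40, 0.10, 0.40)
  near <- c(0.15, 0.35, 0.15, 0.35)
  m <- cbind(
    matrix(rep(tract, 15), nrow = 4),      # -20 .. -6 pyrimidine tract
    matrix(rep(near, 3), nrow = 4),        # -5 .. -3
    c(1, 0, 0, 0),                         # -2 A
    c(0, 0, 1, 0),                         # -1 G
    c(0.25, 0.10, 0.50, 0.15),             # +1
    c(0.25, 0.25, 0.25, 0.25),             # +2
    c(0.25, 0.25, 0.25, 0.25)              # +3
  )
  rownames(m) <- BASES
  m
}

DONOR_STRENGTH_FLOOR <- 6
ACCEPTOR_STRENGTH_FLOOR <- 7

# draw a window from a motif matrix, rejecting draws whose log2-odds score
# (vs a uniform background) falls below `floor`
draw_motif_site <- function(pwm, floor, max_tries = 500L) {
  npos <- ncol(pwm)
  best <- NULL
  best_score <- -Inf
  for (i in seq_len(max_tries)) {
    idx <- vapply(seq_len(npos),
                  function(j) sample.int(4L, 1L, prob = pwm[, j]), integer(1))
    score <- sum(log2(pwm[cbind(idx, seq_len(npos))] / 0.25))
    if (score >= floor) return(BASES[idx])
    if (score > best_score) {
      best <- BASES[idx]
      best_score <- score
    }
  }
  best
}

#' Simulation configuration
#'
#' Defines the toy study: genome geometry, read properties, circRNA truth,
#' and the differential-expression design. The defaults describe a small
#' three-chromosome genome with forty multi-exon genes and a 3-vs-3 count
#' design, mirroring a pooled tumour/normal comparison.
#'
#' @param seed Integer seed; all outputs are pure functions of the
#'   configuration including this seed.
#' @param n_chromosomes,chrom_length Genome geometry (chromosome count and
#'   length in nt).
#' @param n_genes Number of genes to place (round-robin over chromosomes).
#' @param exons_per_gene,exon_length,intron_length Integer ranges
#'   (length-2 vectors) for gene structure; introns must be at least 30 nt so
#'   donor and acceptor motif windows cannot collide.
#' @param mrna_fraction Probability a gene is mRNA (else lncRNA).
#' @param read_length Read length in nt; must be at least `2 * min_overhang`.
#' @param base_error_rate Per-base substitution probability.
#' @param n_fraction Per-base probability of emitting `N`.
#' @param linear_depth Mean reads per transcript (Poisson).
#' @param circ_fraction Fraction of multi-exon genes hosting at least one
#'   circRNA (used when `n_circles` is `NULL`).
#' @param n_circles Exact number of circles to simulate (overrides
#'   `circ_fraction` when given).
#' @param circ_read_range Integer range of junction-spanning reads per circle.
#' @param min_overhang Minimum bases on each side of the backsplice junction
#'   for simulated junction reads (default 6).
#' @param n_noise Number of random (genome-free) reads.
#' @param n_contaminant Number of QC-bait reads carrying excess `N` bases and
#'   a low-quality tail.
#' @param adaptor,adaptor_fraction Optional 3' adaptor contamination: a
#'   fraction of linear reads carries a shortened insert completed with the
#'   adaptor prefix.
#' @param de_design List with `n_per_condition` and `fold_changes` (the
#'   spiked fold-change list) used by [simulate_counts()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_length = 100000L,
                       n_genes = 40L,
                       exons_per_gene = c(3L, 6L),
                       exon_length = c(100L, 300L),
                       intron_length = c(100L, 400L),
                       mrna_fraction = 0.7,
                       read_length = 50L,
                       base_error_rate = 0,
                       n_fraction = 0,
                       linear_depth = 30,
                       circ_fraction = 0.5,
                       n_circles = NULL,
                       circ_read_range = c(2L, 30L),
                       min_overhang = 6L,
                       n_noise = 0L,
                       n_contaminant = 0L,
                       adaptor = "",
                       adaptor_fraction = 0,
                       de_design = list(n_per_condition = 3L,
                                        fold_changes = c(8, 8, 8, 0.125, 0.125))) {
  stopifnot(
    length(exons_per_gene) == 2, exons_per_gene[1] <= exons_per_gene[2],
    length(exon_length) == 2, exon_length[1] <= exon_length[2],
    length(intron_length) == 2, intron_length[1] <= intron_length[2],
    length(circ_read_range) == 2, circ_read_range[1] <= circ_read_range[2],
    base_error_rate >= 0, base_error_rate <= 1,
    n_fraction >= 0, n_fraction <= 1
  )
  if (intron_length[1] < 30) {
    abort("intron_length minimum must be >= 30 nt (motif window geometry)")
  }
  if (exon_length[1] < 20) abort("exon_length minimum must be >= 20 nt")
  if (read_length < 2 * min_overhang) {
    abort("read_length must be >= 2 * min_overhang")
  }
  structure(
    list(
      seed = as.integer(seed),
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length = as.integer(chrom_length),
      n_genes = as.integer(n_genes),
      exons_per_gene = as.integer(exons_per_gene),
      exon_length = as.integer(exon_length),
      intron_length = as.integer(intron_length),
      mrna_fraction = mrna_fraction,
      read_length = as.integer(read_length),
      base_error_rate = base_error_rate,
      n_fraction = n_fraction,
      linear_depth = linear_depth,
      circ_fraction = circ_fraction,
      n_circles = if (is.null(n_circles)) NULL else as.integer(n_circles),
      circ_read_range = as.integer(circ_read_range),
      min_overhang = as.integer(min_overhang),
      n_noise = as.integer(n_noise),
      n_contaminant = as.integer(n_contaminant),
      adaptor = toupper(adaptor),
      adaptor_fraction = adaptor_fraction,
      de_design = de_design
    ),
    class = "sim_config"
  )
}

#' Generate a toy genome and gene annotation
#'
#' Chromosome sequences are uniform random DNA; genes are placed round-robin
#' with random spacing, each a single multi-exon transcript whose introns
#' begin with `GT` and end with `AG` on the coding strand, embedded in
#' consensus-biased donor/acceptor motif windows. mRNA genes receive 5'/3'
#' UTR annotations at the transcript ends.
#'
#' @param config A [sim_config()].
#' @return A `genome_bundle`: list with `sequences` (named character vector),
#'   `genes`, `exons`, and `utrs` tibbles. All coordinates are 0-based
#'   half-open.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  base_vecs <- lapply(chroms, function(ch) {
    sample(BASES, config$chrom_length, replace = TRUE)
  })
  names(base_vecs) <- chroms

  genes <- list()
  exons <- list()
  utrs <- list()
  cursors <- setNames(rep(200L, length(chroms)), chroms)

  if (config$n_genes > 0) {
    don_pwm <- donor_motif()
    acc_pwm <- acceptor_motif()
    for (gi in seq_len(config$n_genes)) {
      chrom <- chroms[(gi - 1L) %% length(chroms) + 1L]
      gene_id <- sprintf("g%03d", gi)
      n_ex <- sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
      ex_lens <- sample(config$exon_length[1]:config$exon_length[2], n_ex,
                        replace = TRUE)
      in_lens <- if (n_ex > 1) {
        sample(config$intron_length[1]:config$intron_length[2], n_ex - 1L,
               replace = TRUE)
      } else integer(0)
      gap <- sample(300:1500, 1L)
      start <- cursors[[chrom]] + gap
      span <- sum(ex_lens) + sum(in_lens)
      if (start + span > config$chrom_length - 200L) {
        abort(sprintf(
          paste0("chrom_length %d is too small to place %d genes: gene %s ",
                 "needs [%d, %d) on %s"),
          config$chrom_length, config$n_genes, gene_id, start, start + span,
          chrom
        ))
      }
      cursors[[chrom]] <- start + span
      strand <- sample(c("+", "-"), 1L)
      biotype <- if (stats::runif(1) < config$mrna_fraction) "mRNA" else "lncRNA"

      ex_starts <- start + cumsum(c(0L, head(ex_lens, -1L) + in_lens))
      ex_ends <- ex_starts + ex_lens

      # embed splice-site motifs at every intron boundary (genomic order)
      if (n_ex > 1) {
        for (ii in seq_len(n_ex - 1L)) {
          don <- draw_motif_site(don_pwm, DONOR_STRENGTH_FLOOR)
          acc <- draw_motif_site(acc_pwm, ACCEPTOR_STRENGTH_FLOOR)
          if (strand == "+") {
            # donor at exon ii end; acceptor at exon ii+1 start
            e <- ex_ends[ii]
            a <- ex_starts[ii + 1L]
            base_vecs[[chrom]][(e - 2L):(e + 6L)] <- don
            base_vecs[[chrom]][(a - 19L):(a + 3L)] <- acc
          } else {
            # transcript runs high -> low: donor at exon ii+1 genomic start,
            # acceptor at exon ii genomic end, reverse-complemented
            p <- ex_starts[ii + 1L]
            e <- ex_ends[ii]
            base_vecs[[chrom]][(p - 5L):(p + 3L)] <- rev(
              chartr("ACGT", "TGCA", don)
            )
            base_vecs[[chrom]][(e - 2L):(e + 20L)] <- rev(
              chartr("ACGT", "TGCA", acc)
            )
          }
        }
      }

      genes[[gi]] <- tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        start = ex_starts[1], end = ex_ends[n_ex],
        biotype = biotype, n_exons = n_ex
      )
      rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      exons[[gi]] <- tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        exon_index = seq_len(n_ex), exon_rank = rank,
        start = ex_starts, end = ex_ends
      )
      if (biotype == "mRNA") {
        u5 <- min(80L, ex_lens[if (strand == "+") 1L else n_ex] - 10L)
        u3 <- min(80L, ex_lens[if (strand == "+") n_ex else 1L] - 10L)
        if (strand == "+") {
          u_start <- c(ex_starts[1], ex_ends[n_ex] - u3)
          u_end <- c(ex_starts[1] + u5, ex_ends[n_ex])
        } else {
          u_start <- c(ex_ends[n_ex] - u5, ex_starts[1])
          u_end <- c(ex_ends[n_ex], ex_starts[1] + u3)
        }
        utrs[[gi]] <- tibble(
          gene_id = gene_id, chrom = chrom, strand = strand,
          type = c("five_utr", "three_utr"),
          start = u_start, end = u_end
        )
      }
    }
  }

  structure(
    list(
      sequences = vapply(base_vecs, paste, character(1), collapse = ""),
      genes = if (length(genes)) bind_rows(genes) else tibble(
        gene_id = character(), chrom = character(), strand = character(),
        start = integer(), end = integer(), biotype = character(),
        n_exons = integer()
      ),
      exons = if (length(exons)) bind_rows(exons) else tibble(
        gene_id = character(), chrom = character(), strand = character(),
        exon_index = integer(), exon_rank = integer(),
        start = integer(), end = integer()
      ),
      utrs = if (length(utrs)) bind_rows(utrs) else tibble(
        gene_id = character(), chrom = character(), strand = character(),
        type = character(), start = integer(), end = integer()
      )
    ),
    class = "genome_bundle"
  )
}

# spliced transcript sequence of a gene (5'->3')
transcript_sequence <- function(bundle, gene_id) {
  ex <- bundle$exons[bundle$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0) abort(sprintf("unknown gene_id %s", gene_id))
  ex <- ex[order(ex$start), , drop = FALSE]
  seqs <- subseq0(bundle$sequences[[ex$chrom[1]]], ex$start, ex$end)
  joined <- paste(seqs, collapse = "")
  if (ex$strand[1] == "-") revcomp(joined) else joined
}

#' Simulate a circRNA truth set
#'
#' Circles are exon-bounded: the acceptor is an exon start and the donor an
#' exon end of the host gene, so junction flanks carry the host's canonical
#' splice sites (AG upstream of the start on the intron side, GT downstream
#' of the end, on the coding strand). When at least two circles are drawn,
#' one host gene receives two distinct circles so per-gene multiplicity is
#' exercised.
#'
#' @param bundle A `genome_bundle` from [generate_genome()].
#' @param config The same [sim_config()].
#' @return Tibble with columns `circ_id`, `host_gene`, `chrom`, `strand`,
#'   `start`, `end`, `exon_from`, `exon_to` (transcript-order exon range),
#'   `circ_length` (exonic circumference) and `true_junction_reads`.
#' @export
simulate_circles <- function(bundle, config) {
  stopifnot(inherits(bundle, "genome_bundle"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  # circle junctions are genuine splice sites, so both boundary exons must
  # have a flanking intron: only internal exons of >= 3-exon genes qualify
  hosts_pool <- bundle$genes$gene_id[bundle$genes$n_exons >= 3]
  if (length(hosts_pool) == 0) {
    abort("no gene with >= 3 exons available to host circles")
  }
  n_circ <- config$n_circles %||%
    max(1L, round(config$circ_fraction * length(hosts_pool)))
  # hosts: first host repeated so one gene gets >= 2 distinct circles
  hosts <- sample(hosts_pool, min(n_circ, length(hosts_pool)))
  if (n_circ >= 2) {
    hosts <- rep(c(hosts[1], hosts), length.out = n_circ)
  }
  out <- list()
  seen <- character(0)
  for (ci in seq_along(hosts)) {
    g <- hosts[ci]
    ex <- bundle$exons[bundle$exons$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    n_ex <- nrow(ex)
    for (try in 1:200) {
      i <- resample(2:(n_ex - 1L))
      j <- resample(i:(n_ex - 1L))
      key <- paste(g, i, j)
      len <- sum(ex$end[i:j] - ex$start[i:j])
      if (!(key %in% seen) && len >= config$read_length) {
        seen <- c(seen, key)
        n_reads <- resample(config$circ_read_range[1]:config$circ_read_range[2])
        strand <- ex$strand[1]
        # transcript-order exon range
        ranks <- ex$exon_rank[i:j]
        out[[length(out) + 1L]] <- tibble(
          circ_id = sprintf("circ_%s_%d", g, sum(vapply(
            out, function(o) o$host_gene == g, logical(1)
          )) + 1L),
          host_gene = g, chrom = ex$chrom[1], strand = strand,
          start = ex$start[i], end = ex$end[j],
          exon_from = min(ranks), exon_to = max(ranks),
          circ_length = len, true_junction_reads = n_reads
        )
        break
      }
    }
  }
  truth <- bind_rows(out)
  stopifnot(all(truth$end - truth$start <= 1e6))
  truth
}

# exonic circle sequence in transcript orientation (5'->3' around the circle)
circle_sequence_from_truth <- function(bundle, circ) {
  ex <- bundle$exons[bundle$exons$gene_id == circ$host_gene, , drop = FALSE]
  ex <- ex[ex$start >= circ$start & ex$end <= circ$end, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  seqs <- subseq0(bundle$sequences[[circ$chrom]], ex$start, ex$end)
  joined <- paste(seqs, collapse = "")
  if (circ$strand == "-") revcomp(joined) else joined
}

# inject substitution errors and N bases; pure function of the RNG state
apply_read_noise <- function(seqs, error_rate, n_fraction) {
  if (error_rate <= 0 && n_fraction <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    L <- length(ch)
    if (error_rate > 0) {
      n_err <- rbinom(1L, L, error_rate)
      if (n_err > 0) {
        pos <- sample.int(L, n_err)
        for (p in pos) {
          ch[p] <- sample(setdiff(BASES, ch[p]), 1L)
        }
      }
    }
    if (n_fraction > 0) {
      n_n <- rbinom(1L, L, n_fraction)
      if (n_n > 0) ch[sample.int(L, n_n)] <- "N"
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate single-end reads
#'
#' Emits (a) linear transcript reads at a Poisson depth per gene, (b) for
#' each circle exactly `true_junction_reads` reads spanning the backsplice
#' junction with at least `min_overhang` nt on each side, drawn uniformly
#' over the admissible overhangs from the circular (wrap-around) sequence,
#' and (c) optional noise and contaminant reads. Qualities are constant Q35
#' except for contaminant tails. Read names carry an `origin:source:pos`
#' suffix so every read can be audited against the truth (see
#' [parse_read_origin()]).
#'
#' @param bundle A `genome_bundle`.
#' @param circles Truth tibble from [simulate_circles()] (may have 0 rows).
#' @param config The [sim_config()].
#' @param sample_id Sample label used in read names.
#' @param sample_index Integer; distinct indices give independent samples
#'   under the same configuration seed.
#' @param path Optional FASTQ output path.
#' @return Tibble of reads (`read_id`, `sequence`, `quality`).
#' @export
simulate_reads <- function(bundle, circles, config,
                           sample_id = "s1", sample_index = 1L, path = NULL) {
  stopifnot(inherits(bundle, "genome_bundle"), inherits(config, "sim_config"))
  set.seed(config$seed + 101L * as.integer(sample_index) + 2L)
  L <- config$read_length
  q35 <- strrep(intToUtf8(35L + 33L), L)

  ids <- character(0); seqs <- character(0); quals <- character(0)

  # (a) linear transcript reads
  for (g in bundle$genes$gene_id) {
    tseq <- transcript_sequence(bundle, g)
    tlen <- nchar(tseq)
    if (tlen < L) next
    n <- rpois(1L, config$linear_depth)
    if (n == 0) next
    pos <- resample(0:(tlen - L), n, replace = TRUE)
    rseq <- substring(tseq, pos + 1L, pos + L)
    if (config$adaptor_fraction > 0 && nzchar(config$adaptor)) {
      withad <- stats::runif(n) < config$adaptor_fraction
      if (any(withad)) {
        ins <- resample(25:(L - 6L), sum(withad), replace = TRUE)
        rseq[withad] <- paste0(
          substring(rseq[withad], 1L, ins),
          substring(strrep(config$adaptor, ceiling(L / nchar(config$adaptor))),
                    1L, L - ins)
        )
      }
    }
    ids <- c(ids, sprintf("%s_lin_%s_%03d|linear:%s:%d",
                          sample_id, g, seq_len(n), g, pos))
    seqs <- c(seqs, rseq)
  }

  # (b) backsplice-junction reads
  if (!is.null(circles) && nrow(circles) > 0) {
    mo <- config$min_overhang
    for (ci in seq_len(nrow(circles))) {
      circ <- circles[ci, ]
      cseq <- circle_sequence_from_truth(bundle, circ)
      clen <- nchar(cseq)
      if (L > clen) {
        abort(sprintf(
          "read_length %d exceeds the circumference (%d nt) of circle %s",
          L, clen, circ$circ_id
        ))
      }
      n <- circ$true_junction_reads
      # left overhang (bases from the circle 3' tail) uniform over the
      # admissible range; both overhangs are then >= min_overhang
      ol <- resample(mo:(L - mo), n, replace = TRUE)
      rseq <- vapply(ol, function(o) circular_substr(cseq, clen - o, L),
                     character(1))
      ids <- c(ids, sprintf("%s_circ_%s_%03d|circ:%s:%d",
                            sample_id, circ$circ_id, seq_len(n),
                            circ$circ_id, ol))
      seqs <- c(seqs, rseq)
    }
  }

  quals <- rep(q35, length(seqs))

  # (c) noise and contaminant reads
  if (config$n_noise > 0) {
    nseq <- vapply(seq_len(config$n_noise), function(i) random_dna(L),
                   character(1))
    ids <- c(ids, sprintf("%s_noise_%05d|noise:na:0",
                          sample_id, seq_len(config$n_noise)))
    seqs <- c(seqs, nseq)
    quals <- c(quals, rep(q35, config$n_noise))
  }
  if (config$n_contaminant > 0) {
    cseqs <- vapply(seq_len(config$n_contaminant), function(i) {
      ch <- sample(BASES, L, replace = TRUE)
      ch[sample.int(L, ceiling(0.08 * L))] <- "N"
      paste(ch, collapse = "")
    }, character(1))
    tail_len <- ceiling(0.3 * L)
    cq <- paste0(strrep(intToUtf8(35L + 33L), L - tail_len),
                 strrep(intToUtf8(8L + 33L), tail_len))
    ids <- c(ids, sprintf("%s_contam_%05d|contam:na:0",
                          sample_id, seq_len(config$n_contaminant)))
    seqs <- c(seqs, cseqs)
    quals <- c(quals, rep(cq, config$n_contaminant))
  }

  # substitution/N noise applies to genuine reads only (noise reads are
  # already random; contaminants are constructed)
  n_real <- length(seqs) - config$n_noise - config$n_contaminant
  if (n_real > 0) {
    seqs[seq_len(n_real)] <- apply_read_noise(
      seqs[seq_len(n_real)], config$base_error_rate, config$n_fraction
    )
  }

  reads <- tibble(read_id = ids, sequence = seqs, quality = quals)
  if (!is.null(path)) write_fastq(reads, path)
  reads
}

#' Decode the truth suffix of simulated read names
#'
#' @param read_ids Character vector of read ids produced by
#'   [simulate_reads()].
#' @return Tibble with `read_id`, `origin` (`linear`, `circ`, `noise`,
#'   `contam`), `source` (gene or circle id) and `pos`.
#' @export
parse_read_origin <- function(read_ids) {
  suffix <- sub("^[^|]*\\|", "", read_ids)
  parts <- strsplit(suffix, ":", fixed = TRUE)
  tibble(
    read_id = read_ids,
    origin = vapply(parts, `[`, character(1), 1L),
    source = vapply(parts, `[`, character(1), 2L),
    pos = as.integer(vapply(parts, `[`, character(1), 3L))
  )
}

#' Simulate a negative-binomial count matrix with spiked fold changes
#'
#' Per-feature base means are log-normal; counts are negative-binomial with
#' a common dispersion. Spiked features have their condition-2 (tumour) mean
#' multiplied by the stated fold changes.
#'
#' @param n_features Number of features.
#' @param n_per_condition Samples per condition (at least 2).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   0 gives Poisson counts.
#' @param fold_changes Numeric vector of spiked fold changes (one spiked
#'   feature per entry); empty for a null matrix.
#' @param mean_meanlog,mean_sdlog Log-normal parameters of base means.
#' @param spike_min_mean Spiked features are drawn with base mean at least
#'   this value (default 100) so the spike is detectable at the design size.
#' @param seed Integer seed.
#' @return List with `counts` (tibble: `feature_id`, `biotype`, one column
#'   per sample), `design` (tibble: `sample_id`, `condition`) and `truth`
#'   (tibble of spiked features and their fold changes).
#' @export
simulate_counts <- function(n_features = 1000L,
                            n_per_condition = 3L,
                            dispersion = 0.1,
                            fold_changes = numeric(0),
                            mean_meanlog = log(100),
                            mean_sdlog = 1,
                            spike_min_mean = 100,
                            seed = 1L) {
  if (n_per_condition < 2) abort("need >= 2 samples per condition")
  if (dispersion < 0) abort("dispersion must be non-negative")
  set.seed(as.integer(seed))
  mu <- rlnorm(n_features, mean_meanlog, mean_sdlog)
  if (any(mu <= 0)) abort("non-positive means generated; check parameters")
  n_spike <- length(fold_changes)
  spiked <- integer(0)
  if (n_spike > 0) {
    if (n_spike > n_features) abort("more fold changes than features")
    spiked <- sort(sample.int(n_features, n_spike))
    for (i in seq_along(spiked)) {
      while (mu[spiked[i]] < spike_min_mean) {
        mu[spiked[i]] <- rlnorm(1L, mean_meanlog, mean_sdlog)
      }
    }
  }
  mu2 <- mu
  if (n_spike > 0) mu2[spiked] <- mu[spiked] * fold_changes

  draw <- function(m) {
    if (dispersion == 0) rpois(length(m), m)
    else rnbinom(length(m), mu = m, size = 1 / dispersion)
  }
  samples_a <- paste0("normal_", seq_len(n_per_condition))
  samples_b <- paste0("tumor_", seq_len(n_per_condition))
  counts <- cbind(
    vapply(samples_a, function(s) draw(mu), numeric(n_features)),
    vapply(samples_b, function(s) draw(mu2), numeric(n_features))
  )
  feature_id <- sprintf("f%05d", seq_len(n_features))
  counts_tbl <- as_tibble(counts)
  counts_tbl <- bind_cols(
    tibble(feature_id = feature_id, biotype = "mRNA"), counts_tbl
  )
  list(
    counts = counts_tbl,
    design = tibble(
      sample_id = c(samples_a, samples_b),
      condition = rep(c("normal", "tumor"), each = n_per_condition)
    ),
    truth = tibble(
      feature_id = feature_id[spiked],
      fold_change = if (n_spike > 0) fold_changes else numeric(0)
    )
  )
}

#' Write the genome as FASTA
#'
#' @param bundle A `genome_bundle`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(bundle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(bundle$sequences)) {
    writeLines(paste0(">", ch), con)
    seq <- bundle$sequences[[ch]]
    n <- nchar(seq)
    starts <- seq(1L, n, by = 70L)
    writeLines(substring(seq, starts, pmin(starts + 69L, n)), con)
  }
  invisible(path)
}

#' Write the gene annotation as GTF
#'
#' GTF is 1-based inclusive; attributes carry `gene_id`, `transcript_id`
#' (one transcript per gene) and `transcript_biotype` (`mRNA` or `lncRNA`).
#' UTR features are written for mRNA genes.
#'
#' @param bundle A `genome_bundle`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(bundle, path) {
  rows <- character(0)
  fmt <- function(chrom, type, start0, end0, strand, gene_id, biotype) {
    sprintf(
      "%s\tcircprofiler\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\"; transcript_biotype \"%s\";",
      chrom, type, start0 + 1L, end0, strand, gene_id, gene_id, biotype
    )
  }
  for (gi in seq_len(nrow(bundle$genes))) {
    g <- bundle$genes[gi, ]
    rows <- c(rows, fmt(g$chrom, "transcript", g$start, g$end, g$strand,
                        g$gene_id, g$biotype))
    ex <- bundle$exons[bundle$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (ei in seq_len(nrow(ex))) {
      rows <- c(rows, fmt(g$chrom, "exon", ex$start[ei], ex$end[ei],
                          g$strand, g$gene_id, g$biotype))
    }
    ut <- bundle$utrs[bundle$utrs$gene_id == g$gene_id, , drop = FALSE]
    for (ui in seq_len(nrow(ut))) {
      type <- if (ut$type[ui] == "five_utr") "five_prime_utr" else "three_prime_utr"
      rows <- c(rows, fmt(g$chrom, type, ut$start[ui], ut$end[ui],
                          g$strand, g$gene_id, g$biotype))
    }
  }
  writeLines(rows, path)
  invisible(path)
}
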