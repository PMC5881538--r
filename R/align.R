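# Desk-scale linear read alignment. A k-mer index over both genome strands
# (and, when annotation is supplied, over exon-exon junction constructs)
# drives seed-and-extend mapping: a read is mapped iff it has a full-length
# alignment, contiguous or split across one annotated intron, with at most
# max_mismatches substitutions. max_mismatches + 1 non-overlapping seeds per
# read make the search complete by pigeonhole whenever the read is long
# enough to carry them. Everything internal is 0-based half-open; reverse
# strand search goes through reverse-complement "targets" whose coordinates
# are folded back at the end.

target_name <- function(kind, id, strand) paste(kind, id, strand, sep = "|")

#' Build a k-mer index over the genome (and annotated junctions)
#'
#' @param bundle A `genome_bundle`.
#' @param k K-mer length (default 15, minimum 8).
#' @param read_length When given, exon-exon junction constructs of width
#'   `read_length - 1` per side are indexed as well, enabling spliced
#'   full-length alignment across one annotated intron.
#' @return A `kmer_index` object.
#' @export
build_kmer_index <- function(bundle, k = 15L, read_length = NULL) {
  stopifnot(inherits(bundle, "genome_bundle"))
  if (k < 8) abort("k must be >= 8")
  k <- as.integer(k)

  targets <- character(0)
  info <- list()
  for (ch in names(bundle$sequences)) {
    seq <- bundle$sequences[[ch]]
    len <- nchar(seq)
    targets[[target_name("C", ch, "+")]] <- seq
    targets[[target_name("C", ch, "-")]] <- revcomp(seq)
    info[[length(info) + 1L]] <- tibble(
      target = c(target_name("C", ch, "+"), target_name("C", ch, "-")),
      kind = "chrom", chrom = ch, strand = c("+", "-"), chrom_len = len,
      lend = NA_integer_, rstart = NA_integer_, w1 = NA_integer_
    )
  }

  if (!is.null(read_length) && nrow(bundle$exons) > 0) {
    w <- as.integer(read_length) - 1L
    for (g in unique(bundle$exons$gene_id)) {
      ex <- bundle$exons[bundle$exons$gene_id == g, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) < 2) next
      ch <- ex$chrom[1]
      seq <- bundle$sequences[[ch]]
      len <- nchar(seq)
      for (ii in seq_len(nrow(ex) - 1L)) {
        lend <- ex$end[ii]
        rstart <- ex$start[ii + 1L]
        w1 <- min(w, lend - ex$start[ii])
        w2 <- min(w, ex$end[ii + 1L] - rstart)
        cons <- paste0(subseq0(seq, lend - w1, lend),
                       subseq0(seq, rstart, rstart + w2))
        jid <- sprintf("%s.j%d", g, ii)
        targets[[target_name("J", jid, "+")]] <- cons
        targets[[target_name("J", jid, "-")]] <- revcomp(cons)
        info[[length(info) + 1L]] <- tibble(
          target = c(target_name("J", jid, "+"), target_name("J", jid, "-")),
          kind = "junction", chrom = ch, strand = c("+", "-"),
          chrom_len = len, lend = lend, rstart = rstart, w1 = w1
        )
      }
    }
  }

  tabs <- lapply(names(targets), function(tn) {
    seq <- targets[[tn]]
    n <- nchar(seq)
    if (n < k) return(NULL)
    kmers <- substring(seq, 1:(n - k + 1L), k:n)
    keep <- !grepl("N", kmers, fixed = TRUE)
    data.table::data.table(kmer = kmers[keep],
                           target = tn,
                           pos = (0:(n - k))[keep])
  })
  tab <- data.table::rbindlist(tabs)
  data.table::setkey(tab, kmer)

  structure(
    list(k = k, table = tab, targets = targets,
         target_info = bind_rows(info)),
    class = "kmer_index"
  )
}

#' Look up a k-mer in the index
#'
#' @param index A `kmer_index`.
#' @param kmer Character k-mer (length must equal `index$k`).
#' @return Tibble of hits: `chrom`, `pos` (0-based genomic start of the
#'   matching window), `strand`. Genome targets only.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"), nchar(kmer) == index$k)
  query <- data.table::data.table(kmer = kmer)
  hits <- index$table[query, nomatch = NULL]
  if (nrow(hits) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character()))
  }
  hits <- as_tibble(hits)
  hits <- inner_join(hits, index$target_info, by = "target")
  hits <- hits[hits$kind == "chrom", , drop = FALSE]
  gpos <- ifelse(hits$strand == "+", hits$pos,
                 hits$chrom_len - hits$pos - index$k)
  tibble(chrom = hits$chrom, pos = as.integer(gpos), strand = hits$strand) |>
    arrange(.data$chrom, .data$pos, .data$strand)
}

# seeds for full-length alignment: max_mm + 1 non-overlapping k-mers when the
# read length allows, fewer otherwise (completeness then degrades gracefully)
seed_offsets <- function(L, k, max_mm) {
  if (L < k) return(integer(0))
  s <- min(max_mm + 1L, L %/% k)
  s <- max(s, 1L)
  unique(as.integer(floor(seq(0L, L - k, length.out = s))))
}

#' Align reads linearly to the genome
#'
#' A read is mapped iff it has a full-length alignment with at most
#' `max_mismatches` substitutions, either contiguous on a chromosome or
#' split across one annotated intron (via the index's junction constructs).
#' The best alignment has the fewest mismatches; ties go to the lowest
#' (chromosome, position), preferring contiguous over spliced placements.
#'
#' @param reads Tibble of reads (`read_id`, `sequence`, `quality`).
#' @param index A [build_kmer_index()] result (built with `read_length` if
#'   spliced reads are expected).
#' @param max_mismatches Maximum substitutions for a valid alignment
#'   (default 2).
#' @return List with `alignments` (tibble: `read_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_blocks`, `b1_start`, `b1_end`, `b2_start`, `b2_end`,
#'   `mismatches`) and `unmapped` (the unmapped reads, verbatim).
#' @export
align_linear <- function(reads, index, max_mismatches = 2L) {
  assert_tibble_cols(reads, c("read_id", "sequence"), "reads")
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  empty_aln <- tibble(
    read_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), n_blocks = integer(),
    b1_start = integer(), b1_end = integer(),
    b2_start = integer(), b2_end = integer(), mismatches = integer()
  )
  if (nrow(reads) == 0) {
    return(list(alignments = empty_aln, unmapped = reads))
  }

  lens <- nchar(reads$sequence)
  seed_list <- lapply(unique(lens), function(L) {
    offs <- seed_offsets(L, k, max_mismatches)
    idx <- which(lens == L)
    if (length(offs) == 0 || length(idx) == 0) return(NULL)
    data.table::data.table(
      read_idx = rep(idx, each = length(offs)),
      off = rep(offs, length(idx)),
      L = L
    )
  })
  seeds <- data.table::rbindlist(seed_list)
  if (is.null(seeds) || nrow(seeds) == 0) {
    return(list(alignments = empty_aln, unmapped = reads))
  }
  seeds[, kmer := substring(reads$sequence[read_idx], off + 1L, off + k)]

  hits <- index$table[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  best <- NULL
  if (nrow(hits) > 0) {
    hits[, gstart := pos - off]
    tlen <- nchar(index$targets)
    hits[, tl := tlen[target]]
    cand <- unique(hits[gstart >= 0L & gstart + L <= tl,
                        .(read_idx, target, gstart, L)])
    if (nrow(cand) > 0) {
      # verify candidates target by target
      cand[, sub := substring(index$targets[target], gstart + 1L, gstart + L)]
      cand[, mm := count_mismatches(sub, reads$sequence[read_idx])]
      cand <- cand[mm <= max_mismatches]
    }
    if (nrow(cand) > 0) {
      ti <- index$target_info
      cand <- as_tibble(cand[, .(read_idx, target, gstart, L, mm)])
      cand <- left_join(cand, ti, by = "target")
      cand$cons_len <- as.integer(nchar(index$targets)[cand$target])
      # fold target coordinates back to the genome
      conv <- convert_target_hits(cand)
      if (nrow(conv) > 0) {
        conv$read_id <- reads$read_id[conv$read_idx]
        conv <- conv |>
          arrange(.data$read_idx, .data$mismatches, .data$chrom, .data$start,
                  .data$n_blocks, .data$strand, .data$b1_end) |>
          distinct(.data$read_idx, .keep_all = TRUE)
        best <- conv
      }
    }
  }

  if (is.null(best) || nrow(best) == 0) {
    return(list(alignments = empty_aln, unmapped = reads))
  }
  alignments <- best |>
    select(all_of(names(empty_aln))) |>
    arrange(.data$chrom, .data$start, .data$read_id)
  unmapped <- reads[!(reads$read_id %in% alignments$read_id), , drop = FALSE]
  list(alignments = alignments, unmapped = unmapped)
}

# turn verified target-space hits into genomic alignments (1 or 2 blocks)
convert_target_hits <- function(cand) {
  ch <- cand[cand$kind == "chrom", , drop = FALSE]
  out1 <- NULL
  if (nrow(ch) > 0) {
    s <- ifelse(ch$strand == "+", ch$gstart, ch$chrom_len - ch$gstart - ch$L)
    out1 <- tibble(
      read_idx = ch$read_idx, chrom = ch$chrom, strand = ch$strand,
      start = as.integer(s), end = as.integer(s + ch$L), n_blocks = 1L,
      b1_start = as.integer(s), b1_end = as.integer(s + ch$L),
      b2_start = NA_integer_, b2_end = NA_integer_,
      mismatches = as.integer(ch$mm)
    )
  }
  jn <- cand[cand$kind == "junction", , drop = FALSE]
  out2 <- NULL
  if (nrow(jn) > 0) {
    fs <- ifelse(jn$strand == "+", jn$gstart, jn$cons_len - jn$gstart - jn$L)
    fe <- fs + jn$L
    keep <- fs < jn$w1 & fe > jn$w1  # must span the junction point
    jn <- jn[keep, , drop = FALSE]
    fs <- fs[keep]
    fe <- fe[keep]
    if (nrow(jn) > 0) {
      b1s <- jn$lend - (jn$w1 - fs)
      b2e <- jn$rstart + (fe - jn$w1)
      out2 <- tibble(
        read_idx = jn$read_idx, chrom = jn$chrom, strand = jn$strand,
        start = as.integer(b1s), end = as.integer(b2e), n_blocks = 2L,
        b1_start = as.integer(b1s), b1_end = as.integer(jn$lend),
        b2_start = as.integer(jn$rstart), b2_end = as.integer(b2e),
        mismatches = as.integer(jn$mm)
      )
    }
  }
  bind_rows(out1, out2)
}

#' Discover local segment matches for unmapped reads
#'
#' Maximal exact k-mer seeded matches, extended with at most one mismatch
#' per 25 aligned bases, reported when the score (length minus mismatches)
#' reaches `min_segment`. When two segments of a read overlap in read
#' coordinates (junction micro-homology), the later segment's head is
#' trimmed so reported segments never overlap on the read.
#'
#' @param reads Unmapped reads tibble (`read_id`, `sequence`).
#' @param index A `kmer_index`.
#' @param min_segment Minimum segment score (default 18).
#' @param mismatch_per Mismatch budget: one per this many aligned bases
#'   (default 25; `Inf` for exact extension, the right setting when the
#'   error model is substitution-free).
#' @return Tibble of segment matches: `read_id`, `read_start`, `read_end`,
#'   `chrom`, `strand`, `g_start`, `g_end`, `mismatches`, `score`; ordered by
#'   read and read offset.
#' @export
find_segments <- function(reads, index, min_segment = 18L, mismatch_per = 25L) {
  assert_tibble_cols(reads, c("read_id", "sequence"), "reads")
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  empty <- tibble(
    read_id = character(), read_start = integer(), read_end = integer(),
    chrom = character(), strand = character(),
    g_start = integer(), g_end = integer(),
    mismatches = integer(), score = integer()
  )
  if (nrow(reads) == 0) return(empty)

  chrom_targets <- index$target_info$target[index$target_info$kind == "chrom"]
  lens <- nchar(reads$sequence)
  seed_list <- lapply(which(lens >= k), function(i) {
    L <- lens[i]
    data.table::data.table(read_idx = i, off = 0:(L - k))
  })
  seeds <- data.table::rbindlist(seed_list)
  if (is.null(seeds) || nrow(seeds) == 0) return(empty)
  seeds[, kmer := substring(reads$sequence[read_idx], off + 1L, off + k)]
  hits <- index$table[seeds, on = "kmer", nomatch = NULL,
                      allow.cartesian = TRUE]
  hits <- hits[target %in% chrom_targets]
  if (nrow(hits) == 0) return(empty)
  hits[, diag := pos - off]

  segs <- list()
  grp <- hits[, .(offs = list(sort(off))), by = .(read_idx, target, diag)]
  for (i in seq_len(nrow(grp))) {
    ri <- grp$read_idx[i]
    tn <- grp$target[i]
    dg <- grp$diag[i]
    offs <- grp$offs[[i]]
    rs_seq <- reads$sequence[ri]
    L <- nchar(rs_seq)
    tseq <- index$targets[[tn]]
    tlenn <- nchar(tseq)
    # split into runs of consecutive offsets (a mismatch breaks the chain)
    runs <- split(offs, cumsum(c(1L, diff(offs) != 1L)))
    for (run in runs) {
      rstart <- run[1]
      rend <- run[length(run)] + k
      mism <- 0L
      budget <- function(len) {
        if (is.finite(mismatch_per)) len %/% mismatch_per else 0L
      }
      # extend right
      while (rend < L && rend + dg < tlenn) {
        match <- substring(rs_seq, rend + 1L, rend + 1L) ==
          substring(tseq, rend + dg + 1L, rend + dg + 1L)
        if (match) {
          rend <- rend + 1L
        } else if (mism + 1L <= budget(rend - rstart + 1L)) {
          mism <- mism + 1L
          rend <- rend + 1L
        } else break
      }
      # extend left
      while (rstart > 0L && rstart + dg > 0L) {
        match <- substring(rs_seq, rstart, rstart) ==
          substring(tseq, rstart + dg, rstart + dg)
        if (match) {
          rstart <- rstart - 1L
        } else if (mism + 1L <= budget(rend - rstart + 1L)) {
          mism <- mism + 1L
          rstart <- rstart - 1L
        } else break
      }
      segs[[length(segs) + 1L]] <- tibble(
        read_idx = ri, target = tn, read_start = rstart, read_end = rend,
        t_start = rstart + dg, t_end = rend + dg, mismatches = mism
      )
    }
  }
  if (length(segs) == 0) return(empty)
  segs <- bind_rows(segs) |>
    distinct(.data$read_idx, .data$target, .data$read_start, .data$read_end,
             .keep_all = TRUE)
  segs$score <- segs$read_end - segs$read_start - segs$mismatches
  segs <- segs[segs$score >= min_segment, , drop = FALSE]
  if (nrow(segs) == 0) return(empty)

  # resolve read-coordinate overlaps: trim later segments' heads
  segs <- segs |> arrange(.data$read_idx, .data$read_start, .data$read_end)
  out <- list()
  for (ri in unique(segs$read_idx)) {
    sub <- segs[segs$read_idx == ri, , drop = FALSE]
    max_end <- -1L
    for (j in seq_len(nrow(sub))) {
      o <- max_end - sub$read_start[j]
      if (o > 0L) {
        sub$read_start[j] <- sub$read_start[j] + o
        sub$t_start[j] <- sub$t_start[j] + o
        sub$score[j] <- sub$read_end[j] - sub$read_start[j] -
          sub$mismatches[j]
      }
      max_end <- max(max_end, sub$read_end[j])
    }
    out[[length(out) + 1L]] <- sub
  }
  segs <- bind_rows(out)
  segs <- segs[segs$score >= min_segment, , drop = FALSE]
  if (nrow(segs) == 0) return(empty)

  ti <- index$target_info
  segs <- left_join(segs, ti, by = "target")
  g_start <- ifelse(segs$strand == "+", segs$t_start,
                    segs$chrom_len - segs$t_end)
  g_end <- ifelse(segs$strand == "+", segs$t_end,
                  segs$chrom_len - segs$t_start)
  res <- tibble(
    read_id = segs$read_idx,
    read_start = as.integer(segs$read_start),
    read_end = as.integer(segs$read_end),
    chrom = segs$chrom, strand = segs$strand,
    g_start = as.integer(g_start), g_end = as.integer(g_end),
    mismatches = as.integer(segs$mismatches),
    score = as.integer(segs$score)
  )
  res$read_id <- reads$read_id[res$read_id]
  res |> arrange(.data$read_id, .data$read_start)
}

#' Assign each alignment to a genomic region category
#'
#' Fixed priority: TSS > TES > 5'UTR > 3'UTR > exon > intron > intergenic.
#' TSS/TES are windows around the annotated transcript start/end (default
#' +/- 1000 nt); an alignment falls in a category when its genomic span
#' overlaps any interval of that category.
#'
#' @param alignments Alignment tibble from [align_linear()].
#' @param bundle A `genome_bundle`.
#' @param tss_window,tes_window Window half-widths in nt (default 1000).
#' @return The alignments tibble with a `region` column appended.
#' @export
annotate_regions <- function(alignments, bundle,
                             tss_window = 1000L, tes_window = 1000L) {
  stopifnot(inherits(bundle, "genome_bundle"))
  n <- nrow(alignments)
  region <- rep(NA_character_, n)
  if (n == 0) {
    alignments$region <- character(0)
    return(alignments)
  }
  g <- bundle$genes
  tss <- ifelse(g$strand == "+", g$start, g$end)
  tes <- ifelse(g$strand == "+", g$end, g$start)
  cats <- list(
    TSS = tibble(chrom = g$chrom, start = tss - tss_window,
                 end = tss + tss_window),
    TES = tibble(chrom = g$chrom, start = tes - tes_window,
                 end = tes + tes_window),
    five_utr = bundle$utrs[bundle$utrs$type == "five_utr",
                           c("chrom", "start", "end")],
    three_utr = bundle$utrs[bundle$utrs$type == "three_utr",
                            c("chrom", "start", "end")],
    exon = bundle$exons[, c("chrom", "start", "end")],
    intron = tibble(chrom = g$chrom, start = g$start, end = g$end)
  )
  spans <- tibble(chrom = alignments$chrom,
                  start = alignments$start, end = alignments$end)
  remaining <- seq_len(n)
  for (cat in names(cats)) {
    iv <- cats[[cat]]
    if (length(remaining) == 0 || nrow(iv) == 0) next
    hit <- vapply(remaining, function(i) {
      any(iv$chrom == spans$chrom[i] &
            iv$start < spans$end[i] & spans$start[i] < iv$end)
    }, logical(1))
    region[remaining[hit]] <- cat
    remaining <- remaining[!hit]
  }
  region[remaining] <- "intergenic"
  alignments$region <- region
  alignments
}

#' Tally alignments per region category
#'
#' @param alignments Output of [annotate_regions()].
#' @return Tibble `region`, `n`; categories sum to the number of alignments.
#' @export
region_tally <- function(alignments) {
  assert_tibble_cols(alignments, "region", "alignments")
  lv <- c("TSS", "TES", "five_utr", "three_utr", "exon", "intron",
          "intergenic")
  alignments |>
    count(region = factor(.data$region, levels = lv), .drop = FALSE) |>
    mutate(region = as.character(.data$region))
}

#' Tally alignments per chromosome
#'
#' @param alignments Alignment tibble.
#' @return Tibble `chrom`, `n`; the counts sum to the number of alignments.
#' @export
chromosome_tally <- function(alignments) {
  assert_tibble_cols(alignments, "chrom", "alignments")
  alignments |> count(.data$chrom, name = "n") |> arrange(.data$chrom)
}
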