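# Backsplice (head-to-tail) junction discovery. Segment matches of unmapped
# reads are paired under the retention rules — same chromosome, same strand,
# genomic order reversed relative to read order, span at most 1 Mb — then
# each raw junction is refined by sliding the (acceptor, donor) pair jointly
# over the sequence-consistent shift range and keeping the shift with the
# strongest donor + acceptor splice score. Junctions supported by at least
# `min_reads` distinct reads with a splice score at or above `min_score`
# become circRNA calls.

#' Pair segment matches into raw backsplice junction candidates
#'
#' For each read, every ordered pair (A = earlier read segment, B = later
#' read segment) with non-overlapping read intervals is retained iff both
#' segments lie on the same chromosome and strand, the genomic order is
#' reversed relative to an ordinary spliced read (B upstream of A on the
#' plus strand, mirrored on the minus strand), and the genomic span is at
#' most `max_span`.
#'
#' @param segments Segment-match tibble ([find_segments()] or
#'   [ingest_sam()]`$segments`).
#' @param max_span Maximum genomic span in nt (default 1e6).
#' @return Tibble of raw candidates: `read_id`, `chrom`, `strand`,
#'   `acceptor_pos`, `donor_end`, `span`.
#' @export
find_segment_pairs <- function(segments, max_span = 1000000L) {
  assert_tibble_cols(
    segments,
    c("read_id", "read_start", "read_end", "chrom", "strand",
      "g_start", "g_end"),
    "segments"
  )
  empty <- tibble(
    read_id = character(), chrom = character(), strand = character(),
    acceptor_pos = integer(), donor_end = integer(), span = integer()
  )
  if (nrow(segments) == 0) return(empty)
  a <- segments |>
    rename(a_rs = "read_start", a_re = "read_end",
           a_gs = "g_start", a_ge = "g_end")
  b <- segments |>
    rename(b_rs = "read_start", b_re = "read_end",
           b_gs = "g_start", b_ge = "g_end") |>
    select(all_of(c("read_id", "chrom", "strand",
                    "b_rs", "b_re", "b_gs", "b_ge")))
  pairs <- inner_join(a, b, by = c("read_id", "chrom", "strand"),
                      relationship = "many-to-many")
  pairs <- pairs |>
    filter(
      .data$a_rs < .data$b_rs,        # A earlier on the read
      .data$a_re <= .data$b_rs,       # non-overlapping read intervals
      ifelse(.data$strand == "+",
             .data$b_ge <= .data$a_gs,   # B genomically upstream of A
             .data$a_ge <= .data$b_gs)   # mirrored on the minus strand
    ) |>
    mutate(
      acceptor_pos = as.integer(ifelse(.data$strand == "+",
                                       .data$b_gs, .data$a_gs)),
      donor_end = as.integer(ifelse(.data$strand == "+",
                                    .data$a_ge, .data$b_ge)),
      span = .data$donor_end - .data$acceptor_pos
    ) |>
    filter(.data$span > 0, .data$span <= max_span)
  if (nrow(pairs) == 0) return(empty)
  pairs |>
    select(all_of(names(empty))) |>
    distinct() |>
    arrange(.data$read_id, .data$chrom, .data$acceptor_pos)
}

# shifts s where the junction (a+s, d+s) yields the same junction-spanning
# sequence: s > 0 needs genome[a+t] == genome[d+t] for t in 0..s-1;
# s < 0 needs the same equality for t in s..-1
consistent_shift_range <- function(seq, a, d, window) {
  n <- nchar(seq)
  smax <- 0L
  while (smax < window) {
    t <- smax
    if (a + t >= n || d + t >= n) break
    if (substring(seq, a + t + 1L, a + t + 1L) !=
        substring(seq, d + t + 1L, d + t + 1L)) break
    smax <- smax + 1L
  }
  smin <- 0L
  while (smin > -window) {
    t <- smin - 1L
    if (a + t < 0L || d + t < 0L) break
    if (substring(seq, a + t + 1L, a + t + 1L) !=
        substring(seq, d + t + 1L, d + t + 1L)) break
    smin <- smin - 1L
  }
  smin:smax
}

#' Refine junction candidates with splice-site scores
#'
#' The exact junction position is ambiguous whenever the sequence flanks
#' repeat across the junction; all coordinate shifts applied jointly to
#' (acceptor, donor) that leave the junction-spanning sequence unchanged are
#' scored, and the shift maximizing donor + acceptor splice strength is
#' kept (ties go to the smallest acceptor position).
#'
#' @param candidates Raw candidates from [find_segment_pairs()].
#' @param bundle A `genome_bundle`.
#' @param scorer A [splice_scorer()].
#' @param shift_window Maximum shift magnitude considered (default 10).
#' @return Candidates with refined `acceptor_pos`, `donor_end`, and
#'   `splice_score` (donor + acceptor), `donor_score`, `acceptor_score`.
#' @export
refine_junctions <- function(candidates, bundle, scorer, shift_window = 10L) {
  stopifnot(inherits(bundle, "genome_bundle"),
            inherits(scorer, "splice_scorer"))
  if (nrow(candidates) == 0) {
    return(mutate(candidates, splice_score = numeric(0),
                  donor_score = numeric(0), acceptor_score = numeric(0)))
  }
  keys <- candidates |>
    distinct(.data$chrom, .data$strand, .data$acceptor_pos, .data$donor_end)
  refined <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    ch <- keys$chrom[i]; st <- keys$strand[i]
    a0 <- keys$acceptor_pos[i]; d0 <- keys$donor_end[i]
    seq <- bundle$sequences[[ch]]
    shifts <- consistent_shift_range(seq, a0, d0, as.integer(shift_window))
    a_sh <- a0 + shifts
    d_sh <- d0 + shifts
    if (st == "+") {
      dw <- vapply(d_sh, function(d) donor_window(seq, "+", d), character(1))
      aw <- vapply(a_sh, function(a) acceptor_window(seq, "+", a),
                   character(1))
    } else {
      dw <- vapply(a_sh, function(a) donor_window(seq, "-", a), character(1))
      aw <- vapply(d_sh, function(d) acceptor_window(seq, "-", d),
                   character(1))
    }
    sc <- score_splice_sites(scorer, dw, aw)
    total <- sc$donor_score + sc$acceptor_score
    # argmax; ties -> smallest acceptor position (shifts are ascending)
    best <- which(total == max(total))[1]
    refined[[i]] <- tibble(
      chrom = ch, strand = st, acceptor_pos = a0, donor_end = d0,
      new_acceptor = as.integer(a_sh[best]),
      new_donor = as.integer(d_sh[best]),
      donor_score = sc$donor_score[best],
      acceptor_score = sc$acceptor_score[best],
      splice_score = total[best]
    )
  }
  refined <- bind_rows(refined)
  candidates |>
    left_join(refined,
              by = c("chrom", "strand", "acceptor_pos", "donor_end")) |>
    mutate(acceptor_pos = .data$new_acceptor,
           donor_end = .data$new_donor,
           span = .data$donor_end - .data$acceptor_pos) |>
    select(-all_of(c("new_acceptor", "new_donor")))
}

#' Call circRNAs from refined junction candidates
#'
#' Candidates are aggregated by junction; each read supports at most one
#' junction (its best-scoring one). A junction is reported iff it has at
#' least `min_reads` distinct supporting reads and a splice score at or
#' above `min_score` (both bounds inclusive as stated). Host genes are
#' same-strand genes whose span contains the junction.
#'
#' @param refined Refined candidates from [refine_junctions()].
#' @param bundle A `genome_bundle`.
#' @param min_reads Minimum distinct supporting reads (default 2).
#' @param min_score Minimum splice score (default 10).
#' @return Tibble of calls: `circ_id`, `chrom`, `strand`, `start`, `end`,
#'   `n_backspliced_reads`, `splice_score`, `host_gene`, `host_genes`,
#'   `exonic_length`.
#' @export
call_circrnas <- function(refined, bundle, min_reads = 2L, min_score = 10) {
  stopifnot(inherits(bundle, "genome_bundle"))
  empty <- tibble(
    circ_id = character(), chrom = character(), strand = character(),
    start = integer(), end = integer(), n_backspliced_reads = integer(),
    splice_score = numeric(), host_gene = character(),
    host_genes = character(), exonic_length = integer()
  )
  if (nrow(refined) == 0) return(empty)

  # a read counts toward at most one junction: the highest splice score,
  # ties resolved by the lowest (chrom, acceptor, donor)
  assigned <- refined |>
    arrange(.data$read_id, desc(.data$splice_score), .data$chrom,
            .data$acceptor_pos, .data$donor_end) |>
    distinct(.data$read_id, .keep_all = TRUE)

  calls <- assigned |>
    group_by(.data$chrom, .data$strand, .data$acceptor_pos,
             .data$donor_end) |>
    summarise(
      n_backspliced_reads = n_distinct(.data$read_id),
      splice_score = first(.data$splice_score),
      .groups = "drop"
    ) |>
    filter(.data$n_backspliced_reads >= min_reads,
           .data$splice_score >= min_score)
  if (nrow(calls) == 0) return(empty)

  g <- bundle$genes
  host <- purrr::pmap(
    list(calls$chrom, calls$strand, calls$acceptor_pos, calls$donor_end),
    function(ch, st, a, d) {
      hit <- g[g$chrom == ch & g$strand == st & g$start <= a & g$end >= d, ,
               drop = FALSE]
      hit <- hit[order(hit$start), , drop = FALSE]
      if (nrow(hit) == 0) return(list(first = NA_character_, all = ""))
      list(first = hit$gene_id[1], all = paste(hit$gene_id, collapse = ","))
    }
  )
  exonic_len <- purrr::pmap_int(
    list(vapply(host, `[[`, character(1), "first"),
         calls$acceptor_pos, calls$donor_end),
    function(hg, a, d) {
      if (is.na(hg)) return(as.integer(d - a))
      ex <- bundle$exons[bundle$exons$gene_id == hg &
                           bundle$exons$start >= a &
                           bundle$exons$end <= d, , drop = FALSE]
      if (nrow(ex) == 0) return(as.integer(d - a))
      as.integer(sum(ex$end - ex$start))
    }
  )
  calls |>
    mutate(
      circ_id = sprintf("%s:%d-%d:%s", .data$chrom, .data$acceptor_pos,
                        .data$donor_end, .data$strand),
      host_gene = vapply(host, `[[`, character(1), "first"),
      host_genes = vapply(host, `[[`, character(1), "all"),
      exonic_length = exonic_len
    ) |>
    rename(start = "acceptor_pos", end = "donor_end") |>
    select(all_of(names(empty))) |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' Read a BED file of known circRNA junctions
#'
#' 0-based half-open BED with at least six columns (strand in column 6).
#'
#' @param path BED path.
#' @return Tibble `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 6 ||
        is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))) ||
        !(f[6] %in% c("+", "-"))) {
      abort(sprintf("malformed BED line %d in %s", i, path))
    }
  }
  tibble(
    chrom = vapply(rows, `[`, character(1), 1),
    start = as.integer(vapply(rows, `[`, character(1), 2)),
    end = as.integer(vapply(rows, `[`, character(1), 3)),
    name = vapply(rows, `[`, character(1), 4),
    score = vapply(rows, `[`, character(1), 5),
    strand = vapply(rows, `[`, character(1), 6)
  )
}

#' Label calls as known or novel against a reference junction set
#'
#' A call is `known` iff an entry matches its (chrom, strand, start, end)
#' exactly; otherwise `novel`.
#'
#' @param calls Calls tibble from [call_circrnas()].
#' @param known A BED path or a tibble with `chrom`, `start`, `end`,
#'   `strand`.
#' @return Calls with a `novelty` column appended.
#' @export
compare_to_known <- function(calls, known) {
  if (is.character(known)) known <- read_bed(known)
  assert_tibble_cols(known, c("chrom", "start", "end", "strand"), "known")
  key <- paste(known$chrom, known$strand, known$start, known$end)
  calls |>
    mutate(novelty = ifelse(
      paste(.data$chrom, .data$strand, .data$start, .data$end) %in% key,
      "known", "novel"
    ))
}

#' Write circRNA calls as BED6+
#'
#' Columns: chrom, start, end, circ_id, read count, strand, then
#' splice_score, host_genes and (when present) novelty.
#'
#' @param calls Calls tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circ_bed <- function(calls, path) {
  extra <- c("splice_score", "host_genes",
             intersect("novelty", names(calls)))
  lines <- do.call(paste, c(
    list(calls$chrom, calls$start, calls$end, calls$circ_id,
         calls$n_backspliced_reads, calls$strand),
    lapply(extra, function(cn) calls[[cn]]),
    sep = "\t"
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Rescue junction candidates for reads with one short arm
#'
#' A backsplice read whose breakpoint sits near one end has a long arm
#' (found by [find_segments()]) and a short arm below the minimum segment
#' score that no general local alignment can anchor. Guided by the long
#' arm, the short remainder is searched exactly within `max_span` of the
#' anchor on the same chromosome and strand, in the orientation a
#' head-to-tail junction requires, and each placement is emitted as a raw
#' junction candidate. Spurious placements are subsequently removed by
#' splice-score refinement, the one-junction-per-read assignment, and the
#' support/score thresholds of [call_circrnas()].
#'
#' @param reads Unmapped reads tibble.
#' @param segments Long segments from [find_segments()].
#' @param index The `kmer_index` (provides target sequences).
#' @param min_rescue Shortest remainder searched (default 4: junction
#'   micro-homology can shave the anchored arm below the nominal overhang
#'   floor; the score refinement undoes the resulting coordinate shift).
#' @param min_segment Segment score floor used in discovery; remainders at
#'   or above it are already handled by [find_segment_pairs()] (default 18).
#' @param max_span Maximum genomic span (default 1e6).
#' @param max_hits Cap on placements per remainder (first `max_hits` by
#'   position; default 200).
#' @return Tibble of raw candidates in the [find_segment_pairs()] layout.
#' @export
rescue_junction_candidates <- function(reads, segments, index,
                                       min_rescue = 4L, min_segment = 18L,
                                       max_span = 1000000L,
                                       max_hits = 200L) {
  empty <- tibble(
    read_id = character(), chrom = character(), strand = character(),
    acceptor_pos = integer(), donor_end = integer(), span = integer()
  )
  if (nrow(segments) == 0 || nrow(reads) == 0) return(empty)
  ti <- index$target_info
  chrom_len <- setNames(ti$chrom_len[ti$kind == "chrom" & ti$strand == "+"],
                        ti$chrom[ti$kind == "chrom" & ti$strand == "+"])
  out <- list()
  seq_of <- setNames(reads$sequence, reads$read_id)
  for (rid in unique(segments$read_id)) {
    segs <- segments[segments$read_id == rid, , drop = FALSE]
    rseq <- seq_of[[rid]]
    if (is.null(rseq)) next
    L <- nchar(rseq)
    rs_min <- min(segs$read_start)
    re_max <- max(segs$read_end)
    sides <- list()
    if (rs_min >= min_rescue && rs_min < min_segment) {
      sides$head <- c(0L, rs_min)
    }
    if (L - re_max >= min_rescue && L - re_max < min_segment) {
      sides$tail <- c(re_max, L)
    }
    if (length(sides) == 0) next
    for (side in names(sides)) {
      iv <- sides[[side]]
      remainder <- substring(rseq, iv[1] + 1L, iv[2])
      rem_len <- iv[2] - iv[1]
      # anchor: the long segment adjacent to the remainder
      anchor <- if (side == "head") {
        segs[segs$read_start == rs_min, , drop = FALSE][1, ]
      } else {
        segs[segs$read_end == re_max, , drop = FALSE][1, ]
      }
      st <- anchor$strand
      ch <- anchor$chrom
      clen <- chrom_len[[ch]]
      # anchor coordinates in target (transcript-orientation) space
      if (st == "+") {
        a_ts <- anchor$g_start; a_te <- anchor$g_end
      } else {
        a_ts <- clen - anchor$g_end; a_te <- clen - anchor$g_start
      }
      tname <- target_name("C", ch, st)
      tseq <- index$targets[[tname]]
      if (side == "head") {
        # remainder = circle tail: must land downstream of the anchor
        win_lo <- a_te
        win_hi <- min(clen, a_ts + max_span)
      } else {
        # remainder = circle head: must land upstream of the anchor
        win_lo <- max(0L, a_te - max_span)
        win_hi <- a_ts
      }
      if (win_hi - win_lo < rem_len) next
      window <- subseq0(tseq, win_lo, win_hi)
      occ <- gregexpr(remainder, window, fixed = TRUE)[[1]]
      if (occ[1] == -1) next
      occ <- occ[seq_len(min(length(occ), max_hits))] - 1L + win_lo
      for (o in occ) {
        if (side == "head") {
          acc_t <- a_ts
          don_t <- o + rem_len
        } else {
          acc_t <- o
          don_t <- a_te
        }
        span <- don_t - acc_t
        if (span <= 0 || span > max_span) next
        if (st == "+") {
          acc_g <- acc_t; don_g <- don_t
        } else {
          acc_g <- clen - don_t; don_g <- clen - acc_t
        }
        out[[length(out) + 1L]] <- tibble(
          read_id = rid, chrom = ch, strand = st,
          acceptor_pos = as.integer(acc_g), donor_end = as.integer(don_g),
          span = as.integer(span)
        )
      }
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) |>
    distinct() |>
    arrange(.data$read_id, .data$chrom, .data$acceptor_pos)
}

#' Detect circRNAs from unmapped reads
#'
#' Convenience wrapper running segment discovery, junction pairing,
#' short-arm rescue, splice-score refinement and calling in one step.
#'
#' @param unmapped Unmapped reads tibble.
#' @param index A `kmer_index`.
#' @param bundle A `genome_bundle`.
#' @param scorer A `splice_scorer` (default: trained from the bundle).
#' @param min_segment,max_span,mismatch_per,min_rescue,shift_window,min_reads,min_score
#'   Stage parameters; see the underlying functions.
#' @return List with `calls`, `segments`, `candidates`, `refined`.
#' @export
detect_circrnas <- function(unmapped, index, bundle,
                            scorer = NULL,
                            min_segment = 18L, max_span = 1000000L,
                            mismatch_per = 25L, min_rescue = 4L,
                            shift_window = 10L,
                            min_reads = 2L, min_score = 10) {
  if (is.null(scorer)) scorer <- train_splice_scorer(bundle)
  segments <- find_segments(unmapped, index, min_segment = min_segment,
                            mismatch_per = mismatch_per)
  pairs <- find_segment_pairs(segments, max_span = max_span)
  rescued <- rescue_junction_candidates(
    unmapped, segments, index,
    min_rescue = min_rescue, min_segment = min_segment,
    max_span = max_span
  )
  candidates <- bind_rows(pairs, rescued) |> distinct()
  refined <- refine_junctions(candidates, bundle, scorer,
                              shift_window = shift_window)
  calls <- call_circrnas(refined, bundle, min_reads = min_reads,
                         min_score = min_score)
  list(calls = calls, segments = segments, candidates = candidates,
       refined = refined)
}
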