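# SAM ingestion: the external-aligner entry point. Primary full-length
# records become linear alignments; soft-clipped or supplementary records
# become segment matches keyed by read, the same currency the built-in
# segment finder produces. The SAM line format is parsed directly because
# the contract covers plain-text SAM with per-record skip-and-warn handling
# (the installed BAM machinery requires binary input).

parse_cigar <- function(cigar) {
  if (cigar == "*") return(NULL)
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  list(
    len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
    op = sub("^\\d+", "", toks)
  )
}

#' Ingest alignments from a SAM file
#'
#' Primary records whose CIGAR is pure match (optionally split by `N`)
#' become linear alignments. Records with soft/hard clips of at least
#' `min_segment` aligned bases, and supplementary records, become segment
#' matches (read-coordinate intervals are reported in the original read
#' orientation). Flag-4 records go to the unmapped pool. Unparseable lines
#' are skipped with a warning and counted.
#'
#' @param path Path to a SAM file.
#' @param bundle A `genome_bundle` (used to validate reference names).
#' @param min_segment Minimum aligned length for a clipped record to yield a
#'   segment match (default 18).
#' @return List with `alignments`, `segments`, `unmapped` tibbles and
#'   `skipped` (count of unparseable records).
#' @export
ingest_sam <- function(path, bundle, min_segment = 18L) {
  stopifnot(inherits(bundle, "genome_bundle"))
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  aln <- list(); seg <- list(); unm <- list()
  skipped <- 0L
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      warn(sprintf("skipping unparseable SAM record at line %d", li))
      skipped <- skipped + 1L
      next
    }
    flag <- suppressWarnings(as.integer(f[2]))
    pos1 <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos1)) {
      warn(sprintf("skipping unparseable SAM record at line %d", li))
      skipped <- skipped + 1L
      next
    }
    read_id <- f[1]
    if (bitwAnd(flag, 4L) > 0L) {
      unm[[length(unm) + 1L]] <- tibble(
        read_id = read_id, sequence = toupper(f[10]), quality = f[11]
      )
      next
    }
    chrom <- f[3]
    if (!chrom %in% names(bundle$sequences)) {
      warn(sprintf("skipping SAM record with unknown reference %s (line %d)",
                   chrom, li))
      skipped <- skipped + 1L
      next
    }
    cig <- parse_cigar(f[6])
    if (is.null(cig)) {
      warn(sprintf("skipping SAM record with missing CIGAR at line %d", li))
      skipped <- skipped + 1L
      next
    }
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    supplementary <- bitwAnd(flag, 2048L) > 0L
    nm <- 0L
    nm_tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(nm_tag) > 0) nm <- as.integer(sub("^NM:i:", "", nm_tag[1]))

    gstart <- pos1 - 1L
    ops <- cig$op; lens <- cig$len
    clip_lead <- if (ops[1] %in% c("S", "H")) lens[1] else 0L
    clip_trail <- if (ops[length(ops)] %in% c("S", "H")) {
      lens[length(ops)]
    } else 0L
    core <- which(!(ops %in% c("S", "H")))
    core_ops <- ops[core]; core_lens <- lens[core]
    if (any(core_ops %in% c("I", "D", "P"))) {
      warn(sprintf("skipping SAM record with indel CIGAR at line %d", li))
      skipped <- skipped + 1L
      next
    }
    match_len <- sum(core_lens[core_ops %in% c("M", "=", "X")])
    ref_span <- sum(core_lens)  # M/=/X/N all consume reference here
    read_len <- clip_lead + match_len + clip_trail

    is_clipped <- clip_lead > 0L || clip_trail > 0L
    if (!is_clipped && !supplementary) {
      # full-length linear alignment; N splits into blocks
      starts <- integer(0); ends <- integer(0)
      cur <- gstart
      for (oi in seq_along(core_ops)) {
        if (core_ops[oi] == "N") {
          cur <- cur + core_lens[oi]
        } else {
          starts <- c(starts, cur)
          cur <- cur + core_lens[oi]
          ends <- c(ends, cur)
        }
      }
      # merge abutting match runs
      keep_s <- starts[c(TRUE, starts[-1] != ends[-length(ends)])]
      keep_e <- ends[c(starts[-1] != ends[-length(ends)], TRUE)]
      if (length(keep_s) > 2) {
        warn(sprintf("skipping SAM record with >2 blocks at line %d", li))
        skipped <- skipped + 1L
        next
      }
      aln[[length(aln) + 1L]] <- tibble(
        read_id = read_id, chrom = chrom, strand = strand,
        start = keep_s[1], end = keep_e[length(keep_e)],
        n_blocks = length(keep_s),
        b1_start = keep_s[1], b1_end = keep_e[1],
        b2_start = if (length(keep_s) > 1) keep_s[2] else NA_integer_,
        b2_end = if (length(keep_s) > 1) keep_e[2] else NA_integer_,
        mismatches = nm
      )
    } else if (match_len >= min_segment) {
      # clipped or supplementary: a local segment match
      if (strand == "+") {
        rs <- clip_lead
        re <- clip_lead + match_len
      } else {
        rs <- clip_trail
        re <- clip_trail + match_len
      }
      seg[[length(seg) + 1L]] <- tibble(
        read_id = read_id, read_start = rs, read_end = re,
        chrom = chrom, strand = strand,
        g_start = gstart, g_end = gstart + ref_span,
        mismatches = nm, score = match_len - nm
      )
    }
  }
  empty_reads <- tibble(read_id = character(), sequence = character(),
                        quality = character())
  list(
    alignments = if (length(aln)) bind_rows(aln) else tibble(
      read_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), n_blocks = integer(),
      b1_start = integer(), b1_end = integer(),
      b2_start = integer(), b2_end = integer(), mismatches = integer()
    ),
    segments = if (length(seg)) {
      bind_rows(seg) |> arrange(.data$read_id, .data$read_start)
    } else tibble(
      read_id = character(), read_start = integer(), read_end = integer(),
      chrom = character(), strand = character(),
      g_start = integer(), g_end = integer(),
      mismatches = integer(), score = integer()
    ),
    unmapped = if (length(unm)) bind_rows(unm) else empty_reads,
    skipped = skipped
  )
}
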