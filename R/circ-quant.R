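# circRNA quantification against pseudo-circular junction references.
# Each call gets a junction construct of length 2*(read_length -
# min_overhang) centred on the backsplice point: the circle's 3'-terminal
# bases concatenated with its 5'-initial bases. Any read that fits entirely
# inside the construct necessarily covers the junction with at least
# min_overhang bases on each side, so counting reduces to substring
# alignment.

# circle sequence in transcript orientation for an arbitrary call:
# same-strand annotated exons of the host gene inside [start, end), with the
# genomic span as fallback
circle_sequence <- function(bundle, chrom, strand, start, end,
                            host_gene = NA_character_) {
  seq <- bundle$sequences[[chrom]]
  if (is.null(seq)) abort(sprintf("unknown chromosome %s", chrom))
  joined <- NULL
  if (!is.na(host_gene)) {
    ex <- bundle$exons[bundle$exons$gene_id == host_gene &
                         bundle$exons$start >= start &
                         bundle$exons$end <= end, , drop = FALSE]
    if (nrow(ex) > 0) {
      ex <- ex[order(ex$start), , drop = FALSE]
      joined <- paste(subseq0(seq, ex$start, ex$end), collapse = "")
    }
  }
  if (is.null(joined)) joined <- subseq0(seq, start, end)
  if (nchar(joined) == 0) {
    abort(sprintf("zero-length circle sequence for %s:%d-%d", chrom, start,
                  end))
  }
  if (strand == "-") revcomp(joined) else joined
}

#' Build pseudo-circular junction references for circRNA calls
#'
#' The junction construct is the circle's last `read_length - min_overhang`
#' bases followed by its first `read_length - min_overhang` bases, so the
#' backsplice point sits exactly at the midpoint. Circles shorter than one
#' arm wrap around.
#'
#' @param calls Calls tibble from [call_circrnas()] (columns `circ_id`,
#'   `chrom`, `strand`, `start`, `end`, optionally `host_gene`).
#' @param bundle A `genome_bundle`.
#' @param read_length Read length the construct is built for.
#' @param min_overhang Minimum junction overhang (default 6).
#' @return Tibble `circ_id`, `junction_sequence`, `circ_length`.
#' @export
build_pseudo_reference <- function(calls, bundle, read_length,
                                   min_overhang = 6L) {
  stopifnot(inherits(bundle, "genome_bundle"))
  assert_tibble_cols(calls, c("circ_id", "chrom", "strand", "start", "end"),
                     "calls")
  w <- as.integer(read_length) - as.integer(min_overhang)
  if (w <= 0) abort("read_length must exceed min_overhang")
  host <- if ("host_gene" %in% names(calls)) calls$host_gene else {
    rep(NA_character_, nrow(calls))
  }
  seqs <- character(nrow(calls))
  lens <- integer(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cs <- circle_sequence(bundle, calls$chrom[i], calls$strand[i],
                          calls$start[i], calls$end[i], host[i])
    n <- nchar(cs)
    lens[i] <- n
    seqs[i] <- paste0(circular_substr(cs, (n - (w %% n)) %% n, w),
                      circular_substr(cs, 0L, w))
  }
  tibble(circ_id = calls$circ_id, junction_sequence = seqs,
         circ_length = lens)
}

#' Count junction-spanning reads per circRNA
#'
#' A read counts for a circRNA iff it aligns (either orientation) entirely
#' within the junction construct with at most `max_mismatches`
#' substitutions — which by construction means it covers at least
#' `min_overhang` bases on both sides of the backsplice point. A read
#' counts for at most one circRNA: the best alignment wins, ties go to the
#' lexicographically smallest `circ_id`.
#'
#' @param pseudo_refs Tibble from [build_pseudo_reference()].
#' @param reads Unmapped reads tibble (`read_id`, `sequence`).
#' @param min_overhang Must match the value the constructs were built with.
#' @param max_mismatches Substitutions tolerated in the junction alignment
#'   (default 2).
#' @return Tibble `circ_id`, `junction_reads` (one row per construct, zero
#'   rows of input reads give all-zero counts).
#' @export
count_junction_reads <- function(pseudo_refs, reads,
                                 min_overhang = 6L, max_mismatches = 2L) {
  assert_tibble_cols(pseudo_refs, c("circ_id", "junction_sequence"),
                     "pseudo_refs")
  assert_tibble_cols(reads, c("read_id", "sequence"), "reads")
  refs <- pseudo_refs |> arrange(.data$circ_id)
  counts <- setNames(integer(nrow(refs)), refs$circ_id)
  if (nrow(reads) > 0 && nrow(refs) > 0) {
    # byte matrices per construct for the mismatch-tolerant path
    ref_bytes <- lapply(refs$junction_sequence, charToRaw)
    for (ri in seq_len(nrow(reads))) {
      s <- reads$sequence[ri]
      L <- nchar(s)
      best_mm <- Inf
      best_circ <- NA_character_
      for (orient in c("fwd", "rev")) {
        sq <- if (orient == "fwd") s else revcomp(s)
        # exact containment first
        hit <- which(vapply(refs$junction_sequence, function(cs) {
          grepl(sq, cs, fixed = TRUE)
        }, logical(1), USE.NAMES = FALSE))
        if (length(hit) > 0) {
          if (best_mm > 0) {
            best_mm <- 0
            best_circ <- refs$circ_id[hit[1]]
          }
          next
        }
        if (max_mismatches == 0) next
        rb <- charToRaw(sq)
        for (ci in seq_len(nrow(refs))) {
          cb <- ref_bytes[[ci]]
          w2 <- length(cb)
          if (w2 < L) next
          for (o in 0:(w2 - L)) {
            mm <- sum(cb[(o + 1):(o + L)] != rb)
            if (mm <= max_mismatches && mm < best_mm) {
              best_mm <- mm
              best_circ <- refs$circ_id[ci]
            }
          }
        }
      }
      if (!is.na(best_circ)) {
        counts[best_circ] <- counts[best_circ] + 1L
      }
    }
  }
  tibble(circ_id = refs$circ_id, junction_reads = as.integer(counts))
}

#' Quantify circRNAs across samples
#'
#' Convenience wrapper: builds the pseudo references once and counts
#' junction reads in each sample's unmapped pool.
#'
#' @param calls Calls tibble.
#' @param bundle A `genome_bundle`.
#' @param unmapped_by_sample Named list of unmapped-read tibbles.
#' @param read_length,min_overhang,max_mismatches See
#'   [build_pseudo_reference()] and [count_junction_reads()].
#' @return Tibble with `circ_id` and one integer column per sample.
#' @export
quantify_circrnas <- function(calls, bundle, unmapped_by_sample,
                              read_length, min_overhang = 6L,
                              max_mismatches = 2L) {
  refs <- build_pseudo_reference(calls, bundle, read_length, min_overhang)
  out <- tibble(circ_id = sort(refs$circ_id))
  for (s in names(unmapped_by_sample)) {
    cnt <- count_junction_reads(refs, unmapped_by_sample[[s]],
                                min_overhang, max_mismatches)
    out[[s]] <- cnt$junction_reads[match(out$circ_id, cnt$circ_id)]
  }
  out
}

#' Summarize circRNA calls and expression
#'
#' @param calls Calls tibble (with `exonic_length`, `host_gene`).
#' @param expressions Tibble `circ_id`, `junction_reads` (a single sample or
#'   a row sum across samples).
#' @return List with `summary` (one-row tibble: `n_circ`, `median_length`,
#'   `frac_lt10_reads`, `n_single_circ_genes`, `max_multiplicity_gene`,
#'   `max_multiplicity`, `total_backspliced_reads`), `length_dist`,
#'   `read_histogram`, and `per_gene` tibbles.
#' @export
summarize_circ <- function(calls, expressions) {
  assert_tibble_cols(calls, c("circ_id", "exonic_length"), "calls")
  assert_tibble_cols(expressions, c("circ_id", "junction_reads"),
                     "expressions")
  per_gene <- calls |>
    filter(!is.na(.data$host_gene)) |>
    count(.data$host_gene, name = "n_circ") |>
    arrange(desc(.data$n_circ), .data$host_gene)
  read_hist <- expressions |>
    count(.data$junction_reads, name = "n_circ") |>
    arrange(.data$junction_reads)
  max_row <- if (nrow(per_gene) > 0) per_gene[1, ] else {
    tibble(host_gene = NA_character_, n_circ = NA_integer_)
  }
  list(
    summary = tibble(
      n_circ = nrow(calls),
      median_length = if (nrow(calls)) median(calls$exonic_length) else NA,
      frac_lt10_reads = if (nrow(expressions)) {
        mean(expressions$junction_reads < 10)
      } else NA_real_,
      n_single_circ_genes = sum(per_gene$n_circ == 1),
      max_multiplicity_gene = max_row$host_gene,
      max_multiplicity = max_row$n_circ,
      total_backspliced_reads = sum(expressions$junction_reads)
    ),
    length_dist = calls |> select(all_of(c("circ_id", "exonic_length"))),
    read_histogram = read_hist,
    per_gene = per_gene
  )
}
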