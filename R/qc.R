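# Read quality control: 3' adaptor trimming followed by three removal rules
# (length floor, ambiguous-base fraction, low-quality-base fraction), with a
# per-rule accounting report. Removal thresholds are strict inequalities:
# a read is dropped iff its N fraction is *greater than* max_n_fraction, or
# its fraction of bases below the quality threshold is *greater than*
# max_low_q_fraction, both evaluated after trimming.

#' Quality-control parameters
#'
#' @param adaptor 3' adaptor sequence to trim; `""` disables trimming.
#' @param min_adaptor_overlap Minimum number of adaptor bases that must match
#'   at the read 3' end for a trim to happen (default 5).
#' @param max_adaptor_mismatches Mismatches tolerated in the adaptor overlap
#'   (default 0).
#' @param max_n_fraction Maximum tolerated fraction of `N` bases; reads
#'   strictly above are removed (default 0.05).
#' @param low_q_threshold Phred score below which a base counts as
#'   low-quality (default 13, i.e. bases with quality < 13).
#' @param max_low_q_fraction Maximum tolerated fraction of low-quality bases;
#'   reads strictly above are removed (default 0.20).
#' @param min_length_after_trim Reads shorter than this after trimming are
#'   removed (default 20).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(adaptor = "",
                      min_adaptor_overlap = 5L,
                      max_adaptor_mismatches = 0L,
                      max_n_fraction = 0.05,
                      low_q_threshold = 13L,
                      max_low_q_fraction = 0.20,
                      min_length_after_trim = 20L) {
  stopifnot(
    max_n_fraction >= 0, max_n_fraction <= 1,
    max_low_q_fraction >= 0, max_low_q_fraction <= 1,
    min_adaptor_overlap >= 1, min_length_after_trim >= 1
  )
  structure(
    list(
      adaptor = toupper(adaptor),
      min_adaptor_overlap = as.integer(min_adaptor_overlap),
      max_adaptor_mismatches = as.integer(max_adaptor_mismatches),
      max_n_fraction = max_n_fraction,
      low_q_threshold = as.integer(low_q_threshold),
      max_low_q_fraction = max_low_q_fraction,
      min_length_after_trim = as.integer(min_length_after_trim)
    ),
    class = "qc_params"
  )
}

# 3'-end semi-global adaptor search: the adaptor prefix may hang off the read
# end. Returns the 0-based read position where the adaptor starts, or NA.
find_adaptor_start <- function(sequence, adaptor, min_overlap, max_mm) {
  n <- nchar(sequence)
  a <- nchar(adaptor)
  if (n < min_overlap) return(NA_integer_)
  for (pos in 0:(n - min_overlap)) {
    ov <- min(n - pos, a)
    if (ov < min_overlap) break
    frag <- substring(sequence, pos + 1L, pos + ov)
    ref <- substring(adaptor, 1L, ov)
    if (frag == ref || count_mismatches(frag, ref) <= max_mm) {
      return(pos)
    }
  }
  NA_integer_
}

#' Filter reads into clean reads
#'
#' Applies, in order: 3' adaptor trimming, a minimum-length floor, an
#' ambiguous-base (`N`) fraction filter, and a low-quality-base fraction
#' filter. The fraction filters use strict inequalities (a 100-nt read with
#' exactly 5 `N`s or exactly 20 bases under the quality threshold is kept).
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (see
#'   [read_fastq()]).
#' @param params A [qc_params()] object.
#' @return The tibble of kept (possibly trimmed) reads, with a per-rule
#'   accounting tibble attached as attribute `qc_report` (see [qc_report()]).
#' @export
filter_reads <- function(reads, params = qc_params()) {
  assert_tibble_cols(reads, c("read_id", "sequence", "quality"), "reads")
  stopifnot(inherits(params, "qc_params"))
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed read record (sequence/quality length mismatch) for read id: %s",
      reads$read_id[bad[1]]
    ))
  }
  n_in <- nrow(reads)
  n_trimmed <- 0L

  if (nzchar(params$adaptor) && n_in > 0) {
    starts <- vapply(
      reads$sequence, find_adaptor_start, integer(1),
      adaptor = params$adaptor,
      min_overlap = params$min_adaptor_overlap,
      max_mm = params$max_adaptor_mismatches,
      USE.NAMES = FALSE
    )
    hit <- !is.na(starts)
    n_trimmed <- sum(hit)
    if (n_trimmed > 0) {
      reads$sequence[hit] <- substring(reads$sequence[hit], 1L, starts[hit])
      reads$quality[hit] <- substring(reads$quality[hit], 1L, starts[hit])
    }
  }

  len <- nchar(reads$sequence)
  short <- len < params$min_length_after_trim
  n_short <- sum(short)
  reads <- reads[!short, , drop = FALSE]
  len <- len[!short]

  n_count <- vapply(strsplit(reads$sequence, "", fixed = TRUE),
                    function(ch) sum(ch == "N"), integer(1))
  n_frac_bad <- n_count / pmax(len, 1L) > params$max_n_fraction
  n_nfrac <- sum(n_frac_bad)
  reads <- reads[!n_frac_bad, , drop = FALSE]
  len <- len[!n_frac_bad]

  lowq_frac <- vapply(string_to_phred(reads$quality),
                      function(q) mean(q < params$low_q_threshold), numeric(1))
  if (nrow(reads) == 0) lowq_frac <- numeric(0)
  q_bad <- lowq_frac > params$max_low_q_fraction
  n_lowq <- sum(q_bad)
  reads <- reads[!q_bad, , drop = FALSE]

  report <- tibble(
    rule = c("input", "adaptor_trimmed", "removed_short",
             "removed_n_fraction", "removed_low_quality", "kept"),
    n = c(n_in, n_trimmed, n_short, n_nfrac, n_lowq, nrow(reads))
  )
  attr(reads, "qc_report") <- report
  reads
}

#' Retrieve the QC accounting report
#'
#' @param reads The tibble returned by [filter_reads()].
#' @return Tibble with columns `rule` and `n`. The removal rules partition
#'   the input: `removed_short + removed_n_fraction + removed_low_quality +
#'   kept = input`.
#' @export
qc_report <- function(reads) {
  rep <- attr(reads, "qc_report")
  if (is.null(rep)) abort("no qc_report attribute; was filter_reads() run?")
  rep
}
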