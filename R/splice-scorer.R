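# Pluggable splice-site strength scoring. The default scorer is a
# first-order position weight matrix with the classic window geometry:
# donor = 9 nt (3 exonic + 6 intronic, GT at intronic positions 1-2),
# acceptor = 23 nt (20 intronic ending in AG + 3 exonic). Scores are
# log2-odds of the window under the model against background base
# frequencies, summed over positions; a window that matches the background
# exactly scores 0. Matrices can be trained from the annotation's own
# splice sites or loaded from a TSV.

DONOR_WIDTH <- 9L
DONOR_EXONIC <- 3L
ACCEPTOR_WIDTH <- 23L
ACCEPTOR_INTRONIC <- 20L

#' Construct a splice-site scorer
#'
#' @param donor 4 x 9 probability matrix (rows A,C,G,T; columns positions
#'   -3..+6 across the donor site); each column must sum to 1.
#' @param acceptor 4 x 23 probability matrix (columns -20..+3 across the
#'   acceptor site).
#' @param background Length-4 base frequency vector (A,C,G,T).
#' @return A `splice_scorer` object.
#' @export
splice_scorer <- function(donor, acceptor, background = rep(0.25, 4)) {
  stopifnot(
    is.matrix(donor), nrow(donor) == 4, ncol(donor) == DONOR_WIDTH,
    is.matrix(acceptor), nrow(acceptor) == 4,
    ncol(acceptor) == ACCEPTOR_WIDTH,
    length(background) == 4
  )
  if (any(abs(colSums(donor) - 1) > 1e-6) ||
      any(abs(colSums(acceptor) - 1) > 1e-6)) {
    abort("scorer matrix columns must each sum to 1")
  }
  background <- background / sum(background)
  rownames(donor) <- rownames(acceptor) <- BASES
  names(background) <- BASES
  structure(list(donor = donor, acceptor = acceptor, background = background),
            class = "splice_scorer")
}

# strand-aware genomic windows around a splice boundary.
# `pos` is the junction genomic coordinate (0-based): the exon end for a
# plus-strand donor / minus-strand acceptor, the exon start for a
# plus-strand acceptor / minus-strand donor. Out-of-bounds bases pad as N.
extract_window <- function(seq, start, end, rc = FALSE) {
  n <- nchar(seq)
  lo <- max(start, 0L)
  hi <- min(end, n)
  core <- if (hi > lo) subseq0(seq, lo, hi) else ""
  left_pad <- strrep("N", max(0L, lo - start))
  right_pad <- strrep("N", max(0L, end - hi))
  w <- paste0(left_pad, core, right_pad)
  if (rc) revcomp(w) else w
}

donor_window <- function(seq, strand, pos) {
  if (strand == "+") {
    extract_window(seq, pos - DONOR_EXONIC, pos + DONOR_WIDTH - DONOR_EXONIC)
  } else {
    extract_window(seq, pos - (DONOR_WIDTH - DONOR_EXONIC),
                   pos + DONOR_EXONIC, rc = TRUE)
  }
}

acceptor_window <- function(seq, strand, pos) {
  if (strand == "+") {
    extract_window(seq, pos - ACCEPTOR_INTRONIC,
                   pos + ACCEPTOR_WIDTH - ACCEPTOR_INTRONIC)
  } else {
    extract_window(seq, pos - (ACCEPTOR_WIDTH - ACCEPTOR_INTRONIC),
                   pos + ACCEPTOR_INTRONIC, rc = TRUE)
  }
}

pwm_score <- function(windows, pwm, background) {
  vapply(windows, function(w) {
    ch <- strsplit(w, "", fixed = TRUE)[[1]]
    if (length(ch) != ncol(pwm)) {
      abort(sprintf("window length %d does not match model width %d",
                    length(ch), ncol(pwm)))
    }
    idx <- match(ch, BASES)
    if (anyNA(idx)) return(-Inf)  # N or other ambiguity: site unusable
    sum(log2(pwm[cbind(idx, seq_along(idx))] / background[idx]))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score donor and acceptor windows
#'
#' @param scorer A [splice_scorer()].
#' @param donor_seq Character vector of 9-nt donor windows (exon last 3 nt
#'   then intron first 6 nt, transcript orientation).
#' @param acceptor_seq Character vector of 23-nt acceptor windows (intron
#'   last 20 nt then exon first 3 nt).
#' @return Tibble with `donor_score` and `acceptor_score` (log2-odds; `-Inf`
#'   when a window contains `N`).
#' @export
score_splice_sites <- function(scorer, donor_seq, acceptor_seq) {
  stopifnot(inherits(scorer, "splice_scorer"))
  tibble(
    donor_score = pwm_score(donor_seq, scorer$donor, scorer$background),
    acceptor_score = pwm_score(acceptor_seq, scorer$acceptor,
                               scorer$background)
  )
}

#' Train the default PWM scorer from the annotation's splice sites
#'
#' Collects every annotated intron's donor and acceptor windows (transcript
#' orientation), estimates per-position base probabilities with add-one
#' smoothing, and uses the genome's base composition as background.
#'
#' @param bundle A `genome_bundle` with multi-exon genes.
#' @param pseudocount Add-one style smoothing constant (default 1).
#' @return A `splice_scorer`.
#' @export
train_splice_scorer <- function(bundle, pseudocount = 1) {
  stopifnot(inherits(bundle, "genome_bundle"))
  donors <- character(0)
  acceptors <- character(0)
  for (g in unique(bundle$exons$gene_id)) {
    ex <- bundle$exons[bundle$exons$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2) next
    seq <- bundle$sequences[[ex$chrom[1]]]
    strand <- ex$strand[1]
    for (ii in seq_len(nrow(ex) - 1L)) {
      if (strand == "+") {
        donors <- c(donors, donor_window(seq, "+", ex$end[ii]))
        acceptors <- c(acceptors, acceptor_window(seq, "+",
                                                  ex$start[ii + 1L]))
      } else {
        donors <- c(donors, donor_window(seq, "-", ex$start[ii + 1L]))
        acceptors <- c(acceptors, acceptor_window(seq, "-", ex$end[ii]))
      }
    }
  }
  if (length(donors) == 0) {
    abort("no multi-exon genes: cannot train a splice scorer")
  }
  count_matrix <- function(windows, width) {
    m <- matrix(pseudocount, nrow = 4, ncol = width,
                dimnames = list(BASES, NULL))
    for (w in windows) {
      ch <- strsplit(w, "", fixed = TRUE)[[1]]
      idx <- match(ch, BASES)
      ok <- !is.na(idx)
      m[cbind(idx[ok], seq_len(width)[ok])] <-
        m[cbind(idx[ok], seq_len(width)[ok])] + 1
    }
    sweep(m, 2, colSums(m), "/")
  }
  bg <- base_composition(bundle)
  splice_scorer(
    donor = count_matrix(donors, DONOR_WIDTH),
    acceptor = count_matrix(acceptors, ACCEPTOR_WIDTH),
    background = bg
  )
}

base_composition <- function(bundle) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (seq in bundle$sequences) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    tb <- table(factor(ch, levels = BASES))
    counts <- counts + as.numeric(tb)
  }
  if (sum(counts) == 0) return(rep(0.25, 4))
  counts / sum(counts)
}

#' Write a splice scorer to TSV
#'
#' Long format: `model` (donor/acceptor/background), `position`, `base`,
#' `probability`.
#'
#' @param scorer A `splice_scorer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splice_scorer <- function(scorer, path) {
  stopifnot(inherits(scorer, "splice_scorer"))
  long <- function(m, name) {
    tibble(
      model = name,
      position = rep(seq_len(ncol(m)), each = 4),
      base = rep(BASES, ncol(m)),
      probability = as.vector(m)
    )
  }
  out <- bind_rows(
    long(scorer$donor, "donor"),
    long(scorer$acceptor, "acceptor"),
    tibble(model = "background", position = 1L, base = BASES,
           probability = unname(scorer$background))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a splice scorer from TSV
#'
#' @param path TSV written by [write_splice_scorer()].
#' @return A `splice_scorer`.
#' @export
read_splice_scorer <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  wide <- function(name, width) {
    sub <- tab[tab$model == name, , drop = FALSE]
    m <- matrix(NA_real_, 4, width, dimnames = list(BASES, NULL))
    m[cbind(match(sub$base, BASES), sub$position)] <- sub$probability
    m
  }
  bgt <- tab[tab$model == "background", , drop = FALSE]
  splice_scorer(
    donor = wide("donor", DONOR_WIDTH),
    acceptor = wide("acceptor", ACCEPTOR_WIDTH),
    background = bgt$probability[match(BASES, bgt$base)]
  )
}
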