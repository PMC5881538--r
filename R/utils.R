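# Shared low-level helpers. Coordinates are 0-based half-open everywhere
# inside the package; conversion to 1-based happens only at GTF boundaries.

BASES <- c("A", "C", "G", "T")

# data.table is used via :: but with `[` NSE syntax
.datatable.aware <- TRUE

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences over `A`, `C`, `G`, `T`, `N`
#'   (case-insensitive).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGTAC"))
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

# 0-based half-open substring of a single sequence string
subseq0 <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

# Hamming distance between equal-length string pairs; vectorised with a fast
# path for exact equality (the common case on error-free data).
count_mismatches <- function(x, y) {
  stopifnot(length(x) == length(y))
  out <- integer(length(x))
  ne <- which(x != y)
  for (i in ne) {
    out[i] <- sum(charToRaw(x[i]) != charToRaw(y[i]))
  }
  out
}

# Phred+33 helpers --------------------------------------------------------

phred_to_string <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

string_to_phred <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# deterministic random DNA
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# sample() that treats a length-1 x as a single value, not as 1:x
resample <- function(x, size = 1L, replace = FALSE) {
  if (length(x) == 1L) return(rep(x, size))
  sample(x, size, replace = replace)
}

# circular substring: `len` bases starting at 0-based `start` of a circular
# sequence `seq`, wrapping as needed
circular_substr <- function(seq, start, len) {
  n <- nchar(seq)
  start <- start %% n
  reps <- ceiling((start + len) / n)
  lin <- paste(rep(seq, reps), collapse = "")
  substring(lin, start + 1L, start + len)
}

assert_tibble_cols <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must contain column(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}
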