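# FASTQ input/output. Reads are carried through the pipeline as a tibble
# with one row per read: read_id, sequence, quality (Phred+33 string).
# A four-line parser is used (rather than an XStringSet round trip) because
# the QC contract requires a parse error naming the offending read id and
# byte-stable output for the determinism guarantees.

#' Read a FASTQ file into a tibble
#'
#' @param path Path to an uncompressed FASTQ file (Phred+33).
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character()))
  }
  if (length(lines) %% 4 != 0) {
    abort(sprintf("FASTQ file %s is truncated (line count not a multiple of 4)",
                  path))
  }
  idx <- seq(1, length(lines), by = 4)
  ids <- sub("^@", "", lines[idx])
  seqs <- lines[idx + 1]
  quals <- lines[idx + 3]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed FASTQ record (sequence/quality length mismatch) for read id: %s",
      ids[bad[1]]
    ))
  }
  tibble(read_id = ids, sequence = toupper(seqs), quality = quals)
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  assert_tibble_cols(reads, c("read_id", "sequence", "quality"), "reads")
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                         "+", reads$quality))
  writeLines(out, path)
  invisible(path)
}
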