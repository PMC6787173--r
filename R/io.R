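#' Read and write event tables, layouts and summaries as CSV
#'
#' Event tables are stored one row per event with one column per channel
#' (long format with a `well_id` column); layouts and well summaries are
#' plain CSV. These are thin wrappers around [utils::read.csv()] /
#' [utils::write.csv()] that validate the expected columns.
#'
#' @param path File path.
#' @param x Object to write.
#' @return `read_event_table()` returns a `data.frame` with at least the
#'   channel columns `FSC`, `SSC`, `PI`, `AF647`, `FITC`.
#' @name event_io
NULL

#' @rdname event_io
#' @export
read_event_table <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("FSC", "SSC", "PI", "AF647", "FITC")
  missing <- setdiff(need, names(ev))
  if (length(missing) > 0L) {
    stop(sprintf("event table '%s' lacks channel column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ev
}

#' @rdname event_io
#' @export
write_event_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read and write FASTA sequence sets
#'
#' Wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()] returning/accepting plain named character
#' vectors, the representation used by [scan_sites()].
#'
#' @param path File path.
#' @param seqs Named character vector of DNA sequences.
#' @name fasta_io
NULL

#' @rdname fasta_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname fasta_io
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
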