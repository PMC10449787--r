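#' Read nucleotide contigs from a FASTA file
#'
#' Reads a nucleotide FASTA file into a contig tibble. Sequences are
#' uppercased on read and record order is preserved. Only the first
#' whitespace-delimited token of each header is kept as the contig id.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig_id`, `sequence` and `length` (bp),
#'   one row per record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "acgtacgt", ">c2", "GGGCCC"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  # Biostrings accepts some malformed input silently; pre-check that the
  # first non-blank line starts a record so we can name the offending line.
  lines <- readLines(path, n = 100L, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first) && !startsWith(trimws(lines[first]), ">")) {
    abort(paste0("Malformed FASTA: line ", first, " of ", path,
                 " is not a header ('>') line"))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble(contig_id = character(), sequence = character(),
                  length = integer()))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(paste0("Duplicate contig id(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("Non-nucleotide characters in record(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(contig_id = ids, sequence = unname(seqs),
         length = nchar(unname(seqs)))
}

#' Write contigs to a FASTA file
#'
#' @param contigs A contig tibble with columns `contig_id` and `sequence`
#'   (as returned by [read_fasta()] or [simulate_dataset()]).
#' @param path Output file path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 80L) {
  stopifnot(all(c("contig_id", "sequence") %in% names(contigs)))
  if (anyNA(contigs$sequence)) {
    abort(paste0("Cannot write FASTA: sequence not realized for contig(s) ",
                 paste(head(contigs$contig_id[is.na(contigs$sequence)], 5),
                       collapse = ", "),
                 ". Regenerate with realize_sequence = TRUE."))
  }
  set <- Biostrings::DNAStringSet(setNames(contigs$sequence,
                                           contigs$contig_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# GC fraction of a vector of sequences (N bases excluded from denominator).
gc_fraction <- function(sequence) {
  n_gc <- nchar(gsub("[^GC]", "", sequence))
  n_acgt <- nchar(gsub("[^ACGT]", "", sequence))
  ifelse(n_acgt == 0, 0, n_gc / n_acgt)
}
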