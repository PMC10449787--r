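#' Predict protein-coding genes on contigs
#'
#' Obtains ORF calls for each contig, either through an external
#' metagenome-mode gene caller (the `"prodigal"` backend, run as a
#' subprocess) or through a built-in six-frame scanner (`"naive"`) that
#' needs no external binary. The naive scanner reports complete ORFs of at
#' least `min_orf_nt` nucleotides running from a start codon (ATG, GTG or
#' TTG) to the next in-frame stop; ambiguous bases (N) terminate extension.
#' It approximates the external caller for fixtures and simulations and is
#' not claimed equivalent to it.
#'
#' Coordinates are 1-based inclusive and include the terminal stop codon
#' (the gene-caller convention); `aa_seq` excludes the stop, so a complete
#' ORF of L nucleotides yields L/3 - 1 amino acids.
#'
#' @param contigs A contig tibble (see [read_fasta()]).
#' @param backend `"naive"` (default, no external dependency) or
#'   `"prodigal"` (requires the binary on `PATH`; invoked with the
#'   metagenome flag `-p meta`).
#' @param min_orf_nt Minimum ORF length in nucleotides for the naive
#'   scanner (start through stop codon inclusive).
#' @return An ORF tibble with columns `contig_id`, `orf_id`, `start`,
#'   `end`, `strand` (+1/-1), `partial_left`, `partial_right`, `aa_seq`.
#'   Zero rows is a valid result.
#' @export
call_genes <- function(contigs, backend = c("naive", "prodigal"),
                       min_orf_nt = 90L) {
  backend <- match.arg(backend)
  stopifnot(all(c("contig_id", "sequence") %in% names(contigs)))
  if (backend == "prodigal") {
    return(call_genes_prodigal(contigs))
  }
  res <- purrr::map2(contigs$contig_id, contigs$sequence, scan_orfs_naive,
                     min_orf_nt = min_orf_nt)
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) return(empty_orf_table())
  out
}

empty_orf_table <- function() {
  tibble(contig_id = character(), orf_id = character(),
         start = integer(), end = integer(), strand = integer(),
         partial_left = logical(), partial_right = logical(),
         aa_seq = character())
}

START_CODONS <- c("ATG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Six-frame complete-ORF scan of one contig. Within a frame, the first
# start codon after the previous stop opens an ORF; the next in-frame stop
# closes it (non-overlapping per frame). N-containing codons reset the
# open start without emitting.
scan_orfs_naive <- function(contig_id, sequence, min_orf_nt = 90L) {
  len <- nchar(sequence)
  if (len < min_orf_nt) return(empty_orf_table())
  fwd <- scan_strand(sequence, min_orf_nt)
  rc <- revcomp(sequence)
  rev <- scan_strand(rc, min_orf_nt)
  orfs <- dplyr::bind_rows(
    if (nrow(fwd)) dplyr::mutate(fwd, strand = 1L),
    if (nrow(rev)) dplyr::mutate(rev,
                                 start2 = len - .data$end + 1L,
                                 end = len - .data$start + 1L,
                                 start = .data$start2, strand = -1L)
  )
  if (is.null(orfs) || nrow(orfs) == 0L) return(empty_orf_table())
  orfs <- orfs |>
    dplyr::select("start", "end", "strand", "aa_seq") |>
    dplyr::arrange(.data$start, .data$end, .data$strand)
  tibble(contig_id = contig_id,
         orf_id = sprintf("%s_orf%03d", contig_id, seq_len(nrow(orfs))),
         start = orfs$start, end = orfs$end, strand = orfs$strand,
         partial_left = FALSE, partial_right = FALSE,
         aa_seq = orfs$aa_seq)
}

# Scan the three forward frames of `sequence`; coordinates on that strand.
scan_strand <- function(sequence, min_orf_nt) {
  len <- nchar(sequence)
  hits <- list()
  for (frame in 0:2) {
    n_codon <- (len - frame) %/% 3L
    if (n_codon < 2L) next
    pos <- frame + seq(1L, by = 3L, length.out = n_codon)
    codons <- substring(sequence, pos, pos + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% START_CODONS
    has_n <- grepl("N", codons, fixed = TRUE)
    events <- which(is_stop | is_start | has_n)
    cur <- NA_integer_
    for (i in events) {
      if (has_n[i]) {
        cur <- NA_integer_
      } else if (is_stop[i]) {
        if (!is.na(cur) && (i - cur + 1L) * 3L >= min_orf_nt) {
          hits[[length(hits) + 1L]] <- c(pos[cur], pos[i] + 2L)
        }
        cur <- NA_integer_
      } else if (is.na(cur)) {
        cur <- i
      }
    }
  }
  if (length(hits) == 0L) {
    return(tibble(start = integer(), end = integer(), aa_seq = character()))
  }
  m <- do.call(rbind, hits)
  aa <- vapply(seq_len(nrow(m)), function(k) {
    translate_orf(substr(sequence, m[k, 1], m[k, 2] - 3L))
  }, character(1))
  tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]), aa_seq = aa)
}

# Translate a coding sequence (stop codon already removed); alternative
# starts (GTG/TTG) are reported as M, as gene callers do.
translate_orf <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  if (nchar(aa) > 0L) substr(aa, 1L, 1L) <- "M"
  aa
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# External gene-caller adapter: writes contigs to a temp FASTA, runs the
# caller in metagenome mode, parses its GFF coordinates and protein FASTA.
call_genes_prodigal <- function(contigs) {
  if (Sys.which("prodigal") == "") {
    abort(paste0("External gene caller 'prodigal' not found on PATH. ",
                 "Use call_genes(..., backend = \"naive\") for the ",
                 "built-in scanner."))
  }
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff")
  faa <- tempfile(fileext = ".faa")
  on.exit(unlink(c(fa, gff, faa)), add = TRUE)
  write_fasta(contigs, fa)
  status <- system2("prodigal",
                    c("-p", "meta", "-i", fa, "-f", "gff", "-o", gff,
                      "-a", faa, "-q"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) abort("External gene caller exited with non-zero status")
  parse_prodigal_output(gff, faa)
}

parse_prodigal_output <- function(gff_path, faa_path) {
  lines <- readLines(gff_path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) return(empty_orf_table())
  f <- strsplit(lines, "\t", fixed = TRUE)
  contig_id <- vapply(f, `[[`, "", 1L)
  start <- as.integer(vapply(f, `[[`, "", 4L))
  end <- as.integer(vapply(f, `[[`, "", 5L))
  strand <- ifelse(vapply(f, `[[`, "", 7L) == "+", 1L, -1L)
  attrs <- vapply(f, `[[`, "", 9L)
  gene_no <- sub("^ID=[^_]*_([0-9]+);.*$", "\\1", attrs)
  partial <- sub(".*partial=([01]{2}).*", "\\1", attrs)
  aa <- Biostrings::readAAStringSet(faa_path)
  aa_ids <- sub("\\s.*$", "", names(aa))
  orf_id <- paste0(contig_id, "_", gene_no)
  aa_seq <- sub("\\*$", "", as.character(aa)[match(orf_id, aa_ids)])
  tibble(contig_id = contig_id, orf_id = orf_id, start = start, end = end,
         strand = strand,
         partial_left = substr(partial, 1L, 1L) == "1",
         partial_right = substr(partial, 2L, 2L) == "1",
         aa_seq = unname(aa_seq))
}

#' Read or write a cached gene-call table
#'
#' Gene calls are cached as plain TSV with 1-based inclusive coordinates so
#' a pipeline run can skip gene calling. Columns: `contig_id`, `orf_id`,
#' `start`, `end`, `strand` (+1/-1), `partial_left`, `partial_right` and
#' optionally `aa_seq`.
#'
#' @param path Path to the TSV file.
#' @return For `read_gene_table()`, an ORF tibble; `write_gene_table()`
#'   returns `path` invisibly.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("contig_id", "orf_id", "start", "end", "strand",
           "partial_left", "partial_right")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    abort(paste0("Gene table ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"aa_seq" %in% names(df)) df$aa_seq <- NA_character_
  bad <- df$start >= df$end | df$start < 1L
  if (any(bad)) {
    abort(paste0("Invalid coordinates (need 1 <= start < end) for: ",
                 paste(df$orf_id[bad], collapse = ", ")))
  }
  as_tibble(df[c(req, "aa_seq")]) |>
    dplyr::mutate(start = as.integer(.data$start),
                  end = as.integer(.data$end),
                  strand = as.integer(.data$strand))
}

#' @param orfs An ORF tibble.
#' @rdname read_gene_table
#' @export
write_gene_table <- function(orfs, path) {
  utils::write.table(orfs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
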