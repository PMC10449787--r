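#' Homology-search e-value thresholds
#'
#' The filtering ceilings applied to the three search layers before any
#' hit enters the feature table: protein-vs-protein hits are kept below
#' 1e-5, profile-HMM hits below a full-sequence e-value of 1e-10, and
#' iterative-profile hits below 1e-5. All comparisons are strict (`<`).
#'
#' @param protein_evalue_max Ceiling for protein-vs-protein hits.
#' @param hmm_fullseq_evalue_max Ceiling for profile-HMM hits
#'   (full-sequence e-value column, not per-domain).
#' @param iterative_evalue_max Ceiling for iterative-profile hits.
#' @return A named list of class `av_thresholds`.
#' @export
search_thresholds <- function(protein_evalue_max = 1e-5,
                              hmm_fullseq_evalue_max = 1e-10,
                              iterative_evalue_max = 1e-5) {
  stopifnot(protein_evalue_max > 0, hmm_fullseq_evalue_max > 0,
            iterative_evalue_max > 0)
  structure(list(protein_evalue_max = protein_evalue_max,
                 hmm_fullseq_evalue_max = hmm_fullseq_evalue_max,
                 iterative_evalue_max = iterative_evalue_max),
            class = "av_thresholds")
}

HIT_SOURCES <- c("protein_nr", "pvog_hmm", "ocav_profile", "pfam")
HIT_CLASSES <- c("archaeal_virus", "phage", "archaea", "bacteria",
                 "other", "unknown")
# Class groupings used for affiliation counts: hits to archaea or archaeal
# viruses count as archaeal evidence, hits to bacteria or phages as phage
# evidence (mirrors "affiliated with reference archaea or archaeal viruses").
ARCHAEAL_CLASSES <- c("archaeal_virus", "archaea")
PHAGE_CLASSES <- c("phage", "bacteria")

empty_hit_table <- function() {
  tibble(orf_id = character(), contig_id = character(),
         target_id = character(), evalue = numeric(),
         bitscore = numeric(), target_class = character(),
         source_db = character())
}

#' Describe a reference database for homology searches
#'
#' A reference descriptor names the search target (a protein FASTA or a
#' profile collection), the tabular `target_id -> target_class` metadata
#' map shipped with it, and which search layer it feeds. Target classes are
#' always taken from this map, never guessed from free-text annotations.
#'
#' @param path Path to the database file(s) (unused by the mock backend).
#' @param metadata Either a tibble with columns `target_id` and
#'   `target_class`, or the path to a two-column TSV with those columns.
#' @param source_db One of `"protein_nr"`, `"pvog_hmm"`, `"ocav_profile"`,
#'   `"pfam"`.
#' @param fixture Optional hit tibble returned verbatim by the mock backend.
#' @return A list of class `av_refdb`.
#' @export
reference_db <- function(path = NULL, metadata = NULL,
                         source_db = HIT_SOURCES, fixture = NULL) {
  source_db <- match.arg(source_db)
  if (is.character(metadata)) {
    metadata <- as_tibble(utils::read.table(metadata, header = TRUE,
                                            sep = "\t",
                                            stringsAsFactors = FALSE))
  }
  if (!is.null(metadata)) {
    stopifnot(all(c("target_id", "target_class") %in% names(metadata)))
    bad <- setdiff(unique(metadata$target_class), HIT_CLASSES)
    if (length(bad)) {
      abort(paste0("Unknown target_class value(s) in metadata: ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(list(path = path, metadata = metadata, source_db = source_db,
                 fixture = fixture),
            class = "av_refdb")
}

#' Run or ingest a homology search
#'
#' Produces a typed hit table from one of the three search layers. Three
#' backends are supported: `"precomputed"` parses an existing tabular
#' output file (BLAST-style 12-column format for protein mode, HMMER tblout
#' for the profile modes), `"external"` invokes the search binary as a
#' subprocess and parses its output, and `"mock"` returns the descriptor's
#' fixture table verbatim, which keeps the whole pipeline runnable offline.
#'
#' @param proteins Path to the query protein FASTA (external backend only).
#' @param db An [reference_db()] descriptor.
#' @param mode `"protein"`, `"hmm"` or `"iterative"`.
#' @param backend `"precomputed"`, `"external"` or `"mock"`.
#' @param hits_file Path to the tabular output (precomputed backend).
#' @param orfs Optional ORF tibble used to map `orf_id` to `contig_id`;
#'   without it the contig id is derived by stripping the final
#'   `_`-delimited suffix of the ORF id.
#' @param iterations Number of iterations for the iterative mode (external
#'   backend).
#' @return A hit tibble with columns `orf_id`, `contig_id`, `target_id`,
#'   `evalue`, `bitscore`, `target_class`, `source_db`. Unfiltered: apply
#'   [filter_hits()] before summarising.
#' @export
run_search <- function(proteins = NULL, db, mode = c("protein", "hmm",
                                                     "iterative"),
                       backend = c("precomputed", "external", "mock"),
                       hits_file = NULL, orfs = NULL, iterations = 3L) {
  mode <- match.arg(mode)
  backend <- match.arg(backend)
  stopifnot(inherits(db, "av_refdb"))
  if (backend == "mock") {
    if (is.null(db$fixture)) abort("Mock backend needs a fixture hit table")
    return(as_tibble(db$fixture))
  }
  if (backend == "external") {
    hits_file <- run_search_external(proteins, db, mode, iterations)
  }
  if (is.null(hits_file)) {
    abort("Precomputed backend needs a hits_file path")
  }
  raw <- if (mode == "protein") read_blast_tab(hits_file)
         else read_hmmer_tblout(hits_file)
  finalize_hits(raw, db, orfs)
}

run_search_external <- function(proteins, db, mode, iterations) {
  tool <- switch(mode, protein = "blastp", hmm = "hmmsearch",
                 iterative = "jackhmmer")
  if (Sys.which(tool) == "") {
    abort(paste0("Search binary '", tool, "' not found on PATH. Use ",
                 "backend = \"precomputed\" with an existing hit table, ",
                 "or backend = \"mock\" with a fixture."))
  }
  out <- tempfile(fileext = ".tab")
  args <- switch(mode,
    protein = c("-query", proteins, "-db", db$path, "-outfmt", "6",
                "-out", out),
    hmm = c("--tblout", out, db$path, proteins),
    iterative = c("-N", as.character(iterations), "--tblout", out,
                  proteins, db$path))
  status <- system2(tool, args, stdout = FALSE, stderr = FALSE)
  if (status != 0L) abort(paste0(tool, " exited with status ", status))
  out
}

# Attach contig ids and target classes to a parsed raw hit table.
finalize_hits <- function(raw, db, orfs = NULL) {
  if (nrow(raw) == 0L) return(empty_hit_table())
  contig_id <- if (!is.null(orfs)) {
    orfs$contig_id[match(raw$orf_id, orfs$orf_id)]
  } else {
    sub("_[^_]+$", "", raw$orf_id)
  }
  cls <- if (is.null(db$metadata)) rep(NA_character_, nrow(raw)) else
    db$metadata$target_class[match(raw$target_id, db$metadata$target_id)]
  if (anyNA(cls)) {
    warn(paste0(sum(is.na(cls)), " hit(s) to target(s) absent from the ",
                "reference metadata map; classed 'unknown'"))
    cls[is.na(cls)] <- "unknown"
  }
  tibble(orf_id = raw$orf_id, contig_id = contig_id,
         target_id = raw$target_id, evalue = raw$evalue,
         bitscore = raw$bitscore, target_class = cls,
         source_db = db$source_db)
}

#' Parse BLAST-style 12-column tabular output
#'
#' @param path Path to a tab-separated file in the classic 12-column
#'   format (query, target, pident, length, mismatch, gapopen, qstart,
#'   qend, sstart, send, evalue, bitscore).
#' @return A tibble with `orf_id`, `target_id`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  if (file.size(path) == 0L) {
    return(tibble(orf_id = character(), target_id = character(),
                  evalue = numeric(), bitscore = numeric()))
  }
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 12L) {
    abort(paste0("Expected >= 12 tab-separated columns in ", path,
                 ", found ", ncol(df)))
  }
  tibble(orf_id = as.character(df[[1]]), target_id = as.character(df[[2]]),
         evalue = as.numeric(df[[11]]), bitscore = as.numeric(df[[12]]))
}

#' Parse HMMER tblout output
#'
#' Reads the whitespace-separated per-target table written by
#' `hmmsearch --tblout` / `jackhmmer --tblout`. The query protein is the
#' target sequence column; the profile is the query column. The
#' full-sequence e-value and score columns (5 and 6) are used.
#'
#' @param path Path to a tblout file.
#' @return A tibble with `orf_id`, `target_id`, `evalue`, `bitscore`.
#' @export
read_hmmer_tblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(orf_id = character(), target_id = character(),
                  evalue = numeric(), bitscore = numeric()))
  }
  f <- strsplit(trimws(lines), "[[:space:]]+")
  short <- lengths(f) < 6L
  if (any(short)) {
    abort(paste0("Malformed tblout line(s) in ", path, ": ",
                 paste(which(short), collapse = ", ")))
  }
  tibble(orf_id = vapply(f, `[[`, "", 1L),
         target_id = vapply(f, `[[`, "", 3L),
         evalue = as.numeric(vapply(f, `[[`, "", 5L)),
         bitscore = as.numeric(vapply(f, `[[`, "", 6L)))
}

#' Filter homology hits by source-specific e-value ceilings
#'
#' Keeps a hit iff its e-value is strictly below the ceiling for its
#' search layer (a hit at exactly the ceiling is removed). Row order is
#' preserved; the operation is idempotent and monotone in the thresholds.
#'
#' @param hits A hit tibble (see [run_search()]).
#' @param thresholds A [search_thresholds()] object.
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, thresholds = search_thresholds()) {
  if (nrow(hits) == 0L) return(hits)
  ceiling_for <- c(protein_nr = thresholds$protein_evalue_max,
                   pvog_hmm = thresholds$hmm_fullseq_evalue_max,
                   ocav_profile = thresholds$iterative_evalue_max)
  bad <- setdiff(unique(hits$source_db), names(ceiling_for))
  if (length(bad)) {
    abort(paste0("No e-value threshold defined for source_db: ",
                 paste(bad, collapse = ", ")))
  }
  hits[hits$evalue < ceiling_for[hits$source_db], , drop = FALSE]
}

# Best hit per ORF (optionally per source_db): max bitscore, ties broken
# by min e-value, then lexicographically smallest target_id.
best_hits <- function(hits, per_db = TRUE) {
  keys <- if (per_db) c("orf_id", "source_db") else "orf_id"
  hits |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)),
                   dplyr::desc(.data$bitscore), .data$evalue,
                   .data$target_id) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys)), .keep_all = TRUE)
}

#' Summarise filtered homology hits per contig
#'
#' Aggregates a filtered hit table into the per-contig, per-search-layer
#' quantities the feature table is built from. For every layer the best
#' hit per ORF is chosen by maximum bitscore (ties: minimum e-value, then
#' lexicographic target id). The result is one wide row per contig.
#'
#' @param orfs ORF tibble; defines the universe of valid `orf_id`s and the
#'   per-contig ORF counts.
#' @param hits A filtered hit tibble ([filter_hits()]).
#' @param contigs Optional contig tibble; contigs without ORFs or hits are
#'   then included with zero counts.
#' @return A tibble with one row per contig: for each layer
#'   `<db>_n_hits`, `<db>_n_orfs_with_hit`, `<db>_fraction_orfs_annotated`,
#'   `<db>_n_best_archaeal`, `<db>_n_best_phage`, `<db>_mean_best_bitscore`;
#'   plus `ocav_hit_count` (all filtered iterative-profile hits) and
#'   `archaeal_fraction_annotated` (fraction of hit-carrying ORFs whose
#'   overall best hit is to archaea or archaeal viruses).
#' @export
summarize_hits <- function(orfs, hits, contigs = NULL) {
  stray <- setdiff(unique(hits$orf_id), orfs$orf_id)
  if (length(stray)) {
    abort(paste0("Hits reference unknown orf_id(s): ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  ids <- if (!is.null(contigs)) contigs$contig_id else
    unique(c(orfs$contig_id, hits$contig_id))
  n_orfs <- orfs |> dplyr::count(.data$contig_id, name = "n_orfs")
  base <- tibble(contig_id = ids) |>
    dplyr::left_join(n_orfs, by = "contig_id") |>
    dplyr::mutate(n_orfs = dplyr::coalesce(.data$n_orfs, 0L))

  dbs <- c("protein_nr", "pvog_hmm", "ocav_profile")
  hits <- hits |>
    dplyr::mutate(contig_id = orfs$contig_id[match(.data$orf_id,
                                                   orfs$orf_id)])
  per_db_cols <- c("n_hits", "n_orfs_with_hit", "fraction_orfs_annotated",
                   "n_best_archaeal", "n_best_phage", "mean_best_bitscore")
  out <- base
  for (db in dbs) {
    h <- hits[hits$source_db == db, , drop = FALSE]
    n_all <- h |> dplyr::count(.data$contig_id, name = "n_hits")
    bh <- best_hits(h)
    agg <- bh |>
      dplyr::group_by(.data$contig_id) |>
      dplyr::summarise(
        n_orfs_with_hit = dplyr::n(),
        n_best_archaeal = sum(.data$target_class %in% ARCHAEAL_CLASSES),
        n_best_phage = sum(.data$target_class %in% PHAGE_CLASSES),
        mean_best_bitscore = mean(.data$bitscore),
        .groups = "drop")
    out <- out |>
      dplyr::left_join(n_all, by = "contig_id") |>
      dplyr::left_join(agg, by = "contig_id") |>
      dplyr::mutate(dplyr::across(dplyr::all_of(setdiff(per_db_cols,
                                  "fraction_orfs_annotated")),
                                  ~ dplyr::coalesce(as.numeric(.x), 0)),
                    fraction_orfs_annotated =
                      ifelse(.data$n_orfs == 0L, 0,
                             .data$n_orfs_with_hit / .data$n_orfs)) |>
      dplyr::rename_with(~ paste0(db, "_", .x),
                         dplyr::all_of(per_db_cols))
  }

  overall <- best_hits(hits, per_db = FALSE) |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(
      n_annotated = dplyr::n(),
      archaeal_fraction_annotated =
        mean(.data$target_class %in% ARCHAEAL_CLASSES),
      .groups = "drop")
  out |>
    dplyr::left_join(overall, by = "contig_id") |>
    dplyr::mutate(
      n_annotated = dplyr::coalesce(.data$n_annotated, 0L),
      archaeal_fraction_annotated =
        dplyr::coalesce(.data$archaeal_fraction_annotated, 0),
      ocav_hit_count = .data$ocav_profile_n_hits)
}

#' Read or write a cached hit table
#'
#' Hit tables are cached as TSV with the full typed column set so searches
#' can be run once and reused.
#'
#' @param path Path to the TSV file.
#' @return For `read_hit_table()`, a hit tibble; `write_hit_table()`
#'   returns `path` invisibly.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("orf_id", "contig_id", "target_id", "evalue", "bitscore",
           "target_class", "source_db")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    abort(paste0("Hit table ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  as_tibble(df[req])
}

#' @param hits A hit tibble.
#' @rdname read_hit_table
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
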