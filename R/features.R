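#' The per-contig feature catalog
#'
#' The 27 named features the classifier is trained on: nine genome
#' architecture attributes, five hit summaries for each of the three
#' homology layers (protein-vs-protein, profile-HMM, iterative-profile),
#' the raw iterative-profile hit count, the archaeal fraction among
#' annotated ORFs, and the no-genes flag. Column order is fixed and
#' versioned; a trained model stores the catalog version it was built with
#' and refuses tables built under a different one.
#'
#' @return Character vector of 27 feature names, with a `version` attribute.
#' @export
feature_catalog <- function() {
  dbs <- c("protein_nr", "pvog_hmm", "ocav_profile")
  per_db <- c("n_orfs_with_hit", "fraction_orfs_annotated",
              "n_best_archaeal", "n_best_phage", "mean_best_bitscore")
  cat <- c(
    "mean_gene_length", "median_gene_length", "gene_density",
    "coding_fraction", "strand_bias", "strand_switch_rate",
    "contig_length", "gc_content", "mean_intergenic_gap",
    as.vector(t(outer(dbs, per_db, paste, sep = "_"))),
    "ocav_hit_count", "archaeal_fraction_annotated", "no_genes"
  )
  attr(cat, "version") <- "arcvir-catalog-1"
  cat
}

#' Assemble the per-contig feature table
#'
#' Builds one numeric row per contig from the genomic attributes and the
#' filtered-hit summaries, in the fixed [feature_catalog()] column order.
#' Absent evidence is encoded as 0 (with the `no_genes` flag marking
#' contigs without any gene call) rather than as missing values.
#'
#' @param contigs Contig tibble. An optional `label` column
#'   (`"archaeal_virus"` / `"phage"`) is carried through for training.
#' @param orfs ORF tibble covering the contigs (possibly with zero rows
#'   for some contigs).
#' @param hits Filtered hit tibble ([filter_hits()]).
#' @param labels Optional named character vector or tibble
#'   (`contig_id`, `label`) overriding `contigs$label`.
#' @return A tibble with `contig_id`, the 27 feature columns, and `label`
#'   (possibly `NA`). Attribute `catalog_version` records the catalog.
#' @export
build_feature_table <- function(contigs, orfs, hits, labels = NULL) {
  missing_in_orfs <- setdiff(unique(orfs$contig_id), contigs$contig_id)
  if (length(missing_in_orfs)) {
    abort(paste0("ORF table references contig(s) absent from input: ",
                 paste(head(missing_in_orfs, 5), collapse = ", ")))
  }
  attrs <- genomic_attributes(contigs, orfs)
  sums <- summarize_hits(orfs, hits, contigs = contigs)
  tab <- attrs |>
    dplyr::left_join(sums, by = "contig_id")

  lab <- rep(NA_character_, nrow(contigs))
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      lab <- labels$label[match(contigs$contig_id, labels$contig_id)]
    } else {
      lab <- unname(labels[contigs$contig_id])
    }
  } else if ("label" %in% names(contigs)) {
    lab <- contigs$label
  }
  known <- lab[!is.na(lab)]
  bad <- setdiff(unique(known), c(av_positive_class, av_negative_classes))
  if (length(bad)) {
    abort(paste0("Unknown label value(s): ", paste(bad, collapse = ", ")))
  }

  cat <- feature_catalog()
  out <- tab[, c("contig_id", cat)]
  out$label <- lab[match(out$contig_id, contigs$contig_id)]
  out <- as_tibble(out)
  attr(out, "catalog_version") <- attr(cat, "version")
  out
}

#' Remove co-correlated feature columns
#'
#' Greedy pruning of highly correlated features before model training:
#' columns are scanned in their fixed catalog order and, for every pair
#' with absolute Pearson correlation above `r_max`, the later column is
#' dropped. Zero-variance columns (correlation undefined) are retained
#' with a warning and excluded from the comparison. The operation is
#' idempotent and surviving columns have pairwise |r| <= `r_max`.
#'
#' @param table A feature table ([build_feature_table()]).
#' @param r_max Absolute Pearson correlation ceiling (default 0.95).
#' @return A list with `table` (the pruned feature table) and `removed`
#'   (tibble `feature`, `correlated_with`, `r` — the removal log).
#' @export
prune_correlated <- function(table, r_max = 0.95) {
  feat_cols <- setdiff(names(table), c("contig_id", "label"))
  if (nrow(table) < 2L) abort("Need at least 2 rows to compute correlations")
  x <- as.matrix(table[, feat_cols])
  sds <- apply(x, 2L, stats::sd)
  constant <- feat_cols[sds == 0]
  if (length(constant)) {
    warn(paste0("Zero-variance column(s) retained, excluded from ",
                "correlation: ", paste(constant, collapse = ", ")))
  }
  active <- setdiff(feat_cols, constant)
  removed <- tibble(feature = character(), correlated_with = character(),
                    r = numeric())
  if (length(active) >= 2L) {
    cm <- stats::cor(x[, active, drop = FALSE])
    dropped <- character()
    for (i in seq_along(active)) {
      if (active[i] %in% dropped) next
      for (j in seq_along(active)) {
        if (j <= i || active[j] %in% dropped) next
        if (abs(cm[i, j]) > r_max) {
          dropped <- c(dropped, active[j])
          removed <- dplyr::bind_rows(removed,
            tibble(feature = active[j], correlated_with = active[i],
                   r = cm[i, j]))
        }
      }
    }
  }
  keep <- setdiff(feat_cols, removed$feature)
  out <- table[, c("contig_id", keep,
                   intersect("label", names(table)))]
  attr(out, "catalog_version") <- attr(table, "catalog_version")
  list(table = out, removed = removed)
}

#' Read or write a feature table as TSV
#'
#' The table is serialized with a header row; the catalog version travels
#' in a `# catalog_version:` comment line so models can verify provenance.
#'
#' @param table Feature table.
#' @param path File path.
#' @return For `read_feature_table()`, the feature tibble with its
#'   `catalog_version` attribute restored; `write_feature_table()` returns
#'   `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- attr(table, "catalog_version") %||% "unversioned"
  writeLines(paste0("# catalog_version: ", ver), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  first <- readLines(path, n = 1L)
  ver <- if (startsWith(first, "# catalog_version: "))
    sub("^# catalog_version: ", "", first) else NA_character_
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  out <- as_tibble(df)
  if ("label" %in% names(out)) {
    out$label[out$label %in% c("NA", "")] <- NA_character_
  }
  attr(out, "catalog_version") <- ver
  out
}
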