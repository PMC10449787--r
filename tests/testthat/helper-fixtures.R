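# Programmatic fixtures shared across test files.

# Contig with one planted complete ORF on an all-A background (the
# background and its reverse complement contain no start-to-stop spans,
# so the planted ORF is the only one).
planted_orf_contig <- function(orf_nt = 300L, pad_left = 50L,
                               pad_right = 47L, strand = 1L) {
  n_mid <- (orf_nt - 6L) / 3L
  orf <- paste0("ATG", strrep("CAC", n_mid), "TAA")
  if (strand == -1L) {
    orf <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(orf)))
  }
  seq <- paste0(strrep("A", pad_left), orf, strrep("A", pad_right))
  tibble::tibble(contig_id = "planted", sequence = seq,
                 length = nchar(seq))
}

# Quick hit-table constructor with sane defaults.
make_hits <- function(orf_id, contig_id = sub("_[^_]+$", "", orf_id),
                      target_id = paste0("t", seq_along(orf_id)),
                      evalue = 1e-20, bitscore = 100,
                      target_class = "archaeal_virus",
                      source_db = "protein_nr") {
  tibble::tibble(orf_id = orf_id, contig_id = contig_id,
                 target_id = target_id,
                 evalue = rep_len(evalue, length(orf_id)),
                 bitscore = rep_len(bitscore, length(orf_id)),
                 target_class = rep_len(target_class, length(orf_id)),
                 source_db = rep_len(source_db, length(orf_id)))
}

# Minimal ORF table: n ORFs of gene_nt each, laid head to tail with
# gap nt between, on the given strands.
make_orfs <- function(contig_id, n, gene_nt = 300L, gap = 100L,
                      strand = rep(1L, n)) {
  start <- 1L + (seq_len(n) - 1L) * (gene_nt + gap)
  tibble::tibble(contig_id = contig_id,
                 orf_id = sprintf("%s_orf%03d", contig_id, seq_len(n)),
                 start = start, end = start + gene_nt - 1L,
                 strand = rep_len(strand, n),
                 partial_left = FALSE, partial_right = FALSE,
                 aa_seq = NA_character_)
}

# Labeled feature-like table with pure noise columns and optionally one
# perfectly class-separating column, for classifier tests that do not
# need the full catalog.
make_toy_table <- function(n_per_class, n_noise = 9L, planted = TRUE,
                           seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  label <- rep(c("archaeal_virus", "phage"), each = n_per_class)
  tab <- tibble::tibble(contig_id = sprintf("c%03d", seq_len(n)))
  if (planted) {
    tab$signal <- ifelse(label == "archaeal_virus", 1, 0) +
      rnorm(n, sd = 0.05)
  }
  for (k in seq_len(n_noise)) {
    tab[[paste0("noise", k)]] <- rnorm(n)
  }
  tab$label <- label
  tab
}

# Small trained model + dataset pair reused by several classifier tests.
fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(sim_config(n_per_class = 60L, seed = 101L,
                                        realize_sequence = FALSE))
      ft <- dataset_features(ds)
      parts <- split_train_test(ft, seed = 5L)
      m <- train_forest(parts$train, n_trees = 200L, seed = 5L)
      cache <<- list(dataset = ds, features = ft, parts = parts,
                     model = m)
    }
    cache
  }
})
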