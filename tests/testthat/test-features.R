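test_that("feature table has one row per contig and the fixed 27 columns", {
  contigs <- tibble::tibble(
    contig_id = c("a", "b"), sequence = NA_character_,
    length = c(20000L, 30000L), gc = c(0.4, 0.5),
    label = c("archaeal_virus", "phage"))
  orfs <- dplyr::bind_rows(make_orfs("a", 10L), make_orfs("b", 5L))
  hits <- make_hits(c("a_orf001", "a_orf002"), source_db = "ocav_profile")
  ft <- build_feature_table(contigs, orfs, hits)
  expect_equal(nrow(ft), 2L)
  expect_equal(setdiff(names(ft), c("contig_id", "label")),
               as.vector(feature_catalog()))
  expect_equal(ft$contig_id, c("a", "b"))
  expect_equal(ft$label, c("archaeal_virus", "phage"))
  # contig b has no hits anywhere: all hit features zero
  b <- ft[ft$contig_id == "b", ]
  hit_cols <- grep(paste0("n_orfs_with_hit|fraction_orfs_annotated|",
                          "n_best_|mean_best_bitscore|ocav_hit_count|",
                          "archaeal_fraction_annotated"),
                   names(ft), value = TRUE)
  expect_true(all(b[, hit_cols] == 0))
  expect_error(build_feature_table(contigs[1, ], orfs, hits),
               "absent from input")
})

test_that("a fixture contig's feature row matches independent arithmetic", {
  contig <- tibble::tibble(contig_id = "fx", sequence = NA_character_,
                           length = 10000L, gc = 0.42,
                           label = "archaeal_virus")
  orfs <- make_orfs("fx", 4L, gene_nt = 600L, gap = 200L,
                    strand = c(1L, 1L, -1L, 1L))
  hits <- dplyr::bind_rows(
    make_hits("fx_orf001", bitscore = 120,
              target_class = "archaeal_virus"),
    make_hits("fx_orf002", bitscore = 80, target_class = "phage"),
    make_hits(c("fx_orf001", "fx_orf001", "fx_orf003"),
              evalue = 1e-8, bitscore = c(60, 70, 55),
              target_class = "archaeal_virus",
              source_db = "ocav_profile"))
  ft <- build_feature_table(contig, orfs, hits)
  expect_equal(ft$mean_gene_length, 600)
  expect_equal(ft$gene_density, 0.4)             # 1000 * 4 / 10000
  expect_equal(ft$coding_fraction, 0.24)         # 4 * 600 / 10000
  expect_equal(ft$strand_bias, 0.75)
  expect_equal(ft$strand_switch_rate, 2 / 3)
  expect_equal(ft$mean_intergenic_gap, 200)
  expect_equal(ft$gc_content, 0.42)
  expect_equal(ft$protein_nr_n_orfs_with_hit, 2)
  expect_equal(ft$protein_nr_fraction_orfs_annotated, 0.5)
  expect_equal(ft$protein_nr_mean_best_bitscore, 100)  # (120 + 80) / 2
  expect_equal(ft$ocav_hit_count, 3)
  expect_equal(ft$ocav_profile_n_orfs_with_hit, 2)
  # overall best per ORF: orf1 nr 120 (archaeal), orf2 nr 80 (phage),
  # orf3 ocav 55 (archaeal) -> 2/3 archaeal among annotated
  expect_equal(ft$archaeal_fraction_annotated, 2 / 3, tolerance = 1e-12)
  expect_equal(ft$no_genes, 0)
})

test_that("feature table construction is input-order invariant", {
  ds <- simulate_dataset(sim_config(n_per_class = 10L, seed = 4L,
                                    realize_sequence = FALSE))
  ft1 <- dataset_features(ds)
  perm <- sample(nrow(ds$contigs))
  ds2 <- ds
  ds2$contigs <- ds$contigs[perm, ]
  ds2$hits <- ds$hits[sample(nrow(ds$hits)), ]
  ft2 <- dataset_features(ds2)
  expect_equal(dplyr::arrange(ft2, contig_id),
               dplyr::arrange(ft1, contig_id))
})

test_that("correlation pruning drops the later of any |r| > r_max pair", {
  set.seed(9)
  n <- 40L
  tab <- tibble::tibble(contig_id = sprintf("c%02d", 1:n),
                        f1 = rnorm(n))
  tab$f2 <- tab$f1                       # duplicate -> r = 1
  tab$f3 <- rnorm(n)
  tab$f4 <- -tab$f3 + rnorm(n, sd = 0.01) # strong negative correlation
  tab$f5 <- rnorm(n)
  res <- prune_correlated(tab, r_max = 0.95)
  expect_setequal(res$removed$feature, c("f2", "f4"))
  expect_true(all(c("f1", "f3", "f5") %in% names(res$table)))
  # idempotent
  again <- prune_correlated(res$table, r_max = 0.95)
  expect_equal(nrow(again$removed), 0L)
})

test_that("pruning removals match the all-pairs oracle on random tables", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30L
    p <- 8L
    mat <- matrix(rnorm(n * p), n, p)
    # plant correlated pairs
    mat[, 3] <- mat[, 1] * 0.99 + rnorm(n, sd = 0.01)
    mat[, 7] <- mat[, 4]
    colnames(mat) <- paste0("v", 1:p)
    tab <- dplyr::bind_cols(tibble::tibble(contig_id = sprintf("c%02d", 1:n)),
                            tibble::as_tibble(mat))
    res <- prune_correlated(tab, r_max = 0.95)
    expect_equal(sort(res$removed$feature),
                 sort(prune_oracle(mat, 0.95)), info = paste("seed", seed))
    # surviving columns pairwise below the ceiling
    keep <- setdiff(names(res$table), "contig_id")
    cm <- cor(as.matrix(res$table[, keep]))
    expect_true(all(abs(cm[upper.tri(cm)]) <= 0.95))
  }
})

test_that("zero-variance columns are retained with a warning", {
  tab <- tibble::tibble(contig_id = c("a", "b", "c"),
                        f1 = c(1, 2, 3), f2 = c(0, 0, 0))
  expect_warning(res <- prune_correlated(tab), "Zero-variance")
  expect_true("f2" %in% names(res$table))
})

test_that("feature tables round-trip through TSV with catalog version", {
  ds <- simulate_dataset(sim_config(n_per_class = 5L, seed = 2L,
                                    realize_sequence = FALSE))
  ft <- dataset_features(ds)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  again <- read_feature_table(path)
  expect_equal(attr(again, "catalog_version"), attr(ft, "catalog_version"))
  expect_equal(as.data.frame(again), as.data.frame(ft), tolerance = 1e-9)
})
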