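test_that("e-value filters are strict, source-specific ceilings", {
  hits <- dplyr::bind_rows(
    make_hits("c1_orf001", evalue = 1e-6, source_db = "protein_nr"),
    make_hits("c1_orf002", evalue = 1e-4, source_db = "protein_nr"),
    make_hits("c1_orf003", evalue = 1e-9, source_db = "pvog_hmm"),
    make_hits("c1_orf004", evalue = 1e-11, source_db = "pvog_hmm"),
    make_hits("c1_orf005", evalue = 1e-5, source_db = "ocav_profile"),
    make_hits("c1_orf006", evalue = 9.99e-6, source_db = "ocav_profile"))
  kept <- filter_hits(hits)
  expect_equal(kept$orf_id, c("c1_orf001", "c1_orf004", "c1_orf006"))
  # idempotent
  expect_equal(filter_hits(kept), kept)
})

test_that("relaxing a threshold never removes a retained hit", {
  set.seed(3)
  hits <- make_hits(sprintf("c1_orf%03d", 1:50),
                    evalue = 10^-runif(50, 0, 15),
                    source_db = sample(c("protein_nr", "pvog_hmm",
                                         "ocav_profile"), 50,
                                       replace = TRUE))
  strict <- filter_hits(hits, search_thresholds())
  relaxed <- filter_hits(hits, search_thresholds(1e-3, 1e-8, 1e-3))
  expect_true(all(strict$orf_id %in% relaxed$orf_id))
  expect_error(
    filter_hits(make_hits("x_orf001", source_db = "pfam")),
    "No e-value threshold")
})

test_that("tabular search outputs parse with typed columns", {
  blast <- withr::local_tempfile(fileext = ".tab")
  writeLines(c(
    "c1_orf001\ttargA\t88.2\t120\t10\t1\t1\t120\t5\t124\t1e-30\t250.1",
    "c1_orf001\ttargB\t70.0\t100\t30\t2\t1\t100\t1\t100\t1e-10\t120.5",
    "c2_orf001\ttargA\t99.0\t200\t2\t0\t1\t200\t1\t200\t0.0\t400"),
    blast)
  parsed <- read_blast_tab(blast)
  expect_equal(nrow(parsed), 3L)
  expect_type(parsed$evalue, "double")
  expect_equal(parsed$bitscore[1], 250.1)

  empty <- withr::local_tempfile(fileext = ".tab")
  file.create(empty)
  expect_equal(nrow(read_blast_tab(empty)), 0L)

  tbl <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c(
    "#                                             --- full sequence ----",
    "# target name  accession  query name accession   E-value  score bias",
    "c1_orf001 - VOG001 - 1.2e-15 55.3 0.1 1.2e-15 55.0 0.1 1 1 0 1 1 1 1 desc",
    "c1_orf002 - ocav_12 - 3e-7 30.1 0.0 4e-7 29.8 0.0 1 1 0 1 1 1 1 desc"),
    tbl)
  parsed <- read_hmmer_tblout(tbl)
  expect_equal(parsed$orf_id, c("c1_orf001", "c1_orf002"))
  expect_equal(parsed$target_id, c("VOG001", "ocav_12"))
  expect_equal(parsed$evalue, c(1.2e-15, 3e-7))
  expect_equal(parsed$bitscore, c(55.3, 30.1))
})

test_that("run_search attaches classes from metadata and flags unknowns", {
  meta <- tibble::tibble(target_id = c("targA", "targB"),
                         target_class = c("archaeal_virus", "phage"))
  blast <- withr::local_tempfile(fileext = ".tab")
  writeLines(c(
    "c1_orf001\ttargA\t88\t120\t10\t1\t1\t120\t5\t124\t1e-30\t250",
    "c1_orf002\ttargX\t70\t100\t30\t2\t1\t100\t1\t100\t1e-10\t120"),
    blast)
  db <- reference_db(metadata = meta, source_db = "protein_nr")
  expect_warning(hits <- run_search(db = db, mode = "protein",
                                    backend = "precomputed",
                                    hits_file = blast),
                 "unknown")
  expect_equal(hits$target_class, c("archaeal_virus", "unknown"))
  expect_equal(hits$contig_id, c("c1", "c1"))

  fx <- make_hits("c9_orf001")
  mock <- reference_db(source_db = "protein_nr", fixture = fx)
  expect_equal(run_search(db = mock, mode = "protein", backend = "mock"),
               fx)

  expect_error(reference_db(metadata = tibble::tibble(
    target_id = "t", target_class = "dragon"), source_db = "pfam"),
    "Unknown target_class")
})

test_that("missing search binary suggests the offline alternatives", {
  withr::local_envvar(PATH = withr::local_tempdir())
  db <- reference_db(path = "db.hmm", source_db = "pvog_hmm")
  expect_error(run_search("q.faa", db, mode = "hmm", backend = "external"),
               "precomputed")
})

test_that("hit summaries count best hits per ORF with the tie-break rule", {
  orfs <- make_orfs("c1", 10L)
  contig <- tibble::tibble(contig_id = "c1", length = 10000L, gc = 0.5)
  hits <- dplyr::bind_rows(
    make_hits(orfs$orf_id[1:4], target_class = "archaeal_virus"),
    make_hits(orfs$orf_id[5:6], target_class = "phage"))
  s <- summarize_hits(orfs, hits, contigs = contig)
  expect_equal(s$protein_nr_n_orfs_with_hit, 6)
  expect_equal(s$protein_nr_fraction_orfs_annotated, 0.6)
  expect_equal(s$protein_nr_n_best_archaeal, 4)
  expect_equal(s$protein_nr_n_best_phage, 2)
  expect_equal(s$archaeal_fraction_annotated, 4 / 6, tolerance = 1e-12)

  none <- summarize_hits(orfs, arcvir:::empty_hit_table(),
                         contigs = contig)
  expect_equal(none$ocav_hit_count, 0)
  expect_equal(none$protein_nr_fraction_orfs_annotated, 0)

  expect_error(summarize_hits(orfs, make_hits("ghost_orf001")),
               "unknown orf_id")
})

test_that("equal-bitscore ties resolve by e-value then target id, in any order", {
  orfs <- make_orfs("c1", 1L)
  base <- dplyr::bind_rows(
    make_hits("c1_orf001", target_id = "b", evalue = 1e-8, bitscore = 100,
              target_class = "phage"),
    make_hits("c1_orf001", target_id = "a", evalue = 1e-6, bitscore = 100,
              target_class = "archaeal_virus"),
    make_hits("c1_orf001", target_id = "c", evalue = 1e-8, bitscore = 90,
              target_class = "archaeal_virus"))
  contig <- tibble::tibble(contig_id = "c1", length = 10000L, gc = 0.5)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  for (p in perms) {
    s <- summarize_hits(orfs, base[p, ], contigs = contig)
    # bitscore 100 beats 90; among those, e-value 1e-8 ("b") wins
    expect_equal(s$protein_nr_n_best_phage, 1, info = paste(p,
                                                            collapse = ","))
    expect_equal(s$protein_nr_n_best_archaeal, 0)
  }
  # equal bitscore AND e-value: lexicographic target id
  tie <- base
  tie$evalue <- 1e-8
  tie$bitscore <- 100
  s <- summarize_hits(orfs, tie, contigs = contig)
  expect_equal(s$archaeal_fraction_annotated, 1) # target "a" wins
})

test_that("ocav_hit_count matches a brute-force recount of filtered hits", {
  set.seed(11)
  orfs <- make_orfs("c1", 20L)
  hits <- make_hits(sample(orfs$orf_id, 40, replace = TRUE),
                    evalue = 10^-runif(40, 2, 12),
                    source_db = "ocav_profile")
  kept <- filter_hits(hits)
  s <- summarize_hits(orfs, kept,
                      contigs = tibble::tibble(contig_id = "c1",
                                               length = 10000L, gc = 0.5))
  expect_equal(s$ocav_hit_count, sum(hits$evalue < 1e-5))
})

test_that("hit tables round-trip through TSV", {
  hits <- make_hits(c("c1_orf001", "c2_orf001"), evalue = c(1e-6, 1e-9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, path)
  expect_equal(read_hit_table(path), hits)
})
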