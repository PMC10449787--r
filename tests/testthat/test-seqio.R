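test_that("FASTA reading echoes records, uppercases, and round-trips", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1 some description", "acgtacgt", ">c2", "GGGCC", "CNN"),
             fa)
  contigs <- read_fasta(fa)
  expect_equal(contigs$contig_id, c("c1", "c2"))
  expect_equal(contigs$sequence, c("ACGTACGT", "GGGCCCNN"))
  expect_equal(contigs$length, c(8L, 8L))

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(contigs, out)
  again <- read_fasta(out)
  expect_equal(again$contig_id, contigs$contig_id)
  expect_equal(again$sequence, contigs$sequence)
})

test_that("FASTA edge cases: empty file, duplicate ids, malformed input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  file.create(fa)
  expect_equal(nrow(read_fasta(fa)), 0L)

  writeLines(c(">dup", "ACGT", ">dup", "GGGG"), fa)
  expect_error(read_fasta(fa), "Duplicate contig id")

  writeLines(c("ACGT", ">c1", "ACGT"), fa)
  expect_error(read_fasta(fa), "line 1")
})

test_that("naive scanner recovers a planted ORF at its exact coordinates", {
  for (strand in c(1L, -1L)) {
    contig <- planted_orf_contig(orf_nt = 300L, strand = strand)
    orfs <- call_genes(contig, backend = "naive")
    expect_equal(nrow(orfs), 1L)
    expect_equal(orfs$start, 51L)
    expect_equal(orfs$end, 350L)
    expect_equal(orfs$strand, strand)
    # coordinates include the stop codon; the protein excludes it
    expect_equal(nchar(orfs$aa_seq), 300L / 3L - 1L)
    oracle <- orf_oracle(contig$sequence)
    expect_equal(nrow(oracle), 1L)
    expect_equal(oracle$start, 51L)
    expect_equal(oracle$end, 350L)
  }
})

test_that("naive scanner output is a subset of the brute-force oracle", {
  set.seed(7)
  for (rep in 1:8) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 600, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    contig <- tibble::tibble(contig_id = "r", sequence = seq,
                             length = 600L)
    got <- call_genes(contig, backend = "naive")
    oracle <- orf_oracle(seq)
    if (nrow(got) > 0) {
      got_keys <- paste(got$start, got$end, got$strand)
      oracle_keys <- paste(oracle$start, oracle$end, oracle$strand)
      expect_true(all(got_keys %in% oracle_keys),
                  info = paste("rep", rep))
    }
    # the scanner's first-start convention picks the longest span ending
    # at each stop, which the oracle also contains
    expect_lte(nrow(got), nrow(oracle))
  }
})

test_that("all-N contigs and short contigs yield no ORFs", {
  contig <- tibble::tibble(contig_id = "n", sequence = strrep("N", 500),
                           length = 500L)
  expect_equal(nrow(call_genes(contig, backend = "naive")), 0L)
  tiny <- tibble::tibble(contig_id = "t", sequence = "ATGAAATAA",
                         length = 9L)
  expect_equal(nrow(call_genes(tiny, backend = "naive")), 0L)
})

test_that("external caller output parses into coordinates and strands", {
  gff <- withr::local_tempfile(fileext = ".gff")
  faa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(
    "# comment",
    paste("ctgA", "Prodigal_v2.6.3", "CDS", "100", "399", "52.1", "+",
          "0", "ID=1_1;partial=00;start_type=ATG;", sep = "\t"),
    paste("ctgA", "Prodigal_v2.6.3", "CDS", "500", "802", "33.0", "-",
          "0", "ID=1_2;partial=01;start_type=GTG;", sep = "\t")),
    gff)
  writeLines(c(">ctgA_1 # 100 # 399 # 1", "MKLV*",
               ">ctgA_2 # 500 # 802 # -1", "MAAA"), faa)
  orfs <- arcvir:::parse_prodigal_output(gff, faa)
  expect_equal(nrow(orfs), 2L)
  expect_equal(orfs$strand, c(1L, -1L))
  expect_equal(orfs$start, c(100L, 500L))
  expect_equal(orfs$end, c(399L, 802L))
  expect_equal(orfs$partial_right, c(FALSE, TRUE))
  expect_equal(orfs$aa_seq[1], "MKLV")
})

test_that("gene tables round-trip through TSV and validate coordinates", {
  orfs <- make_orfs("ctg1", 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(orfs, path)
  again <- read_gene_table(path)
  expect_equal(again$start, orfs$start)
  expect_equal(again$strand, orfs$strand)

  bad <- orfs
  bad$end[1] <- bad$start[1] - 1L
  write_gene_table(bad, path)
  expect_error(read_gene_table(path), "Invalid coordinates")
})

test_that("genomic attributes follow their defining formulas", {
  contig <- tibble::tibble(contig_id = "g", sequence = NA_character_,
                           length = 10000L, gc = 0.5)
  orfs <- make_orfs("g", 10L, gene_nt = 900L, gap = 80L,
                    strand = rep(c(1L, -1L), 5L))
  at <- genomic_attributes(contig, orfs)
  expect_equal(at$gene_density, 1.0)
  expect_equal(at$coding_fraction, 0.9)
  expect_equal(at$strand_bias, 0.5)
  expect_equal(at$strand_switch_rate, 1.0)
  expect_equal(at$mean_intergenic_gap, 80)
  expect_equal(at$no_genes, 0)

  allf <- genomic_attributes(contig, make_orfs("g", 10L, gene_nt = 900L))
  expect_equal(allf$strand_bias, 1.0)
  expect_equal(allf$strand_switch_rate, 0)

  lens <- make_orfs("g", 3L, gene_nt = 300L)
  lens$end <- lens$start + c(300L, 600L, 900L) - 1L
  at3 <- genomic_attributes(contig, lens)
  expect_equal(at3$mean_gene_length, 600)
  expect_equal(at3$median_gene_length, 600)
})

test_that("zero-ORF contigs get the stated conventions and flag", {
  contig <- tibble::tibble(contig_id = "empty", sequence = strrep("AC", 500),
                           length = 1000L)
  at <- genomic_attributes(contig, arcvir:::empty_orf_table())
  expect_equal(at$gene_density, 0)
  expect_equal(at$strand_bias, 1.0)
  expect_equal(at$mean_gene_length, 0)
  expect_equal(at$no_genes, 1)
  expect_equal(at$gc_content, 0.5)
})

test_that("attributes are scale-consistent under self-concatenation", {
  seq1 <- strrep("ACGT", 2500)
  contig1 <- tibble::tibble(contig_id = "c", sequence = seq1,
                            length = 10000L)
  orfs1 <- make_orfs("c", 8L, gene_nt = 600L, gap = 500L)
  doubled <- tibble::tibble(contig_id = "c", sequence = strrep(seq1, 2),
                            length = 20000L)
  orfs2 <- dplyr::bind_rows(
    orfs1,
    dplyr::mutate(orfs1, start = start + 10000L, end = end + 10000L,
                  orf_id = paste0(orf_id, "b")))
  a1 <- genomic_attributes(contig1, orfs1)
  a2 <- genomic_attributes(doubled, orfs2)
  expect_equal(a1$gene_density, a2$gene_density)
  expect_equal(a1$coding_fraction, a2$coding_fraction)
  expect_equal(a1$gc_content, a2$gc_content)
})
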