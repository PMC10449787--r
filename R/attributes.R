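#' Per-contig genomic attributes
#'
#' Computes the genome-architecture attributes used as classifier features:
#' gene length statistics, gene density, coding fraction, strand bias and
#' switch rate, contig length, GC content and mean intergenic gap. Gene
#' lengths are in nucleotides (start through stop codon inclusive).
#'
#' Zero-ORF contigs are kept, not dropped: by convention they get
#' `gene_density = 0`, `strand_bias = 1`, zero length statistics, and the
#' `no_genes` flag set, which propagates into the feature table.
#'
#' @param contigs Contig tibble. GC content is computed from `sequence`;
#'   if `sequence` is `NA` (unrealized simulated contigs) a `gc` column is
#'   used instead.
#' @param orfs ORF tibble; every `contig_id` in `orfs` must appear in
#'   `contigs`.
#' @return A tibble with one row per contig and columns `contig_id`,
#'   `mean_gene_length`, `median_gene_length` (bp), `gene_density`
#'   (genes/kb), `coding_fraction`, `strand_bias`, `strand_switch_rate`,
#'   `contig_length` (bp), `gc_content`, `mean_intergenic_gap` (bp),
#'   `no_genes` (0/1).
#' @export
genomic_attributes <- function(contigs, orfs) {
  stopifnot(all(c("contig_id", "length") %in% names(contigs)))
  stray <- setdiff(unique(orfs$contig_id), contigs$contig_id)
  if (length(stray)) {
    abort(paste0("ORFs reference unknown contig(s): ",
                 paste(stray, collapse = ", ")))
  }
  gc <- if ("sequence" %in% names(contigs) && !anyNA(contigs$sequence)) {
    gc_fraction(contigs$sequence)
  } else if ("gc" %in% names(contigs)) {
    contigs$gc
  } else {
    abort("Need either a non-NA 'sequence' column or a 'gc' column")
  }

  per_orf <- orfs |>
    dplyr::mutate(gene_length = .data$end - .data$start + 1L) |>
    dplyr::arrange(.data$contig_id, .data$start) |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(
      n_orfs = dplyr::n(),
      mean_gene_length = mean(.data$gene_length),
      median_gene_length = median(.data$gene_length),
      coding_bp = sum(.data$gene_length),
      strand_bias = max(sum(.data$strand == 1L),
                        sum(.data$strand == -1L)) / dplyr::n(),
      strand_switch_rate = if (dplyr::n() < 2L) 0 else
        mean(diff(.data$strand) != 0L),
      mean_intergenic_gap = if (dplyr::n() < 2L) 0 else
        mean(pmax(0L, .data$start[-1L] -
                       .data$end[-dplyr::n()] - 1L)),
      .groups = "drop"
    )

  tibble(contig_id = contigs$contig_id,
         contig_length = as.numeric(contigs$length),
         gc_content = gc) |>
    dplyr::left_join(per_orf, by = "contig_id") |>
    dplyr::mutate(
      no_genes = as.numeric(is.na(.data$n_orfs)),
      n_orfs = dplyr::coalesce(.data$n_orfs, 0L),
      mean_gene_length = dplyr::coalesce(.data$mean_gene_length, 0),
      median_gene_length = dplyr::coalesce(as.numeric(.data$median_gene_length), 0),
      strand_bias = dplyr::coalesce(.data$strand_bias, 1),
      strand_switch_rate = dplyr::coalesce(.data$strand_switch_rate, 0),
      mean_intergenic_gap = dplyr::coalesce(.data$mean_intergenic_gap, 0),
      gene_density = 1000 * .data$n_orfs / .data$contig_length,
      coding_fraction = pmin(1, dplyr::coalesce(.data$coding_bp, 0L) /
                                  .data$contig_length)
    ) |>
    dplyr::select("contig_id", "mean_gene_length", "median_gene_length",
                  "gene_density", "coding_fraction", "strand_bias",
                  "strand_switch_rate", "contig_length", "gc_content",
                  "mean_intergenic_gap", "no_genes")
}
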