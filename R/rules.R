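#' Annotate genes with the legacy homology-rule filters
#'
#' Re-implementation of the per-gene annotation step of the legacy
#' rule-based archaeal-virus classifier. Raw (unfiltered) hits are reduced
#' to at most one affiliation per ORF: the best protein-homology hit is
#' retained if its bitscore exceeds 50 and its e-value passes the 0.001
#' gate, and the best protein-domain hit if its bitscore exceeds 40 at
#' e-value below 1e-5. When both kinds survive, the homology affiliation
#' takes precedence. Hits to archaea or archaeal viruses affiliate the
#' gene with archaeal viruses; hits to bacteria or phages with phages.
#'
#' The published description reads "evalue >0.001" for the homology gate;
#' every other filter in the method is a ceiling, so the default treats
#' this as an e-value ceiling (`evalue < 0.001`). Set
#' `evalue_ceiling = FALSE` to apply the literal floor instead.
#'
#' @param hits Raw hit tibble; `source_db` `"pfam"` rows are treated as
#'   domain-model evidence, everything else as protein homology.
#' @param evalue_ceiling Direction of the 0.001 homology e-value gate.
#' @return A tibble with one row per ORF carrying any surviving evidence:
#'   `orf_id`, `contig_id`, `affiliation` (`"archaeal_virus"`, `"phage"`,
#'   `"none"`), `bitscore`, `source` (`"homology"` / `"domain_model"`).
#' @export
annotate_rules <- function(hits, evalue_ceiling = TRUE) {
  if (nrow(hits) == 0L) {
    return(tibble(orf_id = character(), contig_id = character(),
                  affiliation = character(), bitscore = numeric(),
                  source = character()))
  }
  hits <- hits |>
    dplyr::mutate(source = ifelse(.data$source_db == "pfam",
                                  "domain_model", "homology"))
  hom <- hits |>
    dplyr::filter(.data$source == "homology") |>
    best_hits(per_db = FALSE) |>
    dplyr::filter(.data$bitscore > 50,
                  if (evalue_ceiling) .data$evalue < 0.001
                  else .data$evalue > 0.001)
  dom <- hits |>
    dplyr::filter(.data$source == "domain_model") |>
    best_hits(per_db = FALSE) |>
    dplyr::filter(.data$bitscore > 40, .data$evalue < 1e-5)
  # homology wins when an ORF has both kinds of surviving evidence
  dom <- dom[!dom$orf_id %in% hom$orf_id, , drop = FALSE]
  dplyr::bind_rows(hom, dom) |>
    dplyr::mutate(affiliation = dplyr::case_when(
      .data$target_class %in% ARCHAEAL_CLASSES ~ av_positive_class,
      .data$target_class %in% PHAGE_CLASSES ~ "phage",
      TRUE ~ "none")) |>
    dplyr::select("orf_id", "contig_id", "affiliation", "bitscore",
                  "source") |>
    dplyr::arrange(.data$contig_id, .data$orf_id)
}

#' Classify contigs with the legacy category rules
#'
#' Applies the legacy category rules to per-gene annotations: a contig is
#' a category 1 putative archaeal virus when strictly more than 2/3 of its
#' affiliated genes are archaeal-virus affiliated, category 2 when
#' strictly more than 1/2 are, in both cases additionally requiring the
#' best archaeal-affiliated bitscore to exceed 75 and to be strictly
#' higher than the best phage-affiliated bitscore. Fractions are computed
#' over affiliated genes only; contigs without any affiliated gene are
#' category `"none"` with the `no_annotation` flag set.
#'
#' @param annotations Output of [annotate_rules()] (one or more contigs).
#' @return A tibble with one row per contig: `contig_id`, `category`
#'   (`"1"`, `"2"`, `"none"`), `archaeal_fraction`, `passing_bitscore`,
#'   `no_annotation`, `is_archaeal_virus` (category 1 or 2).
#' @export
classify_rules <- function(annotations) {
  if (nrow(annotations) == 0L) {
    return(tibble(contig_id = character(), category = character(),
                  archaeal_fraction = numeric(),
                  passing_bitscore = logical(), no_annotation = logical(),
                  is_archaeal_virus = logical()))
  }
  annotations |>
    dplyr::filter(.data$affiliation != "none") |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(
      n_affiliated = dplyr::n(),
      n_archaeal = sum(.data$affiliation == av_positive_class),
      best_archaeal = suppressWarnings(
        max(.data$bitscore[.data$affiliation == av_positive_class],
            na.rm = TRUE)),
      best_phage = suppressWarnings(
        max(.data$bitscore[.data$affiliation == "phage"], na.rm = TRUE)),
      .groups = "drop") |>
    dplyr::right_join(tibble(contig_id = unique(annotations$contig_id)),
                      by = "contig_id") |>
    dplyr::mutate(
      no_annotation = is.na(.data$n_affiliated) | .data$n_affiliated == 0L,
      archaeal_fraction = ifelse(.data$no_annotation, NA_real_,
                                 .data$n_archaeal / .data$n_affiliated),
      best_archaeal = ifelse(is.finite(.data$best_archaeal),
                             .data$best_archaeal, -Inf),
      best_phage = ifelse(is.finite(.data$best_phage),
                          .data$best_phage, -Inf),
      passing_bitscore = !.data$no_annotation &
        .data$best_archaeal > 75 & .data$best_archaeal > .data$best_phage,
      category = dplyr::case_when(
        .data$no_annotation | !.data$passing_bitscore ~ "none",
        .data$archaeal_fraction > 2 / 3 ~ "1",
        .data$archaeal_fraction > 1 / 2 ~ "2",
        TRUE ~ "none"),
      is_archaeal_virus = .data$category %in% c("1", "2")) |>
    dplyr::select("contig_id", "category", "archaeal_fraction",
                  "passing_bitscore", "no_annotation",
                  "is_archaeal_virus") |>
    dplyr::arrange(.data$contig_id)
}
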