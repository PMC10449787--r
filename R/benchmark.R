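#' Size-fractionate a dataset into fixed-length fragments
#'
#' Cuts every contig into non-overlapping windows of exactly
#' `target_size` bp anchored at the 5' end (the terminal remainder shorter
#' than the target is dropped), inherits labels, clips the planted ORF and
#' hit tables to the windows (an ORF is kept iff it lies wholly inside one
#' window; its coordinates are shifted), and finally subsamples the
#' fragments back to the original sequence count so dataset size is held
#' constant across size fractions.
#'
#' @param dataset An `av_dataset`.
#' @param target_size Fragment length in bp, or `Inf` for pass-through
#'   (the ">10 kb" fraction: the dataset is returned unchanged).
#' @param seed Integer seed for the fragment subsample.
#' @return A new `av_dataset` of fragments.
#' @export
fragment_dataset <- function(dataset, target_size, seed = 1L) {
  stopifnot(inherits(dataset, "av_dataset"), target_size > 0)
  if (is.infinite(target_size)) return(dataset)
  contigs <- dataset$contigs
  too_short <- contigs$length < target_size
  if (all(too_short)) {
    abort(paste0("No contig is at least ", target_size, " bp"))
  }
  if (any(too_short)) {
    warn(paste0(sum(too_short), " contig(s) shorter than ", target_size,
                " bp contribute no fragments"))
  }
  src <- contigs[!too_short, , drop = FALSE]
  frags <- src |>
    dplyr::mutate(n_frag = .data$length %/% as.integer(target_size)) |>
    tidyr::uncount(.data$n_frag, .id = "frag") |>
    dplyr::mutate(
      w_start = (.data$frag - 1L) * as.integer(target_size) + 1L,
      w_end = .data$frag * as.integer(target_size),
      parent_id = .data$contig_id,
      contig_id = sprintf("%s_f%03d", .data$contig_id, .data$frag),
      sequence = ifelse(is.na(.data$sequence), NA_character_,
                        substr(.data$sequence, .data$w_start,
                               .data$w_end)),
      length = as.integer(target_size))
  if ("sequence" %in% names(frags) && !anyNA(frags$sequence)) {
    frags$gc <- gc_fraction(frags$sequence)
  }
  # clip ORFs wholly inside a window; shift to fragment coordinates
  windows <- frags |>
    dplyr::transmute(parent_id = .data$parent_id,
                     frag_id = .data$contig_id,
                     w_start = .data$w_start, w_end = .data$w_end)
  orfs <- dataset$orfs |>
    dplyr::inner_join(windows, by = c(contig_id = "parent_id"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$start >= .data$w_start,
                  .data$end <= .data$w_end) |>
    dplyr::mutate(contig_id = .data$frag_id,
                  start = .data$start - .data$w_start + 1L,
                  end = .data$end - .data$w_start + 1L) |>
    dplyr::select(dplyr::all_of(names(dataset$orfs)))
  hits <- dataset$hits |>
    dplyr::filter(.data$orf_id %in% orfs$orf_id) |>
    dplyr::mutate(contig_id = orfs$contig_id[match(.data$orf_id,
                                                   orfs$orf_id)])
  out <- structure(list(
    contigs = dplyr::select(frags, -dplyr::any_of(c("frag", "w_start",
                                                    "w_end", "parent_id"))),
    orfs = orfs, hits = hits, config = dataset$config),
    class = "av_dataset")
  n_orig <- nrow(dataset$contigs)
  if (nrow(out$contigs) > n_orig) {
    out <- subsample_dataset(out, n_orig / nrow(out$contigs), seed = seed,
                             exact_n = n_orig)
  }
  out
}

#' Spike a viral dataset with microbial contaminant fragments
#'
#' Adds cellular genome fragments so they make up `proportion` of the
#' final dataset: `round(p/(1-p) * n_viral)` fragments are drawn without
#' replacement from the pool, half from archaea and half from bacteria.
#' Pool fragments must be 10-200 kb; out-of-range rows are excluded before
#' drawing. Spiked rows keep their `"non_viral"` label so they count as
#' negatives (false-positive fodder) in metric accounting.
#'
#' @param dataset Labeled viral `av_dataset`.
#' @param pool Contaminant `av_dataset` ([simulate_contaminants()]); its
#'   contig tibble must have a `domain` column (`"archaea"`/`"bacteria"`).
#' @param proportion Target contaminant fraction of the final dataset.
#' @param seed Integer seed.
#' @return The combined `av_dataset`.
#' @export
spike_contamination <- function(dataset, pool, proportion, seed = 1L) {
  stopifnot(inherits(dataset, "av_dataset"), inherits(pool, "av_dataset"),
            proportion > 0, proportion < 1)
  ok <- pool$contigs$length >= 10000L & pool$contigs$length <= 200000L
  pool_contigs <- pool$contigs[ok, , drop = FALSE]
  n_viral <- nrow(dataset$contigs)
  n_microbial <- round(proportion / (1 - proportion) * n_viral)
  n_arch <- n_microbial %/% 2L
  n_bact <- n_microbial - n_arch
  have <- table(factor(pool_contigs$domain,
                       levels = c("archaea", "bacteria")))
  if (have["archaea"] < n_arch || have["bacteria"] < n_bact) {
    abort(paste0("Contaminant pool too small: need ", n_arch,
                 " archaea and ", n_bact, " bacteria fragments of ",
                 "10-200 kb, have ", have["archaea"], " and ",
                 have["bacteria"]))
  }
  set.seed(seed)
  take <- c(sample(pool_contigs$contig_id[pool_contigs$domain == "archaea"],
                   n_arch),
            sample(pool_contigs$contig_id[pool_contigs$domain == "bacteria"],
                   n_bact))
  spike <- pool_contigs[pool_contigs$contig_id %in% take, , drop = FALSE]
  spike$label <- "non_viral"
  keep_cols <- names(dataset$contigs)
  spike <- spike[, intersect(c(keep_cols, "domain"), names(spike))]
  structure(list(
    contigs = dplyr::bind_rows(dataset$contigs, spike[, keep_cols]),
    orfs = dplyr::bind_rows(dataset$orfs,
                            pool$orfs[pool$orfs$contig_id %in% take, ]),
    hits = dplyr::bind_rows(dataset$hits,
                            pool$hits[pool$hits$contig_id %in% take, ]),
    config = dataset$config), class = "av_dataset")
}

#' Randomly subsample a dataset
#'
#' Simple random sample of `round(fraction * n)` contigs without
#' replacement (seeded), carrying their ORFs and hits along.
#'
#' @param dataset An `av_dataset`.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @param exact_n Optional exact sample size overriding the rounding.
#' @return The subsampled `av_dataset`.
#' @export
subsample_dataset <- function(dataset, fraction, seed = 1L,
                              exact_n = NULL) {
  stopifnot(inherits(dataset, "av_dataset"), fraction > 0, fraction <= 1)
  n <- nrow(dataset$contigs)
  size <- exact_n %||% round(fraction * n)
  if (size < 1L) abort("Subsample size rounds to zero")
  set.seed(seed)
  take <- sample(dataset$contigs$contig_id, size)
  structure(list(
    contigs = dataset$contigs[dataset$contigs$contig_id %in% take, ],
    orfs = dataset$orfs[dataset$orfs$contig_id %in% take, ],
    hits = dataset$hits[dataset$hits$contig_id %in% take, ],
    config = dataset$config), class = "av_dataset")
}

#' Evaluate a trained classifier on a dataset
#'
#' Builds the feature table, predicts at the given threshold, and returns
#' confusion-derived metrics plus ROC/PR areas (areas only when both
#' classes are present among the true viral labels).
#'
#' @param model An `av_model`.
#' @param dataset An `av_dataset` with labeled contigs.
#' @param threshold Decision threshold.
#' @return One-row tibble: `threshold`, `n`, `TP`, `FP`, `TN`, `FN`, the
#'   [compute_metrics()] columns, `auroc`, `auprc`.
#' @export
evaluate_dataset <- function(model, dataset, threshold = 0.5) {
  feats <- dataset_features(dataset)
  pred <- predict_contigs(model, feats, threshold = threshold)
  truth <- feats$label
  cc <- confusion_counts(truth, pred$predicted_class)
  met <- compute_metrics(cc)
  curve <- if (length(unique(truth)) >= 2L) {
    roc_pr(pred$p_archaeal, truth)
  } else NULL
  dplyr::bind_cols(tibble(threshold = threshold, n = length(truth)), cc,
                   met,
                   tibble(auroc = curve$auroc %||% NA_real_,
                          auprc = curve$auprc %||% NA_real_))
}

#' Run the perturbation benchmark grid
#'
#' Reproduces the dataset-perturbation benchmarking design: evaluates a
#' trained model on the unmodified dataset, on each size fraction, on each
#' microbial-contamination proportion (contamination draws are reused
#' across thresholds so threshold comparisons are paired), and on each
#' random subsample, all seeded.
#'
#' @param model An `av_model`.
#' @param dataset Labeled viral `av_dataset`.
#' @param pool Contaminant pool (required when `contamination` is
#'   non-empty).
#' @param fragment_sizes Fragment lengths in bp (use `Inf` for the
#'   pass-through ">10 kb" fraction).
#' @param contamination Contaminant proportions of the final dataset.
#' @param subsample Subsampling fractions.
#' @param thresholds Decision thresholds to evaluate at.
#' @param seed Integer seed.
#' @return A tibble with one row per (variant, parameter, threshold).
#' @export
run_benchmark <- function(model, dataset, pool = NULL,
                          fragment_sizes = c(1000, 2500, 5000, 7500,
                                             10000, Inf),
                          contamination = c(0.10, 0.25, 0.50, 0.75, 0.95),
                          subsample = c(0.05, 0.25, 0.50, 0.75),
                          thresholds = c(0.5, 0.8), seed = 1L) {
  rows <- list()
  for (t in thresholds) {
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(
      tibble(variant = "original", parameter = NA_real_),
      evaluate_dataset(model, dataset, t))
  }
  for (fs in fragment_sizes) {
    ds <- fragment_dataset(dataset, fs, seed = seed)
    for (t in thresholds) {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(variant = "fragment", parameter = fs),
        evaluate_dataset(model, ds, t))
    }
  }
  if (length(contamination) > 0L) {
    if (is.null(pool)) abort("Contamination grid needs a contaminant pool")
    for (p in contamination) {
      ds <- spike_contamination(dataset, pool, p, seed = seed)
      for (t in thresholds) {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble(variant = "contamination", parameter = p),
          evaluate_dataset(model, ds, t))
      }
    }
  }
  for (f in subsample) {
    ds <- subsample_dataset(dataset, f, seed = seed)
    for (t in thresholds) {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(variant = "subsample", parameter = f),
        evaluate_dataset(model, ds, t))
    }
  }
  dplyr::bind_rows(rows)
}
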