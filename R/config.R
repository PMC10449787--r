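#' Pipeline configuration with published defaults
#'
#' Collects every tunable constant of the pipeline in one validated
#' object; each numeric default equals the published value where one
#' exists (e-value ceilings 1e-5/1e-10/1e-5, correlation ceiling 0.95,
#' 70:30 split, five folds, minimum 5 features, prediction threshold
#' 0.80, fragment/contamination/subsample grids). A snapshot of the
#' config is embedded in every artifact the subcommands write.
#'
#' @param seed Integer seed (mandatory; governs every random choice).
#' @param thresholds [search_thresholds()].
#' @param correlation_threshold Pruning ceiling on |Pearson r|.
#' @param split_ratio Training fraction.
#' @param folds Cross-validation folds for feature elimination.
#' @param min_features Feature-elimination floor.
#' @param n_trees Trees in the final forest.
#' @param prediction_threshold Default decision threshold.
#' @param fragment_sizes,contamination,subsample Benchmark grids. Two
#'   subsampling grids appear in the literature (5-75% vs 10-95%); the
#'   default exposes `{0.05, 0.25, 0.50, 0.75}`.
#' @param n_per_class Simulated contigs per class for `simulate`.
#' @return A list of class `av_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            thresholds = search_thresholds(),
                            correlation_threshold = 0.95,
                            split_ratio = 0.7,
                            folds = 5L,
                            min_features = 5L,
                            n_trees = 1000L,
                            prediction_threshold = 0.80,
                            fragment_sizes = c(1000, 2500, 5000, 7500,
                                               10000, Inf),
                            contamination = c(0.10, 0.25, 0.50, 0.75,
                                              0.95),
                            subsample = c(0.05, 0.25, 0.50, 0.75),
                            n_per_class = 400L) {
  cfg <- structure(list(seed = as.integer(seed), thresholds = thresholds,
                        correlation_threshold = correlation_threshold,
                        split_ratio = split_ratio,
                        folds = as.integer(folds),
                        min_features = as.integer(min_features),
                        n_trees = as.integer(n_trees),
                        prediction_threshold = prediction_threshold,
                        fragment_sizes = fragment_sizes,
                        contamination = contamination,
                        subsample = subsample,
                        n_per_class = as.integer(n_per_class)),
                   class = "av_config")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config An `av_config` (or plain list read from a YAML file).
#' @return The validated `av_config`, invisibly; aborts with a
#'   field-level message on any violation.
#' @export
validate_config <- function(config) {
  check <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(paste0("Config field '", field, "': ", msg))
  }
  check(is.numeric(config$seed) && length(config$seed) == 1 &&
          !is.na(config$seed), "seed", "must be a single integer")
  check(config$correlation_threshold > 0 &&
          config$correlation_threshold <= 1, "correlation_threshold",
        "must be in (0, 1]")
  check(config$split_ratio > 0 && config$split_ratio < 1, "split_ratio",
        "must be in (0, 1)")
  check(config$folds >= 2, "folds", "must be >= 2")
  check(config$min_features >= 1, "min_features", "must be >= 1")
  check(config$n_trees >= 1, "n_trees", "must be >= 1")
  check(config$prediction_threshold >= 0 &&
          config$prediction_threshold <= 1, "prediction_threshold",
        "must be in [0, 1]")
  check(all(config$contamination > 0 & config$contamination < 1),
        "contamination", "proportions must be in (0, 1)")
  check(all(config$subsample > 0 & config$subsample <= 1), "subsample",
        "fractions must be in (0, 1]")
  th <- config$thresholds
  check(all(c(th$protein_evalue_max, th$hmm_fullseq_evalue_max,
              th$iterative_evalue_max) > 0), "thresholds",
        "e-value ceilings must be positive")
  invisible(config)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields override the [pipeline_config()] defaults; unknown
#' fields abort.
#'
#' @param path Path to a YAML file.
#' @return A validated `av_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is needed to read config files")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), c(known, "protein_evalue_max",
                                    "hmm_fullseq_evalue_max",
                                    "iterative_evalue_max"))
  if (length(unknown)) {
    abort(paste0("Unknown config field(s) in ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  th_fields <- intersect(names(vals), c("protein_evalue_max",
                                        "hmm_fullseq_evalue_max",
                                        "iterative_evalue_max"))
  th <- do.call(search_thresholds, vals[th_fields])
  args <- vals[intersect(names(vals), known)]
  args$thresholds <- th
  if (!is.null(args$fragment_sizes)) {
    args$fragment_sizes <- as.numeric(ifelse(args$fragment_sizes %in%
                                               c("Inf", ">10kb"),
                                             Inf, args$fragment_sizes))
  }
  do.call(pipeline_config, args)
}

config_snapshot <- function(config, path) {
  flat <- config
  flat$thresholds <- NULL
  flat <- c(flat, unclass(config$thresholds))
  flat$fragment_sizes <- as.character(flat$fragment_sizes)
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(lapply(unclass(flat), unname), path)
  } else {
    writeLines(paste(names(flat),
                     vapply(flat, function(v)
                       paste(v, collapse = ","), ""), sep = ": "), path)
  }
  invisible(path)
}

#' Run one pipeline stage as a subcommand
#'
#' The programmatic core of the command-line interface: executes one
#' pipeline stage with a validated configuration and writes its artifacts
#' (plus a config snapshot) to `out_dir`. Stages: `"simulate"` (write a
#' synthetic labeled dataset), `"features"` (gene-call/hit tables to
#' feature TSV), `"train"` (feature TSV to model archive + RFE trace),
#' `"predict"` (model + feature TSV to prediction TSV), `"benchmark"`
#' (model + dataset directory to the perturbation-grid TSV),
#' `"v1-classify"` (hit TSV to legacy rule calls).
#'
#' @param name Subcommand name.
#' @param config An `av_config`.
#' @param args Named list of stage arguments: `out_dir` always;
#'   `features`: `orfs`, `hits`, `labels` (optional TSV paths);
#'   `train`/`predict`: `features` (TSV), `model`; `predict`: `threshold`
#'   override; `benchmark`: `dataset_dir`, `model`; `v1-classify`: `hits`.
#' @return Invisibly, a character vector of artifact paths.
#' @export
run_subcommand <- function(name, config, args = list()) {
  known <- c("simulate", "features", "train", "predict", "benchmark",
             "v1-classify")
  if (!name %in% known) {
    abort(paste0("Unknown subcommand: ", name, " (expected one of ",
                 paste(known, collapse = ", "), ")"))
  }
  validate_config(config)
  out_dir <- args$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[arcvir] ", ...)
  log_msg("stage=", name, " seed=", config$seed)
  artifacts <- character()
  snap <- file.path(out_dir, "config_snapshot.yaml")
  config_snapshot(config, snap)
  artifacts <- c(artifacts, snap)

  if (name == "simulate") {
    ds <- simulate_dataset(sim_config(n_per_class = config$n_per_class,
                                      seed = config$seed))
    write_dataset(ds, out_dir)
    artifacts <- c(artifacts, file.path(out_dir, c("contigs.fasta",
                                                   "orfs.tsv", "hits.tsv",
                                                   "labels.tsv")))
  } else if (name == "features") {
    orfs <- read_gene_table(args$orfs)
    hits <- read_hit_table(args$hits)
    if (is.null(args$fasta)) {
      abort("features stage needs --fasta (contig sequences)")
    }
    contigs <- read_fasta(args$fasta)
    if (!is.null(args$labels)) {
      lab <- utils::read.table(args$labels, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      contigs$label <- lab$label[match(contigs$contig_id, lab$contig_id)]
    }
    ft <- build_feature_table(contigs, orfs,
                              filter_hits(hits, config$thresholds))
    path <- file.path(out_dir, "features.tsv")
    write_feature_table(ft, path)
    artifacts <- c(artifacts, path)
  } else if (name == "train") {
    ft <- read_feature_table(args$features)
    model <- train_classifier(ft, seed = config$seed,
                              n_trees = config$n_trees,
                              ratio = config$split_ratio,
                              folds = config$folds,
                              min_features = config$min_features,
                              r_max = config$correlation_threshold)
    mp <- args$model %||% file.path(out_dir, "model.rds")
    save_model(model, mp)
    tp <- file.path(out_dir, "rfe_trace.tsv")
    utils::write.table(dplyr::select(model$rfe_trace, -"features"), tp,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, mp, tp)
  } else if (name == "predict") {
    if (is.null(args$model)) abort("predict stage needs a model path")
    model <- load_model(args$model)
    ft <- read_feature_table(args$features)
    thr <- args$threshold %||% config$prediction_threshold
    pred <- predict_contigs(model, ft, threshold = thr)
    path <- file.path(out_dir, "predictions.tsv")
    utils::write.table(pred, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(artifacts, path)
  } else if (name == "benchmark") {
    if (is.null(args$model)) abort("benchmark stage needs a model path")
    model <- load_model(args$model)
    ds <- args$dataset
    pool <- args$pool
    res <- run_benchmark(model, ds, pool = pool,
                         fragment_sizes = config$fragment_sizes,
                         contamination = config$contamination,
                         subsample = config$subsample,
                         thresholds = c(0.5, config$prediction_threshold),
                         seed = config$seed)
    path <- file.path(out_dir, "benchmark.tsv")
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(artifacts, path)
  } else if (name == "v1-classify") {
    hits <- read_hit_table(args$hits)
    res <- classify_rules(annotate_rules(hits))
    path <- file.path(out_dir, "v1_classifications.tsv")
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts <- c(artifacts, path)
  }
  log_msg("wrote ", length(artifacts), " artifact(s) to ", out_dir)
  invisible(artifacts)
}
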