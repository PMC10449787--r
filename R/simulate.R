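#' Configuration for the synthetic contig generator
#'
#' Defines the class-conditional structure of simulated dsDNA viral
#' contigs. Defaults emulate the published training data statistics:
#' archaeal-virus contigs have on average 27% (sd 23%) of ORFs receiving a
#' protein annotation, of which 71% (sd 21%) affiliate with archaea or
#' archaeal viruses, and carry iterative-profile hit counts with mean 18;
#' phage contigs have 70% (sd 33%) of ORFs annotated, of which only 2%
#' (sd 6%) affiliate archaeal, and a near-zero iterative-profile hit rate
#' (0.5). Per-contig fractions are drawn from moment-matched truncated
#' normals on \[0, 1\] so the simulated class means reproduce the quoted
#' statistics.
#'
#' @param n_per_class Contigs per class.
#' @param seed Integer seed.
#' @param archaeal,phage Per-class profiles: lists with `annotated_mean`,
#'   `annotated_sd` (fraction of ORFs with a protein hit),
#'   `archaeal_frac_mean`, `archaeal_frac_sd` (archaeal affiliation among
#'   annotated), `ocav_rate` (Poisson mean of iterative-profile hits),
#'   `pvog_mean`, `pvog_sd` (fraction of ORFs with a profile-HMM hit),
#'   `pvog_archaeal_frac` (probability a profile-HMM hit is to an
#'   archaeal-virus orthologous group rather than a phage one).
#' @param contig_length_range Contig lengths, uniform over this range (bp).
#' @param orf_length_meanlog,orf_length_sdlog Log-normal ORF length
#'   parameters (nt; rounded to codon multiples, floor 90 nt).
#' @param realize_sequence If `FALSE`, contig sequences are left `NA` and
#'   only the per-contig GC value is stored; all feature construction
#'   works either way, and [write_fasta()] requires realized sequences.
#' @return A list of class `av_sim_config`.
#' @export
sim_config <- function(n_per_class = 400L, seed = 1L,
                       archaeal = list(annotated_mean = 0.27,
                                       annotated_sd = 0.23,
                                       archaeal_frac_mean = 0.71,
                                       archaeal_frac_sd = 0.21,
                                       ocav_rate = 18,
                                       pvog_mean = 0.10, pvog_sd = 0.10,
                                       pvog_archaeal_frac = 0.8),
                       phage = list(annotated_mean = 0.70,
                                    annotated_sd = 0.33,
                                    archaeal_frac_mean = 0.02,
                                    archaeal_frac_sd = 0.06,
                                    ocav_rate = 0.5,
                                    pvog_mean = 0.35, pvog_sd = 0.20,
                                    pvog_archaeal_frac = 0.05),
                       contig_length_range = c(10000L, 50000L),
                       orf_length_meanlog = log(750),
                       orf_length_sdlog = 0.45,
                       realize_sequence = TRUE) {
  for (p in list(archaeal, phage)) {
    stopifnot(p$annotated_mean >= 0, p$annotated_mean <= 1,
              p$archaeal_frac_mean >= 0, p$archaeal_frac_mean <= 1,
              p$ocav_rate >= 0, p$pvog_mean >= 0, p$pvog_mean <= 1)
  }
  structure(list(n_per_class = n_per_class, seed = seed,
                 archaeal = archaeal, phage = phage,
                 contig_length_range = contig_length_range,
                 orf_length_meanlog = orf_length_meanlog,
                 orf_length_sdlog = orf_length_sdlog,
                 realize_sequence = realize_sequence),
            class = "av_sim_config")
}

# Mean of a normal(mu, sd) truncated to [0, 1].
truncnorm01_mean <- function(mu, sd) {
  a <- (0 - mu) / sd
  b <- (1 - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Location parameter whose [0,1]-truncated normal has the target mean.
truncnorm01_match <- function(target_mean, sd) {
  if (target_mean <= 0) return(-6 * sd)
  if (target_mean >= 1) return(1 + 6 * sd)
  stats::uniroot(function(mu) truncnorm01_mean(mu, sd) - target_mean,
                 interval = c(-6 * sd, 1 + 6 * sd), tol = 1e-9)$root
}

# Inverse-CDF draws from a normal truncated to [0, 1].
rtruncnorm01 <- function(n, mu, sd) {
  lo <- stats::pnorm(0, mu, sd)
  hi <- stats::pnorm(1, mu, sd)
  stats::qnorm(runif(n, lo, hi), mu, sd)
}

random_sequence <- function(length, gc) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Sequential non-overlapping ORF layout over one contig: exponential
# intergenic gaps, log-normal codon-multiple lengths, sticky strands.
layout_orfs <- function(contig_id, contig_length, meanlog, sdlog,
                        gap_mean = 50, switch_prob = 0.3) {
  starts <- integer()
  ends <- integer()
  pos <- 1L + as.integer(round(stats::rexp(1, 1 / gap_mean)))
  while (TRUE) {
    len <- max(90L, 3L * as.integer(round(stats::rlnorm(1, meanlog,
                                                        sdlog) / 3)))
    if (pos + len - 1L > contig_length) break
    starts <- c(starts, pos)
    ends <- c(ends, pos + len - 1L)
    pos <- pos + len + as.integer(round(stats::rexp(1, 1 / gap_mean)))
  }
  n <- length(starts)
  if (n == 0L) return(empty_orf_table())
  strand <- integer(n)
  strand[1] <- sample(c(1L, -1L), 1L)
  if (n > 1L) {
    flip <- runif(n - 1L) < switch_prob
    for (i in 2:n) strand[i] <- if (flip[i - 1L]) -strand[i - 1L] else
      strand[i - 1L]
  }
  tibble(contig_id = contig_id,
         orf_id = sprintf("%s_orf%03d", contig_id, seq_len(n)),
         start = starts, end = ends, strand = strand,
         partial_left = FALSE, partial_right = FALSE,
         aa_seq = NA_character_)
}

# Planted homology hits for one contig's ORFs under a class profile.
plant_hits <- function(orfs, profile) {
  n <- nrow(orfs)
  hits <- list()
  if (n > 0L) {
    a_frac <- rtruncnorm01(1, truncnorm01_match(profile$annotated_mean,
                                                profile$annotated_sd),
                           profile$annotated_sd)
    n_annot <- round(a_frac * n)
    if (n_annot > 0L) {
      annot <- sample(orfs$orf_id, n_annot)
      f <- rtruncnorm01(1,
                        truncnorm01_match(profile$archaeal_frac_mean,
                                          profile$archaeal_frac_sd),
                        profile$archaeal_frac_sd)
      n_arch <- round(f * n_annot)
      arch_orfs <- if (n_arch > 0L) sample(annot, n_arch) else character()
      cls <- ifelse(annot %in% arch_orfs,
                    sample(ARCHAEAL_CLASSES, n_annot, replace = TRUE,
                           prob = c(0.7, 0.3)),
                    sample(c("phage", "bacteria", "other"), n_annot,
                           replace = TRUE, prob = c(0.8, 0.15, 0.05)))
      hits$protein <- tibble(
        orf_id = annot, contig_id = orfs$contig_id[1],
        target_id = sprintf("nr_%06d", sample.int(999999L, n_annot)),
        evalue = 10^-runif(n_annot, 6, 50),
        bitscore = runif(n_annot, 60, 300),
        target_class = cls, source_db = "protein_nr")
    }
    p_frac <- rtruncnorm01(1, truncnorm01_match(profile$pvog_mean,
                                                profile$pvog_sd),
                           profile$pvog_sd)
    n_pvog <- round(p_frac * n)
    if (n_pvog > 0L) {
      pv <- sample(orfs$orf_id, n_pvog)
      hits$pvog <- tibble(
        orf_id = pv, contig_id = orfs$contig_id[1],
        target_id = sprintf("VOG%05d", sample.int(99999L, n_pvog)),
        evalue = 10^-runif(n_pvog, 11, 60),
        bitscore = runif(n_pvog, 40, 200),
        target_class = sample(c("archaeal_virus", "phage"), n_pvog,
                              replace = TRUE,
                              prob = c(profile$pvog_archaeal_frac,
                                       1 - profile$pvog_archaeal_frac)),
        source_db = "pvog_hmm")
    }
    n_ocav <- rpois(1, profile$ocav_rate)
    if (n_ocav > 0L) {
      hits$ocav <- tibble(
        orf_id = sample(orfs$orf_id, n_ocav, replace = TRUE),
        contig_id = orfs$contig_id[1],
        target_id = sprintf("ocav_%04d", sample.int(9999L, n_ocav)),
        evalue = 10^-runif(n_ocav, 6, 40),
        bitscore = runif(n_ocav, 50, 250),
        target_class = "archaeal_virus", source_db = "ocav_profile")
    }
  }
  if (length(hits) == 0L) empty_hit_table() else dplyr::bind_rows(hits)
}

#' Simulate a labeled two-class contig dataset
#'
#' Generates archaeal-virus and phage contigs with planted non-overlapping
#' ORF layouts and class-conditional homology-hit tables (protein,
#' profile-HMM and iterative-profile layers), all of whose planted hits
#' pass the default [search_thresholds()]. Hit tables are generated
#' directly rather than by running real searches: the unit under test is
#' the pipeline, not the aligner. Regeneration from the same config is
#' bit-identical.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `av_dataset`: `contigs` (tibble `contig_id`,
#'   `sequence`, `length`, `gc`, `label`), `orfs`, `hits`, and the
#'   `config` manifest.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "av_sim_config"))
  set.seed(config$seed)
  n <- config$n_per_class
  labels <- rep(c(av_positive_class, "phage"), each = n)
  ids <- sprintf("%s_%04d", ifelse(labels == av_positive_class, "av", "ph"),
                 c(seq_len(n), seq_len(n)))
  lens <- as.integer(round(runif(2L * n, config$contig_length_range[1],
                                 config$contig_length_range[2])))
  gc <- pmin(0.75, pmax(0.25, rnorm(2L * n, 0.45, 0.05)))
  orfs <- vector("list", 2L * n)
  hits <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    orfs[[i]] <- layout_orfs(ids[i], lens[i], config$orf_length_meanlog,
                             config$orf_length_sdlog)
    profile <- if (labels[i] == av_positive_class) config$archaeal else
      config$phage
    hits[[i]] <- plant_hits(orfs[[i]], profile)
  }
  sequence <- if (config$realize_sequence) {
    vapply(seq_len(2L * n), function(i) random_sequence(lens[i], gc[i]),
           character(1))
  } else rep(NA_character_, 2L * n)
  structure(list(
    contigs = tibble(contig_id = ids, sequence = sequence, length = lens,
                     gc = gc, label = labels),
    orfs = dplyr::bind_rows(orfs),
    hits = dplyr::bind_rows(hits),
    config = config
  ), class = "av_dataset")
}

#' @export
print.av_dataset <- function(x, ...) {
  cat("Synthetic contig dataset:", nrow(x$contigs), "contigs,",
      nrow(x$orfs), "ORFs,", nrow(x$hits), "hits\n")
  print(table(x$contigs$label))
  invisible(x)
}

#' Simulate a microbial contaminant pool
#'
#' Generates cellular genome fragments of 10-200 kb, half tagged archaea
#' and half bacteria, with microbial-like gene layouts, protein hits to
#' their own domain and near-zero viral-database hit rates. Archaeal
#' cellular genomes share sequence with archaeal viruses (proviruses,
#' co-evolved genes), so archaea-domain fragments additionally carry a low
#' rate of iterative-profile hits (`archaea_ocav_rate`, default Poisson
#' mean 2 against the archaeal-virus class mean of 18) — the mechanism by
#' which cellular contamination produces archaeal-virus false positives.
#' All rows are labeled `"non_viral"`.
#'
#' @param n Number of fragments (>= 2).
#' @param seed Integer seed.
#' @param archaea_ocav_rate Poisson mean of iterative-profile hits on
#'   archaea-domain fragments (bacteria-domain fragments carry none).
#' @param realize_sequence See [sim_config()].
#' @return An `av_dataset` whose contig tibble has a `domain` column.
#' @export
simulate_contaminants <- function(n, seed = 1L, archaea_ocav_rate = 2,
                                  realize_sequence = TRUE) {
  stopifnot(n >= 2L)
  set.seed(seed)
  ids <- sprintf("contam_%04d", seq_len(n))
  domain <- rep(c("archaea", "bacteria"), length.out = n)
  lens <- as.integer(round(runif(n, 10000L, 200000L)))
  gc <- pmin(0.75, pmax(0.25, rnorm(n, 0.5, 0.07)))
  orfs <- vector("list", n)
  hits <- vector("list", n)
  for (i in seq_len(n)) {
    orfs[[i]] <- layout_orfs(ids[i], lens[i], log(900), 0.4,
                             gap_mean = 120)
    o <- orfs[[i]]
    if (nrow(o) > 0L) {
      h <- list()
      a_frac <- rtruncnorm01(1, truncnorm01_match(0.3, 0.15), 0.15)
      n_annot <- round(a_frac * nrow(o))
      if (n_annot > 0L) {
        annot <- sample(o$orf_id, n_annot)
        h$protein <- tibble(
          orf_id = annot, contig_id = ids[i],
          target_id = sprintf("nr_%06d", sample.int(999999L, n_annot)),
          evalue = 10^-runif(n_annot, 6, 40),
          bitscore = runif(n_annot, 60, 250),
          target_class = domain[i], source_db = "protein_nr")
      }
      if (domain[i] == "archaea" && archaea_ocav_rate > 0) {
        n_ocav <- rpois(1, archaea_ocav_rate)
        if (n_ocav > 0L) {
          h$ocav <- tibble(
            orf_id = sample(o$orf_id, n_ocav, replace = TRUE),
            contig_id = ids[i],
            target_id = sprintf("ocav_%04d", sample.int(9999L, n_ocav)),
            evalue = 10^-runif(n_ocav, 6, 40),
            bitscore = runif(n_ocav, 50, 250),
            target_class = "archaeal_virus", source_db = "ocav_profile")
        }
      }
      if (length(h)) hits[[i]] <- dplyr::bind_rows(h)
    }
  }
  sequence <- if (realize_sequence) {
    vapply(seq_len(n), function(i) random_sequence(lens[i], gc[i]),
           character(1))
  } else rep(NA_character_, n)
  hits <- dplyr::bind_rows(hits)
  structure(list(
    contigs = tibble(contig_id = ids, sequence = sequence, length = lens,
                     gc = gc, label = "non_viral", domain = domain),
    orfs = dplyr::bind_rows(orfs),
    hits = if (nrow(hits)) hits else empty_hit_table(),
    config = list(n = n, seed = seed)
  ), class = "av_dataset")
}

#' Feature table of a (synthetic or assembled) dataset
#'
#' Applies the e-value filters and builds the 27-column feature table for
#' an `av_dataset` in one step.
#'
#' @param dataset An `av_dataset`.
#' @param thresholds [search_thresholds()] to apply to the hit table.
#' @return A labeled feature tibble (see [build_feature_table()]).
#' @export
dataset_features <- function(dataset, thresholds = search_thresholds()) {
  stopifnot(inherits(dataset, "av_dataset"))
  build_feature_table(dataset$contigs, dataset$orfs,
                      filter_hits(dataset$hits, thresholds))
}

#' Write a dataset's artifacts to a directory
#'
#' Serializes the FASTA (when sequences are realized), the gene-call TSV,
#' the hit TSV and a label TSV, plus a plain-text manifest of the
#' generating configuration.
#'
#' @param dataset An `av_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!anyNA(dataset$contigs$sequence)) {
    write_fasta(dataset$contigs, file.path(dir, "contigs.fasta"))
  }
  write_gene_table(dataset$orfs, file.path(dir, "orfs.tsv"))
  write_hit_table(dataset$hits, file.path(dir, "hits.tsv"))
  utils::write.table(dataset$contigs[, c("contig_id", "label")],
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(utils::capture.output(utils::str(dataset$config)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
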