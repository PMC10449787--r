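# Independent oracles, deliberately implemented differently from the
# package paths they check.

# Brute-force six-frame ORF enumeration: walk from EVERY start codon to
# its in-frame stop (N codons invalidate). Returns all (start, end,
# strand) triples >= min_nt, 1-based inclusive coordinates on the input.
orf_oracle <- function(sequence, min_nt = 90L) {
  walk_strand <- function(s) {
    L <- nchar(s)
    out <- list()
    for (pos in seq_len(max(0L, L - 2L))) {
      codon <- substr(s, pos, pos + 2L)
      if (!codon %in% c("ATG", "GTG", "TTG")) next
      p <- pos + 3L
      while (p + 2L <= L) {
        c2 <- substr(s, p, p + 2L)
        if (grepl("N", c2, fixed = TRUE)) break
        if (c2 %in% c("TAA", "TAG", "TGA")) {
          if (p + 2L - pos + 1L >= min_nt) {
            out[[length(out) + 1L]] <- c(pos, p + 2L)
          }
          break
        }
        p <- p + 3L
      }
    }
    out
  }
  L <- nchar(sequence)
  fwd <- walk_strand(sequence)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sequence)))
  rev <- walk_strand(rc)
  rows <- c(
    lapply(fwd, function(x) data.frame(start = x[1], end = x[2],
                                       strand = 1L)),
    lapply(rev, function(x) data.frame(start = L - x[2] + 1L,
                                       end = L - x[1] + 1L,
                                       strand = -1L))
  )
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = integer()))
  }
  unique(do.call(rbind, rows))
}

# Rank-statistic AUROC: mean over all (positive, negative) pairs of
# 1 / 0.5 / 0 for concordant / tied / discordant scores.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == "archaeal_virus"]
  neg <- scores[labels != "archaeal_virus"]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Legacy-rule oracle: category decision from a per-gene affiliation table
# (columns affiliation, bitscore), written as a direct transcription of
# the published rule set.
rules_oracle <- function(genes) {
  aff <- genes[genes$affiliation != "none", , drop = FALSE]
  if (nrow(aff) == 0L) return("none")
  frac <- sum(aff$affiliation == "archaeal_virus") / nrow(aff)
  best_a <- suppressWarnings(
    max(aff$bitscore[aff$affiliation == "archaeal_virus"]))
  best_p <- suppressWarnings(max(aff$bitscore[aff$affiliation == "phage"]))
  gate <- is.finite(best_a) && best_a > 75 &&
    (best_a > best_p || !is.finite(best_p))
  if (!gate) return("none")
  if (frac > 2 / 3) "1" else if (frac > 1 / 2) "2" else "none"
}

# All-pairs Pearson pruning oracle: which columns does the greedy
# later-column-dropped rule remove?
prune_oracle <- function(mat, r_max = 0.95) {
  p <- ncol(mat)
  dropped <- logical(p)
  for (i in seq_len(p)) {
    if (dropped[i]) next
    for (j in seq_len(p)) {
      if (j <= i || dropped[j]) next
      if (abs(cor(mat[, i], mat[, j])) > r_max) dropped[j] <- TRUE
    }
  }
  colnames(mat)[dropped]
}
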