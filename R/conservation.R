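AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Robinson-Robinson background amino-acid frequencies
#'
#' Overall amino-acid composition of proteins (Robinson & Robinson style
#' frequencies), used as the default background distribution for the
#' conservation scorer. Override by passing any named frequency vector that
#' covers the 20 standard residues and sums to 1.
#'
#' @return Named numeric vector over the 20 standard amino acids, summing
#'   to 1.
#' @export
robinson_frequencies <- function() {
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f / sum(f)
}

#' Read an aligned FASTA file
#'
#' Reads a protein multiple sequence alignment. Gap characters `-` and `.`
#' are both accepted and normalized to `-`; sequences are upper-cased.
#'
#' @param file Path to an aligned FASTA file.
#' @return An object of class `kinase_msa`: a list with `ids` (character) and
#'   `seqs` (character matrix, one row per sequence, one column per alignment
#'   column).
#' @export
read_msa <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  msa_from_strings(as.character(aa), names(aa))
}

msa_from_strings <- function(seqs, ids) {
  if (length(seqs) < 2) stop("an alignment needs at least 2 sequences")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) {
    off <- ids[widths != widths[1]][1]
    stop("ragged alignment: sequence '", off, "' has a different length")
  }
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- ids
  structure(list(ids = ids, seqs = m), class = "kinase_msa")
}

#' Write an alignment to aligned FASTA
#'
#' @param msa A `kinase_msa`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_msa <- function(msa, file) {
  x <- Biostrings::AAStringSet(apply(msa$seqs, 1, paste0, collapse = ""))
  names(x) <- msa$ids
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @export
print.kinase_msa <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences x %d columns\n",
              nrow(x$seqs), ncol(x$seqs)))
  invisible(x)
}

#' Position-based (Henikoff-Henikoff) sequence weights
#'
#' Computes position-based sequence weights: in each column a sequence
#' carrying residue `a` receives `1 / (r * s_a)` where `r` is the number of
#' distinct residues in the column and `s_a` the number of sequences carrying
#' `a`; gaps contribute nothing. Weights are normalized to sum to 1. This
#' down-weights redundant sequences so over-represented subfamilies do not
#' dominate column scores.
#'
#' @param msa A `kinase_msa`.
#' @return Named numeric vector of weights summing to 1, all positive.
#' @export
sequence_weights <- function(msa) {
  m <- msa$seqs
  n <- nrow(m)
  w <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    keep <- col %in% AMINO_ACIDS
    if (!any(keep)) next
    counts <- table(col[keep])
    r <- length(counts)
    w[keep] <- w[keep] + 1 / (r * as.numeric(counts[col[keep]]))
  }
  if (all(w == 0)) w <- rep(1, n)  # fully-gapped alignment: uniform
  # every sequence must keep positive weight even if gapped everywhere
  w[w == 0] <- min(w[w > 0]) * 1e-6
  w <- w / sum(w)
  names(w) <- msa$ids
  w
}

# Weighted residue distribution of one column (gaps and non-standard
# residues excluded); returns NULL for a fully gapped column.
column_distribution <- function(col, weights) {
  keep <- col %in% AMINO_ACIDS
  if (!any(keep)) return(NULL)
  p <- stats::setNames(numeric(length(AMINO_ACIDS)), AMINO_ACIDS)
  for (i in which(keep)) p[col[i]] <- p[col[i]] + weights[i]
  p / sum(p)
}

js_divergence <- function(p, q) {
  m <- (p + q) / 2
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  h(m) - (h(p) + h(q)) / 2
}

#' Per-column conservation scores
#'
#' Scores each alignment column by the Jensen-Shannon divergence (log base 2)
#' between its weighted residue distribution and a background distribution,
#' scaled by the column's weighted non-gap fraction so gappy columns cannot
#' outrank fully occupied columns of the same composition. Fully gapped
#' columns score 0. Higher scores mean stronger conservation relative to
#' background.
#'
#' @param msa A `kinase_msa`.
#' @param weights Sequence weights from [sequence_weights()].
#' @param background Named background frequencies over the 20 amino acids,
#'   summing to 1 (default [robinson_frequencies()]).
#' @return Numeric vector of scores, one per column.
#' @export
column_scores <- function(msa, weights = sequence_weights(msa),
                          background = robinson_frequencies()) {
  miss <- setdiff(AMINO_ACIDS, names(background))
  if (length(miss) > 0) {
    stop("background is missing amino acid(s): ", paste(miss, collapse = ", "))
  }
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  q <- background[AMINO_ACIDS]
  m <- msa$seqs
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    p <- column_distribution(col, weights)
    if (is.null(p)) return(0)
    nongap_w <- sum(weights[col %in% AMINO_ACIDS])
    js_divergence(p, q) * nongap_w
  }, numeric(1))
}

#' Map conservation scores to 1-9 grades
#'
#' Ranks of the scores are split into nine equal-count bins; grade 9 is the
#' top (most conserved) bin and grade 1 the bottom. Tied scores share the
#' grade of their first-occurrence bin (minimum rank), so the mapping is
#' monotone: a higher score never receives a lower grade. When every score is
#' identical all columns collapse to the neutral midpoint grade 5.
#'
#' @param scores Numeric vector of column scores.
#' @return Integer vector of grades in 1..9.
#' @export
grade_scores <- function(scores) {
  n <- length(scores)
  if (n == 0) return(integer(0))
  if (length(unique(scores)) == 1) return(rep(5L, n))
  r <- rank(scores, ties.method = "min")
  as.integer(floor((r - 1) * 9 / n) + 1L)
}

#' Bootstrap low-confidence flags for conservation grades
#'
#' Flags columns whose grade is not trustworthy: a column is flagged when its
#' non-gap count is below `min_nongap` (too few observations), or when the
#' central 95% interval of its grade across bootstrap resamples of the
#' sequences (with replacement; weights and scores recomputed per resample)
#' is wider than `max_ci_width` grade points.
#'
#' @param msa A `kinase_msa`.
#' @param n_bootstrap Number of bootstrap resamples (default 200, minimum 50).
#' @param seed Integer seed; required so flags are reproducible.
#' @param background Background frequencies passed to [column_scores()].
#' @param min_nongap Columns with fewer non-gap residues are flagged
#'   (default 6).
#' @param max_ci_width Maximum tolerated width of the 95% bootstrap grade
#'   interval (default 3).
#' @return Logical vector, one flag per column.
#' @export
flag_confidence <- function(msa, n_bootstrap = 200, seed,
                            background = robinson_frequencies(),
                            min_nongap = 6, max_ci_width = 3) {
  if (missing(seed)) stop("an explicit integer seed is required")
  if (n_bootstrap < 50) stop("n_bootstrap must be at least 50")
  m <- msa$seqs
  n_seq <- nrow(m)
  n_col <- ncol(m)
  nongap <- colSums(matrix(m %in% AMINO_ACIDS, nrow = n_seq))
  boot_grades <- matrix(NA_integer_, nrow = n_bootstrap, ncol = n_col)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(n_seq, n_seq, replace = TRUE)
    bm <- structure(list(ids = paste0("b", seq_len(n_seq)),
                         seqs = m[idx, , drop = FALSE]),
                    class = "kinase_msa")
    rownames(bm$seqs) <- bm$ids
    sc <- column_scores(bm, sequence_weights(bm), background)
    boot_grades[b, ] <- grade_scores(sc)
  }
  width <- apply(boot_grades, 2, function(g) {
    qs <- stats::quantile(g, c(0.025, 0.975), names = FALSE, type = 1)
    qs[2] - qs[1]
  })
  nongap < min_nongap | width > max_ci_width
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Pairwise percent identity to a reference sequence
#'
#' Identity between each sequence and the reference is computed over the
#' columns where *both* sequences are non-gap:
#' `100 * matches / mutually-non-gap positions`.
#'
#' @param msa A `kinase_msa`.
#' @param reference_id Id of the reference sequence (must be in the
#'   alignment).
#' @return `data.frame` with `query_id`, `reference_id`, `identity`
#'   (percent), `n_aligned`.
#' @export
pairwise_identity <- function(msa, reference_id) {
  if (!reference_id %in% msa$ids) {
    stop("reference '", reference_id, "' is not in the alignment")
  }
  ref <- msa$seqs[reference_id, ]
  rows <- lapply(msa$ids, function(id) {
    q <- msa$seqs[id, ]
    both <- ref %in% AMINO_ACIDS & q %in% AMINO_ACIDS
    n <- sum(both)
    data.frame(query_id = id, reference_id = reference_id,
               identity = if (n > 0) 100 * sum(ref[both] == q[both]) / n
                          else NA_real_,
               n_aligned = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map alignment columns onto reference residue numbers
#'
#' The k-th non-gap position of the reference sequence maps to
#' `first_residue_number + k - 1`; columns where the reference is gapped are
#' unmapped (`NA`).
#'
#' @param msa A `kinase_msa`.
#' @param reference_id Id of the reference sequence.
#' @param first_residue_number Author residue number of the reference's first
#'   non-gap residue.
#' @return Integer vector (one entry per column) of author residue numbers,
#'   `NA` where the reference is gapped.
#' @export
map_to_reference <- function(msa, reference_id, first_residue_number) {
  if (!reference_id %in% msa$ids) {
    stop("reference '", reference_id, "' is not in the alignment")
  }
  ref <- msa$seqs[reference_id, ]
  nongap <- ref != "-"
  out <- rep(NA_integer_, length(ref))
  out[nongap] <- first_residue_number + seq_len(sum(nongap)) - 1L
  out
}

#' Full conservation profile of an alignment
#'
#' Runs the scorer end to end: Henikoff weights, Jensen-Shannon column
#' scores, 1-9 grades, bootstrap confidence flags, and the mapping onto the
#' reference sequence's author numbering.
#'
#' @param msa A `kinase_msa`.
#' @param reference_id Reference sequence id used for residue numbering.
#' @param first_residue_number Author number of the reference's first non-gap
#'   residue.
#' @param seed Integer seed for the bootstrap confidence flags.
#' @param n_bootstrap Bootstrap replicate count (default 200).
#' @param background Background frequencies (default
#'   [robinson_frequencies()]).
#' @param msa_id Label stored with the profile.
#' @return `data.frame` of class `conservation_profile` with columns
#'   `column` (0-based), `residue_number`, `score`, `grade`, `n_nongap`,
#'   `low_confidence`; attributes `msa_id`, `reference_id`, `method_tag`
#'   (`"jsd-henikoff-v1"`).
#' @export
conservation_profile <- function(msa, reference_id, first_residue_number,
                                 seed, n_bootstrap = 200,
                                 background = robinson_frequencies(),
                                 msa_id = "msa") {
  w <- sequence_weights(msa)
  scores <- column_scores(msa, w, background)
  grades <- grade_scores(scores)
  flags <- flag_confidence(msa, n_bootstrap = n_bootstrap, seed = seed,
                           background = background)
  resno <- map_to_reference(msa, reference_id, first_residue_number)
  nongap <- apply(msa$seqs, 2, function(col) sum(col %in% AMINO_ACIDS))
  prof <- data.frame(column = seq_along(scores) - 1L,
                     residue_number = resno, score = scores, grade = grades,
                     n_nongap = as.integer(nongap), low_confidence = flags)
  attr(prof, "msa_id") <- msa_id
  attr(prof, "reference_id") <- reference_id
  attr(prof, "method_tag") <- "jsd-henikoff-v1"
  class(prof) <- c("conservation_profile", "data.frame")
  prof
}

#' Write a conservation profile as TSV
#'
#' @param profile A `conservation_profile`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile <- function(profile, file) {
  utils::write.table(as.data.frame(profile), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
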