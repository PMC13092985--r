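#' Global alignment and pairwise-identity cohort comparison
#'
#' A small Needleman-Wunsch global aligner with a linear gap penalty
#' (defaults +1 match / -1 mismatch / -2 per gap column) backs the
#' sequence-conservation comparisons and the center-star multiple
#' alignment used in reassignment validation.  Percent identity counts
#' matched columns over the full alignment length, gapped (including
#' terminal-gap) columns in the denominator.  Absolute identity values are
#' aligner-dialect dependent; cohort comparisons are the supported output.
#'
#' @name alignment
NULL

#' Needleman-Wunsch global alignment
#'
#' @param a,b Non-empty sequences (character strings; nucleotide or
#'   protein - comparisons are exact after uppercasing).
#' @param match,mismatch,gap Scoring parameters (linear gap).
#' @return List of class `alignment_result`: `aligned_a`, `aligned_b`
#'   (gapped strings of equal length), `score`, `identity_pct`.
#' @examples
#' nw_align("ACGU", "ACGA")$identity_pct  # 75
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  score <- matrix(0, n + 1, m + 1)
  score[1, ] <- gap * (0:m)
  score[, 1] <- gap * (0:n)
  for (i in seq_len(n)) {
    sub <- ifelse(bv == av[i], match, mismatch)
    prev <- score[i, ]
    cur <- numeric(m + 1)
    cur[1] <- gap * i
    for (j in seq_len(m)) {
      cur[j + 1] <- max(prev[j] + sub[j], prev[j + 1] + gap, cur[j] + gap)
    }
    score[i + 1, ] <- cur
  }
  # traceback; at score ties gap moves are taken before the diagonal so
  # that length differences consolidate as terminal gaps (an insertion at
  # the end aligns as a C-terminal overhang, not interleaved gaps)
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && score[i + 1, j + 1] == score[i, j + 1] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1
    } else if (j > 0 && score[i + 1, j + 1] == score[i + 1, j] + gap) {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1
    } else {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1; j <- j - 1
    }
  }
  aligned_a <- paste(ra, collapse = "")
  aligned_b <- paste(rb, collapse = "")
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score[n + 1, m + 1],
                 identity_pct = alignment_identity(aligned_a, aligned_b)),
            class = "alignment_result")
}

#' Percent identity of two gapped rows
#'
#' @param x,y Gapped strings of equal length.
#' @return `100 * matches / alignment_length`; gap columns count in the
#'   denominator but never as matches.
#' @export
alignment_identity <- function(x, y) {
  xv <- strsplit(toupper(x), "")[[1]]
  yv <- strsplit(toupper(y), "")[[1]]
  stopifnot(length(xv) == length(yv))
  100 * sum(xv == yv & xv != "-") / length(xv)
}

#' Within-cohort pairwise identities
#'
#' @param seqs Character vector of >= 2 sequences.
#' @param ... Scoring parameters passed to [nw_align()].
#' @return Numeric vector of all `choose(n, 2)` pairwise identity
#'   percentages.
#' @export
pairwise_identities <- function(seqs, ...) {
  stopifnot(length(seqs) >= 2)
  cmb <- utils::combn(length(seqs), 2)
  apply(cmb, 2, function(ix)
    nw_align(seqs[ix[1]], seqs[ix[2]], ...)$identity_pct)
}

#' Compare sequence conservation between two cohorts
#'
#' Computes all within-cohort pairwise identities for each set (e.g. the
#' 4-bp-stem and 5-bp-stem tRNA-Trp(CCA) gene cohorts), then compares the
#' two identity distributions with a Student t-test and Cohen's d.
#'
#' @param set4,set5 Character vectors of >= 2 sequences each.
#' @param ... Scoring parameters passed to [nw_align()].
#' @return List with `median4`, `median5`, `identities4`, `identities5`,
#'   `t_test` (a `test_result`), `d` (Cohen's d).
#' @export
identity_cohorts <- function(set4, set5, ...) {
  if (length(set4) < 2 || length(set5) < 2)
    stop("each cohort needs >= 2 sequences", call. = FALSE)
  id4 <- pairwise_identities(set4, ...)
  id5 <- pairwise_identities(set5, ...)
  tt <- student_t(id4, id5)
  list(median4 = stats::median(id4), median5 = stats::median(id5),
       identities4 = id4, identities5 = id5,
       t_test = tt, d = tt$effect_size)
}
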